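#' Fold a sequence by base-pair maximisation
#'
#' Predicts a pseudoknot-free secondary structure maximising the number of
#' canonical (A:U, G:C) plus G:U base pairs, with a minimum hairpin loop of
#' `min_loop` unpaired bases (Nussinov recursion with traceback; DNA and
#' RNA input are equivalent, T = U). This is a combinatorial, not a
#' thermodynamic, folding: it is the structure model used throughout the
#' precursor evaluation.
#'
#' @param seq Sequence (single string, A/C/G/T/U).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @return A list of class `rna_fold`: `partner` (1-based pairing partner
#'   per position, 0 = unpaired), `dotbracket`, `n_pairs`.
#' @export
fold_hairpin <- function(seq, min_loop = 3) {
  if (!grepl("^[ACGTUacgtu]*$", seq)) {
    stop("sequence must be A/C/G/T/U only", call. = FALSE)
  }
  partner <- .nussinov_fold(toupper(seq), as.integer(min_loop))
  db <- rep(".", length(partner))
  db[partner > seq_along(partner)] <- "("
  db[partner > 0 & partner < seq_along(partner)] <- ")"
  structure(list(partner = partner,
                 dotbracket = paste(db, collapse = ""),
                 n_pairs = sum(partner > 0) / 2),
            class = "rna_fold")
}

#' @export
print.rna_fold <- function(x, ...) {
  cat("Base-pair-maximisation fold: ", x$n_pairs, " pairs\n",
      x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Evaluate a precursor candidate's hairpin structure
#'
#' Folds the precursor by base-pair maximisation and applies the plant
#' pre-miRNA criteria (all thresholds configurable, defaults conventional):
#' the mature span must lie entirely within one arm of a stem (no pairing
#' with itself, all partners on one side — a mature spanning the terminal
#' loop fails), at least `min_mature_paired` mature positions must be
#' paired, at most `max_mature_unpaired` may be unpaired (the surrogate for
#' mature/star mismatches), and the mature span may contain at most
#' `max_internal_loops` internal unpaired runs.
#'
#' @param precursor Precursor sequence (5'->3' on the hit strand).
#' @param mature_start,mature_end 1-based closed mature span within the
#'   precursor.
#' @param min_mature_paired Minimum paired mature positions (default 14).
#' @param max_mature_unpaired Maximum unpaired mature positions (default 6).
#' @param max_internal_loops Maximum unpaired runs strictly inside the
#'   mature span (default 1).
#' @param min_loop Minimum hairpin loop passed to [fold_hairpin()].
#' @return One-row tibble of class `hairpin_eval`: pairing statistics, the
#'   dot-bracket string and `passes_criteria`. The full fold is attached as
#'   attribute `fold`.
#' @export
hairpin_eval <- function(precursor, mature_start, mature_end,
                         min_mature_paired = 14, max_mature_unpaired = 6,
                         max_internal_loops = 1, min_loop = 3) {
  n <- nchar(precursor)
  stopifnot(mature_start >= 1, mature_end <= n, mature_start <= mature_end)
  fold <- fold_hairpin(precursor, min_loop = min_loop)
  span <- mature_start:mature_end
  p <- fold$partner[span]
  paired <- sum(p > 0)
  unpaired <- sum(p == 0)
  # one-arm test: no mature position may pair inside the mature span, and
  # all partners must sit on the same side of it
  self_paired <- any(p %in% span)
  sides <- unique(sign(p[p > 0] - mature_start))
  one_arm <- !self_paired && length(unique(p[p > 0] > mature_end)) <= 1
  runs <- rle(fold$partner[span] == 0)
  internal_unpaired_runs <- {
    # loops are unpaired runs of >= 2 nt strictly inside the span;
    # single-base mismatch bulges and runs touching the span ends (arm
    # offsets) do not count
    idx <- which(runs$values & runs$lengths >= 2)
    idx <- idx[idx != 1 & idx != length(runs$values)]
    length(idx)
  }
  mature_arm_fraction <- paired / length(span)
  passes <- one_arm &&
    paired >= min_mature_paired &&
    unpaired <= max_mature_unpaired &&
    internal_unpaired_runs <= max_internal_loops
  out <- tibble(
    length = n, n_pairs = fold$n_pairs,
    mature_paired = paired, mature_unpaired = unpaired,
    mature_arm_fraction = mature_arm_fraction,
    one_arm = one_arm, internal_loops = internal_unpaired_runs,
    dotbracket = fold$dotbracket, passes_criteria = passes
  )
  class(out) <- c("hairpin_eval", class(out))
  attr(out, "fold") <- fold
  out
}
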