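#' Build a position-specific scoring matrix from domain instances
#'
#' Constructs a log-odds PSSM (base 2, uniform background, additive
#' pseudocounts) from equal-length ungapped instances of a domain. The
#' returned model carries a score threshold used by [scan_domain()] to
#' decide family membership; calibrate it on known positives and negatives
#' (the default is the fraction `threshold_frac` of the consensus
#' self-score, which separates planted instances from random sequence
#' comfortably at domain lengths of ~70 aa).
#'
#' @param instances Character vector of equal-length domain sequences.
#' @param pseudocount Additive pseudocount per amino acid.
#' @param threshold Explicit score threshold; overrides `threshold_frac`.
#' @param threshold_frac Fraction of the maximal (consensus) score used as
#'   threshold when `threshold` is not given.
#' @return A list of class `domain_pssm`: `matrix` (20 x L log-odds),
#'   `length`, `threshold`, `consensus`.
#' @export
build_pssm <- function(instances, pseudocount = 1, threshold = NULL,
                       threshold_frac = 0.5) {
  L <- unique(nchar(instances))
  if (length(L) != 1) stop("instances must share one length", call. = FALSE)
  chars <- do.call(rbind, strsplit(instances, ""))
  bad <- setdiff(unique(as.vector(chars)), AMINO_ACIDS)
  if (length(bad) > 0) {
    stop("non-standard residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(instances)
  bg <- 1 / length(AMINO_ACIDS)
  mat <- vapply(seq_len(L), function(j) {
    cnt <- table(factor(chars[, j], levels = AMINO_ACIDS))
    freq <- (as.numeric(cnt) + pseudocount * bg) / (n + pseudocount)
    log2(freq / bg)
  }, numeric(length(AMINO_ACIDS)))
  rownames(mat) <- AMINO_ACIDS
  if (!all(is.finite(mat))) stop("non-finite PSSM scores", call. = FALSE)
  consensus <- paste(AMINO_ACIDS[apply(mat, 2, which.max)], collapse = "")
  max_score <- sum(apply(mat, 2, max))
  structure(
    list(matrix = mat, length = L,
         threshold = if (is.null(threshold)) threshold_frac * max_score
                     else threshold,
         consensus = consensus),
    class = "domain_pssm"
  )
}

#' Scan a protein for the best-scoring domain window
#'
#' Slides the PSSM over the protein (ungapped) and reports the maximal
#' window. `hit` is `TRUE` iff the best score reaches the model threshold;
#' family membership in the identification pipeline is decided by this flag
#' alone. Proteins shorter than the model cannot hit.
#'
#' @param proteins Named character vector of proteins.
#' @param model A `domain_pssm` from [build_pssm()].
#' @return Tibble with `protein_id`, `score`, `start`, `end`, `hit`.
#' @export
scan_domain <- function(proteins, model) {
  stopifnot(inherits(model, "domain_pssm"))
  L <- model$length
  purrr::imap(proteins, function(p, id) {
    n <- nchar(p)
    if (n < L) {
      return(tibble(protein_id = id, score = NA_real_,
                    start = NA_integer_, end = NA_integer_, hit = FALSE))
    }
    idx <- match(strsplit(p, "")[[1]], AMINO_ACIDS)
    if (anyNA(idx)) {
      stop("non-standard residue in protein ", id, call. = FALSE)
    }
    offs <- seq_len(n - L + 1)
    scores <- vapply(offs, function(o) {
      sum(model$matrix[cbind(idx[o:(o + L - 1)], seq_len(L))])
    }, numeric(1))
    best <- which.max(scores)
    tibble(protein_id = id, score = scores[best],
           start = as.integer(best), end = as.integer(best + L - 1),
           hit = scores[best] >= model$threshold)
  }) |>
    dplyr::bind_rows()
}
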