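#' Optimal global protein alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (affine gap penalties) via
#' [Biostrings::pairwiseAlignment()]. Defaults are the conventional
#' protein-search settings: BLOSUM62, gap open 11, gap extend 1.
#'
#' @param a,b Protein sequences (single strings, non-empty).
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings, or a numeric matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A list of class `sbp_alignment` with elements `aligned_a`,
#'   `aligned_b` (gapped strings) and `score`.
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("global_align requires non-empty sequences", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  structure(
    list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
         aligned_b = as.character(Biostrings::alignedSubject(aln)),
         score = Biostrings::score(aln)),
    class = "sbp_alignment"
  )
}

#' @export
print.sbp_alignment <- function(x, ...) {
  cat("Global alignment (score ", format(x$score), ")\n", sep = "")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

count_gap_opens <- function(aligned) {
  lengths(regmatches(aligned, gregexpr("-+", aligned)))
}

# Documented E-value surrogate: E = n_query * n_subject * 2^(-score),
# floored to stay representable. Monotone in the alignment score; only
# threshold-style use (e.g. <= 1e-10) is supported, absolute calibration
# is not claimed.
evalue_surrogate <- function(score, nq, ns) {
  pmax(exp(log(as.numeric(nq)) + log(as.numeric(ns)) - score * log(2)),
       1e-300)
}

#' All-vs-all internal homology search
#'
#' Fallback homology caller for modest protein sets when no external search
#' output is supplied: scores every unordered pair by local affine-gap
#' alignment (BLOSUM62, open 11, extend 1) and emits the standard 12-column
#' homology dialect consumed by [read_homology_table()]. The E-value
#' surrogate is `n_query * n_subject * 2^(-score)`.
#'
#' Intended for family-scale sets (hundreds of proteins); genome-scale
#' all-vs-all searches should be run with a dedicated search engine and
#' loaded with [read_homology_table()].
#'
#' @param proteins Named character vector of protein sequences (>= 2).
#' @param score_threshold Minimum local alignment score to report a pair.
#' @return Homology tibble (one row per unordered pair above threshold,
#'   `self_hit` always `FALSE`).
#' @export
internal_homology_search <- function(proteins, score_threshold = 60) {
  if (length(proteins) < 2) {
    stop("internal_homology_search needs at least 2 proteins", call. = FALSE)
  }
  if (is.null(names(proteins))) stop("proteins must be named", call. = FALSE)
  ids <- names(proteins)
  set <- Biostrings::AAStringSet(proteins)
  rows <- vector("list", length(proteins))
  for (j in seq_along(proteins)[-1]) {
    pats <- set[seq_len(j - 1)]
    aln <- Biostrings::pairwiseAlignment(
      pattern = pats, subject = set[[j]], type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
    )
    tab <- alignment_stats(aln, ids[seq_len(j - 1)], ids[j],
                           nchar(proteins[seq_len(j - 1)]),
                           nchar(proteins[j]))
    rows[[j]] <- tab[tab$bitscore >= score_threshold, ]
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty_homology_table())
  dplyr::mutate(out, self_hit = FALSE)
}

# Vectorised 12-column stats for a PairwiseAlignments object; avoids the
# costly per-element aligned-string extraction.
alignment_stats <- function(aln, qids, sid, q_len, s_len) {
  sc <- Biostrings::score(aln)
  ind <- Biostrings::nindel(aln)
  ins <- Biostrings::insertion(ind)
  del <- Biostrings::deletion(ind)
  nmat <- unname(Biostrings::nmatch(aln))
  nmis <- unname(Biostrings::nmismatch(aln))
  aln_len <- nmat + nmis + unname(ins[, "WidthSum"]) +
    unname(del[, "WidthSum"])
  tibble(
    qseqid = qids, sseqid = sid,
    pident = 100 * nmat / aln_len,
    length = as.integer(aln_len),
    mismatch = as.integer(nmis),
    gapopen = as.integer(unname(ins[, "Length"]) +
                           unname(del[, "Length"])),
    qstart = Biostrings::start(Biostrings::pattern(aln)),
    qend = Biostrings::end(Biostrings::pattern(aln)),
    sstart = Biostrings::start(Biostrings::subject(aln)),
    send = Biostrings::end(Biostrings::subject(aln)),
    evalue = evalue_surrogate(sc, q_len, s_len),
    bitscore = sc
  )
}

#' Assign a family-group label by best reference alignment
#'
#' Labels each query with the group of its best-scoring global alignment
#' against a labelled reference set. Exact score ties between two different
#' labels are surfaced as `ambiguous = TRUE` with `group = NA`, never broken
#' silently, because group identity feeds every downstream census.
#'
#' @param queries Named character vector of query proteins.
#' @param references Named character vector of reference proteins.
#' @param ref_groups Character vector of group labels, parallel to
#'   `references`.
#' @return Tibble with `query_id`, `group`, `score`, `ambiguous`.
#' @export
assign_group <- function(queries, references, ref_groups) {
  if (length(references) == 0) stop("empty reference set", call. = FALSE)
  stopifnot(length(references) == length(ref_groups))
  purrr::imap(queries, function(q, qid) {
    scores <- vapply(references, function(r) global_align(q, r)$score,
                     numeric(1))
    best <- max(scores)
    labs <- unique(ref_groups[scores == best])
    tibble(query_id = qid,
           group = if (length(labs) == 1) labs else NA_character_,
           score = best,
           ambiguous = length(labs) > 1)
  }) |>
    dplyr::bind_rows()
}
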