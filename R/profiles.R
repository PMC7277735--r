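#' Extract upstream regulatory regions
#'
#' Collects the region from `far` nt down to `near` nt upstream of the
#' transcription initiation site (taken as the gene-feature 5' end):
#' `[TSS - far, TSS - near]` on the plus strand and the strand-reflected
#' equivalent on the minus strand, truncated at chromosome ends, sequence
#' reported 5'->3' on the gene strand. The region never overlaps the gene
#' body; a gene with nothing upstream yields an empty, flagged region.
#'
#' @param annotation Gene table.
#' @param genome Named character vector of chromosome sequences.
#' @param near,far Window bounds in nt upstream of the TSS (defaults 100
#'   and 2000, i.e. the -2000..-100 window; maximum length 1901 nt).
#' @param gene_ids Genes to process (default: all family genes, falling
#'   back to all genes when no family labels are present).
#' @return Tibble with `gene_id`, `chromosome`, `start`, `end`, `strand`,
#'   `sequence`, `truncated`, `empty`.
#' @export
extract_upstream <- function(annotation, genome, near = 100, far = 2000,
                             gene_ids = NULL) {
  stopifnot(near <= far)
  if (is.null(gene_ids)) {
    gene_ids <- if (any(annotation$family)) {
      annotation$gene_id[annotation$family]
    } else annotation$gene_id
  }
  chrlen <- stats::setNames(nchar(genome), names(genome))
  rows <- purrr::map(gene_ids, function(id) {
    g <- annotation[annotation$gene_id == id, ]
    if (nrow(g) != 1) stop("unknown gene id: ", id, call. = FALSE)
    if (g$strand == "+") {
      s <- g$start - far; e <- g$start - near
      s_t <- max(1L, s); e_t <- min(e, g$start - 1L)
    } else {
      s <- g$end + near; e <- g$end + far
      e_t <- min(chrlen[[g$chromosome]], e); s_t <- max(s, g$end + 1L)
    }
    empty <- e_t < s_t
    seq <- if (empty) "" else {
      x <- substring(genome[[g$chromosome]], s_t, e_t)
      if (g$strand == "-") revcomp(x) else x
    }
    tibble(gene_id = id, chromosome = g$chromosome,
           start = if (empty) NA_integer_ else as.integer(s_t),
           end = if (empty) NA_integer_ else as.integer(e_t),
           strand = g$strand, sequence = seq,
           truncated = !empty && (s_t != s || e_t != e), empty = empty)
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$truncated | out$empty)) {
    log_filter("upstream extraction", length(gene_ids),
               sum(!out$empty), "regions truncated at sequence ends")
  }
  out
}

#' Hypergeometric over-representation test
#'
#' Exact hypergeometric upper-tail test of each annotation term in the
#' selected gene set against the universe, with Benjamini-Hochberg
#' adjustment across the tested terms. Terms annotating fewer than
#' `min_support` genes (in the universe) are dropped before testing - the
#' generic form of support filtering applied before enrichment.
#'
#' @param selected Character vector of selected genes (subset of
#'   `universe`).
#' @param annotation_map Named list: term -> character vector of genes.
#' @param universe Character vector of all genes.
#' @param min_support Minimum genes a term must annotate to be tested.
#' @return Tibble with `term`, `overlap`, `selected_size`, `annotated`,
#'   `universe_size`, `p_value`, `p_adjust`, sorted by `p_value`.
#' @export
enrich_terms <- function(selected, annotation_map, universe,
                         min_support = 1) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!all(selected %in% universe)) {
    stop("selected genes must be a subset of the universe", call. = FALSE)
  }
  selected <- unique(selected)
  universe <- unique(universe)
  ann <- purrr::map(annotation_map, ~ intersect(unique(.x), universe))
  n_in <- length(ann)
  ann <- ann[lengths(ann) >= min_support]
  if (n_in != length(ann)) {
    log_filter("enrichment terms", n_in, length(ann),
               sprintf("term support >= %d", min_support))
  }
  if (length(ann) == 0) {
    return(tibble(term = character(), overlap = integer(),
                  selected_size = integer(), annotated = integer(),
                  universe_size = integer(), p_value = double(),
                  p_adjust = double()))
  }
  res <- purrr::imap(ann, function(genes, term) {
    k <- length(intersect(genes, selected))
    tibble(term = term, overlap = k, selected_size = length(selected),
           annotated = length(genes), universe_size = length(universe),
           p_value = stats::phyper(k - 1, length(genes),
                                   length(universe) - length(genes),
                                   length(selected), lower.tail = FALSE))
  }) |> dplyr::bind_rows()
  res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
  dplyr::arrange(res, .data$p_value)
}

#' Count stress-responsive experiments per gene
#'
#' For every gene and stress condition, counts the treatment experiments
#' in which expression changed by at least two-fold in either direction:
#' treatment/control ratio `>= 2` or `<= 0.5` (both boundaries inclusive).
#' A zero control with non-zero treatment counts as responsive; zero/zero
#' does not.
#'
#' @param expr Expression matrix (genes x samples) or tibble with a
#'   `gene_id` column.
#' @param design Tibble with one row per experiment: `condition`,
#'   `control` (control column name), `treatment` (treatment column name).
#' @return Tibble with `gene_id`, `condition`, `n_experiments`,
#'   `n_responsive`.
#' @export
stress_response_count <- function(expr, design) {
  if (inherits(expr, "data.frame")) {
    stopifnot("gene_id" %in% colnames(expr))
    genes <- expr$gene_id
    mat <- as.matrix(expr[, setdiff(colnames(expr), "gene_id")])
    rownames(mat) <- genes
  } else {
    mat <- as.matrix(expr)
  }
  missing <- setdiff(unique(c(design$control, design$treatment)),
                     colnames(mat))
  if (length(missing) > 0) {
    stop("design names absent column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  purrr::map(unique(design$condition), function(cond) {
    d <- design[design$condition == cond, ]
    flags <- vapply(seq_len(nrow(d)), function(i) {
      ctrl <- mat[, d$control[i]]
      trt <- mat[, d$treatment[i]]
      (ctrl > 0 & (trt / ctrl >= 2 | trt / ctrl <= 0.5)) |
        (ctrl == 0 & trt > 0)
    }, logical(nrow(mat)))
    responsive <- rowSums(matrix(flags, nrow = nrow(mat)))
    tibble(gene_id = rownames(mat), condition = cond,
           n_experiments = nrow(d),
           n_responsive = as.integer(responsive))
  }) |> dplyr::bind_rows()
}

#' Log-transform an expression matrix
#'
#' `log2(x + 1)` elementwise, the transform used before visualising
#' tissue-expression profiles. Negative values are rejected.
#'
#' @param expr Numeric matrix or tibble with a `gene_id` column.
#' @return Same shape as the input, transformed.
#' @export
log_matrix <- function(expr) {
  if (inherits(expr, "data.frame")) {
    num <- setdiff(colnames(expr), "gene_id")
    vals <- as.matrix(expr[, num])
    if (any(vals < 0)) stop("negative expression values", call. = FALSE)
    expr[, num] <- log2(vals + 1)
    return(expr)
  }
  if (any(expr < 0)) stop("negative expression values", call. = FALSE)
  log2(expr + 1)
}
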