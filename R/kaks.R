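# NG86 Ka/Ks estimation: per-codon synonymous-site fractions, equal-weight
# averaging over all minimal mutational pathways (stop-crossing paths
# dropped, weights renormalised), Jukes-Cantor correction. Authored here;
# the test suite checks it against an independently written path enumerator.

.ng86_cache <- new.env(parent = emptyenv())

# Synonymous sites of one codon: at each position, the fraction of the three
# single-nucleotide changes that are synonymous. Changes to stop codons
# count as nonsynonymous (denominator stays 3).
codon_syn_sites <- function(codon) {
  key <- paste0("S_", codon)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  aa <- GENETIC_CODE_DNA[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (GENETIC_CODE_DNA[[alt]] == aa) s <- s + 1 / 3
    }
  }
  .ng86_cache[[key]] <- s
  s
}

perms_of <- function(k) {
  switch(k,
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
}

# Sd/Nd contribution of one codon pair: enumerate all orders of the
# differing positions, walk each path one substitution at a time, classify
# each step as synonymous or nonsynonymous, drop paths that pass through a
# stop codon and renormalise. If every path crosses a stop (possible for
# some 2- and 3-difference pairs), all paths are used as a documented
# fallback so the pair still contributes.
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0(c1, c2)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- perms_of(length(pos))
  walk <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0; stopped <- FALSE
    for (p in pos[order]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GENETIC_CODE_DNA[[nxt]] == "*") stopped <- TRUE
      if (GENETIC_CODE_DNA[[nxt]] == GENETIC_CODE_DNA[[cur]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd, nd, stopped)
  }
  res <- vapply(paths, walk, numeric(3))
  ok <- res[3, ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  out <- c(sd = mean(res[1, ok]), nd = mean(res[2, ok]))
  .ng86_cache[[key]] <- out
  out
}

#' Thread a protein alignment back onto codons
#'
#' Expands each column of a gapped protein alignment into the corresponding
#' codon column of the two coding sequences, producing the ungapped
#' codon-pair list that [ng86()] consumes. The coding sequences must
#' translate exactly to the ungapped proteins of the alignment (terminal
#' stop codons are trimmed first).
#'
#' @param cds_a,cds_b Coding sequences (length divisible by 3).
#' @param alignment An `sbp_alignment` from [global_align()] of the two
#'   translated proteins, or a list with `aligned_a`/`aligned_b`.
#' @return A list of class `codon_alignment`: `columns` (tibble with gapped
#'   `codon_a`, `codon_b`) and `pairs` (tibble of ungapped, stop-free codon
#'   pairs).
#' @export
codon_align <- function(cds_a, cds_b, alignment) {
  trim_stop <- function(cds) {
    last <- substr(cds, nchar(cds) - 2, nchar(cds))
    if (nchar(cds) >= 3 && GENETIC_CODE_DNA[[last]] == "*") {
      substr(cds, 1, nchar(cds) - 3)
    } else cds
  }
  cds_a <- trim_stop(toupper(cds_a)); cds_b <- trim_stop(toupper(cds_b))
  pa <- strsplit(alignment$aligned_a, "")[[1]]
  pb <- strsplit(alignment$aligned_b, "")[[1]]
  check <- function(cds, prot_aln, label) {
    prot <- paste(prot_aln[prot_aln != "-"], collapse = "")
    tr <- translate_cds(cds)
    if (tr != prot) {
      bad <- which(strsplit(tr, "")[[1]] !=
                     strsplit(prot, "")[[1]])[1]
      stop("CDS ", label, " does not translate to the aligned protein ",
           "(first mismatch at residue ", bad, ")", call. = FALSE)
    }
  }
  check(cds_a, pa, "A"); check(cds_b, pb, "B")
  cod_a <- split_codons(cds_a); cod_b <- split_codons(cds_b)
  col_a <- character(length(pa)); col_b <- character(length(pb))
  ia <- 0; ib <- 0
  for (k in seq_along(pa)) {
    if (pa[k] == "-") col_a[k] <- "---" else {
      ia <- ia + 1; col_a[k] <- cod_a[ia]
    }
    if (pb[k] == "-") col_b[k] <- "---" else {
      ib <- ib + 1; col_b[k] <- cod_b[ib]
    }
  }
  ungapped <- col_a != "---" & col_b != "---"
  pairs <- tibble(codon_a = col_a[ungapped], codon_b = col_b[ungapped])
  pairs <- dplyr::filter(pairs, GENETIC_CODE_DNA[.data$codon_a] != "*",
                         GENETIC_CODE_DNA[.data$codon_b] != "*")
  structure(list(columns = tibble(codon_a = col_a, codon_b = col_b),
                 pairs = pairs),
            class = "codon_alignment")
}

#' NG86 Ka/Ks estimate for a codon alignment
#'
#' Nei-Gojobori (1986) estimator: synonymous/nonsynonymous site counts `S`
#' and `N` are per-codon synonymous-site fractions summed and averaged over
#' the two sequences; difference counts `Sd`/`Nd` average all minimal
#' mutational pathways per codon pair with equal weights (stop-crossing
#' paths excluded); the proportions `ps = Sd/S` and `pn = Nd/N` are
#' Jukes-Cantor corrected. Proportions at or beyond the correction limit
#' (3/4) raise a saturation error. `ratio` is `NA` when `Ks = 0`.
#'
#' @param alignment A `codon_alignment` from [codon_align()], or a tibble
#'   with columns `codon_a`, `codon_b`.
#' @return One-row tibble of class `ng86_result`: `ka`, `ks`, `ratio`, `S`,
#'   `N`, `Sd`, `Nd`, `n_codons`.
#' @export
ng86 <- function(alignment) {
  pairs <- if (inherits(alignment, "codon_alignment")) alignment$pairs
           else as_tibble(alignment)
  if (nrow(pairs) < 1) {
    stop("ng86 requires at least one ungapped codon pair", call. = FALSE)
  }
  s_a <- sum(vapply(pairs$codon_a, codon_syn_sites, numeric(1)))
  s_b <- sum(vapply(pairs$codon_b, codon_syn_sites, numeric(1)))
  S <- (s_a + s_b) / 2
  N <- 3 * nrow(pairs) - S
  d <- purrr::map2(pairs$codon_a, pairs$codon_b, codon_pair_diffs)
  Sd <- sum(vapply(d, `[[`, numeric(1), "sd"))
  Nd <- sum(vapply(d, `[[`, numeric(1), "nd"))
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  if (ps >= 3 / 4 || pn >= 3 / 4) {
    stop("NG86 saturation: observed proportion at or beyond the ",
         "Jukes-Cantor limit (ps = ", signif(ps, 3), ", pn = ",
         signif(pn, 3), ")", call. = FALSE)
  }
  jc <- function(p) -3 / 4 * log(1 - 4 / 3 * p)
  ks <- jc(ps); ka <- jc(pn)
  out <- tibble(ka = ka, ks = ks,
                ratio = if (ks > 0) ka / ks else NA_real_,
                S = S, N = N, Sd = Sd, Nd = Nd, n_codons = nrow(pairs))
  class(out) <- c("ng86_result", class(out))
  out
}

#' Ka/Ks for a table of gene pairs
#'
#' Convenience batch driver: for each (`id_a`, `id_b`) row, translates the
#' two CDSs, aligns the proteins globally, threads the codons and runs
#' [ng86()]. Saturated pairs are returned with `NA` estimates and the error
#' message in `note` rather than aborting the batch.
#'
#' @param pairs Tibble with columns `id_a`, `id_b`.
#' @param cds Named character vector of coding sequences.
#' @return `pairs` with `ka`, `ks`, `ratio`, `S`, `N`, `Sd`, `Nd`, `note`
#'   columns appended.
#' @export
kaks_pairs <- function(pairs, cds) {
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(cds))
  if (length(missing) > 0) {
    stop("no CDS for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  res <- purrr::map2(pairs$id_a, pairs$id_b, function(a, b) {
    out <- tryCatch({
      aln <- global_align(translate_cds(cds[[a]]), translate_cds(cds[[b]]))
      r <- ng86(codon_align(cds[[a]], cds[[b]], aln))
      dplyr::mutate(as_tibble(r), note = NA_character_)
    }, error = function(e) {
      tibble(ka = NA_real_, ks = NA_real_, ratio = NA_real_, S = NA_real_,
             N = NA_real_, Sd = NA_real_, Nd = NA_real_,
             n_codons = NA_integer_, note = conditionMessage(e))
    })
    out
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(res))
}
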