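#' Protein length, molecular weight and isoelectric point
#'
#' Physicochemical characterisation of family proteins: chain length,
#' molecular weight from average residue masses plus one water, and the
#' isoelectric point found by bisection on the Henderson-Hasselbalch net
#' charge with a Bjellqvist-style pKa set (N/C termini plus D, E, C, Y, H,
#' K, R side chains). Only the 20 standard amino acids are accepted.
#'
#' @param proteins Named character vector of protein sequences.
#' @param tol Bisection tolerance on pH (default `1e-4`).
#' @return Tibble with `protein_id`, `length`, `molecular_weight`,
#'   `isoelectric_point`.
#' @export
protein_properties <- function(proteins, tol = 1e-4) {
  purrr::imap(proteins, function(p, id) {
    if (!nzchar(p)) stop("empty protein: ", id, call. = FALSE)
    aa <- strsplit(p, "")[[1]]
    bad <- setdiff(unique(aa), names(RESIDUE_MASS_AVG))
    if (length(bad) > 0) {
      stop("non-standard residue(s) in ", id, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    mw <- sum(RESIDUE_MASS_AVG[aa]) + WATER_MASS_AVG
    tibble(protein_id = id, length = length(aa), molecular_weight = mw,
           isoelectric_point = isoelectric_point(aa, tol))
  }) |>
    dplyr::bind_rows()
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch net charge used by [protein_properties()]; exposed
#' so the root can be checked directly.
#'
#' @param protein Protein sequence (string).
#' @param ph pH value(s).
#' @return Numeric net charge, vectorised over `ph`.
#' @export
net_charge <- function(protein, ph) {
  aa <- strsplit(protein, "")[[1]]
  vapply(ph, function(x) charge_at(aa, x), numeric(1))
}

charge_at <- function(aa, ph) {
  pos_res <- c("K", "R", "H")
  neg_res <- c("D", "E", "C", "Y")
  pos_counts <- c(1, vapply(pos_res, function(r) sum(aa == r), numeric(1)))
  pos_pka <- c(PKA_SET$n_term, PKA_SET$side[pos_res])
  neg_counts <- c(1, vapply(neg_res, function(r) sum(aa == r), numeric(1)))
  neg_pka <- c(PKA_SET$c_term, PKA_SET$side[neg_res])
  sum(pos_counts / (1 + 10^(ph - pos_pka))) -
    sum(neg_counts / (1 + 10^(neg_pka - ph)))
}

isoelectric_point <- function(aa, tol = 1e-4) {
  lo <- 0; hi <- 14
  f_lo <- charge_at(aa, lo)
  if (f_lo < 0) return(lo)  # degenerate: negative even at pH 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (charge_at(aa, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
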