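# broom-style tidiers for the package's result objects.

#' Tidy a synteny census
#'
#' @param x A `synteny_census` object.
#' @param ... Unused.
#' @return Long tibble of group-by-group pair counts.
#' @export
tidy.synteny_census <- function(x, ...) {
  tidyr::pivot_longer(x$matrix, -"group", names_to = "partner",
                      values_to = "n")
}

#' @rdname tidy.synteny_census
#' @return For `glance()`: a one-row summary with intra/inter totals and
#'   the number of genes involved.
#' @export
glance.synteny_census <- function(x, ...) {
  dplyr::mutate(x$totals, n_genes = nrow(x$incidence))
}

#' Tidy an NG86 result
#'
#' @param x An `ng86_result`.
#' @param ... Unused.
#' @return Long tibble of estimator components.
#' @export
tidy.ng86_result <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(unclass(x)), dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' @rdname tidy.ng86_result
#' @export
glance.ng86_result <- function(x, ...) {
  as_tibble(unclass(x))[, c("ka", "ks", "ratio", "n_codons")]
}

#' Tidy a hairpin evaluation
#'
#' @param x A `hairpin_eval` result.
#' @param ... Unused.
#' @return Per-position tibble: position, base pairing partner, whether
#'   the position is paired.
#' @export
tidy.hairpin_eval <- function(x, ...) {
  fold <- attr(x, "fold")
  tibble(position = seq_along(fold$partner), partner = fold$partner,
         paired = fold$partner > 0)
}

#' @rdname tidy.hairpin_eval
#' @export
glance.hairpin_eval <- function(x, ...) {
  as_tibble(unclass(x))[, c("length", "n_pairs", "mature_paired",
                            "mature_unpaired", "one_arm",
                            "passes_criteria")]
}

#' Tidy a synthetic simulation
#'
#' @param x An `sbp_simulation`.
#' @param ... Unused.
#' @return The truth ledger as one long tibble of planted events.
#' @export
tidy.sbp_simulation <- function(x, ...) {
  dplyr::bind_rows(
    if (nrow(x$truth$tandem)) {
      dplyr::transmute(x$truth$tandem, type = "tandem",
                       id = .data$copy_id, chromosome = .data$chromosome)
    },
    if (nrow(x$truth$segmental)) {
      dplyr::transmute(x$truth$segmental, type = "segmental",
                       id = paste0("block", .data$event),
                       chromosome = .data$chromosome_dst)
    },
    if (nrow(x$truth$mirna)) {
      dplyr::transmute(x$truth$mirna, type = "mirna",
                       id = paste0("locus", .data$locus),
                       chromosome = .data$chromosome)
    },
    if (nrow(x$truth$face_to_face)) {
      dplyr::transmute(x$truth$face_to_face, type = "face_to_face",
                       id = .data$id_plus, chromosome = .data$chromosome)
    }
  )
}

#' @rdname tidy.sbp_simulation
#' @export
glance.sbp_simulation <- function(x, ...) {
  tibble(
    n_chromosomes = length(x$genome),
    n_genes = nrow(x$annotation),
    n_family = sum(x$annotation$family),
    n_tandem = nrow(x$truth$tandem),
    n_segmental = nrow(x$truth$segmental),
    n_mirna = nrow(x$truth$mirna),
    n_face_to_face = nrow(x$truth$face_to_face)
  )
}
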