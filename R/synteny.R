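#' Build the micro-fragment around an anchor gene
#'
#' The unit of synteny comparison: the ordered window of up to `k` coding
#' genes upstream and `k` downstream of the anchor on its chromosome
#' (truncated at chromosome ends), so at most `2k + 1` genes.
#'
#' @param annotation Gene table (see [read_gff3()]).
#' @param anchor Anchor gene id.
#' @param k Genes per side (default 30).
#' @return Tibble with `anchor`, `gene_id`, `chromosome`, `offset`
#'   (signed rank distance from the anchor).
#' @export
micro_fragment <- function(annotation, anchor, k = 30) {
  row <- annotation[annotation$gene_id == anchor, ]
  if (nrow(row) != 1) stop("unknown anchor gene: ", anchor, call. = FALSE)
  chr <- annotation[annotation$chromosome == row$chromosome, ]
  chr <- dplyr::arrange(chr, .data$rank)
  i <- which(chr$gene_id == anchor)
  lo <- max(1, i - k); hi <- min(nrow(chr), i + k)
  tibble(anchor = anchor,
         gene_id = chr$gene_id[lo:hi],
         chromosome = row$chromosome,
         offset = (lo:hi) - i)
}

# Greedy one-to-one maximum matching of homologous gene pairs between two
# gene sets, by descending bit score. Each gene participates in at most one
# supporting pair; self pairs (same gene id on both sides) never count.
match_fragment_genes <- function(genes_a, genes_b, homology,
                                 family_only = NULL) {
  hits <- homology[homology$qseqid %in% genes_a &
                     homology$sseqid %in% genes_b &
                     homology$qseqid != homology$sseqid, ]
  if (!is.null(family_only)) {
    hits <- hits[hits$qseqid %in% family_only &
                   hits$sseqid %in% family_only, ]
  }
  if (nrow(hits) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  bitscore = double()))
  }
  hits <- dplyr::arrange(hits, dplyr::desc(.data$bitscore))
  used <- character(0)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    qa <- hits$qseqid[i]; sb <- hits$sseqid[i]
    if (!(qa %in% used) && !(sb %in% used)) {
      keep[i] <- TRUE
      used <- c(used, qa, sb)
    }
  }
  tibble(gene_a = hits$qseqid[keep], gene_b = hits$sseqid[keep],
         bitscore = hits$bitscore[keep])
}

#' Detect synteny between two micro-fragments
#'
#' Two micro-fragments are syntenic when they share at least `min_pairs`
#' distinct homologous gene pairs (greedy one-to-one matching by descending
#' score, each gene used at most once). Within one species this evidences
#' segmental duplication; between species, shared ancestry. Collinear order
#' is not required, only co-occurrence. Self-comparison (identical anchors)
#' never yields a pair; overlapping same-chromosome fragments are allowed
#' when the anchors differ.
#'
#' @param annotation Gene table.
#' @param homology Homology table (already E-value filtered).
#' @param anchor_a,anchor_b Anchor gene ids.
#' @param min_pairs Minimum supporting homolog pairs (default 10).
#' @param k Fragment half-width (default 30).
#' @param strict_family If `TRUE`, only pairs of focal-family genes count
#'   as support.
#' @return One-row tibble (`anchor_a`, `anchor_b`, `n_support`,
#'   `same_chromosome`, `support` list-column) or `NULL` when below
#'   threshold.
#' @export
detect_synteny <- function(annotation, homology, anchor_a, anchor_b,
                           min_pairs = 10, k = 30, strict_family = FALSE) {
  detect_synteny_core(annotation, symmetrize_homology(homology),
                      anchor_a, anchor_b, min_pairs, k, strict_family)
}

# Core with a pre-symmetrised homology table (hot path for the batch
# callers, which symmetrise once).
detect_synteny_core <- function(annotation, hom, anchor_a, anchor_b,
                                min_pairs = 10, k = 30,
                                strict_family = FALSE) {
  if (anchor_a == anchor_b) return(NULL)
  frag_a <- micro_fragment(annotation, anchor_a, k)
  frag_b <- micro_fragment(annotation, anchor_b, k)
  fam <- if (strict_family) {
    annotation$gene_id[annotation$family]
  } else NULL
  m <- match_fragment_genes(frag_a$gene_id, frag_b$gene_id, hom, fam)
  if (nrow(m) < min_pairs) return(NULL)
  tibble(anchor_a = anchor_a, anchor_b = anchor_b, n_support = nrow(m),
         same_chromosome = frag_a$chromosome[1] == frag_b$chromosome[1],
         support = list(m))
}

#' Classify a homologous gene pair as tandem or not
#'
#' Tandem duplication: the two paralogs sit on the same chromosome and are
#' adjacent, or are separated by exactly one gene that is homologous to
#' neither of them.
#'
#' @param annotation Gene table.
#' @param homology Homology table.
#' @param gene_a,gene_b Gene ids.
#' @return `TRUE` (tandem) or `FALSE`.
#' @export
classify_tandem <- function(annotation, homology, gene_a, gene_b) {
  classify_tandem_core(annotation, symmetrize_homology(homology),
                       gene_a, gene_b)
}

classify_tandem_core <- function(annotation, hom, gene_a, gene_b) {
  ra <- annotation[annotation$gene_id == gene_a, ]
  rb <- annotation[annotation$gene_id == gene_b, ]
  if (nrow(ra) != 1 || nrow(rb) != 1) {
    stop("unknown gene id", call. = FALSE)
  }
  if (ra$chromosome != rb$chromosome) return(FALSE)
  sep <- abs(ra$rank - rb$rank)
  if (sep == 1) return(TRUE)
  if (sep != 2) return(FALSE)
  between_rank <- (ra$rank + rb$rank) / 2
  mid <- annotation[annotation$chromosome == ra$chromosome &
                      annotation$rank == between_rank, ]
  mid_hom <- any(hom$qseqid == mid$gene_id &
                   hom$sseqid %in% c(gene_a, gene_b))
  !mid_hom
}

#' Call and classify duplication events among family genes
#'
#' Classifies every homologous pair of focal-family genes (within one
#' species): tandem first (tandem takes precedence when a pair satisfies
#' both definitions), else segmental when the two genes' micro-fragments
#' are syntenic at `min_pairs` support, else `unclassified` (reported but
#' excluded from event counts downstream).
#'
#' @param annotation Gene table.
#' @param homology Homology table.
#' @param min_pairs Synteny support threshold (default 10).
#' @param k Fragment half-width (default 30).
#' @return Tibble with `id_a`, `id_b`, `group_a`, `group_b`, `class`
#'   (`"tandem"`, `"segmental"`, `"unclassified"`), `n_support`,
#'   `intra_group`.
#' @export
call_duplications <- function(annotation, homology, min_pairs = 10,
                              k = 30) {
  fam <- annotation[annotation$family, ]
  hom <- symmetrize_homology(homology)
  pairs <- hom[hom$qseqid %in% fam$gene_id &
                 hom$sseqid %in% fam$gene_id &
                 hom$qseqid < hom$sseqid, c("qseqid", "sseqid")]
  pairs <- dplyr::distinct(pairs)
  # restrict to within-species pairs: duplication is a same-genome relation
  sp <- stats::setNames(annotation$species, annotation$gene_id)
  pairs <- pairs[sp[pairs$qseqid] == sp[pairs$sseqid], ]
  if (nrow(pairs) == 0) {
    return(tibble(id_a = character(), id_b = character(),
                  group_a = character(), group_b = character(),
                  class = character(), n_support = integer(),
                  intra_group = logical()))
  }
  grp <- stats::setNames(annotation$group, annotation$gene_id)
  res <- purrr::map2(pairs$qseqid, pairs$sseqid, function(a, b) {
    cls <- "unclassified"
    n_support <- NA_integer_
    if (classify_tandem_core(annotation, hom, a, b)) {
      cls <- "tandem"
    } else {
      syn <- detect_synteny_core(annotation, hom, a, b,
                                 min_pairs = min_pairs, k = k)
      if (!is.null(syn)) {
        cls <- "segmental"
        n_support <- syn$n_support
      }
    }
    tibble(id_a = a, id_b = b, group_a = unname(grp[a]),
           group_b = unname(grp[b]), class = cls, n_support = n_support,
           intra_group = identical(grp[[a]], grp[[b]]))
  })
  dplyr::bind_rows(res)
}

#' Group-level synteny census
#'
#' Aggregates synteny/duplication pairs into the group-by-group count
#' matrix, intra- versus inter-group totals, per-group inter-group
#' percentage shares (each group's shares sum to 100), and the gene-level
#' incidence table in which each synteny is counted once for each of the
#' two genes making it up.
#'
#' @param pairs Tibble with `id_a`, `id_b`, `group_a`, `group_b`.
#' @return List of class `synteny_census`: `totals`, `matrix` (symmetric
#'   count matrix as a tibble), `inter_shares`, `incidence`.
#' @export
synteny_census <- function(pairs) {
  pairs <- dplyr::filter(pairs, !is.na(.data$group_a),
                         !is.na(.data$group_b))
  groups <- sort(unique(c(pairs$group_a, pairs$group_b)))
  intra <- sum(pairs$group_a == pairs$group_b)
  inter <- sum(pairs$group_a != pairs$group_b)
  mat <- matrix(0L, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$group_a[i]; gb <- pairs$group_b[i]
    mat[ga, gb] <- mat[ga, gb] + 1L
    if (ga != gb) mat[gb, ga] <- mat[gb, ga] + 1L
  }
  inter_shares <- purrr::map(groups, function(g) {
    cnt <- stats::setNames(as.integer(mat[g, , drop = FALSE]), groups)
    cnt[g] <- 0L
    tot <- sum(cnt)
    if (tot == 0) return(NULL)
    tibble(group = g, partner = groups[cnt > 0],
           n = unname(cnt[cnt > 0]),
           share = unname(100 * cnt[cnt > 0] / tot))
  }) |> dplyr::bind_rows()
  incidence <- tibble(gene_id = c(pairs$id_a, pairs$id_b)) |>
    dplyr::count(.data$gene_id, name = "n_syntenies")
  structure(
    list(totals = tibble(intra_group = intra, inter_group = inter),
         matrix = as_tibble(mat, rownames = "group"),
         inter_shares = inter_shares,
         incidence = incidence),
    class = "synteny_census"
  )
}

#' @export
print.synteny_census <- function(x, ...) {
  cat("Synteny census: ", x$totals$intra_group, " intra-group, ",
      x$totals$inter_group, " inter-group pairs; ",
      nrow(x$incidence), " genes involved\n", sep = "")
  invisible(x)
}

#' Aggregate one-to-many Ks values
#'
#' A gene in synteny with several partners contributes one averaged Ks per
#' partner species: values sharing a partner species are averaged, values
#' from different species are kept separate (never averaged across
#' species).
#'
#' @param ks_table Tibble with `gene_id`, `partner_species`, `ks`.
#' @return Tibble with `gene_id`, `partner_species`, `ks` (one row per
#'   gene-species combination) and `n_partners`.
#' @export
aggregate_ks <- function(ks_table) {
  stopifnot(all(is.finite(ks_table$ks)))
  ks_table |>
    dplyr::group_by(.data$gene_id, .data$partner_species) |>
    dplyr::summarise(ks = mean(.data$ks), n_partners = dplyr::n(),
                     .groups = "drop")
}

#' Bin Ks values into WGD-era categories
#'
#' Fractions of events per category (e.g. intra- vs inter-group) falling
#' into the Ks bins delimited by `edges` (defaults 1.2 and 2.0, the edges
#' that separate recent duplications from the older gamma/tau-era ones).
#' Fractions within a non-empty category sum to 1; an empty category is
#' reported with `NA` fractions (undefined, not 0).
#'
#' @param ks Numeric Ks values.
#' @param category Parallel category labels.
#' @param edges Increasing bin edges (default `c(1.2, 2)`).
#' @return Tibble with `category`, `bin`, `n`, `fraction`.
#' @export
ks_binning <- function(ks, category, edges = c(1.2, 2)) {
  stopifnot(length(ks) == length(category), !is.unsorted(edges))
  labs <- c(paste0("<", edges[1]),
            if (length(edges) > 1) {
              paste0("[", edges[-length(edges)], ",", edges[-1], ")")
            },
            paste0(">=", edges[length(edges)]))
  cats <- if (is.factor(category)) levels(category)
          else sort(unique(as.character(category)))
  df <- tibble(category = as.character(category), ks = ks) |>
    dplyr::filter(is.finite(.data$ks)) |>
    dplyr::mutate(bin = cut(.data$ks, breaks = c(-Inf, edges, Inf),
                            labels = labs, right = FALSE))
  tidyr::expand_grid(category = cats, bin = factor(labs, levels = labs)) |>
    dplyr::left_join(dplyr::count(df, .data$category, .data$bin),
                     by = c("category", "bin")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n)
                  else NA_real_) |>
    dplyr::ungroup()
}
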