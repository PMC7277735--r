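# miR156 locus prediction and co-evolution analyses: homology scan for
# mature sequences, precursor extraction, coding-gene filtering, target
# scoring, co-location with SBP micro-fragments, miR156-SBP synteny and
# face-to-face origin detection.

mature_variants <- function(mature, min_len) {
  mature <- rna_to_dna(mature)
  L <- nchar(mature)
  if (L < min_len) return(character(0))
  vars <- mature
  if (L > min_len) {
    for (l in seq(min_len, L - 1)) {
      vars <- c(vars, substr(mature, 1, l), substr(mature, L - l + 1, L))
    }
  }
  unique(vars)
}

#' Scan a genome for mature miRNA homologs
#'
#' Exhaustive ungapped Hamming scan of every chromosome, both strands, for
#' each reference mature sequence and each of its prefixes/suffixes of at
#' least `min_len` nt. Windows at Hamming distance `<= max_mismatch` are
#' reported (the "> 18 nt, fewer than three mismatches" collection rule at
#' the defaults); overlapping hits of the same mature on the same strand
#' are merged to the best one (fewest mismatches, then longest, then
#' leftmost). Coordinates are always on the plus strand, 1-based closed.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param matures Named character vector of mature miRNA sequences
#'   (RNA or DNA).
#' @param min_len Minimum matched length (default 19).
#' @param max_mismatch Maximum Hamming distance (default 2).
#' @return Tibble with `mature_id`, `chromosome`, `start`, `end`, `strand`,
#'   `matched_len`, `mismatches`.
#' @export
mature_scan <- function(genome, matures, min_len = 19, max_mismatch = 2) {
  stopifnot(!is.null(names(genome)), !is.null(names(matures)))
  rows <- list()
  for (mid in names(matures)) {
    vars <- mature_variants(matures[[mid]], min_len)
    for (chr in names(genome)) {
      subj <- Biostrings::DNAString(genome[[chr]])
      for (v in vars) {
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") v else revcomp(v)
          m <- Biostrings::matchPattern(pat, subj,
                                        max.mismatch = max_mismatch,
                                        with.indels = FALSE)
          if (length(m) == 0) next
          mm <- lengths(Biostrings::mismatch(Biostrings::DNAString(pat), m))
          rows[[length(rows) + 1]] <- tibble(
            mature_id = mid, chromosome = chr,
            start = Biostrings::start(m), end = Biostrings::end(m),
            strand = strand, matched_len = nchar(v), mismatches = mm
          )
        }
      }
    }
  }
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) == 0) {
    return(tibble(mature_id = character(), chromosome = character(),
                  start = integer(), end = integer(), strand = character(),
                  matched_len = integer(), mismatches = integer()))
  }
  merge_overlapping_hits(hits)
}

# Best-hit merging: within (mature, chromosome, strand), overlapping
# intervals collapse to the single best hit.
merge_overlapping_hits <- function(hits) {
  hits |>
    dplyr::group_by(.data$mature_id, .data$chromosome, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(.data$start >
                                     dplyr::lag(cummax(.data$end),
                                                default = -1L))) |>
    dplyr::group_by(.data$cluster, .add = TRUE) |>
    dplyr::arrange(.data$mismatches, dplyr::desc(.data$matched_len),
                   .data$start, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"cluster") |>
    dplyr::arrange(.data$chromosome, .data$start)
}

#' Extract precursor candidates around mature hits
#'
#' Attaches `flank` nt of genomic context upstream and downstream of each
#' hit (truncated at sequence ends: when less than `flank` nt is available
#' the entire available sequence is used). The precursor sequence is
#' reported 5'->3' on the hit strand, with the mature offset within it.
#'
#' @param hits Hit table from [mature_scan()].
#' @param genome Named character vector of chromosome sequences.
#' @param flank Flank length in nt (default 200).
#' @return `hits` with `prec_start`, `prec_end`, `precursor`,
#'   `mature_offset`, `mature_end_offset` columns appended.
#' @export
extract_precursor <- function(hits, genome, flank = 200) {
  chrlen <- stats::setNames(nchar(genome), names(genome))
  hits |>
    dplyr::mutate(
      prec_start = pmax(1L, .data$start - as.integer(flank)),
      prec_end = pmin(unname(chrlen[.data$chromosome]),
                      .data$end + as.integer(flank)),
      precursor = {
        s <- substring(genome[.data$chromosome], .data$prec_start,
                       .data$prec_end)
        ifelse(.data$strand == "-", revcomp(s), s)
      },
      mature_offset = ifelse(.data$strand == "+",
                             .data$start - .data$prec_start + 1L,
                             .data$prec_end - .data$end + 1L),
      mature_end_offset = .data$mature_offset + (.data$end - .data$start)
    )
}

#' Remove candidates overlapping protein-coding genes
#'
#' Drops every candidate whose mature-hit interval overlaps any annotated
#' gene by at least 1 nt (either strand); removals are logged.
#'
#' @param hits Hit table from [mature_scan()].
#' @param annotation Gene table.
#' @return Filtered hit table.
#' @export
coding_filter <- function(hits, annotation) {
  overlaps <- vapply(seq_len(nrow(hits)), function(i) {
    g <- annotation[annotation$chromosome == hits$chromosome[i], ]
    any(g$start <= hits$end[i] & g$end >= hits$start[i])
  }, logical(1))
  out <- hits[!overlaps, ]
  log_filter("coding filter", nrow(hits), nrow(out),
             "mature hit overlaps a gene by >= 1 nt")
  out
}

#' Score miRNA target sites on a transcript
#'
#' Ungapped complementarity scan in the psRNATarget style: each window of
#' the transcript is scored against the mature (antiparallel), summing
#' per-position penalties of 1.0 for a mismatch and 0.5 for a G:U wobble,
#' doubled at mature positions 2-13 (the seed-proximal region). Windows
#' with expectation `<= max_expectation` are reported, best first. Gapped
#' duplexes are not searched; the declared gap penalty (2.0) is exposed for
#' completeness.
#'
#' @param mature Mature miRNA sequence (RNA or DNA), 5'->3'.
#' @param transcript Transcript sequence (RNA or DNA), 5'->3'.
#' @param max_expectation Maximum reported expectation (default 5.0).
#' @param seed_from,seed_to Mature positions with doubled penalties
#'   (defaults 2 and 13).
#' @return Tibble with `start`, `end` (transcript coordinates),
#'   `expectation` and a `penalties` list-column (per mature position).
#' @export
target_scan <- function(mature, transcript, max_expectation = 5,
                        seed_from = 2, seed_to = 13) {
  m <- strsplit(dna_to_rna(mature), "")[[1]]
  t_rna <- strsplit(dna_to_rna(transcript), "")[[1]]
  L <- length(m); n <- length(t_rna)
  if (n < L) stop("transcript shorter than mature", call. = FALSE)
  base_pen <- function(mi, tj) {
    comp <- (mi == "A" & tj == "U") | (mi == "U" & tj == "A") |
      (mi == "G" & tj == "C") | (mi == "C" & tj == "G")
    wobble <- (mi == "G" & tj == "U") | (mi == "U" & tj == "G")
    ifelse(comp, 0, ifelse(wobble, 0.5, 1))
  }
  n_win <- n - L + 1
  pen <- matrix(0, nrow = n_win, ncol = L)
  for (i in seq_len(L)) {
    # mature position i pairs with window position L - i + 1 (antiparallel)
    tj <- t_rna[(seq_len(n_win) - 1) + (L - i + 1)]
    p <- base_pen(m[i], tj)
    if (i >= seed_from && i <= seed_to) p <- 2 * p
    pen[, i] <- p
  }
  expectation <- rowSums(pen)
  keep <- which(expectation <= max_expectation)
  keep <- keep[order(expectation[keep])]
  tibble(start = keep, end = keep + L - 1L,
         expectation = expectation[keep],
         penalties = purrr::map(keep, function(k) pen[k, ]))
}

GAP_PENALTY <- 2.0

#' Co-location of miRNA hits with SBP micro-fragments
#'
#' A miR156 hit is co-located with an SBP gene when the hit interval falls
#' within the genomic span (first gene start to last gene end) of that
#' gene's micro-fragment.
#'
#' @param hits Hit table from [mature_scan()] (a `hit_id` column is added
#'   from row order if absent).
#' @param annotation Gene table.
#' @param anchors Anchor gene ids (default: all family genes).
#' @param k Fragment half-width (default 30).
#' @return Tibble with `hit_id`, `anchor`, `chromosome`.
#' @export
co_location <- function(hits, annotation, anchors = NULL, k = 30) {
  if (is.null(anchors)) anchors <- annotation$gene_id[annotation$family]
  hits <- ensure_hit_id(hits)
  spans <- purrr::map(anchors, function(a) {
    frag <- micro_fragment(annotation, a, k)
    g <- annotation[match(frag$gene_id, annotation$gene_id), ]
    tibble(anchor = a, chromosome = frag$chromosome[1],
           span_start = min(g$start), span_end = max(g$end))
  }) |> dplyr::bind_rows()
  dplyr::inner_join(hits, spans, by = "chromosome",
                    relationship = "many-to-many") |>
    dplyr::filter(.data$start >= .data$span_start,
                  .data$end <= .data$span_end) |>
    dplyr::select("hit_id", "anchor", "chromosome")
}

ensure_hit_id <- function(hits) {
  if (!"hit_id" %in% colnames(hits)) {
    hits$hit_id <- sprintf("hit%03d", seq_len(nrow(hits)))
  }
  hits
}

# Micro-fragment around a genomic position rather than an anchor gene: the
# nearest k genes on each side (genes overlapping the position included).
position_fragment <- function(annotation, chromosome, start, end, k = 30) {
  chr <- annotation[annotation$chromosome == chromosome, ]
  chr <- dplyr::arrange(chr, .data$rank)
  up <- which(chr$end < start)
  down <- which(chr$start > end)
  over <- which(chr$start <= end & chr$end >= start)
  idx <- c(utils::tail(up, k), over, utils::head(down, k))
  chr$gene_id[sort(unique(idx))]
}

#' miR156-SBP synteny pairs (co-locations excluded)
#'
#' Compares the micro-fragment around each miR156 hit (nearest `k` genes on
#' each side of the hit) with the micro-fragment of every family (SBP)
#' gene using the same `>= min_pairs` homolog-pair rule as
#' [detect_synteny()]. Pairs where the miR156 hit co-locates with the SBP
#' fragment (hit inside the fragment span) are excluded first.
#'
#' @param hits Hit table from [mature_scan()].
#' @param annotation Gene table.
#' @param homology Homology table.
#' @param min_pairs Support threshold (default 10).
#' @param k Fragment half-width (default 30).
#' @return Tibble with `hit_id`, `anchor` (SBP gene), `n_support`.
#' @export
mir_sbp_synteny <- function(hits, annotation, homology, min_pairs = 10,
                            k = 30) {
  hits <- ensure_hit_id(hits)
  anchors <- annotation$gene_id[annotation$family]
  hom <- symmetrize_homology(homology)
  coloc <- co_location(hits, annotation, anchors, k)
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    frag_m <- position_fragment(annotation, hits$chromosome[i],
                                hits$start[i], hits$end[i], k)
    if (length(frag_m) == 0) next
    for (a in anchors) {
      if (any(coloc$hit_id == hits$hit_id[i] & coloc$anchor == a)) next
      frag_s <- micro_fragment(annotation, a, k)$gene_id
      m <- match_fragment_genes(frag_m, frag_s, hom)
      if (nrow(m) >= min_pairs) {
        rows[[length(rows) + 1]] <- tibble(hit_id = hits$hit_id[i],
                                           anchor = a,
                                           n_support = nrow(m))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(hit_id = character(), anchor = character(),
                  n_support = integer())
  }
  out
}

#' Scan for convergent (face-to-face) gene pairs between two groups
#'
#' Finds pairs of genes, one from each group, on the same chromosome and
#' opposite strands with their 3' ends facing each other (the plus-strand
#' gene entirely upstream of the minus-strand gene) across an intergenic
#' gap strictly below `max_gap` nt (gap = downstream start - upstream end
#' - 1). The intergenic region is attached as the candidate hairpin input
#' of the miR156 origin model.
#'
#' @param annotation Gene table.
#' @param group_a,group_b Group labels (defaults `"g1"` and `"g6"`, the
#'   groups whose convergent arrangement the origin model proposes).
#' @param max_gap Strict upper bound on the intergenic gap (default 8000).
#' @return Tibble with `id_plus`, `id_minus`, `group_plus`, `group_minus`,
#'   `chromosome`, `gap`, `hairpin_start`, `hairpin_end`.
#' @export
face_to_face_scan <- function(annotation, group_a = "g1", group_b = "g6",
                              max_gap = 8000) {
  ga <- annotation[!is.na(annotation$group) & annotation$group == group_a, ]
  gb <- annotation[!is.na(annotation$group) & annotation$group == group_b, ]
  rows <- list()
  for (i in seq_len(nrow(ga))) {
    for (j in seq_len(nrow(gb))) {
      A <- ga[i, ]; B <- gb[j, ]
      if (A$chromosome != B$chromosome) next
      left <- if (A$start <= B$start) A else B
      right <- if (A$start <= B$start) B else A
      if (left$end >= right$start) next        # overlapping bodies
      if (left$strand != "+" || right$strand != "-") next
      gap <- right$start - left$end - 1L
      if (gap >= max_gap) next
      rows[[length(rows) + 1]] <- tibble(
        id_plus = left$gene_id, id_minus = right$gene_id,
        group_plus = left$group, group_minus = right$group,
        chromosome = A$chromosome, gap = gap,
        hairpin_start = left$end + 1L, hairpin_end = right$start - 1L
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(id_plus = character(), id_minus = character(),
                  group_plus = character(), group_minus = character(),
                  chromosome = character(), gap = integer(),
                  hairpin_start = integer(), hairpin_end = integer())
  }
  dplyr::distinct(out)
}
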