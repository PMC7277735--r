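# Synthetic multi-chromosome genomes with planted ground truth: tandem and
# segmental duplications, coding sequences diverged to target Ka/Ks, miR156
# loci (positives and designed negatives), convergent face-to-face gene
# pairs, and a machine-readable truth ledger. Every downstream stage of the
# pipeline is exercised against these genomes, so the generator is
# first-class, tested code.

#' Simulation configuration
#'
#' Builds and validates the knob set for [simulate_genome()]. The defaults
#' describe the standard study genome used throughout the test-bench: two
#' chromosomes of 300 genes, a small focal family (5% of genes, 11 group
#' labels), five tandem events (alternating 0/1 intervening genes), three
#' segmental blocks of 61 genes at 25% homolog retention with Ks targets
#' 0.3/0.5/1.0, six miR156 loci of which two are designed negatives (one
#' with 3 mismatches, one inside a coding gene), and three face-to-face
#' pairs at gaps 4000/6000/8000 nt (the last a boundary negative for the
#' strict < 8000 rule).
#'
#' @param seed Integer master seed; fixes every byte of the output.
#' @param n_chromosomes,genes_per_chromosome Genome shape.
#' @param mean_gene_length Mean coding length in nt (multiple of 3).
#' @param mean_intergenic_gap Mean intergenic gap in nt.
#' @param family_fraction Proportion of genes carrying family/group labels.
#' @param group_labels Group label set.
#' @param n_tandem_events,tandem_intervening,tandem_ks Tandem planting:
#'   count, intervening genes (0 or 1, recycled), divergence targets
#'   (recycled).
#' @param n_segmental_events,segmental_block_len,segmental_retention,target_ks_values
#'   Segmental planting: count, block length (>= 61 by convention), retained
#'   homolog-pair proportion, per-event Ks targets (recycled).
#' @param n_mirna_loci,mirna_mutation_counts,mirna_strands,mirna_inside_coding,mirna_hairpin
#'   miR156 planting: count and per-locus mismatch counts, strands,
#'   inside-coding flags and hairpin-context flags (all recycled).
#' @param n_face_to_face_pairs,face_to_face_gaps Convergent-pair planting:
#'   count and intergenic gaps in nt (recycled).
#' @param matures Named character vector of reference mature miRNA
#'   sequences (RNA).
#' @return A validated list of class `sbp_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       genes_per_chromosome = 300L,
                       mean_gene_length = 900L,
                       mean_intergenic_gap = 600L,
                       family_fraction = 0.03,
                       group_labels = c(paste0("g", 1:9), "ds", "ms"),
                       n_tandem_events = 5L,
                       tandem_intervening = c(0L, 1L),
                       tandem_ks = 0.2,
                       n_segmental_events = 3L,
                       segmental_block_len = 61L,
                       segmental_retention = 0.25,
                       target_ks_values = c(0.3, 0.5, 1.0),
                       n_mirna_loci = 6L,
                       mirna_mutation_counts = c(0L, 1L, 2L, 0L, 3L, 0L),
                       mirna_strands = c("+", "-", "+", "+", "+", "+"),
                       mirna_inside_coding = c(FALSE, FALSE, FALSE, FALSE,
                                               FALSE, TRUE),
                       mirna_hairpin = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                                         FALSE),
                       n_face_to_face_pairs = 3L,
                       face_to_face_gaps = c(4000L, 6000L, 8000L),
                       matures = MIR156_MATURE_DEFAULT) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    mean_gene_length = as.integer(mean_gene_length),
    mean_intergenic_gap = as.integer(mean_intergenic_gap),
    family_fraction = family_fraction, group_labels = group_labels,
    n_tandem_events = as.integer(n_tandem_events),
    tandem_intervening = as.integer(tandem_intervening),
    tandem_ks = tandem_ks,
    n_segmental_events = as.integer(n_segmental_events),
    segmental_block_len = as.integer(segmental_block_len),
    segmental_retention = segmental_retention,
    target_ks_values = target_ks_values,
    n_mirna_loci = as.integer(n_mirna_loci),
    mirna_mutation_counts = as.integer(mirna_mutation_counts),
    mirna_strands = mirna_strands,
    mirna_inside_coding = mirna_inside_coding,
    mirna_hairpin = mirna_hairpin,
    n_face_to_face_pairs = as.integer(n_face_to_face_pairs),
    face_to_face_gaps = as.integer(face_to_face_gaps),
    matures = matures
  )
  counts <- c("n_chromosomes", "genes_per_chromosome", "n_tandem_events",
              "n_segmental_events", "n_mirna_loci", "n_face_to_face_pairs")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop(nm, " must be a count >= 0", call. = FALSE)
    }
  }
  for (nm in c("family_fraction", "segmental_retention")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop(nm, " must be a proportion in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$mean_gene_length %% 3 != 0 || cfg$mean_gene_length < 150) {
    stop("mean_gene_length must be a multiple of 3 and >= 150",
         call. = FALSE)
  }
  if (any(!cfg$tandem_intervening %in% c(0L, 1L))) {
    stop("tandem_intervening values must be 0 or 1", call. = FALSE)
  }
  if (cfg$n_segmental_events > 0) {
    n_pairs <- ceiling(cfg$segmental_retention * cfg$segmental_block_len)
    if (n_pairs < 1) {
      stop("segmental_retention yields < 1 retained pair ",
           "(undetectable block)", call. = FALSE)
    }
  }
  if (any(nchar(rna_to_dna(cfg$matures)) < 19)) {
    stop("mature sequences must be >= 19 nt", call. = FALSE)
  }
  structure(cfg, class = "sbp_sim_config")
}

random_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

encode_protein <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    syn <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA == a]
    syn[sample.int(length(syn), 1)]
  }, character(1))
  paste(codons, collapse = "")
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

child_seed <- function() sample.int(.Machine$integer.max - 1, 1)

mutate_positions <- function(dna, n_mut, positions = seq_len(nchar(dna))) {
  if (n_mut == 0) return(dna)
  pos <- positions[sample.int(length(positions), n_mut)]
  for (p in pos) {
    cur <- substr(dna, p, p)
    substr(dna, p, p) <- sample(setdiff(DNA_BASES, cur), 1)
  }
  dna
}

# Mutate a planted mature copy. Designed negatives (>= 3 mismatches) must
# fail the scan for every reportable window (the full mature and every
# prefix/suffix of >= min_len nt), so their mismatch positions are drawn
# from the intersection of all those windows.
mutate_mature <- function(mature_dna, n_mut, min_len = 19L,
                          max_mismatch = 2L) {
  L <- nchar(mature_dna)
  positions <- if (n_mut > max_mismatch) {
    # intersection of every window of length >= min_len
    seq(L - min_len + 1L, min_len)
  } else {
    seq_len(L)
  }
  mutate_positions(mature_dna, n_mut, positions)
}

# Hairpin cassette: arm + loop + a slightly imperfect reverse complement of
# the arm. The planted mature sits inside the 5' arm; the star arm carries
# >= 3 substitutions inside the mature image (so the star side is never
# itself reported by the <= 2 mismatch scan) plus 2 outside it, which still
# leaves >= 17 of the mature positions paired.
build_hairpin_cassette <- function(mature_dna) {
  ext5 <- 15L; ext3 <- 25L
  arm <- paste0(random_dna(ext5), mature_dna, random_dna(ext3))
  star <- revcomp(arm)
  L <- nchar(arm); mlen <- nchar(mature_dna)
  # image of the mature within the star arm (star position k pairs arm
  # position L - k + 1)
  img <- sort(L - (ext5 + c(4L, 10L, 16L)) + 1L)
  outside <- c(3L, L - 2L)
  for (p in c(img, outside)) {
    cur <- substr(star, p, p)
    substr(star, p, p) <- sample(setdiff(DNA_BASES, cur), 1)
  }
  loop <- "ACAAACAA"  # 8-nt non-pairing loop
  list(cassette = paste0(arm, loop, star),
       mature_rel_start = ext5 + 1L,
       mature_rel_end = ext5 + mlen)
}

#' Generate a synthetic genome with planted ground truth
#'
#' Realises the configuration into chromosome sequences, a gene annotation,
#' CDS/protein sets, a pairwise-homology table computed from the emitted
#' sequences, and a truth ledger listing every planted event with its
#' realised coordinates. Identical configurations produce byte-identical
#' output.
#'
#' Family genes are diverged copies of per-group ancestor sequences that
#' share a planted domain segment, so domain scanning and group assignment
#' are exercisable; with-target groups (g3, g6, g7, g8, g9, ds) carry a
#' miR156 binding site in their coding sequence. The first positive miR156
#' locus is planted inside the first segmental source block (when both are
#' requested), which makes the miR156-SBP synteny path observable.
#'
#' @param config An `sbp_sim_config` from [sim_config()].
#' @return A list of class `sbp_simulation`: `genome`, `annotation`,
#'   `cds`, `proteins`, `matures`, `homology`, `truth`, `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sbp_sim_config"))
  cfg <- config
  if (cfg$genes_per_chromosome == 0 &&
      (cfg$n_tandem_events > 0 || cfg$n_segmental_events > 0 ||
       cfg$n_face_to_face_pairs > 0)) {
    stop("infeasible packing on chromosome chr1: planted events require ",
         "genes but genes_per_chromosome is 0", call. = FALSE)
  }
  if (cfg$n_segmental_events > 0 &&
      cfg$genes_per_chromosome < cfg$segmental_block_len) {
    stop("infeasible packing: segmental blocks need ",
         cfg$segmental_block_len, " genes per chromosome", call. = FALSE)
  }
  with_seed_local(cfg$seed, simulate_genome_impl(cfg))
}

simulate_genome_impl <- function(cfg) {
  target_site_dna <- paste0(revcomp(rna_to_dna(cfg$matures[[1]])), "A")
  with_target_groups <- intersect(cfg$group_labels,
                                  c("g3", "g6", "g7", "g8", "g9", "ds"))

  # --- group ancestors -------------------------------------------------
  n_codons_family <- cfg$mean_gene_length / 3
  ancestors <- stats::setNames(
    lapply(cfg$group_labels, function(g) {
      domain_cds <- encode_protein(SBP_DOMAIN_CONSENSUS)
      tail_len <- n_codons_family - nchar(SBP_DOMAIN_CONSENSUS) - 7
      tail_cds <- random_cds(max(tail_len, 10))
      if (g %in% with_target_groups) {
        paste0(domain_cds, tail_cds, target_site_dna)
      } else {
        paste0(domain_cds, tail_cds, random_cds(7))
      }
    }), cfg$group_labels)

  # --- base gene plan --------------------------------------------------
  n_total <- cfg$n_chromosomes * cfg$genes_per_chromosome
  n_family <- round(cfg$family_fraction * n_total)
  fam_idx <- if (n_family > 0) sort(sample.int(n_total, n_family))
             else integer(0)
  fam_groups <- if (n_family > 0) {
    cfg$group_labels[1 + (seq_len(n_family) - 1) %% length(cfg$group_labels)]
  } else character(0)
  plan <- vector("list", n_total)
  gi <- 0
  seeds_used <- list()
  for (ch in seq_len(cfg$n_chromosomes)) {
    for (r in seq_len(cfg$genes_per_chromosome)) {
      gi <- gi + 1
      fam_pos <- match(gi, fam_idx)
      if (!is.na(fam_pos)) {
        grp <- fam_groups[fam_pos]
        sd <- child_seed()
        cds <- evolve_cds(ancestors[[grp]],
                          target_ks = stats::runif(1, 0.05, 0.45),
                          target_ka = stats::runif(1, 0.005, 0.03),
                          seed = sd)
        seeds_used[[length(seeds_used) + 1]] <-
          tibble(what = "family_gene", id = sprintf("c%dg%03d", ch, r),
                 seed = sd)
      } else {
        grp <- NA_character_
        n_cod <- round(stats::runif(1, 0.5, 1.5) *
                         cfg$mean_gene_length / 3)
        cds <- random_cds(max(n_cod, 50))
      }
      plan[[gi]] <- list(
        id = sprintf("c%dg%03d", ch, r), chromosome = paste0("chr", ch),
        key = r, cds = cds, strand = sample(c("+", "-"), 1),
        family = !is.na(fam_pos), group = grp, gap_before = NA_integer_
      )
    }
  }
  plan <- dplyr::bind_rows(lapply(plan, as_tibble))
  used <- character(0)  # gene ids reserved by planted events

  # --- segmental blocks ------------------------------------------------
  truth_segmental <- list()
  mirna_block_gap <- NULL  # (chromosome, key) gap hosting the first miRNA
  if (cfg$n_segmental_events > 0) {
    half <- (cfg$segmental_block_len - 1) %/% 2
    ks_vec <- rep_len(cfg$target_ks_values, cfg$n_segmental_events)
    for (ev in seq_len(cfg$n_segmental_events)) {
      chr_src <- paste0("chr", 1 + (ev - 1) %% cfg$n_chromosomes)
      chr_dst <- paste0("chr", 1 + ev %% cfg$n_chromosomes)
      # pick a free block-length window holding a family gene in its
      # central region (so the family anchor's fragment overlaps most of
      # the block and keeps full synteny support)
      blk <- cfg$segmental_block_len
      margin <- max(ceiling(blk / 4), 1)  # family gene this far from ends
      cand <- plan[plan$chromosome == chr_src & plan$family &
                     plan$key == floor(plan$key) &
                     !(plan$id %in% used), ]
      src_win <- NULL
      for (i in sample.int(max(nrow(cand), 1))) {
        if (nrow(cand) == 0) break
        ctr <- cand$key[i]
        lo <- max(1, ctr - (blk - margin))
        hi <- min(cfg$genes_per_chromosome - blk + 1, ctr - margin + 1)
        if (lo > hi) next
        starts <- lo:hi
        starts <- starts[ctr - starts + 1 >= margin &
                           ctr - starts + 1 <= blk - margin + 1]
        if (length(starts) == 0) next
        for (w in sample(starts)) {
          win <- plan[plan$chromosome == chr_src &
                        plan$key >= w & plan$key <= w + blk - 1, ]
          if (nrow(win) == blk && !any(win$id %in% used)) {
            src_win <- win
            break
          }
        }
        if (!is.null(src_win)) break
      }
      if (is.null(src_win)) {
        stop("infeasible packing: no free ", blk,
             "-gene window holding a family gene on ", chr_src,
             call. = FALSE)
      }
      # destination insertion point: a gap on chr_dst outside used windows
      dst_cand <- plan[plan$chromosome == chr_dst &
                         plan$key == floor(plan$key) &
                         !(plan$id %in% used), ]
      dst_pick <- dst_cand[sample.int(nrow(dst_cand), 1), ]
      dst_after <- dst_pick$key
      used <- c(used, dst_pick$id)
      n_ret <- ceiling(cfg$segmental_retention * cfg$segmental_block_len)
      fam_pos_in_block <- which(src_win$family)
      ret <- fam_pos_in_block
      if (length(ret) > n_ret) ret <- ret[seq_len(n_ret)]
      # spread the remaining retained positions evenly over the block so
      # every family anchor's fragment overlap keeps enough support pairs
      spaced <- unique(round(seq(1, cfg$segmental_block_len,
                                 length.out = n_ret)))
      spaced <- setdiff(spaced, ret)
      ret <- sort(c(ret, utils::head(spaced, n_ret - length(ret))))
      if (length(ret) < n_ret) {
        pool <- setdiff(seq_len(cfg$segmental_block_len), ret)
        ret <- sort(c(ret, pool[sample.int(length(pool),
                                           n_ret - length(ret))]))
      }
      new_rows <- list()
      pairs <- list()
      for (p in seq_len(cfg$segmental_block_len)) {
        src_row <- src_win[p, ]
        new_id <- sprintf("%s_s%d", src_row$id, ev)
        if (p %in% ret) {
          sd <- child_seed()
          cds <- evolve_cds(src_row$cds, target_ks = ks_vec[ev],
                            target_ka = 0, seed = sd)
          seeds_used[[length(seeds_used) + 1]] <-
            tibble(what = "segmental_copy", id = new_id, seed = sd)
          pairs[[length(pairs) + 1]] <-
            tibble(source_id = src_row$id, copy_id = new_id)
          fam <- src_row$family; grp <- src_row$group
        } else {
          cds <- random_cds(max(round(nchar(src_row$cds) / 3), 50))
          fam <- FALSE; grp <- NA_character_
        }
        new_rows[[p]] <- tibble(
          id = new_id, chromosome = chr_dst,
          key = dst_after + p / (cfg$segmental_block_len + 1),
          cds = cds, strand = src_row$strand, family = fam, group = grp,
          gap_before = NA_integer_
        )
      }
      new_rows <- dplyr::bind_rows(new_rows)
      plan <- dplyr::bind_rows(plan, new_rows)
      used <- c(used, src_win$id, new_rows$id)
      truth_segmental[[ev]] <- tibble(
        event = ev, chromosome_src = chr_src, chromosome_dst = chr_dst,
        target_ks = ks_vec[ev],
        n_retained = length(ret),
        source_ids = list(src_win$id), copy_ids = list(new_rows$id),
        retained_pairs = list(dplyr::bind_rows(pairs))
      )
      if (ev == 1) {
        # remember a gap inside the source block for the first miRNA locus
        mid <- src_win[ceiling(nrow(src_win) / 2), ]
        mirna_block_gap <- list(chromosome = chr_src, key = mid$key)
      }
    }
  }

  # --- tandem duplications --------------------------------------------
  truth_tandem <- list()
  if (cfg$n_tandem_events > 0) {
    iv_vec <- rep_len(cfg$tandem_intervening, cfg$n_tandem_events)
    ks_vec <- rep_len(cfg$tandem_ks, cfg$n_tandem_events)
    for (ev in seq_len(cfg$n_tandem_events)) {
      cand <- plan[plan$family & !(plan$id %in% used), ]
      if (nrow(cand) == 0) {
        stop("infeasible packing: no free family gene left for tandem ",
             "event ", ev, call. = FALSE)
      }
      src <- cand[sample.int(nrow(cand), 1), ]
      sd <- child_seed()
      copy_id <- sprintf("%s_t%d", src$id, ev)
      copy_cds <- evolve_cds(src$cds, target_ks = ks_vec[ev],
                             target_ka = 0, seed = sd)
      seeds_used[[length(seeds_used) + 1]] <-
        tibble(what = "tandem_copy", id = copy_id, seed = sd)
      add <- list(tibble(
        id = copy_id, chromosome = src$chromosome,
        key = src$key + if (iv_vec[ev] == 1) 0.02 else 0.01,
        cds = copy_cds, strand = src$strand, family = TRUE,
        group = src$group, gap_before = NA_integer_
      ))
      if (iv_vec[ev] == 1) {
        add[[2]] <- tibble(
          id = sprintf("%s_tsp%d", src$id, ev), chromosome = src$chromosome,
          key = src$key + 0.01, cds = random_cds(100), strand = "+",
          family = FALSE, group = NA_character_, gap_before = NA_integer_
        )
      }
      plan <- dplyr::bind_rows(plan, dplyr::bind_rows(add))
      used <- c(used, src$id, vapply(add, function(x) x$id, character(1)))
      truth_tandem[[ev]] <- tibble(
        event = ev, source_id = src$id, copy_id = copy_id,
        intervening = iv_vec[ev], target_ks = ks_vec[ev],
        chromosome = src$chromosome
      )
    }
  }

  # --- face-to-face pairs ---------------------------------------------
  truth_face <- list()
  if (cfg$n_face_to_face_pairs > 0) {
    gaps <- rep_len(cfg$face_to_face_gaps, cfg$n_face_to_face_pairs)
    grp_a <- if ("g1" %in% cfg$group_labels) "g1" else cfg$group_labels[1]
    grp_b <- if ("g6" %in% cfg$group_labels) "g6" else
      cfg$group_labels[min(2, length(cfg$group_labels))]
    for (ev in seq_len(cfg$n_face_to_face_pairs)) {
      chr <- paste0("chr", 1 + (ev - 1) %% cfg$n_chromosomes)
      cand <- plan[plan$chromosome == chr & plan$key == floor(plan$key) &
                     !(plan$id %in% used), ]
      anchor <- cand[sample.int(nrow(cand), 1), ]
      after <- anchor$key
      used <- c(used, anchor$id)
      sd_a <- child_seed(); sd_b <- child_seed()
      id_a <- sprintf("ftf%d_a", ev); id_b <- sprintf("ftf%d_b", ev)
      row_a <- tibble(id = id_a, chromosome = chr, key = after + 0.31,
                      cds = evolve_cds(ancestors[[grp_a]], 0.2, 0.02,
                                       seed = sd_a),
                      strand = "+", family = TRUE, group = grp_a,
                      gap_before = NA_integer_)
      row_b <- tibble(id = id_b, chromosome = chr, key = after + 0.32,
                      cds = evolve_cds(ancestors[[grp_b]], 0.2, 0.02,
                                       seed = sd_b),
                      strand = "-", family = TRUE, group = grp_b,
                      gap_before = gaps[ev])
      plan <- dplyr::bind_rows(plan, row_a, row_b)
      used <- c(used, id_a, id_b)
      seeds_used[[length(seeds_used) + 1]] <-
        tibble(what = "face_to_face", id = id_a, seed = sd_a)
      seeds_used[[length(seeds_used) + 1]] <-
        tibble(what = "face_to_face", id = id_b, seed = sd_b)
      truth_face[[ev]] <- tibble(
        event = ev, id_plus = id_a, id_minus = id_b, chromosome = chr,
        gap = gaps[ev],
        boundary_negative = gaps[ev] >= 8000L
      )
    }
  }

  # --- miR156 loci (planned; coordinates realised at layout) ----------
  mirna_plan <- list()
  if (cfg$n_mirna_loci > 0) {
    mm <- rep_len(cfg$mirna_mutation_counts, cfg$n_mirna_loci)
    strands <- rep_len(cfg$mirna_strands, cfg$n_mirna_loci)
    inside <- rep_len(cfg$mirna_inside_coding, cfg$n_mirna_loci)
    hairpin <- rep_len(cfg$mirna_hairpin, cfg$n_mirna_loci)
    mature_dna <- rna_to_dna(cfg$matures[[1]])
    first_intergenic_placed <- FALSE
    for (ev in seq_len(cfg$n_mirna_loci)) {
      planted <- mutate_mature(mature_dna, mm[ev])
      if (inside[ev]) {
        host <- plan[!plan$family & plan$strand == "+" &
                       !(plan$id %in% used), ]
        if (nrow(host) == 0) {
          stop("inside_coding miRNA requested but no free plus-strand ",
               "gene available", call. = FALSE)
        }
        h <- host[sample.int(nrow(host), 1), ]
        off <- 90L  # overwrite a central slice of the host CDS
        cds <- h$cds
        substr(cds, off + 1, off + nchar(planted)) <- planted
        plan$cds[plan$id == h$id] <- cds
        used <- c(used, h$id)
        # in-gene loci always sit on the plus strand of a plus-strand host
        mirna_plan[[ev]] <- list(type = "in_gene", locus = ev,
                                 host_id = h$id, rel_start = off + 1L,
                                 planted = planted, strand = "+",
                                 mismatches = mm[ev], hairpin = FALSE,
                                 inside_coding = TRUE)
      } else {
        if (hairpin[ev]) {
          cass <- build_hairpin_cassette(planted)
        } else {
          cass <- list(cassette = paste0(random_dna(30), planted,
                                         random_dna(30)),
                       mature_rel_start = 31L,
                       mature_rel_end = 30L + nchar(planted))
        }
        cassette <- cass$cassette
        rs <- cass$mature_rel_start; re <- cass$mature_rel_end
        if (strands[ev] == "-") {
          n <- nchar(cassette)
          cassette <- revcomp(cassette)
          new_rs <- n - re + 1L; re <- n - rs + 1L; rs <- new_rs
        }
        if (!first_intergenic_placed && !is.null(mirna_block_gap)) {
          chr <- mirna_block_gap$chromosome
          key <- mirna_block_gap$key
          first_intergenic_placed <- TRUE
        } else {
          cand <- plan[plan$key == floor(plan$key) &
                         !(plan$id %in% used), ]
          pick <- cand[sample.int(nrow(cand), 1), ]
          chr <- pick$chromosome; key <- pick$key
          used <- c(used, pick$id)
        }
        mirna_plan[[ev]] <- list(type = "in_gap", locus = ev,
                                 chromosome = chr, before_key = key,
                                 cassette = cassette, rel_start = rs,
                                 rel_end = re, planted = planted,
                                 strand = strands[ev], mismatches = mm[ev],
                                 hairpin = hairpin[ev],
                                 inside_coding = FALSE)
      }
    }
  }

  # --- layout / materialisation ---------------------------------------
  plan <- dplyr::arrange(plan, .data$chromosome, .data$key)
  genome <- character(0)
  ann_rows <- list()
  mirna_truth <- list()
  for (ch in unique(plan$chromosome)) {
    rows <- plan[plan$chromosome == ch, ]
    pieces <- character(0)
    pos <- 0L
    for (i in seq_len(nrow(rows))) {
      g <- rows[i, ]
      gap_len <- if (!is.na(g$gap_before)) g$gap_before else {
        as.integer(round(stats::runif(1, 0.5, 1.5) *
                           cfg$mean_intergenic_gap))
      }
      # cassettes assigned to the gap before this gene
      gap_cassettes <- purrr::keep(mirna_plan, function(m) {
        m$type == "in_gap" && m$chromosome == ch &&
          isTRUE(all.equal(m$before_key, g$key))
      })
      if (length(gap_cassettes) > 0) {
        pad <- 60L
        for (m in gap_cassettes) {
          left <- random_dna(pad)
          pieces <- c(pieces, left)
          pos <- pos + pad
          cstart <- pos + 1L
          pieces <- c(pieces, m$cassette)
          mirna_truth[[length(mirna_truth) + 1]] <- tibble(
            locus = m$locus, chromosome = ch,
            start = cstart + m$rel_start - 1L,
            end = cstart + m$rel_end - 1L,
            strand = m$strand, mismatches = m$mismatches,
            inside_coding = FALSE, hairpin = m$hairpin,
            designed_positive = m$mismatches <= 2 && m$hairpin
          )
          pos <- pos + nchar(m$cassette)
        }
        gap_seq <- random_dna(max(gap_len, pad))
      } else {
        gap_seq <- random_dna(gap_len)
      }
      pieces <- c(pieces, gap_seq)
      pos <- pos + nchar(gap_seq)
      gseq <- if (g$strand == "+") g$cds else revcomp(g$cds)
      start <- pos + 1L
      end <- pos + nchar(gseq)
      pieces <- c(pieces, gseq)
      pos <- end
      ann_rows[[length(ann_rows) + 1]] <- tibble(
        gene_id = g$id, chromosome = ch, start = start, end = end,
        strand = g$strand, family = g$family, group = g$group,
        species = "synthetic"
      )
      # in-gene miRNA coordinates become known here
      for (m in purrr::keep(mirna_plan, function(x)
        x$type == "in_gene" && x$host_id == g$id)) {
        ms <- start + m$rel_start - 1L  # hosts are plus-strand genes
        mirna_truth[[length(mirna_truth) + 1]] <- tibble(
          locus = m$locus, chromosome = ch, start = ms,
          end = ms + nchar(m$planted) - 1L, strand = "+",
          mismatches = m$mismatches, inside_coding = TRUE,
          hairpin = FALSE, designed_positive = FALSE
        )
      }
    }
    # trailing gap so the last gene is not flush with the end
    pieces <- c(pieces, random_dna(cfg$mean_intergenic_gap))
    genome[ch] <- paste(pieces, collapse = "")
  }
  annotation <- annotate_ranks(dplyr::bind_rows(ann_rows))

  cds <- stats::setNames(plan$cds, plan$id)
  proteins <- stats::setNames(
    as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                       if.fuzzy.codon = "solve")),
    names(cds))

  homology <- simulate_homology(plan, proteins, truth_segmental)

  truth <- list(
    tandem = if (length(truth_tandem)) dplyr::bind_rows(truth_tandem)
             else tibble(),
    segmental = if (length(truth_segmental)) {
      dplyr::bind_rows(truth_segmental)
    } else tibble(),
    mirna = if (length(mirna_truth)) {
      dplyr::arrange(dplyr::bind_rows(mirna_truth), .data$locus)
    } else tibble(),
    face_to_face = if (length(truth_face)) dplyr::bind_rows(truth_face)
                   else tibble(),
    seeds = if (length(seeds_used)) dplyr::bind_rows(seeds_used)
            else tibble()
  )
  structure(
    list(genome = genome, annotation = annotation, cds = cds,
         proteins = proteins, matures = cfg$matures, homology = homology,
         truth = truth, config = cfg),
    class = "sbp_simulation"
  )
}

# Homology table computed from the emitted sequences: all-vs-all local
# alignment of family proteins, plus direct scoring of the planted
# segmental background pairs. Pairs failing the E <= 1e-10 surrogate
# threshold are dropped, mirroring the filter applied to external tables.
simulate_homology <- function(plan, proteins, truth_segmental,
                              max_evalue = 1e-10) {
  fam_ids <- plan$id[plan$family]
  tabs <- list()
  if (length(fam_ids) >= 2) {
    tabs[[1]] <- internal_homology_search(proteins[fam_ids],
                                          score_threshold = 40)
  }
  extra <- list()
  for (i in seq_along(truth_segmental)) {
    tp <- truth_segmental[[i]]$retained_pairs[[1]]
    fam <- tp$source_id %in% fam_ids
    if (any(!fam)) {
      extra[[length(extra) + 1]] <- tp[!fam, ]
    }
  }
  if (length(extra) > 0) {
    extra <- dplyr::bind_rows(extra)
    tabs[[length(tabs) + 1]] <- score_protein_pairs(
      proteins, extra$source_id, extra$copy_id)
  }
  hom <- dplyr::bind_rows(tabs)
  if (nrow(hom) == 0) return(empty_homology_table())
  n_in <- nrow(hom)
  hom <- hom[hom$evalue <= max_evalue, ]
  log_filter("simulated homology", n_in, nrow(hom),
             sprintf("E-value <= %g", max_evalue))
  hom
}

# Local alignment scores for an explicit list of protein id pairs,
# formatted in the 12-column homology dialect.
score_protein_pairs <- function(proteins, ids_a, ids_b) {
  rows <- purrr::map2(ids_a, ids_b, function(a, b) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(proteins[[a]]),
      subject = Biostrings::AAString(proteins[[b]]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1
    )
    alignment_stats(aln, a, b, nchar(proteins[[a]]), nchar(proteins[[b]]))
  })
  dplyr::mutate(dplyr::bind_rows(rows), self_hit = FALSE)
}

#' @export
print.sbp_simulation <- function(x, ...) {
  cat("Synthetic genome: ", length(x$genome), " chromosome(s), ",
      nrow(x$annotation), " genes (", sum(x$annotation$family),
      " family members)\n", sep = "")
  cat("Planted: ", nrow(x$truth$tandem), " tandem, ",
      nrow(x$truth$segmental), " segmental, ", nrow(x$truth$mirna),
      " miR156, ", nrow(x$truth$face_to_face), " face-to-face\n", sep = "")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits the simulation as plain-text files: `genome.fa`, `genes.gff3`,
#' `cds.fa`, `proteins.fa`, `mature.fa`, `homology.tsv` and `truth.json`
#' (the ledger, with list-columns flattened; schema documented in the
#' vignette).
#'
#' @param sim An `sbp_simulation`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sbp_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gff3(sim$annotation, file.path(dir, "genes.gff3"))
  write_fasta(sim$cds, file.path(dir, "cds.fa"))
  write_fasta(sim$proteins, file.path(dir, "proteins.fa"))
  write_fasta(rna_to_dna(sim$matures), file.path(dir, "mature.fa"))
  write_homology_table(sim$homology, file.path(dir, "homology.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate an expression matrix with planted fold changes
#'
#' Control/treatment column pairs per condition, with requested per-gene
#' fold changes realised exactly before (optional, bounded) noise.
#'
#' @param gene_ids Gene ids (rows).
#' @param conditions Condition names.
#' @param responses Tibble with `gene_id`, `condition`, `fold`
#'   (all folds > 0).
#' @param base_level Control expression level.
#' @param noise_sd Bounded multiplicative noise: values are multiplied by
#'   `2^e` with `e ~ U(-noise_sd, noise_sd)`. Default 0 (exact).
#' @param seed Integer seed.
#' @return List: `expr` (tibble, `gene_id` + one control and one treatment
#'   column per condition), `design` (for [stress_response_count()]),
#'   `truth` (the realised responses).
#' @export
simulate_expression <- function(gene_ids, conditions, responses,
                                base_level = 10, noise_sd = 0, seed = 1L) {
  if (any(responses$fold <= 0)) stop("folds must be > 0", call. = FALSE)
  unknown <- setdiff(responses$gene_id, gene_ids)
  if (length(unknown) > 0) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  with_seed_local(seed, {
    expr <- tibble(gene_id = gene_ids)
    for (cond in conditions) {
      ctrl <- rep(base_level, length(gene_ids))
      trt <- ctrl
      resp <- responses[responses$condition == cond, ]
      idx <- match(resp$gene_id, gene_ids)
      trt[idx] <- ctrl[idx] * resp$fold
      if (noise_sd > 0) {
        ctrl <- ctrl * 2^stats::runif(length(ctrl), -noise_sd, noise_sd)
        trt <- trt * 2^stats::runif(length(trt), -noise_sd, noise_sd)
      }
      expr[[paste0(cond, "_control")]] <- ctrl
      expr[[paste0(cond, "_treatment")]] <- trt
    }
    design <- tibble(condition = conditions,
                     control = paste0(conditions, "_control"),
                     treatment = paste0(conditions, "_treatment"))
    list(expr = expr, design = design, truth = responses)
  })
}
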