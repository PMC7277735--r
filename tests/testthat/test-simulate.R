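test_that("identical configurations reproduce byte-identical output", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1, genes_per_chromosome = 70,
                    n_tandem_events = 1, n_segmental_events = 0,
                    n_mirna_loci = 1, mirna_mutation_counts = 0L,
                    mirna_inside_coding = FALSE, mirna_hairpin = TRUE,
                    mirna_strands = "+", n_face_to_face_pairs = 1,
                    face_to_face_gaps = 3000L, family_fraction = 0.1)
  s1 <- suppressMessages(simulate_genome(cfg))
  s2 <- suppressMessages(simulate_genome(cfg))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$cds, s2$cds)
  expect_identical(s1$truth, s2$truth)
})

test_that("every planted event appears exactly once in the truth ledger", {
  sim <- default_sim()
  cfg <- sim$config
  expect_equal(nrow(sim$truth$tandem), cfg$n_tandem_events)
  expect_equal(nrow(sim$truth$segmental), cfg$n_segmental_events)
  expect_equal(nrow(sim$truth$mirna), cfg$n_mirna_loci)
  expect_equal(nrow(sim$truth$face_to_face), cfg$n_face_to_face_pairs)
  expect_false(anyDuplicated(sim$truth$mirna$locus) > 0)
  # ids resolve to the emitted annotation
  expect_true(all(sim$truth$tandem$source_id %in%
                    sim$annotation$gene_id))
  expect_true(all(sim$truth$tandem$copy_id %in% sim$annotation$gene_id))
  expect_true(all(unlist(sim$truth$segmental$copy_ids) %in%
                    sim$annotation$gene_id))
})

test_that("infeasible event requests are rejected by name", {
  expect_error(
    sim_config(segmental_retention = 0, segmental_block_len = 61),
    "undetectable block")
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 0,
                    n_tandem_events = 1, n_segmental_events = 0,
                    n_mirna_loci = 0, n_face_to_face_pairs = 0)
  expect_error(simulate_genome(cfg), "infeasible packing")
})

test_that("tandem copies sit adjacent or behind one fresh spacer gene", {
  sim <- default_sim()
  ann <- sim$annotation
  for (i in seq_len(nrow(sim$truth$tandem))) {
    tt <- sim$truth$tandem[i, ]
    ra <- ann[ann$gene_id == tt$source_id, ]
    rb <- ann[ann$gene_id == tt$copy_id, ]
    expect_equal(ra$chromosome, rb$chromosome)
    expect_equal(abs(rb$rank - ra$rank), tt$intervening + 1L)
    if (tt$intervening == 1) {
      mid <- ann[ann$chromosome == ra$chromosome &
                   ann$rank == (ra$rank + rb$rank) / 2, ]
      expect_false(mid$family)
    }
  }
})

test_that("zero-divergence evolution is the identity and seeds reproduce", {
  cds <- "ATGAAATTTGGGCCCTAG"
  cds <- substr(cds, 1, 15)
  expect_identical(evolve_cds(cds, 0, 0, seed = 1), cds)
  set.seed(77)
  big <- paste(sample(sbpmir:::SENSE_CODONS, 200, replace = TRUE),
               collapse = "")
  m1 <- evolve_cds(big, 0.4, 0.05, seed = 9)
  m2 <- evolve_cds(big, 0.4, 0.05, seed = 9)
  m3 <- evolve_cds(big, 0.4, 0.05, seed = 10)
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
  # frame preserved, no stops introduced
  expect_equal(nchar(m1), nchar(big))
  expect_false(grepl("\\*", sbpmir:::translate_cds(m1)))
  # targets beyond the sequence's mutational capacity are rejected
  expect_error(evolve_cds(big, 0.5, 3, seed = 1),
               "unreachable|saturation")
})

test_that("segmental blocks honour the retention ceiling rule", {
  sim <- default_sim()
  n_exp <- ceiling(sim$config$segmental_retention *
                     sim$config$segmental_block_len)
  for (i in seq_len(nrow(sim$truth$segmental))) {
    seg <- sim$truth$segmental[i, ]
    expect_equal(seg$n_retained, n_exp)
    expect_equal(nrow(seg$retained_pairs[[1]]), n_exp)
    expect_length(seg$copy_ids[[1]], sim$config$segmental_block_len)
    # order preserved: copies appear in the same relative order
    ann <- sim$annotation
    copies <- ann[match(seg$copy_ids[[1]], ann$gene_id), ]
    expect_true(all(diff(copies$rank) == 1))
  }
})

test_that("face-to-face planting realises the exact intergenic gap", {
  sim <- default_sim()
  ann <- sim$annotation
  for (i in seq_len(nrow(sim$truth$face_to_face))) {
    ftf <- sim$truth$face_to_face[i, ]
    a <- ann[ann$gene_id == ftf$id_plus, ]
    b <- ann[ann$gene_id == ftf$id_minus, ]
    expect_equal(a$strand, "+")
    expect_equal(b$strand, "-")
    expect_lt(a$end, b$start)
    expect_equal(b$start - a$end - 1L, ftf$gap)
  }
})

test_that("planted miR156 loci match the emitted genome at the stated distance", {
  sim <- default_sim()
  mature <- sbpmir:::rna_to_dna(sim$matures[[1]])
  for (i in seq_len(nrow(sim$truth$mirna))) {
    tr <- sim$truth$mirna[i, ]
    s <- substr(sim$genome[[tr$chromosome]], tr$start, tr$end)
    if (tr$strand == "-") s <- sbpmir:::revcomp(s)
    d <- sum(strsplit(s, "")[[1]] != strsplit(mature, "")[[1]])
    expect_equal(d, tr$mismatches, info = paste("locus", tr$locus))
  }
})

test_that("annotation invariants hold: sorted, unique, non-overlapping", {
  sim <- default_sim()
  ann <- sim$annotation
  expect_false(anyDuplicated(ann$gene_id) > 0)
  expect_true(all(ann$start <= ann$end))
  by_chr <- split(ann, ann$chromosome)
  for (chr in by_chr) {
    chr <- chr[order(chr$rank), ]
    expect_true(all(diff(chr$start) > 0))
    expect_true(all(utils::head(chr$end, -1) < utils::tail(chr$start, -1)))
  }
  # group labels only on family members
  expect_true(all(is.na(ann$group[!ann$family])))
  expect_true(all(!is.na(ann$group[ann$family])))
})

test_that("written simulations are readable by the package readers", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(genome, sim$genome)
  ann <- read_gff3(file.path(dir, "genes.gff3"))
  expect_equal(ann$gene_id, sim$annotation$gene_id)
  hom <- suppressMessages(
    read_homology_table(file.path(dir, "homology.tsv")))
  expect_equal(nrow(hom), nrow(sim$homology))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth$tandem, nrow(sim$truth$tandem))
})

test_that("expression generator realises planted folds exactly", {
  genes <- paste0("g", 1:5)
  resp <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         condition = "cold",
                         fold = c(2, 1.5, 0.5))
  out <- simulate_expression(genes, c("cold", "heat"), resp)
  expect_equal(out$expr$cold_treatment[1:3] / out$expr$cold_control[1:3],
               c(2, 1.5, 0.5))
  counts <- stress_response_count(out$expr, out$design)
  cold <- counts[counts$condition == "cold", ]
  expect_equal(cold$n_responsive[match(genes, cold$gene_id)],
               c(1L, 0L, 1L, 0L, 0L))
  expect_error(
    simulate_expression(genes, "cold",
                        tibble::tibble(gene_id = "nope",
                                       condition = "cold", fold = 2)),
    "unknown gene")
  expect_error(
    simulate_expression(genes, "cold",
                        tibble::tibble(gene_id = "g1",
                                       condition = "cold", fold = 0)),
    "> 0")
})
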