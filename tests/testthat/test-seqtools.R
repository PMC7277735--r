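test_that("global alignment is optimal on exhaustively enumerable pairs", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(42)
  alphabet <- c("A", "R", "N", "D", "W")
  for (rep in 1:12) {
    a <- random_protein(sample(1:6, 1), alphabet)
    b <- random_protein(sample(1:6, 1), alphabet)
    got <- global_align(a, b)$score
    want <- oracle_global_align_score(a, b, BLOSUM62, 11, 1)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("self-alignment scores the substitution diagonal and empties error", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  p <- "MKVWLA"
  aln <- global_align(p, p)
  aa <- strsplit(p, "")[[1]]
  expect_equal(aln$score, sum(BLOSUM62[cbind(aa, aa)]))
  expect_equal(aln$aligned_a, aln$aligned_b)
  expect_error(global_align("MKV", ""), "non-empty")
})

test_that("internal homology search finds true pairs and round-trips", {
  prots <- c(p1 = strrep("MKVLAWDE", 20), p2 = strrep("MKVLAWDE", 20),
             p3 = random_protein(150))
  hom <- internal_homology_search(prots, score_threshold = 100)
  expect_true(any(hom$qseqid == "p1" & hom$sseqid == "p2"))
  top <- hom[hom$qseqid == "p1" & hom$sseqid == "p2", ]
  expect_equal(top$pident, 100)
  expect_true(all(hom$evalue >= 0))

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_homology_table(hom, tmp)
  back <- suppressMessages(read_homology_table(tmp, max_evalue = Inf))
  expect_equal(nrow(back), nrow(hom))
})

test_that("unrelated random proteins yield no hits at a stringent cutoff", {
  set.seed(7)
  # empirical null: shuffled 100-mers must not reach the E <= 1e-10
  # surrogate over repeated trials
  n_hits <- 0
  for (trial in 1:20) {
    prots <- stats::setNames(replicate(6, random_protein(100)),
                             paste0("r", 1:6))
    hom <- internal_homology_search(prots, score_threshold = 0)
    n_hits <- n_hits + sum(hom$evalue <= 1e-10)
  }
  expect_equal(n_hits, 0)
})

test_that("PSSM scanning finds planted domains and is flank-invariant", {
  set.seed(3)
  instances <- vapply(1:8, function(i) {
    x <- sbpmir:::SBP_DOMAIN_CONSENSUS
    pos <- sample(nchar(x), 4)
    for (p in pos) substr(x, p, p) <- sample(sbpmir:::AMINO_ACIDS, 1)
    x
  }, character(1))
  model <- build_pssm(instances)
  expect_true(scan_domain(c(q = model$consensus), model)$hit)

  short <- scan_domain(c(q = "MKV"), model)
  expect_false(short$hit)
  expect_true(is.na(short$score))

  planted <- paste0(random_protein(40), instances[1], random_protein(60))
  res <- scan_domain(c(q = planted), model)
  expect_true(res$hit)
  expect_equal(res$start, 41L)

  padded <- paste0(random_protein(25), planted, random_protein(25))
  res2 <- scan_domain(c(q = padded), model)
  expect_equal(res2$score, res$score)
  expect_equal(res2$start, res$start + 25L)
})

test_that("group assignment takes the best reference and surfaces ties", {
  refs <- c(r1 = strrep("MKVLAW", 30), r2 = strrep("DDEERK", 30),
            r3 = strrep("GGSSTT", 30))
  labs <- c("g7", "g3", "g8")
  got <- assign_group(c(q = strrep("MKVLAW", 30)), refs, labs)
  expect_equal(got$group, "g7")
  expect_false(got$ambiguous)

  tied <- assign_group(c(q = strrep("MKVLAW", 30)),
                       c(a = strrep("MKVLAW", 30),
                         b = strrep("MKVLAW", 30)),
                       c("g3", "g8"))
  expect_true(tied$ambiguous)
  expect_true(is.na(tied$group))
  expect_error(assign_group(c(q = "MKV"), character(0), character(0)),
               "empty reference")
})

test_that("generator group labels are recovered from sequence alone", {
  sim <- small_sim()
  ann <- sim$annotation
  fam <- ann[ann$family, ]
  fam <- fam[!grepl("_", fam$gene_id), ]  # base family genes
  fam <- fam[seq_len(min(8, nrow(fam))), ]
  refs <- vapply(sim$config$group_labels, function(g) {
    ids <- fam$gene_id[fam$group == g]
    if (length(ids) == 0) NA_character_ else sim$proteins[[ids[1]]]
  }, character(1))
  keep <- !is.na(refs)
  got <- assign_group(sim$proteins[fam$gene_id], refs[keep],
                      sim$config$group_labels[keep])
  expect_equal(got$group, fam$group)
})

test_that("protein properties match direct mass sums and pKa arithmetic", {
  gg <- protein_properties(c(p = "GG"))
  expect_equal(gg$molecular_weight, 2 * 57.0519 + 18.01524,
               tolerance = 1e-6)
  expect_equal(gg$length, 2L)

  acidic <- protein_properties(c(p = "DDD"))
  basic <- protein_properties(c(p = "KKK"))
  expect_lt(acidic$isoelectric_point, 4.5)
  expect_gt(basic$isoelectric_point, 9.5)
  # independent check: the Henderson-Hasselbalch net charge changes sign
  # around the reported pI
  expect_gt(net_charge("DDD", acidic$isoelectric_point - 0.1), 0)
  expect_lt(net_charge("DDD", acidic$isoelectric_point + 0.1), 0)
  expect_lt(abs(net_charge("KKK", basic$isoelectric_point)), 1e-3)

  expect_error(protein_properties(c(p = "MKXV")), "non-standard")
})

test_that("pI is monotone non-decreasing in lysine count", {
  backbone <- "MSTGAV"
  pis <- vapply(0:6, function(k) {
    protein_properties(
      c(p = paste0(backbone, strrep("K", k))))$isoelectric_point
  }, numeric(1))
  expect_true(all(diff(pis) >= -1e-6))
})
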