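test_that("micro-fragments truncate at chromosome ends", {
  ann <- make_ann(200)
  expect_equal(nrow(micro_fragment(ann, "g50", k = 30)), 61L)
  expect_equal(nrow(micro_fragment(ann, "g1", k = 30)), 31L)
  frag <- micro_fragment(ann, "g100", k = 0)
  expect_equal(frag$gene_id, "g100")
  expect_error(micro_fragment(ann, "nope"), "unknown anchor")
  # order matches chromosomal order
  f <- micro_fragment(ann, "g50", k = 5)
  expect_equal(f$gene_id, paste0("g", 45:55))
  expect_equal(f$offset, -5:5)
})

test_that("synteny detection enforces the >= 10 pair rule exactly", {
  ann <- dplyr::bind_rows(make_ann(80, "chr1", prefix = "a"),
                          make_ann(80, "chr2", prefix = "b"))
  ann <- sbpmir:::annotate_ranks(ann)
  mk <- function(n) make_hom(paste0("a", 20 + seq_len(n)),
                             paste0("b", 20 + seq_len(n)))
  syn10 <- detect_synteny(ann, mk(10), "a25", "b25")
  expect_equal(syn10$n_support, 10L)
  expect_null(detect_synteny(ann, mk(9), "a25", "b25"))
  expect_null(detect_synteny(ann, mk(10), "a25", "a25"))
})

test_that("synteny detection is symmetric and greedy-matches one-to-one", {
  ann <- dplyr::bind_rows(make_ann(80, "chr1", prefix = "a"),
                          make_ann(80, "chr2", prefix = "b"))
  ann <- sbpmir:::annotate_ranks(ann)
  # one promiscuous gene hits 12 partners; only one pair may count
  hom <- dplyr::bind_rows(
    make_hom(rep("a25", 12), paste0("b", 20:31)),
    make_hom(paste0("a", 30:37), paste0("b", 40:47))
  )
  syn <- detect_synteny(ann, hom, "a25", "b25", min_pairs = 5)
  expect_equal(syn$n_support, 9L)  # 1 (promiscuous) + 8 distinct
  rev <- detect_synteny(ann, hom, "b25", "a25", min_pairs = 5)
  expect_equal(rev$n_support, syn$n_support)
})

test_that("tandem classification follows the intervening-gene rule", {
  ann <- make_ann(10, family = TRUE, group = "g1")
  hom_ab <- make_hom("g1", "g2")
  expect_true(classify_tandem(ann, hom_ab, "g1", "g2"))

  # one intervening non-homologous gene: tandem
  hom_ac <- make_hom("g1", "g3")
  expect_true(classify_tandem(ann, hom_ac, "g1", "g3"))
  # the intervening gene homologous to one of the pair: not tandem
  hom_mid <- dplyr::bind_rows(hom_ac, make_hom("g2", "g3"))
  expect_false(classify_tandem(ann, hom_mid, "g1", "g3"))
  # two intervening genes: never tandem
  expect_false(classify_tandem(ann, make_hom("g1", "g4"), "g1", "g4"))
  # different chromosomes: never tandem
  ann2 <- dplyr::bind_rows(make_ann(5, "chr1", prefix = "x"),
                           make_ann(5, "chr2", prefix = "y"))
  ann2 <- sbpmir:::annotate_ranks(ann2)
  expect_false(classify_tandem(ann2, make_hom("x1", "y1"), "x1", "y1"))
})

test_that("tandem classification agrees with brute force on the study genome", {
  sim <- default_sim()
  ann <- sim$annotation
  hom <- sim$homology
  fam <- ann$gene_id[ann$family]
  pairs <- hom[hom$qseqid %in% fam & hom$sseqid %in% fam &
                 hom$qseqid < hom$sseqid, c("qseqid", "sseqid")]
  pairs <- dplyr::distinct(pairs)
  got <- mapply(function(a, b) classify_tandem(ann, hom, a, b),
                pairs$qseqid, pairs$sseqid)
  want <- mapply(function(a, b) oracle_tandem(ann, hom, a, b),
                 pairs$qseqid, pairs$sseqid)
  expect_equal(unname(got), unname(want))
})

test_that("duplication calling recovers planted events with precedence", {
  sim <- default_sim()
  ev <- call_duplications(sim$annotation, sim$homology)
  tt <- sim$truth$tandem
  for (i in seq_len(nrow(tt))) {
    hit <- ev[(ev$id_a == tt$source_id[i] & ev$id_b == tt$copy_id[i]) |
                (ev$id_a == tt$copy_id[i] & ev$id_b == tt$source_id[i]), ]
    expect_equal(hit$class, "tandem", info = paste("tandem", i))
  }
  # each planted block pair is evidenced by >= 1 segmental family pair
  fam <- sim$annotation$gene_id[sim$annotation$family]
  for (i in seq_len(nrow(sim$truth$segmental))) {
    rp <- sim$truth$segmental$retained_pairs[[i]]
    rp <- rp[rp$source_id %in% fam & rp$copy_id %in% fam, ]
    ok <- mapply(function(a, b) {
      any((ev$id_a == a & ev$id_b == b | ev$id_a == b & ev$id_b == a) &
            ev$class == "segmental")
    }, rp$source_id, rp$copy_id)
    expect_gte(sum(ok), 1)
  }
  expect_equal(nrow(call_duplications(sim$annotation,
                                      sbpmir:::empty_homology_table())),
               0L)
})

test_that("a pair that is both tandem-adjacent and block-supported is tandem", {
  # 15 adjacent homologous pairs across two runs of one chromosome would
  # support synteny, but adjacency must win for the adjacent pair
  ann <- make_ann(100, family = TRUE, group = "g1")
  hom <- make_hom(paste0("g", 30:49), paste0("g", 31:50))
  expect_true(classify_tandem(ann, hom, "g40", "g41"))
  ev <- call_duplications(ann, hom, min_pairs = 5)
  pair <- ev[ev$id_a == "g40" & ev$id_b == "g41", ]
  expect_equal(pair$class, "tandem")
})

test_that("the synteny census counts each pair once per gene", {
  pairs <- tibble::tibble(
    id_a = c("a1", "a2", "a3", "a4", "a5"),
    id_b = c("b1", "b2", "b3", "b4", "a1"),
    group_a = c("g1", "g1", "g1", "g1", "g2"),
    group_b = c("g7", "g7", "g7", "g6", "g2")
  )
  cen <- synteny_census(pairs)
  expect_equal(cen$totals$intra_group, 1L)
  expect_equal(cen$totals$inter_group, 4L)
  g1 <- cen$inter_shares[cen$inter_shares$group == "g1", ]
  expect_equal(g1$share[g1$partner == "g7"], 75)
  expect_equal(g1$share[g1$partner == "g6"], 25)
  expect_equal(sum(g1$share), 100)
  # a1 participates in two syntenies -> incidence 2
  expect_equal(cen$incidence$n_syntenies[cen$incidence$gene_id == "a1"],
               2L)
  # matrix symmetry
  m <- as.matrix(cen$matrix[, -1])
  rownames(m) <- cen$matrix$group
  expect_equal(m, t(m))

  intra_only <- synteny_census(pairs[5, ])
  expect_equal(intra_only$totals$inter_group, 0L)
  expect_equal(nrow(intra_only$inter_shares), 0L)
})

test_that("one-to-many Ks values average within, never across, species", {
  tab <- tibble::tibble(
    gene_id = c("g", "g", "g", "h"),
    partner_species = c("spX", "spX", "spY", "spX"),
    ks = c(1, 2, 2, 0.7)
  )
  agg <- aggregate_ks(tab)
  g <- agg[agg$gene_id == "g", ]
  expect_equal(sort(g$ks), c(1.5, 2))
  expect_equal(nrow(g), 2L)
  expect_equal(agg$ks[agg$gene_id == "h"], 0.7)
})

test_that("Ks binning fractions are per category and NA when empty", {
  bins <- ks_binning(c(0.5, 0.8, 1.5), rep("intra", 3))
  lt <- bins[bins$category == "intra" & bins$bin == "<1.2", ]
  expect_equal(lt$fraction, 2 / 3)
  expect_equal(sum(bins$fraction), 1)

  two <- ks_binning(c(0.5, 2.5, 1.5, 1.9),
                    c("intra", "intra", "inter", "inter"))
  inter <- two[two$category == "inter", ]
  expect_equal(inter$fraction[inter$bin == "[1.2,2)"], 1)
  # constructed all-inter > 1.2 scenario
  old <- ks_binning(c(1.3, 1.8, 2.4), rep("inter", 3))
  expect_equal(sum(old$fraction[old$bin != "<1.2"]), 1)
  expect_equal(old$fraction[old$bin == "<1.2"], 0)

  with_empty <- ks_binning(c(0.5), factor("intra", levels = c("intra",
                                                              "inter")))
  expect_true(all(is.na(
    with_empty$fraction[with_empty$category == "inter"])))
})
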