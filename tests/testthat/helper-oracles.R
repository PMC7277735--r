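# Independent oracles: each re-derives an expected result by brute force
# or exhaustive enumeration, never by calling the implementation path it
# checks.

# Sliding-window Hamming scan, both strands, pure R. Reports every window
# at distance <= max_mismatch for each pattern variant of length >= min_len
# (full mature plus its prefixes/suffixes), without any merging.
oracle_hamming_scan <- function(seq, mature_dna, min_len = 19,
                                max_mismatch = 2) {
  revcomp_chr <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  L0 <- nchar(mature_dna)
  variants <- unique(c(mature_dna, unlist(lapply(
    seq(min_len, max(min_len, L0 - 1)), function(l) {
      if (l >= L0) return(character(0))
      c(substr(mature_dna, 1, l), substr(mature_dna, L0 - l + 1, L0))
    }))))
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  out <- list()
  for (v in variants) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") v else revcomp_chr(v)
      p <- strsplit(pat, "")[[1]]
      L <- length(p)
      if (n < L) next
      mism <- integer(n - L + 1)
      for (k in seq_len(L)) {
        mism <- mism + (s[k:(n - L + k)] != p[k])
      }
      hit <- which(mism <= max_mismatch)
      if (length(hit) > 0) {
        out[[length(out) + 1]] <- data.frame(
          start = hit, end = hit + L - 1L, strand = strand,
          matched_len = L, mismatches = mism[hit]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), matched_len = integer(),
                      mismatches = integer()))
  }
  unique(do.call(rbind, out))
}

# Exhaustive enumeration of all global alignments of a and b with affine
# gap costs; returns the optimal score. Exponential: for test lengths <= 6
# only.
oracle_global_align_score <- function(a, b, submat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, last, score) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, "m", score + submat[av[i], bv[j]])
    }
    if (i <= length(av)) {
      cost <- if (last == "a") gap_extend else gap_open + gap_extend
      rec(i + 1, j, "a", score - cost)
    }
    if (j <= length(bv)) {
      cost <- if (last == "b") gap_extend else gap_open + gap_extend
      rec(i, j + 1, "b", score - cost)
    }
  }
  rec(1, 1, "m", 0)
  best
}

# Independent NG86 per-codon-pair pathway counts: builds every ordering of
# the differing positions by recursive insertion (a different construction
# from the implementation's permutation list), translates with the
# Biostrings genetic code, drops stop-crossing paths and renormalises.
oracle_codon_pair_diffs <- function(c1, c2) {
  translate1 <- function(codon) {
    as.character(Biostrings::GENETIC_CODE[[codon]])
  }
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  orderings <- list(integer(0))
  for (p in pos) {
    orderings <- unlist(lapply(orderings, function(o) {
      lapply(0:length(o), function(at) append(o, p, after = at))
    }), recursive = FALSE)
  }
  orderings <- unique(orderings)
  res <- lapply(orderings, function(ord) {
    cur <- c1; sd <- 0; nd <- 0; crossed_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (translate1(nxt) == "*") crossed_stop <- TRUE
      if (translate1(nxt) == translate1(cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, crossed_stop)
  })
  m <- do.call(rbind, res)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, 1]), nd = mean(m[ok, 2]))
}

# Brute-force tandem check straight from the definition: same chromosome,
# ranks adjacent, or exactly one gene between that is homologous to
# neither.
oracle_tandem <- function(annotation, homology, a, b) {
  ra <- annotation[annotation$gene_id == a, ]
  rb <- annotation[annotation$gene_id == b, ]
  if (ra$chromosome != rb$chromosome) return(FALSE)
  d <- abs(ra$rank - rb$rank)
  if (d == 1) return(TRUE)
  if (d != 2) return(FALSE)
  mid <- annotation$gene_id[annotation$chromosome == ra$chromosome &
                              annotation$rank == min(ra$rank, rb$rank) + 1]
  hom_pairs <- rbind(cbind(homology$qseqid, homology$sseqid),
                     cbind(homology$sseqid, homology$qseqid))
  !any(hom_pairs[, 1] == mid & hom_pairs[, 2] %in% c(a, b))
}

# All-pairs brute-force face-to-face scan straight from the definition.
oracle_face_to_face <- function(annotation, group_a, group_b, max_gap) {
  ga <- annotation[!is.na(annotation$group) & annotation$group == group_a, ]
  gb <- annotation[!is.na(annotation$group) & annotation$group == group_b, ]
  found <- character(0)
  for (i in seq_len(nrow(ga))) for (j in seq_len(nrow(gb))) {
    A <- ga[i, ]; B <- gb[j, ]
    if (A$chromosome != B$chromosome) next
    left <- if (A$start <= B$start) A else B
    right <- if (A$start <= B$start) B else A
    if (left$end >= right$start) next
    if (left$strand == "+" && right$strand == "-" &&
        right$start - left$end - 1 < max_gap) {
      found <- c(found, paste(left$gene_id, right$gene_id))
    }
  }
  sort(unique(found))
}

# Exact hypergeometric upper tail by direct combinatorial summation.
oracle_hyper_upper <- function(overlap, annotated, universe, selected) {
  ks <- overlap:min(annotated, selected)
  sum(choose(annotated, ks) * choose(universe - annotated, selected - ks)) /
    choose(universe, selected)
}

# Small annotation builder: equally spaced, non-overlapping genes.
make_ann <- function(n, chromosome = "chr1", len = 100L, gap = 50L,
                     strand = "+", family = FALSE, group = NA_character_,
                     prefix = "g") {
  starts <- (seq_len(n) - 1L) * (len + gap) + gap + 1L
  tibble::tibble(
    gene_id = paste0(prefix, seq_len(n)), chromosome = chromosome,
    start = starts, end = starts + len - 1L,
    strand = rep_len(strand, n), family = rep_len(family, n),
    group = rep_len(group, n), species = "synthetic",
    rank = seq_len(n)
  )
}

# Minimal homology rows connecting the given id pairs.
make_hom <- function(ids_a, ids_b, bitscore = 500) {
  n <- length(ids_a)
  tibble::tibble(
    qseqid = ids_a, sseqid = ids_b, pident = 95, length = 100L,
    mismatch = 5L, gapopen = 0L, qstart = 1L, qend = 100L, sstart = 1L,
    send = 100L, evalue = 1e-50, bitscore = rep_len(bitscore, n),
    self_hit = ids_a == ids_b
  )
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E", "F", "G",
                                           "H", "I", "K", "L", "M", "N",
                                           "P", "Q", "R", "S", "T", "V",
                                           "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
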