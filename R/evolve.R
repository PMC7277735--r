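# Controlled coding-sequence divergence for the simulator: applies a
# computed number of synonymous and nonsynonymous single-nucleotide
# substitutions (at most one per codon, never creating a stop) so that the
# expected NG86 estimates recover the requested Ka/Ks targets.

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

codon_neighbours <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      out <- c(out, alt)
    }
  }
  out
}

syn_neighbours <- function(codon) {
  nb <- codon_neighbours(codon)
  nb[GENETIC_CODE_DNA[nb] == GENETIC_CODE_DNA[[codon]] &
       GENETIC_CODE_DNA[nb] != "*"]
}

nonsyn_neighbours <- function(codon) {
  nb <- codon_neighbours(codon)
  nb[GENETIC_CODE_DNA[nb] != GENETIC_CODE_DNA[[codon]] &
       GENETIC_CODE_DNA[nb] != "*"]
}

# Inverse Jukes-Cantor: expected observed proportion for a target distance.
jc_proportion <- function(d) 3 / 4 * (1 - exp(-4 / 3 * d))

#' Diverge a coding sequence toward target Ka/Ks
#'
#' Produces a mutated copy of `cds` whose NG86 comparison against the
#' original recovers `target_ks` and `target_ka` in expectation. The number
#' of synonymous (nonsynonymous) substitutions is the Jukes-Cantor-inverted
#' proportion times the sequence's synonymous (nonsynonymous) site count;
#' substitutions are placed at distinct codons (one per codon, so observed
#' difference counts are exact), drawn uniformly among the codon's
#' synonymous (nonsynonymous) non-stop single-nucleotide neighbours. The
#' reading frame is preserved and no stop codons are ever introduced.
#'
#' @param cds Coding sequence, length divisible by 3, no internal stops.
#' @param target_ks,target_ka Target synonymous / nonsynonymous divergence
#'   (substitutions per site, Jukes-Cantor corrected scale).
#' @param seed Integer seed; the same seed reproduces the same output. The
#'   caller's RNG state is left untouched.
#' @return The mutated CDS (single string).
#' @export
evolve_cds <- function(cds, target_ks, target_ka = 0, seed = 1L) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length not divisible by 3", call. = FALSE)
  }
  codons <- split_codons(cds)
  if (any(GENETIC_CODE_DNA[codons] == "*")) {
    stop("internal stop codon in CDS", call. = FALSE)
  }
  if (target_ks < 0 || target_ka < 0) {
    stop("divergence targets must be >= 0", call. = FALSE)
  }
  if (target_ks == 0 && target_ka == 0) return(cds)
  S <- sum(vapply(codons, codon_syn_sites, numeric(1)))
  N <- 3 * length(codons) - S
  sd_needed <- round(jc_proportion(target_ks) * S)
  nd_needed <- round(jc_proportion(target_ka) * N)
  with_seed_local(seed, {
    syn_ok <- which(vapply(codons, function(x)
      length(syn_neighbours(x)) > 0, logical(1)))
    if (sd_needed > length(syn_ok)) {
      stop("unreachable target_ks: ", sd_needed,
           " synonymous substitutions needed but only ", length(syn_ok),
           " codons have synonymous neighbours (saturation)",
           call. = FALSE)
    }
    syn_pick <- if (sd_needed > 0) {
      syn_ok[sample.int(length(syn_ok), sd_needed)]
    } else integer(0)
    for (i in syn_pick) {
      nb <- syn_neighbours(codons[i])
      codons[i] <- nb[sample.int(length(nb), 1)]
    }
    nonsyn_ok <- setdiff(which(vapply(codons, function(x)
      length(nonsyn_neighbours(x)) > 0, logical(1))), syn_pick)
    if (nd_needed > length(nonsyn_ok)) {
      stop("unreachable target_ka: ", nd_needed,
           " nonsynonymous substitutions needed but only ",
           length(nonsyn_ok), " untouched codons available (saturation)",
           call. = FALSE)
    }
    ns_pick <- if (nd_needed > 0) {
      nonsyn_ok[sample.int(length(nonsyn_ok), nd_needed)]
    } else integer(0)
    for (i in ns_pick) {
      nb <- nonsyn_neighbours(codons[i])
      codons[i] <- nb[sample.int(length(nb), 1)]
    }
    paste(codons, collapse = "")
  })
}
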