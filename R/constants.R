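# Domain constants: genetic code, amino-acid masses, pKa values, and the
# synthetic SBP-like domain consensus used by the simulator and the PSSM
# examples. Kept as plain R objects (no binary data files).

# Standard genetic code, DNA alphabet, "*" = stop.
GENETIC_CODE_DNA <- {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- chartr("U", "T", names(Biostrings::GENETIC_CODE))
  gc
}

SENSE_CODONS <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA != "*"]
STOP_CODONS  <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA == "*"]

DNA_BASES <- c("A", "C", "G", "T")

AMINO_ACIDS <- sort(unique(GENETIC_CODE_DNA[GENETIC_CODE_DNA != "*"]))

# Average (not monoisotopic) residue masses in Da; water added once per chain.
RESIDUE_MASS_AVG <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
WATER_MASS_AVG <- 18.01524

# Bjellqvist-style pKa values (the set popularised by the ExPASy tools).
PKA_SET <- list(
  n_term = 7.50, c_term = 3.55,
  side = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00, H = 5.98,
           K = 10.00, R = 12.00)
)

# Synthetic 76-aa SBP-like domain consensus (zinc-finger-sized). This is an
# invented stand-in for a curated domain profile: the simulator plants
# diverged copies of it into family proteins and build_pssm() can recover a
# scoring model from those instances. It is NOT a curated database profile.
SBP_DOMAIN_CONSENSUS <- paste0(
  "CQVEGCRADLSKAKQYHRRHKVCEFHSKASTVVAAGLSQRFCQQCSRFHLLSEFDEGKRSCRKRLADHNRRRRK",
  "P"
)

# Canonical plant mature miR156 (20 nt, RNA). Used as the default reference
# mature sequence by the simulator; users supply their own FASTA for real data.
MIR156_MATURE_DEFAULT <- c(mir156_ref = "UGACAGAAGAGAGUGAGCAC")

rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                     if.fuzzy.codon = "error"))
}

split_codons <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3 == 0)
  substring(cds, seq(1, n, by = 3), seq(3, n, by = 3))
}
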