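---
title: "Models and methods behind sbpmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sbpmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbpmir)
```

`sbpmir` studies the expansion of the plant SBP-box (SPL) gene family and
its coevolution with miR156 through microsynteny. This vignette is the
package's own account of the models it implements, the parameters that
matter, the numerical choices behind them, and what the synthetic
test-bench does and does not establish about real data.

## The micro-fragment synteny model

The unit of comparison is the *micro-fragment*: an anchor gene with up to
`k = 30` coding genes on each side in chromosomal order, truncated at
chromosome ends, so a window of at most `2k + 1 = 61` genes
(`micro_fragment()`). Two fragments are called syntenic
(`detect_synteny()`) when they share at least `min_pairs = 10` distinct
homologous gene pairs at stringent similarity (homology rows are
pre-filtered at E ≤ 1e-10 by `read_homology_table()`). Within one genome a
syntenic fragment pair evidences segmental duplication; between genomes,
shared ancestry — one code path serves both, with a `same_chromosome`
flag.

Three decisions deserve note:

* **Support counting is a one-to-one greedy matching** by descending bit
  score: a single promiscuous gene can contribute at most one supporting
  pair, and a gene is used at most once across both fragments. Without
  this, one multi-copy family could satisfy the threshold on its own.
* **Support pairs may come from any gene family.** Restricting support to
  the focal family is available (`strict_family = TRUE`) but is not the
  default, matching standard collinearity practice where the background
  genes carry the signal.
* **Collinear order is not required.** The rule is a co-occurrence count,
  not MCScanX-style chaining; this makes the detector more permissive for
  rearranged blocks and is deliberately simpler to reason about and to
  test.

Duplicated family pairs are classified by `call_duplications()` with
*tandem* taking precedence: two paralogs on the same chromosome, adjacent
or separated by exactly one gene that is homologous to neither, are
tandem; otherwise a pair whose fragments are syntenic is segmental;
everything else is reported `unclassified` and excluded from event
counts. Precedence matters because the definitions are not mutually
exclusive — a tandem pair inside a duplicated block satisfies both.

## Ka/Ks estimation and Ks binning

Divergence dating uses the Nei–Gojobori (1986) estimator (`ng86()`) on
codon alignments threaded from protein alignments (`codon_align()`,
`global_align()`; BLOSUM62, gap open 11, extend 1 — the conventional
protein-search defaults). Synonymous site counts are per-codon fractions
(mutations to stop codons count as nonsynonymous, denominator 3),
averaged over the two sequences. Difference counts average all minimal
mutational pathways per codon pair with equal weights; pathways through a
stop codon are removed and the weights renormalised (if every pathway
crosses a stop, all are used — a documented fallback that keeps the pair
informative). Both proportions receive the Jukes–Cantor correction
`d = -3/4 log(1 - 4/3 p)`; a proportion at or beyond 3/4 raises a
saturation error rather than returning a number.

A model-averaged estimator would differ in the third decimal for the
divergences simulated here; the downstream analyses depend only on coarse
Ks bins with edges at 1.2 and 2.0 (`ks_binning()`), which NG86 resolves
comfortably (the test-bench recovers targets 0.3/0.5/1.0 to within
±0.01 on average at 300 codons). Bins are left-closed (`< 1.2` means
strictly less); an empty category reports `NA` fractions, never 0.

Genes in synteny with several partners aggregate their Ks values by
`aggregate_ks()`: values sharing a partner species are averaged into one;
values from different species are never averaged — each species keeps its
own entry.

## miR156 prediction

`mature_scan()` is an exhaustive ungapped Hamming scan of both genome
strands for each reference mature sequence and every prefix/suffix of at
least 19 nt, reporting windows within 2 mismatches (the "longer than
18 nt, fewer than three mismatches" rule). Exhaustive scanning is exact
and fast at these scales; gapped matches are intentionally out of scope —
the mismatch rule is ungapped in spirit, and indel-tolerant matching
would change the meaning of "mismatch".

Precursor candidates attach 200 nt of context on each side, truncated at
sequence ends (`extract_precursor()`), and are removed if the mature hit
overlaps any annotated gene by ≥ 1 nt (`coding_filter()`; the overlap
quantum is a choice — one shared nucleotide is already incompatible with
an independent miRNA precursor).

Hairpin evaluation folds the precursor by base-pair maximisation
(`fold_hairpin()`: Nussinov dynamic programme in C++, canonical pairs
plus G:U, minimum hairpin loop 3). This is a combinatorial substitute for
thermodynamic folding: it maximises pair counts, not stability, and on
long random flanks it will pair much of the sequence. The pass criteria
(`hairpin_eval()`, all configurable because conventional rather than
canonical) are therefore phrased on the mature span: the mature must lie
on one arm (no self-pairing, all partners on one side — a mature across
the terminal loop fails), at least 14 of its positions must be paired, at
most 6 unpaired, and at most one *internal loop* — an unpaired run of
≥ 2 nt strictly inside the span. Single-nucleotide bulges do not count as
loops; counting them would contradict the 6-mismatch allowance, since any
scattered mismatches would then fail the loop rule first.

Target sites are scored by `target_scan()` with the declared penalty
scheme: mismatch 1.0, G:U wobble 0.5, penalties doubled at mature
positions 2–13, expectation = penalty sum, sites kept at expectation
≤ 5.0. The scan is ungapped; the gap penalty (2.0) is defined but gapped
duplexes are not searched.

## Co-location, miR156–SBP synteny and the face-to-face origin model

A miR156 hit *co-locates* with an SBP gene when the hit interval lies
inside the genomic span of that gene's micro-fragment (`co_location()`).
`mir_sbp_synteny()` anchors a fragment on the miRNA position itself (the
nearest ≤ 30 genes each side) and applies the same ≥ 10-pair rule against
every SBP fragment, after removing co-locations — co-located pairs would
trivially share their own neighbourhood.

The origin model is tested by `face_to_face_scan()`: two genes from the
designated groups (defaults g1 and g6), same chromosome, opposite strands
with 3′ ends facing (plus-strand gene entirely upstream of the
minus-strand gene) across an intergenic gap strictly below 8000 nt. The
gap is measured between gene bodies (`downstream start − upstream end −
1`) — the most conservative reading of "separated by less than 8000
nucleotides", which the source material does not define further. The
intergenic region is returned as the candidate hairpin substrate.

## Identification and profiling surrogates

Family identification uses a position-specific scoring matrix
(`build_pssm()`/`scan_domain()`): log-odds over a uniform background with
additive pseudocounts, best ungapped window, membership decided by a
threshold calibrated on known positives and negatives (default: half the
consensus self-score, which cleanly separates planted instances from
random sequence at domain length ~76). The package ships a *synthetic*
76-residue domain consensus used by the generator and the examples; it is
an invented stand-in, not a curated database profile, and real analyses
should build the PSSM from their own curated instances. Group labels are
assigned by best global-alignment score against labelled references
(`assign_group()`); exact ties between different labels are surfaced as
ambiguous, never broken silently, because group identity feeds every
census downstream.

Protein characterisation (`protein_properties()`) sums average residue
masses plus one water for the molecular weight and finds the isoelectric
point by bisection (tolerance 1e-4 pH) on the Henderson–Hasselbalch net
charge with a Bjellqvist-style pKa set (N-term 7.5, C-term 3.55; D 4.05,
E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0), pinned as package
constants.

Upstream regulatory regions are the −2000..−100 window relative to the
gene 5′ end (the annotation carries no separate TSS feature), strand
reflected and truncated at chromosome ends (`extract_upstream()`).
Over-representation (`enrich_terms()`) is the exact hypergeometric upper
tail with Benjamini–Hochberg adjustment, on any user-supplied term→gene
map; a minimum-support filter drops thin terms before testing.
Stress-response counting (`stress_response_count()`) uses the symmetric
two-fold rule with both boundaries inclusive (ratio ≥ 2 or ≤ 0.5); a
zero control with non-zero treatment counts as responsive, zero/zero does
not. The visualisation transform is pinned to `log2(x + 1)`.

## The synthetic test-bench

`simulate_genome()` builds multi-chromosome genomes in which every event
the pipeline should find is planted and ledgered: tandem duplications
(copy adjacent or behind one fresh spacer gene, CDS diverged to a target
Ks by `evolve_cds()`), segmental blocks (61 genes re-inserted elsewhere
with an evenly spread ⌈retention × 61⌉ subset of diverged homolog pairs,
the remainder replaced by fresh genes), miR156 loci (exact and mutated
copies, both strands, inside and outside coding genes, with or without a
planted inverted-repeat hairpin context), and convergent face-to-face
pairs at exact intergenic gaps.

The default configuration is the standard study genome used by the tests
and the acceptance script: 2 chromosomes × 300 genes (~900 nt genes,
~600 nt gaps), 5 tandem events alternating 0/1 intervening genes, 3
segmental blocks at retention 0.25 with Ks targets 0.3/0.5/1.0, 6 miR156
loci of which two are designed negatives (one at 3 mismatches, one inside
a coding gene) and one positive sits inside a segmental block so the
miR156–SBP synteny path is observable, and 3 face-to-face pairs at gaps
4000/6000/8000 nt (the last a boundary negative for the strict `< 8000`
rule). Problem sizes were chosen so the full pipeline runs in seconds to
a couple of minutes on one CPU while every detector still sees a
non-trivial search space.

Choices worth spelling out:

* **Family density.** 3% of genes carry family/group labels (~24 in the
  default genome). Family members all share the planted domain, so the
  intra-family homology graph is complete at E ≤ 1e-10 — exactly as a
  protein search behaves on a real gene family. The ≥ 10-pair synteny
  rule then owes its specificity to family *sparsity*: micro-fragments
  must typically hold far fewer than 10 family genes. Real densities are
  of order 10⁻³ (a few hundred family members in genomes of tens of
  thousands of genes); 3% is still orders of magnitude denser, the
  minimum needed to plant events, and low enough that a 61-gene window
  essentially never collects 10 family members.
* **Divergence targeting.** `evolve_cds()` inverts the Jukes–Cantor
  correction to an expected observed proportion, applies that many
  synonymous (or nonsynonymous) single-nucleotide substitutions at
  distinct codons (one per codon, never creating a stop), so observed
  difference counts are exact and NG86 recovers the targets in
  expectation. Multiple hits per codon, transition/transversion bias and
  rate heterogeneity are deliberately absent.
* **Designed negatives are designed.** A 3-mismatch locus draws its
  mismatch positions from the intersection of every reportable scan
  window, so no 19-nt sub-window of it can slip under the 2-mismatch
  bound; planted hairpin cassettes carry a slightly imperfect star arm
  (≥ 3 substitutions inside the mature image) so the star side is never
  itself reported as a locus.
* **Determinism.** One master seed drives the whole genome; per-event
  child seeds are recorded in the truth ledger, and the caller's RNG
  state is restored. Identical configurations are byte-identical, which
  the suite asserts.

The truth ledger (`truth.json` via `write_simulation()`) holds one record
per planted event: tandem `(source_id, copy_id, intervening, target_ks)`,
segmental `(source_ids, copy_ids, retained_pairs, target_ks)`, miR156
`(chromosome, start, end, strand, mismatches, inside_coding, hairpin,
designed_positive)`, face-to-face `(id_plus, id_minus, gap,
boundary_negative)`, plus the child seeds.

What passing the synthetic suite shows: every rule fires exactly at its
stated boundary, the detectors recover what was planted and reject what
was planted to fail, and the estimators recover their parameters. What it
does not show: behaviour under intron/exon structure, indels,
annotation errors, assembly gaps, repeat-induced spurious homology, or
real miRNA biogenesis — genes here are single-exon coding spans and
folding is combinatorial. Conclusions about real genomes still require
real homology searches and curated annotations as inputs.

## Degenerate inputs and tie-breaking

Readers reject structural violations (duplicate ids, `end < start`,
unknown strand, malformed rows) with the offending record or line rather
than repairing them; every filtering step logs input and output counts
with the rule applied. `ng86()` flags a zero-Ks ratio as undefined rather
than dividing; `ks_binning()` reports empty categories as `NA`;
`assign_group()` surfaces exact score ties; the Nussinov traceback uses a
fixed deterministic tie-break (pairing preferred, bifurcation checked
last) so dot-brackets are reproducible; `detect_synteny()` never compares
a fragment to itself, and overlapping same-chromosome fragments are
allowed only when anchors differ.

## Session info

```{r}
sessionInfo()
```
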