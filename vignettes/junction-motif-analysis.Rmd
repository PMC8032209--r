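---
title: "Back-splice junction motifs, genetic constraint, and circRNA exon bounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Back-splice junction motifs, genetic constraint, and circRNA exon bounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circmotif)
```

## The problem

Back-splicing joins the donor (3') end of a downstream exon to the acceptor
(5') end of an upstream exon, producing a covalently closed circular RNA.
The junction point of such a circle is flanked by a sequence that exists in
no linear transcript: the suffix of the donor exon followed by the prefix
of the acceptor exon. If that chimeric neighbourhood happens to form a
protein-binding motif, the motif is *created by circularization* — it
cannot be found by scanning the genome or the mRNA, and it disappears when
the circle does. This package implements the computational side of that
argument for a TTN-like locus whose I-band region produces a class of
RBM20-dependent circRNAs:

1. **Junction sequences** (`build_bsj_sequence`, `build_lj_sequences`):
   fixed windows around back-splice junctions (BSJ) and ordinary linear
   junctions (LJ), in transcript orientation, with the junction offset
   marked.
2. **Consensus discovery** (`discover_consensus`): the shared
   junction-spanning k-mer of a circRNA class, by exhaustive exact k-mer
   voting.
3. **Motif enrichment** (`enrichment_compare`, `run_standard_comparisons`):
   IUPAC presence of RBP motifs compared between sequence classes with
   two-sided Fisher exact tests and Benjamini–Hochberg adjustment.
4. **Genetic constraint** (`expected_variants`, `oe_with_ci`,
   `constraint_report`): observed vs expected rare variants under a
   trinucleotide-context neutral mutation model with methylation strata,
   sequencing-depth correction and calibration on synonymous sites.
5. **Isoform bounds** (`bounds_from_inclusion`): upper and lower bounds on
   the exon content of a large circRNA from a per-sample exon-inclusion
   matrix.
6. **Synthetic data** (`synth_config`, `generate_dataset`): a generator
   that produces all inputs with the statistical structure the analysis
   assumes, so the whole pipeline runs and is tested without downloads.

## Coordinate and orientation conventions

All coordinates are 1-based inclusive (the GTF/VCF convention); BED12 input
is converted at the boundary. Exons are numbered 1..N in transcript
(5'→3') order, so exon 1 of a minus-strand transcript is the exon with the
highest genomic coordinates. A circle is written as the exon-number
interval `[acceptor_exon, donor_exon]` with acceptor ≤ donor — the focal
circle here joins exon 145 (donor) back to exon 79 (acceptor), spanning 67
exons. Junction and motif sequences are always expressed in transcript
orientation because the motif is an RNA-level object; `junction_interval_to_genomic`
maps occurrences back to genomic sites through the exon model. Where the
field describes back-splicing with the opposite donor/acceptor vocabulary,
we follow the convention implied by the exon-145-to-exon-79 circle: the
donor is the 3'-most exon of the circle.

## Junction windows

`w = 25` bases are taken from each side of the junction (configurable).
There is no canonical window width; the only hard requirement is
`w ≥ k_max − 1` so that a junction-spanning occurrence of the longest
candidate motif fits, and 25 leaves ample margin over an 8-nt motif.
Exons shorter than `w` clamp the window to the exon — the window never
walks across another splice junction, which keeps BSJ and LJ sequences
independent of the circle-internal splicing that short-read data cannot
resolve. Occurrences are reported at every position (overlaps included);
presence/absence per sequence is derived downstream where enrichment needs
it.

## Consensus discovery

The discovered object is a single ungapped k-mer, so discovery is
exhaustive and exact rather than an EM-style motif search: over all
k in `[k_min, k_max]` (defaults 5..12) and every exact k-mer that spans the
junction in at least `min_prevalence` of the class sequences (default 0.5,
which recovers a 70%-prevalent motif with margin), the winner maximizes
prevalence, ties broken toward larger k, then lexicographically. The
larger-k tie-break matters: every substring of a junction-spanning motif
that still crosses the junction has at least the motif's prevalence, so
without it discovery would return an arbitrary short fragment. Results are
invariant to input order by construction.

## Enrichment comparisons

Five standard comparisons are run: BSJ sequences of RBM20-dependent vs
-independent circRNAs; BSJ sequences of TTN-hosted vs other circRNAs; full
circRNA sequences of TTN vs other circRNAs; TTN circRNA sequences vs the
linear TTN mRNA; and TTN exons included in at least one circRNA vs exons in
none. Each motif contributes one 2×2 presence table, a two-sided Fisher
exact p, a sample odds ratio (Haldane–Anscombe 0.5 correction when a cell
is zero, so reported ORs are finite), and a BH q computed within the
comparison — comparisons are not pooled, mirroring per-panel reporting.
For the circRNA-vs-mRNA comparison the two sets have very different
lengths, so presence is computed on non-overlapping 500-nt tiles (trailing
remainders of at least half a tile are kept) and the table counts tiles;
without this, sequence length confounds presence. The exon comparison uses
whole exons as units, which are comparable in length.

## The constraint model

Rare variants are those with allele frequency strictly below 0.1%
(`allele_count/allele_number < 0.001`, AC ≥ 1); only single-nucleotide
substitutions enter the model, because the neutral context model is defined
for substitutions. The expected count for a site class is

    E = λ · Σ_sites Σ_alts  μ(context, ref→alt, methyl bin) · f(depth)

* **μ** comes from a strand-collapsed trinucleotide table keyed by
  (left, ref, alt, right, methylation bin); a key and its reverse
  complement share one rate. CpG sites carry bins 0/1/2 (none, partial,
  high methylation); all other sites use bin 0, and non-zero bins are only
  legal on CpG keys.
* **f(depth)** corrects for under-calling at low coverage:
  `f = min(1, a + b·ln d)` below `d0 = 30` and 1 at or above it. The
  coefficients are not taken from elsewhere; `fit_depth_model` refits them
  by least squares of binned observed/expected (normalized by the
  full-coverage ratio) against ln depth on calibration sites.
* **λ** is calibrated so that the synonymous class — assumed under minimal
  selection — has observed/expected exactly 1 on the calibration set
  (`calibrate_lambda`).

The o/e ratio is reported with an exact Poisson 90% interval in the
chi-square quantile form, `[χ²(0.05, 2·obs), χ²(0.95, 2·obs+2)] / (2·E)`,
treating the expectation as fixed. This is the standard interval for
observed/expected summaries and its endpoints are checkable against direct
numeric inversion of the Poisson tails. Being an exact interval it is
conservative: its realized coverage sits above the nominal level rather
than at it, which is the usual price of guaranteed-level Poisson intervals.
Classes whose upper bound falls below 1 are flagged as constrained.

Site classes for the motif follow its formation context: LJ-created
(all, and split by whether both flanking exons are included in or excluded
from circRNAs; junctions whose two exons disagree count only toward the
"all" class), BSJ-created (only the genomic sites of the two exon-resident
halves — the junction itself has no genomic locus), and within-exon.
Validation classes (synonymous/missense/truncating) come from exhaustive
codon translation of every exonic (site, alt) pair, with the spliced
transcript treated as the CDS; stop-loss is folded into missense.

## What the generator emulates — and what it does not

`synth_config()` defaults encode the study conditions: 363 exons, circ
region exons 79–145, 63 dependent junctions of which 44 carry the motif
(44/63 = 69.8%, rounding to the reported 70%), 200 independent junctions
with 3 carriers, motif `AAAGAACC` split 4 donor-side + 4 acceptor-side
bases, allele number 251,496 (2 × 125,748 exomes), log-normal median
depths (meanlog ln 40, sdlog 0.5, truncated at 1), and a 3-sample
inclusion matrix with exactly 9 never-included and 35 always-detected
exons over the focal 67-exon span. The 63/200 class sizes are a design
choice: the printed prevalence (70%) and carrier counts (44 and 3) do not
determine the denominators, and 63/200 realizes all three simultaneously.
The motif's donor/acceptor split is likewise not printed anywhere, so the
symmetric 4+4 default is configurable.

Carrier motifs are written into the genome by overwriting bases (never
inserting — annotation coordinates stay immutable). Non-carrier junctions
are rejection-sampled so that no ≥5-nt substring of the motif spans their
junction; this makes the manifest exact ground truth (exactly 44 and 3
junction-spanning carriers, and no shorter motif fragment can outvote the
planted 8-mer at discovery). LJ-created and within-exon motif copies are
planted as well (6 included-region LJs, 6 excluded-region LJs, 10 exon
bodies) so every formation context of the constraint analysis is
populated. Selection is emulated by binomial thinning of per-site Poisson
mutation counts (defaults: BSJ motif sites s = 0.5, within-exon motif
sites s = 0.7, truncating sites s = 0.2, everything else neutral).

What the generator does **not** emulate: real mutation-rate heterogeneity
beyond the transition/transversion and CpG-methylation structure (the
shipped rate table is fixture-grade — transitions 3× transversions,
partially/highly methylated CpG transitions 4×/10×); linkage, recurrence
and population structure of real cohorts; reads, assembly and the
uncertainty of circRNA internal splicing; and any sequence realism of the
locus (exon/intron lengths are uniform draws). Passing tests therefore
demonstrate that the pipeline's logic and statistics are correct and that
planted effects are recovered at the designed sizes — not that real data
would yield these numbers.

## Numerical choices and degenerate inputs

Patterns longer than their subject yield an empty occurrence list, not an
error. A discovery run in which nothing reaches `min_prevalence` returns
an empty result with a diagnostic string. Classes with no sites are
reported with observed 0 and undefined (NA) ratio rather than failing the
whole report. Calibration with zero observed variants on the calibration
class is an error — there is nothing to anchor the model to. Sites whose
trinucleotide context contains N are rejected, as are variants with
ref = alt, AC > AN, or missing depth. All generators are deterministic
under the configured seed, including the rejection-sampling paths.

## Problem sizes in the test suite

The suite regenerates everything in code: the default dataset (one ~370 kb
contig, 41 transcripts, 263 junctions) once per run, plus smaller designed
genomes (3–70 kb) for the statistical property checks — Fisher p against
full hypergeometric enumeration on all 2×2 tables with total ≤ 30, CI
endpoints against tail inversion, thinning recovery over 50 seeded
simulations, calibration neutrality over 20, and the 576-case codon
oracle. These sizes were chosen so properties are tested at tight
tolerances while the whole suite stays desk-scale.

## Known limitations

One transcript per gene; the TTN-like exon numbering is the single
coordinate authority. Indels and structural variants are out of scope.
Motif scanning is IUPAC presence, not PWM scoring, and no RNA secondary
structure weighting is applied. The isoform bounds deliberately cannot
distinguish inter-sample variability caused by different back-splicing
from variability caused by internal linear splicing — both simply widen
the gap between the bounds.
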