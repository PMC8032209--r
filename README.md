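# circmotif

Analysis of sequence motifs **created by back-splicing** in circular RNAs,
with the supporting population-genetic and isoform-composition analyses,
for a TTN-like locus whose I-band region produces RBM20-dependent
circRNAs.

When a circRNA forms, the donor (3') end of a downstream exon is joined to
the acceptor (5') end of an upstream exon. The sequence flanking that
back-splice junction (BSJ) — donor-exon suffix followed by acceptor-exon
prefix — exists only in the circular molecule. This package asks, and
answers on fully synthetic data, the questions that argument raises:

* Do the BSJs of a circRNA class share a junction-spanning consensus, and
  at what prevalence? (exhaustive k-mer voting over the junction windows)
* Is that motif enriched in one sequence class over another? (per-motif
  2×2 presence tables, two-sided Fisher exact test, sample odds ratio with
  Haldane–Anscombe correction, Benjamini–Hochberg adjustment per
  comparison)
* Are the genomic sites that form the motif under genetic constraint?
  The observed number of rare variants (allele frequency < 0.1%) is
  compared with the expectation under a neutral mutation model:

      E = λ · Σ_sites Σ_alts μ(trinucleotide context, ref→alt, methylation bin) · f(depth)

  with `f(d) = min(1, a + b·ln d)` below a full-coverage depth threshold
  (coefficients refit on calibration sites), λ calibrated so synonymous
  sites have o/e = 1, and the o/e ratio reported with an exact Poisson 90%
  CI, `[χ²(0.05, 2·obs), χ²(0.95, 2·obs + 2)]/(2E)`.
* How large can a circRNA spanning exons 79–145 be? From a per-sample
  exon-inclusion matrix: exons detected in no sample bound the content
  from above, exons detected in every sample bound it from below.

The synthetic-data module is first-class, tested code: it generates the
genome, annotation, junction classes (with the 8-nt motif `AAAGAACC`
planted across the BSJs of a configurable carrier fraction), methylation
track, mutation-rate table, rare variants with class-specific selection
thinning, and the exon-inclusion matrix — so every stage runs with no
external downloads.

## Worked example

The analysis is organised as numbered driver scripts over the package
functions:

```sh
Rscript analysis/01_simulate.R         # genome, annotation, junctions, tracks
Rscript analysis/02_junction_motifs.R  # BSJ windows + consensus discovery
Rscript analysis/03_enrichment.R       # RBP motif enrichment comparisons
Rscript analysis/04_constraint.R       # observed/expected rare variants
Rscript analysis/05_isoform_bounds.R   # exon bounds of the focal circRNA
```

With the default configuration (seed 42) this prints, among other things:

```
<consensus_result> AAAGAACC (k=8) prevalence 69.8% (44/63 carriers)
consensus forms the BSJ of 44/63 TTN and 3/200 non-TTN circRNAs
dependent-class prevalence: 70%
```

— the RBM20-dependent class shares an 8-nt junction-spanning consensus at
70% prevalence, formed by 44 TTN-hosted circRNAs and only 3 others —

```
              label observed expected    oe ci90_low ci90_high constrained_flag
1      motif_lj_all        9     9.06 0.994    0.518     1.734            FALSE
4         motif_bsj       11    14.24 0.773    0.433     1.279            FALSE
6          missense     3179  3214.74 0.989    0.960     1.018            FALSE
7        synonymous     1390  1390.00 1.000    0.956     1.045            FALSE
8        truncating       35   173.58 0.202    0.149     0.267             TRUE
```

— sites where the motif is formed by ordinary linear splicing are neutral
(o/e ≈ 1), BSJ-forming sites trend below 1 under the configured selection
thinning, the synonymous calibration class is exactly 1 by construction,
and truncating sites are strongly constrained —

```
<bounds_result> span 67 exons | never included 9 | always detected 35
  => 35 to 58 exons (5823 to 10250 nt)
```

— the focal circle (exon 145 back-spliced to exon 79) spans 67 exons, of
which 9 are never detected and 35 are detected in all samples, bounding
the isoform at 35 to 58 exons.

The same computations are available directly:

```r
library(circmotif)
ds <- generate_dataset(synth_config(seed = 42))
run_motif_stage(ds)                       # consensus + carrier counts
bounds_from_inclusion(ds$focal, ds$inclusion, ds$models$TTN)
```

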