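#!/usr/bin/env Rscript

# Stage 3 — RBP motif enrichment across circRNA sequence classes.
#
# Scans the ATtRACT-like motif table against five sequence-set comparisons
# (BSJ dependent vs independent; BSJ TTN vs other; full circRNA TTN vs
# other; TTN circRNA tiles vs linear mRNA tiles; TTN exons included vs
# excluded from circRNAs), testing per-motif presence with a two-sided
# Fisher exact test and BH adjustment within each comparison.
#
# Usage: Rscript analysis/03_enrichment.R [--data results/synthetic_data]

suppressPackageStartupMessages({library(optparse); library(circmotif)})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--data", type = "character", default = "results/synthetic_data"),
  make_option("--out", type = "character", default = "results/enrichment")
)))

genome <- read_genome(file.path(opts$data, "genome.fa"))
models <- read_exon_annotation(file.path(opts$data, "annotation.gtf"), "gtf")
jx <- read_junctions(file.path(opts$data, "junctions.tsv"))
motifs <- read_motif_table(file.path(opts$data, "motifs.tsv"))

cmp <- run_standard_comparisons(genome, models, jx, motifs)
dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
for (nm in names(cmp)) {
  if (is.null(cmp[[nm]])) next
  write_enrichment(cmp[[nm]], file.path(opts$out, paste0(nm, ".tsv")))
  top <- cmp[[nm]][1, ]
  cat(sprintf("%-32s top hit %s (%s): OR %.2f, q = %.3g\n", nm,
              top$motif_id, top$rbp_name, top$odds_ratio, top$q_value))
}
cat(sprintf("wrote %s/*.tsv\n", opts$out))
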