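#!/usr/bin/env Rscript

# Stage 1 — simulate the study's inputs.
#
# Generates a TTN-like locus (363 exons, circRNA-producing region exons
# 79-145), the two circRNA classes (63 RBM20-dependent junctions with the
# AAAGAACC motif planted across 44 back-splice junctions; 200 independent
# junctions on background genes with 3 carriers), a CpG methylation track,
# a trinucleotide mutation-rate table, an ATtRACT-like RBP motif table and
# the 3-sample exon-inclusion matrix for the focal 67-exon circRNA.
#
# Usage: Rscript analysis/01_simulate.R [--seed 42] [--out results/synthetic_data]

suppressPackageStartupMessages({library(optparse); library(circmotif)})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 42L),
  make_option("--out", type = "character", default = "results/synthetic_data")
)))

ds <- generate_dataset(synth_config(seed = opts$seed))
write_synthetic_dataset(ds, opts$out)

cat(sprintf("genome: %d nt on %s\n", sum(Biostrings::width(ds$genome)),
            names(ds$genome)[1]))
cat(sprintf("transcripts: %d (TTN-like with %d exons)\n",
            length(ds$models), nrow(ds$models$TTN$exons)))
cat(sprintf("junctions: %d dependent (%d carriers), %d independent (%d carriers)\n",
            ds$manifest$n_dependent, length(ds$manifest$dependent_carrier_ids),
            ds$manifest$n_other, length(ds$manifest$other_carrier_ids)))
cat(sprintf("wrote %s\n", opts$out))
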