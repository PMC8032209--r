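#!/usr/bin/env Rscript

# Stage 5 — exon-composition bounds of the focal large circRNA.
#
# The focal circle joins exon 145 (donor) back to exon 79 (acceptor), a
# 67-exon span. From the 3-sample exon-inclusion matrix: exons detected in
# no sample cannot be part of the circle; exons detected in every sample
# form its core. This bounds the isoform's exon content (and, with exon
# lengths, its size in nt).
#
# Usage: Rscript analysis/05_isoform_bounds.R [--data results/synthetic_data]

suppressPackageStartupMessages({library(optparse); library(circmotif)})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--data", type = "character", default = "results/synthetic_data"),
  make_option("--out", type = "character", default = "results")
)))

inc <- read_inclusion_matrix(file.path(opts$data, "inclusion.tsv"))
models <- read_exon_annotation(file.path(opts$data, "annotation.gtf"), "gtf")
focal <- list(acceptor_exon = min(inc$exon_number),
              donor_exon = max(inc$exon_number))

cat(sprintf("focal junction: exon %d -> exon %d, span %d exons\n",
            focal$donor_exon, focal$acceptor_exon, exon_span(focal)))
b <- bounds_from_inclusion(focal, inc, models$TTN)
print(b)

dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
write_bounds(b, file.path(opts$out, "isoform_bounds.json"))
cat(sprintf("wrote %s/isoform_bounds.json\n", opts$out))
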