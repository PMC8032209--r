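#!/usr/bin/env Rscript

# Stage 2 — junction sequences and consensus discovery.
#
# Builds the back-splice-junction sequence of every circRNA, discovers the
# shared junction-spanning consensus of the RBM20-dependent class by
# exhaustive k-mer voting (k 5..12, prevalence >= 50%), and counts the
# junctions of each host class that form the consensus across their BSJ.
#
# Usage: Rscript analysis/02_junction_motifs.R [--data results/synthetic_data]

suppressPackageStartupMessages({library(optparse); library(circmotif)})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--data", type = "character", default = "results/synthetic_data"),
  make_option("--out", type = "character", default = "results")
)))

genome <- read_genome(file.path(opts$data, "genome.fa"))
models <- read_exon_annotation(file.path(opts$data, "annotation.gtf"), "gtf")
jx <- read_junctions(file.path(opts$data, "junctions.tsv"))

bsj <- bsj_sequences(genome, models, jx)
dep <- jx$dependency_class == "rbm20_dependent"
cons <- discover_consensus(bsj[dep], k_min = 5L, k_max = 12L, min_prevalence = 0.5)
print(cons)

spans <- vapply(bsj, function(j) {
  any(find_occurrences(j, cons$consensus)$spans_junction)
}, logical(1))
ttn <- jx$host_class == "TTN"
cat(sprintf("consensus forms the BSJ of %d/%d TTN and %d/%d non-TTN circRNAs\n",
            sum(spans & ttn), sum(ttn), sum(spans & !ttn), sum(!ttn)))
cat(sprintf("dependent-class prevalence: %d%%\n",
            round(100 * sum(spans & dep) / sum(dep))))

# per-junction occurrence report
occ <- do.call(rbind, lapply(seq_along(bsj), function(i) {
  o <- find_occurrences(bsj[[i]], cons$consensus)
  if (nrow(o) == 0L) return(NULL)
  data.frame(junction_id = bsj[[i]]$id, origin = "BSJ",
             pattern = cons$consensus, start = o$start,
             spans_junction = o$spans_junction)
}))
dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
utils::write.table(occ, file.path(opts$out, "consensus_occurrences.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(consensus = cons$consensus, k = cons$k, prevalence = cons$prevalence,
       carriers = cons$carrier_ids),
  file.path(opts$out, "consensus.json"), auto_unbox = TRUE, digits = NA)
cat(sprintf("wrote %s/consensus.json and consensus_occurrences.tsv\n", opts$out))
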