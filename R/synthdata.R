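#' Configuration of the synthetic dataset
#'
#' Defaults encode the study conditions the analysis assumes: a TTN-like
#' transcript of 363 exons whose I-band-like region (exons 79-145) hosts the
#' RBM20-dependent circRNA class (63 junctions, 44 of which carry the
#' 8-nt junction motif AAAGAACC, i.e. 70% prevalence after rounding), a
#' background of non-TTN transcripts hosting 200 RBM20-independent circRNAs
#' with 3 motif carriers, gnomAD-like allele numbers (2 x 125,748), a strict
#' rare-variant threshold of AF < 0.1%, log-normal median site depths, and a
#' 3-sample exon-inclusion matrix with 9 never-included and 35
#' always-detected exons over the focal 67-exon span.
#'
#' @param seed integer RNG seed (default 42).
#' @param ... overrides of any default listed above.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 42L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_exons = 363L,
    circ_region = c(79L, 145L),
    exon_len_range = c(50L, 300L),
    intron_len_range = c(100L, 400L),
    n_background_genes = 40L,
    exons_per_background = 12L,
    n_dependent_circ = 63L,
    n_dependent_carriers = 44L,
    n_other_circ = 200L,
    n_other_carriers = 3L,
    motif = "AAAGAACC",
    motif_split = c(4L, 4L),
    n_lj_included_motifs = 6L,
    n_lj_excluded_motifs = 6L,
    n_within_exon_motifs = 10L,
    window = 25L,
    rare_af_threshold = 0.001,
    allele_number = 251496L,
    mu_scale = 3,
    depth_meanlog = log(40),
    depth_sdlog = 0.5,
    selection_thinning = c(motif_bsj = 0.5, motif_within_exon = 0.7,
                           truncating = 0.2, default = 1.0),
    n_samples_inclusion = 3L,
    never_included = 9L,
    always_detected = 35L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ","))
  cfg[names(over)] <- over
  stopifnot(cfg$n_dependent_carriers <= cfg$n_dependent_circ,
            cfg$n_other_carriers <= cfg$n_other_circ,
            sum(cfg$motif_split) == nchar(cfg$motif))
  structure(cfg, class = "synth_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exon lengths whose sum is divisible by 3 (CDS frame over the whole mRNA)
cds_exon_lengths <- function(n, range) {
  len <- sample(seq(range[1], range[2]), n, replace = TRUE)
  len[n] <- len[n] - sum(len) %% 3L
  len
}

#' Generate the synthetic genome and exon annotation
#'
#' One contig carrying a plus-strand TTN-like transcript with
#' `cfg$n_exons` exons, followed by `cfg$n_background_genes` shorter
#' background transcripts (alternating strand) that host the non-TTN
#' circRNA class. Every transcript's exonic length is divisible by 3 so the
#' spliced sequence doubles as a CDS for consequence classification.
#'
#' @param cfg `synth_config`.
#' @return list: `genome` (DNAStringSet), `models` (named list of
#'   `exon_model`s, TTN first), `cfg`.
#' @export
generate_genome_and_annotation <- function(cfg) {
  set.seed(cfg$seed + 1L)
  gap <- 500L
  build <- function(id, strand, n_ex, at) {
    elen <- cds_exon_lengths(n_ex, cfg$exon_len_range)
    ilen <- sample(seq(cfg$intron_len_range[1], cfg$intron_len_range[2]),
                   n_ex - 1L, replace = TRUE)
    starts <- at + cumsum(c(0L, elen[-n_ex] + ilen))
    list(model = exon_model(id, "chrS", strand, starts, starts + elen - 1L),
         next_at = starts[n_ex] + elen[n_ex] - 1L + gap)
  }
  at <- gap
  ttn <- build("TTN", "+", cfg$n_exons, at)
  models <- list(TTN = ttn$model)
  at <- ttn$next_at
  for (i in seq_len(cfg$n_background_genes)) {
    id <- sprintf("BG%03d", i)
    b <- build(id, if (i %% 2L == 0L) "-" else "+", cfg$exons_per_background, at)
    models[[id]] <- b$model
    at <- b$next_at
  }
  total <- at + gap
  genome <- genome_seq(stats::setNames(
    Biostrings::DNAStringSet(random_dna(total)), "chrS"))
  list(genome = genome, models = models, cfg = cfg)
}

safe_sample <- function(x, n) {
  n <- min(n, length(x))
  if (n <= 0L) return(x[0])
  x[sample.int(length(x), n)]
}

drop_head <- function(d, n) if (n > 0L) d[-seq_len(n), , drop = FALSE] else d

replace_bases <- function(genome, contig, pos, bases) {
  o <- order(pos)
  genome[[contig]] <- Biostrings::replaceLetterAt(
    genome[[contig]], pos[o], paste(bases[o], collapse = ""))
  genome
}

# overwrite genome bases so that the junction's BSJ sequence carries the
# motif split across the junction (split[1] donor-side, split[2] acceptor)
plant_motif <- function(genome, model, acceptor, donor, motif, split) {
  s1 <- split[1]; s2 <- split[2]
  don <- exon_row(model, donor)
  chars <- strsplit(motif, "")[[1]]
  pos_d <- exon_offset_to_genomic(model, donor, seq(don$width - s1 + 1L, don$width))
  pos_a <- exon_offset_to_genomic(model, acceptor, seq_len(s2))
  ch_d <- chars[seq_len(s1)]; ch_a <- chars[seq(s1 + 1L, s1 + s2)]
  if (model$strand == "-") {
    ch_d <- unname(COMP[ch_d]); ch_a <- unname(COMP[ch_a])
  }
  replace_bases(genome, model$contig, c(pos_d, pos_a), c(ch_d, ch_a))
}

# write the motif into the middle of an exon body (transcript orientation)
plant_in_exon <- function(genome, model, exon, motif) {
  e <- exon_row(model, exon)
  k <- nchar(motif)
  if (e$width < k + 20L) stop("exon ", exon, " too short for interior planting")
  c0 <- (e$width - k) %/% 2L + 1L
  pos <- exon_offset_to_genomic(model, exon, seq(c0, c0 + k - 1L))
  ch <- strsplit(motif, "")[[1]]
  if (model$strand == "-") ch <- unname(COMP[ch])
  replace_bases(genome, model$contig, pos, ch)
}

# TRUE when the junction's BSJ window contains a junction-spanning
# occurrence of any >= 5 nt substring of the motif (and hence of the motif)
has_spurious_motif <- function(genome, model, acceptor, donor, motif, w) {
  js <- build_bsj_sequence(genome, model,
                           list(acceptor_exon = acceptor, donor_exon = donor,
                                junction_id = "chk"), w = w)
  k <- nchar(motif)
  subs <- unique(substring(motif, seq_len(k - 4L), seq(5L, k)))
  for (p in subs) {
    if (any(find_occurrences(js, p)$spans_junction)) return(TRUE)
  }
  FALSE
}

#' Generate circRNA junctions with planted junction motifs
#'
#' Samples the RBM20-dependent class inside the TTN circ region and the
#' independent class on background transcripts. Carrier junctions get the
#' motif written into the genome (overwriting bases, coordinates unchanged)
#' as `motif_split[1]` bases ending the donor exon and `motif_split[2]`
#' bases starting the acceptor exon. Non-carrier junctions are rejection-
#' sampled so that no >= 5 nt substring of the motif spans their junction:
#' the planted carrier set is exactly the set of junction-spanning motif
#' carriers, making the generator's manifest exact ground truth.
#'
#' @param cfg `synth_config`.
#' @param ga output of [generate_genome_and_annotation()].
#' @return list: `genome` (edited), `junctions` (`circ_junctions`),
#'   `manifest` (motif, split, class sizes, carrier ids).
#' @export
generate_circ_junctions <- function(cfg, ga) {
  set.seed(cfg$seed + 2L)
  genome <- ga$genome
  models <- ga$models
  w <- cfg$window
  reg <- seq(cfg$circ_region[1], cfg$circ_region[2])
  pairs <- expand.grid(acceptor = reg, donor = reg)
  pairs <- pairs[pairs$acceptor < pairs$donor, ]
  if (nrow(pairs) < cfg$n_dependent_circ) stop("circ region too small")
  perm <- pairs[sample.int(nrow(pairs)), ]
  carriers <- perm[seq_len(cfg$n_dependent_carriers), ]
  for (i in seq_len(nrow(carriers))) {
    genome <- plant_motif(genome, models$TTN, carriers$acceptor[i],
                          carriers$donor[i], cfg$motif, cfg$motif_split)
  }
  # background carriers planted before any non-carrier is screened
  bg_ids <- setdiff(names(models), "TTN")
  bg_pool <- do.call(rbind, lapply(bg_ids, function(id) {
    n <- n_exons(models[[id]])
    g <- expand.grid(acceptor = seq_len(n), donor = seq_len(n))
    g <- g[g$acceptor < g$donor, ]
    g$transcript_id <- id
    g
  }))
  bg_perm <- bg_pool[sample.int(nrow(bg_pool)), ]
  bg_carriers <- bg_perm[seq_len(cfg$n_other_carriers), ]
  for (i in seq_len(nrow(bg_carriers))) {
    genome <- plant_motif(genome, models[[bg_carriers$transcript_id[i]]],
                          bg_carriers$acceptor[i], bg_carriers$donor[i],
                          cfg$motif, cfg$motif_split)
  }
  # LJ-created and within-exon motif copies, so every formation context of
  # the constraint analysis is populated (planted before screening)
  in_span <- sort(unique(unlist(lapply(seq_len(nrow(carriers)), function(i) {
    seq(carriers$acceptor[i], carriers$donor[i])
  }))))
  lj_inc_pool <- in_span[(in_span + 1L) %in% in_span]
  lj_inc <- safe_sample(lj_inc_pool, cfg$n_lj_included_motifs)
  out_lo <- cfg$circ_region[2] + 2L
  lj_exc <- safe_sample(seq(out_lo, cfg$n_exons - 2L), cfg$n_lj_excluded_motifs)
  for (i in c(lj_inc, lj_exc)) {
    genome <- plant_motif(genome, models$TTN, i + 1L, i, cfg$motif, cfg$motif_split)
  }
  n_we_in <- cfg$n_within_exon_motifs %/% 2L
  we_in <- safe_sample(in_span, n_we_in)
  we_out <- safe_sample(seq(out_lo, cfg$n_exons),
                        cfg$n_within_exon_motifs - n_we_in)
  for (e in c(we_in, we_out)) {
    genome <- plant_in_exon(genome, models$TTN, e, cfg$motif)
  }
  pick_clean <- function(pool, model_of, n_needed) {
    out <- list(); i <- 1L
    while (length(out) < n_needed) {
      if (i > nrow(pool)) stop("exhausted junction pool while screening for spurious motifs")
      cand <- pool[i, ]; i <- i + 1L
      if (!has_spurious_motif(genome, model_of(cand), cand$acceptor,
                              cand$donor, cfg$motif, w)) {
        out[[length(out) + 1L]] <- cand
      }
    }
    do.call(rbind, out)
  }
  dep_rest <- pick_clean(drop_head(perm, cfg$n_dependent_carriers),
                         function(cand) models$TTN,
                         cfg$n_dependent_circ - cfg$n_dependent_carriers)
  bg_rest <- pick_clean(drop_head(bg_perm, cfg$n_other_carriers),
                        function(cand) models[[cand$transcript_id]],
                        cfg$n_other_circ - cfg$n_other_carriers)
  with_flag <- function(d, flag) {
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    d$carrier <- flag
    d
  }
  dep <- rbind(with_flag(carriers, TRUE), with_flag(dep_rest, FALSE))
  keep <- c("acceptor", "donor", "transcript_id", "carrier")
  oth <- rbind(with_flag(bg_carriers, TRUE), with_flag(bg_rest, FALSE))
  oth <- oth[, keep]
  junctions <- circ_junctions(
    transcript_id = c(rep("TTN", nrow(dep)), oth$transcript_id),
    acceptor_exon = c(dep$acceptor, oth$acceptor),
    donor_exon = c(dep$donor, oth$donor),
    dependency_class = c(rep("rbm20_dependent", nrow(dep)),
                         rep("rbm20_independent", nrow(oth))),
    host_class = c(rep("TTN", nrow(dep)), rep("other", nrow(oth)))
  )
  manifest <- list(
    motif = cfg$motif, motif_split = cfg$motif_split,
    n_dependent = nrow(dep), n_other = nrow(oth),
    dependent_carrier_ids = junctions$junction_id[seq_len(nrow(dep))][dep$carrier],
    other_carrier_ids = junctions$junction_id[nrow(dep) + seq_len(nrow(oth))][oth$carrier],
    lj_included_planted = sort(lj_inc), lj_excluded_planted = sort(lj_exc),
    within_exon_planted = sort(c(we_in, we_out))
  )
  list(genome = genome, junctions = junctions, manifest = manifest)
}

#' Generate a methylation track for all CpG sites
#'
#' Each CpG dinucleotide gets one bin (0 none, 1 partial, 2 high), written
#' for both of its positions.
#'
#' @param cfg `synth_config`.
#' @param genome genome `DNAStringSet`.
#' @export
generate_methylation <- function(cfg, genome) {
  set.seed(cfg$seed + 5L)
  rows <- lapply(names(genome), function(ct) {
    cg <- BiocGenerics::start(Biostrings::matchPattern("CG", genome[[ct]]))
    if (length(cg) == 0L) return(NULL)
    bin <- sample(0:2, length(cg), replace = TRUE, prob = c(0.4, 0.3, 0.3))
    data.frame(contig = ct, pos = c(cg, cg + 1L), bin = c(bin, bin))
  })
  out <- do.call(rbind, rows)
  out[order(out$contig, out$pos), ]
}

#' Generate median site depths
#'
#' Log-normal(`depth_meanlog`, `depth_sdlog`) rounded and truncated at 1.
#'
#' @param cfg `synth_config`.
#' @param contig contig name.
#' @param pos integer positions.
#' @return named numeric vector keyed `"contig:pos"`.
#' @export
generate_depths <- function(cfg, contig, pos) {
  set.seed(cfg$seed + 3L)
  pos <- sort(unique(pos))
  d <- pmax(1, round(stats::rlnorm(length(pos), cfg$depth_meanlog, cfg$depth_sdlog)))
  stats::setNames(d, paste0(contig, ":", pos))
}

#' Generate rare variants by per-site Poisson sampling with selection thinning
#'
#' For every (site, alt) pair, draws a Poisson count with mean
#' `rate * mu_scale * depth_factor(depth)` under the generator's detection
#' model, thins it binomially by the site's selection coefficient `s`, and
#' emits one record (AC = surviving count, AN = `cfg$allele_number`) when
#' any mutation survives. `s = 1` is neutrality; `s < 1` emulates purifying
#' selection.
#'
#' @param cfg `synth_config`.
#' @param genome genome `DNAStringSet`.
#' @param rates `rate_table`.
#' @param sites data.frame `contig, pos[, alt][, s]` (missing alt = all
#'   three; missing s = 1).
#' @param methyl methylation track or NULL.
#' @param depths named depth vector (see [generate_depths()]); NULL = full
#'   coverage.
#' @param dm generator detection `depth_model` (default [depth_model()]).
#' @param seed RNG seed (default derived from the config).
#' @return variant data.frame in [read_variants()] layout.
#' @export
generate_variants <- function(cfg, genome, rates, sites, methyl = NULL,
                              depths = NULL, dm = depth_model(),
                              seed = cfg$seed + 4L) {
  set.seed(seed)
  s_col <- if (is.null(sites$s)) rep(1, nrow(sites)) else sites$s
  sites$s <- s_col
  sa <- expand_site_alts(genome, sites[, c("contig", "pos",
                                           intersect(c("alt", "s"), names(sites)))])
  key <- paste(sa$contig, sa$pos, sa$alt)
  sa <- sa[!duplicated(key), ]
  ctx_left <- character(nrow(sa)); ctx_right <- character(nrow(sa))
  for (ct in unique(sa$contig)) {
    i <- which(sa$contig == ct)
    ctx <- as.character(Biostrings::extractAt(
      genome[[ct]], IRanges::IRanges(sa$pos[i] - 1L, width = 3L)))
    ctx_left[i] <- substr(ctx, 1, 1); ctx_right[i] <- substr(ctx, 3, 3)
  }
  bins <- methyl_bins_at(methyl, sa$contig, sa$pos)
  r <- rate_lookup(rates, ctx_left, sa$ref, sa$alt, ctx_right, bins)
  d <- if (is.null(depths)) rep(Inf, nrow(sa)) else {
    dd <- depths[paste0(sa$contig, ":", sa$pos)]
    if (anyNA(dd)) stop("missing depth for a site")
    dd
  }
  lam <- r * cfg$mu_scale * depth_factor(dm, d)
  k <- stats::rpois(nrow(sa), lam)
  kept <- stats::rbinom(nrow(sa), k, sa$s)
  hit <- which(kept > 0L)
  if (length(hit) == 0L) {
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      allele_count = integer(0), allele_number = integer(0),
                      median_depth = numeric(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(contig = sa$contig[hit], pos = sa$pos[hit],
                    ref = sa$ref[hit], alt = sa$alt[hit],
                    allele_count = as.integer(kept[hit]),
                    allele_number = cfg$allele_number,
                    median_depth = ifelse(is.finite(d[hit]), d[hit], 100),
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Generate the exon-inclusion matrix for the focal circRNA span
#'
#' Over the span of the focal junction and `cfg$n_samples_inclusion`
#' samples: exactly `cfg$never_included` interior exons detected in no
#' sample, exactly `cfg$always_detected` exons (always containing the two
#' junction exons) detected in every sample, and the remaining exons
#' detected in a random nonempty strict subset of samples.
#'
#' @param cfg `synth_config`.
#' @param cj focal junction (one-row `circ_junctions` slice or list).
#' @return an `inclusion_matrix`.
#' @export
generate_inclusion_matrix <- function(cfg, cj) {
  set.seed(cfg$seed + 6L)
  span <- seq(cj$acceptor_exon, cj$donor_exon)
  ns <- cfg$n_samples_inclusion
  interior <- setdiff(span, c(cj$acceptor_exon, cj$donor_exon))
  if (cfg$never_included + cfg$always_detected > length(span)) {
    stop("never_included + always_detected exceed the span")
  }
  never <- sample(interior, cfg$never_included)
  pool <- setdiff(interior, never)
  always <- c(cj$acceptor_exon, cj$donor_exon,
              sample(pool, cfg$always_detected - 2L))
  rest <- setdiff(span, c(never, always))
  det <- matrix(FALSE, nrow = length(span), ncol = ns,
                dimnames = list(span, sprintf("heart%d", seq_len(ns))))
  det[as.character(always), ] <- TRUE
  for (e in rest) {
    det[as.character(e), sample(ns, sample(ns - 1L, 1L))] <- TRUE
  }
  inclusion_matrix(span, det)
}

#' Generate the complete in-memory synthetic dataset
#'
#' Runs every generator in order and returns genome, annotation, junctions,
#' manifest, rate table, methylation track and the focal-junction inclusion
#' matrix. Variants are left to the caller (they depend on the site classes
#' under study).
#'
#' @param cfg `synth_config` (default `synth_config()`).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  ga <- generate_genome_and_annotation(cfg)
  cj <- generate_circ_junctions(cfg, ga)
  focal <- list(acceptor_exon = cfg$circ_region[1], donor_exon = cfg$circ_region[2])
  list(cfg = cfg, genome = cj$genome, models = ga$models,
       junctions = cj$junctions, manifest = cj$manifest,
       rates = default_rate_table(),
       methyl = generate_methylation(cfg, cj$genome),
       inclusion = generate_inclusion_matrix(cfg, focal),
       focal = focal)
}

#' ATtRACT-like motif table for the synthetic study
#'
#' One SRSF10-like record whose pattern is the planted junction motif, plus
#' deterministic decoy RBP motifs (length 6-8, drawn from the IUPAC
#' alphabet with mild degeneracy).
#'
#' @param cfg `synth_config`.
#' @param n_decoys number of decoy motifs (default 20).
#' @return motif table data.frame (see [motif_table()]).
#' @export
generate_motif_table <- function(cfg, n_decoys = 20L) {
  set.seed(cfg$seed + 7L)
  alph <- c(rep(c("A", "C", "G", "T"), 5), "R", "Y", "S", "W")
  decoys <- vapply(seq_len(n_decoys), function(i) {
    paste(sample(alph, sample(6:8, 1), replace = TRUE), collapse = "")
  }, character(1))
  motif_table(
    motif_id = c("M_SRSF10", sprintf("M_DEC%02d", seq_len(n_decoys))),
    rbp_name = c("SRSF10", sprintf("RBP%02d", seq_len(n_decoys))),
    pattern = c(cfg$motif, decoys)
  )
}

#' Write a GTF exon annotation
#'
#' @param models named list of `exon_model`s.
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(m) {
    ex <- m$exons[order(m$exons$start), ]
    sprintf(
      '%s\tcircmotif\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; exon_number "%d";',
      m$contig, ex$start, ex$end, m$strand, m$transcript_id, m$transcript_id,
      ex$exon_number)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write the full synthetic dataset to a directory
#'
#' Emits FASTA, GTF, junction TSV, rate-table TSV, methylation TSV,
#' inclusion TSV and a ground-truth manifest JSON, all readable by the
#' package's readers.
#'
#' @param ds output of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return the directory path.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(ds$genome, file.path(dir, "genome.fa"))
  write_gtf(ds$models, file.path(dir, "annotation.gtf"))
  write_junctions(ds$junctions, file.path(dir, "junctions.tsv"))
  write_rate_table(ds$rates, file.path(dir, "rates.tsv"))
  write_methylation(ds$methyl, file.path(dir, "methylation.tsv"))
  write_inclusion_matrix(ds$inclusion, file.path(dir, "inclusion.tsv"))
  utils::write.table(generate_motif_table(ds$cfg), file.path(dir, "motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
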