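COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Trinucleotide-context mutation-rate table
#'
#' Per-site, per-allele neutral mutation probabilities keyed by
#' (left context, ref, alt, right context, methylation bin). Keys are
#' strand-collapsed: a key and its reverse complement share one rate, and
#' the canonical form has ref in {A, C}. Methylation bins other than 0 exist
#' only for CpG-context keys (canonical ref C followed by G).
#'
#' @param df data.frame with columns `left, ref, alt, right, methyl_bin,
#'   rate` (rates > 0).
#' @return object of class `rate_table`.
#' @export
rate_table <- function(df) {
  need <- c("left", "ref", "alt", "right", "methyl_bin", "rate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("rate table missing columns: ", paste(miss, collapse = ","))
  if (any(df$rate <= 0)) stop("all rates must be > 0")
  key <- canonical_key(df$left, df$ref, df$alt, df$right, df$methyl_bin)
  cpg <- grepl("^.\\|C\\|.\\|G\\|", key)
  if (any(df$methyl_bin != 0L & !cpg)) {
    stop("methyl_bin != 0 on non-CpG context key: ", key[df$methyl_bin != 0L & !cpg][1])
  }
  dup <- duplicated(key)
  if (any(df$rate[dup] != df$rate[match(key[dup], key)])) {
    stop("conflicting rates for strand-equivalent keys")
  }
  rates <- stats::setNames(df$rate[!dup], key[!dup])
  structure(list(df = df, rates = rates), class = "rate_table")
}

canonical_key <- function(left, ref, alt, right, bin) {
  flip <- ref %in% c("G", "T")
  l <- ifelse(flip, unname(COMP[right]), left)
  r <- ifelse(flip, unname(COMP[left]), right)
  rf <- ifelse(flip, unname(COMP[ref]), ref)
  al <- ifelse(flip, unname(COMP[alt]), alt)
  paste(l, rf, al, r, bin, sep = "|")
}

#' Look up mutation rates for site contexts
#'
#' @param rt `rate_table`.
#' @param left,ref,alt,right base vectors (any strand; collapsed internally).
#' @param methyl_bin integer vector; coerced to 0 for non-CpG contexts.
#' @return numeric vector of rates; error when a key is absent.
#' @export
rate_lookup <- function(rt, left, ref, alt, right, methyl_bin = 0L) {
  methyl_bin <- rep_len(as.integer(methyl_bin), length(ref))
  key <- canonical_key(left, ref, alt, right, methyl_bin)
  cpg <- grepl("^.\\|C\\|.\\|G\\|", key)
  key[!cpg] <- canonical_key(left[!cpg], ref[!cpg], alt[!cpg], right[!cpg], 0L)
  r <- rt$rates[key]
  if (anyNA(r)) stop("no rate for context key ", key[is.na(r)][1])
  unname(r)
}

#' Default synthetic mutation-rate table
#'
#' Fixture-grade rates for the synthetic genome: transversions at `mu0`,
#' transitions at 3x, CpG transitions at 4x (partial methylation, bin 1) and
#' 10x (high methylation, bin 2) the transition rate. Real analyses must
#' supply their own empirically calibrated table.
#'
#' @param mu0 per-site per-allele transversion probability (default 0.004).
#' @export
default_rate_table <- function(mu0 = 0.004) {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(left = bases, ref = c("A", "C"), alt = bases,
                   right = bases, stringsAsFactors = FALSE)
  g <- g[g$alt != g$ref, ]
  transition <- (g$ref == "A" & g$alt == "G") | (g$ref == "C" & g$alt == "T")
  g$methyl_bin <- 0L
  g$rate <- ifelse(transition, 3 * mu0, mu0)
  cpg <- g[g$ref == "C" & g$right == "G", ]
  cpg_ti <- cpg$alt == "T"
  b1 <- cpg; b1$methyl_bin <- 1L; b1$rate <- ifelse(cpg_ti, 4 * 3 * mu0, cpg$rate)
  b2 <- cpg; b2$methyl_bin <- 2L; b2$rate <- ifelse(cpg_ti, 10 * 3 * mu0, cpg$rate)
  rate_table(rbind(g, b1, b2))
}

#' @rdname rate_table
#' @param path TSV path (columns left, ref, alt, right, methyl_bin, rate).
#' @export
read_rate_table <- function(path) {
  rate_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname rate_table
#' @param rt a `rate_table`.
#' @export
write_rate_table <- function(rt, path) {
  utils::write.table(rt$df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Methylation track: CpG positions and bins
#'
#' TSV columns `contig, pos, bin` (bin 0 none / 1 partial / 2 high). Both
#' positions of a CpG dinucleotide carry the same bin. Positions absent from
#' the track are bin 0.
#'
#' @param path TSV path.
#' @export
read_methylation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "pos", "bin") %in% names(d)))
  d
}

#' @rdname read_methylation
#' @param methyl methylation data.frame.
#' @export
write_methylation <- function(methyl, path) {
  utils::write.table(methyl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

methyl_bins_at <- function(methyl, contig, pos) {
  if (is.null(methyl) || nrow(methyl) == 0L) return(rep(0L, length(pos)))
  m <- match(paste(contig, pos), paste(methyl$contig, methyl$pos))
  out <- methyl$bin[m]
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Sequencing-depth correction model
#'
#' Below the full-coverage threshold `d0`, expected variant counts are
#' multiplied by `min(1, a + b * ln d)` (clamped to [0, 1]); at or above
#' `d0` the factor is 1.
#'
#' @param d0 full-coverage median depth threshold (default 30).
#' @param a,b correction coefficients (`b >= 0` so the factor is monotone).
#' @export
depth_model <- function(d0 = 30, a = 1 - 0.3 * log(30), b = 0.3) {
  stopifnot(b >= 0, d0 > 0)
  structure(list(d0 = d0, a = a, b = b), class = "depth_model")
}

#' @rdname depth_model
#' @param dm a `depth_model` (NULL = no correction, factor 1).
#' @param d numeric vector of median site depths.
#' @export
depth_factor <- function(dm, d) {
  if (is.null(dm)) return(rep(1, length(d)))
  ifelse(d >= dm$d0, 1, pmin(1, pmax(0, dm$a + dm$b * log(pmax(d, 1e-9)))))
}

#' Fit depth-correction coefficients from calibration sites
#'
#' Bins sites below `d0` by depth, computes per-bin observed/expected (the
#' expected computed at factor 1), normalises by the observed/expected ratio
#' of full-coverage sites, and least-squares fits the normalised ratio
#' against ln(depth).
#'
#' @param depth per-site median depths.
#' @param observed per-site observed rare-variant counts.
#' @param expected per-site expected counts computed without depth
#'   correction.
#' @param d0 full-coverage threshold.
#' @param n_bins number of low-depth bins (default 6).
#' @return a fitted `depth_model`.
#' @export
fit_depth_model <- function(depth, observed, expected, d0 = 30, n_bins = 6) {
  stopifnot(length(depth) == length(observed), length(depth) == length(expected))
  hi <- depth >= d0
  if (!any(hi) || sum(observed[hi]) == 0) {
    stop("need full-coverage sites with observed variants to normalise")
  }
  lambda_hat <- sum(observed[hi]) / sum(expected[hi])
  lo <- which(!hi)
  if (length(lo) < 2 * n_bins) stop("too few low-coverage sites to fit")
  br <- unique(stats::quantile(depth[lo], probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(depth[lo], breaks = br, include.lowest = TRUE)
  ratio <- tapply(observed[lo], bin, sum) / tapply(expected[lo], bin, sum) / lambda_hat
  dbar <- tapply(depth[lo], bin, mean)
  ok <- is.finite(ratio)
  fit <- stats::lm(ratio[ok] ~ log(dbar[ok]))
  depth_model(d0 = d0, a = unname(stats::coef(fit)[1]),
              b = max(0, unname(stats::coef(fit)[2])))
}

expand_site_alts <- function(genome, sites) {
  # sites: data.frame(contig, pos[, alt]); fills ref from the genome and
  # expands missing alt to all three non-ref bases
  ref <- character(nrow(sites))
  for (ct in unique(sites$contig)) {
    i <- which(sites$contig == ct)
    ref[i] <- genome_base(genome, ct, sites$pos[i])
  }
  sites$ref <- ref
  if (is.null(sites$alt)) sites$alt <- NA_character_
  todo <- is.na(sites$alt)
  if (!any(todo)) return(sites)
  idx <- rep(seq_len(nrow(sites)), times = ifelse(todo, 3L, 1L))
  out <- sites[idx, , drop = FALSE]
  fill <- is.na(out$alt)
  out$alt[fill] <- unlist(lapply(sites$ref[todo], function(r) {
    setdiff(c("A", "C", "G", "T"), r)
  }))
  rownames(out) <- NULL
  out
}

#' Expected rare-variant count for a site class under the neutral model
#'
#' `expected = lambda_cal * sum over sites and alts of
#' rate(context, ref->alt, methyl_bin) * depth_factor(median depth)`.
#' Sites whose trinucleotide context contains N are rejected.
#'
#' @param genome genome `DNAStringSet`.
#' @param sites data.frame `contig, pos` (all three alts) or
#'   `contig, pos, alt`.
#' @param rates `rate_table`.
#' @param methyl methylation track data.frame or NULL.
#' @param depths named numeric vector of median depths keyed
#'   `"contig:pos"`, or NULL for full coverage.
#' @param dm `depth_model` or NULL (no correction).
#' @param lambda_cal calibration scalar (default 1).
#' @return positive scalar expected count.
#' @export
expected_variants <- function(genome, sites, rates, methyl = NULL,
                              depths = NULL, dm = NULL, lambda_cal = 1) {
  stopifnot(lambda_cal > 0)
  if (nrow(sites) == 0L) return(0)
  comp <- expected_components(genome, sites, rates, methyl)
  f <- if (is.null(depths)) rep(1, nrow(comp)) else {
    d <- depths[paste0(comp$contig, ":", comp$pos)]
    if (anyNA(d)) stop("missing depth for site ",
                       paste0(comp$contig, ":", comp$pos)[is.na(d)][1])
    depth_factor(dm, d)
  }
  lambda_cal * sum(comp$rate * f)
}

#' Per-(site, alt) neutral rates underlying the expected count
#'
#' @inheritParams expected_variants
#' @return data.frame `contig, pos, ref, alt, rate` (one row per site-alt
#'   pair, depth factor not applied).
#' @export
expected_components <- function(genome, sites, rates, methyl = NULL) {
  sa <- expand_site_alts(genome, sites)
  ctx <- character(nrow(sa))
  for (ct in unique(sa$contig)) {
    i <- which(sa$contig == ct)
    s <- genome[[ct]]
    if (any(sa$pos[i] < 2L | sa$pos[i] > length(s) - 1L)) {
      stop("site too close to contig edge for trinucleotide context")
    }
    ctx[i] <- as.character(Biostrings::extractAt(
      s, IRanges::IRanges(sa$pos[i] - 1L, width = 3L)))
  }
  if (any(grepl("N", ctx))) {
    bad <- which(grepl("N", ctx))[1]
    stop("N in trinucleotide context at ", sa$contig[bad], ":", sa$pos[bad])
  }
  left <- substr(ctx, 1, 1); right <- substr(ctx, 3, 3)
  bins <- methyl_bins_at(methyl, sa$contig, sa$pos)
  sa$rate <- rate_lookup(rates, left, sa$ref, sa$alt, right, bins)
  sa[, c("contig", "pos", "ref", "alt", "rate")]
}

#' Count observed rare variants falling in a site class
#'
#' @param variants rare-filtered variant data.frame.
#' @param sites site data.frame (`contig, pos` = any alt; with `alt` =
#'   that substitution only).
#' @return integer count of matching variant records.
#' @export
observed_count <- function(variants, sites) {
  if (nrow(variants) == 0L || nrow(sites) == 0L) return(0L)
  if (is.null(sites$alt)) {
    sum(paste(variants$contig, variants$pos) %in% paste(sites$contig, sites$pos))
  } else {
    sum(paste(variants$contig, variants$pos, variants$alt) %in%
          paste(sites$contig, sites$pos, sites$alt))
  }
}

#' Calibrate the neutral model on a minimally selected site class
#'
#' @param observed_cal observed rare-variant count on the calibration class
#'   (typically synonymous sites).
#' @param expected_cal uncalibrated expected count for the same class.
#' @return `lambda_cal = observed_cal / expected_cal`.
#' @export
calibrate_lambda <- function(observed_cal, expected_cal) {
  stopifnot(expected_cal > 0)
  if (observed_cal == 0) stop("cannot calibrate: zero observed variants on calibration class")
  observed_cal / expected_cal
}

#' Observed/expected ratio with exact Poisson confidence interval
#'
#' The interval treats `expected` as fixed and inverts the Poisson tails of
#' the observed count via the chi-square quantile form:
#' `lower = qchisq(alpha, 2*observed) / (2*expected)` (0 when observed = 0),
#' `upper = qchisq(1 - alpha, 2*(observed + 1)) / (2*expected)`,
#' with `alpha = (1 - level)/2`.
#'
#' @param observed non-negative integer count.
#' @param expected positive expected count.
#' @param level confidence level (default 0.90).
#' @param label optional class label carried into the result.
#' @return list of class `constraint_result`: `label, observed, expected,
#'   oe, ci_low, ci_high, level`.
#' @export
oe_with_ci <- function(observed, expected, level = 0.90, label = NA_character_) {
  if (expected <= 0) stop("expected must be > 0")
  stopifnot(observed >= 0, observed == round(observed))
  alpha <- (1 - level) / 2
  lo <- if (observed == 0) 0 else stats::qchisq(alpha, 2 * observed) / (2 * expected)
  hi <- stats::qchisq(1 - alpha, 2 * (observed + 1)) / (2 * expected)
  structure(list(label = label, observed = as.integer(observed),
                 expected = expected, oe = observed / expected,
                 ci_low = lo, ci_high = hi, level = level),
            class = "constraint_result")
}

#' @export
print.constraint_result <- function(x, ...) {
  cat(sprintf("<constraint> %s o/e = %d/%.2f = %.3f [%.3f, %.3f] (%d%% CI)\n",
              x$label, x$observed, x$expected, x$oe, x$ci_low, x$ci_high,
              round(100 * x$level)))
  invisible(x)
}

#' Classify a codon substitution
#'
#' @param codon reference codon (3 bases).
#' @param pos_in_codon 1, 2 or 3.
#' @param alt alternate base at that position.
#' @return `"synonymous"`, `"missense"` or `"truncating"` (stop gained);
#'   stop-loss is folded into missense.
#' @export
classify_codon <- function(codon, pos_in_codon, alt) {
  codon <- toupper(codon)
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[codon])
  altcodon <- codon
  substr(altcodon, pos_in_codon, pos_in_codon) <- alt
  alt_aa <- unname(gc[altcodon])
  ifelse(alt_aa == ref_aa, "synonymous",
         ifelse(alt_aa == "*" & ref_aa != "*", "truncating", "missense"))
}

#' Classify the coding consequence of a genomic SNV
#'
#' The transcript's spliced sequence is treated as the CDS (length must be
#' divisible by 3, reading frame from position 1).
#'
#' @param genome genome `DNAStringSet`.
#' @param model `exon_model`.
#' @param pos genomic position (must be exonic).
#' @param alt alternate base on the genomic plus strand.
#' @export
classify_consequence <- function(genome, model, pos, alt) {
  tx <- transcript_sequence(genome, model)
  if (nchar(tx) %% 3 != 0) stop("CDS length not divisible by 3")
  loc <- genomic_to_tx(model, pos)
  alt_tx <- if (model$strand == "+") alt else unname(COMP[alt])
  ci <- (loc$tx_pos - 1L) %/% 3L + 1L
  within <- (loc$tx_pos - 1L) %% 3L + 1L
  classify_codon(substr(tx, 3L * ci - 2L, 3L * ci), within, alt_tx)
}

#' Synonymous/missense/truncating site classes over a transcript region
#'
#' Enumerates every exonic position and alt allele of the chosen exons and
#' groups the (site, alt) pairs by coding consequence.
#'
#' @inheritParams classify_consequence
#' @param exon_numbers subset of exons to cover (default all).
#' @return named list of data.frames (`contig, pos, alt`), names
#'   `synonymous`, `missense`, `truncating`.
#' @export
consequence_site_classes <- function(genome, model, exon_numbers = NULL) {
  tx <- transcript_sequence(genome, model)
  if (nchar(tx) %% 3 != 0) stop("CDS length not divisible by 3")
  ex <- model$exons
  if (is.null(exon_numbers)) exon_numbers <- ex$exon_number
  cum_before <- c(0L, cumsum(ex$width))[match(exon_numbers, ex$exon_number)]
  rows <- lapply(seq_along(exon_numbers), function(j) {
    e <- exon_row(model, exon_numbers[j])
    offs <- seq_len(e$width)
    data.frame(pos = exon_offset_to_genomic(model, exon_numbers[j], offs),
               tx_pos = cum_before[j] + offs)
  })
  d <- do.call(rbind, rows)
  ci <- (d$tx_pos - 1L) %/% 3L + 1L
  within <- (d$tx_pos - 1L) %% 3L + 1L
  codon <- substring(tx, 3L * ci - 2L, 3L * ci)
  ref_tx <- substring(tx, d$tx_pos, d$tx_pos)
  out <- do.call(rbind, lapply(c("A", "C", "G", "T"), function(b) {
    keep <- ref_tx != b
    lab <- classify_codon(codon[keep], within[keep], b)
    alt_genomic <- if (model$strand == "+") b else unname(COMP[b])
    data.frame(contig = model$contig, pos = d$pos[keep],
               alt = alt_genomic, label = lab, stringsAsFactors = FALSE)
  }))
  split(out[, c("contig", "pos", "alt")], out$label)
}

#' Genomic site classes of a motif across formation contexts
#'
#' Maps every occurrence of `pattern` to genomic coordinates and groups the
#' covered sites into the five motif classes used in the constraint plot:
#' all LJ-created sites, LJ-created split by circRNA inclusion of both
#' flanking exons, BSJ-created sites (the two exon-resident halves), and
#' within-exon sites. LJ occurrences whose flanking exons disagree on
#' inclusion count only toward `motif_lj_all`.
#'
#' @inheritParams classify_genomic_motif_sites
#' @param pattern motif (IUPAC).
#' @return named list of site data.frames (`contig, pos`), all alts allowed.
#' @export
build_motif_site_classes <- function(genome, model, circ_set, pattern, w = 25L) {
  uniq <- function(d) {
    if (is.null(d) || nrow(d) == 0L) {
      return(data.frame(contig = character(0), pos = integer(0)))
    }
    d <- unique(d[, c("contig", "pos")])
    rownames(d) <- NULL
    d
  }
  inc <- exon_inclusion_labels(model, circ_set)
  bsj <- list(); lj_all <- list(); lj_inc <- list(); lj_exc <- list()
  for (i in seq_len(nrow(circ_set))) {
    js <- build_bsj_sequence(genome, model, circ_set[i, ], w = w)
    occ <- find_occurrences(js, pattern)
    occ <- occ[occ$spans_junction, , drop = FALSE]
    for (r in seq_len(nrow(occ))) {
      bsj[[length(bsj) + 1L]] <-
        junction_interval_to_genomic(model, js, occ$start[r], occ$end[r])
    }
  }
  for (js in build_lj_sequences(genome, model, w = w)) {
    occ <- find_occurrences(js, pattern)
    occ <- occ[occ$spans_junction, , drop = FALSE]
    if (nrow(occ) == 0L) next
    both <- unname(c(inc[as.character(js$donor_exon)],
                     inc[as.character(js$acceptor_exon)]))
    for (r in seq_len(nrow(occ))) {
      g <- junction_interval_to_genomic(model, js, occ$start[r], occ$end[r])
      lj_all[[length(lj_all) + 1L]] <- g
      if (all(both == "included_in_circRNA")) lj_inc[[length(lj_inc) + 1L]] <- g
      if (all(both == "excluded")) lj_exc[[length(lj_exc) + 1L]] <- g
    }
  }
  we <- scan_exon_bodies(genome, model, pattern)
  wes <- lapply(seq_len(nrow(we)), function(r) {
    data.frame(contig = model$contig,
               pos = exon_offset_to_genomic(model, we$exon_number[r],
                                            seq(we$start[r], we$end[r])))
  })
  list(
    motif_lj_all = uniq(do.call(rbind, lj_all)),
    motif_lj_included = uniq(do.call(rbind, lj_inc)),
    motif_lj_excluded = uniq(do.call(rbind, lj_exc)),
    motif_bsj = uniq(do.call(rbind, bsj)),
    motif_within_exon = uniq(do.call(rbind, wes))
  )
}

#' Constraint report over site classes
#'
#' Computes observed and expected rare-variant counts per class, calibrates
#' the neutral model on the named calibration class, and reports o/e with
#' its exact Poisson CI; classes with `ci_high < 1` are flagged constrained.
#'
#' @param classes named list of site data.frames (`contig, pos[, alt]`).
#' @param variants variant table (rare-filtered internally).
#' @param genome,rates,methyl,depths,dm see [expected_variants()].
#' @param calibration name of the calibration class (default
#'   `"synonymous"`; NULL = no calibration, lambda 1).
#' @param level CI level.
#' @param af_threshold rare allele-frequency cutoff.
#' @return data.frame: label, observed, expected, oe, ci90_low, ci90_high,
#'   constrained_flag.
#' @export
constraint_report <- function(classes, variants, genome, rates, methyl = NULL,
                              depths = NULL, dm = NULL,
                              calibration = "synonymous", level = 0.90,
                              af_threshold = 0.001) {
  rare <- filter_rare(variants, af_threshold)
  exp_uncal <- vapply(classes, function(s) {
    expected_variants(genome, s, rates, methyl, depths, dm)
  }, numeric(1))
  obs <- vapply(classes, function(s) as.numeric(observed_count(rare, s)), numeric(1))
  lam <- 1
  if (!is.null(calibration)) {
    if (!calibration %in% names(classes)) {
      stop("calibration class '", calibration, "' not among classes")
    }
    lam <- calibrate_lambda(obs[[calibration]], exp_uncal[[calibration]])
  }
  rows <- lapply(names(classes), function(nm) {
    if (nrow(classes[[nm]]) == 0L) {
      return(data.frame(label = nm, observed = 0L, expected = 0, oe = NA_real_,
                        ci90_low = NA_real_, ci90_high = NA_real_,
                        constrained_flag = NA, stringsAsFactors = FALSE))
    }
    r <- oe_with_ci(obs[[nm]], lam * exp_uncal[[nm]], level = level, label = nm)
    data.frame(label = nm, observed = r$observed, expected = r$expected,
               oe = r$oe, ci90_low = r$ci_low, ci90_high = r$ci_high,
               constrained_flag = r$ci_high < 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
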