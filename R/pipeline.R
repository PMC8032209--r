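#' Build BSJ sequences for every junction of a table
#'
#' @param genome genome `DNAStringSet`.
#' @param models named list of `exon_model`s.
#' @param junctions `circ_junctions` table.
#' @param w window half-width.
#' @return list of `junction_seq`, one per junction row.
#' @export
bsj_sequences <- function(genome, models, junctions, w = 25L) {
  lapply(seq_len(nrow(junctions)), function(i) {
    cj <- junctions[i, ]
    build_bsj_sequence(genome, models[[cj$transcript_id]], cj, w = w)
  })
}

#' Junction-motif discovery stage
#'
#' Discovers the junction-spanning consensus of the RBM20-dependent class,
#' then counts junction-spanning carriers of that consensus in the TTN and
#' non-TTN classes and the dependent-class prevalence.
#'
#' @param ds dataset list from [generate_dataset()] (or equivalent fields
#'   `genome`, `models`, `junctions`).
#' @param k_min,k_max,min_prevalence see [discover_consensus()].
#' @param w window half-width (default from the dataset config).
#' @return list: `consensus` (`consensus_result`), `ttn_carriers`,
#'   `other_carriers`, `n_dependent`, `prevalence_pct` (rounded percent of
#'   dependent junctions forming the consensus).
#' @export
run_motif_stage <- function(ds, k_min = 5L, k_max = 12L, min_prevalence = 0.5,
                            w = NULL) {
  w <- w %||% ds$cfg$window %||% 25L
  jx <- ds$junctions
  bsj <- bsj_sequences(ds$genome, ds$models, jx, w = w)
  dep <- jx$dependency_class == "rbm20_dependent"
  cons <- discover_consensus(bsj[dep], k_min, k_max, min_prevalence)
  if (is.na(cons$consensus)) {
    return(list(consensus = cons, ttn_carriers = NA_integer_,
                other_carriers = NA_integer_, n_dependent = sum(dep),
                prevalence_pct = NA_integer_))
  }
  spans <- vapply(bsj, function(j) {
    any(find_occurrences(j, cons$consensus)$spans_junction)
  }, logical(1))
  ttn <- jx$host_class == "TTN"
  list(consensus = cons,
       ttn_carriers = sum(spans & ttn),
       other_carriers = sum(spans & !ttn),
       n_dependent = sum(dep),
       prevalence_pct = as.integer(round(100 * sum(spans & dep) / sum(dep))))
}

#' Genetic-constraint stage on the synthetic dataset
#'
#' Builds the five motif site classes plus synonymous/missense/truncating
#' validation classes on the TTN-like transcript, simulates rare variants
#' under the config's selection-thinning map, fits the depth-correction
#' coefficients on synonymous sites, calibrates the neutral model on the
#' synonymous class and reports o/e with 90% CIs.
#'
#' @param ds dataset from [generate_dataset()].
#' @param pattern motif whose sites are classified (default: the planted
#'   motif recorded in the manifest).
#' @param exon_numbers exons over which the consequence classes are built
#'   (default all).
#' @param thinning named selection map (label -> s); defaults from config.
#' @param fit_depth fit depth coefficients from the data (default TRUE;
#'   FALSE uses the generator's detection model).
#' @return list: `classes`, `variants`, `depths`, `dm`, `report`.
#' @export
run_constraint_stage <- function(ds, pattern = NULL, exon_numbers = NULL,
                                 thinning = NULL, fit_depth = TRUE) {
  cfg <- ds$cfg
  pattern <- pattern %||% ds$manifest$motif
  thinning <- thinning %||% cfg$selection_thinning
  ttn_jx <- ds$junctions[ds$junctions$host_class == "TTN", , drop = FALSE]
  motif_classes <- build_motif_site_classes(ds$genome, ds$models$TTN, ttn_jx,
                                            pattern, w = cfg$window)
  cons_classes <- consequence_site_classes(ds$genome, ds$models$TTN, exon_numbers)
  classes <- c(motif_classes, cons_classes)
  pos_all <- unique(unlist(lapply(classes, `[[`, "pos")))
  depths <- generate_depths(cfg, ds$models$TTN$contig, pos_all)
  site_s <- do.call(rbind, lapply(names(classes), function(nm) {
    s <- classes[[nm]]
    if (nrow(s) == 0L) return(NULL)
    if (is.null(s$alt)) s$alt <- NA_character_
    s$s <- unname(if (nm %in% names(thinning)) thinning[[nm]] else thinning[["default"]])
    s[, c("contig", "pos", "alt", "s")]
  }))
  variants <- generate_variants(cfg, ds$genome, ds$rates, site_s,
                                ds$methyl, depths)
  dm <- depth_model()
  if (fit_depth) {
    syn <- classes$synonymous
    rare <- filter_rare(variants, cfg$rare_af_threshold)
    comp <- expected_components(ds$genome, syn, ds$rates, ds$methyl)
    d_syn <- unname(depths[paste0(comp$contig, ":", comp$pos)])
    obs_i <- as.integer(paste(comp$contig, comp$pos, comp$alt) %in%
                          paste(rare$contig, rare$pos, rare$alt))
    dm <- fit_depth_model(d_syn, obs_i, comp$rate, d0 = dm$d0)
  }
  report <- constraint_report(classes, variants, ds$genome, ds$rates,
                              ds$methyl, depths, dm,
                              calibration = "synonymous",
                              af_threshold = cfg$rare_af_threshold)
  list(classes = classes, variants = variants, depths = depths,
       dm = dm, report = report)
}
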