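#' Junction-spanning k-mers of one sequence
#'
#' All exact k-mers whose occurrence covers the junction point (the boundary
#' between position `junction_offset` and `junction_offset + 1`).
#'
#' @param js `junction_seq`.
#' @param k k-mer length.
#' @return character vector of unique spanning k-mers (possibly empty).
#' @export
spanning_kmers <- function(js, k) {
  L <- nchar(js$seq); off <- js$junction_offset
  lo <- max(1L, off - k + 2L); hi <- min(off, L - k + 1L)
  if (lo > hi) return(character(0))
  unique(substring(js$seq, lo:hi, lo:hi + k - 1L))
}

#' Discover the shared junction-spanning consensus of a sequence class
#'
#' Exhaustive exact k-mer voting: over all k in `[k_min, k_max]` and all
#' k-mers that span the junction in at least `min_prevalence` of the class
#' sequences, returns the k-mer maximising prevalence, ties broken by larger
#' k, then lexicographically smallest. Prevalence is the fraction of all
#' class sequences carrying a junction-spanning exact occurrence.
#'
#' @param class_seqs list of `junction_seq` objects.
#' @param k_min,k_max k-mer length range searched (defaults 5..12).
#' @param min_prevalence minimum fraction of sequences (default 0.5).
#' @return list of class `consensus_result`: `consensus` (NA if none
#'   reaches `min_prevalence`), `k`, `prevalence`, `carrier_ids`,
#'   `n_sequences`, `diagnostic`.
#' @export
discover_consensus <- function(class_seqs, k_min = 5L, k_max = 12L,
                               min_prevalence = 0.5) {
  stopifnot(length(class_seqs) > 0L, k_min >= 1L, k_min <= k_max)
  half_min <- min(vapply(class_seqs, function(j) {
    min(j$junction_offset, nchar(j$seq) - j$junction_offset)
  }, integer(1)))
  if (k_max > 2L * half_min) {
    stop("k_max (", k_max, ") exceeds twice the minimum junction half-length (",
         half_min, ")")
  }
  n <- length(class_seqs)
  best <- NULL
  for (k in seq(k_min, k_max)) {
    votes <- table(unlist(lapply(class_seqs, spanning_kmers, k = k)))
    votes <- votes[votes / n >= min_prevalence]
    if (length(votes) == 0L) next
    prev <- max(votes) / n
    cand <- sort(names(votes)[votes == max(votes)])[1]
    if (is.null(best) || prev >= best$prevalence) {
      # >= : equal prevalence at larger k wins (k ascends)
      best <- list(consensus = cand, k = k, prevalence = prev)
    }
  }
  if (is.null(best)) {
    return(structure(list(consensus = NA_character_, k = NA_integer_,
                          prevalence = 0, carrier_ids = character(0),
                          n_sequences = n,
                          diagnostic = sprintf(
                            "no k-mer in [%d,%d] spans the junction in >= %.0f%% of %d sequences",
                            k_min, k_max, 100 * min_prevalence, n)),
                     class = "consensus_result"))
  }
  carriers <- vapply(class_seqs, function(j) {
    any(find_occurrences(j, best$consensus)$spans_junction)
  }, logical(1))
  structure(list(consensus = best$consensus, k = best$k,
                 prevalence = best$prevalence,
                 carrier_ids = vapply(class_seqs[carriers], `[[`, character(1), "id"),
                 n_sequences = n, diagnostic = NA_character_),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  if (is.na(x$consensus)) {
    cat("<consensus_result> none:", x$diagnostic, "\n")
  } else {
    cat(sprintf("<consensus_result> %s (k=%d) prevalence %.1f%% (%d/%d carriers)\n",
                x$consensus, x$k, 100 * x$prevalence,
                length(x$carrier_ids), x$n_sequences))
  }
  invisible(x)
}

#' Read an ATtRACT-like motif table
#'
#' TSV with columns `motif_id`, `rbp_name`, `pattern` (IUPAC, length >= 3).
#'
#' @param path TSV path.
#' @export
read_motif_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("motif_id", "rbp_name", "pattern")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) stop("motif table missing columns: ", paste(miss, collapse = ", "))
  motif_table(d$motif_id, d$rbp_name, d$pattern)
}

#' @rdname read_motif_table
#' @param motif_id,rbp_name,pattern vectors of motif records.
#' @export
motif_table <- function(motif_id, rbp_name, pattern) {
  pattern <- toupper(pattern)
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", pattern) & nchar(pattern) >= 3L
  if (any(!ok)) stop("invalid IUPAC pattern(s): ", paste(pattern[!ok], collapse = ","))
  data.frame(motif_id = as.character(motif_id), rbp_name = as.character(rbp_name),
             pattern = pattern, stringsAsFactors = FALSE)
}

seq_chars <- function(seqs) {
  if (inherits(seqs, "junction_seq")) seqs <- list(seqs)
  if (is.list(seqs)) {
    ids <- vapply(seqs, function(s) if (inherits(s, "junction_seq")) s$id else NA_character_,
                  character(1))
    seqs <- vapply(seqs, function(s) if (inherits(s, "junction_seq")) s$seq else as.character(s),
                   character(1))
    if (anyNA(ids)) ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
    names(seqs) <- ids
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Presence of each motif in each sequence
#'
#' Presence means at least one IUPAC occurrence anywhere in the sequence.
#'
#' @param seqs list of `junction_seq` objects or character vector.
#' @param motifs motif table (see [motif_table()]).
#' @return logical matrix, rows = sequences, columns = motif ids.
#' @export
scan_motif_table <- function(seqs, motifs) {
  seqs <- seq_chars(seqs)
  if (nrow(motifs) == 0L) {
    return(matrix(logical(0), nrow = length(seqs), ncol = 0,
                  dimnames = list(names(seqs), character(0))))
  }
  subj <- Biostrings::DNAStringSet(seqs)
  pres <- vapply(motifs$pattern, function(p) {
    Biostrings::vcountPattern(p, subj, fixed = c(pattern = FALSE, subject = TRUE)) > 0L
  }, logical(length(seqs)))
  pres <- matrix(pres, nrow = length(seqs),
                 dimnames = list(names(seqs), motifs$motif_id))
  pres
}

fisher_or_p <- function(a, b, c, d) {
  # 2x2: rows present/absent, cols set A/set B
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
  if (any(c(a, b, c, d) == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  c(or = or, p = p)
}

#' Motif enrichment between two sequence sets
#'
#' Per motif, a 2x2 presence table (sequences with >= 1 occurrence vs
#' without, in set A vs set B), two-sided Fisher exact p, the sample odds
#' ratio (Haldane-Anscombe 0.5 correction when any cell is zero) and
#' Benjamini-Hochberg q across the motifs of this comparison.
#'
#' @param set_a,set_b sequence sets (lists of `junction_seq` or character).
#' @param motifs motif table.
#' @return data.frame: motif_id, rbp_name, count_a, total_a, count_b,
#'   total_b, odds_ratio, p_value, q_value, ordered by q then p.
#' @export
enrichment_compare <- function(set_a, set_b, motifs) {
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("both sequence sets must be non-empty")
  }
  pa <- scan_motif_table(set_a, motifs)
  pb <- scan_motif_table(set_b, motifs)
  enrichment_from_counts(colSums(pa), nrow(pa), colSums(pb), nrow(pb), motifs)
}

#' Enrichment rows from precomputed presence counts
#'
#' @param count_a,count_b per-motif presence counts (named by motif_id).
#' @param total_a,total_b set sizes (scalars or per-motif vectors).
#' @param motifs motif table aligned with the counts.
#' @export
enrichment_from_counts <- function(count_a, total_a, count_b, total_b, motifs) {
  stopifnot(length(count_a) == nrow(motifs), length(count_b) == nrow(motifs))
  total_a <- rep_len(total_a, nrow(motifs))
  total_b <- rep_len(total_b, nrow(motifs))
  stopifnot(all(count_a <= total_a), all(count_b <= total_b))
  orp <- t(mapply(function(ca, ta, cb, tb) fisher_or_p(ca, ta - ca, cb, tb - cb),
                  count_a, total_a, count_b, total_b))
  out <- data.frame(motif_id = motifs$motif_id, rbp_name = motifs$rbp_name,
                    count_a = as.integer(count_a), total_a = as.integer(total_a),
                    count_b = as.integer(count_b), total_b = as.integer(total_b),
                    odds_ratio = orp[, "or"], p_value = orp[, "p"],
                    q_value = stats::p.adjust(orp[, "p"], method = "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$q_value, out$p_value, out$motif_id), ]
}

#' Cut sequences into non-overlapping tiles
#'
#' Used when comparing sets of very different sequence lengths (full circRNA
#' vs linear mRNA): presence is computed per tile and the 2x2 table counts
#' tiles, removing length confounding. A trailing remainder shorter than
#' `tile` is kept if it is at least half a tile.
#'
#' @param seqs character vector of sequences.
#' @param tile tile width in nt (default 500).
#' @return named character vector of tiles.
#' @export
tile_sequences <- function(seqs, tile = 500L) {
  seqs <- seq_chars(seqs)
  out <- character(0)
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    starts <- seq(1L, max(1L, L), by = tile)
    for (s in starts) {
      e <- min(L, s + tile - 1L)
      if (e - s + 1L >= tile / 2 || s == 1L) {
        out[sprintf("%s_t%d", names(seqs)[i], s)] <- substr(seqs[i], s, e)
      }
    }
  }
  out
}

#' Run the standard enrichment comparisons of the junction-motif analysis
#'
#' Five comparisons: (1) BSJ sequences of RBM20-dependent vs -independent
#' circRNAs; (2) BSJ sequences of TTN-hosted vs other circRNAs; (3) full
#' circRNA sequences of TTN vs other circRNAs; (4) 500-nt tiles of TTN
#' circRNA sequences vs tiles of the linear TTN mRNA; (5) TTN exons included
#' in at least one circRNA vs exons in none.
#'
#' @param genome genome `DNAStringSet`.
#' @param models named list of `exon_model`s (must contain the TTN-like
#'   transcript named in `ttn_id`).
#' @param junctions `circ_junctions` table over those transcripts.
#' @param motifs motif table.
#' @param ttn_id transcript id of the TTN-like host (default "TTN").
#' @param w BSJ/LJ window half-width.
#' @param tile tile width for the linear-mRNA comparison.
#' @return named list of enrichment data.frames.
#' @export
run_standard_comparisons <- function(genome, models, junctions, motifs,
                                     ttn_id = "TTN", w = 25L, tile = 500L) {
  need <- c("rbm20_dependent", "rbm20_independent")
  miss <- setdiff(need, unique(junctions$dependency_class))
  if (length(miss) > 0) stop("missing dependency class(es): ", paste(miss, collapse = ","))
  if (!ttn_id %in% names(models)) stop("no exon model for ", ttn_id)
  bsj <- lapply(seq_len(nrow(junctions)), function(i) {
    cj <- junctions[i, ]
    build_bsj_sequence(genome, models[[cj$transcript_id]], cj, w = w)
  })
  dep <- junctions$dependency_class == "rbm20_dependent"
  ttn <- junctions$host_class == "TTN"
  circ <- vapply(seq_len(nrow(junctions)), function(i) {
    cj <- junctions[i, ]
    circ_sequence(genome, models[[cj$transcript_id]], cj)
  }, character(1))
  names(circ) <- junctions$junction_id
  mrna <- stats::setNames(transcript_sequence(genome, models[[ttn_id]]), ttn_id)
  inc <- exon_inclusion_labels(models[[ttn_id]], junctions)
  exseq <- vapply(models[[ttn_id]]$exons$exon_number, function(e) {
    exon_sequence(genome, models[[ttn_id]], e)
  }, character(1))
  names(exseq) <- paste0("exon", models[[ttn_id]]$exons$exon_number)
  inc_ex <- exseq[inc == "included_in_circRNA"]
  exc_ex <- exseq[inc == "excluded"]
  out <- list(
    bsj_dependent_vs_independent = enrichment_compare(bsj[dep], bsj[!dep], motifs),
    bsj_ttn_vs_other = enrichment_compare(bsj[ttn], bsj[!ttn], motifs),
    circ_ttn_vs_other = enrichment_compare(circ[ttn], circ[!ttn], motifs),
    circ_ttn_vs_linear_mrna = enrichment_compare(
      tile_sequences(circ[ttn], tile), tile_sequences(mrna, tile), motifs),
    exons_included_vs_excluded =
      if (length(inc_ex) > 0L && length(exc_ex) > 0L)
        enrichment_compare(inc_ex, exc_ex, motifs) else NULL
  )
  out
}

#' Write one enrichment comparison as TSV
#' @param rows enrichment data.frame.
#' @param path output path.
#' @export
write_enrichment <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
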