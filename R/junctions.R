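#' Circular-RNA junction table
#'
#' A back-splice junction joins the donor (3') end of the downstream exon to
#' the acceptor (5') end of the upstream exon, so in exon-number space a
#' circle is the interval `[acceptor_exon, donor_exon]` with
#' `acceptor_exon <= donor_exon`.
#'
#' @param transcript_id,acceptor_exon,donor_exon vectors defining one
#'   junction per element.
#' @param dependency_class `"rbm20_dependent"` or `"rbm20_independent"`.
#' @param host_class `"TTN"` or `"other"`.
#' @return data.frame of class `circ_junctions` with a `junction_id` column.
#' @export
circ_junctions <- function(transcript_id, acceptor_exon, donor_exon,
                           dependency_class, host_class) {
  acceptor_exon <- as.integer(acceptor_exon)
  donor_exon <- as.integer(donor_exon)
  if (any(acceptor_exon > donor_exon)) {
    stop("acceptor_exon > donor_exon for junction ",
         which(acceptor_exon > donor_exon)[1])
  }
  stopifnot(all(dependency_class %in% c("rbm20_dependent", "rbm20_independent")),
            all(host_class %in% c("TTN", "other")))
  d <- data.frame(
    junction_id = sprintf("%s_e%d_e%d", transcript_id, acceptor_exon, donor_exon),
    transcript_id = transcript_id,
    acceptor_exon = acceptor_exon, donor_exon = donor_exon,
    dependency_class = dependency_class, host_class = host_class,
    stringsAsFactors = FALSE
  )
  class(d) <- c("circ_junctions", "data.frame")
  d
}

#' @rdname circ_junctions
#' @param path TSV with columns transcript_id, acceptor_exon, donor_exon,
#'   dependency_class, host_class.
#' @export
read_junctions <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  circ_junctions(d$transcript_id, d$acceptor_exon, d$donor_exon,
                 d$dependency_class, d$host_class)
}

#' @rdname circ_junctions
#' @param junctions a `circ_junctions` data.frame.
#' @export
write_junctions <- function(junctions, path) {
  utils::write.table(
    junctions[, c("transcript_id", "acceptor_exon", "donor_exon",
                  "dependency_class", "host_class")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_junction_seq <- function(seq, junction_offset, origin, transcript_id,
                             donor_exon, acceptor_exon, id) {
  stopifnot(junction_offset > 0L, junction_offset < nchar(seq))
  structure(
    list(id = id, seq = seq, junction_offset = as.integer(junction_offset),
         origin = origin, transcript_id = transcript_id,
         donor_exon = as.integer(donor_exon),
         acceptor_exon = as.integer(acceptor_exon)),
    class = "junction_seq"
  )
}

#' @export
print.junction_seq <- function(x, ...) {
  cat(sprintf("<junction_seq %s> %s | offset %d\n%s*%s\n", x$origin, x$id,
              x$junction_offset, substr(x$seq, 1, x$junction_offset),
              substr(x$seq, x$junction_offset + 1, nchar(x$seq))))
  invisible(x)
}

#' Build the back-splice-junction sequence of a circRNA
#'
#' Takes the last `min(w, exon length)` bases of the donor exon followed by
#' the first `min(w, exon length)` bases of the acceptor exon, both in
#' transcript orientation. The window never walks into a neighbouring exon,
#' so the sequence is independent of the circle's internal splicing.
#'
#' @param genome genome `DNAStringSet`.
#' @param model `exon_model` of the host transcript.
#' @param cj one-row slice of a `circ_junctions` table (or a list with
#'   `acceptor_exon`, `donor_exon`, `junction_id`).
#' @param w window half-width in bases (default 25).
#' @return a `junction_seq` with `origin = "BSJ"`; `junction_offset` is the
#'   number of donor-side bases.
#' @export
build_bsj_sequence <- function(genome, model, cj, w = 25L) {
  don <- exon_row(model, cj$donor_exon)
  acc <- exon_row(model, cj$acceptor_exon)
  if (don$width == 0L || acc$width == 0L) stop("zero-length exon in junction")
  dseq <- exon_sequence(genome, model, cj$donor_exon)
  aseq <- exon_sequence(genome, model, cj$acceptor_exon)
  dn <- min(w, nchar(dseq)); an <- min(w, nchar(aseq))
  new_junction_seq(
    seq = paste0(substr(dseq, nchar(dseq) - dn + 1L, nchar(dseq)),
                 substr(aseq, 1L, an)),
    junction_offset = dn, origin = "BSJ",
    transcript_id = model$transcript_id,
    donor_exon = cj$donor_exon, acceptor_exon = cj$acceptor_exon,
    id = if (!is.null(cj$junction_id)) cj$junction_id else
      sprintf("%s_e%d_e%d", model$transcript_id, cj$acceptor_exon, cj$donor_exon)
  )
}

#' Build all linear-junction sequences of a transcript
#'
#' One sequence per adjacent exon pair (i, i+1): suffix of exon i followed by
#' prefix of exon i+1, clamped to exon lengths.
#'
#' @inheritParams build_bsj_sequence
#' @return list of `junction_seq` objects with `origin = "LJ"`, length N-1.
#' @export
build_lj_sequences <- function(genome, model, w = 25L) {
  n <- n_exons(model)
  if (n < 2L) stop("linear junctions need >= 2 exons")
  lapply(seq_len(n - 1L), function(i) {
    dseq <- exon_sequence(genome, model, i)
    aseq <- exon_sequence(genome, model, i + 1L)
    dn <- min(w, nchar(dseq)); an <- min(w, nchar(aseq))
    new_junction_seq(
      seq = paste0(substr(dseq, nchar(dseq) - dn + 1L, nchar(dseq)),
                   substr(aseq, 1L, an)),
      junction_offset = dn, origin = "LJ",
      transcript_id = model$transcript_id,
      donor_exon = i, acceptor_exon = i + 1L,
      id = sprintf("%s_lj_%d_%d", model$transcript_id, i, i + 1L)
    )
  })
}

#' Mature circRNA sequence (all exons acceptor..donor)
#'
#' @inheritParams build_bsj_sequence
#' @return character string of the concatenated exons in transcript order.
#' @export
circ_sequence <- function(genome, model, cj) {
  paste(vapply(seq(cj$acceptor_exon, cj$donor_exon), function(i) {
    exon_sequence(genome, model, i)
  }, character(1)), collapse = "")
}

#' Find IUPAC motif occurrences in a junction sequence
#'
#' Matches `pattern` (IUPAC degenerate alphabet) at every position of the
#' sequence; an occurrence spans the junction when it covers both the last
#' donor-side base and the first acceptor-side base.
#'
#' @param js a `junction_seq`, or a plain character string (then
#'   `junction_offset` must be given).
#' @param pattern IUPAC pattern string.
#' @param junction_offset override for plain-string input.
#' @return data.frame with `start`, `end` (1-based inclusive) and
#'   `spans_junction`; zero rows when the pattern is longer than the
#'   sequence or never matches.
#' @export
find_occurrences <- function(js, pattern, junction_offset = NULL) {
  if (inherits(js, "junction_seq")) {
    seq <- js$seq; off <- js$junction_offset
  } else {
    seq <- as.character(js); off <- junction_offset
  }
  if (is.null(off)) stop("junction_offset required for plain sequences")
  pattern <- toupper(pattern)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", pattern)) {
    stop("invalid IUPAC pattern: ", pattern)
  }
  k <- nchar(pattern)
  if (k > nchar(seq)) {
    return(data.frame(start = integer(0), end = integer(0),
                      spans_junction = logical(0)))
  }
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                fixed = c(pattern = FALSE, subject = TRUE))
  st <- BiocGenerics::start(m)
  data.frame(start = st, end = st + k - 1L,
             spans_junction = st <= off & st + k - 1L >= off + 1L)
}

#' Genomic footprint of a junction-sequence interval
#'
#' Maps positions `start..end` of a BSJ or LJ `junction_seq` back to genomic
#' coordinates through the exon model. Donor-side positions land at the 3'
#' end of the donor exon, acceptor-side positions at the 5' start of the
#' acceptor exon.
#'
#' @param model `exon_model`.
#' @param js `junction_seq`.
#' @param start,end 1-based inclusive interval within `js$seq`.
#' @return data.frame `contig`, `pos` (one row per base, transcript order),
#'   plus `side` ("donor"/"acceptor") and `exon_number`.
#' @export
junction_interval_to_genomic <- function(model, js, start, end) {
  stopifnot(start >= 1L, end <= nchar(js$seq), start <= end)
  off <- js$junction_offset
  don <- exon_row(model, js$donor_exon)
  pos_one <- function(p) {
    if (p <= off) {
      eoff <- don$width - off + p  # offset within donor exon
      c(exon = js$donor_exon, side = 1L,
        g = exon_offset_to_genomic(model, js$donor_exon, eoff))
    } else {
      c(exon = js$acceptor_exon, side = 2L,
        g = exon_offset_to_genomic(model, js$acceptor_exon, p - off))
    }
  }
  m <- t(vapply(seq(start, end), pos_one, c(exon = 0L, side = 0L, g = 0L)))
  data.frame(contig = model$contig, pos = as.integer(m[, "g"]),
             side = c("donor", "acceptor")[m[, "side"]],
             exon_number = as.integer(m[, "exon"]))
}

#' Exon inclusion labels relative to a circRNA set
#'
#' An exon is `included_in_circRNA` iff its number lies within
#' `[acceptor_exon, donor_exon]` of at least one circle of the host
#' transcript; otherwise `excluded`.
#'
#' @param model `exon_model`.
#' @param circ_set `circ_junctions` table.
#' @return character vector over the model's exons, named by exon number.
#' @export
exon_inclusion_labels <- function(model, circ_set) {
  cs <- circ_set[circ_set$transcript_id == model$transcript_id, , drop = FALSE]
  inc <- vapply(model$exons$exon_number, function(e) {
    any(e >= cs$acceptor_exon & e <= cs$donor_exon)
  }, logical(1))
  stats::setNames(ifelse(inc, "included_in_circRNA", "excluded"),
                  model$exons$exon_number)
}

#' Scan exon bodies for motif occurrences
#'
#' Finds all IUPAC occurrences fully inside single exons of a transcript
#' (class `within_exon`), with their genomic footprints.
#'
#' @inheritParams exon_inclusion_labels
#' @param genome genome `DNAStringSet`.
#' @param pattern IUPAC pattern.
#' @return data.frame `exon_number`, `start` (exon-local, transcript
#'   orientation), `end`.
#' @export
scan_exon_bodies <- function(genome, model, pattern) {
  k <- nchar(pattern)
  res <- lapply(model$exons$exon_number, function(e) {
    s <- exon_sequence(genome, model, e)
    if (nchar(s) < k) return(NULL)
    m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(s),
                                  fixed = c(pattern = FALSE, subject = TRUE))
    if (length(m) == 0L) return(NULL)
    data.frame(exon_number = e, start = BiocGenerics::start(m),
               end = BiocGenerics::start(m) + k - 1L)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(exon_number = integer(0), start = integer(0),
                               end = integer(0)) else out
}

#' Classify motif occurrences by how their sequence context was formed
#'
#' Scans the BSJ sequences of a circRNA set, all LJ sequences and all exon
#' bodies of a transcript for a pattern and labels each occurrence
#' `bsj_created`, `lj_created` or `within_exon`. Junction occurrences that do
#' not span their junction are redundant with the exon-body scan and are
#' dropped. Each occurrence also carries the inclusion label(s) of the
#' exon(s) it touches.
#'
#' @inheritParams scan_exon_bodies
#' @param circ_set `circ_junctions` for the transcript.
#' @param w junction window half-width.
#' @return data.frame with `occurrence_class`, `junction_id` (NA for
#'   within-exon), `donor_exon`, `acceptor_exon`, `exon_number` (within-exon
#'   only), `start`, `inclusion` (for LJ/within-exon classes).
#' @export
classify_genomic_motif_sites <- function(genome, model, circ_set, pattern,
                                         w = 25L) {
  inc <- exon_inclusion_labels(model, circ_set)
  rows <- list()
  for (i in seq_len(nrow(circ_set))) {
    js <- build_bsj_sequence(genome, model, circ_set[i, ], w = w)
    occ <- find_occurrences(js, pattern)
    occ <- occ[occ$spans_junction, , drop = FALSE]
    if (nrow(occ) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        occurrence_class = "bsj_created", junction_id = js$id,
        donor_exon = js$donor_exon, acceptor_exon = js$acceptor_exon,
        exon_number = NA_integer_, start = occ$start,
        inclusion = "included_in_circRNA")
    }
  }
  for (js in build_lj_sequences(genome, model, w = w)) {
    occ <- find_occurrences(js, pattern)
    occ <- occ[occ$spans_junction, , drop = FALSE]
    if (nrow(occ) > 0L) {
      both <- unname(c(inc[as.character(js$donor_exon)],
                       inc[as.character(js$acceptor_exon)]))
      lab <- if (all(both == "included_in_circRNA")) "included_in_circRNA"
             else if (all(both == "excluded")) "excluded" else "mixed"
      rows[[length(rows) + 1L]] <- data.frame(
        occurrence_class = "lj_created", junction_id = js$id,
        donor_exon = js$donor_exon, acceptor_exon = js$acceptor_exon,
        exon_number = NA_integer_, start = occ$start, inclusion = lab)
    }
  }
  we <- scan_exon_bodies(genome, model, pattern)
  if (nrow(we) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      occurrence_class = "within_exon", junction_id = NA_character_,
      donor_exon = NA_integer_, acceptor_exon = NA_integer_,
      exon_number = we$exon_number, start = we$start,
      inclusion = unname(inc[as.character(we$exon_number)]))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(occurrence_class = character(0), junction_id = character(0),
                      donor_exon = integer(0), acceptor_exon = integer(0),
                      exon_number = integer(0), start = integer(0),
                      inclusion = character(0))
  }
  rownames(out) <- NULL
  out
}
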