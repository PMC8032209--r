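#' Exon model of a transcript
#'
#' The coordinate authority for all junction work: ordered, numbered exons of
#' a single transcript. Coordinates are 1-based inclusive genomic positions.
#' Exon numbering is in transcript (5'->3') order, so on the minus strand
#' exon 1 is the exon with the highest genomic coordinates.
#'
#' @param transcript_id transcript identifier.
#' @param contig contig name.
#' @param strand "+" or "-".
#' @param starts,ends integer vectors of 1-based inclusive exon coordinates,
#'   in any order.
#' @return an object of class `exon_model`: a list with `transcript_id`,
#'   `contig`, `strand` and an `exons` data.frame
#'   (`exon_number`, `start`, `end`, `width`) sorted in transcript order.
#' @export
exon_model <- function(transcript_id, contig, strand, starts, ends) {
  if (!strand %in% c("+", "-")) {
    stop("unknown strand '", strand, "' for transcript ", transcript_id)
  }
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) == 0L || length(starts) != length(ends)) {
    stop("transcript ", transcript_id, ": need >= 1 exon with matching starts/ends")
  }
  if (any(ends < starts)) stop("transcript ", transcript_id, ": exon end < start")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (length(starts) > 1L && any(starts[-1] <= ends[-length(ends)])) {
    stop("overlapping exons within transcript ", transcript_id)
  }
  # transcript order: ascending genomic on +, descending on -
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
  exons <- data.frame(
    exon_number = seq_along(starts),
    start = starts, end = ends,
    width = ends - starts + 1L
  )
  structure(
    list(transcript_id = transcript_id, contig = contig,
         strand = strand, exons = exons),
    class = "exon_model"
  )
}

#' @export
print.exon_model <- function(x, ...) {
  cat(sprintf("<exon_model> %s %s(%s) %d exons, %d nt exonic\n",
              x$transcript_id, x$contig, x$strand,
              nrow(x$exons), sum(x$exons$width)))
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)

exon_row <- function(model, exon_number) {
  i <- match(exon_number, model$exons$exon_number)
  if (is.na(i)) {
    stop("exon ", exon_number, " not in transcript ", model$transcript_id,
         " (1..", n_exons(model), ")")
  }
  model$exons[i, ]
}

#' Read exon annotation into exon models
#'
#' Parses a GTF (exon features grouped by `transcript_id`) or BED12 file and
#' returns one `exon_model` per transcript. Minus-strand transcripts are
#' numbered from the genomic 3' end so that exon 1 is always the 5'-most exon.
#'
#' @param path annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @return named list of `exon_model` objects (names = transcript ids).
#' @export
read_exon_annotation <- function(path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
    if (length(gr) == 0L) stop("no exon features in ", path)
    ids <- as.character(gr$transcript_id)
    if (anyNA(ids)) stop("exon feature without transcript_id in ", path)
    out <- lapply(split(seq_along(gr), ids), function(i) {
      g <- gr[i]
      str <- unique(as.character(BiocGenerics::strand(g)))
      if (length(str) != 1L || !str %in% c("+", "-")) {
        stop("unknown or mixed strand for transcript ", ids[i[1]])
      }
      exon_model(ids[i[1]], as.character(GenomicRanges::seqnames(g))[1], str,
                 BiocGenerics::start(g), BiocGenerics::end(g))
    })
    out[order(names(out))]
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$blocks)) {
      # single-block BED: each row one exon-less transcript
      gr$blocks <- IRanges::IRangesList(lapply(
        BiocGenerics::width(gr), function(w) IRanges::IRanges(1L, w)
      ))
    }
    out <- lapply(seq_along(gr), function(i) {
      bl <- gr$blocks[[i]]
      str <- as.character(BiocGenerics::strand(gr[i]))
      if (!str %in% c("+", "-")) {
        stop("unknown strand for BED record ", gr$name[i])
      }
      # rtracklayer block starts are relative to chromStart (already 1-based)
      exon_model(gr$name[i], as.character(GenomicRanges::seqnames(gr[i])), str,
                 BiocGenerics::start(gr[i]) + BiocGenerics::start(bl) - 1L,
                 BiocGenerics::start(gr[i]) + BiocGenerics::end(bl) - 1L)
    })
    names(out) <- vapply(out, `[[`, character(1), "transcript_id")
    out[order(names(out))]
  }
}

#' Native TSV round-trip for exon models
#'
#' One row per exon: transcript_id, contig, strand, start, end, exon_number.
#'
#' @param models named list of `exon_model`s.
#' @param path TSV path.
#' @export
write_exon_models <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(m) {
    data.frame(transcript_id = m$transcript_id, contig = m$contig,
               strand = m$strand, start = m$exons$start, end = m$exons$end,
               exon_number = m$exons$exon_number)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exon_models
#' @export
read_exon_models <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$transcript_id), function(g) {
    exon_model(g$transcript_id[1], g$contig[1], g$strand[1], g$start, g$end)
  })
  out[order(names(out))]
}

#' Transcript-orientation sequence of one exon
#'
#' @param genome genome `DNAStringSet`.
#' @param model an `exon_model`.
#' @param exon_number exon number in transcript order.
#' @return character string, 5'->3' in the mRNA.
#' @export
exon_sequence <- function(genome, model, exon_number) {
  e <- exon_row(model, exon_number)
  genome_slice(genome, model$contig, e$start, e$end, model$strand)
}

#' Mature (spliced) transcript sequence
#'
#' Concatenates exon sequences in transcript orientation; minus-strand
#' transcripts are reverse-complemented exon by exon.
#'
#' @inheritParams exon_sequence
#' @return character string of the spliced mRNA.
#' @export
transcript_sequence <- function(genome, model) {
  if (n_exons(model) == 0L) stop("empty exon list")
  clen <- length(genome[[model$contig]])
  if (any(model$exons$start < 1L) || any(model$exons$end > clen)) {
    bad <- model$exons[model$exons$start < 1L | model$exons$end > clen, ]
    stop(sprintf("exon outside contig %s: %d-%d", model$contig,
                 bad$start[1], bad$end[1]))
  }
  paste(vapply(model$exons$exon_number, function(i) {
    exon_sequence(genome, model, i)
  }, character(1)), collapse = "")
}

#' Map an exon-local transcript-orientation offset to a genomic position
#'
#' `offset` 1 is the 5'-most base of the exon in the mRNA; on the minus
#' strand that is the exon's highest genomic coordinate.
#'
#' @inheritParams exon_sequence
#' @param offset integer vector of 1-based offsets within the exon.
#' @return integer vector of 1-based genomic positions.
#' @export
exon_offset_to_genomic <- function(model, exon_number, offset) {
  e <- exon_row(model, exon_number)
  if (any(offset < 1L | offset > e$width)) {
    stop("offset outside exon ", exon_number, " (width ", e$width, ")")
  }
  if (model$strand == "+") e$start + offset - 1L else e$end - offset + 1L
}

#' Map a genomic position to (exon, transcript position)
#'
#' @inheritParams exon_sequence
#' @param pos 1-based genomic position.
#' @return list with `exon_number`, `exon_offset`, `tx_pos` (1-based position
#'   in the spliced transcript), or an error if `pos` is intronic/outside.
#' @export
genomic_to_tx <- function(model, pos) {
  ex <- model$exons
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) != 1L) {
    stop("position ", pos, " is not exonic in transcript ", model$transcript_id)
  }
  off <- if (model$strand == "+") pos - ex$start[hit] + 1L else ex$end[hit] - pos + 1L
  before <- if (hit > 1L) sum(ex$width[seq_len(hit - 1L)]) else 0L
  list(exon_number = ex$exon_number[hit], exon_offset = off,
       tx_pos = before + off)
}
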