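#' Genome sequence container
#'
#' A genome is represented as a named [Biostrings::DNAStringSet], one entry
#' per contig, alphabet restricted to A, C, G, T, N. `genome_seq()` validates
#' an existing `DNAStringSet` (or a named character vector) and
#' `read_genome()` / `write_genome()` move it through FASTA.
#'
#' @param x a named `DNAStringSet` or named character vector of sequences.
#' @return a validated `DNAStringSet`.
#' @export
genome_seq <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (!methods::is(x, "DNAStringSet")) {
    stop("genome must be a DNAStringSet or named character vector")
  }
  if (is.null(names(x)) || anyDuplicated(names(x)) || any(names(x) == "")) {
    stop("genome contigs must have unique non-empty names")
  }
  if (any(Biostrings::width(x) == 0L)) stop("contig sequences must be non-empty")
  freq <- Biostrings::alphabetFrequency(x, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- setdiff(colnames(freq)[colSums(freq) > 0], allowed)
  if (length(bad) > 0) {
    stop("genome contains characters outside A/C/G/T/N: ", paste(bad, collapse = ","))
  }
  x
}

#' @rdname genome_seq
#' @param path FASTA file path.
#' @export
read_genome <- function(path) {
  genome_seq(Biostrings::readDNAStringSet(path))
}

#' @rdname genome_seq
#' @param genome a genome `DNAStringSet`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Look up bases at 1-based genomic positions
#'
#' @param genome genome `DNAStringSet`.
#' @param contig contig name (scalar).
#' @param pos integer vector of 1-based positions.
#' @return character vector of single bases.
#' @export
genome_base <- function(genome, contig, pos) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  s <- genome[[contig]]
  if (any(pos < 1L | pos > length(s))) {
    stop("position outside contig ", contig, " (length ", length(s), ")")
  }
  as.character(Biostrings::extractAt(s, IRanges::IRanges(pos, width = 1L)))
}

#' Fetch a genomic interval as a character string
#'
#' @inheritParams genome_base
#' @param start,end 1-based inclusive interval.
#' @param strand "+" returns the forward sequence, "-" its reverse complement.
#' @export
genome_slice <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  s <- genome[[contig]]
  if (start < 1L || end > length(s) || start > end) {
    stop(sprintf("interval %s:%d-%d outside contig bounds (1-%d)",
                 contig, start, end, length(s)))
  }
  out <- Biostrings::subseq(s, start, end)
  if (strand == "-") out <- Biostrings::reverseComplement(out)
  as.character(out)
}

#' Reverse complement of a character DNA string
#' @param x character vector of DNA strings.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
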