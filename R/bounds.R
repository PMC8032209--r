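#' Number of exons spanned by a back-splice junction
#'
#' The circle formed by back-splicing of `donor_exon` to `acceptor_exon`
#' spans `donor_exon - acceptor_exon + 1` exons (inclusive interval in
#' exon-number space).
#'
#' @param cj one-row `circ_junctions` slice (or list with `acceptor_exon`,
#'   `donor_exon`).
#' @return integer exon span.
#' @export
exon_span <- function(cj) {
  if (cj$acceptor_exon > cj$donor_exon) {
    stop("acceptor exon (", cj$acceptor_exon, ") downstream of donor exon (",
         cj$donor_exon, ")")
  }
  as.integer(cj$donor_exon - cj$acceptor_exon + 1L)
}

#' Exon-inclusion matrix
#'
#' Boolean detection of exons inside circRNAs per sample (RNase-R-treated
#' RNA-seq assembly output). TSV format: first column `exon_number`, one
#' logical/0-1 column per sample.
#'
#' @param exon_number integer vector.
#' @param detected logical matrix (exons x samples) with sample column
#'   names.
#' @export
inclusion_matrix <- function(exon_number, detected) {
  detected <- as.matrix(detected)
  stopifnot(nrow(detected) == length(exon_number), ncol(detected) >= 1L,
            !is.null(colnames(detected)))
  storage.mode(detected) <- "logical"
  rownames(detected) <- exon_number
  structure(list(exon_number = as.integer(exon_number), detected = detected),
            class = "inclusion_matrix")
}

#' @rdname inclusion_matrix
#' @param path TSV path.
#' @export
read_inclusion_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (names(d)[1] != "exon_number") stop("first column must be exon_number")
  inclusion_matrix(d$exon_number, d[, -1, drop = FALSE])
}

#' @rdname inclusion_matrix
#' @param m an `inclusion_matrix`.
#' @export
write_inclusion_matrix <- function(m, path) {
  d <- data.frame(exon_number = m$exon_number,
                  m$detected * 1L, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exon-composition bounds of a circRNA from an inclusion matrix
#'
#' Over the junction's exon span: exons detected in no sample cannot be part
#' of the circle (`max_exons = span - never_included`), exons detected in
#' every sample are taken as its core (`min_exons = always_detected`).
#' Nucleotide size bounds are reported when an `exon_model` supplies exon
#' lengths: the minimum sums the always-detected exons, the maximum sums all
#' in-span exons detected in at least one sample.
#'
#' @param cj one-row junction (acceptor/donor exon numbers).
#' @param m `inclusion_matrix` covering the span.
#' @param model optional `exon_model` for nt sizes.
#' @return list of class `bounds_result`: `span_exons, never_included,
#'   always_detected, max_exons, min_exons, n_samples` and (with a model)
#'   `min_size_nt, max_size_nt`.
#' @export
bounds_from_inclusion <- function(cj, m, model = NULL) {
  span <- seq(cj$acceptor_exon, cj$donor_exon)
  missing_ex <- setdiff(span, m$exon_number)
  if (length(missing_ex) > 0L) {
    stop("inclusion matrix missing in-span exons: ",
         paste(missing_ex, collapse = ","))
  }
  det <- m$detected[match(span, m$exon_number), , drop = FALSE]
  never <- rowSums(det) == 0L
  always <- rowSums(det) == ncol(det)
  out <- list(span_exons = length(span),
              never_included = sum(never),
              always_detected = sum(always),
              max_exons = length(span) - sum(never),
              min_exons = sum(always),
              n_samples = ncol(det))
  if (!is.null(model)) {
    w <- stats::setNames(model$exons$width, model$exons$exon_number)
    out$min_size_nt <- sum(w[as.character(span[always])])
    out$max_size_nt <- sum(w[as.character(span[!never])])
  }
  structure(out, class = "bounds_result")
}

#' @export
print.bounds_result <- function(x, ...) {
  cat(sprintf(
    "<bounds_result> span %d exons | never included %d | always detected %d\n  => %d to %d exons",
    x$span_exons, x$never_included, x$always_detected, x$min_exons, x$max_exons))
  if (!is.null(x$min_size_nt)) {
    cat(sprintf(" (%d to %d nt)", x$min_size_nt, x$max_size_nt))
  }
  cat("\n")
  invisible(x)
}

#' Write a bounds result as JSON
#' @param b `bounds_result`.
#' @param path output path.
#' @export
write_bounds <- function(b, path) {
  jsonlite::write_json(unclass(b), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
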