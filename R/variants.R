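#' Read a rare-variant table
#'
#' Accepts either a TSV with columns `contig, pos, ref, alt, AC, AN,
#' DP_median` or a VCF 4.x file whose INFO field carries `AC`, `AN` and
#' `DP_MEDIAN`. Only single-nucleotide substitutions are retained; indels and
#' multi-allelic rows are skipped and counted (attribute `n_skipped`).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return data.frame with columns `contig, pos, ref, alt, allele_count,
#'   allele_number, median_depth`; attribute `n_skipped` holds the number of
#'   non-SNV rows dropped.
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig", "pos", "ref", "alt", "AC", "AN", "DP_median")
    miss <- setdiff(need, names(d))
    if (length(miss) > 0) stop("variant TSV missing columns: ", paste(miss, collapse = ", "))
    tab <- data.frame(contig = as.character(d$contig), pos = as.integer(d$pos),
                      ref = toupper(d$ref), alt = toupper(d$alt),
                      allele_count = as.integer(d$AC),
                      allele_number = as.integer(d$AN),
                      median_depth = as.numeric(d$DP_median),
                      stringsAsFactors = FALSE)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- v@fix
    ac <- suppressWarnings(as.integer(vcfR::extract.info(v, "AC")))
    an <- suppressWarnings(as.integer(vcfR::extract.info(v, "AN")))
    dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP_MEDIAN")))
    tab <- data.frame(contig = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
                      ref = toupper(fx[, "REF"]), alt = toupper(fx[, "ALT"]),
                      allele_count = ac, allele_number = an, median_depth = dp,
                      stringsAsFactors = FALSE)
  }
  is_snv <- nchar(tab$ref) == 1L & nchar(tab$alt) == 1L &
    tab$ref %in% c("A", "C", "G", "T") & tab$alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snv)
  tab <- tab[is_snv, , drop = FALSE]
  if (any(tab$ref == tab$alt)) stop("record with ref == alt at pos ",
                                    tab$pos[tab$ref == tab$alt][1])
  bad <- is.na(tab$allele_count) | is.na(tab$allele_number) | is.na(tab$median_depth)
  if (any(bad)) {
    stop("missing AC/AN/depth for record at ", tab$contig[bad][1], ":", tab$pos[bad][1])
  }
  if (any(tab$allele_count > tab$allele_number)) {
    stop("allele_count > allele_number at pos ",
         tab$pos[tab$allele_count > tab$allele_number][1])
  }
  rownames(tab) <- NULL
  attr(tab, "n_skipped") <- n_skipped
  tab
}

#' Write variants as TSV
#' @param variants data.frame as returned by [read_variants()].
#' @param path output path.
#' @export
write_variants <- function(variants, path) {
  out <- data.frame(contig = variants$contig, pos = variants$pos,
                    ref = variants$ref, alt = variants$alt,
                    AC = variants$allele_count, AN = variants$allele_number,
                    DP_median = variants$median_depth)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep rare variants
#'
#' Retains records with allele frequency strictly below `af_threshold`
#' (default 0.1%) and allele count >= 1.
#'
#' @param variants variant data.frame.
#' @param af_threshold allele-frequency cutoff (strict `<`).
#' @export
filter_rare <- function(variants, af_threshold = 0.001) {
  stopifnot(all(variants$allele_number > 0))
  af <- variants$allele_count / variants$allele_number
  keep <- variants$allele_count >= 1L & af < af_threshold
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
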