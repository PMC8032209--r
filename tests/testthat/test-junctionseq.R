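test_that("BSJ sequence is donor suffix ++ acceptor prefix (hand-sliced oracle)", {
  s <- toy_seq()
  g <- toy_genome(s)
  m <- toy_model_plus()
  cj <- list(acceptor_exon = 1L, donor_exon = 3L, junction_id = "t")
  js <- build_bsj_sequence(g, m, cj, w = 4L)
  # exon 3 = 41..50, exon 1 = 11..20: last 4 of exon 3 ++ first 4 of exon 1
  expect_equal(js$seq, paste0(substr(s, 47, 50), substr(s, 11, 14)))
  expect_equal(js$junction_offset, 4L)
  expect_equal(js$origin, "BSJ")
  # single-exon circle: suffix ++ prefix of the same exon
  js1 <- build_bsj_sequence(g, m, list(acceptor_exon = 2L, donor_exon = 2L,
                                       junction_id = "t2"), w = 4L)
  expect_equal(js1$seq, paste0(substr(s, 32, 35), substr(s, 26, 29)))
})

test_that("windows clamp to exon length instead of crossing exon borders", {
  g <- toy_genome(toy_seq())
  m <- toy_model_plus()  # 10-base exons
  js <- build_bsj_sequence(g, m, list(acceptor_exon = 1L, donor_exon = 2L,
                                      junction_id = "t"), w = 25L)
  expect_equal(nchar(js$seq), 20L)
  expect_equal(js$junction_offset, 10L)
  ljs <- build_lj_sequences(g, m, w = 25L)
  expect_true(all(vapply(ljs, function(j) j$junction_offset, integer(1)) == 10L))
})

test_that("a transcript with N exons yields N-1 LJ sequences, each a substring of the mRNA", {
  ds <- default_ds()
  m <- ds$models$BG001
  ljs <- build_lj_sequences(ds$genome, m, w = 25L)
  expect_length(ljs, nrow(m$exons) - 1L)
  tx <- transcript_sequence(ds$genome, m)
  cum <- cumsum(m$exons$width)
  for (i in seq_along(ljs)) {
    # the LJ sequence must appear in the mRNA exactly at its junction coordinate
    at <- cum[i] - ljs[[i]]$junction_offset + 1L
    expect_equal(substr(tx, at, at + nchar(ljs[[i]]$seq) - 1L), ljs[[i]]$seq)
  }
})

test_that("minus-strand BSJ sequences are in transcript orientation", {
  s <- toy_seq()
  g <- toy_genome(s)
  m <- toy_model_minus()  # exon 1 = 41..50, exon 3 = 11..20
  js <- build_bsj_sequence(g, m, list(acceptor_exon = 1L, donor_exon = 3L,
                                      junction_id = "t"), w = 4L)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  # donor exon 3 occupies 11..20; its transcript-orientation suffix is
  # revcomp of genomic 11..14. Acceptor exon 1 prefix is revcomp of 47..50.
  expect_equal(js$seq, paste0(rc(substr(s, 11, 14)), rc(substr(s, 47, 50))))
})

test_that("IUPAC occurrence finder matches a naive scanner on random strings", {
  set.seed(101)
  patterns <- c("RAC", "AAAGAACC", "NNGC", "TWYA", "SSS")
  for (rep in 1:200) {
    L <- sample(20:60, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    p <- sample(patterns, 1)
    got <- find_occurrences(s, p, junction_offset = L %/% 2L)
    expect_equal(got$start, naive_iupac_scan(s, p),
                 info = sprintf("pattern %s on %s", p, s))
  }
})

test_that("spans_junction flags exactly the occurrences crossing the junction", {
  # plant AAAGAACC straddling the junction with 4 bases on each side
  left <- "TTTTTTTTTTTTTTTTTTTTTAAAG"
  right <- "AACCTTTTTTTTTTTTTTTTTTTTT"
  js <- structure(
    list(id = "x", seq = paste0(left, right), junction_offset = 25L,
         origin = "BSJ", transcript_id = "t", donor_exon = 2L,
         acceptor_exon = 1L), class = "junction_seq")
  occ <- find_occurrences(js, "AAAGAACC")
  expect_equal(nrow(occ), 1L)
  expect_true(occ$spans_junction)
  expect_equal(occ$start, 22L)
  # same pattern fully inside the donor half does not span
  occ2 <- find_occurrences(paste0("AAAGAACC", strrep("T", 20)), "AAAGAACC",
                           junction_offset = 15L)
  expect_false(occ2$spans_junction)
  # pattern longer than sequence: empty, not an error
  expect_equal(nrow(find_occurrences("ACGT", "AAAGAACC", junction_offset = 2L)), 0L)
})

test_that("BSJ neighbourhood is consistent with the rotated mature circle", {
  ds <- default_ds()
  jx <- ds$junctions[ds$junctions$host_class == "TTN", ][1:5, ]
  for (i in seq_len(nrow(jx))) {
    cj <- jx[i, ]
    js <- build_bsj_sequence(ds$genome, ds$models$TTN, cj, w = 25L)
    circ <- circ_sequence(ds$genome, ds$models$TTN, cj)
    # rotate the circle so the junction sits at position w
    rot <- paste0(substr(circ, nchar(circ) - 24L, nchar(circ)),
                  substr(circ, 1L, 25L))
    expect_equal(js$seq, rot)
  }
})

test_that("a BSJ-created occurrence is absent from the linear transcript", {
  # motif halves planted in non-adjacent exons exist only in the circle
  ds <- default_ds()
  motif <- ds$manifest$motif
  carriers <- ds$junctions[ds$junctions$junction_id %in%
                             ds$manifest$dependent_carrier_ids, ]
  nonadj <- carriers[carriers$donor_exon - carriers$acceptor_exon > 1L, ]
  expect_gt(nrow(nonadj), 0L)
  tx <- transcript_sequence(ds$genome, ds$models$TTN)
  for (i in seq_len(min(5L, nrow(nonadj)))) {
    cj <- nonadj[i, ]
    js <- build_bsj_sequence(ds$genome, ds$models$TTN, cj, w = 25L)
    occ <- find_occurrences(js, motif)
    expect_true(any(occ$spans_junction))
    # the junction 50-mer context around the BSJ is nowhere in the mRNA
    ctx <- substr(js$seq, js$junction_offset - 7L, js$junction_offset + 8L)
    expect_false(grepl(ctx, tx, fixed = TRUE))
  }
})

test_that("occurrence classification separates bsj, lj and within-exon contexts", {
  ds <- default_ds()
  ttn <- ds$junctions[ds$junctions$host_class == "TTN", ]
  cls <- classify_genomic_motif_sites(ds$genome, ds$models$TTN, ttn,
                                      ds$manifest$motif)
  expect_setequal(unique(cls$occurrence_class),
                  c("bsj_created", "lj_created", "within_exon"))
  # planted within-exon copies are all recovered with the right label
  we <- cls[cls$occurrence_class == "within_exon", ]
  expect_true(all(ds$manifest$within_exon_planted %in% we$exon_number))
  # planted excluded-region LJ copies carry the excluded label
  lj <- cls[cls$occurrence_class == "lj_created", ]
  exc <- lj[lj$donor_exon %in% ds$manifest$lj_excluded_planted, ]
  expect_true(all(exc$inclusion == "excluded"))
  # exon inclusion: any exon inside a circle span is included
  inc <- exon_inclusion_labels(ds$models$TTN, ttn)
  span <- range(c(ttn$acceptor_exon, ttn$donor_exon))
  expect_true(all(inc[as.character(setdiff(1:363, seq(span[1], span[2])))] == "excluded"))
})
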