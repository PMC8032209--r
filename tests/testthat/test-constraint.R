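test_that("rate keys are strand-collapsed and CpG bins restricted", {
  rt <- default_rate_table()
  # a key and its reverse complement share one rate
  expect_equal(rate_lookup(rt, "A", "C", "T", "G"),
               rate_lookup(rt, "C", "G", "A", "T"))
  expect_equal(rate_lookup(rt, "T", "A", "G", "C"),
               rate_lookup(rt, "G", "T", "C", "A"))
  # CpG transition rates rise with methylation bin
  r0 <- rate_lookup(rt, "A", "C", "T", "G", 0L)
  r1 <- rate_lookup(rt, "A", "C", "T", "G", 1L)
  r2 <- rate_lookup(rt, "A", "C", "T", "G", 2L)
  expect_true(r0 < r1 && r1 < r2)
  expect_equal(r2 / r0, 10)
  # non-CpG contexts ignore the methylation bin
  expect_equal(rate_lookup(rt, "A", "C", "T", "A", 2L),
               rate_lookup(rt, "A", "C", "T", "A", 0L))
  # a rate table with a methylated non-CpG key is rejected
  bad <- rt$df[1, ]; bad$left <- "A"; bad$ref <- "A"; bad$alt <- "G"
  bad$right <- "A"; bad$methyl_bin <- 2L
  expect_error(rate_table(rbind(rt$df, bad)), "non-CpG")
})

test_that("expected counts match a per-site spreadsheet-style oracle", {
  set.seed(55)
  g <- toy_genome(paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                        collapse = ""))
  rt <- default_rate_table()
  sites <- data.frame(contig = "chrT", pos = sample(5:195, 100))
  got <- expected_variants(g, sites, rt)
  # oracle: manual per-site, per-alt summation from first principles
  acc <- 0
  for (p in sites$pos) {
    tri <- substr(as.character(g$chrT), p - 1, p + 1)
    ref <- substr(tri, 2, 2)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      key <- paste0(tri, ">", alt)
      ti <- (ref == "A" & alt == "G") | (ref == "C" & alt == "T") |
        (ref == "G" & alt == "A") | (ref == "T" & alt == "C")
      acc <- acc + ifelse(ti, 3 * 0.004, 0.004)
    }
  }
  expect_equal(got, acc, tolerance = 1e-12)
  # single site, single alt, full depth, lambda 1 -> expected == rate
  s1 <- data.frame(contig = "chrT", pos = 50L,
                   alt = setdiff(c("A", "C", "G", "T"),
                                 genome_base(g, "chrT", 50L))[1])
  r <- expected_components(g, s1, rt)$rate
  expect_equal(expected_variants(g, s1, rt), r)
})

test_that("expected counts are linear and depth-monotone", {
  set.seed(56)
  g <- toy_genome(paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                        collapse = ""))
  rt <- default_rate_table()
  a <- data.frame(contig = "chrT", pos = 10:60)
  b <- data.frame(contig = "chrT", pos = 100:150)
  both <- rbind(a, b)
  expect_equal(expected_variants(g, both, rt),
               expected_variants(g, a, rt) + expected_variants(g, b, rt),
               tolerance = 1e-12)
  # halving every site's depth factor halves the expected count
  dm <- depth_model(d0 = 30, a = 0.25, b = 0)   # constant factor 0.25 below d0
  d_half <- stats::setNames(rep(10, nrow(a)), paste0("chrT:", a$pos))
  dm50 <- depth_model(d0 = 30, a = 0.5, b = 0)
  expect_equal(expected_variants(g, a, rt, depths = d_half, dm = dm),
               expected_variants(g, a, rt, depths = d_half, dm = dm50) / 2,
               tolerance = 1e-12)
  # decreasing any site depth never increases expectation
  dmr <- depth_model()
  d1 <- stats::setNames(rep(25, nrow(a)), paste0("chrT:", a$pos))
  d2 <- d1; d2[3] <- 5
  expect_lte(expected_variants(g, a, rt, depths = d2, dm = dmr),
             expected_variants(g, a, rt, depths = d1, dm = dmr))
  # a site with N context errors
  gn <- toy_genome(paste0(strrep("A", 49), "N", strrep("A", 50)))
  expect_error(expected_variants(gn, data.frame(contig = "chrT", pos = 51L), rt),
               "N in trinucleotide")
})

test_that("lambda calibration is the observed/expected ratio", {
  expect_equal(calibrate_lambda(10, 10), 1)
  expect_equal(calibrate_lambda(20, 10), 2)
  expect_error(calibrate_lambda(0, 10), "zero observed")
})

test_that("o/e CI endpoints match numeric inversion of the Poisson tails", {
  r0 <- oe_with_ci(0, 3)
  expect_equal(r0$oe, 0)
  expect_equal(r0$ci_low, 0)
  expect_equal(r0$ci_high, stats::qchisq(0.95, 2) / 6)
  # oracle: root-find mu such that P(X >= obs | mu) = 0.05 (lower) and
  # P(X <= obs | mu) = 0.05 (upper), independent of the chi-square form
  for (obs in c(1L, 4L, 10L, 37L)) {
    ex <- 10
    r <- oe_with_ci(obs, ex)
    lo <- stats::uniroot(function(mu) 1 - stats::ppois(obs - 1, mu) - 0.05,
                         c(1e-9, 200), tol = 1e-12)$root / ex
    hi <- stats::uniroot(function(mu) stats::ppois(obs, mu) - 0.05,
                         c(1e-9, 200), tol = 1e-12)$root / ex
    expect_equal(r$ci_low, lo, tolerance = 1e-9)
    expect_equal(r$ci_high, hi, tolerance = 1e-9)
    expect_true(r$ci_low <= r$oe && r$oe <= r$ci_high)
  }
  expect_error(oe_with_ci(3, 0), "expected")
})

test_that("consequence classifier agrees with brute-force translation on all 576 codon-SNV cases", {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  n_checked <- 0L
  for (cod in codons) {
    for (pos in 1:3) {
      for (alt in setdiff(bases, substr(cod, pos, pos))) {
        altc <- cod; substr(altc, pos, pos) <- alt
        oracle <- if (gc[[altc]] == gc[[cod]]) "synonymous"
                  else if (gc[[altc]] == "*" && gc[[cod]] != "*") "truncating"
                  else "missense"
        expect_identical(classify_codon(cod, pos, alt), oracle)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_equal(n_checked, 576L)
  expect_identical(classify_codon("CTT", 3, "C"), "synonymous")  # Leu->Leu
  expect_identical(classify_codon("TGG", 3, "A"), "truncating")  # Trp->stop
})

test_that("genomic consequence classification respects strand and frame", {
  # 2-exon minus-strand gene whose mRNA is ATG AAA TGA (Met Lys stop)
  mrna <- "ATGAAATGA"
  pre <- paste0(strrep("C", 10),
                revcomp(substr(mrna, 5, 9)), strrep("C", 9),
                revcomp(substr(mrna, 1, 4)), strrep("C", 10))
  g <- toy_genome(pre)
  m <- exon_model("neg", "chrT", "-", starts = c(25L, 11L), ends = c(28L, 15L))
  expect_equal(transcript_sequence(g, m), mrna)
  # mRNA position 3 (G of ATG) sits at genomic position 26; G->A on the
  # transcript is C->T genomic on the minus strand
  expect_identical(classify_consequence(g, m, 26L, "T"), "missense")
  # synonymous third-position change in AAA (Lys): A->G at mRNA pos 6
  expect_identical(classify_consequence(g, m, 11L + 3L, "C"), "synonymous")
  expect_error(classify_consequence(g, m, 20L, "A"), "not exonic")
})

test_that("site classes from the enumerator partition every exonic (site, alt) pair", {
  ds <- default_ds()
  cls <- consequence_site_classes(ds$genome, ds$models$TTN, exon_numbers = 1:8)
  n_sites <- sum(ds$models$TTN$exons$width[1:8])
  expect_equal(sum(vapply(cls, nrow, integer(1))), 3L * n_sites)
  keys <- unlist(lapply(cls, function(d) paste(d$pos, d$alt)))
  expect_equal(anyDuplicated(keys), 0L)
  # spot-check a handful against the single-site classifier
  set.seed(77)
  for (nm in names(cls)) {
    rows <- cls[[nm]][sample(nrow(cls[[nm]]), 5L), ]
    for (i in 1:5) {
      expect_identical(
        classify_consequence(ds$genome, ds$models$TTN, rows$pos[i], rows$alt[i]),
        nm)
    }
  }
})

test_that("synthetic neutral variants give o/e near 1 and exact 1 on the calibration class", {
  cfg <- synth_config(seed = 7L)
  set.seed(71)
  g <- toy_genome(paste(sample(c("A", "C", "G", "T"), 70000, replace = TRUE),
                        collapse = ""))
  rt <- default_rate_table()
  cal <- data.frame(contig = "chrT", pos = 10:34000)
  held <- data.frame(contig = "chrT", pos = 34001:69990)
  oes <- vapply(1:20, function(s) {
    v <- generate_variants(cfg, g, rt, rbind(cal, held), seed = 9000L + s)
    rare <- filter_rare(v)
    lam <- calibrate_lambda(observed_count(rare, cal),
                            expected_variants(g, cal, rt))
    oe_with_ci(observed_count(rare, held),
               expected_variants(g, held, rt, lambda_cal = lam))$oe
  }, numeric(1))
  expect_true(all(oes > 0.9 & oes < 1.1))
  expect_true(abs(mean(oes) - 1) < 0.05)
  # calibration class o/e is exactly 1 when calibration = validation
  v <- generate_variants(cfg, g, rt, cal, seed = 99L)
  rare <- filter_rare(v)
  lam <- calibrate_lambda(observed_count(rare, cal), expected_variants(g, cal, rt))
  expect_equal(observed_count(rare, cal) /
                 (lam * expected_variants(g, cal, rt)), 1)
})

test_that("depth-model fitting recovers a monotone correction on designed depths", {
  cfg <- synth_config(seed = 5L)
  set.seed(51)
  g <- toy_genome(paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                        collapse = ""))
  rt <- default_rate_table()
  sites <- data.frame(contig = "chrT", pos = 10:19990)
  # designed depths spanning the whole correction range
  d <- stats::setNames(rep(c(3, 6, 10, 15, 22, 28, 40, 60), length.out = nrow(sites)),
                       paste0("chrT:", sites$pos))
  true_dm <- depth_model()
  v <- generate_variants(cfg, g, rt, sites, depths = d, dm = true_dm, seed = 123L)
  rare <- filter_rare(v)
  comp <- expected_components(g, sites, rt)
  dd <- unname(d[paste0(comp$contig, ":", comp$pos)])
  obs <- as.integer(paste(comp$pos, comp$alt) %in% paste(rare$pos, rare$alt))
  fit <- fit_depth_model(dd, obs, comp$rate, d0 = 30)
  # fitted factor tracks the generating factor across the low-depth range
  for (dep in c(5, 12, 25)) {
    expect_equal(depth_factor(fit, dep), depth_factor(true_dm, dep),
                 tolerance = 0.12)
  }
  expect_true(fit$b >= 0)
})
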