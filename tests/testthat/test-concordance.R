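# XY/ZW concordance scoring, system inference and region calling.

test_that("concordance scores match hand counts", {
  sexes <- make_sexes(18, 20)
  # perfect XY pattern at the study's panel size
  expect_equal(xy_concordance(c(rep(1L, 18), rep(0L, 20)), sexes$sex), 1.0)

  # 9 of 10 individuals matching
  sex10 <- c(rep("M", 5), rep("F", 5))
  gt10 <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 2L, 0L, 0L) # one male hom-ref
  expect_equal(xy_concordance(gt10, sex10), 0.9)

  # all individuals hom-ref: only the females match
  expect_equal(xy_concordance(rep(0L, 38), sexes$sex), 20 / 38)

  # either homozygote counts for the homogametic sex
  expect_equal(xy_concordance(c(rep(1L, 18), rep(2L, 20)), sexes$sex), 1.0)

  # missing genotypes leave both numerator and denominator
  expect_equal(xy_concordance(c(1L, NA, 0L, NA), c("M", "M", "F", "F")), 1.0)
  expect_true(is.na(xy_concordance(rep(NA_integer_, 4), sex10[1:4])))

  # all females het, all males hom-alt is the perfect ZW pattern
  expect_equal(zw_concordance(c(rep(2L, 18), rep(1L, 20)), sexes$sex), 1.0)

  # single sample: scores are 0 or 1
  expect_true(xy_concordance(1L, "M") %in% c(0, 1))
  expect_true(xy_concordance(0L, "M") %in% c(0, 1))
})

test_that("zw is exactly xy under swapped labels", {
  withr::with_seed(12, {
    for (i in 1:30) {
      gt <- sample(c(0:2, NA), 24, TRUE)
      sex <- sample(rep(c("M", "F"), 12))
      swapped <- ifelse(sex == "M", "F", "M")
      expect_equal(zw_concordance(gt, sex), xy_concordance(gt, swapped))
    }
  })
})

test_that("a score above 0.90 at n = 38 needs at least 35 matches", {
  matches <- 0:38
  above <- (matches / 38) > 0.90
  expect_equal(min(matches[above]), 35)
  expect_false(34 / 38 > 0.90)
})

test_that("random HWE sites score near the no-signal baseline", {
  cfg <- tiny_config(seed = 21)
  cfg$n_sex_linked_snps <- 0L
  cfg$n_autosomal_snps <- 400L
  cfg$missing_rate <- 0
  sc <- concordance_scan(simulate_genotypes(cfg, build_reference(cfg)))
  # for a site with het fraction h, E[xy - zw] = 0 by label symmetry of HWE
  diff <- mean(sc$xy_score - sc$zw_score)
  se <- sd(sc$xy_score - sc$zw_score) / sqrt(nrow(sc))
  expect_lt(abs(diff), 3 * se + 1e-9)
})

test_that("system inference needs support and a clear majority", {
  mk <- function(xy, zw) {
    tibble::tibble(chrom = "chr1", pos = seq_along(xy), id = as.character(seq_along(xy)),
                   is_indel = FALSE, indel_len = 0L,
                   xy_score = xy, zw_score = zw, n_used = 38)
  }
  cfg <- scan_config(min_snps = 5)
  expect_equal(infer_system(mk(rep(0.95, 10), rep(0.5, 10)), cfg), "XY")
  expect_equal(infer_system(mk(rep(0.5, 10), rep(0.95, 10)), cfg), "ZW")
  expect_equal(infer_system(mk(rep(0.85, 10), rep(0.5, 10)), cfg),
               "undetermined") # nothing above threshold
  expect_equal(infer_system(mk(rep(0.95, 4), rep(0.5, 4)), cfg),
               "undetermined") # below min_snps
  # no 2x majority
  expect_equal(infer_system(mk(c(rep(0.95, 6), rep(0.5, 6)),
                               c(rep(0.5, 6), rep(0.95, 6))), cfg),
               "undetermined")
})

test_that("region calling takes the envelope and flags outliers", {
  mk_scores <- function(chrom, pos, score) {
    tibble::tibble(chrom = chrom, pos = as.integer(pos),
                   id = sprintf("s%02d", seq_along(pos)),
                   is_indel = FALSE, indel_len = 0L,
                   xy_score = score, zw_score = 0.5, n_used = 38)
  }
  # 9 high scorers on chr9, 1 on chr2: region on chr9, one outlier
  sc <- mk_scores(
    c(rep("chr9", 9), "chr2"),
    c(seq(19740000, 22600000, length.out = 9), 5e6),
    rep(0.95, 10)
  )
  called <- call_sd_region(sc, scan_config(), "XY")
  expect_equal(called$region$chrom, "chr9")
  expect_equal(called$region$start, 19740000L)
  expect_equal(called$region$end, 22600000L)
  expect_equal(called$region$n_support, 9L)
  expect_equal(called$outliers$chrom, "chr2")

  # two clusters 5 Mb apart with a 1 Mb gap limit: larger cluster wins
  sc2 <- mk_scores(
    rep("chr9", 10),
    c(seq(1e6, 1.4e6, length.out = 7), seq(6.4e6, 6.6e6, length.out = 3)),
    rep(0.95, 10)
  )
  called2 <- call_sd_region(sc2, scan_config(max_gap = 1e6), "XY")
  expect_equal(called2$region$start, 1000000L)
  expect_equal(called2$region$end, 1400000L)
  expect_equal(called2$region$n_support, 7L)
  expect_equal(nrow(called2$outliers), 3)

  # too few high scorers is a no-region error
  expect_error(call_sd_region(mk_scores("chr9", 1:3 * 1e6, rep(0.95, 3)),
                              scan_config(min_snps = 5), "XY"),
               "no region")
  expect_error(call_sd_region(sc, scan_config(), "undetermined"),
               "undetermined")
})

test_that("raising the threshold never widens the region", {
  sim <- simulate_dataset(sim_config(seed = 4))
  sc <- concordance_scan(sim$dataset)
  spans <- vapply(c(0.90, 0.93, 0.96), function(th) {
    r <- call_sd_region(sc, scan_config(threshold = th), "XY")$region
    r$span
  }, numeric(1))
  expect_true(all(diff(spans) <= 0))
})

test_that("the full scan recovers the simulated truth", {
  sim <- simulate_dataset(sim_config(seed = 6))
  fit <- sd_scan(sim$dataset)
  expect_s3_class(fit, "sd_scan")
  expect_equal(fit$system, "XY")
  expect_equal(fit$region$chrom, "chr9")
  jac <- interval_jaccard(fit$region$start, fit$region$end,
                          sim$config$sd_region[1], sim$config$sd_region[2])
  expect_gt(jac, 0.8)

  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("xy_score", "zw_score", "n_used") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$system, "XY")

  # ZW simulation mirrors
  cfgz <- sim_config(seed = 6, system = "ZW")
  fitz <- sd_scan(simulate_genotypes(cfgz, build_reference(cfgz)))
  expect_equal(fitz$system, "ZW")
})

test_that("scan plots build without error", {
  sim <- simulate_dataset(sim_config(seed = 1))
  fit <- sd_scan(sim$dataset)
  expect_s3_class(autoplot(fit), "ggplot")
  a <- assoc_scan(sim$dataset)
  expect_s3_class(autoplot(a), "ggplot")
})
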