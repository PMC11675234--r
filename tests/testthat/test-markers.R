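# Indel marker development: screening, in-silico PCR, sex calls,
# assay accuracy, and the end-to-end marker pipeline.

test_that("indel screening keeps long, concordant, in-region indels", {
  sexes <- make_sexes(5, 5)
  perfect <- c(rep(1L, 5), rep(0L, 5))
  noise <- c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L) # concordance 0.5
  geno <- rbind(perfect, perfect, perfect, perfect, noise)
  ds <- make_dataset(
    geno, sexes, chrom = "chr9",
    pos = c(1000L, 2000L, 3000L, 9000L, 4000L),
    ref = rep("A", 5),
    alt = c(
      paste0("A", strrep("T", 18)), # 18 bp insertion, in region
      paste0("A", strrep("T", 14)), # 14 bp insertion, in region
      paste0("A", strrep("T", 8)),  # too short
      paste0("A", strrep("T", 20)), # outside region
      paste0("A", strrep("T", 12))  # low concordance
    )
  )
  region <- tibble::tibble(chrom = "chr9", start = 500L, end = 5000L)
  cand <- screen_indels(ds, region = region, system = "XY")
  expect_equal(cand$indel_len, c(18L, 14L))
  expect_equal(cand$pos, c(1000L, 2000L))
  expect_equal(cand$score, c(1, 1))
})

test_that("in-silico PCR finds exact-match products on either strand", {
  fwd <- "AGGTCATTCAGGTCAG"
  rev <- "CTTGAACTGTGATCGT"
  middle <- strrep("A", 50)
  tpl <- paste0("GGGG", fwd, middle, revcomp(rev), "CCCC")
  prod <- in_silico_pcr(tpl, fwd, rev)
  expect_equal(prod$length, nchar(fwd) + 50 + nchar(rev))
  expect_equal(prod$strand, "+")

  # the same amplicon is found if the template arrives reverse-complemented
  prod_rc <- in_silico_pcr(revcomp(tpl), fwd, rev)
  expect_equal(prod_rc$length, prod$length)
  expect_equal(prod_rc$strand, "-")

  # absent primers: no amplification
  expect_equal(nrow(in_silico_pcr(tpl, "GGGGGGGGGGGGGGGG", rev)), 0)

  # two forward sites give two products, ascending
  tpl2 <- paste0(fwd, strrep("T", 10), fwd, strrep("T", 20), revcomp(rev))
  prods2 <- in_silico_pcr(tpl2, fwd, rev)
  expect_equal(prods2$length,
               c(nchar(fwd) + 20 + nchar(rev),
                 2 * nchar(fwd) + 10 + 20 + nchar(rev)))

  # products over the cap are dropped
  expect_equal(nrow(in_silico_pcr(tpl, fwd, rev, max_product = 50)), 0)
})

test_that("truth amplicons amplify at their recorded sizes", {
  ref <- build_reference(sim_config(seed = 3))
  amp <- ref$amplicons
  for (i in seq_len(nrow(amp))) {
    x <- in_silico_pcr(amp$x_template[i], amp$forward[i], amp$reverse[i])
    y <- in_silico_pcr(amp$y_template[i], amp$forward[i], amp$reverse[i])
    expect_equal(x$length, amp$x_product[i])
    expect_equal(y$length, amp$y_product[i])
  }
  # and directly on the chromosome (X allele lives in the reference)
  g <- in_silico_pcr(ref$sequences[[amp$chrom[1]]], amp$forward[1],
                     amp$reverse[1])
  expect_true(amp$x_product[1] %in% g$length)
})

test_that("allele size prediction adds the insertion to the Y product", {
  expect_equal(predict_allele_sizes(346, 18),
               tibble::tibble(x_product = 346, y_product = 364))
  expect_equal(predict_allele_sizes(412, 14),
               tibble::tibble(x_product = 412, y_product = 426))
  expect_equal(predict_allele_sizes(300, 0)$y_product, 300)
  expect_equal(predict_allele_sizes(346, 18, on_y = FALSE)$x_product, 364)
  expect_error(predict_allele_sizes(0, 18), "x_product")
  expect_error(predict_allele_sizes(10, -12), "non-positive")
})

test_that("band patterns call sex under both systems", {
  a <- marker_assay("MFS-1", 346, 364)
  expect_equal(genotype_to_sex(c(346, 364), a), "M")
  expect_equal(genotype_to_sex(346, a), "F")
  expect_equal(genotype_to_sex(numeric(0), a), "no_call")
  expect_equal(genotype_to_sex(364, a), "no_call")
  expect_equal(genotype_to_sex(c(346, 999), a), "no_call")

  z <- marker_assay("zw-marker", 200, 220, system = "ZW")
  expect_equal(genotype_to_sex(c(200, 220), z), "F")
  expect_equal(genotype_to_sex(200, z), "M")

  expect_equal(a$indel_len, 18L)
  expect_error(marker_assay("bad", -1, 10), "products")
})

test_that("genotype dose implies the expected band pattern", {
  a <- marker_assay("MFS-1", 346, 364)
  calls <- call_samples(c(s1 = 1L, s2 = 0L, s3 = 2L, s4 = NA), a)
  expect_equal(calls$predicted, c("M", "F", "no_call", "no_call"))
  expect_equal(calls$bands[[1]], c(346L, 364L)) # X/Y carrier shows both
})

test_that("accuracy is scored over scorable calls only", {
  phen <- tibble::tibble(sample_id = sprintf("s%02d", 1:40),
                         sex = rep(c("M", "F"), 20))
  calls <- tibble::tibble(
    sample_id = phen$sample_id,
    predicted = c(phen$sex[1:36], ifelse(phen$sex[37] == "M", "F", "M"),
                  rep("no_call", 3))
  )
  acc <- assay_accuracy(calls, phen)
  expect_equal(acc$accuracy, 36 / 37)
  expect_equal(round(100 * acc$accuracy, 2), 97.30)
  expect_equal(acc$n_no_call, 3)

  perfect <- assay_accuracy(
    tibble::tibble(sample_id = phen$sample_id[1:10],
                   predicted = phen$sex[1:10]), phen)
  expect_equal(perfect$accuracy, 1)

  wrong <- assay_accuracy(
    tibble::tibble(sample_id = phen$sample_id[1:5],
                   predicted = ifelse(phen$sex[1:5] == "M", "F", "M")), phen)
  expect_equal(wrong$accuracy, 0)

  expect_error(
    assay_accuracy(tibble::tibble(sample_id = phen$sample_id[1:2],
                                  predicted = c("no_call", "no_call")), phen),
    "zero scorable"
  )
})

test_that("noise-free panels genotype perfectly; missingness only mutes", {
  mean_stats <- function(mu, seeds) {
    out <- vapply(seeds, function(s) {
      cfg <- sim_config(seed = s, male_error = 0, female_error = 0,
                        missing_rate = mu)
      sim <- simulate_dataset(cfg)
      fit <- sd_scan(sim$dataset)
      amp <- sim$ref$amplicons
      idx <- match(paste(amp$chrom[1], amp$indel_pos[1]),
                   paste(sim$dataset$sites$chrom, sim$dataset$sites$pos))
      assay <- marker_assay(amp$name[1], amp$x_product[1], amp$y_product[1],
                            system = fit$system)
      calls <- call_samples(sim$dataset$geno[idx, ], assay,
                            samples = sim$dataset$samples)
      acc <- assay_accuracy(calls, sim$dataset$sexes)
      c(acc$accuracy, acc$n_no_call)
    }, numeric(2))
    rowMeans(out)
  }
  zero <- mean_stats(0, 1:5)
  expect_equal(zero[1], 1)       # e = mu = 0: every call correct
  expect_equal(zero[2], 0)
  five <- mean_stats(0.05, 1:8)
  ten <- mean_stats(0.10, 1:8)
  expect_true(zero[1] >= five[1] && five[1] >= ten[1] - 1e-9)
  expect_true(zero[2] < five[2] && five[2] < ten[2]) # no-calls grow with mu
})
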