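# Synthetic-data generator: reference construction, generative model,
# and file round-trips.

test_that("reference construction embeds amplicons and is deterministic", {
  cfg <- sim_config(seed = 7)
  ref <- build_reference(cfg)

  expect_named(ref$sequences, cfg$chromosomes$name)
  expect_equal(unname(nchar(ref$sequences)),
               as.numeric(cfg$chromosomes$length))

  # Y template = X template + its insertion; defaults mirror the two
  # published markers (346 -> 364 bp, 412 -> 426 bp)
  amp <- ref$amplicons
  expect_equal(nchar(amp$x_template), c(346L, 412L))
  expect_equal(nchar(amp$y_template), c(364L, 426L))
  expect_equal(nchar(amp$y_template) - nchar(amp$x_template),
               amp$insertion_len)
  # the X allele is what sits in the chromosome
  expect_equal(
    substr(ref$sequences[[amp$chrom[1]]], amp$start[1], amp$end[1]),
    amp$x_template[1]
  )

  ref2 <- build_reference(sim_config(seed = 7))
  expect_identical(ref$sequences, ref2$sequences)
  expect_identical(ref$amplicons, ref2$amplicons)

  # different seed, different bases
  expect_false(identical(ref$sequences,
                         build_reference(sim_config(seed = 8))$sequences))
})

test_that("an amplicon outside the SD region is a configuration error", {
  ind <- default_indels()
  ind$pos[1] <- 100L # far outside the default region
  expect_error(build_reference(sim_config(seed = 1, indels = ind)),
               "does not fit inside the SD region")
})

test_that("perfect linkage gives the pure XY pattern; no males degenerates", {
  cfg <- tiny_config(seed = 3, decay_length = 1e12,
                     male_error = 0, female_error = 0, missing_rate = 0)
  ds <- simulate_genotypes(cfg, build_reference(cfg))
  sl <- ds$sites$truth == "sex_linked"
  m <- ds$sexes$sex == "M"
  expect_true(all(ds$geno[sl, m] == 1L))
  expect_true(all(ds$geno[sl, !m] == 0L))

  cfg0 <- sim_config(
    n_males = 0, n_females = 6,
    chromosomes = tibble::tibble(name = "chrA", length = 20000L),
    sd_chrom = "chrA", sd_locus = 10000, sd_region = c(5000, 15000),
    n_sex_linked_snps = 5, n_autosomal_snps = 5,
    male_error = 0, female_error = 0, missing_rate = 0,
    indels = default_indels()[0, ], seed = 2
  )
  ds0 <- simulate_genotypes(cfg0, build_reference(cfg0))
  expect_true(all(ds0$sexes$sex == "F"))
  # without heterogametic individuals no site can show the XY pattern
  sc <- concordance_scan(ds0)
  expect_true(all(sc$xy_score[ds0$sites$truth == "sex_linked"] == 1))
  # (all females homozygous matches trivially; no het males exist to test)
  expect_true(all(ds0$geno[ds0$sites$truth == "sex_linked", ] == 0L))
})

test_that("zero configured sites is an error", {
  cfg <- tiny_config(seed = 1)
  cfg$n_sex_linked_snps <- 0L
  cfg$n_autosomal_snps <- 0L
  expect_error(simulate_genotypes(cfg, build_reference(cfg)),
               "zero sites")
})

test_that("male het fraction at distance lambda matches exp(-1)", {
  # fixture pins every sex-linked site at exactly d = lambda
  base <- sim_config(
    n_males = 1000, n_females = 10,
    chromosomes = tibble::tibble(name = "chrA", length = 500000L),
    sd_chrom = "chrA", sd_locus = 100000, sd_region = c(300000, 300000),
    n_sex_linked_snps = 1, n_autosomal_snps = 0,
    decay_length = 2e5, # so d = 200000 = lambda
    male_error = 0, female_error = 0, missing_rate = 0,
    indels = default_indels()[0, ], seed = 1
  )
  ref <- build_reference(base)
  het_frac <- vapply(1:50, function(s) {
    cfg <- base
    cfg$seed <- s
    ds <- simulate_genotypes(cfg, ref)
    mean(ds$geno[1, ds$sexes$sex == "M"] == 1L)
  }, numeric(1))
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / (50 * 1000))
  expect_lt(abs(mean(het_frac) - p), 3 * se)
})

test_that("mean concordance follows the closed-form expectation", {
  # one sex-linked site at d = 20 kb with errors but no missingness:
  # E[score] = (n_m f(d)(1-e_m) + n_f (1-e_f)) / (n_m + n_f)
  base <- sim_config(
    n_males = 18, n_females = 20,
    chromosomes = tibble::tibble(name = "chrA", length = 200000L),
    sd_chrom = "chrA", sd_locus = 100000, sd_region = c(120000, 120000),
    n_sex_linked_snps = 1, n_autosomal_snps = 0,
    decay_length = 2e5, male_error = 0.02, female_error = 0.02,
    missing_rate = 0, indels = default_indels()[0, ], seed = 1
  )
  ref <- build_reference(base)
  scores <- vapply(1:60, function(s) {
    cfg <- base
    cfg$seed <- s
    ds <- simulate_genotypes(cfg, ref)
    concordance_scan(ds)$xy_score[1]
  }, numeric(1))
  f <- linkage_fidelity(20000, 2e5)
  expected <- (18 * f * 0.98 + 20 * 0.98) / 38
  se <- sqrt(expected * (1 - expected) / (38 * 60))
  expect_lt(abs(mean(scores) - expected), 3 * se)
})

test_that("ZW is the sex-swapped mirror of XY", {
  pool_scores <- function(system) {
    unlist(lapply(1:8, function(s) {
      cfg <- tiny_config(seed = s)
      cfg$system <- system
      ds <- simulate_genotypes(cfg, build_reference(cfg))
      sc <- concordance_scan(ds)
      if (system == "XY") sc$xy_score else sc$zw_score
    }))
  }
  ks <- suppressWarnings(stats::ks.test(pool_scores("XY"), pool_scores("ZW")))
  expect_gt(ks$p.value, 0.01)
})

test_that("written datasets round-trip exactly and VCFs are sorted", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      cfg <- tiny_config(
        seed = sample.int(1e6, 1),
        male_error = runif(1, 0, 0.1),
        female_error = runif(1, 0, 0.1),
        missing_rate = runif(1, 0, 0.2)
      )
      out <- withr::local_tempdir()
      sim <- simulate_dataset(cfg, out_dir = out)
      x <- read_vcf(file.path(out, "sim.vcf"))
      expect_identical(x$geno, sim$dataset$geno)
      expect_identical(x$sites$pos, sim$dataset$sites$pos)
      expect_identical(x$sites$ref, sim$dataset$sites$ref)
      expect_identical(x$sites$alt, sim$dataset$sites$alt)
      for (col in c("qd", "mq", "fs", "read_pos_rank_sum", "mq_rank_sum")) {
        expect_equal(x$sites[[col]], sim$dataset$sites[[col]])
      }
      expect_identical(read_phenotypes(file.path(out, "phenotypes.tsv")),
                       sim$dataset$sexes)
      # record count and per-chromosome sortedness
      expect_equal(nrow(x$sites),
                   cfg$n_sex_linked_snps + cfg$n_autosomal_snps)
      by_chrom <- split(x$sites$pos, x$sites$chrom)
      expect_true(all(vapply(by_chrom, function(p) all(diff(p) > 0),
                             logical(1))))
    }
  })
})

test_that("identical seeds give byte-identical VCFs", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  simulate_dataset(tiny_config(seed = 11), out_dir = out1)
  simulate_dataset(tiny_config(seed = 11), out_dir = out2)
  expect_identical(readLines(file.path(out1, "sim.vcf")),
                   readLines(file.path(out2, "sim.vcf")))
})
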