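#' Published primer pairs for the two dmrt1 intron indel markers
#'
#' The two PCR primer pairs (MFS-1 and MFS-2) that assay the 18 bp and
#' 14 bp Y-linked insertions in introns 3 and 5 of *dmrt1*, with their
#' allele-specific product sizes: 364/346 bp and 426/412 bp
#' (male/female).
#'
#' @return A tibble with columns `name`, `forward`, `reverse`,
#'   `x_product`, `y_product`, `insertion_len`.
#' @examples
#' mfs_primers()
#' @export
mfs_primers <- function() {
  tibble::tibble(
    name = c("MFS-1", "MFS-2"),
    forward = c("TATGTCTGGAGGTCACTG", "TGTGAATGGGTGAATGAG"),
    reverse = c("GCTTATTTGGAGGATTGT", "TAGCTTTGTACTTTGTTCC"),
    x_product = c(346L, 412L),
    y_product = c(364L, 426L),
    insertion_len = c(18L, 14L)
  )
}

#' Default genome layout and marker indels for the synthetic panel
#'
#' `default_chromosomes()` gives the 24-chromosome, 300 kb desk-scale
#' layout; `default_indels()` the two Y-linked amplicon insertions
#' (MFS-1: 18 bp in a 346 bp amplicon; MFS-2: 14 bp in 412 bp) placed
#' inside the default SD region.
#'
#' @return A tibble.
#' @export
default_chromosomes <- function() {
  tibble::tibble(
    name = paste0("chr", 1:24),
    length = rep(300000L, 24)
  )
}

#' @rdname default_chromosomes
#' @export
default_indels <- function() {
  p <- mfs_primers()
  tibble::tibble(
    name = p$name,
    pos = c(208840L, 214560L), # amplicon start, inside the default SD region
    x_product = p$x_product,
    insertion_len = p$insertion_len,
    sex_linked = c(TRUE, TRUE),
    forward = p$forward,
    reverse = p$reverse
  )
}

#' Configuration for the synthetic resequencing panel
#'
#' Defines every parameter of the synthetic-data generator: panel
#' composition, genome layout, the sex-determination (SD) locus and
#' region, the heterogamety system, linkage-decay length, genotyping
#' error and missingness, the autosomal minor-allele-frequency range,
#' sex-linked amplicon indels, and the site-annotation model.
#'
#' The defaults are a 1/100 desk-scale replica of a 38-fish
#' resequencing panel: 18 males and 20 females, 24 chromosomes of
#' 300 kb each, and an SD region spanning 197.4-226.0 kb on `chr9`
#' (the 19.74-22.60 Mb interval scaled down), centred on an SD locus
#' at 211.7 kb. Sex-linked SNPs are placed uniformly inside the SD
#' region; a heterogametic-sex individual is heterozygous at such a
#' site with probability `f(d) * (1 - male_error)` where
#' `f(d) = exp(-d / decay_length)` is the linkage fidelity at distance
#' `d` from the SD locus, and a homogametic-sex individual is
#' homozygous-reference with probability `1 - female_error`.
#' Autosomal sites are Hardy-Weinberg draws at a minor-allele
#' frequency uniform over `maf_range`. Every call is independently
#' set missing with probability `missing_rate`.
#'
#' Site annotations (QD, MQ, FS, ReadPosRankSum, MQRankSum) are drawn
#' from a two-component model: with probability `1 - fail_rate` a
#' field comes from a "well-behaved" distribution comfortably inside
#' the standard hard-filter thresholds, otherwise from a failing
#' component beyond its threshold, so a filtered run exercises every
#' criterion.
#'
#' @param n_males,n_females Panel composition (default 18 and 20).
#' @param chromosomes Tibble with columns `name`, `length` (bp).
#' @param sd_chrom Name of the sex chromosome (default `"chr9"`).
#' @param sd_locus SD locus position (bp) on `sd_chrom`.
#' @param sd_region Length-2 integer vector, 1-based inclusive SD
#'   region interval on `sd_chrom`.
#' @param system `"XY"` (heterogametic males) or `"ZW"`
#'   (heterogametic females).
#' @param n_sex_linked_snps,n_autosomal_snps SNP counts.
#' @param decay_length Exponential linkage-decay length lambda in bp.
#' @param male_error,female_error Genotyping-error probabilities
#'   applied to the heterogametic-pattern and homogametic-pattern
#'   genotypes respectively.
#' @param missing_rate Per-call missingness probability.
#' @param maf_range Length-2 vector in (0, 0.5], autosomal MAF range.
#' @param indels Tibble describing amplicon indels (see
#'   [default_indels] layout: `name`, `pos` = amplicon start on
#'   `sd_chrom`, `x_product`, `insertion_len`, `sex_linked`,
#'   `forward`, `reverse`).
#' @param annotation_fail_rate Per-field probability of drawing a
#'   threshold-failing annotation value.
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$sd_region
#' @export
sim_config <- function(n_males = 18,
                       n_females = 20,
                       chromosomes = default_chromosomes(),
                       sd_chrom = "chr9",
                       sd_locus = 211700,
                       sd_region = c(197400, 226000),
                       system = c("XY", "ZW"),
                       n_sex_linked_snps = 60,
                       n_autosomal_snps = 500,
                       decay_length = 2e5,
                       male_error = 0.02,
                       female_error = 0.02,
                       missing_rate = 0.03,
                       maf_range = c(0.05, 0.5),
                       indels = default_indels(),
                       annotation_fail_rate = 0.03,
                       seed) {
  system <- match.arg(system)
  if (missing(seed)) abort("`seed` is mandatory in sim_config().")
  if (!is_count(seed) || seed > 2^31 - 2) {
    abort("`seed` must be a non-negative integer below 2^31 - 1.")
  }
  if (!is_count(n_males) || !is_count(n_females) || n_males + n_females < 2) {
    abort("need n_males + n_females >= 2.")
  }
  chromosomes <- as_tibble(chromosomes)
  if (!all(c("name", "length") %in% names(chromosomes)) ||
      nrow(chromosomes) == 0 || anyDuplicated(chromosomes$name) ||
      any(chromosomes$length < 1)) {
    abort("`chromosomes` needs unique names and positive lengths.")
  }
  if (!sd_chrom %in% chromosomes$name) {
    abort(sprintf("sd_chrom '%s' is not a configured chromosome.", sd_chrom))
  }
  sd_len <- chromosomes$length[chromosomes$name == sd_chrom]
  if (length(sd_region) != 2 || sd_region[1] > sd_region[2] ||
      sd_region[1] < 1 || sd_region[2] > sd_len) {
    abort("`sd_region` must be an interval inside sd_chrom.")
  }
  if (sd_locus < 1 || sd_locus > sd_len) {
    abort("`sd_locus` must lie on sd_chrom.")
  }
  for (p in c(male_error, female_error, missing_rate, annotation_fail_rate)) {
    if (!is_prob(p)) abort("error/missing/annotation rates must be in [0, 1].")
  }
  if (!(decay_length > 0)) abort("`decay_length` must be > 0.")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must lie within (0, 0.5].")
  }
  indels <- as_tibble(indels)
  if (nrow(indels) > 0) {
    needed <- c("name", "pos", "x_product", "insertion_len", "sex_linked",
                "forward", "reverse")
    if (!all(needed %in% names(indels))) {
      abort(paste("`indels` needs columns:", paste(needed, collapse = ", ")))
    }
    if (any(indels$insertion_len < 1) || any(indels$x_product < 1)) {
      abort("indel insertion lengths and amplicon sizes must be positive.")
    }
  }
  structure(
    list(
      n_males = as.integer(n_males), n_females = as.integer(n_females),
      chromosomes = chromosomes, sd_chrom = sd_chrom,
      sd_locus = as.integer(sd_locus), sd_region = as.integer(sd_region),
      system = system,
      n_sex_linked_snps = as.integer(n_sex_linked_snps),
      n_autosomal_snps = as.integer(n_autosomal_snps),
      decay_length = decay_length,
      male_error = male_error, female_error = female_error,
      missing_rate = missing_rate, maf_range = maf_range,
      indels = indels, annotation_fail_rate = annotation_fail_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d M / %d F, %d chromosomes, system %s\n",
    x$n_males, x$n_females, nrow(x$chromosomes), x$system
  ))
  cat(sprintf(
    "  SD region %s:%d-%d (locus %d), lambda = %g bp\n",
    x$sd_chrom, x$sd_region[1], x$sd_region[2], x$sd_locus, x$decay_length
  ))
  cat(sprintf(
    "  %d sex-linked + %d autosomal SNPs, %d indel marker(s), seed %d\n",
    x$n_sex_linked_snps, x$n_autosomal_snps, nrow(x$indels), x$seed
  ))
  invisible(x)
}

# Structural fingerprint used to check that a reference and a config match.
config_fingerprint <- function(config) {
  config[c("chromosomes", "sd_chrom", "sd_locus", "sd_region", "system",
           "indels")]
}
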