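# Sex-genotype concordance scan: per-SNP XY and ZW consistency scores,
# heterogametic-system inference, and sex-determination-region calling.

#' Concordance-scan configuration
#'
#' @param threshold High-concordance cutoff; a site is a supporting
#'   SNP when its winning-model score is strictly greater than this
#'   (default 0.90, i.e. "over 90% consistency").
#' @param min_snps Minimum number of high-scoring SNPs required to
#'   call a system and a region (default 5).
#' @param max_gap Merge distance for region calling in bp: runs of
#'   high scorers separated by more than this are split and only the
#'   largest run is called (default 1 Mb).
#' @param majority_factor System inference requires the winning model
#'   to have more than `majority_factor` times the supporting SNPs of
#'   the other (default 2), preventing coin-flip calls on noisy data.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(threshold = 0.90, min_snps = 5, max_gap = 1e6,
                        majority_factor = 2) {
  if (!(threshold > 0 && threshold <= 1)) abort("threshold must be in (0, 1].")
  if (!is_count(min_snps) || min_snps < 1) abort("min_snps must be >= 1.")
  if (!(max_gap >= 0)) abort("max_gap must be >= 0.")
  structure(
    list(threshold = threshold, min_snps = as.integer(min_snps),
         max_gap = max_gap, majority_factor = majority_factor),
    class = "scan_config"
  )
}

#' XY concordance of one site
#'
#' Fraction of non-missing individuals whose genotype matches the
#' XX/XY expectation: heterozygous males plus homozygous females
#' (either homozygote — restricting to hom-ref would silently depend
#' on reference-allele polarity). Missing genotypes are excluded from
#' both numerator and denominator.
#'
#' @param gt Integer genotype vector (0/1/2/NA), one per sample.
#' @param sex Aligned `"M"`/`"F"` vector.
#' @return Score in `[0, 1]`, or `NA` when no genotype is non-missing.
#' @examples
#' xy_concordance(c(1, 1, 0, 2), c("M", "M", "F", "F"))
#' @export
xy_concordance <- function(gt, sex) {
  concordance_score(gt, sex, het_sex = "M")
}

#' ZW concordance of one site
#'
#' The sex-swapped mirror of [xy_concordance]: heterozygous females
#' plus homozygous males.
#'
#' @inheritParams xy_concordance
#' @return Score in `[0, 1]`, or `NA` when no genotype is non-missing.
#' @export
zw_concordance <- function(gt, sex) {
  concordance_score(gt, sex, het_sex = "F")
}

concordance_score <- function(gt, sex, het_sex) {
  if (length(gt) != length(sex)) abort("gt and sex must be aligned.")
  ok <- !is.na(gt)
  n_used <- sum(ok)
  if (n_used == 0) return(NA_real_)
  match_het <- gt == 1L & sex == het_sex
  match_hom <- gt != 1L & sex != het_sex
  sum((match_het | match_hom)[ok]) / n_used
}

#' Per-site XY/ZW concordance scan
#'
#' Scores every biallelic site of a dataset under both heterogamety
#' hypotheses. Sites with no non-missing genotype are skipped.
#'
#' @param x A `genotype_dataset`.
#' @param phen Phenotype tibble (`sample_id`, `sex`); defaults to the
#'   dataset's own labels when simulated.
#' @return A tibble of class `sdscan_concordance`: `chrom`, `pos`,
#'   `id`, `is_indel`, `indel_len`, `xy_score`, `zw_score`, `n_used`.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1))
#' head(concordance_scan(sim$dataset))
#' @export
concordance_scan <- function(x, phen = x$sexes) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (nrow(x$sites) == 0) abort("no sites to scan.")
  sex <- aligned_sex(x, phen)
  geno <- unname(x$geno)
  m <- sex == "M"
  is_het <- !is.na(geno) & geno == 1L
  is_hom <- !is.na(geno) & geno != 1L
  m_het <- rowSums(is_het[, m, drop = FALSE])
  m_hom <- rowSums(is_hom[, m, drop = FALSE])
  f_het <- rowSums(is_het[, !m, drop = FALSE])
  f_hom <- rowSums(is_hom[, !m, drop = FALSE])
  n_used <- rowSums(!is.na(geno))
  out <- bind_cols(
    select(x$sites, "chrom", "pos", "id", "is_indel", "indel_len"),
    tibble(
      xy_score = (m_het + f_hom) / n_used,
      zw_score = (f_het + m_hom) / n_used,
      n_used = n_used
    )
  )
  out <- filter(out, .data$n_used > 0)
  class(out) <- c("sdscan_concordance", class(tibble()))
  out
}

#' Infer the heterogametic system from a concordance scan
#'
#' Counts supporting SNPs under each hypothesis (winning-model score
#' strictly above the threshold) and calls `"XY"` when the XY count
#' reaches `min_snps` and exceeds `majority_factor` times the ZW
#' count; `"ZW"` by the mirror rule; otherwise `"undetermined"`.
#'
#' @param results A [concordance_scan] table.
#' @param config A [scan_config].
#' @return `"XY"`, `"ZW"` or `"undetermined"`.
#' @export
infer_system <- function(results, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  n_xy <- sum(results$xy_score > config$threshold, na.rm = TRUE)
  n_zw <- sum(results$zw_score > config$threshold, na.rm = TRUE)
  k <- config$majority_factor
  if (n_xy >= config$min_snps && n_xy > k * n_zw) return("XY")
  if (n_zw >= config$min_snps && n_zw > k * n_xy) return("ZW")
  "undetermined"
}

#' Call the sex-determination region
#'
#' Takes the SNPs whose winning-model score exceeds the threshold,
#' assigns the region to their majority chromosome, merges runs of
#' high scorers separated by at most `max_gap`, keeps the run with the
#' most supporting SNPs, and reports its min-max envelope (1-based
#' inclusive). High scorers outside the winning run (other
#' chromosomes or discarded runs) are returned as flagged outliers.
#'
#' @param results A [concordance_scan] table.
#' @param config A [scan_config].
#' @param system `"XY"` or `"ZW"` (e.g. from [infer_system]).
#' @return List with `region` (one-row tibble: `chrom`, `start`,
#'   `end`, `span`, `n_support`, `system`) and `outliers` (tibble of
#'   flagged high scorers).
#' @export
call_sd_region <- function(results, config = scan_config(),
                           system = infer_system(results, config)) {
  stopifnot(inherits(config, "scan_config"))
  if (!system %in% c("XY", "ZW")) {
    abort("cannot call a region for an undetermined system.")
  }
  score <- if (system == "XY") results$xy_score else results$zw_score
  hi <- results[!is.na(score) & score > config$threshold, , drop = FALSE]
  if (nrow(hi) < config$min_snps) {
    abort(sprintf(
      "no region: %d high-scoring SNP(s), need at least %d.",
      nrow(hi), config$min_snps
    ))
  }
  chrom <- names(sort(table(hi$chrom), decreasing = TRUE))[1]
  on_chrom <- arrange(filter(hi, .data$chrom == !!chrom), .data$pos)
  run_id <- cumsum(c(1, diff(on_chrom$pos) > config$max_gap))
  run_sizes <- table(run_id)
  best <- as.integer(names(run_sizes)[which.max(run_sizes)])
  run <- on_chrom[run_id == best, , drop = FALSE]
  if (nrow(run) < config$min_snps) {
    abort(sprintf(
      "no region: largest run holds %d SNP(s), need at least %d.",
      nrow(run), config$min_snps
    ))
  }
  outliers <- bind_rows(
    filter(hi, .data$chrom != !!chrom),
    on_chrom[run_id != best, , drop = FALSE]
  )
  region <- tibble(
    chrom = chrom,
    start = min(run$pos), end = max(run$pos),
    span = max(run$pos) - min(run$pos) + 1L,
    n_support = nrow(run),
    system = system
  )
  list(region = region, outliers = outliers)
}

#' Full sex-determination scan
#'
#' One call from genotypes to a mapped region: concordance scan,
#' system inference, and region calling.
#'
#' @param x A `genotype_dataset`.
#' @param phen Phenotype tibble (`sample_id`, `sex`).
#' @param config A [scan_config].
#' @return An object of class `sd_scan`: list with `scores` (the
#'   concordance table), `system`, `region`, `outliers` and `config`.
#'   `region` and `outliers` are `NULL` when the system is
#'   undetermined or support is insufficient.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1))
#' fit <- sd_scan(sim$dataset)
#' glance(fit)
#' @export
sd_scan <- function(x, phen = x$sexes, config = scan_config()) {
  scores <- concordance_scan(x, phen)
  system <- infer_system(scores, config)
  region <- NULL
  outliers <- NULL
  if (system != "undetermined") {
    called <- tryCatch(call_sd_region(scores, config, system),
                       error = function(e) NULL)
    if (!is.null(called)) {
      region <- called$region
      outliers <- called$outliers
    }
  }
  structure(
    list(scores = scores, system = system, region = region,
         outliers = outliers, config = config),
    class = "sd_scan"
  )
}

#' @export
print.sd_scan <- function(x, ...) {
  cat(sprintf("<sd_scan> %d sites scanned; system: %s\n",
              nrow(x$scores), x$system))
  if (!is.null(x$region)) {
    r <- x$region
    cat(sprintf("  region %s:%d-%d (span %d bp, %d supporting SNPs)\n",
                r$chrom, r$start, r$end, r$span, r$n_support))
    if (nrow(x$outliers) > 0) {
      cat(sprintf("  %d high-scoring outlier(s) flagged\n", nrow(x$outliers)))
    }
  }
  invisible(x)
}

#' @describeIn sd_scan Per-site concordance scores as a tibble.
#' @param x An `sd_scan` object.
#' @param ... Unused.
#' @export
tidy.sd_scan <- function(x, ...) {
  as_tibble(x$scores)
}

#' @describeIn sd_scan One-row summary: system, region coordinates,
#'   support and site counts.
#' @export
glance.sd_scan <- function(x, ...) {
  r <- x$region
  tibble(
    system = x$system,
    chrom = if (is.null(r)) NA_character_ else r$chrom,
    start = if (is.null(r)) NA_integer_ else r$start,
    end = if (is.null(r)) NA_integer_ else r$end,
    span = if (is.null(r)) NA_integer_ else r$span,
    n_support = if (is.null(r)) NA_integer_ else r$n_support,
    n_outliers = if (is.null(r)) NA_integer_ else nrow(x$outliers),
    n_sites = nrow(x$scores),
    threshold = x$config$threshold
  )
}
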