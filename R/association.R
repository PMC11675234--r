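# Case/control allelic association of genotype on phenotypic sex: the
# basic 2x2 allele-count chi-square scan (1 df, no continuity
# correction, no covariates).

#' Allelic 2x2 contingency table for one site
#'
#' Each non-missing diploid genotype contributes its two allele
#' observations to its sex's row; missing genotypes contribute
#' nothing.
#'
#' @param gt Integer genotype vector (0 hom-ref / 1 het / 2 hom-alt /
#'   `NA` missing), one element per sample.
#' @param sex Character vector of `"M"`/`"F"`, aligned with `gt`.
#' @return A 2x2 integer matrix, rows `M`/`F`, columns `ref`/`alt`.
#' @examples
#' allelic_counts(c(1, 0), c("M", "F"))
#' @export
allelic_counts <- function(gt, sex) {
  if (length(gt) != length(sex)) abort("gt and sex must be aligned.")
  if (anyNA(sex) || !all(sex %in% c("M", "F"))) {
    abort("sex must be 'M' or 'F' for every sample.")
  }
  tab <- matrix(0L, 2, 2, dimnames = list(c("M", "F"), c("ref", "alt")))
  for (s in c("M", "F")) {
    g <- gt[sex == s & !is.na(gt)]
    tab[s, "alt"] <- sum(g)
    tab[s, "ref"] <- 2L * length(g) - sum(g)
  }
  tab
}

# Vectorised Pearson chi-square (1 df, no continuity correction) on 2x2
# cell counts a,b (row 1) / c,d (row 2). Degenerate margins -> chi2 0, p 1.
chi2_cells <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("negative counts in 2x2 table.")
  N <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den == 0, 0, N * (a * d - b * c)^2 / den)
  tibble(
    chi2 = chi2,
    p = ifelse(den == 0, 1, pchisq(chi2, df = 1, lower.tail = FALSE))
  )
}

#' Allelic chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction,
#' `chi2 = N (ad - bc)^2 / (r1 r2 c1 c2)`, with the p-value from the
#' 1-df upper tail. A table with any zero row or column margin (e.g. a
#' monomorphic site) is degenerate and returns `chi2 = 0, p = 1`
#' rather than erroring, so genome scans never halt on routine sites.
#'
#' @param table A 2x2 count matrix as from [allelic_counts].
#' @return One-row tibble with `chi2`, `p` and the four cells
#'   `a`, `b`, `c`, `d` (M-ref, M-alt, F-ref, F-alt).
#' @examples
#' chi2_allelic(matrix(c(20, 0, 0, 20), 2, byrow = TRUE))
#' @export
chi2_allelic <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  res <- chi2_cells(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  bind_cols(res, tibble(a = table[1, 1], b = table[1, 2],
                        c = table[2, 1], d = table[2, 2]))
}

#' Genome-wide allelic association scan of sex
#'
#' Runs the allelic chi-square test at every site of a genotype
#' dataset against the sex phenotype, preserving input order, and
#' returns a Manhattan-ready table. The Bonferroni-corrected per-test
#' significance level `alpha / n_tests` is attached as attribute
#' `bonferroni`.
#'
#' @param x A `genotype_dataset`.
#' @param phen Phenotype tibble (`sample_id`, `sex`) covering every
#'   sample of `x`; defaults to the dataset's own labels when
#'   simulated.
#' @param alpha Genome-wide significance level for the Bonferroni
#'   threshold (default 0.05).
#' @return A tibble of class `sdscan_assoc`: `chrom`, `pos`, `id`,
#'   `a`, `b`, `c`, `d` (allele counts, M-ref/M-alt/F-ref/F-alt),
#'   `chi2`, `p`, `minus_log10_p`.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1))
#' head(assoc_scan(sim$dataset))
#' @export
assoc_scan <- function(x, phen = x$sexes, alpha = 0.05) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (nrow(x$sites) == 0) abort("no sites to scan.")
  sex <- aligned_sex(x, phen)
  if (!all(c("M", "F") %in% sex)) {
    abort("association scan needs at least one individual of each sex.")
  }
  geno <- unname(x$geno)
  m <- sex == "M"
  b <- rowSums(geno[, m, drop = FALSE], na.rm = TRUE)
  a <- 2 * rowSums(!is.na(geno[, m, drop = FALSE])) - b
  d <- rowSums(geno[, !m, drop = FALSE], na.rm = TRUE)
  cc <- 2 * rowSums(!is.na(geno[, !m, drop = FALSE])) - d
  res <- chi2_cells(a, b, cc, d)
  out <- bind_cols(
    select(x$sites, "chrom", "pos", "id"),
    tibble(a = a, b = b, c = cc, d = d),
    res
  )
  out$minus_log10_p <- -log10(out$p)
  attr(out, "bonferroni") <- bonferroni_threshold(alpha, nrow(out))
  attr(out, "alpha") <- alpha
  class(out) <- c("sdscan_assoc", class(tibble()))
  out
}

#' Bonferroni per-test significance level
#'
#' @param alpha Genome-wide significance level, in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 1878032)
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1).")
  if (!is_count(n_tests) || n_tests < 1) abort("n_tests must be >= 1.")
  alpha / n_tests
}

# Map a phenotype table onto the dataset's sample order.
aligned_sex <- function(x, phen) {
  if (is.null(phen)) abort("no phenotype labels supplied.")
  phen <- as_tibble(phen)
  idx <- match(x$samples, phen$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("sample '%s' missing from the phenotype table.",
                  x$samples[which(is.na(idx))[1]]))
  }
  phen$sex[idx]
}
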