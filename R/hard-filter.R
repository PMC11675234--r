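# GATK-style hard filtering of variant sites.

#' Hard-filter thresholds
#'
#' The standard GATK site-level hard-filter thresholds. A site is kept
#' only if every *present* annotation satisfies its inequality
#' strictly: `QD > qd_min`, `MQ > mq_min`, `FS < fs_max`,
#' `ReadPosRankSum > read_pos_rank_sum_min`,
#' `MQRankSum > mq_rank_sum_min`. A value exactly equal to its
#' threshold fails; an absent annotation passes that sub-filter
#' (rank-sum fields are undefined at homozygous-only sites and must
#' not exclude them).
#'
#' @param qd_min Quality-by-depth minimum (default 2.0).
#' @param mq_min RMS mapping-quality minimum (default 40.0).
#' @param fs_max Fisher-strand maximum (default 60.0).
#' @param read_pos_rank_sum_min ReadPosRankSum minimum (default -8.0).
#' @param mq_rank_sum_min MQRankSum minimum (default -12.5).
#' @return A list of class `filter_thresholds`.
#' @examples
#' filter_thresholds()
#' @export
filter_thresholds <- function(qd_min = 2.0, mq_min = 40.0, fs_max = 60.0,
                              read_pos_rank_sum_min = -8.0,
                              mq_rank_sum_min = -12.5) {
  th <- list(
    qd_min = qd_min, mq_min = mq_min, fs_max = fs_max,
    read_pos_rank_sum_min = read_pos_rank_sum_min,
    mq_rank_sum_min = mq_rank_sum_min
  )
  if (!all(vapply(th, function(v) is.numeric(v) && is.finite(v), logical(1)))) {
    abort("all thresholds must be finite numbers.")
  }
  structure(th, class = "filter_thresholds")
}

#' Apply hard filters to variant sites
#'
#' Evaluates the [filter_thresholds] inequalities on a site table and
#' reports, per site, whether it passes and which criteria it violates.
#' The pass/fail sets partition the input; re-filtering the pass set is
#' a no-op.
#'
#' @param sites A sites tibble (e.g. `dataset$sites` or the
#'   [read_vcf] site table) with annotation columns `qd`, `mq`, `fs`,
#'   `read_pos_rank_sum`, `mq_rank_sum` (`NA` = annotation absent).
#' @param thresholds A [filter_thresholds].
#' @return The input tibble with two extra columns: `filter_pass`
#'   (logical) and `filter_reasons` (comma-separated names of every
#'   violated criterion, `""` for passing sites).
#' @seealso [filter_dataset] to subset a whole `genotype_dataset`.
#' @export
apply_hard_filters <- function(sites, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  sites <- as_tibble(sites)
  for (col in names(INFO_KEYS)) {
    if (!col %in% names(sites)) sites[[col]] <- NA_real_
    if (!is.numeric(sites[[col]])) {
      abort(sprintf("annotation column '%s' is not numeric.", col))
    }
  }
  viol <- cbind(
    QD = !is.na(sites$qd) & !(sites$qd > thresholds$qd_min),
    MQ = !is.na(sites$mq) & !(sites$mq > thresholds$mq_min),
    FS = !is.na(sites$fs) & !(sites$fs < thresholds$fs_max),
    ReadPosRankSum = !is.na(sites$read_pos_rank_sum) &
      !(sites$read_pos_rank_sum > thresholds$read_pos_rank_sum_min),
    MQRankSum = !is.na(sites$mq_rank_sum) &
      !(sites$mq_rank_sum > thresholds$mq_rank_sum_min)
  )
  sites$filter_pass <- rowSums(viol) == 0
  sites$filter_reasons <- apply(viol, 1, function(v) {
    paste(colnames(viol)[v], collapse = ",")
  })
  sites
}

#' Hard-filter a genotype dataset
#'
#' Applies [apply_hard_filters] and splits the dataset into the passing
#' subset (genotypes retained) and a fail table with per-site reasons.
#'
#' @param x A `genotype_dataset`.
#' @param thresholds A [filter_thresholds].
#' @return List with `pass` (a filtered `genotype_dataset`) and `fail`
#'   (tibble of failing sites with `filter_reasons`).
#' @export
filter_dataset <- function(x, thresholds = filter_thresholds()) {
  stopifnot(inherits(x, "genotype_dataset"))
  ann <- apply_hard_filters(x$sites, thresholds)
  keep <- ann$filter_pass
  pass <- x
  pass$sites <- x$sites[keep, , drop = FALSE]
  pass$geno <- x$geno[keep, , drop = FALSE]
  list(
    pass = pass,
    fail = select(ann[!keep, , drop = FALSE], -"filter_pass")
  )
}
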