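# Readers and writers for the standard formats the pipeline touches:
# VCF v4.2 (vcfR-backed reading), phenotype TSV, BED3, FASTA.

GT_MAP <- c(
  "0/0" = 0L, "0|0" = 0L,
  "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
  "1/1" = 2L, "1|1" = 2L
)

geno_to_gt_string <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 2L] <- "1/1"
  out
}

INFO_KEYS <- c(
  qd = "QD", mq = "MQ", fs = "FS",
  read_pos_rank_sum = "ReadPosRankSum", mq_rank_sum = "MQRankSum"
)

# Write a genotype_dataset as a sorted VCF v4.2 with the five hard-filter
# INFO annotations and per-sample GT calls.
write_vcf <- function(dataset, path, contigs = NULL) {
  sites <- dataset$sites
  info <- vapply(seq_len(nrow(sites)), function(i) {
    vals <- c(sites$qd[i], sites$mq[i], sites$fs[i],
              sites$read_pos_rank_sum[i], sites$mq_rank_sum[i])
    keep <- !is.na(vals)
    if (!any(keep)) return(".")
    paste(paste0(unname(INFO_KEYS)[keep], "=",
                 formatC(vals[keep], format = "fg", digits = 15)),
          collapse = ";")
  }, character(1))

  gt <- apply(dataset$geno, 1, geno_to_gt_string)
  gt <- if (is.matrix(gt)) t(gt) else matrix(gt, nrow = nrow(sites))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sdscan",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", contigs$name, contigs$length)
    },
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Variant Confidence/Quality by Depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS Mapping Quality">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled p-value using Fisher\'s exact test to detect strand bias">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Z-score from Wilcoxon rank sum test of Alt vs. Ref read position bias">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Z-score from Wilcoxon rank sum test of Alt vs. Ref read mapping qualities">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$samples), collapse = "\t")
  )
  body <- paste(
    sites$chrom, sites$pos, sites$id, sites$ref, sites$alt, ".", ".",
    info, "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

parse_region <- function(region) {
  m <- stringr::str_match(region, "^([^:]+)(?::([0-9,]+)-([0-9,]+))?$")
  if (is.na(m[1, 1])) abort(sprintf("cannot parse region '%s'.", region))
  list(
    chrom = m[1, 2],
    start = if (is.na(m[1, 3])) -Inf else as.numeric(gsub(",", "", m[1, 3])),
    end = if (is.na(m[1, 4])) Inf else as.numeric(gsub(",", "", m[1, 4]))
  )
}

#' Read a VCF into a genotype dataset
#'
#' Parses a VCF v4.2 with `vcfR`, mapping each per-sample GT call to an
#' integer alt-allele dose: 0 (hom ref), 1 (het, phase- and
#' order-insensitive), 2 (hom alt), `NA` (missing). Genotypes touching
#' alt alleles beyond the first are set missing, so every analysis is
#' biallelic on the first alt; such sites are flagged `multiallelic`.
#' The five standard hard-filter annotations (QD, MQ, FS,
#' ReadPosRankSum, MQRankSum) are lifted from INFO where present
#' (`NA` = absent, which is distinct from failing).
#'
#' @param path VCF file path.
#' @param region Optional `"chrom"` or `"chrom:start-end"` filter,
#'   1-based inclusive.
#' @return A `genotype_dataset` without sex labels (`sexes = NULL`);
#'   pair it with [read_phenotypes].
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  sites <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = fix$ID,
    ref = fix$REF,
    alt = fix$ALT
  )
  if (any(is.na(sites$pos)) || any(is.na(sites$ref)) ||
      any(!nzchar(sites$ref))) {
    bad <- which(is.na(sites$pos) | is.na(sites$ref) | !nzchar(sites$ref))[1]
    abort(sprintf("malformed VCF record at data line %d of %s.", bad, path))
  }
  sites$multiallelic <- stringr::str_detect(sites$alt, ",")
  first_alt <- stringr::str_split_i(sites$alt, ",", 1)
  sites$alt <- first_alt
  sites$is_indel <- nchar(sites$ref) != nchar(first_alt)
  sites$indel_len <- abs(nchar(first_alt) - nchar(sites$ref))

  for (col in names(INFO_KEYS)) {
    vals <- suppressWarnings(
      vcfR::extract.info(v, element = INFO_KEYS[[col]], as.numeric = TRUE)
    )
    sites[[col]] <- if (is.null(vals)) NA_real_ else as.numeric(vals)
  }

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) abort("VCF has no GT field.")
  samples <- colnames(gt_raw)
  geno <- matrix(GT_MAP[gt_raw], nrow = nrow(gt_raw),
                 dimnames = list(sites$id, samples))

  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- sites$chrom == r$chrom & sites$pos >= r$start & sites$pos <= r$end
    sites <- sites[keep, , drop = FALSE]
    geno <- geno[keep, , drop = FALSE]
  }

  structure(
    list(samples = samples, sexes = NULL, sites = sites, geno = geno),
    class = "genotype_dataset"
  )
}

#' Read a sex-phenotype table
#'
#' Reads a TSV with header columns `sample_id` and `sex`. Sex tokens
#' `M`/`F`/`male`/`female` (any case) are normalised to `M`/`F`;
#' anything else, or a duplicated sample id, is an error.
#'
#' @param path TSV file path.
#' @return A tibble with columns `sample_id`, `sex`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("phenotype table not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("sample_id", "sex") %in% names(tab))) {
    abort("phenotype TSV must have header columns 'sample_id' and 'sex'.")
  }
  sex <- normalize_sex(tab$sex)
  if (anyNA(sex)) {
    bad <- which(is.na(sex))[1]
    abort(sprintf(
      "unrecognised sex token '%s' at line %d (expected M/F/male/female).",
      tab$sex[bad], bad + 1L
    ))
  }
  if (anyDuplicated(tab$sample_id)) {
    dup <- tab$sample_id[duplicated(tab$sample_id)][1]
    abort(sprintf("duplicate sample id '%s' in phenotype table.", dup))
  }
  tibble(sample_id = tab$sample_id, sex = sex)
}

#' Write a region to a BED3 file
#'
#' All intervals inside the package are 1-based inclusive; BED is the
#' only 0-based half-open surface, so the exported start is
#' `start - 1`.
#'
#' @param region One-row data frame with columns `chrom`, `start`,
#'   `end` (1-based inclusive), e.g. the region component of
#'   [call_sd_region].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_region_bed <- function(region, path) {
  region <- as_tibble(region)
  stopifnot(nrow(region) >= 1,
            all(c("chrom", "start", "end") %in% names(region)))
  if (any(region$start > region$end) || any(region$start < 1)) {
    abort("invalid region: need 1 <= start <= end.")
  }
  writeLines(
    sprintf("%s\t%d\t%d", region$chrom,
            as.integer(region$start) - 1L, as.integer(region$end)),
    path
  )
  invisible(path)
}

#' Read a BED3 file back into 1-based inclusive intervals
#'
#' @param path BED file path.
#' @return Tibble with columns `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_region_bed <- function(path) {
  tab <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end"),
    col_types = "cii", progress = FALSE
  )
  mutate(tab, start = .data$start + 1L)
}

#' Read primer pairs from a TSV
#'
#' Expects header columns `name`, `forward`, `reverse`.
#'
#' @param path TSV file path.
#' @return Tibble of primer pairs.
#' @export
read_primers <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("name", "forward", "reverse") %in% names(tab))) {
    abort("primer TSV must have columns 'name', 'forward', 'reverse'.")
  }
  tab$forward <- toupper(tab$forward)
  tab$reverse <- toupper(tab$reverse)
  ok <- grepl("^[ACGT]+$", tab$forward) & grepl("^[ACGT]+$", tab$reverse)
  if (!all(ok)) abort("primer sequences must be over the A/C/G/T alphabet.")
  as_tibble(tab)
}

#' Read a reference FASTA as plain character sequences
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}
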