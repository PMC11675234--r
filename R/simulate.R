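# Synthetic-data generator: reference sequences, amplicon truth, and a
# genotyped, sexed diploid panel with the statistical structure the
# downstream scans assume.

#' Linkage fidelity at a distance from the SD locus
#'
#' `f(d) = exp(-d / lambda)`: the probability that a sex-linked site at
#' physical distance `d` from the sex-determination locus still shows
#' the fully sex-linked genotype pattern.
#'
#' @param d Distance in bp (vectorised).
#' @param lambda Decay length in bp.
#' @return Numeric vector in (0, 1].
#' @export
linkage_fidelity <- function(d, lambda) {
  stopifnot(lambda > 0)
  exp(-abs(d) / lambda)
}

#' Build the synthetic reference and amplicon truth set
#'
#' Generates one random nucleotide sequence per configured chromosome
#' and embeds, inside the SD region, one X-allele amplicon template per
#' configured indel marker: forward primer + random filler + reverse
#' complement of the reverse primer, totalling `x_product` bp. The
#' Y-allele template is the X template with `insertion_len` random
#' bases inserted midway between the primer sites; only the X allele is
#' written into the chromosome sequence (the reference individual is
#' taken from the homogametic sex).
#'
#' Uses the RNG stream seeded with `config$seed`; the same seed gives
#' byte-identical sequences.
#'
#' @param config A [sim_config].
#' @return A `reference_set`: list with `sequences` (named character),
#'   `sd_truth` (chrom, region, system), `amplicons` (tibble with the
#'   X/Y templates and insertion coordinates) and the structural
#'   fingerprint of `config`.
#' @examples
#' ref <- build_reference(sim_config(seed = 1))
#' nchar(ref$sequences[["chr1"]])
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seqs <- setNames(
    vapply(config$chromosomes$length, random_dna, character(1)),
    config$chromosomes$name
  )

  amp <- config$indels
  amplicons <- NULL
  if (nrow(amp) > 0) {
    rows <- vector("list", nrow(amp))
    for (i in seq_len(nrow(amp))) {
      fwd <- toupper(amp$forward[i])
      rev <- toupper(amp$reverse[i])
      xlen <- amp$x_product[i]
      ilen <- amp$insertion_len[i]
      start <- amp$pos[i]
      end <- start + xlen - 1
      if (start < config$sd_region[1] || end > config$sd_region[2]) {
        abort(sprintf(
          "amplicon '%s' (%d-%d) does not fit inside the SD region %d-%d.",
          amp$name[i], start, end, config$sd_region[1], config$sd_region[2]
        ))
      }
      filler <- xlen - nchar(fwd) - nchar(rev)
      if (filler < 1) abort("amplicon shorter than its primers.")
      x_template <- paste0(fwd, random_dna(filler), revcomp(rev))
      # insertion point: midway through the filler, 1-based offset of the
      # base after which the insertion sits (VCF-style anchor base)
      offset <- nchar(fwd) + filler %/% 2
      insertion <- random_dna(ilen)
      y_template <- paste0(
        substr(x_template, 1, offset), insertion,
        substr(x_template, offset + 1, xlen)
      )
      sdseq <- seqs[[config$sd_chrom]]
      substr(sdseq, start, end) <- x_template
      seqs[[config$sd_chrom]] <- sdseq
      rows[[i]] <- tibble(
        name = amp$name[i], chrom = config$sd_chrom,
        start = start, end = end,
        forward = fwd, reverse = rev,
        x_product = xlen, y_product = xlen + ilen,
        insertion_len = ilen, insertion_seq = insertion,
        insertion_offset = offset,
        indel_pos = start + offset - 1,     # genomic anchor base of the indel
        sex_linked = amp$sex_linked[i],
        x_template = x_template, y_template = y_template
      )
    }
    amplicons <- bind_rows(rows)
  } else {
    amplicons <- tibble(
      name = character(), chrom = character(), start = integer(),
      end = integer(), forward = character(), reverse = character(),
      x_product = integer(), y_product = integer(),
      insertion_len = integer(), insertion_seq = character(),
      insertion_offset = integer(), indel_pos = integer(),
      sex_linked = logical(),
      x_template = character(), y_template = character()
    )
  }

  structure(
    list(
      sequences = seqs,
      sd_truth = list(
        chrom = config$sd_chrom,
        region = config$sd_region,
        system = config$system
      ),
      amplicons = amplicons,
      fingerprint = config_fingerprint(config)
    ),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "<reference_set> %d sequence(s), %d amplicon(s); SD truth %s:%d-%d (%s)\n",
    length(x$sequences), nrow(x$amplicons), x$sd_truth$chrom,
    x$sd_truth$region[1], x$sd_truth$region[2], x$sd_truth$system
  ))
  invisible(x)
}

# Two-component annotation model: well-behaved vs threshold-failing draws.
draw_annotations <- function(n, fail_rate) {
  pick <- function(pass, fail) {
    bad <- runif(n) < fail_rate
    ifelse(bad, fail, pass)
  }
  tibble(
    qd = round(pick(rgamma(n, shape = 8, scale = 2.5), runif(n, 0, 2)), 4),
    mq = round(pick(rnorm(n, 60, 2), runif(n, 20, 40)), 4),
    fs = round(pick(rexp(n, 1 / 5), runif(n, 60, 120)), 4),
    read_pos_rank_sum = round(pick(rnorm(n, 0, 1.5), runif(n, -20, -8)), 4),
    mq_rank_sum = round(pick(rnorm(n, 0, 2), runif(n, -30, -12.5)), 4)
  )
}

base_at <- function(seqs, chrom, pos) {
  substr(seqs[[chrom]], pos, pos)
}

other_base <- function(ref) {
  unname(vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1),
                character(1)))
}

#' Simulate genotypes for the configured panel
#'
#' Draws the genotype matrix of the synthetic panel under the
#' generative model described in [sim_config]: sex-linked SNPs inside
#' the SD region with exponentially decaying linkage fidelity,
#' perfectly sex-linked amplicon indels, Hardy-Weinberg autosomal SNPs,
#' per-call genotyping error and missingness, and hard-filter-style
#' site annotations. Under `system = "ZW"` the sexes swap roles
#' (females heterogametic).
#'
#' Uses the RNG stream seeded with `config$seed + 1`, so the genotype
#' draw is reproducible and independent of whether the reference was
#' rebuilt.
#'
#' @param config A [sim_config].
#' @param ref The [build_reference] output for a structurally identical
#'   config (the seed may differ; only layout must match).
#' @return A `genotype_dataset`: list with `samples`, `sexes` (tibble
#'   `sample_id`, `sex`), `sites` (tibble, one row per variant, sorted
#'   by chromosome then position) and `geno` (integer matrix sites x
#'   samples; 0 hom-ref, 1 het, 2 hom-alt, NA missing).
#' @examples
#' cfg <- sim_config(seed = 1)
#' ds <- simulate_genotypes(cfg, build_reference(cfg))
#' dim(ds$geno)
#' @export
simulate_genotypes <- function(config, ref) {
  stopifnot(inherits(config, "sim_config"), inherits(ref, "reference_set"))
  if (!identical(config_fingerprint(config), ref$fingerprint)) {
    abort("`ref` was built from a structurally different config.")
  }
  n_sites <- config$n_sex_linked_snps + config$n_autosomal_snps +
    nrow(config$indels)
  if (n_sites == 0) abort("zero sites configured; nothing to simulate.")
  set.seed(config$seed + 1L)

  n_m <- config$n_males
  n_f <- config$n_females
  samples <- c(
    if (n_m > 0) sprintf("M%03d", seq_len(n_m)),
    if (n_f > 0) sprintf("F%03d", seq_len(n_f))
  )
  sex <- c(rep("M", n_m), rep("F", n_f))
  sexes <- tibble(sample_id = samples, sex = sex)
  n <- n_m + n_f

  # --- site coordinates ------------------------------------------------
  region <- config$sd_region
  reserved <- as.integer(ref$amplicons$indel_pos) # indel anchor bases
  sl_pool <- setdiff(seq(region[1], region[2]), reserved)
  if (config$n_sex_linked_snps > length(sl_pool)) {
    abort("SD region too small for the requested sex-linked SNP count.")
  }
  # sample() treats a length-1 pool as 1:n; guard against that
  sl_pos <- if (length(sl_pool) == 1 && config$n_sex_linked_snps == 1) {
    sl_pool
  } else {
    sort(sample(sl_pool, config$n_sex_linked_snps))
  }

  chroms <- config$chromosomes
  auto_idx <- sample.int(nrow(chroms), config$n_autosomal_snps,
                         replace = TRUE, prob = chroms$length)
  auto_counts <- table(factor(chroms$name[auto_idx], levels = chroms$name))
  auto <- purrr::map2_dfr(chroms$name, as.integer(auto_counts),
    function(nm, k) {
      if (k == 0) return(NULL)
      L <- chroms$length[chroms$name == nm]
      # positions already taken on this chromosome must stay unique
      excl <- if (nm == config$sd_chrom) c(sl_pos, reserved) else integer(0)
      if (k + length(excl) > L) abort("chromosome too small for SNP count.")
      pos <- setdiff(sample.int(L, k + length(excl)), excl)[seq_len(k)]
      tibble(chrom = nm, pos = as.integer(pos))
    })

  sites <- bind_rows(
    tibble(chrom = config$sd_chrom, pos = as.integer(sl_pos),
           truth = "sex_linked", indel_len = 0L),
    mutate(auto, truth = "autosomal", indel_len = 0L),
    if (nrow(ref$amplicons) > 0) {
      tibble(chrom = ref$amplicons$chrom,
             pos = as.integer(ref$amplicons$indel_pos),
             truth = "indel",
             indel_len = as.integer(ref$amplicons$insertion_len))
    }
  )

  # ref base from the sequence; SNP alt is a different base, indel alt is
  # ref base + the inserted sequence
  sites$ref <- mapply(base_at, chrom = sites$chrom, pos = sites$pos,
                      MoreArgs = list(seqs = ref$sequences), USE.NAMES = FALSE)
  sites$alt <- other_base(sites$ref)
  if (nrow(ref$amplicons) > 0) {
    idx <- match(
      paste(ref$amplicons$chrom, ref$amplicons$indel_pos),
      paste(sites$chrom, sites$pos)
    )
    sites$alt[idx] <- paste0(sites$ref[idx], ref$amplicons$insertion_seq)
  }
  sites$is_indel <- nchar(sites$ref) != nchar(sites$alt)

  # --- genotypes -------------------------------------------------------
  het_sex <- if (config$system == "XY") "M" else "F"
  e_het <- if (config$system == "XY") config$male_error else config$female_error
  e_hom <- if (config$system == "XY") config$female_error else config$male_error
  is_het_sex <- sex == het_sex

  m_sites <- nrow(sites)
  geno <- matrix(NA_integer_, nrow = m_sites, ncol = n)

  linked <- sites$truth %in% c("sex_linked", "indel")
  fid <- numeric(m_sites)
  fid[sites$truth == "sex_linked"] <- linkage_fidelity(
    sites$pos[sites$truth == "sex_linked"] - config$sd_locus,
    config$decay_length
  )
  fid[sites$truth == "indel"] <- 1 # marker indels are fully sex-linked

  n_linked <- sum(linked)
  if (n_linked > 0 && n > 0) {
    p_het_carrier <- fid[linked] * (1 - e_het)
    het_mat <- matrix(0L, nrow = n_linked, ncol = n)
    if (any(is_het_sex)) {
      k <- sum(is_het_sex)
      het_mat[, is_het_sex] <- rbinom(n_linked * k, 1, rep(p_het_carrier, k))
    }
    if (any(!is_het_sex)) {
      k <- sum(!is_het_sex)
      het_mat[, !is_het_sex] <- rbinom(n_linked * k, 1, rep(e_hom, n_linked * k))
    }
    geno[linked, ] <- het_mat
  }

  is_auto <- sites$truth == "autosomal"
  n_auto <- sum(is_auto)
  if (n_auto > 0 && n > 0) {
    maf <- runif(n_auto, config$maf_range[1], config$maf_range[2])
    geno[is_auto, ] <- matrix(
      rbinom(n_auto * n, 2, rep(maf, n)), nrow = n_auto
    )
  }

  if (config$missing_rate > 0 && n > 0) {
    geno[matrix(runif(m_sites * n) < config$missing_rate,
                nrow = m_sites)] <- NA_integer_
  }

  sites <- bind_cols(sites, draw_annotations(m_sites, config$annotation_fail_rate))

  ord <- order(match(sites$chrom, chroms$name), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  sites$id <- sprintf("site_%05d", seq_len(nrow(sites)))
  sites <- select(
    sites, "chrom", "pos", "id", "ref", "alt", "is_indel", "indel_len",
    "qd", "mq", "fs", "read_pos_rank_sum", "mq_rank_sum", "truth"
  )
  dimnames(geno) <- list(sites$id, samples)

  structure(
    list(samples = samples, sexes = sexes, sites = sites, geno = geno),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  sx <- table(factor(x$sexes$sex, levels = c("M", "F")))
  cat(sprintf(
    "<genotype_dataset> %d sites x %d samples (%d M / %d F), %d indel(s)\n",
    nrow(x$sites), length(x$samples), sx[["M"]], sx[["F"]],
    sum(x$sites$is_indel)
  ))
  invisible(x)
}

#' Write a simulated dataset to standard files
#'
#' Emits a sorted VCF v4.2 (with QD, MQ, FS, ReadPosRankSum and
#' MQRankSum in INFO and per-sample GT), a phenotype TSV
#' (`sample_id<TAB>sex`), the reference FASTA, and a truth JSON holding
#' the SD region, the heterogamety system and the marker amplicon
#' templates.
#'
#' @param dataset A `genotype_dataset`.
#' @param ref The matching `reference_set`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths
#'   (`vcf`, `phenotypes`, `fasta`, `truth`).
#' @export
write_dataset <- function(dataset, ref, out_dir) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(ref, "reference_set"))
  if (nrow(dataset$sites) == 0) abort("empty dataset; nothing to write.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(out_dir, "sim.vcf"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    fasta = file.path(out_dir, "ref.fa"),
    truth = file.path(out_dir, "truth.json")
  )

  contigs <- tibble(
    name = names(ref$sequences),
    length = nchar(unname(ref$sequences))
  )
  write_vcf(dataset, paths$vcf, contigs = contigs)

  readr::write_tsv(dataset$sexes, paths$phenotypes)

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ref$sequences), paths$fasta
  )

  truth <- list(
    sd_chrom = ref$sd_truth$chrom,
    sd_start = ref$sd_truth$region[1],
    sd_end = ref$sd_truth$region[2],
    system = ref$sd_truth$system,
    amplicons = ref$amplicons
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)

  invisible(paths)
}

#' Simulate a complete dataset in one call
#'
#' Convenience wrapper: [build_reference] + [simulate_genotypes], and
#' optionally [write_dataset].
#'
#' @param config A [sim_config].
#' @param out_dir If non-NULL, write the dataset files there.
#' @return List with `config`, `ref`, `dataset` and (if written) `paths`.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1))
#' sim$dataset
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  ref <- build_reference(config)
  dataset <- simulate_genotypes(config, ref)
  paths <- NULL
  if (!is.null(out_dir)) paths <- write_dataset(dataset, ref, out_dir)
  list(config = config, ref = ref, dataset = dataset, paths = paths)
}
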