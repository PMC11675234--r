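# Shared fixtures: hand-built datasets and small simulator configs.

# Minimal genotype_dataset built by hand (0 hom-ref / 1 het / 2 hom-alt / NA).
make_dataset <- function(geno, sexes, chrom = "chr1",
                         pos = seq_len(nrow(geno)) * 100L,
                         ref = rep("A", nrow(geno)),
                         alt = rep("T", nrow(geno)),
                         qd = rep(NA_real_, nrow(geno)),
                         mq = rep(NA_real_, nrow(geno)),
                         fs = rep(NA_real_, nrow(geno)),
                         read_pos_rank_sum = rep(NA_real_, nrow(geno)),
                         mq_rank_sum = rep(NA_real_, nrow(geno))) {
  n_sites <- nrow(geno)
  sites <- tibble::tibble(
    chrom = rep_len(chrom, n_sites), pos = pos,
    id = sprintf("s%03d", seq_len(n_sites)),
    ref = ref, alt = alt,
    is_indel = nchar(ref) != nchar(alt),
    indel_len = abs(nchar(alt) - nchar(ref)),
    qd = qd, mq = mq, fs = fs,
    read_pos_rank_sum = read_pos_rank_sum, mq_rank_sum = mq_rank_sum
  )
  dimnames(geno) <- list(sites$id, sexes$sample_id)
  structure(
    list(samples = sexes$sample_id, sexes = sexes, sites = sites,
         geno = geno),
    class = "genotype_dataset"
  )
}

make_sexes <- function(n_m, n_f) {
  tibble::tibble(
    sample_id = c(sprintf("M%02d", seq_len(n_m)),
                  sprintf("F%02d", seq_len(n_f))),
    sex = c(rep("M", n_m), rep("F", n_f))
  )
}

# Small, fast simulator config for property tests.
tiny_config <- function(seed, ...) {
  defaults <- list(
    n_males = 6, n_females = 6,
    chromosomes = tibble::tibble(name = c("chrA", "chrB"),
                                 length = c(20000L, 20000L)),
    sd_chrom = "chrA", sd_locus = 10000, sd_region = c(5000, 15000),
    n_sex_linked_snps = 15, n_autosomal_snps = 20,
    decay_length = 5e4,
    indels = default_indels()[0, ],
    seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

interval_jaccard <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0, min(a_end, b_end) - max(a_start, b_start) + 1)
  union <- (a_end - a_start + 1) + (b_end - b_start + 1) - inter
  inter / union
}
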