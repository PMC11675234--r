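# Independent oracles and shared toy-file builders used by several
# test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force dictionary oracle for canonical k-mer multiplicities.
oracle_kmer_multiplicities <- function(seq, k) {
  counts <- list()
  L <- nchar(seq)
  if (L < k) return(integer(0))
  for (i in 1:(L - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("N", w, fixed = TRUE)) next
    r <- paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1]]),
               collapse = "")
    key <- if (w <= r) w else r
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  unlist(counts)
}

# Textbook expected-count form of the Pearson statistic, an independent
# computation path from the package's product-of-margins formula.
oracle_chi2_expected_counts <- function(a, b, c, d) {
  N <- a + b + c + d
  E <- outer(c(a + b, c + d), c(a + c, b + d)) / N
  O <- matrix(c(a, c, b, d), 2)
  sum((O - E)^2 / E)
}

# Minimal VCF writer for hand-built fixtures.
toy_vcf <- function(path, records, samples = c("s1", "s2")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="QD">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="MQ">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="FS">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="RPRS">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="MQRS">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}
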