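# k-mer coverage-peak genome-size estimation: the classic
# "genome size = total k-mer instances / homozygous coverage peak"
# arithmetic applied to a k-mer depth histogram.

#' Construct a k-mer depth histogram
#'
#' @param depth Integer vector of depths (>= 1).
#' @param count Number of distinct k-mers observed at each depth.
#' @param k The k-mer length the histogram was built with (optional,
#'   carried as an attribute).
#' @return A tibble of class `kmer_histogram`, sorted by depth.
#' @export
kmer_histogram <- function(depth, count, k = NA_integer_) {
  if (length(depth) != length(count) || any(depth < 1) || any(count < 0)) {
    abort("need depth >= 1 and count >= 0, same length.")
  }
  h <- arrange(tibble(depth = as.integer(depth), count = as.numeric(count)),
               .data$depth)
  structure(h, class = c("kmer_histogram", class(tibble())), k = as.integer(k))
}

#' Read a `depth<TAB>count` histogram TSV
#'
#' The common export format of k-mer counters (two columns, no or any
#' header starting with a non-digit).
#'
#' @param path TSV file path.
#' @param k Optional k-mer length to record on the histogram.
#' @return A [kmer_histogram].
#' @export
read_kmer_histogram <- function(path, k = NA_integer_) {
  lines <- readLines(path)
  lines <- lines[grepl("^\\s*[0-9]", lines)]
  if (length(lines) == 0) abort("no numeric rows in histogram file.")
  parts <- stringr::str_split_fixed(trimws(lines), "\\s+", 2)
  kmer_histogram(as.integer(parts[, 1]), as.numeric(parts[, 2]), k = k)
}

#' Count canonical k-mers in nucleotide sequences
#'
#' Slides a window of width `k` over every sequence, collapsing each
#' k-mer with its reverse complement onto the lexicographically smaller
#' of the two (canonical form, as for unstranded sequencing data).
#' Windows containing `N` are skipped. Multiplicities are accumulated
#' over all sequences and summarised as a depth histogram.
#'
#' @param sequences Character vector of sequences over `A/C/G/T/N`
#'   (case-insensitive).
#' @param k k-mer length (>= 1).
#' @return A [kmer_histogram]; the per-k-mer multiplicities are
#'   attached as attribute `kmers` (named integer vector).
#' @examples
#' count_canonical_kmers("ACGTACGT", k = 4)
#' @export
count_canonical_kmers <- function(sequences, k) {
  stopifnot(is_count(k), k >= 1)
  sequences <- toupper(sequences)
  if (any(!grepl("^[ACGTN]*$", sequences))) {
    abort("sequences must be over the A/C/G/T/N alphabet.")
  }
  if (all(nchar(sequences) < k)) {
    abort(sprintf("k = %d exceeds every sequence length.", k))
  }
  windows <- unlist(lapply(sequences, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  }))
  windows <- windows[!grepl("N", windows, fixed = TRUE)]
  if (length(windows) == 0) abort("no N-free windows; empty histogram.")
  rc <- revcomp(windows)
  canon <- ifelse(windows <= rc, windows, rc)
  mult <- table(canon)
  counts <- table(as.integer(mult))
  h <- kmer_histogram(as.integer(names(counts)), as.numeric(counts), k = k)
  attr(h, "kmers") <- setNames(as.integer(mult), names(mult))
  h
}

#' Total k-mer instances in a histogram
#'
#' `sum(depth * count)`: the number of k-mer windows observed.
#'
#' @param hist A [kmer_histogram].
#' @return A number.
#' @export
total_kmers <- function(hist) {
  sum(as.numeric(hist$depth) * hist$count)
}

#' Locate the homozygous coverage peak of a k-mer histogram
#'
#' Sequencing-error k-mers pile up at low depth; the genome signal
#' forms a mode at the sequencing coverage. Scanning depths in
#' ascending order, the first rise in counts marks the error/signal
#' valley; the peak is the depth with maximal count above that valley.
#' A monotonically non-increasing histogram has no such valley and
#' raises an error.
#'
#' @param hist A [kmer_histogram].
#' @return The peak depth (integer).
#' @examples
#' h <- kmer_histogram(c(1, 2, 3, 16, 17), c(1e6, 1e4, 100, 5e5, 4e5))
#' find_coverage_peak(h)
#' @export
find_coverage_peak <- function(hist) {
  if (nrow(hist) == 0) abort("empty histogram.")
  full <- numeric(max(hist$depth))
  full[hist$depth] <- hist$count
  rises <- which(diff(full) > 0)
  if (length(rises) == 0) {
    abort("histogram is non-increasing: no diploid coverage peak.")
  }
  valley <- rises[1]
  upper <- full[(valley + 1):length(full)]
  as.integer(valley + which.max(upper))
}

#' Estimate genome size from total k-mers and the coverage peak
#'
#' `genome size = total k-mer instances / peak depth`, rounded half-up
#' to the nearest base pair.
#'
#' @param total_kmers Total k-mer instances (> 0). Vectorised.
#' @param peak Coverage peak depth (>= 1). Vectorised.
#' @return Genome size in bp.
#' @examples
#' estimate_genome_size(11246682729, 16)
#' @export
estimate_genome_size <- function(total_kmers, peak) {
  if (any(peak < 1)) abort("peak depth must be >= 1.")
  if (any(total_kmers <= 0)) abort("total_kmers must be > 0.")
  round_half_up(total_kmers / peak)
}

#' Single-copy proportion of the genome
#'
#' `single_copy_size / genome_size`, rounded half-up to 3 decimals.
#'
#' @param single_copy_size Single-copy (non-repetitive) size in bp.
#' @param genome_size Genome size in bp (> 0).
#' @return Proportion in `[0, 1]`, 3 decimals.
#' @examples
#' single_copy_proportion(576367348, 702917671)
#' @export
single_copy_proportion <- function(single_copy_size, genome_size) {
  if (any(genome_size <= 0)) abort("genome_size must be > 0.")
  if (any(single_copy_size < 0) ||
      any(single_copy_size > genome_size * 1.001)) {
    abort("single_copy_size must lie in [0, genome_size].")
  }
  round_half_up(single_copy_size / genome_size, 3)
}

#' Genome-size summary table across k-mer lengths
#'
#' Combines the size arithmetic into the familiar one-row-per-k layout:
#' peak, total k-mers, genome size, and (optionally) single-copy size
#' and proportion.
#'
#' @param k K-mer lengths.
#' @param total_kmers Total k-mer instances per k.
#' @param peak Coverage peak per k.
#' @param single_copy_size Optional single-copy sizes per k.
#' @return A tibble with one row per k.
#' @export
genome_size_table <- function(k, total_kmers, peak, single_copy_size = NULL) {
  gs <- estimate_genome_size(total_kmers, peak)
  out <- tibble(
    k = as.integer(k), peak = as.integer(peak),
    total_kmers = total_kmers, genome_size = gs
  )
  if (!is.null(single_copy_size)) {
    out$single_copy <- single_copy_size
    out$proportion <- single_copy_proportion(single_copy_size, gs)
  }
  out
}
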