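# Indel PCR sex markers: screening sex-linked indels in the mapped
# region, in-silico PCR product prediction, band-pattern sex calls,
# and assay accuracy.

#' Screen the SD region for candidate marker indels
#'
#' Returns the indel sites that lie inside the called region, are
#' longer than `min_len` (strictly), and whose winning-model
#' concordance exceeds `score_threshold`, sorted by concordance then
#' indel length, both descending. An empty result is allowed.
#'
#' @param x A `genotype_dataset`.
#' @param phen Phenotype tibble (`sample_id`, `sex`).
#' @param region One-row region tibble (`chrom`, `start`, `end`), e.g.
#'   from [call_sd_region].
#' @param system `"XY"` or `"ZW"`.
#' @param min_len Minimum indel length in bp, exclusive (default 10).
#' @param score_threshold Concordance cutoff, exclusive (default 0.9).
#' @return Tibble of candidate indels with their concordance scores.
#' @export
screen_indels <- function(x, phen = x$sexes, region, system = "XY",
                          min_len = 10, score_threshold = 0.9) {
  stopifnot(inherits(x, "genotype_dataset"))
  region <- as_tibble(region)
  scores <- concordance_scan(x, phen)
  scores$score <- if (system == "XY") scores$xy_score else scores$zw_score
  cand <- filter(
    scores,
    .data$is_indel,
    .data$chrom == region$chrom[1],
    .data$pos >= region$start[1], .data$pos <= region$end[1],
    .data$indel_len > min_len,
    .data$score > score_threshold
  )
  cand <- arrange(cand, desc(.data$score), desc(.data$indel_len))
  select(cand, "chrom", "pos", "id", "indel_len", "score", "n_used")
}

#' In-silico PCR
#'
#' Predicts PCR products on a template: a product spans an exact match
#' of the forward primer and an exact match of the reverse complement
#' of the reverse primer downstream on the same strand, with length
#' measured inclusively from the 5' end of the forward match to the 5'
#' end of the reverse primer (i.e. primers are part of the amplicon,
#' as gel sizes are reported). Both template strands are searched and
#' all occurrences are combined; no amplification returns an empty
#' result. Matching is exact (0 mismatches) by design — the operation
#' stays deterministic.
#'
#' @param template Nucleotide string.
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param max_product Longest product to report (default 5000 bp).
#' @return Tibble with one row per product: `strand`, `start`, `end`
#'   (1-based inclusive, forward-strand coordinates of the searched
#'   strand), `length`; sorted by ascending length.
#' @examples
#' tpl <- paste0("GG", "ACGTACGT", "TTTT", revcomp("CCCGGG"), "AA")
#' in_silico_pcr(tpl, "ACGTACGT", "CCCGGG")
#' @export
in_silico_pcr <- function(template, forward, reverse, max_product = 5000) {
  stopifnot(is.character(template), length(template) == 1, nzchar(template))
  template <- toupper(template)
  forward <- toupper(forward)
  reverse <- toupper(reverse)
  scan_strand <- function(seq, strand) {
    f_starts <- locate_all(seq, forward)
    r_starts <- locate_all(seq, revcomp(reverse))
    if (length(f_starts) == 0 || length(r_starts) == 0) return(NULL)
    hits <- tidyr::expand_grid(f = f_starts, r = r_starts)
    hits$end <- hits$r + nchar(reverse) - 1L
    hits$length <- hits$end - hits$f + 1L
    hits <- filter(hits, .data$r >= .data$f,
                   .data$length <= max_product)
    if (nrow(hits) == 0) return(NULL)
    tibble(strand = strand, start = hits$f, end = hits$end,
           length = hits$length)
  }
  out <- bind_rows(
    scan_strand(template, "+"),
    scan_strand(revcomp(template), "-")
  )
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(strand = character(), start = integer(),
                  end = integer(), length = integer()))
  }
  arrange(out, .data$length, .data$start)
}

locate_all <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  as.integer(m[m > 0])
}

#' Predict allele-specific product sizes for an indel marker
#'
#' Given the X(W)-allele product size and a signed indel length
#' carried on the Y(Z)-linked allele, the heterogametic-allele product
#' is `x_product + indel_len`.
#'
#' @param x_product X-allele product size in bp (> 0).
#' @param indel_len Signed insertion (+) / deletion (-) length on the
#'   Y-linked allele.
#' @param on_y Whether the indel sits on the Y(Z)-linked allele
#'   (default TRUE; FALSE swaps the roles).
#' @return One-row tibble with `x_product`, `y_product`.
#' @examples
#' predict_allele_sizes(346, 18)
#' @export
predict_allele_sizes <- function(x_product, indel_len, on_y = TRUE) {
  if (x_product <= 0) abort("x_product must be > 0.")
  other <- x_product + indel_len
  if (other <= 0) abort("indel length implies a non-positive product.")
  if (on_y) {
    tibble(x_product = x_product, y_product = other)
  } else {
    tibble(x_product = other, y_product = x_product)
  }
}

#' Define a marker assay
#'
#' A PCR sex-genotyping assay: a named primer pair with its two
#' allele-specific product sizes under a heterogamety system.
#'
#' @param name Assay name.
#' @param x_product,y_product Product sizes (bp) of the X(W)- and
#'   Y(Z)-linked alleles; they must differ by the indel length.
#' @param system `"XY"` or `"ZW"`.
#' @param forward,reverse Optional primer sequences.
#' @return One-row tibble of class `marker_assay`.
#' @export
marker_assay <- function(name, x_product, y_product,
                         system = c("XY", "ZW"),
                         forward = NA_character_, reverse = NA_character_) {
  system <- match.arg(system)
  if (x_product <= 0 || y_product <= 0) abort("products must be > 0.")
  out <- tibble(
    name = name, forward = forward, reverse = reverse,
    x_product = as.integer(x_product), y_product = as.integer(y_product),
    indel_len = abs(as.integer(y_product) - as.integer(x_product)),
    system = system
  )
  class(out) <- c("marker_assay", class(tibble()))
  out
}

#' Call sex from a band pattern
#'
#' Under XX/XY, the heterogametic male shows both allele products and
#' the female only the X product; ZZ/ZW is mirrored. Any other
#' pattern (no bands, only the heterogametic band, or unexpected
#' sizes) is a `no_call`.
#'
#' @param bands Numeric vector of observed product sizes.
#' @param assay A [marker_assay].
#' @return `"M"`, `"F"` or `"no_call"`.
#' @examples
#' a <- marker_assay("MFS-1", 346, 364)
#' genotype_to_sex(c(346, 364), a)
#' @export
genotype_to_sex <- function(bands, assay) {
  stopifnot(inherits(assay, "marker_assay"))
  bands <- unique(as.integer(bands))
  if (length(bands) > 0 &&
      !all(bands %in% c(assay$x_product, assay$y_product))) {
    return("no_call")
  }
  has_x <- assay$x_product %in% bands
  has_y <- assay$y_product %in% bands
  het <- if (assay$system == "XY") "M" else "F"
  hom <- if (assay$system == "XY") "F" else "M"
  if (has_x && has_y) return(het)
  if (has_x && !has_y) return(hom)
  "no_call"
}

#' Band patterns implied by VCF indel genotypes
#'
#' Converts the alt-allele dose at a Y(Z)-insertion indel site into the
#' band pattern each sample would show on a gel, then to a sex call.
#' Hom-ref carries only the X(W) product, het both, hom-alt only the
#' heterogametic product (itself a `no_call`, as on a gel it would be
#' read as an anomalous single-band male pattern only with linked
#' information), missing amplifies nothing.
#'
#' @param gt Integer genotype vector (0/1/2/NA), one per sample.
#' @param assay A [marker_assay].
#' @param samples Optional sample ids.
#' @return Tibble with `sample_id`, `bands` (list column), `predicted`.
#' @export
call_samples <- function(gt, assay, samples = names(gt)) {
  stopifnot(inherits(assay, "marker_assay"))
  if (is.null(samples)) samples <- paste0("s", seq_along(gt))
  bands <- lapply(gt, function(g) {
    if (is.na(g)) return(integer(0))
    switch(as.character(g),
      "0" = assay$x_product,
      "1" = c(assay$x_product, assay$y_product),
      "2" = assay$y_product,
      integer(0)
    )
  })
  tibble(
    sample_id = unname(samples),
    bands = unname(bands),
    predicted = unname(vapply(bands, genotype_to_sex, character(1),
                              assay = assay))
  )
}

#' Score assay accuracy against known sexes
#'
#' Accuracy is computed over scorable calls only
#' (`correct / (correct + incorrect)`); `no_call` samples are reported
#' separately and excluded from the denominator. The full confusion
#' matrix preserves the information either way.
#'
#' @param calls Tibble with `sample_id`, `predicted`
#'   (`M`/`F`/`no_call`), e.g. from [call_samples].
#' @param phen Phenotype tibble (`sample_id`, `sex`).
#' @return List with `accuracy`, `n_correct`, `n_scorable`,
#'   `n_no_call` and `confusion` (tibble `truth` x `predicted` with
#'   counts).
#' @examples
#' calls <- tibble::tibble(sample_id = c("a", "b"), predicted = c("M", "F"))
#' phen <- tibble::tibble(sample_id = c("a", "b"), sex = c("M", "F"))
#' assay_accuracy(calls, phen)$accuracy
#' @export
assay_accuracy <- function(calls, phen) {
  calls <- as_tibble(calls)
  phen <- as_tibble(phen)
  joined <- left_join(calls, phen, by = "sample_id")
  if (anyNA(joined$sex)) {
    abort("every called sample needs a true sex label.")
  }
  scorable <- joined$predicted %in% c("M", "F")
  if (!any(scorable)) abort("zero scorable calls.")
  correct <- joined$predicted[scorable] == joined$sex[scorable]
  confusion <- count(joined, truth = .data$sex, predicted = .data$predicted)
  list(
    accuracy = mean(correct),
    n_correct = sum(correct),
    n_scorable = sum(scorable),
    n_no_call = sum(!scorable),
    confusion = confusion
  )
}

#' Design in-silico assays for candidate indels
#'
#' For each primer pair, amplifies the reference (X-allele) sequence,
#' finds the product containing each candidate indel, and re-amplifies
#' after splicing the VCF insertion allele into the template to obtain
#' the Y-allele product size.
#'
#' @param candidates Candidate indel tibble from [screen_indels],
#'   joined with `ref`/`alt` alleles (columns `chrom`, `pos`, `id`,
#'   `ref`, `alt`, `indel_len`).
#' @param sequences Named character vector of reference sequences.
#' @param primers Primer tibble (`name`, `forward`, `reverse`).
#' @param system `"XY"` or `"ZW"`.
#' @param max_product Longest product considered (default 5000 bp).
#' @return A `marker_assay` tibble with one row per (primer pair,
#'   candidate) match, including the indel position.
#' @export
design_assays <- function(candidates, sequences, primers, system = "XY",
                          max_product = 5000) {
  rows <- list()
  for (i in seq_len(nrow(primers))) {
    for (j in seq_len(nrow(candidates))) {
      chrom <- candidates$chrom[j]
      if (!chrom %in% names(sequences)) next
      tpl <- sequences[[chrom]]
      prods <- in_silico_pcr(tpl, primers$forward[i], primers$reverse[i],
                             max_product = max_product)
      prods <- filter(prods, .data$strand == "+",
                      .data$start <= candidates$pos[j],
                      .data$end >= candidates$pos[j])
      if (nrow(prods) == 0) next
      x_product <- prods$length[1]
      # splice the insertion allele (alt = anchor base + inserted bases)
      ins <- substr(candidates$alt[j], nchar(candidates$ref[j]) + 1,
                    nchar(candidates$alt[j]))
      y_tpl <- paste0(
        substr(tpl, 1, candidates$pos[j]), ins,
        substr(tpl, candidates$pos[j] + 1, nchar(tpl))
      )
      y_prods <- in_silico_pcr(y_tpl, primers$forward[i], primers$reverse[i],
                               max_product = max_product + nchar(ins))
      y_prods <- filter(y_prods, .data$strand == "+",
                        .data$start <= candidates$pos[j],
                        .data$end >= candidates$pos[j])
      if (nrow(y_prods) == 0) next
      rows[[length(rows) + 1]] <- marker_assay(
        name = sprintf("%s@%s", primers$name[i], candidates$id[j]),
        x_product = x_product, y_product = y_prods$length[1],
        system = system,
        forward = primers$forward[i], reverse = primers$reverse[i]
      ) |> mutate(chrom = chrom, indel_pos = candidates$pos[j],
                  site_id = candidates$id[j])
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      name = character(), forward = character(), reverse = character(),
      x_product = integer(), y_product = integer(), indel_len = integer(),
      system = character(), chrom = character(), indel_pos = integer(),
      site_id = character()
    ))
  }
  out <- bind_rows(rows)
  class(out) <- c("marker_assay", class(tibble()))
  out
}
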