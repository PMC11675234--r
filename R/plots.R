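# Manhattan and concordance plots for scan results.

chrom_offsets <- function(tbl) {
  tbl |>
    group_by(.data$chrom) |>
    summarise(chrom_max = max(.data$pos), .groups = "drop") |>
    mutate(offset = cumsum(dplyr::lag(.data$chrom_max, default = 0)))
}

#' Manhattan plot of an association scan
#'
#' @param assoc An [assoc_scan] result.
#' @param threshold P-value line to draw (defaults to the scan's
#'   Bonferroni level).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(assoc, threshold = attr(assoc, "bonferroni")) {
  offs <- chrom_offsets(assoc)
  dat <- left_join(as_tibble(assoc), offs, by = "chrom") |>
    mutate(
      x = .data$pos + .data$offset,
      parity = factor(match(.data$chrom, unique(.data$chrom)) %% 2)
    )
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$minus_log10_p,
                                         colour = .data$parity)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey40", "steelblue")) +
    ggplot2::labs(x = "genomic position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @export
autoplot.sdscan_assoc <- function(object, ...) {
  plot_manhattan(object, ...)
}

#' Concordance scatter plot
#'
#' Winning-model concordance score along a chromosome, with the
#' high-score threshold and (optionally) the called region shaded.
#'
#' @param scores A [concordance_scan] table (or [tidy] of an
#'   `sd_scan`).
#' @param system `"XY"` or `"ZW"` — which score to draw.
#' @param threshold Horizontal cutoff line (default 0.9).
#' @param region Optional one-row region tibble to shade.
#' @param chrom Optional chromosome to restrict to.
#' @return A ggplot object.
#' @export
plot_concordance <- function(scores, system = "XY", threshold = 0.9,
                             region = NULL, chrom = NULL) {
  dat <- as_tibble(scores)
  if (!is.null(chrom)) dat <- filter(dat, .data$chrom == !!chrom)
  dat$score <- if (system == "XY") dat$xy_score else dat$zw_score
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$pos, .data$score)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = sprintf("%s concordance", system)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(region)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(region),
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "purple",
      inherit.aes = FALSE
    )
  }
  p
}

#' @export
autoplot.sd_scan <- function(object, ...) {
  r <- object$region
  plot_concordance(
    object$scores,
    system = if (object$system == "undetermined") "XY" else object$system,
    threshold = object$config$threshold,
    region = r,
    chrom = if (!is.null(r)) r$chrom,
    ...
  )
}
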