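# End-to-end orchestration: filter -> association -> concordance scan ->
# region call -> marker development, with per-stage logging, a summary
# JSON and a manifest of content hashes.

stage_abort <- function(stage, msg) {
  abort(sprintf("[%s stage] %s", stage, msg))
}

log_msg <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the full sex-determination-mapping pipeline
#'
#' Executes the stages in order: hard filter, allelic association
#' scan, XY/ZW concordance scan, system inference and region calling,
#' and indel marker development, writing every stage artifact plus a
#' summary JSON and a manifest of output hashes to `out_dir`. Any
#' stage error aborts with a stage-named message; artifacts already
#' written are retained. A rerun with identical inputs and parameters
#' is byte-identical (no timestamps are recorded).
#'
#' @param vcf Path to the input VCF.
#' @param phenotypes Path to the phenotype TSV (`sample_id`, `sex`).
#' @param out_dir Output directory (created if needed).
#' @param reference Optional reference FASTA; enables in-silico assay
#'   design when `primers` is also given.
#' @param primers Optional primer TSV (`name`, `forward`, `reverse`).
#' @param thresholds A [filter_thresholds].
#' @param config A [scan_config].
#' @param alpha Genome-wide significance level for the association
#'   Bonferroni line.
#' @param min_indel_len Minimum marker indel length (bp, exclusive).
#' @param max_product In-silico PCR product cap (bp).
#' @param verbose Log per-stage record counts to the console.
#' @return Invisibly, the summary as a list (class `run_summary`).
#' @export
run_pipeline <- function(vcf, phenotypes, out_dir,
                         reference = NULL, primers = NULL,
                         thresholds = filter_thresholds(),
                         config = scan_config(),
                         alpha = 0.05,
                         min_indel_len = 10,
                         max_product = 5000,
                         verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fail = file.path(out_dir, "filter_fail.tsv"),
    assoc = file.path(out_dir, "assoc.tsv"),
    scan = file.path(out_dir, "scan.tsv"),
    region_bed = file.path(out_dir, "region.bed"),
    markers = file.path(out_dir, "markers.tsv"),
    calls = file.path(out_dir, "marker_calls.tsv"),
    summary = file.path(out_dir, "summary.json"),
    manifest = file.path(out_dir, "manifest.json")
  )

  # -- load -------------------------------------------------------------
  x <- read_vcf(vcf)
  phen <- read_phenotypes(phenotypes)
  log_msg(verbose, "[load] %d sites, %d samples", nrow(x$sites),
          length(x$samples))

  # -- filter -----------------------------------------------------------
  flt <- filter_dataset(x, thresholds)
  readr::write_tsv(
    select(flt$fail, "chrom", "pos", "id", "filter_reasons"), paths$fail
  )
  log_msg(verbose, "[filter] %d pass / %d fail", nrow(flt$pass$sites),
          nrow(flt$fail))
  if (nrow(flt$pass$sites) == 0) {
    stage_abort("scan", "zero variants passed the hard filter.")
  }
  pass <- flt$pass

  # -- association ------------------------------------------------------
  assoc <- tryCatch(assoc_scan(pass, phen, alpha = alpha),
                    error = function(e) stage_abort("assoc", conditionMessage(e)))
  readr::write_tsv(as_tibble(assoc), paths$assoc)
  log_msg(verbose, "[assoc] %d tests, Bonferroni %.3g", nrow(assoc),
          attr(assoc, "bonferroni"))

  # -- concordance scan + region ---------------------------------------
  fit <- tryCatch(sd_scan(pass, phen, config),
                  error = function(e) stage_abort("scan", conditionMessage(e)))
  readr::write_tsv(as_tibble(fit$scores), paths$scan)
  log_msg(verbose, "[scan] %d sites scored, system %s", nrow(fit$scores),
          fit$system)
  if (is.null(fit$region)) {
    stage_abort("region", sprintf(
      "system '%s' with insufficient support; no region called.", fit$system
    ))
  }
  write_region_bed(fit$region, paths$region_bed)
  log_msg(verbose, "[region] %s:%d-%d (%d SNPs)", fit$region$chrom,
          fit$region$start, fit$region$end, fit$region$n_support)

  # -- markers ----------------------------------------------------------
  cand <- screen_indels(pass, phen, fit$region, fit$system,
                        min_len = min_indel_len,
                        score_threshold = config$threshold)
  log_msg(verbose, "[markers] %d candidate indel(s)", nrow(cand))
  assays <- NULL
  accuracy <- NULL
  calls <- NULL
  if (nrow(cand) > 0) {
    cand_full <- left_join(
      cand, select(pass$sites, "id", "ref", "alt"), by = "id"
    )
    if (!is.null(reference) && !is.null(primers)) {
      seqs <- read_fasta_sequences(reference)
      prim <- if (is.data.frame(primers)) as_tibble(primers)
              else read_primers(primers)
      assays <- design_assays(cand_full, seqs, prim, system = fit$system,
                              max_product = max_product)
    }
    if (is.null(assays) || nrow(assays) == 0) {
      # no primer/reference route: product sizes from the VCF alleles,
      # normalising the X product to a nominal per-candidate amplicon
      assays <- bind_rows(lapply(seq_len(nrow(cand_full)), function(j) {
        marker_assay(
          name = cand_full$id[j],
          x_product = 200L,
          y_product = 200L + cand_full$indel_len[j],
          system = fit$system
        ) |> mutate(chrom = cand_full$chrom[j],
                    indel_pos = cand_full$pos[j], site_id = cand_full$id[j])
      }))
    }
    readr::write_tsv(as_tibble(assays), paths$markers)

    top <- assays[1, , drop = FALSE]
    gt <- pass$geno[match(top$site_id, pass$sites$id), ]
    calls <- call_samples(gt, top, samples = pass$samples)
    readr::write_tsv(
      select(calls, "sample_id", "predicted"), paths$calls
    )
    accuracy <- assay_accuracy(calls, phen)
    log_msg(verbose, "[markers] top assay %s: accuracy %.4f (%d/%d scorable)",
            top$name, accuracy$accuracy, accuracy$n_correct,
            accuracy$n_scorable)
  }

  summary <- list(
    n_input_sites = nrow(x$sites),
    n_pass = nrow(pass$sites),
    n_fail = nrow(flt$fail),
    n_samples = length(x$samples),
    bonferroni = attr(assoc, "bonferroni"),
    min_assoc_p = min(assoc$p),
    top_assoc = as.list(assoc[which.min(assoc$p), c("chrom", "pos", "p")]),
    system = fit$system,
    region = as.list(fit$region),
    n_outliers = nrow(fit$outliers),
    n_candidate_indels = nrow(cand),
    markers = if (!is.null(assays)) {
      as.list(select(as_tibble(assays), "name", "x_product", "y_product",
                     "indel_len"))
    },
    marker_accuracy = if (!is.null(accuracy)) {
      accuracy[c("accuracy", "n_correct", "n_scorable", "n_no_call")]
    },
    parameters = list(
      thresholds = unclass(thresholds),
      scan = unclass(config),
      alpha = alpha,
      min_indel_len = min_indel_len
    )
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(
    inputs = as.list(tools::md5sum(c(vcf = vcf, phenotypes = phenotypes))),
    outputs = as.list(tools::md5sum(unlist(
      paths[setdiff(names(paths), "manifest")]
    )))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(structure(summary, class = "run_summary", paths = paths))
}
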