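#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline with their defaults: E-value
#' ceiling 0.05, PSM-level FDR 1% (global), loess span 0.5 with a 10-anchor
#' minimum, per-dataset median-ppm recalibration, clustering tolerances
#' 10 ppm and 2 min, max-within / sum-across CV roll-up, quantifiability
#' minimum of 2 complete donor pairs, volcano cutoffs p < 0.05 and
#' |log2FC| > 1, and presence-probability cutoff 0.01.
#'
#' @param ... Named overrides of any default.
#' @return A named list of thresholds.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    evalue_max = 0.05,
    target_fdr = 0.01,
    fdr_scope = "global",
    span = 0.5,
    min_anchors = 10,
    recal_scope = "dataset",
    ppm_tol = 10,
    rt_tol_min = 2,
    within_cv = "max",
    min_pairs = 2,
    p_cut = 0.05,
    lfc_cut = 1,
    presence_alpha = 0.01
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  modifyList(cfg, overrides)
}

#' Run the full post-identification pipeline
#'
#' Executes the stages in order: E-value ceiling, target-decoy FDR
#' filtering, retention-time alignment, median-ppm mass recalibration,
#' mass/RT clustering, identification transfer, CV roll-up and matrix
#' construction, median-polish normalization, moderated paired testing with
#' BH adjustment and volcano classification, presence/absence testing, and
#' region annotation.
#'
#' @param psm PSM tibble in the canonical dialect (all acquisitions). A
#'   `theo_mass_da` column (theoretical mass of each identified record) is
#'   used for recalibration; without it masses pass through uncorrected
#'   with a warning.
#' @param design Sample design ([validate_design()]).
#' @param region_map Region map; packaged default.
#' @param config Thresholds from [pipeline_config()].
#' @return A `proformr_run` list: `records` (filtered, aligned,
#'   recalibrated, clustered), `quant` (normalized `proteoform_quant`),
#'   `fit` (`moderated_fit` with classes and regions), `presence`,
#'   `summary` (stage counts, EB hyperparameters and all thresholds),
#'   `config`.
#' @export
run_islet_pipeline <- function(psm, design, region_map = default_region_map(),
                               config = pipeline_config()) {
  psm <- validate_psm(psm)
  design <- validate_design(design)
  n_in <- nrow(psm)
  rec <- evalue_ceiling(psm, max_e = config$evalue_max)
  n_ceiling <- nrow(rec)
  rec <- fdr_filter(rec, target_fdr = config$target_fdr,
                    scope = config$fdr_scope)
  n_fdr <- nrow(rec)
  rec <- align_retention_times(rec, span = config$span,
                               min_anchors = config$min_anchors)
  alignment <- attr(rec, "alignment")
  if (!"theo_mass_da" %in% names(rec)) {
    warn("no theo_mass_da column; masses left uncalibrated")
    rec$theo_mass_da <- NA_real_
  }
  rec <- suppressWarnings(
    recalibrate_masses(rec, scope = config$recal_scope))
  recal <- attr(rec, "recalibration")
  rec <- cluster_observations(rec, ppm_tol = config$ppm_tol,
                              rt_tol_min = config$rt_tol_min)
  quant <- build_quant_matrix(rec, design, within_cv = config$within_cv)
  quant <- normalize_quant(quant)
  fit <- differential_abundance(quant, region_map = region_map,
                                min_pairs = config$min_pairs,
                                p_cut = config$p_cut,
                                lfc_cut = config$lfc_cut,
                                normalize = FALSE)
  presence <- presence_test(quant, alpha = config$presence_alpha)
  res <- fit$results
  summary <- c(
    list(
      n_records = n_in,
      n_post_ceiling = n_ceiling,
      n_post_fdr = n_fdr,
      reference_dataset = alignment$reference,
      n_clusters = n_distinct(rec$cluster_id),
      n_proteoforms = nrow(quant$abundance),
      n_quantifiable = nrow(res),
      n_excluded_quant = attr(fit, "n_excluded"),
      n_increased = sum(res$class == "increased"),
      n_decreased = sum(res$class == "decreased"),
      eb_d0 = fit$eb$d0,
      eb_s0_sq = fit$eb$s0_sq,
      n_presence_significant = sum(presence$significant, na.rm = TRUE)
    ),
    config
  )
  structure(list(records = rec, quant = quant, fit = fit,
                 presence = presence, alignment = alignment,
                 recalibration = recal, summary = summary, config = config),
            class = "proformr_run")
}

#' @export
print.proformr_run <- function(x, ...) {
  s <- x$summary
  cat("<proformr_run>\n")
  cat(sprintf("  records: %d -> %d (E-value ceiling) -> %d (FDR)\n",
              s$n_records, s$n_post_ceiling, s$n_post_fdr))
  cat(sprintf("  clusters: %d; identified proteoforms: %d; quantifiable: %d\n",
              s$n_clusters, s$n_proteoforms, s$n_quantifiable))
  cat(sprintf("  increased: %d, decreased: %d; presence-significant: %d\n",
              s$n_increased, s$n_decreased, s$n_presence_significant))
  invisible(x)
}

#' @describeIn run_islet_pipeline One-row run summary as a tibble.
#' @method glance proformr_run
#' @param x A `proformr_run`.
#' @param ... Unused.
#' @export
glance.proformr_run <- function(x, ...) {
  as_tibble(x$summary[c("n_records", "n_post_ceiling", "n_post_fdr",
                        "n_clusters", "n_proteoforms", "n_quantifiable",
                        "n_increased", "n_decreased", "eb_d0", "eb_s0_sq",
                        "n_presence_significant")])
}

#' Write a pipeline run to disk
#'
#' Emits the differential results and presence tests as TSV, the
#' quantification matrix (wide and long) and spectral counts as CSV,
#' alignment/recalibration diagnostics as TSV, and the run summary
#' (counts and every threshold used) as JSON.
#'
#' @param run A `proformr_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$fit$results, file.path(dir, "differential.tsv"))
  readr::write_tsv(run$presence, file.path(dir, "presence.tsv"))
  ab <- as_tibble(run$quant$abundance, rownames = "label")
  readr::write_csv(ab, file.path(dir, "quant_wide.csv"))
  readr::write_csv(as_tibble(run$quant$counts, rownames = "label"),
                   file.path(dir, "spectral_counts.csv"))
  readr::write_tsv(tidy(run$quant), file.path(dir, "quant_long.tsv"))
  diag <- tidy(run$alignment) |>
    left_join(run$recalibration, by = "dataset_id")
  readr::write_tsv(diag, file.path(dir, "alignment_recal.tsv"))
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
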