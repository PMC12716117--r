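#' Cluster observations by recalibrated mass and aligned retention time
#'
#' Complete-linkage agglomerative clustering under the scaled distance
#' `d = max(|dmass| / (mass * ppm_tol * 1e-6), |dRT| / rt_tol_min)` (pair
#' mass taken as the mean of the two masses), with the tree cut at `d = 1`,
#' so a cluster's diameter is bounded by the tolerances. Observations are
#' first partitioned into mass blocks separated by gaps that no pair can
#' bridge, which makes the procedure exact but scalable.
#'
#' @param records PSM tibble; uses `mass_recal`/`rt_aligned` when present,
#'   falling back to `mass_da`/`rt_min`.
#' @param ppm_tol Mass tolerance in ppm (default 10).
#' @param rt_tol_min RT tolerance in minutes (default 2).
#' @return Records with an integer `cluster_id` column; every observation
#'   belongs to exactly one cluster. Deterministic and invariant to input
#'   order (records are canonically sorted before linkage).
#' @export
cluster_observations <- function(records, ppm_tol = 10, rt_tol_min = 2) {
  stopifnot(ppm_tol > 0, rt_tol_min > 0)
  if (nrow(records) == 0) {
    records$cluster_id <- integer(0)
    return(records)
  }
  m <- if ("mass_recal" %in% names(records)) records$mass_recal else records$mass_da
  r <- if ("rt_aligned" %in% names(records)) records$rt_aligned else records$rt_min
  ord <- order(m, r, records$dataset_id, records$scan)
  m <- m[ord]; r <- r[ord]
  # block split: a sorted-neighbor mass gap beyond tolerance (relative to the
  # larger mass) cannot be bridged by any pair under complete linkage
  gap <- c(FALSE, diff(m) > m[-1] * ppm_tol * 1e-6)
  block <- cumsum(gap)
  cl <- integer(length(m))
  next_id <- 0L
  for (b in unique(block)) {
    idx <- which(block == b)
    if (length(idx) == 1) {
      cl[idx] <- next_id + 1L
      next_id <- next_id + 1L
      next
    }
    mm <- m[idx]; rr <- r[idx]
    dm <- abs(outer(mm, mm, "-")) / (outer(mm, mm, "+") / 2 * ppm_tol * 1e-6)
    dr <- abs(outer(rr, rr, "-")) / rt_tol_min
    d <- pmax(dm, dr)
    hc <- hclust(as.dist(d), method = "complete")
    grp <- cutree(hc, h = 1)
    cl[idx] <- next_id + grp
    next_id <- next_id + max(grp)
  }
  records$cluster_id <- integer(nrow(records))
  records$cluster_id[ord] <- cl
  records
}

#' Assign a consensus identity to each cluster
#'
#' Implements identification transfer across runs (the match-between-runs
#' idea): within a cluster, the most frequent identified proteoform key
#' becomes the consensus; ties are broken by the best (lowest) E-value among
#' the tied keys, then lexicographically (flagged). All members inherit the
#' consensus. Clusters with no identified member stay unidentified and are
#' excluded from downstream gene-level statistics.
#'
#' @param records PSM tibble with `cluster_id` (from [cluster_observations()]).
#' @return A tibble with one row per cluster: consensus identity columns
#'   (`gene`, `accession`, `first_aa`, `last_aa`, `mod_signature`,
#'   `modified`, `label`), representative mass/RT (medians), member counts,
#'   and a `tie_flag`.
#' @export
assign_consensus <- function(records) {
  if (!"cluster_id" %in% names(records)) {
    abort("assign_consensus requires cluster_observations() output")
  }
  m <- if ("mass_recal" %in% names(records)) records$mass_recal else records$mass_da
  r <- if ("rt_aligned" %in% names(records)) records$rt_aligned else records$rt_min
  records$.mass <- m
  records$.rt <- r
  records$.key <- proteoform_key(records)
  base <- records |>
    group_by(.data$cluster_id) |>
    summarise(
      n_members = n(),
      n_identified = sum(!is.na(.data$.key)),
      rep_mass = median(.data$.mass),
      rep_rt = median(.data$.rt),
      .groups = "drop"
    )
  cons <- records |>
    filter(!is.na(.data$.key)) |>
    group_by(.data$cluster_id, .data$.key) |>
    summarise(
      n_votes = n(),
      best_evalue = suppressWarnings(min(.data$evalue, na.rm = TRUE)),
      gene = first(.data$gene), accession = first(.data$accession),
      first_aa = first(.data$first_aa), last_aa = first(.data$last_aa),
      mod_signature = first(canonical_mod_signature(.data$mod_shifts)),
      .groups = "drop"
    )
  if (nrow(cons) > 0) {
    cons <- cons |>
      group_by(.data$cluster_id) |>
      mutate(tie_flag = sum(.data$n_votes == max(.data$n_votes) &
                              .data$best_evalue == min(.data$best_evalue[
                                .data$n_votes == max(.data$n_votes)])) > 1) |>
      arrange(desc(.data$n_votes), .data$best_evalue, .data$.key,
              .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup()
  } else {
    cons$tie_flag <- logical(0)
  }
  cons <- select(cons, -".key", -"n_votes", -"best_evalue")
  out <- left_join(base, cons, by = "cluster_id")
  out$modified <- !is.na(out$mod_signature) & nzchar(out$mod_signature)
  out$label <- NA_character_
  has_id <- !is.na(out$first_aa)
  if (any(has_id)) {
    out$label[has_id] <- format_proteoform_name(
      out$gene[has_id], out$first_aa[has_id], out$last_aa[has_id],
      modified = out$modified[has_id], accession = out$accession[has_id]
    )
  }
  out
}

#' Roll up member intensities across compensation-voltage channels
#'
#' Within one (sample, CV channel) cell, multiple member features contribute
#' their maximum (avoiding double-counting of the same elution profile);
#' across CV channels contributions are summed, since the channels partition
#' the ion population. The spectral count is the number of scored member
#' PSMs in the sample.
#'
#' @param records Clustered PSM tibble (with `cluster_id`). `dataset_id` is
#'   taken as the sample identifier (one acquisition per sample).
#' @param within_cv `"max"` (default) or `"sum"` aggregation within a
#'   (sample, CV) cell.
#' @return Long tibble: `cluster_id`, `sample_id`, `abundance` (linear
#'   intensity), `spectral_count`.
#' @export
rollup_cv <- function(records, within_cv = c("max", "sum")) {
  within_cv <- match.arg(within_cv)
  agg <- if (within_cv == "max") max else sum
  records |>
    filter(!is.na(.data$intensity) & .data$intensity > 0 | !is.na(.data$evalue)) |>
    group_by(.data$cluster_id, sample_id = .data$dataset_id, .data$cv_volts) |>
    summarise(
      cv_intensity = if (all(is.na(.data$intensity))) NA_real_
                     else agg(.data$intensity, na.rm = TRUE),
      n_psm = sum(!is.na(.data$evalue)),
      .groups = "drop"
    ) |>
    group_by(.data$cluster_id, .data$sample_id) |>
    summarise(
      abundance = if (all(is.na(.data$cv_intensity))) NA_real_
                  else sum(.data$cv_intensity, na.rm = TRUE),
      spectral_count = sum(.data$n_psm),
      .groups = "drop"
    )
}

#' Build the proteoform x sample quantification object
#'
#' Rolls up clustered observations ([rollup_cv()]), keeps identified
#' clusters as named rows (unidentified clusters are retained separately for
#' diagnostics), log2-transforms abundances, and attaches the sample design.
#' Clusters that resolve to the same consensus proteoform are merged by
#' re-roll-up and flagged.
#'
#' @param records Clustered PSM tibble.
#' @param design Sample design ([validate_design()]); `sample_id` values must
#'   match `dataset_id`s.
#' @param within_cv Passed to [rollup_cv()].
#' @return A `proteoform_quant` object: list with `abundance` (log2 matrix,
#'   proteoforms x samples, `NA` = missing), `counts` (spectral counts),
#'   `features` (per-row metadata), `design`, `unassigned` (roll-up of
#'   unidentified clusters).
#' @export
build_quant_matrix <- function(records, design, within_cv = c("max", "sum")) {
  within_cv <- match.arg(within_cv)
  design <- validate_design(design)
  clusters <- assign_consensus(records)
  # merge clusters sharing a consensus proteoform before roll-up
  keyed <- clusters |>
    filter(!is.na(.data$label)) |>
    group_by(.data$gene, .data$accession, .data$first_aa, .data$last_aa,
             .data$mod_signature) |>
    mutate(merged_id = min(.data$cluster_id),
           merge_flag = n() > 1) |>
    ungroup()
  if (any(keyed$merge_flag)) {
    inform(sprintf("build_quant_matrix: merged %d cluster(s) sharing a consensus key",
                   sum(keyed$merge_flag) - n_distinct(keyed$merged_id[keyed$merge_flag])))
  }
  remap <- setNames(keyed$merged_id, keyed$cluster_id)
  rec <- records
  hit <- as.character(rec$cluster_id) %in% names(remap)
  rec$cluster_id[hit] <- remap[as.character(rec$cluster_id[hit])]
  long <- rollup_cv(rec, within_cv = within_cv)
  features <- keyed |>
    filter(.data$cluster_id == .data$merged_id) |>
    arrange(.data$label) |>
    select("label", "gene", "accession", "first_aa", "last_aa",
           "mod_signature", "modified", "rep_mass", "rep_rt",
           cluster_id = "merged_id", "n_members", "n_identified",
           "tie_flag", "merge_flag")
  # distinct mod signatures can share a display label; row names must be unique
  features$label <- make.unique(features$label)
  samples <- design$sample_id
  ab <- matrix(NA_real_, nrow(features), length(samples),
               dimnames = list(features$label, samples))
  cnt <- matrix(0L, nrow(features), length(samples),
                dimnames = list(features$label, samples))
  idx <- long |>
    inner_join(select(features, "label", "cluster_id"), by = "cluster_id") |>
    filter(.data$sample_id %in% samples)
  ab[cbind(idx$label, idx$sample_id)] <- log2(idx$abundance)
  cnt[cbind(idx$label, idx$sample_id)] <- idx$spectral_count
  unassigned_ids <- setdiff(unique(records$cluster_id), keyed$cluster_id)
  unassigned <- filter(long, .data$cluster_id %in% unassigned_ids)
  structure(list(abundance = ab, counts = cnt, features = features,
                 design = design, unassigned = unassigned),
            class = "proteoform_quant")
}

#' @export
print.proteoform_quant <- function(x, ...) {
  cat(sprintf("<proteoform_quant> %d proteoforms x %d samples (%d unassigned clusters)\n",
              nrow(x$abundance), ncol(x$abundance),
              dplyr::n_distinct(x$unassigned$cluster_id)))
  cat(sprintf("  observed cells: %.1f%%\n",
              100 * mean(!is.na(x$abundance))))
  invisible(x)
}

#' @describeIn build_quant_matrix Long tidy view of a `proteoform_quant`:
#' @method tidy proteoform_quant
#'   one row per (proteoform, sample) with `log2_abundance`,
#'   `spectral_count`, design columns and feature metadata.
#' @param x A `proteoform_quant` object.
#' @param ... Unused.
#' @export
tidy.proteoform_quant <- function(x, ...) {
  long <- as_tibble(x$abundance, rownames = "label") |>
    tidyr::pivot_longer(-"label", names_to = "sample_id",
                        values_to = "log2_abundance")
  cnts <- as_tibble(x$counts, rownames = "label") |>
    tidyr::pivot_longer(-"label", names_to = "sample_id",
                        values_to = "spectral_count")
  long |>
    left_join(cnts, by = c("label", "sample_id")) |>
    left_join(x$design, by = "sample_id") |>
    left_join(select(x$features, "label", "gene", "first_aa", "last_aa",
                     "modified"), by = "label")
}

#' Rank a gene's proteoforms by median spectral count
#'
#' Semi-quantitative abundance ranking by spectral counting: proteoforms of
#' one gene ordered by their median spectral count across all samples
#' (absent observations count 0), descending, ties broken by label.
#'
#' @param quant A `proteoform_quant` object.
#' @param gene Gene symbol.
#' @param n Number of top proteoforms to return (default 30).
#' @return Tibble with `label` and `median_count`, at most `n` rows; empty
#'   when the gene is absent.
#' @export
top_n_by_spectral_count <- function(quant, gene, n = 30) {
  stopifnot(n >= 1)
  rows <- which(quant$features$gene == gene)
  if (length(rows) == 0) return(tibble(label = character(0), median_count = numeric(0)))
  med <- apply(quant$counts[rows, , drop = FALSE], 1, median)
  out <- tibble(label = quant$features$label[rows], median_count = unname(med)) |>
    arrange(desc(.data$median_count), .data$label)
  head(out, n)
}
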