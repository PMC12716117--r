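#' Read a proteoform-spectrum-match table
#'
#' Reads a TSV of PSMs into the canonical dialect (see [psm_columns]). Files
#' in other dialects (e.g. a TopPIC-style export) are handled through
#' `column_map`, a named character vector mapping canonical names to the
#' file's header names. Rows whose mandatory fields (`rt_min`, `mass_da`,
#' `scan`) fail to parse are dropped with a message giving the count.
#'
#' @param path TSV file path.
#' @param column_map Named character vector, canonical -> file column name;
#'   `NULL` for files already in the canonical dialect. Unmapped optional
#'   columns are filled with `NA`.
#' @param dataset_id Override the dataset identifier for all rows; by default
#'   taken from the file's `dataset_id` column.
#' @return A validated PSM tibble.
#' @export
read_psm_table <- function(path, column_map = NULL, dataset_id = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#")
  if (!is.null(column_map)) {
    missing <- setdiff(unname(column_map), names(raw))
    if (length(missing) > 0) {
      abort(paste0("mapped column(s) absent from file: ",
                   paste(missing, collapse = ", ")))
    }
    raw <- raw[, unname(column_map), drop = FALSE]
    names(raw) <- names(column_map)
  }
  mandatory <- c("dataset_id", "scan", "rt_min", "mass_da")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory PSM column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble(
    dataset_id = raw$dataset_id,
    scan = suppressWarnings(as.integer(raw$scan)),
    rt_min = suppressWarnings(as.numeric(raw$rt_min)),
    mass_da = suppressWarnings(as.numeric(raw$mass_da)),
    accession = raw$accession %||% NA_character_,
    gene = raw$gene %||% NA_character_,
    first_aa = suppressWarnings(as.integer(raw$first_aa %||% NA_character_)),
    last_aa = suppressWarnings(as.integer(raw$last_aa %||% NA_character_)),
    mod_shifts = raw$mod_shifts %||% NA_character_,
    evalue = suppressWarnings(as.numeric(raw$evalue %||% NA_character_)),
    is_decoy = tolower(raw$is_decoy %||% "false") %in% c("true", "t", "1"),
    intensity = suppressWarnings(as.numeric(raw$intensity %||% NA_character_)),
    cv_volts = raw$cv_volts %||% NA_character_
  )
  # DECOY_ accession prefix recognized as a fallback decoy flag
  out$is_decoy <- out$is_decoy | grepl("^DECOY_", out$accession %||% "")
  ok <- !is.na(out$scan) & !is.na(out$rt_min) & !is.na(out$mass_da)
  if (any(!ok)) {
    inform(sprintf("read_psm_table: dropped %d row(s) with unparseable mandatory fields",
                   sum(!ok)))
    out <- out[ok, , drop = FALSE]
  }
  if (!is.null(dataset_id)) out$dataset_id <- dataset_id
  validate_psm(out)
}

#' Write PSM records in the canonical dialect
#'
#' @param records PSM tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(records, path) {
  validate_psm(records)
  readr::write_tsv(records[, names(psm_columns)], path)
  invisible(path)
}

#' Apply the search-engine E-value ceiling
#'
#' Retains identified records with `evalue <= max_e` (boundary inclusive).
#' Records without an E-value (unidentified feature observations) pass
#' through untouched.
#'
#' @param records PSM tibble.
#' @param max_e Maximum allowable E-value; default 0.05.
#' @return Filtered tibble.
#' @export
evalue_ceiling <- function(records, max_e = 0.05) {
  stopifnot(max_e > 0)
  filter(records, is.na(.data$evalue) | .data$evalue <= max_e)
}

#' Target-decoy false discovery rate filter
#'
#' Scored records are ranked by ascending E-value (targets before decoys on
#' ties, the conservative convention). The running FDR at rank i is
#' `(# decoys at or above rank i) / max(1, # targets at or above rank i)`;
#' q-values are the cumulative minimum of the running FDR taken from the
#' worst rank upward. Targets with `q <= target_fdr` are retained; decoys are
#' removed from the output. Unscored records (missing E-value) pass through.
#'
#' @param records PSM tibble carrying `evalue` and `is_decoy`.
#' @param target_fdr FDR level in (0, 1); default 0.01.
#' @param scope `"global"` (default) pools all datasets for one threshold;
#'   `"dataset"` filters each acquisition separately.
#' @return Filtered tibble with attribute `"fdr_threshold"`, the worst
#'   retained E-value per scope (a tibble for `scope = "dataset"`).
#' @export
fdr_filter <- function(records, target_fdr = 0.01,
                       scope = c("global", "dataset")) {
  stopifnot(target_fdr > 0, target_fdr < 1)
  scope <- match.arg(scope)
  scored <- filter(records, !is.na(.data$evalue))
  unscored <- filter(records, is.na(.data$evalue))
  one <- function(x) {
    if (nrow(x) == 0) return(list(keep = x[0, ], thr = NA_real_))
    if (!any(!x$is_decoy)) {
      warn("fdr_filter: no target records; returning empty result")
      return(list(keep = x[0, ], thr = NA_real_))
    }
    ord <- order(x$evalue, x$is_decoy)  # targets first on ties
    x <- x[ord, ]
    running <- cumsum(x$is_decoy) / pmax(1, cumsum(!x$is_decoy))
    q <- rev(cummin(rev(running)))
    keep <- !x$is_decoy & q <= target_fdr
    thr <- if (any(keep)) max(x$evalue[keep]) else NA_real_
    list(keep = x[keep, ], thr = thr)
  }
  if (scope == "global") {
    res <- one(scored)
    out <- bind_rows(res$keep, unscored)
    attr(out, "fdr_threshold") <- res$thr
  } else {
    parts <- split(scored, scored$dataset_id)
    res <- purrr::map(parts, one)
    out <- bind_rows(bind_rows(purrr::map(res, "keep")), unscored)
    attr(out, "fdr_threshold") <- tibble(
      dataset_id = names(res),
      threshold = purrr::map_dbl(res, "thr")
    )
  }
  out
}
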