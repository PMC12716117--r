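#' Choose the retention-time alignment reference
#'
#' The reference acquisition is the one with the most distinct identified
#' proteoform keys; ties go to the lexicographically first dataset id.
#'
#' @param records PSM tibble (post-FDR).
#' @return The reference `dataset_id`.
#' @export
choose_reference <- function(records) {
  ided <- records[is_identified(records), , drop = FALSE]
  if (nrow(ided) == 0) abort("no identified records; cannot choose a reference")
  counts <- ided |>
    mutate(key = proteoform_key(ided)) |>
    group_by(.data$dataset_id) |>
    summarise(n_keys = n_distinct(.data$key), .groups = "drop") |>
    arrange(desc(.data$n_keys), .data$dataset_id)
  counts$dataset_id[[1]]
}

#' Find shared-proteoform retention-time anchors
#'
#' For every proteoform key identified in both a dataset and the reference,
#' pairs the retention times of the best-E-value observation per key on each
#' side.
#'
#' @param records PSM tibble.
#' @param dataset_id,reference Dataset ids to pair.
#' @return Tibble with `key`, `rt_local`, `rt_ref`.
#' @export
find_anchors <- function(records, dataset_id, reference) {
  ided <- records[is_identified(records), , drop = FALSE]
  ided$key <- proteoform_key(ided)
  best <- function(id) {
    ided |>
      filter(.data$dataset_id == id) |>
      group_by(.data$key) |>
      slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
      ungroup()
  }
  loc <- best(dataset_id)
  ref <- best(reference)
  inner_join(
    select(loc, "key", rt_local = "rt_min"),
    select(ref, "key", rt_ref = "rt_min"),
    by = "key"
  )
}

#' Fit a locally weighted retention-time alignment curve
#'
#' Degree-1 loess of reference RT on local RT with robustness reweighting
#' (symmetric family). Predictions beyond the anchor range continue the
#' boundary fit linearly rather than clamping to a constant, since RT drift
#' gradients persist at gradient ends.
#'
#' @param anchors Tibble with `rt_local`, `rt_ref` (from [find_anchors()]).
#' @param span Loess span in (0, 1]; default 0.5.
#' @return An object of class `rt_alignment`; use `predict(fit, rt)` to map
#'   local RT onto the reference scale.
#' @export
fit_alignment <- function(anchors, span = 0.5) {
  stopifnot(span > 0, span <= 1, nrow(anchors) >= 2)
  if (diff(range(anchors$rt_local)) == 0) {
    abort("degenerate anchors: all rt_local identical")
  }
  anchors <- arrange(anchors, .data$rt_local, .data$rt_ref)
  fit <- loess(rt_ref ~ rt_local, data = anchors, span = span, degree = 1,
               family = "symmetric",
               control = loess.control(surface = "direct", iterations = 4))
  lo <- min(anchors$rt_local); hi <- max(anchors$rt_local)
  eps <- max(1e-3, (hi - lo) * 1e-3)
  # boundary values and one-sided slopes for linear extrapolation
  p <- predict(fit, newdata = data.frame(rt_local = c(lo, lo + eps, hi - eps, hi)))
  structure(list(fit = fit, lo = lo, hi = hi,
                 f_lo = p[[1]], slope_lo = (p[[2]] - p[[1]]) / eps,
                 f_hi = p[[4]], slope_hi = (p[[4]] - p[[3]]) / eps,
                 span = span, n_anchors = nrow(anchors)),
            class = "rt_alignment")
}

#' @export
predict.rt_alignment <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$rt_local else newdata
  out <- numeric(length(x))
  inside <- x >= object$lo & x <= object$hi
  if (any(inside)) {
    out[inside] <- predict(object$fit, newdata = data.frame(rt_local = x[inside]))
  }
  below <- x < object$lo
  above <- x > object$hi
  out[below] <- object$f_lo + object$slope_lo * (x[below] - object$lo)
  out[above] <- object$f_hi + object$slope_hi * (x[above] - object$hi)
  out
}

identity_alignment <- function() {
  structure(list(fit = NULL, identity = TRUE), class = "rt_alignment_identity")
}

#' @export
predict.rt_alignment_identity <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata$rt_local else newdata
}

#' Align retention times across acquisitions
#'
#' Chooses (or accepts) a reference dataset, fits one alignment curve per
#' other dataset from shared-proteoform anchors, and adds an `rt_aligned`
#' column mapping every record onto the reference RT scale. The reference
#' itself gets the identity map, as does any dataset with fewer than
#' `min_anchors` shared proteoforms (with a warning).
#'
#' @param records PSM tibble (post-FDR).
#' @param reference Reference `dataset_id`; default chosen by
#'   [choose_reference()].
#' @param span Loess span; default 0.5.
#' @param min_anchors Minimum shared proteoforms to fit a curve; default 10.
#' @return The records with `rt_aligned`, plus attribute `"alignment"` (an
#'   `rt_alignment_set`; see [tidy.rt_alignment_set()]).
#' @export
align_retention_times <- function(records, reference = NULL, span = 0.5,
                                  min_anchors = 10) {
  reference <- reference %||% choose_reference(records)
  ids <- sort(unique(records$dataset_id))
  models <- purrr::map(setNames(ids, ids), function(id) {
    if (id == reference) {
      return(list(model = identity_alignment(), n_anchors = NA_integer_))
    }
    anchors <- find_anchors(records, id, reference)
    if (nrow(anchors) < min_anchors) {
      warn(sprintf("alignment: %s has %d anchors (< %d); using identity",
                   id, nrow(anchors), min_anchors))
      return(list(model = identity_alignment(), n_anchors = nrow(anchors)))
    }
    list(model = fit_alignment(anchors, span = span), n_anchors = nrow(anchors))
  })
  records$rt_aligned <- records$rt_min
  for (id in ids) {
    sel <- records$dataset_id == id
    records$rt_aligned[sel] <- predict(models[[id]]$model, records$rt_min[sel])
  }
  aln <- structure(list(reference = reference, span = span, models = models),
                   class = "rt_alignment_set")
  attr(records, "alignment") <- aln
  records
}

#' Tidy alignment diagnostics
#'
#' @param x An `rt_alignment_set`.
#' @param ... Unused.
#' @return Tibble with per-dataset reference, anchor count and span.
#' @method tidy rt_alignment_set
#' @export
tidy.rt_alignment_set <- function(x, ...) {
  tibble(
    dataset_id = names(x$models),
    reference = x$reference,
    is_reference = names(x$models) == x$reference,
    n_anchors = purrr::map_int(x$models, ~ .x$n_anchors %||% NA_integer_),
    span = x$span
  )
}

#' Recalibrate observed masses by median ppm error
#'
#' For each dataset (or globally), the median ppm mass error
#' `(observed - theoretical) / theoretical * 1e6` is computed over
#' confidently identified records carrying a theoretical mass, and every
#' record's mass in that dataset is corrected as
#' `observed / (1 + median_ppm * 1e-6)`, stored in `mass_recal`. Datasets
#' with no usable identified records get a zero correction with a warning.
#'
#' @param records PSM tibble with a `theo_mass_da` column (`NA` where
#'   unknown); typically joined from theoretical proteoform masses.
#' @param scope `"dataset"` (default) or `"global"`.
#' @return Records with `mass_recal` plus attribute `"recalibration"`, a
#'   tibble of per-scope median ppm errors.
#' @export
recalibrate_masses <- function(records, scope = c("dataset", "global")) {
  scope <- match.arg(scope)
  if (!"theo_mass_da" %in% names(records)) {
    abort("recalibrate_masses requires a 'theo_mass_da' column")
  }
  usable <- is_identified(records) & !is.na(records$theo_mass_da)
  ppm <- (records$mass_da - records$theo_mass_da) / records$theo_mass_da * 1e6
  med_for <- function(sel, label) {
    if (!any(sel & usable)) {
      warn(sprintf("recalibration: no identified records for %s; correction 0", label))
      return(0)
    }
    median(ppm[sel & usable])
  }
  if (scope == "global") {
    med <- med_for(rep(TRUE, nrow(records)), "global")
    model <- tibble(dataset_id = "(global)", median_ppm = med,
                    n_identified = sum(usable))
    records$mass_recal <- records$mass_da / (1 + med * 1e-6)
  } else {
    ids <- sort(unique(records$dataset_id))
    meds <- vapply(ids, function(id) med_for(records$dataset_id == id, id),
                   numeric(1))
    model <- tibble(
      dataset_id = ids, median_ppm = unname(meds),
      n_identified = vapply(ids, function(id)
        sum(usable & records$dataset_id == id), integer(1))
    )
    records$mass_recal <- records$mass_da /
      unname(1 + meds[records$dataset_id] * 1e-6)
  }
  attr(records, "recalibration") <- model
  records
}
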