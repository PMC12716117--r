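#' Volcano plot of differential-abundance results
#'
#' log2 fold change against -log10 p, colored by volcano class, with dotted
#' cutoff guides. Restrict to one gene via `gene` to reproduce per-hormone
#' panels; points can then be colored by processing region instead.
#'
#' @param fit A `moderated_fit` (from [differential_abundance()]).
#' @param gene Optional gene symbol to subset to.
#' @param color_by `"class"` (default) or `"region"` (requires annotated
#'   results).
#' @param p_cut,lfc_cut Guide positions (defaults 0.05 and 1).
#' @return A ggplot object.
#' @export
plot_volcano <- function(fit, gene = NULL, color_by = c("class", "region"),
                         p_cut = 0.05, lfc_cut = 1) {
  color_by <- match.arg(color_by)
  res <- fit$results
  if (!is.null(gene)) res <- res[res$gene %in% gene, , drop = FALSE]
  if (color_by == "region" && !"region" %in% names(res)) {
    abort("results carry no 'region' column; run with a region map")
  }
  ggplot2::ggplot(res, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                    color = .data[[color_by]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = "dotted") +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = "dotted") +
    ggplot2::labs(x = "log2 fold change (treated / control)",
                  y = expression(-log[10] ~ p), color = color_by) +
    ggplot2::theme_minimal()
}

#' Data-completeness histogram
#'
#' Number of proteoforms per bin of the fraction of acquisitions in which
#' they are observed.
#'
#' @param quant A `proteoform_quant`.
#' @return A ggplot object.
#' @export
plot_completeness <- function(quant) {
  cs <- completeness_summary(!is.na(quant$abundance))
  ggplot2::ggplot(cs, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "fraction of acquisitions observed",
                  y = "proteoforms") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Retention-time alignment diagnostic
#'
#' Fitted alignment curve over the anchor scatter for one dataset against
#' the reference.
#'
#' @param records Post-FDR PSM tibble.
#' @param dataset_id,reference Dataset ids (reference defaults to
#'   [choose_reference()]).
#' @param span Loess span.
#' @return A ggplot object.
#' @export
plot_alignment <- function(records, dataset_id, reference = NULL, span = 0.5) {
  reference <- reference %||% choose_reference(records)
  anchors <- find_anchors(records, dataset_id, reference)
  fit <- fit_alignment(anchors, span = span)
  grid <- tibble(rt_local = seq(min(anchors$rt_local), max(anchors$rt_local),
                                length.out = 200))
  grid$rt_ref <- predict(fit, grid$rt_local)
  ggplot2::ggplot(anchors, ggplot2::aes(x = .data$rt_local, y = .data$rt_ref)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid, color = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = paste0("RT in ", dataset_id, " (min)"),
                  y = paste0("RT in reference ", reference, " (min)")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param object A `moderated_fit`.
#' @method autoplot moderated_fit
#' @param ... Passed to [plot_volcano()].
#' @export
autoplot.moderated_fit <- function(object, ...) plot_volcano(object, ...)

#' @rdname plot_completeness
#' @param object A `proteoform_quant`.
#' @method autoplot proteoform_quant
#' @param ... Unused.
#' @export
autoplot.proteoform_quant <- function(object, ...) plot_completeness(object)
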