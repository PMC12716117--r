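#' Two-way median polish of a log2 abundance matrix
#'
#' Iteratively removes row and column medians (via [stats::medpolish()],
#' missing cells skipped), decomposing the matrix into overall + row +
#' column + residual. Normalization removes only the column (sample)
#' effects: `normalized = x - column effect`, so between-proteoform
#' structure is retained in the tested values. All-missing rows or columns
#' are dropped with a warning.
#'
#' @param x Numeric matrix (log2 scale), proteoforms x samples.
#' @param tol Convergence tolerance (default 1e-6).
#' @param max_iter Maximum sweep iterations (default 50).
#' @return List with `overall`, `row`, `col`, `residuals`, and `normalized`
#'   (same shape as the retained `x`).
#' @export
median_polish <- function(x, tol = 1e-6, max_iter = 50) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) abort("median_polish needs >= 2 rows and columns")
  bad_row <- rowSums(!is.na(x)) == 0
  bad_col <- colSums(!is.na(x)) == 0
  if (any(bad_row) || any(bad_col)) {
    warn(sprintf("median_polish: dropping %d all-missing row(s), %d column(s)",
                 sum(bad_row), sum(bad_col)))
    x <- x[!bad_row, !bad_col, drop = FALSE]
  }
  mp <- medpolish(x, eps = tol, maxiter = max_iter, na.rm = TRUE,
                  trace.iter = FALSE)
  normalized <- sweep(x, 2, mp$col, "-")
  list(overall = mp$overall, row = mp$row, col = mp$col,
       residuals = mp$residuals, normalized = normalized)
}

#' Median-polish normalize a quantification object
#'
#' @param quant A `proteoform_quant` object.
#' @inheritParams median_polish
#' @return The object with sample effects removed from `abundance`;
#'   attribute `"median_polish"` carries the decomposition.
#' @export
normalize_quant <- function(quant, tol = 1e-6, max_iter = 50) {
  mp <- median_polish(quant$abundance, tol = tol, max_iter = max_iter)
  quant$abundance <- quant$abundance[rownames(mp$normalized),
                                     colnames(mp$normalized), drop = FALSE]
  quant$abundance[] <- mp$normalized
  quant$counts <- quant$counts[rownames(mp$normalized),
                               colnames(mp$normalized), drop = FALSE]
  quant$features <- quant$features[match(rownames(mp$normalized),
                                         quant$features$label), , drop = FALSE]
  attr(quant, "median_polish") <- mp[c("overall", "row", "col")]
  quant
}

#' Per-donor paired log2 differences
#'
#' For every proteoform, the treated-minus-control log2 difference within
#' each donor with both samples observed. The quantifiability filter keeps
#' proteoforms observed in both conditions for at least `min_pairs` donors;
#' the rest are excluded from testing (and counted).
#'
#' @param quant A `proteoform_quant` (ideally normalized).
#' @param min_pairs Minimum complete donor pairs (default 2).
#' @return List: `diffs` (matrix, quantifiable proteoforms x donors, `NA`
#'   for incomplete pairs), `lfc` (tibble with `label`, `n_pairs`,
#'   `log2fc` = mean of available differences), `n_excluded`.
#' @export
paired_log2fc <- function(quant, min_pairs = 2) {
  design <- quant$design
  donors <- sort(unique(design$donor_id))
  get_col <- function(donor, condition) {
    s <- design$sample_id[design$donor_id == donor & design$condition == condition]
    if (length(s) == 1 && s %in% colnames(quant$abundance)) {
      quant$abundance[, s]
    } else {
      rep(NA_real_, nrow(quant$abundance))
    }
  }
  diffs <- vapply(donors, function(d) get_col(d, "treated") - get_col(d, "control"),
                  numeric(nrow(quant$abundance)))
  if (is.null(dim(diffs))) diffs <- matrix(diffs, nrow = 1)
  dimnames(diffs) <- list(rownames(quant$abundance), donors)
  n_pairs <- rowSums(!is.na(diffs))
  keep <- n_pairs >= min_pairs
  lfc <- tibble(
    label = rownames(diffs)[keep],
    n_pairs = as.integer(unname(n_pairs[keep])),
    log2fc = unname(rowMeans(diffs[keep, , drop = FALSE], na.rm = TRUE))
  )
  list(diffs = diffs[keep, , drop = FALSE], lfc = lfc,
       n_excluded = sum(!keep))
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Moment-matching fit of the scaled chi-square variance prior on log s^2:
# z_g = log s_g^2; E z = log s0^2 + digamma(d_g/2) - log(d_g/2)
#                        - digamma(d0/2) + log(d0/2)  (sign per F model)
# Var z = trigamma(d_g/2) + trigamma(d0/2).
estimate_eb_prior <- function(s2, df, d0_cap = 1e6) {
  ok <- is.finite(log(s2)) & df > 0
  if (sum(ok) < 2) {
    warn("fewer than 2 positive sample variances; moderation disabled (d0 = 0)")
    return(list(d0 = 0, s0_sq = NA_real_))
  }
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (d0 > d0_cap) d0 <- d0_cap
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- d0_cap
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated one-sample t-test on paired differences
#'
#' The paired design is tested as a one-sample problem on per-donor
#' differences. Per proteoform, `s_g^2` is the sample variance of the
#' differences with `d_g = n_pairs - 1` residual df. The prior `(d0, s0^2)`
#' of the scaled chi-square variance model is estimated by moment matching
#' on `log s_g^2` using digamma/trigamma relations; the posterior variance
#' `s2_post = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)` yields the moderated
#' statistic `t = mean / (s_post / sqrt(n))` on `d0 + d_g` df, with
#' two-sided p-values and Benjamini-Hochberg adjustment.
#'
#' @param diffs Matrix of paired log2 differences (proteoforms x donors,
#'   `NA` allowed), e.g. `paired_log2fc(quant)$diffs`.
#' @param d0 Prior df override: `NULL` (default) estimates it; `0` disables
#'   moderation (classical one-sample t); large values shrink fully to
#'   `s0_sq`.
#' @param s0_sq Prior variance override (used when `d0` is supplied; ignored
#'   at `d0 = 0`).
#' @param d0_cap Cap representing an effectively infinite prior df.
#' @return A `moderated_fit`: list with `eb` (`d0`, `s0_sq`) and `results`
#'   tibble (`label`, `n_pairs`, `log2fc`, `s2`, `s2_post`, `t`, `df_total`,
#'   `p`, `p_adj`, `zero_var_flag`). See [tidy.moderated_fit()].
#' @export
moderated_t <- function(diffs, d0 = NULL, s0_sq = NULL, d0_cap = 1e6) {
  diffs <- as.matrix(diffs)
  n <- rowSums(!is.na(diffs))
  if (any(n < 2)) abort("every proteoform needs >= 2 paired differences")
  mean_d <- rowMeans(diffs, na.rm = TRUE)
  s2 <- apply(diffs, 1, var, na.rm = TRUE)
  dg <- n - 1
  if (is.null(d0)) {
    if (nrow(diffs) < 2) abort("need >= 2 proteoforms to estimate the prior")
    prior <- estimate_eb_prior(s2, dg, d0_cap = d0_cap)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else {
    d0 <- min(d0, d0_cap)
    if (d0 > 0 && is.null(s0_sq)) {
      abort("s0_sq must be supplied when fixing d0 > 0")
    }
    if (d0 == 0) s0_sq <- NA_real_
  }
  s2_post <- if (d0 == 0) s2 else (d0 * s0_sq + dg * s2) / (d0 + dg)
  zero_var <- s2_post == 0
  tstat <- ifelse(zero_var, NA_real_, mean_d / sqrt(s2_post / n))
  df_total <- d0 + dg
  p <- 2 * pt(-abs(tstat), df = df_total)
  if (any(zero_var)) {
    warn(sprintf("moderated_t: %d zero-variance proteoform(s) flagged (p undefined)",
                 sum(zero_var)))
  }
  results <- tibble(
    label = rownames(diffs) %||% as.character(seq_len(nrow(diffs))),
    n_pairs = as.integer(unname(n)),
    log2fc = unname(mean_d),
    s2 = unname(s2),
    s2_post = unname(s2_post),
    t = unname(tstat),
    df_total = unname(df_total),
    p = unname(p),
    p_adj = p.adjust(p, method = "BH"),
    zero_var_flag = zero_var
  )
  structure(list(eb = list(d0 = d0, s0_sq = s0_sq), results = results),
            class = "moderated_fit")
}

#' @describeIn moderated_t Per-proteoform results tibble.
#' @method tidy moderated_fit
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @export
tidy.moderated_fit <- function(x, ...) x$results

#' @describeIn moderated_t One-row summary: prior df `d0`, prior variance
#' @method glance moderated_fit
#'   `s0_sq`, number tested, number with `p < 0.05`.
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(d0 = x$eb$d0, s0_sq = x$eb$s0_sq,
         n_tested = nrow(x$results),
         n_p05 = sum(x$results$p < 0.05, na.rm = TRUE))
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> %d proteoforms; prior d0 = %.3g, s0^2 = %.4g\n",
              nrow(x$results), x$eb$d0, x$eb$s0_sq %||% NA))
  invisible(x)
}

#' Classify differential results against volcano cutoffs
#'
#' A proteoform is `increased` when `p < p_cut` and `log2fc > lfc_cut`,
#' `decreased` when `p < p_cut` and `log2fc < -lfc_cut`, otherwise `null`
#' (both comparisons strict).
#'
#' @param results Tibble with `p` (or `p_adj` with `use_adjusted = TRUE`)
#'   and `log2fc`.
#' @param p_cut P-value cutoff (default 0.05).
#' @param lfc_cut log2 fold-change cutoff (default 1).
#' @param use_adjusted Classify on BH-adjusted p-values instead.
#' @return `results` with a `class` column.
#' @export
volcano_classify <- function(results, p_cut = 0.05, lfc_cut = 1,
                             use_adjusted = FALSE) {
  p <- if (use_adjusted) results$p_adj else results$p
  results$class <- dplyr::case_when(
    !is.na(p) & p < p_cut & results$log2fc > lfc_cut ~ "increased",
    !is.na(p) & p < p_cut & results$log2fc < -lfc_cut ~ "decreased",
    TRUE ~ "null"
  )
  results
}

#' Hypergeometric presence/absence test
#'
#' For a proteoform observed in `k` samples that all fall in one condition
#' group of size `n_g` out of `N` total samples, the probability that `k`
#' samples drawn uniformly without replacement from `N` all land in that
#' group is `choose(n_g, k) / choose(N, k)`. Group-unique proteoforms with
#' probability below `alpha` (default 0.01) are flagged significant. The
#' test is one-sided per group and not multiplicity-adjusted. Proteoforms
#' observed in both groups are not applicable (`NA` probability).
#'
#' @param quant A `proteoform_quant` object (presence = non-missing
#'   abundance).
#' @param alpha Significance cutoff on the raw probability (default 0.01).
#' @return Tibble: `label`, `k`, `group`, `n_group`, `n_total`,
#'   `probability`, `significant`.
#' @export
presence_test <- function(quant, alpha = 0.01) {
  design <- quant$design
  present <- !is.na(quant$abundance)
  n_total <- nrow(design)
  purrr::map_dfr(seq_len(nrow(present)), function(i) {
    obs <- colnames(present)[present[i, ]]
    k <- length(obs)
    grp <- unique(design$condition[match(obs, design$sample_id)])
    if (k == 0 || length(grp) != 1) {
      return(tibble(label = rownames(present)[i], k = k, group = NA_character_,
                    n_group = NA_integer_, n_total = n_total,
                    probability = NA_real_, significant = NA))
    }
    n_g <- sum(design$condition == grp)
    prob <- choose(n_g, k) / choose(n_total, k)
    tibble(label = rownames(present)[i], k = k, group = grp,
           n_group = as.integer(n_g), n_total = n_total,
           probability = prob, significant = prob < alpha)
  })
}

#' Count regional abundance trends
#'
#' Among tested proteoforms wholly contained in a named region of a gene
#' (closed-interval containment of `[first_aa, last_aa]`), counts how many
#' moved up and down by the sign of `log2fc` (zero counted as neither).
#'
#' @param results Tibble with `gene`, `first_aa`, `last_aa`, `log2fc`.
#' @param region_map Region map tibble ([load_region_map()]).
#' @param gene Gene symbol.
#' @param region Region name within the gene.
#' @return One-row tibble: `gene`, `region`, `n_up`, `n_down`, `n_total`.
#' @export
regional_trend <- function(results, region_map, gene, region) {
  reg <- filter(region_map, .data$gene == !!gene, .data$region == !!region)
  if (nrow(reg) != 1) abort(sprintf("unknown region '%s' for gene %s", region, gene))
  contained <- results$gene %in% gene &
    !is.na(results$first_aa) & !is.na(results$last_aa) &
    results$first_aa >= reg$first_aa & results$last_aa <= reg$last_aa
  lfc <- results$log2fc[contained]
  tibble(gene = gene, region = region,
         n_up = sum(lfc > 0, na.rm = TRUE),
         n_down = sum(lfc < 0, na.rm = TRUE),
         n_total = sum(contained))
}

#' Full differential-abundance analysis of a quantification object
#'
#' Convenience wrapper: median-polish normalization, quantifiability
#' filtering, paired differences, moderated testing with BH adjustment,
#' volcano classification, and region annotation.
#'
#' @param quant A `proteoform_quant` object.
#' @param region_map Optional region map for annotation.
#' @param min_pairs Quantifiability filter (default 2 complete donor pairs).
#' @param p_cut,lfc_cut Volcano cutoffs.
#' @param normalize Apply median-polish normalization first (default TRUE).
#' @return A `moderated_fit` whose results carry feature metadata, `class`
#'   and `region` columns; attribute `"n_excluded"` counts proteoforms
#'   failing the quantifiability filter.
#' @export
differential_abundance <- function(quant, region_map = NULL, min_pairs = 2,
                                   p_cut = 0.05, lfc_cut = 1,
                                   normalize = TRUE) {
  if (normalize) quant <- normalize_quant(quant)
  pairs <- paired_log2fc(quant, min_pairs = min_pairs)
  fit <- moderated_t(pairs$diffs)
  res <- fit$results |>
    left_join(select(quant$features, "label", "gene", "first_aa", "last_aa",
                     "modified"), by = "label") |>
    volcano_classify(p_cut = p_cut, lfc_cut = lfc_cut)
  if (!is.null(region_map)) {
    res$region <- annotate_region(res, region_map)
  }
  fit$results <- res
  attr(fit, "n_excluded") <- pairs$n_excluded
  fit
}

#' Recompute headline differential counts from a results table
#'
#' Given a differential-abundance table (e.g. a published supplementary
#' table with per-proteoform `gene`, `first_aa`, `last_aa`, `p`, `log2fc`),
#' recomputes the headline counts: quantifiable proteoforms, increased and
#' decreased at the volcano cutoffs, and the four prohormone regional
#' trends (major proglucagon fragment, GRPP, LF-19/catestatin,
#' vasostatin-1/2). When a presence matrix is supplied, also counts
#' proteoforms observed in at least half the samples.
#'
#' @param results Differential table (see above).
#' @param presence Optional logical proteoform x sample matrix.
#' @param region_map Region map; packaged default.
#' @param p_cut,lfc_cut Volcano cutoffs (defaults 0.05 and 1).
#' @return Named list of counts.
#' @export
reproduce_reported_counts <- function(results, presence = NULL,
                                      region_map = default_region_map(),
                                      p_cut = 0.05, lfc_cut = 1) {
  res <- volcano_classify(results, p_cut = p_cut, lfc_cut = lfc_cut)
  trends <- list(
    mpgf = regional_trend(res, region_map, "GCG", "major proglucagon fragment"),
    grpp = regional_trend(res, region_map, "GCG", "GRPP"),
    lf19 = regional_trend(res, region_map, "CHGA", "LF-19/catestatin"),
    vs12 = regional_trend(res, region_map, "CHGA", "vasostatin-1/2")
  )
  out <- list(
    n_quantifiable = nrow(res),
    n_increased = sum(res$class == "increased"),
    n_decreased = sum(res$class == "decreased"),
    mpgf_up = trends$mpgf$n_up, mpgf_total = trends$mpgf$n_total,
    grpp_down = trends$grpp$n_down, grpp_total = trends$grpp$n_total,
    lf19_down = trends$lf19$n_down, lf19_total = trends$lf19$n_total,
    vs12_up = trends$vs12$n_up, vs12_total = trends$vs12$n_total
  )
  if (!is.null(presence)) {
    cs <- completeness_summary(presence)
    out$n_half_complete <- sum(cs$fraction >= 0.5)
  }
  out
}
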