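#' Synthetic precursor sequences for the simulator
#'
#' Deterministic synthetic amino-acid sequences standing in for the islet
#' prohormone precursors (INS, GCG, CHGA, SST, IAPP, PPY). They have the
#' canonical precursor lengths and carry dibasic Lys-Arg sites at the true
#' processing-region boundaries (taken from the packaged region map), so
#' that truncation sampling and region annotation behave realistically, but
#' the residues between cleavage sites are pseudorandom - these are
#' synthetic sequences, not the real ones.
#'
#' @return Named character vector of sequences.
#' @export
synthetic_precursors <- function() {
  lengths <- c(INS = 110L, GCG = 180L, CHGA = 457L, SST = 116L,
               IAPP = 89L, PPY = 95L)
  # residue alphabet without C so fixed-mod bookkeeping stays simple to audit
  alphabet <- c("G", "A", "S", "P", "V", "T", "L", "I", "N", "D",
                "Q", "K", "E", "M", "H", "F", "R", "Y", "W")
  map <- default_region_map()
  state <- 20260924
  lcg <- function() {
    state <<- (1103515245 * (state %% 65536) + 12345) %% 2147483648
    state
  }
  out <- vapply(names(lengths), function(g) {
    n <- lengths[[g]]
    res <- vapply(seq_len(n), function(i) alphabet[(lcg() %% length(alphabet)) + 1],
                  character(1))
    regs <- map[map$gene == g, , drop = FALSE]
    for (j in seq_len(nrow(regs))) {
      fa <- regs$first_aa[[j]]; la <- regs$last_aa[[j]]
      if (fa - 2 >= 1) { res[fa - 2] <- "K"; res[fa - 1] <- "R" }
      if (la + 2 <= n) { res[la + 1] <- "K"; res[la + 2] <- "R" }
    }
    paste(res, collapse = "")
  }, character(1))
  out
}

#' Simulation configuration for a paired multi-donor islet study
#'
#' Defaults emulate the study design the pipeline targets: 6 donors, two
#' paired conditions per donor (one acquisition each, 12 datasets), three
#' FAIMS compensation-voltage channels per acquisition, per-dataset ppm
#' mass biases and monotone cubic retention-time distortions, decoy
#' matches, abundance-dependent missingness, and region-wise treatment
#' effects on the prohormone processing products.
#'
#' @param n_donors Number of donors (default 6).
#' @param cv_channels CV channel labels (default -55, -45, -35 V).
#' @param n_proteoforms_per_gene Proteoforms sampled per precursor gene.
#' @param rt_range True elution window in minutes.
#' @param ppm_bias_sd Per-dataset systematic mass bias sd, ppm (default 3).
#' @param ppm_noise_sd Per-observation mass noise sd, ppm (default 2).
#' @param rt_noise_sd Per-observation RT noise sd, minutes (default 0.3).
#' @param warp_offset_range,warp_linear_range,warp_quad_max,warp_cubic_max
#'   Ranges for the per-dataset monotone cubic RT warp coefficients
#'   (offset, linear, quadratic, cubic terms).
#' @param baseline_mean,baseline_sd Per-proteoform baseline log2 abundance.
#' @param donor_sd Donor random-effect sd (log2).
#' @param residual_sd Residual sd of log2 abundance (default 0.3).
#' @param effects Region-wise treatment log2 fold changes: a list of
#'   `gene -> named numeric (region -> log2FC)`.
#' @param miss_intercept,miss_slope Logistic missingness model:
#'   `P(observed) = plogis(intercept + slope * (log2A - baseline_mean))`.
#' @param mod_prob Probability a sampled proteoform carries one variable
#'   modification.
#' @param id_dropout Probability a target observation is exported without
#'   its identification (exercises match-between-runs transfer).
#' @param decoy_fraction Decoy PSMs as a fraction of target rows (default
#'   0.05), with Uniform(0, 1) E-values.
#' @return A `sim_config` list.
#' @export
islet_sim_config <- function(n_donors = 6,
                             cv_channels = c("-55", "-45", "-35"),
                             n_proteoforms_per_gene = 25,
                             rt_range = c(10, 100),
                             ppm_bias_sd = 3,
                             ppm_noise_sd = 2,
                             rt_noise_sd = 0.3,
                             warp_offset_range = c(-2, 2),
                             warp_linear_range = c(0.95, 1.05),
                             warp_quad_max = 5e-4,
                             warp_cubic_max = 3e-6,
                             baseline_mean = 20,
                             baseline_sd = 2,
                             donor_sd = 0.5,
                             residual_sd = 0.3,
                             effects = list(
                               GCG = c("major proglucagon fragment" = 1.5,
                                       "GRPP" = -1.5),
                               CHGA = c("LF-19/catestatin" = -1.5,
                                        "vasostatin-1/2" = 1.0)
                             ),
                             miss_intercept = 2.5,
                             miss_slope = 0.8,
                             mod_prob = 0.25,
                             id_dropout = 0.2,
                             decoy_fraction = 0.05) {
  cfg <- as.list(environment())
  stopifnot(ppm_bias_sd >= 0, ppm_noise_sd >= 0, rt_noise_sd >= 0,
            baseline_sd >= 0, donor_sd >= 0, residual_sd >= 0,
            mod_prob >= 0, mod_prob <= 1, id_dropout >= 0, id_dropout <= 1,
            decoy_fraction >= 0)
  structure(cfg, class = "sim_config")
}

sample_monotone_warp <- function(cfg) {
  hi <- cfg$rt_range[[2]] * 1.1
  for (i in 1:200) {
    coef <- c(
      c0 = runif(1, cfg$warp_offset_range[[1]], cfg$warp_offset_range[[2]]),
      c1 = runif(1, cfg$warp_linear_range[[1]], cfg$warp_linear_range[[2]]),
      c2 = runif(1, -cfg$warp_quad_max, cfg$warp_quad_max),
      c3 = runif(1, -cfg$warp_cubic_max, cfg$warp_cubic_max)
    )
    t <- seq(0, hi, length.out = 200)
    deriv <- coef[["c1"]] + 2 * coef[["c2"]] * t + 3 * coef[["c3"]] * t^2
    if (all(deriv > 0)) return(coef)
  }
  abort("could not sample a monotone warp; widen the coefficient ranges")
}

eval_warp <- function(coef, t) {
  coef[["c0"]] + coef[["c1"]] * t + coef[["c2"]] * t^2 + coef[["c3"]] * t^3
}

sample_catalog <- function(cfg, precursors, map) {
  mods <- list(
    list(name = "Oxidation", delta = mono_mass("O1"), where = "internal"),
    list(name = "Phospho", delta = mono_mass("H1 O3 P1"), where = "internal"),
    list(name = "Amidated", delta = mono_mass("H1 N1 O-1"), where = "cterm")
  )
  rows <- purrr::map_dfr(names(precursors), function(g) {
    seq_g <- precursors[[g]]
    len <- nchar(seq_g)
    regs <- map[map$gene == g, , drop = FALSE]
    picked <- list()
    tries <- 0
    while (length(picked) < cfg$n_proteoforms_per_gene && tries < 50 * cfg$n_proteoforms_per_gene) {
      tries <- tries + 1
      if (nrow(regs) > 0 && runif(1) < 0.7) {
        # ragged inward trimming of a canonical product (exopeptidase-style
        # truncation ladders), so region-derived proteoforms stay contained
        r <- regs[sample.int(nrow(regs), 1), ]
        fa <- max(1L, r$first_aa + sample(0:3, 1))
        la <- min(len, r$last_aa - sample(0:3, 1))
      } else {
        fa <- sample.int(len - 8L, 1)
        la <- fa + sample(8:min(80L, len - fa), 1)
      }
      if (la - fa < 7) next
      key <- paste(fa, la)
      if (!is.null(picked[[key]])) next
      picked[[key]] <- c(fa, la)
    }
    purrr::map_dfr(picked, function(fl) {
      fa <- fl[[1]]; la <- fl[[2]]
      sub <- substr(seq_g, fa, la)
      mod_str <- NA_character_
      deltas <- numeric(0)
      if (runif(1) < cfg$mod_prob) {
        m <- mods[[sample.int(length(mods), 1)]]
        pos <- if (m$where == "cterm") la else sample(fa:la, 1)
        mod_str <- sprintf("%.4f@%d-%d", m$delta, pos, pos)
        deltas <- m$delta
      }
      tibble(
        gene = g, accession = paste0("SYN_", g), first_aa = fa, last_aa = la,
        mod_shifts = mod_str,
        theo_mass = theoretical_mass(sub, mod_deltas = deltas)
      )
    })
  })
  rows <- distinct(rows, .data$gene, .data$first_aa, .data$last_aa,
                   .data$mod_shifts, .keep_all = TRUE)
  rows$pform_id <- seq_len(nrow(rows))
  rows$true_rt <- runif(nrow(rows), cfg$rt_range[[1]], cfg$rt_range[[2]])
  rows$baseline <- rnorm(nrow(rows), cfg$baseline_mean, cfg$baseline_sd)
  rows$region <- annotate_region(rows, map)
  rows$effect <- purrr::map2_dbl(rows$gene, rows$region, function(g, r) {
    e <- cfg$effects[[g]]
    if (is.null(e) || is.na(r) || !r %in% names(e)) 0 else e[[r]]
  })
  rows
}

#' Simulate a paired multi-donor top-down proteomics study
#'
#' Generates one PSM table per (donor, condition) acquisition in the
#' canonical dialect, a sample design table, and a ground-truth manifest
#' from which every expected pipeline output can be recomputed. Observed
#' masses are `theoretical * (1 + (bias + noise) * 1e-6)`; observed RTs are
#' `warp(true RT) + noise`; intensities are split across CV channels by
#' Dirichlet weights; observations are removed by the logistic missingness
#' model; decoy PSMs are appended. All randomness flows from `seed`.
#'
#' @param config A [islet_sim_config()].
#' @param seed Integer seed (required).
#' @return List with `psm` (all acquisitions, canonical columns plus
#'   `theo_mass_da` for identified rows and the bookkeeping column
#'   `truth_pform_id`), `design`, and `manifest` (catalog, per-dataset warp
#'   and bias, per-cell truth, config, seed).
#' @export
simulate_islet_study <- function(config = islet_sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"), is.numeric(seed))
  set.seed(as.integer(seed))
  map <- default_region_map()
  precursors <- synthetic_precursors()
  catalog <- sample_catalog(config, precursors, map)

  design <- tidyr::expand_grid(
    donor_id = sprintf("D%02d", seq_len(config$n_donors)),
    condition = c("control", "treated")
  ) |>
    mutate(sample_id = paste0(.data$donor_id, "_", .data$condition)) |>
    select("sample_id", "donor_id", "condition")

  datasets <- design |>
    mutate(
      ppm_bias = rnorm(n(), 0, config$ppm_bias_sd),
      warp = purrr::map(seq_len(n()), ~ sample_monotone_warp(config))
    )

  donor_eff <- matrix(rnorm(nrow(catalog) * config$n_donors, 0, config$donor_sd),
                      nrow(catalog), config$n_donors,
                      dimnames = list(NULL, unique(design$donor_id)))

  n_cv <- length(config$cv_channels)
  truth <- list(); psm <- list()
  scan_counter <- 0L
  for (i in seq_len(nrow(datasets))) {
    ds <- datasets[i, ]
    treated <- ds$condition == "treated"
    a <- catalog$baseline + donor_eff[, ds$donor_id] +
      (if (treated) catalog$effect else 0) +
      rnorm(nrow(catalog), 0, config$residual_sd)
    p_obs <- plogis(config$miss_intercept +
                      config$miss_slope * (a - config$baseline_mean))
    present <- runif(nrow(catalog)) < p_obs
    truth[[i]] <- tibble(
      pform_id = catalog$pform_id, sample_id = ds$sample_id,
      true_log2 = a, p_observed = p_obs, present = present
    )
    idx <- which(present)
    if (length(idx) > 0) {
      w <- matrix(rgamma(length(idx) * n_cv, shape = 2, rate = 1),
                  length(idx), n_cv)
      w <- w / rowSums(w)
      rows <- purrr::map_dfr(seq_along(idx), function(j) {
        k <- idx[[j]]
        bias_noise <- ds$ppm_bias + rnorm(n_cv, 0, config$ppm_noise_sd)
        dropped <- runif(n_cv) < config$id_dropout
        tibble(
          dataset_id = ds$sample_id,
          scan = 0L,
          rt_min = pmax(0, eval_warp(ds$warp[[1]], catalog$true_rt[[k]]) +
                          rnorm(n_cv, 0, config$rt_noise_sd)),
          mass_da = catalog$theo_mass[[k]] * (1 + bias_noise * 1e-6),
          accession = ifelse(dropped, NA_character_, catalog$accession[[k]]),
          gene = ifelse(dropped, NA_character_, catalog$gene[[k]]),
          first_aa = ifelse(dropped, NA_integer_, catalog$first_aa[[k]]),
          last_aa = ifelse(dropped, NA_integer_, catalog$last_aa[[k]]),
          mod_shifts = ifelse(dropped, NA_character_, catalog$mod_shifts[[k]]),
          evalue = ifelse(dropped, NA_real_,
                          10^(-(1.30103 + rexp(n_cv, rate = 0.5)))),
          is_decoy = FALSE,
          intensity = 2^a[[k]] * w[j, ],
          cv_volts = config$cv_channels,
          theo_mass_da = ifelse(dropped, NA_real_, catalog$theo_mass[[k]]),
          truth_pform_id = catalog$pform_id[[k]]
        )
      })
      n_decoy <- round(config$decoy_fraction * nrow(rows))
      if (n_decoy > 0) {
        decoys <- tibble(
          dataset_id = ds$sample_id,
          scan = 0L,
          rt_min = runif(n_decoy, 0, config$rt_range[[2]] * 1.1),
          mass_da = runif(n_decoy, 1000, 20000),
          accession = paste0("DECOY_", seq_len(n_decoy)),
          gene = NA_character_,
          first_aa = sample.int(50, n_decoy, replace = TRUE),
          last_aa = NA_integer_,
          evalue = runif(n_decoy),
          is_decoy = TRUE,
          intensity = runif(n_decoy, 1, 1e4),
          cv_volts = sample(config$cv_channels, n_decoy, replace = TRUE),
          mod_shifts = NA_character_,
          theo_mass_da = NA_real_,
          truth_pform_id = NA_integer_
        )
        decoys$last_aa <- decoys$first_aa + sample.int(60, n_decoy, replace = TRUE)
        rows <- bind_rows(rows, decoys)
      }
      rows$scan <- scan_counter + seq_len(nrow(rows))
      scan_counter <- scan_counter + nrow(rows)
      psm[[i]] <- rows
    }
  }
  psm <- bind_rows(psm)
  psm <- validate_psm(psm)
  manifest <- list(
    catalog = catalog,
    datasets = select(datasets, "sample_id", "donor_id", "condition",
                      "ppm_bias", "warp"),
    truth = bind_rows(truth),
    config = config,
    seed = as.integer(seed)
  )
  list(psm = psm, design = design, manifest = manifest)
}

#' Recompute oracle outputs from a simulation manifest
#'
#' Deterministic ground-truth targets for verifying the pipeline: expected
#' per-proteoform log2 fold change (mean of true treated-minus-control
#' differences over donors with both sides present), true presence pattern,
#' and the injected region effect.
#'
#' @param sim Output of [simulate_islet_study()].
#' @return Tibble with one row per true proteoform: `pform_id`, `label`,
#'   `gene`, `region`, `injected_lfc`, `expected_lfc` (NA when < 2 complete
#'   pairs), `n_complete_pairs`, `n_present`.
#' @export
expected_outputs <- function(sim) {
  cat <- sim$manifest$catalog
  truth <- sim$manifest$truth |>
    left_join(sim$design, by = "sample_id")
  wide <- truth |>
    mutate(value = ifelse(.data$present, .data$true_log2, NA_real_)) |>
    select("pform_id", "donor_id", "condition", "value") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value") |>
    mutate(diff = .data$treated - .data$control) |>
    group_by(.data$pform_id) |>
    summarise(
      n_complete_pairs = sum(!is.na(.data$diff)),
      expected_lfc = if (sum(!is.na(.data$diff)) >= 2)
        mean(.data$diff, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  n_present <- truth |>
    group_by(.data$pform_id) |>
    summarise(n_present = sum(.data$present), .groups = "drop")
  cat |>
    mutate(label = format_proteoform_name(
      .data$gene, .data$first_aa, .data$last_aa,
      modified = !is.na(.data$mod_shifts))) |>
    select("pform_id", "label", "gene", "first_aa", "last_aa", "region",
           injected_lfc = "effect") |>
    left_join(wide, by = "pform_id") |>
    left_join(n_present, by = "pform_id")
}
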