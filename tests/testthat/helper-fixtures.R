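# Shared fixtures built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Minimal canonical PSM tibble; fields overridable per row set.
make_psm <- function(n = 1, dataset_id = "ds1", scan = seq_len(n),
                     rt_min = 30, mass_da = 5000, accession = "SYN_INS",
                     gene = "INS", first_aa = 25L, last_aa = 54L,
                     mod_shifts = NA_character_, evalue = 1e-5,
                     is_decoy = FALSE, intensity = 1e6, cv_volts = "-45") {
  tibble::tibble(
    dataset_id = dataset_id, scan = as.integer(scan), rt_min = rt_min,
    mass_da = mass_da, accession = accession, gene = gene,
    first_aa = as.integer(first_aa), last_aa = as.integer(last_aa),
    mod_shifts = mod_shifts, evalue = evalue, is_decoy = is_decoy,
    intensity = intensity, cv_volts = cv_volts
  )
}

# A small paired design.
make_design <- function(n_donors = 6) {
  donors <- sprintf("D%02d", seq_len(n_donors))
  tibble::tibble(
    sample_id = c(paste0(donors, "_control"), paste0(donors, "_treated")),
    donor_id = rep(donors, 2),
    condition = rep(c("control", "treated"), each = n_donors)
  )
}

# Wrap a bare log2 matrix as a proteoform_quant for stats-layer tests.
make_quant <- function(abundance, design, counts = NULL,
                       genes = NULL, first_aa = NULL, last_aa = NULL) {
  if (is.null(rownames(abundance))) {
    rownames(abundance) <- paste0("P", seq_len(nrow(abundance)))
  }
  colnames(abundance) <- design$sample_id
  if (is.null(counts)) {
    counts <- matrix(1L, nrow(abundance), ncol(abundance),
                     dimnames = dimnames(abundance))
  }
  features <- tibble::tibble(
    label = rownames(abundance),
    gene = genes %||% NA_character_,
    first_aa = first_aa %||% NA_integer_,
    last_aa = last_aa %||% NA_integer_,
    modified = FALSE
  )
  structure(list(abundance = abundance, counts = counts, features = features,
                 design = design,
                 unassigned = tibble::tibble(cluster_id = integer(0))),
            class = "proteoform_quant")
}

# Small, fast simulation config.
small_sim_config <- function(...) {
  islet_sim_config(n_proteoforms_per_gene = 8, ...)
}

# Noiseless scenario: identity warp, no mass error, no missingness noise in
# localization; used for exact-recovery limit tests.
noiseless_sim_config <- function(...) {
  defaults <- list(
    ppm_bias_sd = 0, ppm_noise_sd = 0, rt_noise_sd = 0,
    warp_offset_range = c(0, 0), warp_linear_range = c(1, 1),
    warp_quad_max = 0, warp_cubic_max = 0,
    residual_sd = 0, donor_sd = 0,
    miss_intercept = 50, miss_slope = 0, mod_prob = 0,
    id_dropout = 0, decoy_fraction = 0,
    n_proteoforms_per_gene = 8
  )
  do.call(islet_sim_config, utils::modifyList(defaults, list(...)))
}
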