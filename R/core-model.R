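#' Canonical proteoform-spectrum-match (PSM) columns
#'
#' The canonical tabular dialect used throughout the package. One row is one
#' proteoform-spectrum match (or, when `evalue` is missing, an MS1 feature
#' observation without an identification). Residue coordinates are 1-based and
#' inclusive, numbered on the full precursor so that the first residue of the
#' signal peptide is residue 1.
#'
#' @format A named character vector mapping canonical column names to their
#'   expected types (`"character"`, `"integer"`, `"double"`, `"logical"`).
#' @export
psm_columns <- c(
  dataset_id = "character",
  scan       = "integer",
  rt_min     = "double",
  mass_da    = "double",
  accession  = "character",
  gene       = "character",
  first_aa   = "integer",
  last_aa    = "integer",
  mod_shifts = "character",
  evalue     = "double",
  is_decoy   = "logical",
  intensity  = "double",
  cv_volts   = "character"
)

#' Validate a table of PSM records
#'
#' Checks the canonical column set and the record invariants: non-negative
#' retention time, positive mass, ordered residue coordinates, non-negative
#' E-value and intensity.
#'
#' @param records A data frame in the canonical PSM dialect.
#' @return The records as a tibble, invisibly validated.
#' @export
validate_psm <- function(records) {
  records <- as_tibble(records)
  missing <- setdiff(names(psm_columns), names(records))
  if (length(missing) > 0) {
    abort(paste0("missing PSM column(s): ", paste(missing, collapse = ", ")))
  }
  chk <- function(ok, what) {
    if (any(!ok, na.rm = TRUE)) abort(paste0("invalid PSM record(s): ", what))
  }
  chk(records$rt_min >= 0, "rt_min must be >= 0")
  chk(records$mass_da > 0, "mass_da must be > 0")
  chk(records$first_aa >= 1, "first_aa must be >= 1")
  chk(records$first_aa <= records$last_aa, "first_aa must be <= last_aa")
  chk(records$evalue >= 0, "evalue must be >= 0")
  chk(records$intensity >= 0, "intensity must be >= 0")
  records
}

#' Is a record an identified target match?
#'
#' A record counts as identified when it carries a gene or accession and
#' residue coordinates; decoy matches are not identifications.
#'
#' @param records PSM tibble.
#' @return Logical vector.
#' @export
is_identified <- function(records) {
  (!is.na(records$gene) | !is.na(records$accession)) &
    !is.na(records$first_aa) & !is.na(records$last_aa) &
    !records$is_decoy %in% TRUE
}

# Canonical modification signature: deltas rounded to 2 decimals (the field's
# reporting precision), localization interval retained, entries sorted.
# Encoding in tables: "delta@first-last" joined by ";"; "" or NA = unmodified.
canonical_mod_signature <- function(mod_shifts) {
  vapply(mod_shifts, function(s) {
    if (is.na(s) || !nzchar(s)) return("")
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    parsed <- vapply(parts, function(p) {
      bits <- strsplit(p, "@", fixed = TRUE)[[1]]
      delta <- round(as.numeric(bits[[1]]), 2)
      loc <- if (length(bits) > 1) bits[[2]] else "?"
      sprintf("%+.2f@%s", delta, loc)
    }, character(1))
    paste(sort(parsed), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Build canonical proteoform keys
#'
#' A proteoform key is the identity used for cross-run matching: gene,
#' accession, first/last residue, and the canonicalized modification
#' signature (delta masses rounded to two decimals plus their localization).
#' Canonicalization is idempotent, so two keys compare equal iff all fields
#' are equal after canonicalization.
#'
#' @param records PSM tibble (canonical dialect).
#' @return Character vector of key strings, `NA` for unidentified records.
#' @export
proteoform_key <- function(records) {
  key <- paste(
    records$gene %||% NA_character_,
    records$accession,
    records$first_aa,
    records$last_aa,
    canonical_mod_signature(records$mod_shifts),
    sep = "|"
  )
  key[!is_identified(records)] <- NA_character_
  key
}

#' Format a proteoform label
#'
#' Labels a proteoform by gene and start/end residue, e.g. the insulin B chain
#' (precursor residues 25-54) is `"INS_25-54"`. A trailing `"*"` marks a
#' modified proteoform. When the gene symbol is missing the accession is used
#' instead, with a warning.
#'
#' @param gene Gene symbol(s).
#' @param first_aa,last_aa 1-based inclusive residue coordinates on the full
#'   precursor (signal peptide residue = 1).
#' @param modified Logical; append `"*"` for modified proteoforms.
#' @param accession Fallback identifier(s) when `gene` is missing.
#' @return Character vector of labels.
#' @examples
#' format_proteoform_name("INS", 25, 54)            # "INS_25-54"
#' format_proteoform_name("INS", 57, 79, modified = TRUE)
#' @export
format_proteoform_name <- function(gene, first_aa, last_aa, modified = FALSE,
                                   accession = NULL) {
  stopifnot(all(first_aa >= 1, na.rm = TRUE),
            all(first_aa <= last_aa, na.rm = TRUE))
  id <- gene
  bad <- is.na(id) | !nzchar(id)
  if (any(bad)) {
    if (is.null(accession) || any(is.na(accession[bad]))) {
      abort("gene symbol missing and no accession fallback available")
    }
    warn("missing gene symbol(s); falling back to accession")
    id[bad] <- accession[bad]
  }
  paste0(id, "_", first_aa, "-", last_aa, ifelse(modified, "*", ""))
}

#' Parse a proteoform label back to its components
#'
#' Inverse of [format_proteoform_name()].
#'
#' @param label Character vector of labels such as `"INS_25-54*"`.
#' @return A tibble with columns `gene`, `first_aa`, `last_aa`, `modified`.
#' @export
parse_proteoform_name <- function(label) {
  m <- regmatches(label, regexec("^(.+)_([0-9]+)-([0-9]+)(\\*?)$", label))
  bad <- vapply(m, length, integer(1)) != 5
  if (any(bad)) abort(paste0("unparseable label(s): ",
                             paste(label[bad], collapse = ", ")))
  tibble(
    gene = vapply(m, `[[`, character(1), 2),
    first_aa = as.integer(vapply(m, `[[`, character(1), 3)),
    last_aa = as.integer(vapply(m, `[[`, character(1), 4)),
    modified = vapply(m, `[[`, character(1), 5) == "*"
  )
}

#' Collapse proteoforms sharing one terminus into a grouped label
#'
#' Proteoforms of one gene that share a single terminus are written with the
#' varying positions separated by `"/"`: INS_57-79, INS_57-80 and INS_57-81
#' collapse to `"INS_57-79/80/81"`; a shared C-terminus varies the start, e.g.
#' `"SCG2_569/570/571-610"`.
#'
#' @param keys A data frame with columns `gene`, `first_aa`, `last_aa`
#'   (one row per proteoform).
#' @return A single character label.
#' @export
format_shared_terminus_group <- function(keys) {
  keys <- distinct(as_tibble(keys), .data$gene, .data$first_aa, .data$last_aa)
  if (n_distinct(keys$gene) != 1) abort("all keys must share one gene")
  if (nrow(keys) == 1) {
    return(format_proteoform_name(keys$gene, keys$first_aa, keys$last_aa))
  }
  share_first <- n_distinct(keys$first_aa) == 1
  share_last <- n_distinct(keys$last_aa) == 1
  if (!share_first && !share_last) {
    abort("keys differ in both termini; no shared terminus to collapse on")
  }
  if (share_first) {
    paste0(keys$gene[[1]], "_", keys$first_aa[[1]], "-",
           paste(sort(unique(keys$last_aa)), collapse = "/"))
  } else {
    paste0(keys$gene[[1]], "_",
           paste(sort(unique(keys$first_aa)), collapse = "/"),
           "-", keys$last_aa[[1]])
  }
}

#' Data-completeness summary of a presence table
#'
#' For each proteoform, the fraction of samples (acquisitions) in which it is
#' observed, binned for display as in a data-completeness histogram.
#'
#' @param presence A logical matrix (proteoforms x samples), or a data frame
#'   coercible to one, where `TRUE`/nonzero means observed.
#' @param breaks Bin breaks on the fraction scale; default deciles.
#' @return A tibble with one row per proteoform: `proteoform`, `n_observed`,
#'   `n_samples`, `fraction`, `bin`. Bin counts over rows sum to the
#'   proteoform count.
#' @export
completeness_summary <- function(presence, breaks = seq(0, 1, by = 0.1)) {
  m <- as.matrix(presence)
  if (nrow(m) == 0 || ncol(m) == 0) abort("presence table must be non-empty")
  mode(m) <- "logical"
  m[is.na(m)] <- FALSE
  frac <- rowMeans(m)
  tibble(
    proteoform = rownames(m) %||% as.character(seq_len(nrow(m))),
    n_observed = as.integer(unname(rowSums(m))),
    n_samples = ncol(m),
    fraction = unname(frac),
    bin = cut(frac, breaks = breaks, include.lowest = TRUE)
  )
}

#' Read a sample design table
#'
#' The design CSV has header `sample_id,donor_id,condition` with condition
#' one of `control`/`treated`. Each donor contributes at most one sample per
#' condition (a paired design when complete).
#'
#' @param path CSV file path.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  design <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    donor_id = readr::col_character(),
    condition = readr::col_character()
  ))
  validate_design(design)
}

#' Validate a sample design table
#'
#' @param design Data frame with `sample_id`, `donor_id`, `condition`.
#' @return The design as a tibble.
#' @export
validate_design <- function(design) {
  design <- as_tibble(design)
  need <- c("sample_id", "donor_id", "condition")
  missing <- setdiff(need, names(design))
  if (length(missing) > 0) {
    abort(paste0("design is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(design$condition %in% c("control", "treated"))) {
    abort("condition must be 'control' or 'treated'")
  }
  if (anyDuplicated(design$sample_id) > 0) abort("sample_id must be unique")
  dup <- duplicated(design[c("donor_id", "condition")])
  if (any(dup)) abort("each donor may appear at most once per condition")
  design
}
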