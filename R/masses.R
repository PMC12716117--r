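#' Monoisotopic atomic masses
#'
#' Standard monoisotopic masses of the most abundant isotope, fixed to five
#' decimals so mass arithmetic is bit-stable across platforms. Iron is
#' included for the common electrospray Fe(III) adduct.
#'
#' @format Named numeric vector, Da.
#' @export
atomic_masses <- c(
  C = 12.00000,
  H = 1.00783,
  N = 14.00307,
  O = 15.99491,
  S = 31.97207,
  P = 30.97376,
  Fe = 55.93494
)

# Residue elemental compositions (the residue, i.e. amino acid minus water).
residue_formulas <- c(
  G = "C2 H3 N1 O1",  A = "C3 H5 N1 O1",  S = "C3 H5 N1 O2",
  P = "C5 H7 N1 O1",  V = "C5 H9 N1 O1",  T = "C4 H7 N1 O2",
  C = "C3 H5 N1 O1 S1", L = "C6 H11 N1 O1", I = "C6 H11 N1 O1",
  N = "C4 H6 N2 O2",  D = "C4 H5 N1 O3",  Q = "C5 H8 N2 O2",
  K = "C6 H12 N2 O1", E = "C5 H7 N1 O3",  M = "C5 H9 N1 O1 S1",
  H = "C6 H7 N3 O1",  F = "C9 H9 N1 O1",  R = "C6 H12 N4 O1",
  Y = "C9 H9 N1 O2",  W = "C11 H10 N2 O1"
)

parse_formula <- function(formula) {
  if (is.numeric(formula)) return(formula)
  formula <- trimws(formula)
  if (!nzchar(formula)) return(setNames(numeric(0), character(0)))
  toks <- strsplit(formula, "[[:space:]]+")[[1]]
  m <- regmatches(toks, regexec("^([A-Z][a-z]?)(-?[0-9]+)$", toks))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) abort(paste0("unparseable formula token(s): ",
                             paste(toks[bad], collapse = ", ")))
  el <- vapply(m, `[[`, character(1), 2)
  cnt <- as.numeric(vapply(m, `[[`, character(1), 3))
  tapply(cnt, el, sum)
}

#' Monoisotopic mass of an elemental composition change
#'
#' Computes the exact monoisotopic delta mass of a signed elemental
#' composition, e.g. a carbonyl addition (+O, -2H) is +13.98 Da and the
#' lysine-to-allysine conversion (+O, -N, -3H) is -1.03 Da.
#'
#' @param formula Either a formula string of signed element counts
#'   (`"O1 H-2"`) or a named numeric vector (`c(O = 1, H = -2)`).
#' @return Delta mass in Da. Linear: `mono_mass(a) + mono_mass(b)` equals the
#'   mass of the summed composition exactly.
#' @examples
#' mono_mass("O1 H-2")       # +13.979 (carbonyl)
#' mono_mass("O1 N-1 H-3")   # -1.032 (allysine)
#' @export
mono_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0) return(0)
  unknown <- setdiff(names(counts), names(atomic_masses))
  if (length(unknown) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  sum(counts * atomic_masses[names(counts)])
}

#' Monoisotopic residue masses
#'
#' @return Named numeric vector of the 20 canonical residue masses in Da,
#'   derived from [atomic_masses] so that residue arithmetic stays linear.
#' @export
residue_masses <- function() {
  vapply(residue_formulas, mono_mass, numeric(1))
}

water_mass <- function() mono_mass("H2 O1")

# Carbamidomethyl (iodoacetamide adduct on Cys), applied as a fixed mod.
carbamidomethyl_mass <- function() mono_mass("C2 H3 N1 O1")

#' Theoretical monoisotopic mass of a proteoform
#'
#' Sum of residue masses plus water, plus the fixed carbamidomethyl adduct on
#' every cysteine (iodoacetamide alkylation, the standard static modification
#' in this workflow), plus any variable modification deltas.
#'
#' @param sequence Amino-acid string (canonical one-letter residues).
#' @param mod_deltas Numeric vector of variable modification delta masses
#'   in Da (possibly empty).
#' @param carbamidomethyl Apply the fixed Cys adduct? Default `TRUE`.
#' @return Monoisotopic neutral mass in Da.
#' @examples
#' theoretical_mass("GG")  # 132.0535
#' @export
theoretical_mass <- function(sequence, mod_deltas = numeric(0),
                             carbamidomethyl = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  rm_tab <- residue_masses()
  bad <- which(!res %in% names(rm_tab))
  if (length(bad) > 0) {
    abort(sprintf("non-canonical residue '%s' at position %d", res[bad[1]], bad[1]))
  }
  mass <- sum(rm_tab[res]) + water_mass()
  if (carbamidomethyl) mass <- mass + sum(res == "C") * carbamidomethyl_mass()
  mass + sum(mod_deltas)
}

#' Load a modification delta-mass table
#'
#' The table is a TSV with columns `name`, `site`, `formula` (signed element
#' counts, e.g. `"O1 H-2"`), and optionally `observed_da` (a reported
#' observed shift where it differs from the composition's theoretical delta).
#' The theoretical `delta_da` is always recomputed from `formula` via
#' [mono_mass()].
#'
#' @param path TSV path; default the packaged table, which carries the 14
#'   dynamic modifications of the open search plus tentative assignments
#'   (carbonyl, allysine, Leu/Ile-to-Ala and His-to-Ala substitutions, an
#'   O-linked Hex2HexNAc1NeuGc3 glycan).
#' @return Tibble with `name`, `site`, `formula`, `delta_da`, `observed_da`.
#' @export
load_mod_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mod_deltas.tsv",
                                package = "proformr", mustWork = TRUE)
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    name = readr::col_character(),
    site = readr::col_character(),
    formula = readr::col_character(),
    observed_da = readr::col_double()
  ))
  tab$delta_da <- vapply(tab$formula, mono_mass, numeric(1), USE.NAMES = FALSE)
  # sanity: any stated observed value must sit near its composition
  off <- !is.na(tab$observed_da) & abs(tab$observed_da - tab$delta_da) > 0.5
  if (any(off)) warn(paste0("observed_da far from formula delta for: ",
                            paste(tab$name[off], collapse = ", ")))
  tab[, c("name", "site", "formula", "delta_da", "observed_da")]
}

#' Annotate an observed mass shift against a modification table
#'
#' Finds the table entry whose theoretical delta is nearest the observed
#' shift, within an absolute tolerance (0.1 Da by default, the standard
#' open-search annotation window). Ties are broken by smaller absolute error,
#' then lexicographic name.
#'
#' @param observed_shift_da Numeric vector of observed delta masses in Da.
#' @param table Modification table from [load_mod_table()].
#' @param tol_da Matching tolerance in Da (> 0).
#' @return Tibble with one row per observed shift: `observed_da`, `name`,
#'   `delta_da`, `error_da` (`NA` name when nothing matches).
#' @export
annotate_shift <- function(observed_shift_da, table = load_mod_table(),
                           tol_da = 0.1) {
  stopifnot(tol_da >= 0)
  purrr::map_dfr(observed_shift_da, function(obs) {
    if (is.null(table) || nrow(table) == 0) {
      return(tibble(observed_da = obs, name = NA_character_,
                    delta_da = NA_real_, error_da = NA_real_))
    }
    err <- abs(obs - table$delta_da)
    ok <- which(err <= tol_da)
    if (length(ok) == 0) {
      return(tibble(observed_da = obs, name = NA_character_,
                    delta_da = NA_real_, error_da = NA_real_))
    }
    ord <- ok[order(err[ok], table$name[ok])]
    best <- ord[[1]]
    tibble(observed_da = obs, name = table$name[[best]],
           delta_da = table$delta_da[[best]], error_da = obs - table$delta_da[[best]])
  })
}

#' Attach theoretical masses to identified PSM records
#'
#' Computes each identified record's theoretical monoisotopic mass from the
#' precursor sequence of its gene: the residue span `[first_aa, last_aa]`
#' plus water, fixed carbamidomethyl on Cys, and the record's declared
#' modification delta masses. Unidentified records, decoys and genes absent
#' from `sequences` get `NA`.
#'
#' @param records PSM tibble (canonical dialect).
#' @param sequences Named character vector of precursor sequences
#'   (gene -> amino-acid string), e.g. [synthetic_precursors()].
#' @return The records with a `theo_mass_da` column.
#' @export
add_theoretical_masses <- function(records, sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  ok <- is_identified(records) & records$gene %in% names(sequences)
  theo <- rep(NA_real_, nrow(records))
  idx <- which(ok)
  if (length(idx) > 0) {
    theo[idx] <- purrr::map_dbl(idx, function(i) {
      seq_g <- sequences[[records$gene[[i]]]]
      if (records$last_aa[[i]] > nchar(seq_g)) return(NA_real_)
      deltas <- parse_mod_shift_deltas(records$mod_shifts[[i]])
      theoretical_mass(substr(seq_g, records$first_aa[[i]],
                              records$last_aa[[i]]),
                       mod_deltas = deltas)
    })
  }
  records$theo_mass_da <- theo
  records
}

# "delta@first-last;..." -> numeric deltas
parse_mod_shift_deltas <- function(mod_shifts) {
  if (is.na(mod_shifts) || !nzchar(mod_shifts)) return(numeric(0))
  parts <- strsplit(mod_shifts, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  vapply(parts, function(p) as.numeric(strsplit(p, "@", fixed = TRUE)[[1]][[1]]),
         numeric(1), USE.NAMES = FALSE)
}
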