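#' Load a prohormone region map
#'
#' A region map lists, per gene, named residue intervals of the mature
#' processing products (1-based closed intervals, numbered on the full
#' precursor with the signal peptide's first residue as 1). The packaged
#' default covers the proglucagon (GCG), insulin (INS), chromogranin-A
#' (CHGA) and somatostatin (SST) products used for regional trend analysis.
#'
#' @param path TSV with columns `gene`, `region`, `first_aa`, `last_aa`;
#'   `NULL` loads the packaged map.
#' @return Validated region tibble.
#' @export
load_region_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "prohormone_regions.tsv",
                                package = "proformr", mustWork = TRUE)
  map <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    gene = readr::col_character(),
    region = readr::col_character(),
    first_aa = readr::col_integer(),
    last_aa = readr::col_integer()
  ))
  bad <- which(is.na(map$first_aa) | is.na(map$last_aa) |
                 map$first_aa < 1 | map$first_aa > map$last_aa)
  if (length(bad) > 0) {
    abort(sprintf("region map row %d: invalid interval", bad[[1]]))
  }
  dup <- which(duplicated(map[c("gene", "region")]))
  if (length(dup) > 0) {
    abort(sprintf("region map row %d: duplicate region name within gene", dup[[1]]))
  }
  map
}

#' @rdname load_region_map
#' @export
default_region_map <- function() load_region_map()

#' Annotate proteoforms with their prohormone processing region
#'
#' A proteoform maps to a region when its `[first_aa, last_aa]` interval is
#' wholly contained in that region; nested containments resolve to the
#' smallest containing region (the most specific named product). Proteoforms
#' overlapping regions without being contained in any - e.g. a precursor
#' spanning several products - are labelled `"Other"`, as are in-gene
#' proteoforms touching no region. Genes absent from the map give
#' `"unmapped"`.
#'
#' @param keys Tibble with `gene`, `first_aa`, `last_aa`.
#' @param map Region map ([load_region_map()]).
#' @return Character vector of region names (or `"Other"` / `"unmapped"`).
#' @export
annotate_region <- function(keys, map = default_region_map()) {
  purrr::pmap_chr(
    list(keys$gene, keys$first_aa, keys$last_aa),
    function(g, fa, la) {
      if (is.na(g) || is.na(fa) || is.na(la)) return(NA_character_)
      regs <- map[map$gene == g, , drop = FALSE]
      if (nrow(regs) == 0) return("unmapped")
      contained <- fa >= regs$first_aa & la <= regs$last_aa
      if (any(contained)) {
        width <- regs$last_aa - regs$first_aa
        hit <- which(contained)
        hit <- hit[order(width[hit], regs$region[hit])]
        return(regs$region[hit[[1]]])
      }
      "Other"
    }
  )
}
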