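#' Reference score components
#'
#' A vendored table of externally derived score components for the 15
#' top-ranked compounds in each species: rank, identifiers, identity
#' percentages, the five factors, the four terms, the final score as
#' displayed (2 decimals), and — where a predicted dissociation constant
#' was reported alongside — `kd_nm` in nanomolar. Used by the regression
#' tests and the acceptance script to check that [composite_score()] and
#' [affinity_factor()] recompose the reference values.
#'
#' @param species Optional filter, `"celegans"` or `"dmelanogaster"`.
#' @return A tibble.
#' @export
reference_components <- function(species = NULL) {
  path <- system.file("extdata", "reference_components.tsv",
                      package = "agerank", mustWork = TRUE)
  out <- readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(), rank = readr::col_integer(),
    het_code = readr::col_character(), name = readr::col_character(),
    targets = readr::col_character(),
    .default = readr::col_double()
  ), na = "NA", progress = FALSE)
  if (!is.null(species)) out <- out[out$species == species, , drop = FALSE]
  out
}
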