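#' Ranking configuration
#'
#' Collects every tunable of the scoring procedure: the target species, the
#' logistic parameters of each transform, the *D. melanogaster*
#' bioavailability substitute, the aging-implication formula reading and
#' mapping penalty, the contact window half-width, the rounding mode of the
#' "50% most dissimilar" site positions, and optional factor/term weights
#' for tailored rankings.
#'
#' @param species `"celegans"` or `"dmelanogaster"`.
#' @param affinity,domain,promiscuity,bioavailability Length-2 numeric
#'   `(location, scale)` pairs for the logistic transforms.
#' @param bioavailability_constant Fixed factor used for *D. melanogaster*.
#' @param aging_formula See [aging_implication()].
#' @param mapping_penalty Weight on identifier-mapping counts.
#' @param window Half-width (residues) of the contact window used when a
#'   contact lies outside annotated domains.
#' @param k_mode Rounding of N/2 in [binding_site_conservation()].
#' @param factor_weights,term_weights Optional named weights for
#'   [tailored_score()]; empty means the standard composite.
#' @return A `ranking_config` list.
#' @export
ranking_config <- function(species = c("celegans", "dmelanogaster"),
                           affinity = c(5, 1),
                           domain = c(0.6, 0.1),
                           promiscuity = c(7, 1),
                           bioavailability = c(4, 2.25),
                           bioavailability_constant = 0.9,
                           aging_formula = c("half_total", "half_mappings"),
                           mapping_penalty = 0.1,
                           window = 50,
                           k_mode = c("floor", "ceil"),
                           factor_weights = numeric(0),
                           term_weights = numeric(0)) {
  species <- match.arg(species)
  pairs <- list(affinity = affinity, domain = domain,
                promiscuity = promiscuity, bioavailability = bioavailability)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (length(p) != 2 || !is.numeric(p) || p[2] <= 0) {
      abort(sprintf("logistic parameters for '%s' must be (location, scale > 0).", nm),
            class = "agerank_error_param")
    }
  }
  if (any(c(factor_weights, term_weights) < 0)) {
    abort("Weights must be >= 0.", class = "agerank_error_param")
  }
  structure(list(
    species = species,
    logistic = pairs,
    bioavailability_constant = bioavailability_constant,
    aging_formula = match.arg(aging_formula),
    mapping_penalty = mapping_penalty,
    window = window,
    k_mode = match.arg(k_mode),
    factor_weights = factor_weights,
    term_weights = term_weights
  ), class = "ranking_config")
}

#' @export
print.ranking_config <- function(x, ...) {
  cat(sprintf("<ranking_config> species: %s, window: +/-%d, aging formula: %s\n",
              x$species, x$window, x$aging_formula))
  invisible(x)
}

#' Read a ranking configuration from YAML
#'
#' Keys mirror the arguments of [ranking_config()]; absent keys keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `ranking_config`.
#' @export
read_ranking_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(ranking_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")),
          class = "agerank_error_input")
  }
  raw$factor_weights <- unlist(raw$factor_weights) %||% numeric(0)
  raw$term_weights <- unlist(raw$term_weights) %||% numeric(0)
  do.call(ranking_config, raw)
}

known_species <- c("hsapiens", "mmusculus", "rnorvegicus", "dmelanogaster",
                   "celegans")
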