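#' Logistic transform
#'
#' \eqn{1 / (1 + e^{-(x - l)/s})}: strictly increasing in `x`, 0.5 at
#' `x = location`. Used for the domain-conservation, binding-affinity,
#' promiscuity and bioavailability transforms.
#'
#' @param x Numeric vector.
#' @param location Midpoint `l`.
#' @param scale Steepness `s`; must be positive.
#' @return Values in \eqn{(0, 1)}.
#' @export
logistic <- function(x, location, scale) {
  if (!is.numeric(scale) || any(scale <= 0)) {
    abort("logistic scale must be > 0.", class = "agerank_error_param")
  }
  1 / (1 + exp(-(x - location) / scale))
}

evidence_categories <- c("experimental", "computational", "author_curator",
                         "automatic_or_none")

#' Gene Ontology evidence score for aging annotation
#'
#' Encodes how direct the evidence linking a protein to aging is: smaller is
#' stronger. Experimental evidence codes score 0.01 (0.02 when the
#' annotation was transferred from an orthologue), computational analysis
#' codes 0.15 (0.16 via orthologue), author/curator statements 0.16, and
#' automatic or missing annotation 0.28 (0.29 via orthologue). A GenAge
#' listing overrides everything with 0.01.
#'
#' @param category One of `"experimental"`, `"computational"`,
#'   `"author_curator"`, `"automatic_or_none"` (vectorised).
#' @param via_orthologue Was the annotation mapped through an orthologue?
#' @param genage Is the gene listed in GenAge?
#' @return Numeric evidence score(s).
#' @export
go_evidence_score <- function(category, via_orthologue = FALSE, genage = FALSE) {
  if (!all(category %in% evidence_categories)) {
    abort(paste0("Invalid evidence category. Allowed: ",
                 paste(evidence_categories, collapse = ", ")),
          class = "agerank_error_input")
  }
  base <- c(experimental = 0.01, computational = 0.15,
            author_curator = 0.16, automatic_or_none = 0.28)[category]
  ortho_bump <- c(experimental = 0.01, computational = 0.01,
                  author_curator = 0, automatic_or_none = 0.01)[category]
  out <- unname(base + ifelse(via_orthologue, ortho_bump, 0))
  ifelse(genage, 0.01, out)
}

#' Aging-implication factor
#'
#' Converts the evidence score and the number of identifier-mapping steps
#' (database cross-references traversed from the evidence source to the
#' target protein, each adding uncertainty) into a factor close to 1 for
#' well-supported direct annotations. Two readings of the published formula
#' are supported: `"half_total"` (default),
#' \eqn{1 - (ev + 0.1 m)/2}, and `"half_mappings"`,
#' \eqn{1 - ev - 0.1 m / 2}. Results are floored at 0.
#'
#' @param ev_score Evidence score in \eqn{[0, 1]} (see
#'   [go_evidence_score()]).
#' @param n_mappings Number of identifier-mapping steps (count, >= 0).
#' @param formula Formula reading (see Details).
#' @param mapping_penalty Weight on the mapping count (default 0.1).
#' @return Factor in \eqn{[0, 1]}.
#' @export
aging_implication <- function(ev_score, n_mappings,
                              formula = c("half_total", "half_mappings"),
                              mapping_penalty = 0.1) {
  formula <- match.arg(formula)
  if (any(ev_score < 0 | ev_score > 1)) {
    abort("ev_score must be in [0, 1].", class = "agerank_error_input")
  }
  if (any(n_mappings < 0)) {
    abort("n_mappings must be >= 0.", class = "agerank_error_input")
  }
  raw <- switch(formula,
    half_total = 1 - (ev_score + mapping_penalty * n_mappings) / 2,
    half_mappings = 1 - ev_score - mapping_penalty * n_mappings / 2
  )
  pmax(0, raw)
}

#' Binding-affinity factor
#'
#' Predicted log-affinity (e.g. an RF-Score value, \eqn{-\log_{10} K_d} with
#' Kd in molar) passed through `logistic(x; 5, 1)`: millimolar binders
#' (x = 3) score ~0.12, nanomolar binders (x = 9) ~0.98.
#'
#' @param log_affinity Predicted log-affinity (log10 units).
#' @param location,scale Logistic parameters (defaults 5 and 1).
#' @return Factor in \eqn{(0, 1)}.
#' @export
affinity_factor <- function(log_affinity, location = 5, scale = 1) {
  if (any(!is.finite(log_affinity))) {
    abort("log_affinity must be finite.", class = "agerank_error_input")
  }
  logistic(log_affinity, location, scale)
}

#' @rdname affinity_factor
#' @param kd Dissociation constant in molar; must be positive.
#' @export
log_affinity_from_kd <- function(kd) {
  if (any(!is.finite(kd) | kd <= 0)) {
    abort("Kd must be positive and finite (molar).", class = "agerank_error_input")
  }
  -log10(kd)
}

#' Bioavailability factor
#'
#' For *C. elegans* the Burns bioaccumulation score is logistically
#' transformed and rescaled: `logistic(burns; 4, 2.25) * 0.8 + 0.2`, giving
#' a factor in \eqn{(0.2, 1)}. For *D. melanogaster*, where no validated
#' predictor is available, a fixed substitute of 0.9 is used.
#'
#' @param species `"celegans"` or `"dmelanogaster"`.
#' @param burns_score Burns predictor output; required for *C. elegans*.
#' @param config A [ranking_config()] supplying the logistic parameters and
#'   the *D. melanogaster* constant.
#' @return Factor in \eqn{(0, 1]}.
#' @export
bioavailability_factor <- function(species, burns_score = NULL,
                                   config = ranking_config(species)) {
  species <- match.arg(species, c("celegans", "dmelanogaster"))
  if (species == "dmelanogaster") {
    return(config$bioavailability_constant)
  }
  if (is.null(burns_score) || anyNA(burns_score)) {
    abort("Burns score required for C. elegans bioavailability.",
          class = "agerank_error_missing_input")
  }
  p <- config$logistic$bioavailability
  logistic(burns_score, p[1], p[2]) * 0.8 + 0.2
}

#' Lipinski rule-of-five violations and loss term
#'
#' One violation per broken rule: molecular weight >= 500 Da, logP > 5,
#' more than 5 hydrogen-bond donors, more than 10 acceptors. The loss term
#' scales the count: \eqn{-n/20}.
#'
#' @param mw Molecular weight (Daltons).
#' @param logp Octanol-water partition coefficient.
#' @param hbd,hba Hydrogen-bond donor and acceptor counts.
#' @return `lipinski_violations()`: integer count 0-4.
#' @export
lipinski_violations <- function(mw, logp, hbd, hba) {
  if (any(!is.finite(c(mw, logp, hbd, hba)))) {
    abort("Lipinski descriptors must be finite.", class = "agerank_error_input")
  }
  (mw >= 500) + (logp > 5) + (hbd > 5) + (hba > 10)
}

#' @rdname lipinski_violations
#' @param n Number of violations.
#' @export
lipinski_loss <- function(n) {
  if (any(n < 0)) abort("Violation count must be >= 0.", class = "agerank_error_input")
  -n / 20
}

#' Binding-promiscuity loss term
#'
#' Compounds crystallised with many different aging-related proteins
#' (ubiquitous metabolites, crystallisation aids) are penalised:
#' \eqn{-\mathrm{logistic}(n; 7, 1)/5}, approaching \eqn{-0.2} for very
#' promiscuous compounds.
#'
#' @param n_targets Number of distinct aging-related proteins the compound
#'   is crystallised with.
#' @param location,scale Logistic parameters (defaults 7 and 1).
#' @return Loss in \eqn{(-0.2, 0)}.
#' @export
promiscuity_loss <- function(n_targets, location = 7, scale = 1) {
  if (any(n_targets < 0)) {
    abort("n_targets must be >= 0.", class = "agerank_error_input")
  }
  -logistic(n_targets, location, scale) / 5
}

#' Purchasability and approval bonus terms
#'
#' Purchasable compounds (listed in ZINC or eMolecules) gain 0.1. Approved
#' drugs (designated known drug in ChEMBL) gain 0.1; compounds present in
#' DrugBank but not designated in ChEMBL gain 0.075; ChEMBL designation
#' takes precedence.
#'
#' @param purchasable Logical.
#' @return Bonus value.
#' @export
purchase_bonus <- function(purchasable) {
  ifelse(as.logical(purchasable), 0.1, 0)
}

#' @rdname purchase_bonus
#' @param status One of `"chembl_drug"`, `"drugbank_only"`, `"none"`.
#' @export
approval_bonus <- function(status) {
  if (!all(status %in% c("chembl_drug", "drugbank_only", "none"))) {
    abort("Invalid approval status.", class = "agerank_error_input")
  }
  unname(c(chembl_drug = 0.1, drugbank_only = 0.075, none = 0)[status])
}

#' Aggregate per-target factors for a multi-target compound
#'
#' For compounds binding more than one protein, the element-wise maximum of
#' the per-target factors is used. The three structure-dependent factors
#' (domain conservation, binding-site conservation, binding affinity) are
#' aggregated this way; the aging factor, when present, is aggregated by
#' maximum too for consistency.
#'
#' @param per_target Data frame with one row per target and columns
#'   `domain_cons`, `site_cons`, `affinity`, optionally `aging`.
#' @return One-row tibble of the column-wise maxima.
#' @export
aggregate_targets <- function(per_target) {
  per_target <- as_tibble(per_target)
  if (nrow(per_target) == 0) {
    abort("At least one target required.", class = "agerank_error_input")
  }
  cols <- intersect(c("aging", "domain_cons", "site_cons", "affinity"),
                    names(per_target))
  summarise(per_target, across(all_of(cols), max))
}

#' Compose the final ranking score
#'
#' The bounded composite of the ranking: the product of the five factors
#' (aging implication, domain conservation, binding-site conservation,
#' binding affinity, bioavailability), plus the Lipinski and promiscuity
#' losses and the purchasability and approval bonuses, clipped to
#' \eqn{[0, 1]}. Multiplicative linkage means no factor can compensate for
#' another; the additive terms only modulate the base score.
#'
#' @param aging,domain_cons,site_cons,affinity,bioavailability The five
#'   factors, each in \eqn{[0, 1]} (vectorised).
#' @param lipinski_loss,promiscuity_loss Non-positive loss terms.
#' @param purchase_bonus Either 0 or 0.1.
#' @param approval_bonus One of 0, 0.075, 0.1.
#' @return A `score_breakdown` tibble retaining every unrounded component
#'   plus the clipped `final` score.
#' @examples
#' composite_score(1, 0.96, 1, 0.95, 0.9,
#'                 purchase_bonus = 0.1, approval_bonus = 0.1)
#' @export
composite_score <- function(aging, domain_cons, site_cons, affinity,
                            bioavailability, lipinski_loss = 0,
                            promiscuity_loss = 0, purchase_bonus = 0,
                            approval_bonus = 0) {
  factors <- tibble(aging, domain_cons, site_cons, affinity, bioavailability)
  if (any(as.matrix(factors) < 0 | as.matrix(factors) > 1, na.rm = FALSE) ||
      anyNA(factors)) {
    abort("All five factors must lie in [0, 1].",
          class = "agerank_error_validation")
  }
  if (any(lipinski_loss > 0) || any(promiscuity_loss > 0)) {
    abort("Loss terms must be <= 0.", class = "agerank_error_validation")
  }
  raw <- aging * domain_cons * site_cons * affinity * bioavailability +
    lipinski_loss + promiscuity_loss + purchase_bonus + approval_bonus
  out <- mutate(factors,
                lipinski_loss = lipinski_loss,
                promiscuity_loss = promiscuity_loss,
                purchase_bonus = purchase_bonus,
                approval_bonus = approval_bonus,
                final = pmin(1, pmax(0, raw)))
  class(out) <- c("score_breakdown", class(out))
  out
}

#' Tailored re-weighted score
#'
#' Recomputes a composite score with user-chosen emphasis: each factor `f`
#' enters as `f^w` (weight 0 excludes it, since \eqn{f^0 = 1}), each
#' additive term is scaled by its weight, and the result is clipped as
#' usual. All weights 1 reproduces [composite_score()] exactly.
#'
#' @param breakdown A `score_breakdown` tibble (any number of rows).
#' @param factor_weights Named numeric vector over
#'   `aging`, `domain_cons`, `site_cons`, `affinity`, `bioavailability`;
#'   missing names default to 1.
#' @param term_weights Named numeric vector over `lipinski_loss`,
#'   `promiscuity_loss`, `purchase_bonus`, `approval_bonus`; missing names
#'   default to 1.
#' @return Numeric vector of tailored final scores in \eqn{[0, 1]}.
#' @export
tailored_score <- function(breakdown, factor_weights = numeric(0),
                           term_weights = numeric(0)) {
  fnames <- c("aging", "domain_cons", "site_cons", "affinity", "bioavailability")
  tnames <- c("lipinski_loss", "promiscuity_loss", "purchase_bonus",
              "approval_bonus")
  fw <- setNames(rep(1, length(fnames)), fnames)
  fw[names(factor_weights)] <- factor_weights
  tw <- setNames(rep(1, length(tnames)), tnames)
  tw[names(term_weights)] <- term_weights
  if (any(c(fw, tw) < 0)) {
    abort("Weights must be >= 0.", class = "agerank_error_param")
  }
  prod_f <- Reduce(`*`, lapply(fnames, function(f) breakdown[[f]]^fw[[f]]), 1)
  terms <- Reduce(`+`, lapply(tnames, function(t) breakdown[[t]] * tw[[t]]), 0)
  pmin(1, pmax(0, prod_f + terms))
}

# display convention of the ranking tables: two decimals, halves up
round_display <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}
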