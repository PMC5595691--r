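#' Score a compound set against one target species
#'
#' The core pipeline step: for every compound, each (compound, target,
#' structure) link is resolved in its family alignment — the
#' representative homologue of the target species is selected, the
#' conservation factors are computed over the ligand contacts and domain
#' regions, and the affinity factor is taken from the predicted
#' log-affinity. Per-target factors are aggregated by maximum, combined
#' with the compound-level bioavailability, loss and bonus terms, and
#' composed into the final score. Compounds whose target families have no
#' member of the species are excluded (reason `no_homologue_in_species`),
#' as are compounds whose required inputs are missing (reason in the
#' exclusion table).
#'
#' @param links Link table (see [read_links_tsv()]).
#' @param compounds Compound table (see [read_compounds_tsv()]).
#' @param evidence Aging-evidence table (see [read_evidence_tsv()]).
#' @param families Named list of [aligned_family()] objects, keyed by
#'   `family_id`.
#' @param contacts Contact table (see [read_contacts_tsv()]).
#' @param domains Domain table (see [read_domains_tsv()]).
#' @param config A [ranking_config()].
#' @return A list with `breakdowns` (one row per scored compound: display
#'   columns plus the full `score_breakdown`) and `excluded` (`het_code`,
#'   `reason`).
#' @export
score_compounds <- function(links, compounds, evidence, families, contacts,
                            domains, config) {
  stopifnot(inherits(config, "ranking_config"))
  missing_fam <- setdiff(unique(links$family_id), names(families))
  if (length(missing_fam) > 0) {
    abort(paste0("Link refers to unknown family: ",
                 paste(missing_fam, collapse = ", ")),
          class = "agerank_error_input")
  }
  rows <- list()
  excluded <- list()
  for (i in seq_len(nrow(compounds))) {
    cmp <- compounds[i, ]
    res <- tryCatch(
      score_one_compound(cmp, links, evidence, families, contacts, domains,
                         config),
      agerank_error_species_absent = function(e)
        list(reason = "no_homologue_in_species"),
      agerank_error_missing_input = function(e)
        list(reason = "missing_burns_score")
    )
    if (!inherits(res, "data.frame")) {
      excluded[[length(excluded) + 1]] <-
        tibble(het_code = cmp$het_code, reason = res$reason)
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  list(breakdowns = bind_rows(rows),
       excluded = bind_rows(excluded) %||%
         tibble(het_code = character(0), reason = character(0)))
}

# factors for one link, or a species-absent condition
score_one_link <- function(link, families, contacts, domains, config) {
  family <- families[[link$family_id]]
  pos <- contacts$position[contacts$structure_id == link$structure_id &
                             contacts$het_code == link$het_code]
  if (length(pos) == 0) {
    abort(sprintf("No contacts for structure %s / compound %s.",
                  link$structure_id, link$het_code),
          class = "agerank_error_input")
  }
  site_cols <- contacts_to_columns(family, pos)
  member <- select_homologue(family, config$species, site_cols)
  dom <- domains[domains$member_id == attr(family, "ref_id"), , drop = FALSE]
  regions <- scoring_regions(pos, dom, ref_ungapped_length(family),
                             window = config$window)
  p_dom <- config$logistic$domain
  tibble(
    target_protein_id = link$target_protein_id,
    member_id = member,
    domain_cons = domain_conservation(family, member, regions,
                                      location = p_dom[1], scale = p_dom[2]),
    site_cons = binding_site_conservation(family, member, site_cols,
                                          k_mode = config$k_mode),
    affinity = affinity_factor(link$log_affinity,
                               location = config$logistic$affinity[1],
                               scale = config$logistic$affinity[2]),
    global_identity = global_identity(family, member),
    site_identity = site_identity(family, member, site_cols)
  )
}

score_one_compound <- function(cmp, links, evidence, families, contacts,
                               domains, config) {
  my_links <- links[links$het_code == cmp$het_code, , drop = FALSE]
  if (nrow(my_links) == 0) {
    abort(sprintf("Compound %s has no target links.", cmp$het_code),
          class = "agerank_error_species_absent")
  }
  per_target <- list()
  for (j in seq_len(nrow(my_links))) {
    res <- tryCatch(
      score_one_link(my_links[j, ], families, contacts, domains, config),
      agerank_error_species_absent = function(e) NULL
    )
    if (!is.null(res)) per_target[[length(per_target) + 1]] <- res
  }
  if (length(per_target) == 0) {
    abort(sprintf("No target of %s has a homologue in %s.", cmp$het_code,
                  config$species),
          class = "agerank_error_species_absent")
  }
  per_target <- bind_rows(per_target)
  ev <- evidence[match(per_target$target_protein_id, evidence$protein_id), ,
                 drop = FALSE]
  if (anyNA(ev$protein_id)) {
    abort(sprintf("No aging evidence for target %s.",
                  per_target$target_protein_id[is.na(ev$protein_id)][1]),
          class = "agerank_error_input")
  }
  per_target$aging <- aging_implication(
    go_evidence_score(ev$category, ev$via_orthologue, ev$genage),
    ev$n_mappings,
    formula = config$aging_formula,
    mapping_penalty = config$mapping_penalty
  )
  agg <- aggregate_targets(per_target)
  bio <- bioavailability_factor(config$species,
                                burns_score = cmp$burns_score,
                                config = config)
  breakdown <- composite_score(
    aging = agg$aging, domain_cons = agg$domain_cons,
    site_cons = agg$site_cons, affinity = agg$affinity,
    bioavailability = bio,
    lipinski_loss = lipinski_loss(cmp$lipinski_violations),
    promiscuity_loss = promiscuity_loss(cmp$n_aging_targets,
                                        location = config$logistic$promiscuity[1],
                                        scale = config$logistic$promiscuity[2]),
    purchase_bonus = purchase_bonus(cmp$purchasable),
    approval_bonus = approval_bonus(cmp$approval)
  )
  best <- which.max(per_target$site_cons)
  bind_cols(
    tibble(het_code = cmp$het_code,
           name = cmp$name,
           targets = paste(sort(unique(per_target$target_protein_id)),
                           collapse = ","),
           global_identity = per_target$global_identity[best],
           site_identity = per_target$site_identity[best]),
    breakdown
  )
}

#' Run the full ranking pipeline from input files
#'
#' Reads every input table and family alignment, scores all compounds for
#' the configured species, ranks them, and (optionally) writes the ranking
#' TSV, JSON report cards, the exclusion log and a run manifest to
#' `out_dir`. Deterministic: identical inputs and configuration give
#' byte-identical outputs.
#'
#' @param config A [ranking_config()].
#' @param compounds_tsv,evidence_tsv,links_tsv,contacts_tsv,domains_tsv
#'   Paths to the five annotation tables.
#' @param family_fastas Character vector of aligned FASTA paths (one per
#'   family; the file name stem is the family id).
#' @param out_dir Optional output directory.
#' @return A list: `ranking` (a `compound_ranking`), `breakdowns`,
#'   `excluded`, `manifest`.
#' @export
run_pipeline <- function(config, compounds_tsv, evidence_tsv, links_tsv,
                         contacts_tsv, domains_tsv, family_fastas,
                         out_dir = NULL) {
  compounds <- read_compounds_tsv(compounds_tsv)
  evidence <- read_evidence_tsv(evidence_tsv)
  links <- read_links_tsv(links_tsv)
  contacts <- read_contacts_tsv(contacts_tsv)
  domains <- read_domains_tsv(domains_tsv)
  families <- lapply(family_fastas, read_family_fasta)
  names(families) <- map_chr(families, attr, "family_id")

  scored <- score_compounds(links, compounds, evidence, families, contacts,
                            domains, config)
  if (nrow(scored$breakdowns) == 0) {
    warn("No compound survived filtering; ranking is empty.")
  }
  ranking <- rank_compounds(scored$breakdowns)
  inputs <- c(compounds = compounds_tsv, evidence = evidence_tsv,
              links = links_tsv, contacts = contacts_tsv,
              domains = domains_tsv,
              setNames(family_fastas, basename(family_fastas)))
  manifest <- run_manifest(config, inputs)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ranking_tsv(ranking, file.path(out_dir, "ranking.tsv"))
    readr::write_tsv(scored$excluded, file.path(out_dir, "excluded.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    card_dir <- file.path(out_dir, "report_cards")
    dir.create(card_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(ranking))) {
      writeLines(render_report_card(ranking[i, ], "json"),
                 file.path(card_dir, paste0(ranking$het_code[i], ".json")))
    }
  }
  list(ranking = ranking, breakdowns = scored$breakdowns,
       excluded = scored$excluded, manifest = manifest)
}
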