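#' Simulate a complete, scoreable input set
#'
#' Generates protein families, ligand contacts, domain annotations,
#' compound records, aging evidence and compound-target links that emulate
#' the real inputs of the ranking pipeline, together with expected score
#' breakdowns computed by an independent straight-line oracle
#' ([oracle_score_breakdowns()]).
#'
#' Each family starts from a random root sequence (the human reference);
#' every other species' member is derived by substituting each site
#' independently with probability `mutation_rate * divergence[species]`
#' (substitutions uniform over the 19 alternative residues, no indels, so
#' all members share the alignment frame). The default divergence
#' multipliers (rodents 0.15, fly 1, worm 1.25) with the default
#' `mutation_rate` give invertebrate global identities around 60-80%,
#' the range typical of the kinase families that dominate real rankings;
#' binding sites default to 10 residues, a typical small-molecule pocket.
#'
#' @param seed Integer seed; the same seed reproduces the same data set
#'   exactly.
#' @param n_families Number of protein families (one aging-related target
#'   protein each).
#' @param n_compounds Number of compounds; each links to one or two
#'   families.
#' @param mutation_rate Base per-site substitution probability.
#' @param site_size Number of ligand-contact residues per structure.
#' @param seq_length Ungapped reference length.
#' @param config A [ranking_config()]; its species decides which member is
#'   scored and how bioavailability enters.
#' @param dir Optional directory: when given, all inputs are also written
#'   as the flat files the pipeline reads (aligned FASTA per family plus
#'   the five TSVs), and their paths are returned.
#' @return A list with the in-memory tables (`families`, `contacts`,
#'   `domains`, `compounds`, `evidence`, `links`), the oracle's `expected`
#'   breakdown per compound, `config`, `seed` and (with `dir`) `paths`.
#' @export
simulate_ranking_data <- function(seed, n_families = 6, n_compounds = 12,
                                  mutation_rate = 0.2, site_size = 10,
                                  seq_length = 300,
                                  config = ranking_config("celegans"),
                                  dir = NULL) {
  if (site_size < 1 || n_families < 1 || n_compounds < 1 || seq_length < 120) {
    abort("Degenerate simulation parameters.", class = "agerank_error_param")
  }
  if (mutation_rate < 0 || mutation_rate > 0.75) {
    abort("mutation_rate must be in [0, 0.75].", class = "agerank_error_param")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  std <- rownames(grantham_distance_matrix())
  divergence <- c(hsapiens = 0, mmusculus = 0.15, rnorvegicus = 0.15,
                  dmelanogaster = 1, celegans = 1.25)

  mutate_seq <- function(chars, rate) {
    hit <- stats::runif(length(chars)) < rate
    chars[hit] <- vapply(chars[hit],
                         function(a) sample(setdiff(std, a), 1), "")
    chars
  }

  families <- list()
  contacts <- list()
  domains <- list()
  evidence <- list()
  for (f in seq_len(n_families)) {
    fid <- sprintf("fam%02d", f)
    root <- sample(std, seq_length, replace = TRUE)
    members <- tibble(
      member_id = paste(fid, names(divergence), sep = "_"),
      species = names(divergence),
      seq = map_chr(divergence, function(d) {
        paste(mutate_seq(root, min(0.95, mutation_rate * d)), collapse = "")
      })
    )
    families[[fid]] <- aligned_family(members, family_id = fid,
                                      ref_id = members$member_id[1])
    dom_start <- sample(1:40, 1)
    dom_end <- min(seq_length, dom_start + sample(150:220, 1))
    domains[[fid]] <- tibble(member_id = members$member_id[1],
                             start = dom_start, end = dom_end)
    # mostly in-domain contacts; occasionally one outside to exercise the
    # +/-window fallback
    pos <- sort(sample(dom_start:dom_end, site_size))
    if (stats::runif(1) < 0.3 && dom_end + 20 < seq_length) {
      pos[site_size] <- sample((dom_end + 1):seq_length, 1)
      pos <- sort(pos)
    }
    contacts[[fid]] <- tibble(structure_id = paste0(fid, "_pdb"),
                              het_code = NA_character_, position = pos)
    evidence[[fid]] <- tibble(
      protein_id = paste0("PROT_", fid),
      category = sample(evidence_categories, 1),
      via_orthologue = stats::runif(1) < 0.3,
      n_mappings = sample(0:2, 1),
      genage = stats::runif(1) < 0.3
    )
  }
  domains <- bind_rows(domains)
  evidence <- bind_rows(evidence)

  compounds <- tibble(
    het_code = sprintf("C%02d", seq_len(n_compounds)),
    name = sprintf("compound-%02d", seq_len(n_compounds)),
    mw = round(stats::runif(n_compounds, 250, 650), 1),
    logp = round(stats::runif(n_compounds, 0, 7), 2),
    hbd = sample(0:7, n_compounds, replace = TRUE),
    hba = sample(2:12, n_compounds, replace = TRUE),
    purchasable = stats::runif(n_compounds) < 0.6,
    approval = sample(c("chembl_drug", "drugbank_only", "none"), n_compounds,
                      replace = TRUE),
    burns_score = round(stats::rnorm(n_compounds, 5, 2), 3),
    n_aging_targets = sample(1:10, n_compounds, replace = TRUE)
  )
  compounds$lipinski_violations <-
    lipinski_violations(compounds$mw, compounds$logp, compounds$hbd,
                        compounds$hba)

  links <- list()
  fam_ids <- names(families)
  for (i in seq_len(n_compounds)) {
    fams <- sample(fam_ids, sample(1:2, 1))
    links[[i]] <- tibble(
      het_code = compounds$het_code[i],
      target_protein_id = paste0("PROT_", fams),
      structure_id = paste0(fams, "_pdb"),
      family_id = fams,
      log_affinity = round(stats::rnorm(length(fams), 6.5, 1.2), 3)
    )
  }
  links <- bind_rows(links)

  # one contact row per (structure, compound) pair actually linked
  contact_rows <- list()
  for (i in seq_len(nrow(links))) {
    cc <- contacts[[links$family_id[i]]]
    cc$het_code <- links$het_code[i]
    contact_rows[[i]] <- cc
  }
  contact_tbl <- dplyr::distinct(bind_rows(contact_rows))

  out <- list(families = families, contacts = contact_tbl, domains = domains,
              compounds = compounds, evidence = evidence, links = links,
              config = config, seed = seed)
  out$expected <- oracle_score_breakdowns(out)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      compounds = file.path(dir, "compounds.tsv"),
      evidence = file.path(dir, "evidence.tsv"),
      links = file.path(dir, "links.tsv"),
      contacts = file.path(dir, "contacts.tsv"),
      domains = file.path(dir, "domains.tsv"),
      families = file.path(dir, paste0(names(families), ".fasta")),
      config = file.path(dir, "config.yaml")
    )
    readr::write_tsv(compounds, paths$compounds)
    readr::write_tsv(evidence, paths$evidence)
    readr::write_tsv(links, paths$links)
    readr::write_tsv(contact_tbl, paths$contacts)
    readr::write_tsv(domains, paths$domains)
    for (i in seq_along(families)) {
      write_family_fasta(families[[i]], paths$families[i])
    }
    yaml::write_yaml(list(species = config$species, window = config$window,
                          aging_formula = config$aging_formula,
                          k_mode = config$k_mode),
                     paths$config)
    out$paths <- paths
  }
  out
}

#' Independent oracle for score breakdowns
#'
#' A deliberately naive, loop-based recomputation of every factor and term
#' from the raw simulated tables, sharing no code with the pipeline beyond
#' the vendored distance TSV: positions are mapped to columns by scanning
#' characters, scoring regions are materialised as a per-position logical
#' mask rather than merged intervals, and every transform is written out
#' inline. Used to cross-check the pipeline on simulated data.
#'
#' @param sim A list as produced by [simulate_ranking_data()] (the
#'   `expected` element is ignored).
#' @return A tibble with one row per rankable compound: `het_code`, the
#'   five factors, four terms and `final`.
#' @export
oracle_score_breakdowns <- function(sim) {
  dpath <- system.file("extdata", "grantham_distance.tsv", package = "agerank",
                       mustWork = TRUE)
  dmat <- as.matrix(utils::read.delim(dpath, row.names = 1,
                                      check.names = FALSE))
  expand <- function(a) {
    if (a == "B") c("D", "N") else if (a == "Z") c("Q", "E")
    else if (a == "X") rownames(dmat) else a
  }
  simi <- function(a, b) {
    vals <- c()
    for (x in expand(a)) for (y in expand(b)) {
      vals <- c(vals, 1 - dmat[x, y] / 215)
    }
    mean(vals)
  }
  lgs <- function(x, l, s) 1 / (1 + exp(-(x - l) / s))
  cfg <- sim$config

  out <- list()
  for (i in seq_len(nrow(sim$compounds))) {
    cmp <- sim$compounds[i, ]
    lk <- sim$links[sim$links$het_code == cmp$het_code, ]
    per <- NULL
    for (j in seq_len(nrow(lk))) {
      fam <- sim$families[[lk$family_id[j]]]
      refseq <- strsplit(fam$seq[fam$member_id == attr(fam, "ref_id")], "")[[1]]
      # ungapped position -> column, by scanning
      colmap <- integer(0)
      for (c in seq_along(refseq)) {
        if (refseq[c] != "-" && refseq[c] != ".") colmap <- c(colmap, c)
      }
      pos <- sim$contacts$position[
        sim$contacts$structure_id == lk$structure_id[j] &
          sim$contacts$het_code == cmp$het_code]
      site_cols <- colmap[pos]
      # pick the species member: fewest site gaps, then site sim/identity
      cand <- fam$member_id[fam$species == cfg$species]
      if (length(cand) == 0) next
      best <- NULL
      for (m in sort(cand)) {
        mseq <- strsplit(fam$seq[fam$member_id == m], "")[[1]]
        g <- sum(mseq[site_cols] %in% c("-", "."))
        s <- mean(vapply(site_cols, function(cc) {
          if (mseq[cc] %in% c("-", ".")) 0 else simi(refseq[cc], mseq[cc])
        }, 0))
        id <- mean(refseq[site_cols] == mseq[site_cols] &
                     !mseq[site_cols] %in% c("-", "."))
        if (is.null(best) || g < best$g ||
            (g == best$g && s > best$s) ||
            (g == best$g && s == best$s && id > best$id)) {
          best <- list(m = m, g = g, s = s, id = id, mseq = mseq)
        }
      }
      # scoring mask over ungapped positions
      dom <- sim$domains[sim$domains$member_id == attr(fam, "ref_id"), ]
      mask <- rep(FALSE, length(colmap))
      for (p in pos) {
        hit <- FALSE
        for (d in seq_len(nrow(dom))) {
          if (p >= dom$start[d] && p <= dom$end[d]) {
            mask[dom$start[d]:dom$end[d]] <- TRUE
            hit <- TRUE
          }
        }
        if (!hit) {
          lo <- max(1, p - cfg$window)
          hi <- min(length(colmap), p + cfg$window)
          mask[lo:hi] <- TRUE
        }
      }
      reg_cols <- colmap[mask]
      sims <- vapply(reg_cols, function(cc) {
        if (best$mseq[cc] %in% c("-", ".")) 0 else simi(refseq[cc], best$mseq[cc])
      }, 0)
      dom_f <- lgs(mean(sims), cfg$logistic$domain[1], cfg$logistic$domain[2])
      site_sims <- sort(vapply(site_cols, function(cc) {
        if (best$mseq[cc] %in% c("-", ".")) 0 else simi(refseq[cc], best$mseq[cc])
      }, 0))
      k <- if (cfg$k_mode == "floor") {
        max(1, floor(length(site_sims) / 2))
      } else {
        max(1, ceiling(length(site_sims) / 2))
      }
      site_f <- mean(site_sims[1:k])
      aff_f <- lgs(lk$log_affinity[j], cfg$logistic$affinity[1],
                   cfg$logistic$affinity[2])
      ev <- sim$evidence[sim$evidence$protein_id == lk$target_protein_id[j], ]
      evs <- if (ev$genage) 0.01 else {
        base <- switch(ev$category, experimental = 0.01, computational = 0.15,
                       author_curator = 0.16, automatic_or_none = 0.28)
        if (ev$via_orthologue && ev$category != "author_curator") {
          base + 0.01
        } else {
          base
        }
      }
      aging <- if (cfg$aging_formula == "half_total") {
        max(0, 1 - (evs + cfg$mapping_penalty * ev$n_mappings) / 2)
      } else {
        max(0, 1 - evs - cfg$mapping_penalty * ev$n_mappings / 2)
      }
      per <- rbind(per, c(aging = aging, dom = dom_f, site = site_f,
                          aff = aff_f))
    }
    if (is.null(per)) next
    bio <- if (cfg$species == "dmelanogaster") {
      cfg$bioavailability_constant
    } else {
      if (is.na(cmp$burns_score)) next
      lgs(cmp$burns_score, cfg$logistic$bioavailability[1],
          cfg$logistic$bioavailability[2]) * 0.8 + 0.2
    }
    lip <- -cmp$lipinski_violations / 20
    prom <- -lgs(cmp$n_aging_targets, cfg$logistic$promiscuity[1],
                 cfg$logistic$promiscuity[2]) / 5
    pur <- if (cmp$purchasable) 0.1 else 0
    app <- switch(cmp$approval, chembl_drug = 0.1, drugbank_only = 0.075,
                  none = 0)
    raw <- max(per[, "aging"]) * max(per[, "dom"]) * max(per[, "site"]) *
      max(per[, "aff"]) * bio + lip + prom + pur + app
    out[[length(out) + 1]] <- tibble(
      het_code = cmp$het_code,
      aging = max(per[, "aging"]), domain_cons = max(per[, "dom"]),
      site_cons = max(per[, "site"]), affinity = max(per[, "aff"]),
      bioavailability = bio, lipinski_loss = lip, promiscuity_loss = prom,
      purchase_bonus = pur, approval_bonus = app,
      final = min(1, max(0, raw))
    )
  }
  bind_rows(out)
}
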