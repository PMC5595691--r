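#' Read and write an aligned family FASTA
#'
#' One aligned FASTA per family, every member in the common alignment
#' frame. Headers follow the convention `member_id|species`; the first
#' record is the structure-bearing reference unless `ref_id` is given.
#'
#' @param path Aligned FASTA file.
#' @param family_id Family identifier; defaults to the file name without
#'   extension.
#' @param ref_id Reference member; defaults to the first record.
#' @return An [aligned_family()].
#' @export
read_family_fasta <- function(path, family_id = NULL, ref_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "agerank_error_input")
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    abort(sprintf("Empty FASTA: %s", path), class = "agerank_error_input")
  }
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- headers[lengths(parts) != 2]
  if (length(bad) > 0) {
    abort(sprintf("FASTA header not in 'member_id|species' form: '%s'", bad[1]),
          class = "agerank_error_parse")
  }
  ids <- map_chr(parts, 1)
  species <- map_chr(parts, 2)
  unknown <- setdiff(unique(species), known_species)
  if (length(unknown) > 0) {
    abort(paste0("Unknown species tag(s): ", paste(unknown, collapse = ", ")),
          class = "agerank_error_input")
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate member id '%s' in %s.", ids[anyDuplicated(ids)], path),
          class = "agerank_error_input")
  }
  lens <- Biostrings::width(set)
  if (length(unique(lens)) != 1) {
    abort(sprintf("Ragged alignment in %s: member '%s' has length %d, expected %d.",
                  path, ids[which(lens != lens[1])[1]],
                  lens[which(lens != lens[1])[1]], lens[1]),
          class = "agerank_error_frame")
  }
  aligned_family(
    tibble(member_id = ids, species = species, seq = as.character(set)),
    family_id = family_id %||% sub("\\.[^.]*$", "", basename(path)),
    ref_id = ref_id %||% ids[1]
  )
}

#' @rdname read_family_fasta
#' @param family An [aligned_family()] to write.
#' @export
write_family_fasta <- function(family, path) {
  # reference first, so a round trip preserves the ref_id convention
  ord <- order(family$member_id != attr(family, "ref_id"))
  fam <- family[ord, ]
  set <- Biostrings::AAStringSet(setNames(fam$seq,
                                          paste(fam$member_id, fam$species,
                                                sep = "|")))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# shared reader: typed TSV + required columns + per-line checks
read_checked_tsv <- function(path, col_types, checks = list()) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "agerank_error_input")
  }
  out <- readr::read_tsv(path, col_types = col_types, progress = FALSE)
  missing <- setdiff(names(col_types$cols), names(out))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "agerank_error_parse")
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("%s line %d: %s", path, probs$row[1] + 1L, probs$expected[1]),
          class = "agerank_error_parse")
  }
  for (nm in names(checks)) {
    ok <- checks[[nm]](out)
    if (!all(ok)) {
      abort(sprintf("%s line %d: %s", path, which(!ok)[1] + 1L, nm),
            class = "agerank_error_parse")
    }
  }
  out
}

#' Read the flat annotation tables
#'
#' Five documented TSV schemas, all 1-based coordinates:
#' \describe{
#'   \item{contacts}{`structure_id`, `het_code`, `position` — one row per
#'     ligand-contact residue on the ungapped reference sequence.}
#'   \item{domains}{`member_id`, `start`, `end` — domain intervals on the
#'     ungapped reference sequence of that member.}
#'   \item{compounds}{`het_code`, `name`, `mw`, `logp`, `hbd`, `hba` (or a
#'     precomputed `lipinski_violations` column instead of the four
#'     descriptors), `purchasable`, `approval`, `burns_score` (may be NA),
#'     `n_aging_targets`.}
#'   \item{evidence}{`protein_id`, `category`, `via_orthologue`,
#'     `n_mappings`, `genage`.}
#'   \item{links}{`het_code`, `target_protein_id`, `structure_id`,
#'     `family_id` and exactly one of `kd` (molar) or `log_affinity`; Kd is
#'     converted to log-affinity at read time.}
#' }
#'
#' @param path TSV file.
#' @return A validated tibble.
#' @export
read_contacts_tsv <- function(path) {
  read_checked_tsv(
    path,
    readr::cols(structure_id = readr::col_character(),
                het_code = readr::col_character(),
                position = readr::col_integer()),
    checks = list("position must be >= 1" = function(d) d$position >= 1)
  )
}

#' @rdname read_contacts_tsv
#' @export
read_domains_tsv <- function(path) {
  read_checked_tsv(
    path,
    readr::cols(member_id = readr::col_character(),
                start = readr::col_integer(),
                end = readr::col_integer()),
    checks = list("start must be >= 1" = function(d) d$start >= 1,
                  "start must be <= end" = function(d) d$start <= d$end)
  )
}

#' @rdname read_contacts_tsv
#' @export
read_compounds_tsv <- function(path) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  has_desc <- all(c("mw", "logp", "hbd", "hba") %in% hdr)
  has_count <- "lipinski_violations" %in% hdr
  if (!has_desc && !has_count) {
    abort(sprintf("%s: need either mw/logp/hbd/hba or lipinski_violations.", path),
          class = "agerank_error_parse")
  }
  base <- readr::cols(het_code = readr::col_character(),
                      name = readr::col_character(),
                      purchasable = readr::col_logical(),
                      approval = readr::col_character(),
                      burns_score = readr::col_double(),
                      n_aging_targets = readr::col_integer())
  if (has_desc) {
    base$cols <- c(base$cols, list(mw = readr::col_double(),
                                   logp = readr::col_double(),
                                   hbd = readr::col_integer(),
                                   hba = readr::col_integer()))
  }
  if (has_count) {
    base$cols <- c(base$cols,
                   list(lipinski_violations = readr::col_integer()))
  }
  out <- read_checked_tsv(
    path, base,
    checks = list(
      "het_code must be non-empty" = function(d) nzchar(d$het_code),
      "invalid approval status" = function(d)
        d$approval %in% c("chembl_drug", "drugbank_only", "none"),
      "n_aging_targets must be >= 0" = function(d) d$n_aging_targets >= 0
    )
  )
  if (anyDuplicated(out$het_code)) {
    abort(sprintf("%s: duplicate het_code.", path), class = "agerank_error_parse")
  }
  if (!has_count) {
    out$lipinski_violations <-
      lipinski_violations(out$mw, out$logp, out$hbd, out$hba)
  }
  out
}

#' @rdname read_contacts_tsv
#' @export
read_evidence_tsv <- function(path) {
  read_checked_tsv(
    path,
    readr::cols(protein_id = readr::col_character(),
                category = readr::col_character(),
                via_orthologue = readr::col_logical(),
                n_mappings = readr::col_integer(),
                genage = readr::col_logical()),
    checks = list(
      "invalid evidence category" = function(d) d$category %in% evidence_categories,
      "n_mappings must be >= 0" = function(d) d$n_mappings >= 0
    )
  )
}

#' @rdname read_contacts_tsv
#' @export
read_links_tsv <- function(path) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  if (all(c("kd", "log_affinity") %in% hdr)) {
    abort(sprintf("%s: provide either kd or log_affinity, not both.", path),
          class = "agerank_error_parse")
  }
  if (!any(c("kd", "log_affinity") %in% hdr)) {
    abort(sprintf("%s: need a kd (molar) or log_affinity column.", path),
          class = "agerank_error_parse")
  }
  spec <- readr::cols(het_code = readr::col_character(),
                      target_protein_id = readr::col_character(),
                      structure_id = readr::col_character(),
                      family_id = readr::col_character())
  if ("kd" %in% hdr) {
    spec$cols <- c(spec$cols, list(kd = readr::col_double()))
    checks <- list("kd must be > 0" = function(d) d$kd > 0)
  } else {
    spec$cols <- c(spec$cols, list(log_affinity = readr::col_double()))
    checks <- list("log_affinity must be finite" =
                     function(d) is.finite(d$log_affinity))
  }
  out <- read_checked_tsv(path, spec, checks)
  if ("kd" %in% names(out)) {
    out$log_affinity <- log_affinity_from_kd(out$kd)
    out$kd <- NULL
  }
  out
}

#' Run manifest
#'
#' Digests of the configuration and every input file plus the package
#' version and (for simulated inputs) the seed, so identical inputs can be
#' recognised across reruns.
#'
#' @param config A [ranking_config()].
#' @param input_paths Named character vector of input files.
#' @param seed Optional fixture seed.
#' @return A list with stable digests.
#' @export
run_manifest <- function(config, input_paths = character(0), seed = NULL) {
  files <- NULL
  if (length(input_paths) > 0) {
    files <- as.list(unname(tools::md5sum(input_paths)))
    names(files) <- names(input_paths) %||% basename(input_paths)
  }
  list(tool = "agerank",
       version = as.character(utils::packageVersion("agerank")),
       config_digest = rlang::hash(unclass(config)),
       input_digests = files,
       seed = seed)
}
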