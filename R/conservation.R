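#' Construct an aligned protein family
#'
#' A family bundles one structure-bearing reference sequence with its
#' orthologues/homologues in a single alignment frame. Members are stored as
#' a tibble with columns `member_id`, `species` and `seq` (aligned residue
#' string); the reference is identified by `ref_id`.
#'
#' @param members A data frame with columns `member_id`, `species`, `seq`.
#' @param family_id Family identifier.
#' @param ref_id `member_id` of the reference (structure) sequence.
#' @return An `aligned_family` object (a tibble subclass carrying
#'   `family_id` and `ref_id` attributes).
#' @export
aligned_family <- function(members, family_id, ref_id) {
  members <- as_tibble(members)
  req <- c("member_id", "species", "seq")
  if (!all(req %in% names(members))) {
    abort(paste0("members must have columns: ", paste(req, collapse = ", ")),
          class = "agerank_error_input")
  }
  if (anyDuplicated(members$member_id)) {
    abort("Duplicate member_id in family.", class = "agerank_error_input")
  }
  if (!ref_id %in% members$member_id) {
    abort(sprintf("Reference '%s' not among family members.", ref_id),
          class = "agerank_error_input")
  }
  lens <- nchar(members$seq)
  if (length(unique(lens)) != 1) {
    off <- members$member_id[lens != lens[members$member_id == ref_id]][1]
    abort(sprintf("Ragged alignment in family '%s' (member '%s').",
                  family_id, off),
          class = "agerank_error_frame")
  }
  structure(members, class = c("aligned_family", class(members)),
            family_id = family_id, ref_id = ref_id)
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family '%s'> ref: %s, %d members, %d columns\n",
              attr(x, "family_id"), attr(x, "ref_id"), nrow(x),
              nchar(x$seq[1])))
  NextMethod()
}

family_member_seq <- function(family, member_id) {
  i <- match(member_id, family$member_id)
  if (is.na(i)) {
    abort(sprintf("No member '%s' in family '%s'.", member_id,
                  attr(family, "family_id")),
          class = "agerank_error_input")
  }
  family$seq[i]
}

family_ref_seq <- function(family) family_member_seq(family, attr(family, "ref_id"))

# alignment column of each ungapped reference position
ref_column_map <- function(family) {
  which(!is_gap(aln_chars(family_ref_seq(family))))
}

ref_ungapped_length <- function(family) length(ref_column_map(family))

#' Map binding-site contacts to alignment columns
#'
#' Ligand-contact residues are recorded as 1-based positions on the ungapped
#' reference sequence (PDBsum-style); scoring happens in alignment
#' coordinates, so each contact is translated to the alignment column
#' holding that reference residue.
#'
#' @param family An [aligned_family()].
#' @param positions Integer vector of 1-based contact positions on the
#'   ungapped reference sequence.
#' @return Sorted integer vector of alignment columns, one per contact.
#' @export
contacts_to_columns <- function(family, positions) {
  positions <- as.integer(positions)
  if (length(positions) == 0) return(integer(0))
  map <- ref_column_map(family)
  if (any(positions < 1L | positions > length(map))) {
    abort(sprintf("Contact position outside the reference sequence (length %d).",
                  length(map)),
          class = "agerank_error_contact")
  }
  sort(unique(map[positions]))
}

#' Derive the domain-conservation scoring regions
#'
#' The regions over which domain conservation is measured are (a) every
#' annotated domain interval containing at least one ligand contact, plus
#' (b) for each contact falling outside all annotated domains, a window of
#' +/- `window` residues around the contact, clipped to the sequence. The
#' union is merged (adjacent intervals included) into a sorted disjoint
#' list.
#'
#' @param contacts Integer vector of 1-based contact positions (ungapped
#'   reference coordinates).
#' @param domains Data frame with columns `start`, `end` (1-based inclusive
#'   intervals on the ungapped reference); may have zero rows.
#' @param seq_length Ungapped reference length used for clipping.
#' @param window Half-width of the fallback window in residues (default 50).
#' @return A tibble with columns `start`, `end`: sorted, disjoint,
#'   non-adjacent intervals.
#' @examples
#' scoring_regions(c(200), data.frame(start = integer(), end = integer()), 300)
#' @export
scoring_regions <- function(contacts, domains, seq_length, window = 50) {
  if (window < 0) abort("window must be >= 0.", class = "agerank_error_param")
  contacts <- as.integer(contacts)
  domains <- as_tibble(domains)
  if (nrow(domains) > 0 &&
      (any(domains$start > domains$end) || any(domains$start < 1) ||
       any(domains$end > seq_length))) {
    abort("Malformed domain interval.", class = "agerank_error_input")
  }
  hit <- domains[purrr::map_lgl(seq_len(nrow(domains)), function(i) {
    any(contacts >= domains$start[i] & contacts <= domains$end[i])
  }), , drop = FALSE]
  in_domain <- purrr::map_lgl(contacts, function(p) {
    nrow(domains) > 0 && any(p >= domains$start & p <= domains$end)
  })
  windows <- tibble(
    start = pmax(1L, contacts[!in_domain] - as.integer(window)),
    end = pmin(as.integer(seq_length), contacts[!in_domain] + as.integer(window))
  )
  merge_intervals(bind_rows(hit[c("start", "end")], windows))
}

# merge sorted 1-based inclusive intervals; adjacent (gap 0) intervals fuse
merge_intervals <- function(iv) {
  iv <- as_tibble(iv)
  if (nrow(iv) == 0) return(tibble(start = integer(0), end = integer(0)))
  iv <- arrange(iv, .data$start, .data$end)
  out_s <- iv$start[1]; out_e <- iv$end[1]
  res_s <- integer(0); res_e <- integer(0)
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out_e + 1L) {
      out_e <- max(out_e, iv$end[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- iv$start[i]; out_e <- iv$end[i]
    }
  }
  tibble(start = as.integer(c(res_s, out_s)), end = as.integer(c(res_e, out_e)))
}

# alignment columns covered by regions given in ungapped ref coordinates
regions_to_columns <- function(family, regions) {
  map <- ref_column_map(family)
  pos <- unlist(purrr::map2(regions$start, regions$end, seq), use.names = FALSE)
  pos <- pos[pos >= 1 & pos <= length(map)]
  sort(unique(map[pos]))
}

#' Domain-conservation factor
#'
#' Grantham-based pairwise similarity between the reference and a family
#' member, restricted to the alignment columns of the scoring regions, then
#' passed through a logistic transform centred at `location` with steepness
#' `scale`. The logistic emphasises differences at medium similarity, where
#' they matter most for conserved binding.
#'
#' @param family An [aligned_family()].
#' @param member_id Member to compare against the reference.
#' @param regions Interval tibble from [scoring_regions()]; must be
#'   non-empty.
#' @param location,scale Logistic parameters (defaults 0.6 and 0.1).
#' @return Factor in \eqn{(0, 1)}.
#' @export
domain_conservation <- function(family, member_id, regions,
                                location = 0.6, scale = 0.1) {
  regions <- as_tibble(regions)
  if (nrow(regions) == 0) {
    abort("Empty scoring-region set; domain conservation undefined.",
          class = "agerank_error_empty_region")
  }
  cols <- regions_to_columns(family, regions)
  sim <- pairwise_similarity(family_ref_seq(family),
                             family_member_seq(family, member_id),
                             columns = cols)
  logistic(sim, location, scale)
}

# per-column reference-vs-member similarities at the site columns;
# member gap scores 0
site_column_similarities <- function(family, member_id, site_columns) {
  r <- aln_chars(family_ref_seq(family))
  h <- aln_chars(family_member_seq(family, member_id))
  cols <- as.integer(site_columns)
  if (any(is_gap(r[cols]))) {
    abort("Site column falls on a reference gap.", class = "agerank_error_contact")
  }
  sims <- numeric(length(cols))
  ok <- !is_gap(h[cols])
  if (any(ok)) sims[ok] <- grantham_similarity(r[cols][ok], h[cols][ok])
  sims
}

#' Binding-site conservation factor
#'
#' Mean Grantham similarity over the 50% most dissimilar binding-site
#' positions (reference vs member). Because most binding sites are largely
#' identical, averaging only the worst half increases the sensitivity of
#' the factor. With `N` site columns, `k = max(1, floor(N/2))` lowest
#' per-column similarities are averaged (`k_mode = "ceil"` rounds up
#' instead).
#'
#' @inheritParams domain_conservation
#' @param site_columns Alignment columns of the binding site (from
#'   [contacts_to_columns()]); must be non-empty.
#' @param k_mode `"floor"` (default) or `"ceil"` rounding of N/2.
#' @return Factor in \eqn{[0, 1]}.
#' @export
binding_site_conservation <- function(family, member_id, site_columns,
                                      k_mode = c("floor", "ceil")) {
  k_mode <- match.arg(k_mode)
  if (length(site_columns) == 0) {
    abort("Empty binding site; conservation undefined.",
          class = "agerank_error_empty_region")
  }
  sims <- site_column_similarities(family, member_id, site_columns)
  n <- length(sims)
  k <- max(1L, if (k_mode == "floor") floor(n / 2) else ceiling(n / 2))
  mean(sort(sims)[seq_len(k)])
}

site_gap_count <- function(family, member_id, site_columns) {
  h <- aln_chars(family_member_seq(family, member_id))
  sum(is_gap(h[as.integer(site_columns)]))
}

#' Select the representative homologue of a species
#'
#' Within one family and species, the member used for scoring is the one
#' with the fewest gaps at the binding-site columns; ties are broken by
#' highest binding-site similarity, then highest binding-site identity,
#' then lexicographic `member_id`.
#'
#' @inheritParams binding_site_conservation
#' @param species Species tag to select within.
#' @return The winning `member_id`.
#' @export
select_homologue <- function(family, species, site_columns) {
  cand <- family$member_id[family$species == species]
  if (length(cand) == 0) {
    abort(sprintf("No member of species '%s' in family '%s'.", species,
                  attr(family, "family_id")),
          class = "agerank_error_species_absent")
  }
  ref <- family_ref_seq(family)
  stats <- tibble(
    member_id = cand,
    gaps = map_dbl(cand, ~ site_gap_count(family, .x, site_columns)),
    sim = map_dbl(cand, ~ mean(site_column_similarities(family, .x, site_columns))),
    ident = map_dbl(cand, ~ pairwise_identity(ref, family_member_seq(family, .x),
                                              columns = site_columns))
  )
  stats <- arrange(stats, .data$gaps, desc(.data$sim), desc(.data$ident),
                   .data$member_id)
  stats$member_id[1]
}

#' Identity percentages for reporting
#'
#' `global_identity()` is the pairwise identity between reference and member
#' over all non-gap reference columns; `site_identity()` restricts to the
#' binding-site columns. Both are reported as whole percents (display
#' convention of the ranking tables).
#'
#' @inheritParams binding_site_conservation
#' @return Percent, rounded to the nearest integer.
#' @export
global_identity <- function(family, member_id) {
  round(100 * pairwise_identity(family_ref_seq(family),
                                family_member_seq(family, member_id)))
}

#' @rdname global_identity
#' @export
site_identity <- function(family, member_id, site_columns) {
  round(100 * pairwise_identity(family_ref_seq(family),
                                family_member_seq(family, member_id),
                                columns = as.integer(site_columns)))
}
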