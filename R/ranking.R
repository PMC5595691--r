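#' Rank compounds by final score
#'
#' Stable sort by decreasing final score, ties broken by ascending HET
#' code; ranks are unique and contiguous from 1 (tied compounds receive
#' distinct consecutive ranks, so statements like "ranked 395th" are
#' well defined).
#'
#' @param breakdowns A data frame with one row per compound: a `het_code`
#'   column, the `score_breakdown` columns (see [composite_score()]), and
#'   optionally `name`, `targets`, `global_identity`, `site_identity`.
#' @return A `compound_ranking` tibble with a leading `rank` column.
#' @export
rank_compounds <- function(breakdowns) {
  breakdowns <- as_tibble(breakdowns)
  if (nrow(breakdowns) == 0) {
    out <- mutate(breakdowns, rank = integer(0), .before = 1)
    class(out) <- c("compound_ranking", class(out))
    return(out)
  }
  if (!all(c("het_code", "final") %in% names(breakdowns))) {
    abort("breakdowns must have het_code and final columns.",
          class = "agerank_error_input")
  }
  if (anyDuplicated(breakdowns$het_code)) {
    abort("Duplicate het_code in breakdowns.", class = "agerank_error_input")
  }
  if (any(!is.finite(breakdowns$final))) {
    abort("Non-finite final score.", class = "agerank_error_input")
  }
  out <- arrange(breakdowns, desc(.data$final), .data$het_code)
  out <- mutate(out, rank = row_number(), .before = 1)
  class(out) <- c("compound_ranking", class(out))
  out
}

#' Score-distribution cutoffs
#'
#' The two reference lines of the score density plots: the score of the
#' compound at rank 15 (or the last rank when fewer than 15 are ranked) and
#' the score at the top-10% boundary, rank `max(1, floor(N/10))`.
#'
#' @param ranking A `compound_ranking` from [rank_compounds()].
#' @return A one-row tibble with `top15_cutoff` and `top10pct_cutoff`.
#' @export
score_cutoffs <- function(ranking) {
  if (nrow(ranking) == 0) {
    abort("Empty ranking has no cutoffs.", class = "agerank_error_input")
  }
  s <- ranking$final[order(ranking$rank)]
  n <- length(s)
  tibble(top15_cutoff = s[min(15L, n)],
         top10pct_cutoff = s[max(1L, floor(n / 10))])
}

ranking_display_columns <- c(
  "rank", "het_code", "name", "targets", "global_identity", "site_identity",
  "aging", "domain_cons", "site_cons", "affinity", "bioavailability",
  "lipinski_loss", "promiscuity_loss", "purchase_bonus", "approval_bonus",
  "final"
)

# fill the optional display columns so every renderer sees the full set
complete_entry <- function(entry) {
  defaults <- list(name = NA_character_, targets = NA_character_,
                   global_identity = NA_real_, site_identity = NA_real_)
  for (nm in names(defaults)) {
    if (!nm %in% names(entry)) entry[[nm]] <- defaults[[nm]]
  }
  entry[ranking_display_columns]
}

#' Render a per-compound report card
#'
#' A report card lists the rank, targets, conservation percentages, every
#' factor and term, and the final score of one ranked compound. Three
#' formats: `"json"` (machine-readable, unrounded score to 6 decimals, and
#' a byte-stable round trip), `"html"` (a small static card with values
#' displayed at 2 decimals), and `"tsv-row"` (one tab-separated row with
#' the 16 ranking-table columns).
#'
#' @param entry A single row of a `compound_ranking`.
#' @param fmt Output format.
#' @return A character scalar holding the document.
#' @export
render_report_card <- function(entry, fmt = c("json", "html", "tsv-row")) {
  fmt <- match.arg(fmt)
  entry <- as_tibble(entry)
  if (nrow(entry) != 1) {
    abort("Report cards are rendered one entry at a time.",
          class = "agerank_error_input")
  }
  entry <- complete_entry(entry)
  switch(fmt,
    json = {
      x <- as.list(entry)
      x$final_display <- round_display(entry$final)
      x$final <- round(entry$final, 6)
      jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
    },
    html = {
      num <- function(v) sprintf("%.2f", round_display(v))
      rows <- c(
        sprintf("<tr><th>Rank</th><td>%d</td></tr>", entry$rank),
        sprintf("<tr><th>HET code</th><td>%s</td></tr>", entry$het_code),
        sprintf("<tr><th>Name</th><td>%s</td></tr>", entry$name),
        sprintf("<tr><th>Targets</th><td>%s</td></tr>", entry$targets),
        sprintf("<tr><th>Global identity</th><td>%s%%</td></tr>",
                entry$global_identity),
        sprintf("<tr><th>Binding-site identity</th><td>%s%%</td></tr>",
                entry$site_identity),
        sprintf("<tr><th>Aging implication</th><td>%s</td></tr>", num(entry$aging)),
        sprintf("<tr><th>Domain conservation</th><td>%s</td></tr>",
                num(entry$domain_cons)),
        sprintf("<tr><th>Binding-site conservation</th><td>%s</td></tr>",
                num(entry$site_cons)),
        sprintf("<tr><th>Binding affinity</th><td>%s</td></tr>",
                num(entry$affinity)),
        sprintf("<tr><th>Bioavailability</th><td>%s</td></tr>",
                num(entry$bioavailability)),
        sprintf("<tr><th>Lipinski loss</th><td>%s</td></tr>",
                num(entry$lipinski_loss)),
        sprintf("<tr><th>Promiscuity loss</th><td>%s</td></tr>",
                num(entry$promiscuity_loss)),
        sprintf("<tr><th>Purchasability bonus</th><td>%s</td></tr>",
                num(entry$purchase_bonus)),
        sprintf("<tr><th>Drug approval bonus</th><td>%s</td></tr>",
                num(entry$approval_bonus)),
        sprintf("<tr><th>Final score</th><td><b>%s</b></td></tr>",
                num(entry$final))
      )
      paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
             sprintf("<title>Report card %s</title>", entry$het_code),
             "</head><body>",
             sprintf("<h1>%s</h1>", entry$het_code),
             "<table>", paste(rows, collapse = ""), "</table>",
             "</body></html>\n")
    },
    `tsv-row` = {
      vals <- purrr::map_chr(as.list(entry), function(v) {
        if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
      })
      paste(vals, collapse = "\t")
    }
  )
}

#' Write and read a ranking as TSV
#'
#' Full-precision (17 significant digits) lossless round trip of every
#' ranking column, including the display columns; an empty ranking writes a
#' header-only file.
#'
#' @param ranking A `compound_ranking`.
#' @param path File path.
#' @return `write_ranking_tsv()` returns `path` invisibly;
#'   `read_ranking_tsv()` returns the `compound_ranking`.
#' @export
write_ranking_tsv <- function(ranking, path) {
  out <- as_tibble(ranking)
  if (nrow(out) > 0) out <- complete_entry(out) else {
    for (nm in setdiff(ranking_display_columns, names(out))) {
      out[[nm]] <- character(0)
    }
    out <- out[ranking_display_columns]
  }
  num <- purrr::map_lgl(out, is.numeric)
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_ranking_tsv
#' @export
read_ranking_tsv <- function(path) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(ranking_display_columns, hdr)
  if (length(missing) > 0) {
    abort(sprintf("line 1: missing ranking column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "agerank_error_parse")
  }
  types <- readr::cols(
    rank = readr::col_integer(), het_code = readr::col_character(),
    name = readr::col_character(), targets = readr::col_character(),
    .default = readr::col_double()
  )
  out <- readr::read_tsv(path, col_types = types, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("line %d: %s", probs$row[1] + 1L, probs$expected[1]),
          class = "agerank_error_parse")
  }
  class(out) <- c("compound_ranking", class(out))
  out
}

#' Score density plot
#'
#' Density of final scores with the top-15 cutoff (dashed) and top-10%
#' cutoff (dotted) marked, the summary view used to compare score
#' distributions between species.
#'
#' @param ranking A `compound_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_score_density <- function(ranking, ...) {
  cuts <- score_cutoffs(ranking)
  ggplot2::ggplot(as_tibble(ranking), ggplot2::aes(x = .data$final)) +
    ggplot2::geom_density(fill = "grey85") +
    ggplot2::geom_vline(xintercept = cuts$top15_cutoff, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = cuts$top10pct_cutoff, linetype = "dotted") +
    ggplot2::labs(x = "Final ranking score", y = "Density") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname plot_score_density
#' @param object A `compound_ranking`.
#' @export
autoplot.compound_ranking <- function(object, ...) {
  plot_score_density(object, ...)
}

#' Broom-style accessors for rankings
#'
#' `tidy()` returns one row per ranked compound with the rank, identifiers
#' and all score components; `glance()` returns a one-row summary (number
#' ranked, score range, the two distribution cutoffs).
#'
#' @param x A `compound_ranking`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.compound_ranking <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "compound_ranking")
  out
}

#' @rdname tidy.compound_ranking
#' @export
glance.compound_ranking <- function(x, ...) {
  cuts <- if (nrow(x) > 0) score_cutoffs(x) else
    tibble(top15_cutoff = NA_real_, top10pct_cutoff = NA_real_)
  tibble(n_ranked = nrow(x),
         min_score = if (nrow(x)) min(x$final) else NA_real_,
         max_score = if (nrow(x)) max(x$final) else NA_real_,
         top15_cutoff = cuts$top15_cutoff,
         top10pct_cutoff = cuts$top10pct_cutoff)
}
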