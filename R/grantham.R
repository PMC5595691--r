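#' Grantham-based residue similarity
#'
#' The Grantham (1974) distance measures the physicochemical difference
#' between two amino acids (composition, polarity, molecular volume), with a
#' maximum of 215 across the 20x20 matrix. Similarity is the distance scaled
#' to \eqn{[0, 1]}: \eqn{sim(a, b) = 1 - d(a, b) / 215}. The ambiguity codes
#' are resolved by averaging: B over \{D, N\}, Z over \{Q, E\}, X over all
#' 20 standard residues (both sides of a pair are expanded, so e.g.
#' \code{sim("B", "B")} averages the four D/N cross pairs).
#'
#' @param a,b Character vectors of single-letter residue codes (recycled to a
#'   common length). Case-insensitive. The 20 standard codes plus B, Z and X
#'   are accepted; anything else (including gaps) is an error.
#' @return Numeric vector of similarities in \eqn{[0, 1]}.
#' @examples
#' grantham_similarity("A", "A")
#' grantham_similarity("Y", "H")  # 1 - 83/215
#' @export
grantham_similarity <- function(a, b) {
  m <- grantham_similarity_matrix()
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  bad <- unique(c(a, b)[!c(a, b) %in% rownames(m)])
  if (length(bad) > 0) {
    abort(
      paste0("Invalid residue code(s): ", paste(bad, collapse = ", "),
             ". Allowed: 20 standard codes plus B, Z, X."),
      class = "agerank_error_residue"
    )
  }
  m[cbind(a, b)]
}

#' The 20x20 Grantham distance matrix
#'
#' Returns the published pairwise amino-acid distance table (symmetric,
#' zero diagonal, maximum 215 for C-W), read from the TSV vendored with the
#' package.
#'
#' @return A 20x20 numeric matrix with standard one-letter row/column names.
#' @export
grantham_distance_matrix <- function() {
  if (is.null(the$grantham_distance)) {
    path <- system.file("extdata", "grantham_distance.tsv", package = "agerank",
                        mustWork = TRUE)
    m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
    stopifnot(identical(rownames(m), colnames(m)), isTRUE(all(m == t(m))))
    the$grantham_distance <- m
  }
  the$grantham_distance
}

# expansion sets for the ambiguity codes
ambiguity_sets <- function() {
  std <- rownames(grantham_distance_matrix())
  list(B = c("D", "N"), Z = c("Q", "E"), X = std)
}

#' The extended Grantham similarity matrix
#'
#' The 23x23 similarity lookup (20 standard residues plus B, Z, X) derived
#' from [grantham_distance_matrix()] as \eqn{1 - d/215}, with ambiguity rows
#' and columns filled by averaging over their expansion sets.
#'
#' @return A symmetric 23x23 numeric matrix with unit diagonal on the 20
#'   standard codes and all entries in \eqn{[0, 1]}.
#' @export
grantham_similarity_matrix <- function() {
  if (is.null(the$grantham_similarity)) {
    d <- grantham_distance_matrix()
    std <- rownames(d)
    sim <- 1 - d / 215
    amb <- ambiguity_sets()
    codes <- c(std, names(amb))
    full <- matrix(NA_real_, length(codes), length(codes),
                   dimnames = list(codes, codes))
    full[std, std] <- sim
    expand <- c(setNames(as.list(std), std), amb)
    for (x in names(amb)) {
      for (y in codes) {
        full[x, y] <- full[y, x] <- mean(sim[expand[[x]], expand[[y]]])
      }
    }
    the$grantham_similarity <- full
  }
  the$grantham_similarity
}

#' Read and write a similarity matrix as TSV
#'
#' Plain TSV with row names in the first column; `write_similarity_matrix()`
#' prints full double precision (17 significant digits) so a
#' write-then-read round trip is bit-exact.
#'
#' @param m A square named numeric matrix.
#' @param path File path.
#' @return `read_similarity_matrix()` returns the matrix;
#'   `write_similarity_matrix()` returns `path` invisibly.
#' @export
write_similarity_matrix <- function(m, path) {
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  lines <- c(paste(c("", colnames(m)), collapse = "\t"),
             paste(rownames(m), txt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}

# split an aligned sequence into upper-case residue characters
aln_chars <- function(x) {
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

is_gap <- function(ch) ch == "-" | ch == "."

# shared validation for the aligned-pair operations
check_aligned_pair <- function(ref, hom, columns) {
  r <- aln_chars(ref)
  h <- aln_chars(hom)
  if (length(r) != length(h)) {
    abort(
      sprintf("Aligned sequences differ in length (%d vs %d); not in a common frame.",
              length(r), length(h)),
      class = "agerank_error_frame"
    )
  }
  if (is.null(columns)) {
    columns <- seq_along(r)
  } else {
    columns <- as.integer(columns)
    if (any(columns < 1L | columns > length(r))) {
      abort("Column indices outside the alignment.", class = "agerank_error_frame")
    }
  }
  list(ref = r, hom = h, columns = columns)
}

#' Pairwise identity and similarity over aligned sequences
#'
#' Both operate column-wise on two sequences in a common alignment frame.
#' Columns where the reference carries a gap are dropped from the
#' denominator; a gap in the homologue counts as a mismatch (identity 0,
#' similarity 0) — deletions at considered positions are penalised, not
#' skipped.
#'
#' @param ref_aligned,hom_aligned Aligned residue strings of equal length
#'   (gaps as `-` or `.`).
#' @param columns Optional integer vector of alignment columns to restrict
#'   to; default all columns.
#' @return `pairwise_identity()`: fraction of considered columns with
#'   identical non-gap residues. `pairwise_similarity()`: arithmetic mean of
#'   per-column Grantham similarity. Both in \eqn{[0, 1]}.
#' @examples
#' pairwise_identity("ACDEF", "ACD-F")   # 0.8
#' pairwise_similarity("YY", "HH")       # mean Y-H similarity
#' @export
pairwise_identity <- function(ref_aligned, hom_aligned, columns = NULL) {
  p <- check_aligned_pair(ref_aligned, hom_aligned, columns)
  keep <- p$columns[!is_gap(p$ref[p$columns])]
  if (length(keep) == 0) {
    abort("No non-gap reference columns to compare.", class = "agerank_error_empty_region")
  }
  mean(p$ref[keep] == p$hom[keep] & !is_gap(p$hom[keep]))
}

#' @rdname pairwise_identity
#' @export
pairwise_similarity <- function(ref_aligned, hom_aligned, columns = NULL) {
  p <- check_aligned_pair(ref_aligned, hom_aligned, columns)
  keep <- p$columns[!is_gap(p$ref[p$columns])]
  if (length(keep) == 0) {
    abort("No non-gap reference columns to compare.", class = "agerank_error_empty_region")
  }
  sims <- numeric(length(keep))
  ok <- !is_gap(p$hom[keep])
  if (any(ok)) {
    sims[ok] <- grantham_similarity(p$ref[keep][ok], p$hom[keep][ok])
  }
  mean(sims)
}
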