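# small in-code fixtures shared across test files

toy_family <- function(ref = "ACDEFGHIKL", members = NULL) {
  members <- members %||% list(
    worm1 = list(species = "celegans", seq = ref),
    fly1 = list(species = "dmelanogaster", seq = ref)
  )
  tbl <- tibble::tibble(
    member_id = c("ref", names(members)),
    species = c("hsapiens", vapply(members, `[[`, "", "species")),
    seq = c(ref, vapply(members, `[[`, "", "seq"))
  )
  aligned_family(tbl, family_id = "toy", ref_id = "ref")
}

# replace characters of a sequence string at given positions
subst <- function(seq, pos, chars) {
  s <- strsplit(seq, "")[[1]]
  s[pos] <- chars
  paste(s, collapse = "")
}

`%||%` <- rlang::`%||%`
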