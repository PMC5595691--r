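test_that("contacts map to the alignment columns of the reference", {
  fam <- toy_family(ref = "AC-DE",
                    members = list(worm1 = list(species = "celegans",
                                                seq = "ACQDE")))
  # 1-based residue 3 of the ungapped reference (D) sits in column 4
  expect_equal(contacts_to_columns(fam, 3), 4L)
  gapless <- toy_family()
  expect_equal(contacts_to_columns(gapless, c(1, 5)), c(1L, 5L))
  expect_equal(contacts_to_columns(gapless, integer(0)), integer(0))
  expect_error(contacts_to_columns(fam, 5), class = "agerank_error_contact")
})

test_that("scoring regions union contact-bearing domains and fallback windows", {
  no_dom <- tibble::tibble(start = integer(0), end = integer(0))
  expect_equal(scoring_regions(c(10, 20), tibble::tibble(start = 1, end = 100),
                               300),
               tibble::tibble(start = 1L, end = 100L))
  expect_equal(scoring_regions(200, no_dom, 300),
               tibble::tibble(start = 150L, end = 250L))
  # mixed rule: domain hit plus an out-of-domain window, clipped and sorted
  expect_equal(scoring_regions(c(30, 400), tibble::tibble(start = 1, end = 50),
                               500),
               tibble::tibble(start = c(1L, 350L), end = c(50L, 450L)))
  # clipping at both sequence ends
  expect_equal(scoring_regions(c(10, 295), no_dom, 300),
               tibble::tibble(start = c(1L, 245L), end = c(60L, 300L)))
  # overlapping and adjacent pieces merge; contact order is irrelevant
  a <- scoring_regions(c(100, 140, 260), no_dom, 400)
  b <- scoring_regions(c(260, 100, 140), no_dom, 400)
  expect_equal(a, b)
  expect_equal(a, tibble::tibble(start = c(50L, 210L), end = c(190L, 310L)))
  expect_true(all(a$start[-1] > a$end[-nrow(a)] + 1))
})

test_that("domain conservation is the logistic of region similarity", {
  n <- 100
  ref <- paste(rep("A", n), collapse = "")
  regions <- tibble::tibble(start = 1, end = n)
  # identical member: similarity 1 -> 1/(1+e^-4)
  fam <- toy_family(ref = ref, members = list(w = list(species = "celegans",
                                                       seq = ref)))
  expect_equal(domain_conservation(fam, "w", regions), 1 / (1 + exp(-4)))
  # all-gap member: similarity 0 -> 1/(1+e^6)
  fam0 <- toy_family(ref = ref,
                     members = list(w = list(species = "celegans",
                                             seq = paste(rep("-", n),
                                                         collapse = ""))))
  expect_equal(domain_conservation(fam0, "w", regions), 1 / (1 + exp(6)))
  expect_error(domain_conservation(fam, "w",
                                   tibble::tibble(start = integer(0),
                                                  end = integer(0))),
               class = "agerank_error_empty_region")
})

test_that("domain conservation increases strictly with region similarity", {
  n <- 50
  ref <- paste(rep("A", n), collapse = "")
  regions <- tibble::tibble(start = 1, end = n)
  vals <- vapply(c(0, 10, 20, 30, 40), function(k) {
    hom <- subst(ref, seq_len(max(k, 1))[seq_len(k)], rep("W", k))
    fam <- toy_family(ref = ref, members = list(w = list(species = "celegans",
                                                         seq = hom)))
    domain_conservation(fam, "w", regions)
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("binding-site conservation averages the worst half of the site", {
  ref <- "AAAAAAAAAAA"
  # one Y->H style change in an 11-residue site: k = 5, (sim + 4)/5
  fam <- toy_family(ref = subst(ref, 1, "Y"),
                    members = list(w = list(species = "celegans",
                                            seq = subst(ref, 1, "H"))))
  expect_equal(binding_site_conservation(fam, "w", 1:11),
               (1 - 83 / 215 + 4) / 5)
  expect_equal(binding_site_conservation(fam, "w", 1:11, k_mode = "ceil"),
               (1 - 83 / 215 + 5) / 6)
  # fully conserved site
  fam1 <- toy_family(ref = "AAAA")
  expect_equal(binding_site_conservation(fam1, "worm1", 1:4), 1)
  # single-residue site still defined (k floors at 1)
  expect_equal(binding_site_conservation(fam1, "worm1", 2), 1)
  expect_error(binding_site_conservation(fam1, "worm1", integer(0)),
               class = "agerank_error_empty_region")
})

test_that("worst-half mean never exceeds the full site mean", {
  set.seed(7)
  std <- rownames(grantham_distance_matrix())
  for (i in 1:20) {
    n <- sample(4:20, 1)
    ref <- paste(sample(std, n, TRUE), collapse = "")
    hom <- paste(sample(c(std, "-"), n, TRUE), collapse = "")
    fam <- toy_family(ref = ref, members = list(w = list(species = "celegans",
                                                         seq = hom)))
    full_mean <- mean(vapply(seq_len(n), function(j) {
      h <- substr(hom, j, j)
      if (h == "-") 0 else grantham_similarity(substr(ref, j, j), h)
    }, 0))
    expect_lte(binding_site_conservation(fam, "w", seq_len(n)),
               full_mean + 1e-12)
  }
})

test_that("homologue selection minimises site gaps with documented tie-breaks", {
  ref <- "ACDEFGHIKL"
  fam <- toy_family(ref = ref, members = list(
    m1 = list(species = "celegans", seq = ref),
    m2 = list(species = "celegans", seq = subst(ref, c(1, 2), c("-", "-")))
  ))
  expect_equal(select_homologue(fam, "celegans", 1:5), "m1")
  # equal gaps: higher site similarity wins
  fam2 <- toy_family(ref = ref, members = list(
    m1 = list(species = "celegans", seq = subst(ref, 1, "W")),  # A->W harsh
    m2 = list(species = "celegans", seq = subst(ref, 1, "S"))   # A->S mild
  ))
  expect_equal(select_homologue(fam2, "celegans", 1:5), "m2")
  # equal gaps and similarity: lexicographic id
  fam3 <- toy_family(ref = ref, members = list(
    b = list(species = "celegans", seq = ref),
    a = list(species = "celegans", seq = ref)
  ))
  expect_equal(select_homologue(fam3, "celegans", 1:5), "a")
  # invariant to member order
  fam3r <- toy_family(ref = ref, members = list(
    a = list(species = "celegans", seq = ref),
    b = list(species = "celegans", seq = ref)
  ))
  expect_equal(select_homologue(fam3, "celegans", 1:5),
               select_homologue(fam3r, "celegans", 1:5))
  expect_error(select_homologue(fam, "dmelanogaster", 1:5),
               class = "agerank_error_species_absent")
})

test_that("identity percentages are reported as rounded percents", {
  ref <- paste(rep("A", 10), collapse = "")
  fam <- toy_family(ref = ref, members = list(
    w = list(species = "celegans", seq = subst(ref, 1, "C"))
  ))
  expect_equal(global_identity(fam, "w"), 90)
  expect_equal(site_identity(fam, "w", 1:10), 90)
  expect_equal(site_identity(fam, "w", 2:10), 100)
  fam_id <- toy_family(ref = ref)
  expect_equal(global_identity(fam_id, "worm1"), 100)
})

test_that("family construction validates frame and membership", {
  bad <- tibble::tibble(member_id = c("a", "b"),
                        species = c("hsapiens", "celegans"),
                        seq = c("ACDE", "ACD"))
  expect_error(aligned_family(bad, "f", "a"), class = "agerank_error_frame")
  expect_error(aligned_family(bad[1, ], "f", "zz"),
               class = "agerank_error_input")
  dup <- tibble::tibble(member_id = c("a", "a"),
                        species = c("hsapiens", "celegans"),
                        seq = c("ACDE", "ACDE"))
  expect_error(aligned_family(dup, "f", "a"), class = "agerank_error_input")
})
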