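test_that("logistic transform has midpoint 0.5 and validates its scale", {
  expect_equal(logistic(0.6, 0.6, 0.1), 0.5)
  expect_equal(logistic(7, 7, 1), 0.5)
  expect_equal(logistic(7, 5, 1), 1 / (1 + exp(-2)))
  expect_error(logistic(1, 0, 0), class = "agerank_error_param")
  expect_error(logistic(1, 0, -1), class = "agerank_error_param")
})

test_that("GO evidence scores follow the category table and GenAge override", {
  expect_equal(go_evidence_score("experimental"), 0.01)
  expect_equal(go_evidence_score("experimental", via_orthologue = TRUE), 0.02)
  expect_equal(go_evidence_score("computational"), 0.15)
  expect_equal(go_evidence_score("computational", via_orthologue = TRUE), 0.16)
  expect_equal(go_evidence_score("author_curator"), 0.16)
  expect_equal(go_evidence_score("author_curator", via_orthologue = TRUE), 0.16)
  expect_equal(go_evidence_score("automatic_or_none"), 0.28)
  expect_equal(go_evidence_score("automatic_or_none", via_orthologue = TRUE),
               0.29)
  # GenAge forces the strongest score regardless of category
  expect_equal(go_evidence_score("automatic_or_none", TRUE, genage = TRUE),
               0.01)
  expect_error(go_evidence_score("anecdotal"), class = "agerank_error_input")
})

test_that("aging implication follows the configured formula reading", {
  expect_equal(aging_implication(0, 0), 1)
  expect_equal(aging_implication(0.01, 0), 0.995)
  expect_equal(aging_implication(0.01, 1), 0.945)
  # alternative reading
  expect_equal(aging_implication(0.01, 1, formula = "half_mappings"),
               1 - 0.01 - 0.05)
  # floored at zero for extreme mapping chains
  expect_equal(aging_implication(1, 50), 0)
  expect_error(aging_implication(1.2, 0), class = "agerank_error_input")
})

test_that("affinity factors reproduce the reference two-decimal values", {
  # frozen closed forms for the five reported dissociation constants
  kd_nm <- c(100, 23, 35, 63, 120)
  expected <- c(0.88, 0.93, 0.92, 0.9, 0.87)
  got <- affinity_factor(log_affinity_from_kd(kd_nm * 1e-9))
  expect_equal(round(got, 2), expected)
  expect_equal(affinity_factor(log_affinity_from_kd(1e-3)),
               1 / (1 + exp(2)))
  expect_error(log_affinity_from_kd(0), class = "agerank_error_input")
  expect_error(log_affinity_from_kd(-1e-9), class = "agerank_error_input")
  expect_error(affinity_factor(Inf), class = "agerank_error_input")
})

test_that("affinity decreases strictly with Kd", {
  kd <- 10^seq(-9, -3, length.out = 20)
  expect_true(all(diff(affinity_factor(log_affinity_from_kd(kd))) < 0))
})

test_that("bioavailability is predictor-scaled for worm, constant for fly", {
  expect_equal(bioavailability_factor("dmelanogaster"), 0.9)
  expect_equal(bioavailability_factor("celegans", burns_score = 4), 0.6)
  expect_equal(bioavailability_factor("celegans", burns_score = 1e6), 1)
  expect_gt(bioavailability_factor("celegans", burns_score = -1e6), 0.2 - 1e-9)
  expect_error(bioavailability_factor("celegans"),
               class = "agerank_error_missing_input")
  expect_error(bioavailability_factor("celegans", burns_score = NA_real_),
               class = "agerank_error_missing_input")
})

test_that("Lipinski violations and loss apply the boundary conventions", {
  expect_equal(lipinski_violations(400, 3, 2, 5), 0)
  expect_equal(lipinski_violations(600, 6, 6, 11), 4)
  # boundary: only the molecular-weight rule fires at equality
  expect_equal(lipinski_violations(500, 5, 5, 10), 1)
  expect_equal(lipinski_loss(0), 0)
  expect_equal(lipinski_loss(2), -0.1)
  expect_equal(lipinski_loss(3), -0.15)
  expect_error(lipinski_loss(-1), class = "agerank_error_input")
})

test_that("promiscuity loss is a scaled logistic in the target count", {
  expect_equal(promiscuity_loss(7), -0.1)
  expect_equal(promiscuity_loss(1), -1 / (1 + exp(6)) / 5)
  expect_equal(promiscuity_loss(1e6), -0.2)
  expect_true(all(diff(promiscuity_loss(0:20)) < 0))
  expect_error(promiscuity_loss(-1), class = "agerank_error_input")
})

test_that("purchase and approval bonuses take their documented values", {
  expect_equal(purchase_bonus(TRUE), 0.1)
  expect_equal(purchase_bonus(FALSE), 0)
  expect_equal(approval_bonus("chembl_drug"), 0.1)
  expect_equal(approval_bonus("drugbank_only"), 0.075)
  expect_equal(approval_bonus("none"), 0)
  expect_error(approval_bonus("fda"), class = "agerank_error_input")
})

test_that("multi-target aggregation is an element-wise maximum", {
  one <- tibble::tibble(domain_cons = 0.9, site_cons = 0.8, affinity = 0.7)
  expect_equal(aggregate_targets(one), one)
  two <- tibble::tibble(domain_cons = c(0.9, 0.8), site_cons = c(0.8, 0.9),
                        affinity = c(0.7, 0.9), aging = c(1, 0.9))
  agg <- aggregate_targets(two)
  expect_equal(agg$domain_cons, 0.9)
  expect_equal(agg$site_cons, 0.9)
  expect_equal(agg$affinity, 0.9)
  expect_equal(agg$aging, 1)
  expect_equal(aggregate_targets(two[2:1, ]), agg)
  expect_error(aggregate_targets(two[0, ]), class = "agerank_error_input")
})

test_that("the composite reproduces reference breakdowns and clips", {
  # dasatinib-style row: product 0.8208 + 0.2 clips to 1
  b <- composite_score(1, 0.96, 1, 0.95, 0.9,
                       purchase_bonus = 0.1, approval_bonus = 0.1)
  expect_equal(b$final, 1)
  # GVP-style row
  b2 <- composite_score(1, 0.95, 0.95, 0.93, 0.81,
                        purchase_bonus = 0.1, approval_bonus = 0.075)
  expect_equal(round(1 * 0.95 * 0.95 * 0.93 * 0.81 + 0.175, 10),
               round(b2$final, 10))
  expect_equal(composite_score(1, 1, 1, 1, 1)$final, 1)
  expect_equal(composite_score(0, 1, 1, 1, 1,
                               lipinski_loss = -0.2)$final, 0)
  expect_error(composite_score(1.2, 1, 1, 1, 1),
               class = "agerank_error_validation")
  expect_error(composite_score(1, 1, 1, 1, 1, lipinski_loss = 0.1),
               class = "agerank_error_validation")
})

test_that("final scores stay in [0,1] over random admissible inputs", {
  set.seed(3)
  n <- 2000
  f <- matrix(runif(5 * n), n)
  fin <- composite_score(f[, 1], f[, 2], f[, 3], f[, 4], f[, 5],
                         lipinski_loss = -runif(n, 0, 0.2),
                         promiscuity_loss = -runif(n, 0, 0.2),
                         purchase_bonus = sample(c(0, 0.1), n, TRUE),
                         approval_bonus = sample(c(0, 0.075, 0.1), n, TRUE))$final
  expect_true(all(fin >= 0 & fin <= 1))
})

test_that("the final score is monotone in each factor and term", {
  set.seed(4)
  base <- runif(5, 0.2, 0.8)
  args <- list(aging = base[1], domain_cons = base[2], site_cons = base[3],
               affinity = base[4], bioavailability = base[5],
               lipinski_loss = -0.05, promiscuity_loss = -0.05,
               purchase_bonus = 0, approval_bonus = 0)
  f0 <- do.call(composite_score, args)$final
  for (nm in names(args)[1:5]) {
    up <- args; up[[nm]] <- min(1, args[[nm]] + 0.1)
    expect_gte(do.call(composite_score, up)$final, f0)
  }
  for (nm in c("lipinski_loss", "promiscuity_loss")) {
    worse <- args; worse[[nm]] <- args[[nm]] - 0.05
    expect_lte(do.call(composite_score, worse)$final, f0)
  }
})

test_that("tailored scores exclude and reweight factors coherently", {
  b <- composite_score(0.9, 0.8, 0.95, 0.7, 0.6,
                       lipinski_loss = -0.05, purchase_bonus = 0.1)
  # unit weights reproduce the composite exactly
  expect_equal(tailored_score(b), b$final)
  # weight 0 equals setting that factor to 1
  b_no_bio <- composite_score(0.9, 0.8, 0.95, 0.7, 1,
                              lipinski_loss = -0.05, purchase_bonus = 0.1)
  expect_equal(tailored_score(b, factor_weights = c(bioavailability = 0)),
               b_no_bio$final)
  # all weights 0: empty product + no terms, clipped to 1
  expect_equal(tailored_score(b,
                              factor_weights = c(aging = 0, domain_cons = 0,
                                                 site_cons = 0, affinity = 0,
                                                 bioavailability = 0),
                              term_weights = c(lipinski_loss = 0,
                                               promiscuity_loss = 0,
                                               purchase_bonus = 0,
                                               approval_bonus = 0)), 1)
  expect_error(tailored_score(b, factor_weights = c(aging = -1)),
               class = "agerank_error_param")
})

test_that("a serialised breakdown recomposes to its stored final score", {
  set.seed(9)
  for (i in 1:20) {
    b <- composite_score(runif(1), runif(1), runif(1), runif(1), runif(1),
                         lipinski_loss = -runif(1, 0, 0.2),
                         promiscuity_loss = -runif(1, 0, 0.2),
                         purchase_bonus = sample(c(0, 0.1), 1),
                         approval_bonus = sample(c(0, 0.075, 0.1), 1))
    again <- composite_score(b$aging, b$domain_cons, b$site_cons, b$affinity,
                             b$bioavailability, b$lipinski_loss,
                             b$promiscuity_loss, b$purchase_bonus,
                             b$approval_bonus)
    expect_identical(again$final, b$final)
  }
})
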