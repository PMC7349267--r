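test_that("median-of-ratios factors match symmetry, forced-scale and oracle cases", {
  m <- matrix(c(5, 10, 2, 5, 10, 2), 3, dimnames = list(paste0("g", 1:3), c("a", "b")))
  f <- estimate_normalization(as_expr_tbl(m, "counts"))
  expect_equal(unname(f), c(1, 1))

  m2 <- cbind(a = c(5, 10, 2), b = 2 * c(5, 10, 2))
  rownames(m2) <- paste0("g", 1:3)
  f2 <- estimate_normalization(as_expr_tbl(m2, "counts"))
  expect_equal(unname(f2), c(1 / sqrt(2), sqrt(2)))

  set.seed(31)
  m3 <- matrix(rpois(100 * 5, 40), 100, 5,
               dimnames = list(paste0("g", 1:100), paste0("s", 1:5)))
  f3 <- estimate_normalization(as_expr_tbl(m3, "counts"))
  expect_equal(unname(f3), unname(oracle_mor_factors(m3)), tolerance = 1e-12)

  zero <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(estimate_normalization(as_expr_tbl(zero, "counts")),
               "pseudo-reference")
})

test_that("common dispersion is recovered by the moment estimator", {
  des4 <- toy_design(species = "MEAM1", reps = 2)
  # constant replicate counts -> zero variance -> phi floored at 0
  m <- matrix(rep(c(10, 50), each = 4), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), des4$sample_id))
  expect_equal(estimate_common_dispersion(as_expr_tbl(m, "counts"), des4,
                                          setNames(rep(1, 4), des4$sample_id)), 0)

  # the median-of-moments estimate converges on the truth as replication
  # grows; 16 replicates per sex keep the finite-sample skew small
  des <- toy_design(species = "MEAM1", reps = 16)
  ns <- nrow(des)
  set.seed(7)
  mu <- rgamma(5000, 2, 0.02) + 5
  pois <- sapply(seq_len(ns), function(j) rpois(5000, mu))
  dimnames(pois) <- list(paste0("g", 1:5000), des$sample_id)
  phi0 <- estimate_common_dispersion(as_expr_tbl(pois, "counts"), des,
                                     setNames(rep(1, ns), des$sample_id))
  expect_lte(phi0, 0.01)

  nb <- sapply(seq_len(ns), function(j) rnbinom(5000, mu = mu, size = 1 / 0.2))
  dimnames(nb) <- dimnames(pois)
  phi <- estimate_common_dispersion(as_expr_tbl(nb, "counts"), des,
                                    setNames(rep(1, ns), des$sample_id))
  expect_lt(abs(phi - 0.2) / 0.2, 0.2)
})

test_that("the conditional NB exact test matches its distributional oracle", {
  # symmetric observed split is modal -> p = 1
  expect_equal(nb_exact_test(c(10, 10), c(10, 10), phi = 0.1), 1)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), phi = 0.1), 1)

  # Poisson limit equals the two-sided exact binomial test with q = 1/2
  for (case in list(c(3, 9), c(20, 8), c(0, 14))) {
    p_pkg <- nb_exact_test(case[1], case[2], phi = 0)
    p_binom <- binom.test(case[1], case[1] + case[2], 0.5)$p.value
    expect_equal(p_pkg, p_binom, tolerance = 1e-12)
  }

  # NB case against an independent dnbinom-product oracle (any mean works:
  # the conditional law is free of it)
  set.seed(2)
  for (rep in 1:20) {
    y1 <- rnbinom(2, mu = 60, size = 20)
    y2 <- rnbinom(2, mu = 100, size = 20)
    phi <- runif(1, 0.01, 0.4)
    expect_equal(nb_exact_test(y1, y2, phi),
                 oracle_nb_exact(y1, y2, phi, mu = runif(1, 1, 50)),
                 tolerance = 1e-9)
  }

  # strong 4-fold difference at moderate counts is significant
  expect_lt(nb_exact_test(c(100, 100), c(400, 400), phi = 0.05), 0.05)
  expect_error(nb_exact_test(c(-1, 2), c(1, 1), phi = 0.1), "non-negative")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.77), 0.77)
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("sex-bias calls honor both gates and sex-label symmetry", {
  cfg <- sim_config(
    n_genes = 400, seed = 77, nb_dispersion = 0.05, sex_effect = 3,
    class_props = c(non_variable = 0.5, sex_variable = 0.5, species_variable = 0,
                    sex_and_species = 0, interaction_variable = 0)
  )
  sim <- simulate_expression(cfg)
  calls <- call_sex_bias(sim$counts, sim$design, "MED")
  # calls respect their defining invariant
  expect_true(all(calls$log2_fc[calls$call == "female_biased"] <= -1))
  expect_true(all(calls$fdr[calls$call == "female_biased"] < 0.05))
  expect_true(all(calls$log2_fc[calls$call == "male_biased"] >= 1))
  expect_true(all(calls$fdr[calls$call == "male_biased"] < 0.05))
  unb <- calls$call == "unbiased"
  expect_true(all(abs(calls$log2_fc[unb]) < 1 | calls$fdr[unb] >= 0.05))

  # swapping the sex labels mirrors calls and negates the fold change
  des2 <- sim$design
  des2$sex <- ifelse(des2$sex == "female", "male", "female")
  swapped <- call_sex_bias(sim$counts, des2, "MED")
  expect_equal(swapped$log2_fc, -calls$log2_fc, tolerance = 1e-12)
  expect_equal(swapped$p_value, calls$p_value, tolerance = 1e-12)
  expect_identical(as.character(swapped$call)[calls$call == "female_biased"],
                   rep("male_biased", sum(calls$call == "female_biased")))

  # a sub-threshold fold change is never called, whatever its FDR
  below_gate <- abs(calls$log2_fc) < 1
  expect_true(all(calls$call[below_gate] == "unbiased"))
})
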