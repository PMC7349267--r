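des6 <- toy_design(species = c("A", "B", "C"), pop_species = "none", reps = 3)

sfpkm_from <- function(m) {
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))), des6$sample_id)
  as_expr_tbl(m, "sfpkm")
}

test_that("batched ANOVA reproduces aov() sums of squares, F and p gene by gene", {
  set.seed(97)
  m <- matrix(2^rnorm(10 * nrow(des6), 5, 1), 10)
  fit <- gene_anova(sfpkm_from(m), des6)
  fs <- factor(des6$sex, levels = c("female", "male"))
  fp <- factor(des6$species)
  for (g in 1:10) {
    y <- log2(m[g, ])
    ref <- summary(aov(y ~ fs * fp))[[1]]
    rownames(ref) <- trimws(rownames(ref))
    expect_equal(fit$ss_sex[g], ref["fs", "Sum Sq"], tolerance = 1e-8)
    expect_equal(fit$ss_species[g], ref["fp", "Sum Sq"], tolerance = 1e-8)
    expect_equal(fit$ss_interaction[g], ref["fs:fp", "Sum Sq"], tolerance = 1e-8)
    expect_equal(fit$ss_resid[g], ref["Residuals", "Sum Sq"], tolerance = 1e-8)
    expect_equal(fit$p_sex[g], ref["fs", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(fit$p_species[g], ref["fp", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(fit$p_interaction[g], ref["fs:fp", "Pr(>F)"], tolerance = 1e-8)
  }
  # balanced decomposition identity
  expect_equal(fit$ss_total,
               fit$ss_sex + fit$ss_species + fit$ss_interaction + fit$ss_resid,
               tolerance = 1e-8)
})

test_that("degenerate and pure-effect genes follow the stated conventions", {
  flat <- matrix(4, 2, nrow(des6))
  fit <- gene_anova(sfpkm_from(flat), des6)
  expect_equal(fit$ss_total, c(0, 0))
  expect_equal(fit$p_sex, c(1, 1))
  expect_equal(fit$p_interaction, c(1, 1))

  # pure sex effect delta with zero noise: SS_sex = N * delta^2 / 4
  delta <- 1.5
  y <- ifelse(des6$sex == "male", 2^(3 + delta / 2), 2^(3 - delta / 2))
  fit2 <- gene_anova(sfpkm_from(matrix(y, 1)), des6)
  N <- nrow(des6)
  expect_equal(fit2$ss_sex, N * delta^2 / 4, tolerance = 1e-10)
  expect_equal(fit2$ss_species, 0, tolerance = 1e-10)
  expect_equal(fit2$ss_interaction, 0, tolerance = 1e-10)
  expect_equal(fit2$p_sex, 0)  # zero residual, positive effect
  expect_equal(fit2$coef_sex_male, delta / 2, tolerance = 1e-10)

  unbalanced <- des6[-1, ]
  expect_error(gene_anova(sfpkm_from(matrix(1:18, 1))[, c("gene_id", unbalanced$sample_id)],
                          unbalanced), "balanced")
})

test_that("Tukey HSD contrasts match stats::TukeyHSD and its monotonicity", {
  set.seed(101)
  m <- matrix(2^rnorm(6 * nrow(des6), 5, 1), 6)
  # plant a strong species shift in gene 1: C far from identical A and B
  shift <- ifelse(des6$species == "C", 6, 0)
  m[1, ] <- 2^(rnorm(nrow(des6), 5, 0.3) + shift)
  fit <- gene_anova(sfpkm_from(m), des6)
  tk <- tukey_hsd_species(fit)
  fs <- factor(des6$sex, levels = c("female", "male"))
  fp <- factor(des6$species)
  for (g in 1:6) {
    y <- log2(m[g, ])
    ref <- TukeyHSD(aov(y ~ fs * fp), "fp")$fp
    sub <- tk[tk$gene_id == paste0("g", g), ]
    for (ctr in rownames(ref)) {
      row <- sub[sub$contrast == ctr, ]
      expect_equal(row$diff, ref[ctr, "diff"], tolerance = 1e-8)
      expect_equal(row$p_adj, ref[ctr, "p adj"], tolerance = 1e-6)
    }
  }
  g1 <- tk[tk$gene_id == "g1", ]
  expect_lt(g1$p_adj[g1$contrast == "C-A"], 0.001)
  expect_lt(g1$p_adj[g1$contrast == "C-B"], 0.001)
  expect_gt(g1$p_adj[g1$contrast == "B-A"], 0.05)

  # all-equal species means: q = 0 -> adjusted p = 1
  eq <- matrix(2^(4 + (des6$sex == "male")), 1, nrow(des6))
  fit_eq <- gene_anova(sfpkm_from(eq), des6)
  tk_eq <- tukey_hsd_species(fit_eq)
  expect_true(all(tk_eq$p_adj > 0.999))
})

test_that("variance classification applies the precedence rule and recovers structure", {
  cfg <- sim_config(
    n_genes = 1500, seed = 103, nb_dispersion = 0.05,
    class_props = c(non_variable = 0.4, sex_variable = 0.2, species_variable = 0.2,
                    sex_and_species = 0.1, interaction_variable = 0.1)
  )
  sim <- simulate_expression(cfg)
  sf <- sfpkm_true(sim$fpkm)
  av <- gene_anova(sf, dplyr::filter(sim$design, population == "pop1"),
                   species = cfg$focal_species)
  cl <- classify_variance(av)
  joined <- dplyr::inner_join(cl, sim$truth, by = c(gene_id = "ortholog_id"))
  for (want in c("sex_variable", "species_variable")) {
    hit <- mean(joined$category[joined$class == want] == want)
    expect_gt(hit, 0.9)
  }
  sexy <- joined[joined$class == "sex_variable" & joined$category == "sex_variable", ]
  expect_gt(mean(sexy$direction == sexy$sex_direction), 0.99)

  # relabeling species never changes a pure-sex gene's category
  des_relab <- dplyr::filter(sim$design, population == "pop1")
  map <- c(MEAM1 = "MED", MED = "AsiaII3", AsiaII3 = "MEAM1", GW = "GW")
  des_relab$species <- unname(map[des_relab$species])
  av2 <- gene_anova(sf, des_relab, species = cfg$focal_species)
  cl2 <- classify_variance(av2)
  sex_ids <- joined$gene_id[joined$class == "sex_variable"]
  expect_identical(cl2$category[cl2$gene_id %in% sex_ids],
                   cl$category[cl$gene_id %in% sex_ids])
})

test_that("a gene significant everywhere is interaction-variable by precedence", {
  set.seed(107)
  base <- rnorm(nrow(des6), 0, 0.05)
  y <- base + ifelse(des6$sex == "male", 3, 0) +
    ifelse(des6$species == "B", 3, 0) +
    ifelse(des6$species == "B" & des6$sex == "male", 4, 0)
  filler <- matrix(2^rnorm(20 * nrow(des6), 3, 0.3), 20)
  m <- rbind(2^y, filler)
  fit <- gene_anova(sfpkm_from(m), des6)
  cl <- classify_variance(fit)
  expect_lt(fit$p_sex[1], 0.001)
  expect_lt(fit$p_species[1], 0.001)
  expect_identical(as.character(cl$category[1]), "interaction_variable")
})
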