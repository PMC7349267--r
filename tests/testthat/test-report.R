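test_that("hypergeometric tails match exhaustive draw enumeration", {
  expect_equal(hyper_test(5, 5, 5, 10)$p_over, 1 / choose(10, 5))
  # zero overlap closed form
  expect_equal(hyper_test(0, 4, 3, 10)$p_under,
               choose(10 - 4, 3) / choose(10, 3))
  # enumeration over a spread of configurations with N <= 12
  for (N in c(5, 8, 12)) {
    for (n in 1:(N - 1)) {
      draws <- combn(N, n)
      for (K in 0:N) {
        overlap <- colSums(draws <= K)
        for (k in max(0, K + n - N):min(K, n)) {
          got <- hyper_test(k, K, n, N)
          expect_equal(got$p_over, mean(overlap >= k), tolerance = 1e-12)
          expect_equal(got$p_under, mean(overlap <= k), tolerance = 1e-12)
        }
      }
    }
  }
  # the two tails share the point mass
  expect_true(all(with(hyper_test(0:3, 5, 3, 12), p_over + p_under) >= 1))
  expect_error(hyper_test(6, 5, 5, 10), "inconsistent")
})

test_that("Mann-Whitney exact branch equals full permutation enumeration", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney(rep(5, 3), rep(5, 4))$p_value, 1)

  # independent enumeration via subset masks, own rank computation
  set.seed(109)
  for (i in 1:10) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    z <- sample(c(runif(m + n), runif(1), runif(1)))[1:(m + n)]
    if (i %% 2 == 0) z[1:2] <- z[3]  # ties in some cases
    x <- z[1:m]; y <- z[-(1:m)]
    got <- mann_whitney(x, y)
    r <- rank(z)
    u_obs <- sum(r[1:m]) - m * (m + 1) / 2
    us <- c()
    for (mask in 0:(2^(m + n) - 1)) {
      sel <- which(bitwAnd(bitwShiftL(1, 0:(m + n - 1)), mask) != 0)
      if (length(sel) != m) next
      us <- c(us, sum(r[sel]) - m * (m + 1) / 2)
    }
    expect_equal(got$p_value,
                 mean(abs(us - m * n / 2) >= abs(u_obs - m * n / 2) - 1e-9),
                 tolerance = 1e-12)
    # tie-free cases also agree with wilcox.test's exact branch
    if (!any(duplicated(z))) {
      expect_equal(got$p_value,
                   suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value),
                   tolerance = 1e-10)
    }
  }
})

test_that("the large-sample Mann-Whitney branch holds its nominal level", {
  set.seed(113)
  rej <- replicate(400, {
    x <- rnorm(30); y <- rnorm(25)
    mann_whitney(x, y)$p_value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.01)
})

test_that("consistency classes match the exhaustive truth table", {
  lv <- c("female_biased", "unbiased", "male_biased")
  triples <- expand.grid(a = lv, b = lv, c = lv, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(triples))) {
    tr <- unlist(triples[i, ])
    want <- if (any(tr == "female_biased") && any(tr == "male_biased")) {
      "switched_opposite"
    } else if (any(tr == "female_biased") && any(tr == "unbiased")) {
      "female_vs_unbiased"
    } else if (any(tr == "male_biased") && any(tr == "unbiased")) {
      "male_vs_unbiased"
    } else "consistent"
    calls <- tibble::tibble(gene_id = "g", species = c("A", "B", "C"), call = tr)
    expect_identical(classify_consistency(calls)$class, want)
  }
})

test_that("correlation matrices are symmetric with unit diagonal and respect structure", {
  set.seed(127)
  dx <- runif(60, 0.1, 3)
  meas <- tibble::tibble(Dx = dx, Rx = dx / 0.5, Sx = runif(60))
  cm <- correlation_matrix(meas)
  expect_equal(cm$rho["Dx", "Rx"], 1)   # Rx proportional to Dx
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 3))

  # independent measures: weak correlation
  ind <- tibble::tibble(a = rnorm(500), b = rnorm(500))
  expect_lt(abs(correlation_matrix(ind)$rho["a", "b"]), 0.15)

  # pairwise deletion of undefined values
  withna <- tibble::tibble(a = c(NA, 2, 3, 4, 5, 1), b = c(9, 8, 7, 5, 6, 2))
  cmn <- correlation_matrix(withna)
  expect_equal(cmn$n_used["a", "b"], 5)
  expect_equal(cmn$rho["a", "b"],
               cor(c(2, 3, 4, 5, 1), c(8, 7, 5, 6, 2), method = "spearman"))
})

test_that("2-D binned summaries conserve counts and match direct recomputation", {
  set.seed(131)
  df <- tibble::tibble(log2_fc = runif(300, -8, 8), Dx = runif(300, 0, 4),
                       avg_ratio = runif(300))
  grid <- bin2d_summary(df, n_bins = 8)
  expect_equal(sum(grid$n_genes), 300)
  # direct recomputation of one occupied cell
  cell <- grid[which.max(grid$n_genes), ]
  xr <- c(-8, 8); yr <- c(0, max(df$Dx))
  xb <- pmin(pmax(1 + floor((df$log2_fc - xr[1]) / diff(xr) * 8), 1), 8)
  yb <- pmin(pmax(1 + floor((df$Dx - yr[1]) / diff(yr) * 8), 1), 8)
  inside <- xb == cell$x_bin & yb == cell$y_bin
  expect_equal(cell$n_genes, sum(inside))
  expect_equal(cell$mean_value, mean(df$avg_ratio[inside]), tolerance = 1e-12)

  one <- bin2d_summary(tibble::tibble(log2_fc = rep(0.1, 5), Dx = rep(1, 5),
                                      avg_ratio = 1:5), n_bins = 4)
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_value, 3)
  empty <- bin2d_summary(tibble::tibble(log2_fc = numeric(), Dx = numeric(),
                                        avg_ratio = numeric()))
  expect_equal(nrow(empty), 0)
})
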