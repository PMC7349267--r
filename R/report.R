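#' Hypergeometric representation test
#'
#' One-sided tail probabilities in both directions for the overlap `k`
#' between a gene set of size `K` and a category of size `n` within a
#' universe of `N` genes: `p_over = P(X >= k)`, `p_under = P(X <= k)` with
#' `X ~ Hypergeometric(N, K, n)`. Vectorized over `k`, `K`, `n`, `N`.
#'
#' @param k Overlap count.
#' @param K Gene-set size.
#' @param n Category size.
#' @param N Universe size.
#' @return Tibble: `k`, `K`, `n`, `N`, `expected`, `p_over`, `p_under`.
#' @export
hyper_test <- function(k, K, n, N) {
  bad <- k > pmin(K, n) | K > N | n > N | k < 0
  if (any(bad)) abort("inconsistent counts: need k <= min(K, n) and K, n <= N")
  tibble(
    k = k, K = K, n = n, N = N,
    expected = as.numeric(n) * K / N,
    p_over = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_under = phyper(k, K, N - K, n, lower.tail = TRUE)
  )
}

#' Mann-Whitney U test
#'
#' Exact p-value by full enumeration of group assignments when
#' `length(x) + length(y) <= 20` (ties handled through average ranks);
#' otherwise the normal approximation with tie correction and continuity
#' correction. `U` is the statistic of `x`
#' (`U = rank-sum of x - m(m+1)/2`). When every value is tied across both
#' samples the p-value is 1 by convention.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return Tibble: `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) abort("both samples must be nonempty")
  m <- length(x); n <- length(y)
  z <- c(x, y)
  if (diff(range(z)) == 0) {
    return(tibble(U = m * n / 2, p_value = 1, method = "degenerate"))
  }
  r <- rank(z)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (m + n <= 20L) {
    idx <- combn(m + n, m)
    u_all <- colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(u_all - m * n / 2) >= abs(u_obs - m * n / 2) - 1e-9),
      less = mean(u_all <= u_obs + 1e-9),
      greater = mean(u_all >= u_obs - 1e-9))
    return(tibble(U = u_obs, p_value = p, method = "exact"))
  }
  mu <- m * n / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((m + n) * (m + n - 1))
  sigma <- sqrt(m * n / 12 * (m + n + 1 - tie_term))
  cc <- 0.5
  p <- switch(alternative,
    two.sided = 2 * pnorm((abs(u_obs - mu) - cc) / sigma, lower.tail = FALSE),
    less = pnorm((u_obs - mu + cc) / sigma),
    greater = pnorm((u_obs - mu - cc) / sigma, lower.tail = FALSE))
  tibble(U = u_obs, p_value = min(1, p), method = "normal")
}

#' Cross-species consistency of sex-bias calls
#'
#' Classifies each ortholog from its per-species sex-bias calls:
#' `switched_opposite` when both female- and male-biased calls occur
#' among the species; `female_vs_unbiased` when female-biased and
#' unbiased both occur with no male-biased call (and symmetrically
#' `male_vs_unbiased`); otherwise `consistent`.
#'
#' @param calls Tibble with columns `gene_id` (or `ortholog_id`),
#'   `species`, `call` -- typically stacked [call_sex_bias()] outputs
#'   joined through the ortholog map.
#' @return Tibble: `gene_id`, `class`.
#' @export
classify_consistency <- function(calls) {
  id_col <- if ("gene_id" %in% names(calls)) "gene_id" else "ortholog_id"
  calls |>
    group_by(gene_id = .data[[id_col]]) |>
    summarise(class = consistency_class(.data$call), .groups = "drop")
}

consistency_class <- function(call) {
  call <- as.character(call)
  has_f <- any(call == "female_biased")
  has_m <- any(call == "male_biased")
  has_u <- any(call == "unbiased")
  if (has_f && has_m) "switched_opposite"
  else if (has_f && has_u) "female_vs_unbiased"
  else if (has_m && has_u) "male_vs_unbiased"
  else "consistent"
}

#' Spearman correlation matrix of evolution measures
#'
#' Pairwise Spearman correlations (average ranks) with pairwise-complete
#' deletion of undefined values (e.g. Rx where Vx was zero, Ka/Ks where Ks
#' was zero); the number of dropped orthologs per pair is recorded.
#' P-values come from the large-sample t approximation.
#'
#' @param measures Tibble of per-ortholog measures; all columns except an
#'   optional id column are correlated (typically Sx, Vx, Dx, Rx, KaKs).
#' @return A `measure_cor` object with `rho`, `p` and `n_used` matrices;
#'   [tidy()] gives the long form, [autoplot()] a correlation tile plot.
#' @export
correlation_matrix <- function(measures) {
  x <- as_tibble(measures)
  x <- x[, !(names(x) %in% c("gene_id", "ortholog_id")), drop = FALSE]
  if (ncol(x) < 2L) abort("need at least two measures")
  vars <- names(x)
  kn <- length(vars)
  rho <- matrix(NA_real_, kn, kn, dimnames = list(vars, vars))
  pm <- rho; nm <- rho
  for (i in seq_len(kn)) {
    for (j in i:kn) {
      ok <- complete.cases(x[[i]], x[[j]])
      nm[i, j] <- nm[j, i] <- sum(ok)
      if (i == j) { rho[i, j] <- 1; pm[i, j] <- 0; next }
      xi <- x[[i]][ok]; xj <- x[[j]][ok]
      if (sum(ok) < 3L || diff(range(xi)) == 0 || diff(range(xj)) == 0) next
      r <- cor(rank(xi), rank(xj))
      rho[i, j] <- rho[j, i] <- r
      nn <- sum(ok)
      tstat <- r * sqrt((nn - 2) / max(1e-300, 1 - r^2))
      pm[i, j] <- pm[j, i] <- 2 * stats::pt(abs(tstat), nn - 2, lower.tail = FALSE)
    }
  }
  structure(list(rho = rho, p = pm, n_used = nm, n_total = nrow(measures)),
            class = "measure_cor")
}

#' @export
print.measure_cor <- function(x, ...) {
  cat("Spearman correlations of", ncol(x$rho), "measures over up to",
      x$n_total, "orthologs\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.measure_cor <- function(x, ...) {
  vars <- rownames(x$rho)
  grid <- expand.grid(measure_a = vars, measure_b = vars, stringsAsFactors = FALSE)
  tibble(
    measure_a = grid$measure_a, measure_b = grid$measure_b,
    rho = x$rho[cbind(grid$measure_a, grid$measure_b)],
    p_value = x$p[cbind(grid$measure_a, grid$measure_b)],
    n_used = x$n_used[cbind(grid$measure_a, grid$measure_b)]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.measure_cor <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(.data$measure_a, .data$measure_b, fill = .data$rho)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$rho)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman rho") +
    theme_minimal()
}

#' Two-dimensional binned summary of an evolution indicator
#'
#' Bins genes on a sex-bias axis (log2 fold change male/female) and a
#' divergence axis (Dx) into an equal-width grid and reports per-cell gene
#' counts and the mean of an indicator (Ka/Ks or Rx).
#'
#' @param data Tibble with the three aligned columns.
#' @param x,y,value Column names (strings) for the two axes and the
#'   indicator.
#' @param n_bins Bins per axis (default 16).
#' @param x_range,y_range Axis ranges; defaults: x in \[-8, 8\], y from 0
#'   to its maximum. Values outside the range are clipped into the
#'   boundary bins.
#' @return A `bin2d_summary` tibble: bin indices, bin centers, `n_genes`,
#'   `mean_value`; supports [autoplot()].
#' @export
bin2d_summary <- function(data, x = "log2_fc", y = "Dx", value = "avg_ratio",
                          n_bins = 16, x_range = c(-8, 8), y_range = NULL) {
  data <- as_tibble(data)
  if (nrow(data) == 0L) {
    return(structure(tibble(x_bin = integer(), y_bin = integer(),
                            x_mid = numeric(), y_mid = numeric(),
                            n_genes = integer(), mean_value = numeric()),
                     class = c("bin2d_summary", class(tibble()))))
  }
  xv <- data[[x]]; yv <- data[[y]]; vv <- data[[value]]
  y_range <- y_range %||% c(0, max(yv, na.rm = TRUE))
  bin_of <- function(v, rng) {
    b <- 1L + floor((v - rng[1L]) / diff(rng) * n_bins)
    pmin(pmax(b, 1L), as.integer(n_bins))
  }
  xb <- bin_of(xv, x_range); yb <- bin_of(yv, y_range)
  out <- tibble(x_bin = xb, y_bin = yb, v = vv) |>
    group_by(.data$x_bin, .data$y_bin) |>
    summarise(n_genes = n(), mean_value = mean(.data$v, na.rm = TRUE), .groups = "drop") |>
    mutate(
      x_mid = x_range[1L] + (.data$x_bin - 0.5) * diff(x_range) / n_bins,
      y_mid = y_range[1L] + (.data$y_bin - 0.5) * diff(y_range) / n_bins
    ) |>
    select("x_bin", "y_bin", "x_mid", "y_mid", "n_genes", "mean_value")
  structure(out, class = c("bin2d_summary", class(out)),
            axes = c(x = x, y = y, value = value))
}

#' @exportS3Method ggplot2::autoplot
autoplot.bin2d_summary <- function(object, ...) {
  axes <- attr(object, "axes")
  ggplot(object, aes(.data$x_mid, .data$y_mid)) +
    geom_point(aes(size = .data$n_genes, colour = .data$mean_value)) +
    scale_size_area(max_size = 8) +
    labs(x = axes[["x"]], y = axes[["y"]], colour = axes[["value"]],
         size = "genes") +
    theme_minimal()
}
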