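#' Median-of-ratios normalization factors
#'
#' For each sample, the factor is the median over genes of
#' `count / geometric mean across samples`, restricted to genes with
#' all-positive counts, then rescaled so the factors have geometric mean 1.
#'
#' @param counts Expression tibble of raw counts.
#' @return Named numeric vector of per-sample scaling factors.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 100, seed = 1))
#' estimate_normalization(sim$counts)
#' @export
estimate_normalization <- function(counts) {
  m <- expr_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) abort("no gene with positive counts in all samples; consider a pseudo-reference fallback")
  mp <- m[pos, , drop = FALSE]
  gm <- exp(rowMeans(log(mp)))
  f <- apply(mp / gm, 2L, median)
  f / exp(mean(log(f)))
}

#' Method-of-moments common negative-binomial dispersion
#'
#' Counts are scaled by the normalization factors; within every
#' (species, population, sex) group with at least two replicates, the
#' per-gene sample mean and variance give a moment estimate
#' `(v - m) / m^2`; the common dispersion is the median of these values
#' pooled across genes and groups, floored at zero.
#'
#' @param counts Expression tibble of raw counts.
#' @param design Sample design tibble.
#' @param factors Per-sample factors from [estimate_normalization()].
#' @return Non-negative scalar dispersion `phi`.
#' @export
estimate_common_dispersion <- function(counts, design, factors = estimate_normalization(counts)) {
  design <- validate_design(design)
  m <- expr_matrix(counts)
  m <- sweep(m[, design$sample_id, drop = FALSE], 2L, factors[design$sample_id], "/")
  key <- paste(design$species, design$population, design$sex, sep = ".")
  vals <- list()
  for (g in unique(key)) {
    cols <- which(key == g)
    if (length(cols) < 2L) next
    sub <- m[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1L, var)
    ok <- mu > 0
    vals[[g]] <- (v[ok] - mu[ok]) / mu[ok]^2
  }
  if (!length(vals)) abort("no group has >= 2 replicates; cannot estimate dispersion")
  max(0, median(unlist(vals)))
}

#' Conditional negative-binomial exact test for two groups
#'
#' Counts are first equalized to a common library size (divided by their
#' normalization factors and rounded to the nearest integer). Conditional
#' on the total of the two group sums, the first group's sum follows --
#' under the null of equal means and common dispersion `phi` -- a
#' beta-binomial-type distribution that is free of the unknown mean:
#' `P(a) proportional to C(a + r1 - 1, a) * C(T - a + r2 - 1, T - a)` with
#' `r_g = n_g / phi` (binomial with `p = n1/(n1+n2)` in the Poisson limit
#' `phi = 0`). The two-sided p-value sums the probabilities of all splits
#' no more probable than the observed one.
#'
#' @param y1,y2 Raw replicate counts of the two groups (e.g. female, male).
#' @param phi Common dispersion (`>= 0`).
#' @param f1,f2 Normalization factors matching `y1`, `y2` (default 1).
#' @return p-value in (0, 1].
#' @export
nb_exact_test <- function(y1, y2, phi, f1 = rep(1, length(y1)), f2 = rep(1, length(y2))) {
  if (any(c(y1, y2) < 0)) abort("counts must be non-negative")
  if (phi < 0) abort("phi must be >= 0")
  a_obs <- sum(round(y1 / f1))
  b_obs <- sum(round(y2 / f2))
  T <- a_obs + b_obs
  if (T == 0) return(1)
  n1 <- length(y1); n2 <- length(y2)
  a <- 0:T
  logp <- if (phi <= 0) {
    dbinom(a, T, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    lgamma(a + r1) - lgamma(a + 1) + lgamma(T - a + r2) - lgamma(T - a + 1)
  }
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  min(1, sum(p[p <= p[a_obs + 1L] * (1 + 1e-7)]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify genes as female-, male- or non-sex-biased within one species
#'
#' Runs the conditional NB exact test per gene between the sexes of one
#' species, adjusts p-values by Benjamini-Hochberg, and calls a gene
#' sex-biased when both the fold-change gate (at least `fc`-fold,
#' male-over-female orientation) and the FDR gate (`fdr < alpha`) pass.
#' The log2 fold change is computed on normalized mean counts with a
#' pseudocount of 0.5; the test itself uses no pseudocount.
#'
#' @param counts Expression tibble of raw counts (all samples may be
#'   present; only the species' samples are used).
#' @param design Sample design.
#' @param species Species to analyze.
#' @param fc Fold-change threshold (default 2).
#' @param alpha FDR threshold (default 0.05).
#' @param phi Optional common dispersion; estimated from this species'
#'   samples when `NULL`.
#' @return Tibble: `gene_id`, `species`, `log2_fc` (male over female),
#'   `p_value`, `fdr`, `call` (factor female_biased/unbiased/male_biased).
#' @export
call_sex_bias <- function(counts, design, species, fc = 2, alpha = 0.05, phi = NULL) {
  design <- validate_design(design)
  sub <- filter(design, .data$species == !!species)
  if (nrow(sub) == 0L) abort(paste0("species '", species, "' not in design"))
  if (!all(c("female", "male") %in% sub$sex)) {
    abort(paste0("species '", species, "' lacks one sex"))
  }
  m <- expr_matrix(counts)[, sub$sample_id, drop = FALSE]
  cnt <- as_expr_tbl(m, "counts")
  factors <- estimate_normalization(cnt)
  if (is.null(phi)) phi <- estimate_common_dispersion(cnt, sub, factors)
  fem <- sub$sample_id[sub$sex == "female"]
  mal <- sub$sample_id[sub$sex == "male"]
  scaled <- sweep(m, 2L, factors[colnames(m)], "/")
  mean_f <- rowMeans(scaled[, fem, drop = FALSE])
  mean_m <- rowMeans(scaled[, mal, drop = FALSE])
  log2_fc <- log2((mean_m + 0.5) / (mean_f + 0.5))
  p <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_test(m[i, fem], m[i, mal], phi, factors[fem], factors[mal])
  }, numeric(1L))
  fdr <- bh_fdr(p)
  lfc_gate <- log2(fc)
  call <- ifelse(fdr < alpha & log2_fc <= -lfc_gate, "female_biased",
          ifelse(fdr < alpha & log2_fc >= lfc_gate, "male_biased", "unbiased"))
  tibble(gene_id = rownames(m), species = species, log2_fc = log2_fc,
         p_value = p, fdr = fdr,
         call = factor(call, levels = c("female_biased", "unbiased", "male_biased")))
}
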