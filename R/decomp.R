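#' Per-gene two-way ANOVA of log2 expression by sex and species
#'
#' Fits `log2(sFPKM) ~ sex + species + sex:species` gene by gene on a
#' balanced design (equal replicates in every sex-species cell, at least
#' two). The design is identical across genes, so sums of squares are
#' computed for all genes at once from the cell means; with a balanced
#' layout the sequential (type-I) decomposition is order-invariant and
#' `SS_total = SS_sex + SS_species + SS_int + SS_resid`. Coefficients use
#' sum-to-zero effect coding: `coef_sex_male` is the male marginal mean
#' minus the grand mean.
#'
#' When a gene has zero residual variance and zero effect variance its
#' p-values are reported as 1 (no evidence of variation by convention).
#'
#' @param sfpkm Expression tibble (sFPKM).
#' @param design Sample design.
#' @param species Species to include (default: the three focal species,
#'   i.e. every species with both sexes except none excluded explicitly).
#' @return A `gene_anova` tibble: `gene_id`, sums of squares, F statistics
#'   and p-values for the sex, species and interaction terms,
#'   `coef_sex_male`, `grand_mean`; degrees of freedom in attributes.
#' @export
gene_anova <- function(sfpkm, design, species = NULL) {
  design <- validate_design(design)
  if (is.null(species)) species <- sort(unique(design$species))
  sub <- filter(design, .data$species %in% !!species)
  m <- expr_matrix(sfpkm)[, sub$sample_id, drop = FALSE]
  y <- log2(m)
  fs <- factor(sub$sex, levels = c("female", "male"))
  fp <- factor(sub$species)
  cell <- interaction(fs, fp, drop = FALSE)
  n_cell <- table(cell)
  if (length(unique(as.integer(n_cell))) != 1L || min(n_cell) < 2L) {
    abort("balanced design with >= 2 replicates per sex-species cell required")
  }
  r <- as.integer(n_cell[1L])
  a <- nlevels(fs); b <- nlevels(fp)
  N <- ncol(y)

  grand <- rowMeans(y)
  mean_by <- function(f) {
    out <- matrix(0, nrow(y), nlevels(f), dimnames = list(NULL, levels(f)))
    for (l in levels(f)) out[, l] <- rowMeans(y[, f == l, drop = FALSE])
    out
  }
  m_sex <- mean_by(fs)
  m_sp <- mean_by(fp)
  m_cell <- mean_by(cell)

  ss_sex <- (N / a) * rowSums((m_sex - grand)^2)
  ss_sp <- (N / b) * rowSums((m_sp - grand)^2)
  cell_lv <- levels(cell)
  cell_sex <- sub("\\..*$", "", cell_lv)
  cell_sp <- sub("^[^.]*\\.", "", cell_lv)
  exp_cell <- m_sex[, cell_sex, drop = FALSE] + m_sp[, cell_sp, drop = FALSE] - grand
  ss_int <- r * rowSums((m_cell - exp_cell)^2)
  fitted <- m_cell[, as.character(cell), drop = FALSE]
  ss_resid <- rowSums((y - fitted)^2)
  ss_total <- rowSums((y - grand)^2)

  df_sex <- a - 1L; df_sp <- b - 1L; df_int <- df_sex * df_sp
  df_resid <- N - a * b
  mse <- ss_resid / df_resid
  fstat <- function(ss, df) (ss / df) / mse
  pval <- function(ss, df) {
    f <- fstat(ss, df)
    p <- pf(f, df, df_resid, lower.tail = FALSE)
    # degenerate genes: no variance anywhere -> no evidence of variation
    p[ss_resid == 0 & ss == 0] <- 1
    p[ss_resid == 0 & ss > 0] <- 0
    p
  }
  out <- tibble(
    gene_id = rownames(y),
    ss_sex = unname(ss_sex), ss_species = unname(ss_sp),
    ss_interaction = unname(ss_int),
    ss_resid = unname(ss_resid), ss_total = unname(ss_total),
    f_sex = unname(fstat(ss_sex, df_sex)), f_species = unname(fstat(ss_sp, df_sp)),
    f_interaction = unname(fstat(ss_int, df_int)),
    p_sex = unname(pval(ss_sex, df_sex)), p_species = unname(pval(ss_sp, df_sp)),
    p_interaction = unname(pval(ss_int, df_int)),
    coef_sex_male = unname(m_sex[, "male"] - grand),
    grand_mean = unname(grand)
  )
  structure(out, class = c("gene_anova", class(out)),
            df = c(sex = df_sex, species = df_sp, interaction = df_int, resid = df_resid),
            n_per_cell = r, species = levels(fp),
            mse = mse, species_means = m_sp)
}

#' @exportS3Method generics::glance
glance.gene_anova <- function(x, ...) {
  df <- attr(x, "df")
  tibble(n_genes = nrow(x), df_sex = df[["sex"]], df_species = df[["species"]],
         df_interaction = df[["interaction"]], df_resid = df[["resid"]],
         n_per_cell = attr(x, "n_per_cell"))
}

#' @exportS3Method generics::tidy
tidy.gene_anova <- function(x, ...) {
  as_tibble(x) |>
    select("gene_id", "ss_sex", "ss_species", "ss_interaction", "ss_resid",
           "p_sex", "p_species", "p_interaction") |>
    tidyr::pivot_longer(-"gene_id",
      names_to = c(".value", "term"),
      names_pattern = "(ss|p)_(.*)")
}

#' Tukey HSD contrasts between species marginal means
#'
#' Studentized-range adjusted p-values for every pair of species, per
#' gene, using each gene's ANOVA mean squared error. For balanced designs
#' this reproduces `stats::TukeyHSD` on the species factor.
#'
#' @param fit A `gene_anova` result.
#' @return Tibble: `gene_id`, `contrast`, `diff`, `p_adj`.
#' @export
tukey_hsd_species <- function(fit) {
  stopifnot(inherits(fit, "gene_anova"))
  df_resid <- attr(fit, "df")[["resid"]]
  if (df_resid <= 0) abort("no residual degrees of freedom for Tukey HSD")
  msp <- attr(fit, "species_means")
  mse <- attr(fit, "mse")
  sp <- attr(fit, "species")
  n_per_sp <- attr(fit, "n_per_cell") * 2L  # both sexes pooled per species
  pairs <- combn(sp, 2L)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    aa <- pairs[1L, k]; bb <- pairs[2L, k]
    diff <- msp[, bb] - msp[, aa]
    se <- sqrt(mse / n_per_sp)
    q <- abs(diff) / se
    p <- ptukey(q, nmeans = length(sp), df = df_resid, lower.tail = FALSE)
    p[mse == 0 & abs(diff) < 1e-12] <- 1
    p[mse == 0 & abs(diff) >= 1e-12] <- 0
    tibble(gene_id = fit$gene_id, contrast = paste(bb, aa, sep = "-"),
           diff = unname(diff), p_adj = unname(p))
  })
  bind_rows(rows)
}

#' Classify orthologs into five variability categories
#'
#' Per-term Benjamini-Hochberg FDR across genes at `fdr_threshold`;
#' a significant interaction takes precedence ("the effect of species
#' depends on sex or vice versa"), then both main effects, then a single
#' main effect, else non-variable. Sex-variable genes carry a direction
#' from the sign of the sex coefficient.
#'
#' @param fit A `gene_anova` result.
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return Tibble: `gene_id`, `fdr_sex`, `fdr_species`, `fdr_interaction`,
#'   `category` (factor over the five classes), `direction`
#'   (female_over/male_over for sex-variable genes, else NA).
#' @export
classify_variance <- function(fit, fdr_threshold = 0.05) {
  stopifnot(inherits(fit, "gene_anova"))
  fdr_sex <- bh_fdr(fit$p_sex)
  fdr_sp <- bh_fdr(fit$p_species)
  fdr_int <- bh_fdr(fit$p_interaction)
  sig_sex <- fdr_sex < fdr_threshold
  sig_sp <- fdr_sp < fdr_threshold
  sig_int <- fdr_int < fdr_threshold
  category <- case_when(
    sig_int ~ "interaction_variable",
    sig_sex & sig_sp ~ "sex_and_species",
    sig_sex ~ "sex_variable",
    sig_sp ~ "species_variable",
    TRUE ~ "non_variable"
  )
  tibble(
    gene_id = fit$gene_id,
    fdr_sex = fdr_sex, fdr_species = fdr_sp, fdr_interaction = fdr_int,
    category = factor(category, levels = c("sex_variable", "species_variable",
                                           "sex_and_species", "interaction_variable",
                                           "non_variable")),
    direction = ifelse(category == "sex_variable",
                       ifelse(fit$coef_sex_male > 0, "male_over", "female_over"),
                       NA_character_)
  )
}
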