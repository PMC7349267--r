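#' Fit the cross-species FPKM scaling model
#'
#' For every non-reference species a slope `beta` is fitted by least
#' squares through the origin, `y = beta * x`, with `x` the species'
#' per-ortholog mean FPKM (across all its samples) and `y` the reference
#' species' means: `beta = sum(x*y) / sum(x^2)`. The reference species has
#' `beta = 1` by construction.
#'
#' @param fpkm Expression tibble of FPKM in ortholog space.
#' @param design Sample design.
#' @param reference Reference species; default is the first species label
#'   alphabetically.
#' @param pseudocount Pseudocount added after scaling (default 0.01).
#' @return An object of class `xnorm_fit` with per-species slopes;
#'   supports [tidy()] and [glance()].
#' @export
fit_xnorm <- function(fpkm, design, reference = NULL, pseudocount = 0.01) {
  design <- validate_design(design)
  m <- expr_matrix(fpkm)
  species <- sort(unique(design$species))
  reference <- reference %||% species[1L]
  if (!reference %in% species) abort(paste0("reference '", reference, "' not in design"))
  sp_means <- vapply(species, function(sp) {
    rowMeans(m[, design$sample_id[design$species == sp], drop = FALSE])
  }, numeric(nrow(m)))
  y <- sp_means[, reference]
  beta <- vapply(species, function(sp) {
    if (sp == reference) return(1)
    fit_scaling(sp_means[, sp], y)
  }, numeric(1L))
  structure(list(beta = beta, reference = reference, pseudocount = pseudocount,
                 n_genes = nrow(m)),
            class = "xnorm_fit")
}

#' @rdname fit_xnorm
#' @param x Target species per-ortholog mean FPKM.
#' @param y Reference species per-ortholog mean FPKM (same orthologs, same
#'   order).
#' @return `fit_scaling()`: the scalar slope `beta`.
#' @export
fit_scaling <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    abort("x and y must be equal-length vectors with >= 2 genes")
  }
  sxx <- sum(x^2)
  if (sxx == 0) abort("all-zero predictor: slope undefined")
  sum(x * y) / sxx
}

#' @export
print.xnorm_fit <- function(x, ...) {
  cat("Cross-species FPKM scaling (origin regression)\n")
  cat("  reference:", x$reference, " pseudocount:", x$pseudocount, "\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.xnorm_fit <- function(x, ...) {
  tibble(species = names(x$beta), beta = unname(x$beta),
         is_reference = names(x$beta) == x$reference)
}

#' @exportS3Method generics::glance
glance.xnorm_fit <- function(x, ...) {
  tibble(reference = x$reference, pseudocount = x$pseudocount,
         n_species = length(x$beta), n_genes = x$n_genes)
}

#' Standardize FPKM across species (sFPKM)
#'
#' Every sample's FPKM is multiplied by its species' fitted slope and the
#' pseudocount is added after scaling:
#' `sFPKM = beta(species) * FPKM + pseudocount`.
#'
#' @param fpkm Expression tibble of FPKM.
#' @param design Sample design.
#' @param fit An `xnorm_fit` from [fit_xnorm()].
#' @return Expression tibble with `units = "sfpkm"`.
#' @export
to_sfpkm <- function(fpkm, design, fit) {
  stopifnot(inherits(fit, "xnorm_fit"))
  design <- validate_design(design)
  m <- expr_matrix(fpkm)
  sp <- design$species[match(colnames(m), design$sample_id)]
  if (anyNA(sp)) abort("sample missing from design")
  missing_beta <- setdiff(unique(sp), names(fit$beta))
  if (length(missing_beta)) {
    abort(paste0("no fitted scaling for species: ", paste(missing_beta, collapse = ", ")))
  }
  out <- sweep(m, 2L, fit$beta[sp], "*") + fit$pseudocount
  as_expr_tbl(out, "sfpkm")
}

#' Filter lowly expressed orthologs
#'
#' Keeps orthologs whose mean sFPKM over all samples is at least
#' `threshold` (genes with mean below the threshold are removed; a mean of
#' exactly `threshold` is retained).
#'
#' @param sfpkm Expression tibble of sFPKM.
#' @param threshold Minimum mean sFPKM (default 2).
#' @return Filtered expression tibble (same units).
#' @export
filter_low_expression <- function(sfpkm, threshold = 2) {
  m <- expr_matrix(sfpkm)
  keep <- rowMeans(m) >= threshold
  out <- sfpkm[keep, , drop = FALSE]
  attr(out, "units") <- expr_units(sfpkm)
  out
}
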