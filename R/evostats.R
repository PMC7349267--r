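#' Per-group mean expression
#'
#' Arithmetic mean of sFPKM across the replicates of each
#' species-population-sex group (or species-sex group with
#' `by_population = FALSE`).
#'
#' @param sfpkm Expression tibble.
#' @param design Sample design.
#' @param by_population Keep populations separate (default) or pool them.
#' @return Tibble: `gene_id` plus one column per group, named
#'   `species.population.sex` (or `species.sex`).
#' @export
group_means <- function(sfpkm, design, by_population = TRUE) {
  design <- validate_design(design)
  m <- expr_matrix(sfpkm)
  if (!all(colnames(m) %in% design$sample_id)) abort("sample missing from design")
  key_of <- function(s) {
    i <- match(s, design$sample_id)
    if (by_population) {
      paste(design$species[i], design$population[i], design$sex[i], sep = ".")
    } else {
      paste(design$species[i], design$sex[i], sep = ".")
    }
  }
  key <- key_of(colnames(m))
  cols <- unique(key)
  out <- matrix(0, nrow(m), length(cols), dimnames = list(NULL, cols))
  for (g in cols) out[, g] <- rowMeans(m[, key == g, drop = FALSE])
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(out))
}

abs_log2_ratio <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) abort("group means must be positive (pseudocount expected)")
  abs(log2(a / b))
}

#' Intraspecific expression variation (Vx)
#'
#' Mean absolute log2 ratio between the two conspecific populations,
#' averaged over the female-female and male-male comparisons:
#' `Vx = (|log2(X_p1f/X_p2f)| + |log2(X_p1m/X_p2m)|) / 2`.
#'
#' @param p1_f,p2_f,p1_m,p2_m Positive group mean vectors (population 1/2,
#'   female/male).
#' @return Numeric vector of Vx.
#' @export
compute_vx <- function(p1_f, p2_f, p1_m, p2_m) {
  (abs_log2_ratio(p1_f, p2_f) + abs_log2_ratio(p1_m, p2_m)) / 2
}

#' Interspecific expression variation (Dx)
#'
#' Mean absolute log2 ratio over the three species pairs within each sex
#' (six terms in total).
#'
#' @param X Named list with elements `<species>.female` / `<species>.male`
#'   (positive mean vectors) for the three focal species.
#' @param species The three focal species labels.
#' @return Numeric vector of Dx.
#' @export
compute_dx <- function(X, species) {
  if (length(species) != 3L) abort("Dx is defined over exactly three species")
  pairs <- combn(species, 2L)
  terms <- list()
  for (sx in c("female", "male")) {
    for (k in seq_len(ncol(pairs))) {
      a <- X[[paste(pairs[1L, k], sx, sep = ".")]]
      b <- X[[paste(pairs[2L, k], sx, sep = ".")]]
      terms[[length(terms) + 1L]] <- abs_log2_ratio(a, b)
    }
  }
  Reduce(`+`, terms) / length(terms)
}

#' Between-sex expression variation (Sx)
#'
#' Mean absolute log2 male/female ratio over the three focal species.
#'
#' @inheritParams compute_dx
#' @return Numeric vector of Sx.
#' @export
compute_sx <- function(X, species) {
  if (length(species) != 3L) abort("Sx is defined over exactly three species")
  terms <- lapply(species, function(sp) {
    abs_log2_ratio(X[[paste(sp, "male", sep = ".")]], X[[paste(sp, "female", sep = ".")]])
  })
  Reduce(`+`, terms) / length(terms)
}

#' Expression-evolution rate (Rx = Dx / Vx)
#'
#' Undefined (NA) when Vx is zero; such orthologs are excluded from rank
#' statistics downstream and their count reported.
#'
#' @param dx,vx Numeric vectors.
#' @return Numeric vector with NA where `vx == 0`.
#' @export
compute_rx <- function(dx, vx) {
  ifelse(vx == 0, NA_real_, dx / vx)
}

#' All four expression-variation statistics per ortholog
#'
#' Computes Dx (between species), Vx (between the two conspecific
#' populations of `pop_species`), Sx (between sexes) and Rx = Dx/Vx from
#' an sFPKM table and the sample design. Species means for Dx and Sx pool
#' all samples of a species (both populations where applicable).
#'
#' @param sfpkm Expression tibble (sFPKM; pseudocount keeps values
#'   positive).
#' @param design Sample design.
#' @param focal_species The three focal species.
#' @param pop_species Species with two populations (for Vx).
#' @return Tibble: `gene_id`, `Dx`, `Vx`, `Sx`, `Rx`.
#' @export
evo_stats <- function(sfpkm, design, focal_species = c("MEAM1", "MED", "AsiaII3"),
                      pop_species = focal_species[1L]) {
  design <- validate_design(design)
  gm_sp <- group_means(sfpkm, design, by_population = FALSE)
  Xs <- as.list(gm_sp[setdiff(names(gm_sp), "gene_id")])
  need <- as.vector(outer(focal_species, c("female", "male"), paste, sep = "."))
  missing <- setdiff(need, names(Xs))
  if (length(missing)) abort(paste0("missing group(s): ", paste(missing, collapse = ", ")))
  gm_pop <- group_means(sfpkm, design, by_population = TRUE)
  Xp <- as.list(gm_pop[setdiff(names(gm_pop), "gene_id")])
  pneed <- as.vector(outer(paste(pop_species, c("pop1", "pop2"), sep = "."),
                           c("female", "male"), paste, sep = "."))
  pmissing <- setdiff(pneed, names(Xp))
  if (length(pmissing)) abort(paste0("missing population group(s): ", paste(pmissing, collapse = ", ")))
  dx <- compute_dx(Xs, focal_species)
  vx <- compute_vx(Xp[[pneed[1L]]], Xp[[pneed[2L]]], Xp[[pneed[3L]]], Xp[[pneed[4L]]])
  sx <- compute_sx(Xs, focal_species)
  tibble(gene_id = gm_sp$gene_id, Dx = dx, Vx = vx, Sx = sx, Rx = compute_rx(dx, vx))
}
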