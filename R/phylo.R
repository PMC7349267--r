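#' Spearman expression distance matrix
#'
#' Pairwise distances `1 - rho` between sample expression profiles, with
#' Spearman's rank correlation computed with average-rank tie handling.
#' With `collapse = TRUE`, per-sample ranks are averaged within each
#' species-sex group before correlating, giving one leaf per group.
#'
#' @param sfpkm Expression tibble (sFPKM).
#' @param design Required when `collapse = TRUE`.
#' @param collapse Average rank profiles within species-sex groups.
#' @return Symmetric numeric matrix with zero diagonal, values in \[0, 2\].
#' @export
spearman_distance <- function(sfpkm, design = NULL, collapse = FALSE) {
  m <- expr_matrix(sfpkm)
  if (nrow(m) < 3L) abort("need >= 3 genes for a rank correlation")
  const <- apply(m, 2L, function(v) diff(range(v)) == 0)
  if (any(const)) {
    abort(paste0("constant expression profile: ", colnames(m)[which(const)[1L]]))
  }
  r <- apply(m, 2L, rank)
  if (collapse) {
    if (is.null(design)) abort("design required to collapse replicates")
    design <- validate_design(design)
    grp <- paste(design$species, design$sex, sep = "_")[match(colnames(m), design$sample_id)]
    r <- vapply(unique(grp), function(g) rowMeans(r[, grp == g, drop = FALSE]),
                numeric(nrow(r)))
  }
  rho <- cor(r, method = "pearson")
  d <- 1 - rho
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

check_dist <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distance must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix is not symmetric")
  if (any(d < 0)) abort("distances must be non-negative")
  if (is.null(rownames(d))) abort("distance matrix needs labels")
  d
}

clamp_negative_edges <- function(tree) {
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warn(paste0(sum(neg), " negative branch length(s) clamped to 0"))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Neighbor-joining expression tree
#'
#' Saitou-Nei neighbor joining on a distance matrix; labels are sorted
#' before tree building so the result does not depend on input order, and
#' negative branch lengths are clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix with labels.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- check_dist(d)
  ord <- order(rownames(d))
  tree <- ape::nj(d[ord, ord])
  clamp_negative_edges(tree)
}

#' Balanced minimum-evolution expression tree
#'
#' Balanced FastME: greedy taxon insertion minimizing the balanced
#' tree-length estimate followed by balanced NNI rearrangements, with
#' balanced least-squares branch lengths.
#'
#' @param d Symmetric distance matrix with labels (>= 4 leaves).
#' @return Unrooted `phylo` tree.
#' @export
bme_tree <- function(d) {
  d <- check_dist(d)
  if (nrow(d) < 4L) abort("balanced minimum evolution needs >= 4 leaves")
  ord <- order(rownames(d))
  tree <- ape::fastme.bal(d[ord, ord], nni = TRUE, spr = TRUE)
  clamp_negative_edges(tree)
}

#' Balanced (Pauplin) tree length
#'
#' Evaluates the balanced minimum-evolution criterion of a topology
#' against a distance matrix: `sum over leaf pairs of 2^(1 - t_ij) d_ij`,
#' where `t_ij` is the number of edges between leaves `i` and `j` in the
#' unrooted binary topology.
#'
#' @param tree `phylo` topology (branch lengths ignored).
#' @param d Distance matrix over the tree's tips.
#' @return Scalar balanced length.
#' @export
balanced_tree_length <- function(tree, d) {
  d <- check_dist(d)
  tree <- ape::unroot(tree)
  topo <- ape::compute.brlen(tree, 1)
  td <- ape::cophenetic.phylo(topo)
  labs <- rownames(td)
  total <- 0
  for (i in seq_len(nrow(td) - 1L)) {
    for (j in (i + 1L):nrow(td)) {
      total <- total + 2^(1 - td[i, j]) * d[labs[i], labs[j]]
    }
  }
  total
}

# canonical split strings of an unrooted tree: for each internal edge, the
# sorted tip set on the side not containing the alphabetically first tip
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  out <- character(0)
  for (k in seq_along(pp)) {
    side <- sort(labels[pp[[k]]])
    if (length(side) >= length(tips) - 1L || length(side) <= 1L) next
    if (anchor %in% side) side <- sort(setdiff(tips, side))
    if (length(side) <= 1L) next
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Gene-bootstrap support for an expression tree
#'
#' Resamples genes with replacement `n_reps` times, rebuilds the tree, and
#' labels every internal bipartition of the reference tree with the
#' percentage of replicates containing it (rounded to integer).
#'
#' @param sfpkm Expression tibble used for the reference tree.
#' @param tree_builder Function from distance matrix to `phylo`
#'   ([nj_tree()] or [bme_tree()]).
#' @param n_reps Bootstrap replicates (default 100).
#' @param seed Integer seed (required for reproducibility).
#' @param design,collapse Passed to [spearman_distance()].
#' @return The reference tree with integer supports in `node.label`.
#' @export
bootstrap_support <- function(sfpkm, tree_builder = bme_tree, n_reps = 100, seed,
                              design = NULL, collapse = FALSE) {
  if (n_reps < 1) abort("n_reps must be >= 1")
  ref <- tree_builder(spearman_distance(sfpkm, design, collapse))
  set.seed(seed)
  ref_splits <- tree_splits(ref)
  tally <- setNames(rep(0L, length(ref_splits)), ref_splits)
  n_genes <- nrow(sfpkm)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(n_genes, n_genes, replace = TRUE)
    boot <- sfpkm[idx, , drop = FALSE]
    boot$gene_id <- sprintf("bg%06d", seq_len(n_genes))
    attr(boot, "units") <- expr_units(sfpkm)
    bt <- try(tree_builder(spearman_distance(boot, design, collapse)), silent = TRUE)
    if (inherits(bt, "try-error")) next
    bs <- tree_splits(bt)
    hit <- ref_splits %in% bs
    tally[hit] <- tally[hit] + 1L
  }
  support <- round(100 * tally / n_reps)
  ref$node.label <- node_support_labels(ref, support)
  ref
}

# map split-level supports back onto internal node labels
node_support_labels <- function(tree, support) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  out <- rep(NA_character_, tree$Nnode)
  for (k in seq_along(pp)) {
    side <- sort(labels[pp[[k]]])
    if (length(side) >= length(tree$tip.label)) { out[k] <- ""; next }
    if (anchor %in% side) side <- sort(setdiff(tips, side))
    key <- paste(side, collapse = "|")
    if (key %in% names(support)) out[k] <- as.character(support[[key]])
  }
  out[is.na(out)] <- ""
  out
}

#' Root a tree on an outgroup
#'
#' @param tree Unrooted `phylo`.
#' @param outgroup Tip label (or labels) of the outgroup.
#' @return Rooted tree.
#' @export
root_tree <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) abort(paste0("outgroup tip(s) not in tree: ", paste(missing, collapse = ", ")))
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Principal component analysis of expression
#'
#' Samples are observations, genes variables. Values are log2-transformed
#' (the sFPKM pseudocount keeps them positive), gene-centered and not
#' scaled. Each component's sign is fixed so that its largest-magnitude
#' gene loading is positive.
#'
#' @param sfpkm Expression tibble.
#' @param log_transform Apply `log2` before the decomposition.
#' @param design Optional design merged into the scores for plotting.
#' @return An `expr_pca` object; [tidy()] gives sample scores, [glance()]
#'   the variance fractions, [autoplot()] a PC1-PC2 scatter.
#' @export
pca_expression <- function(sfpkm, log_transform = TRUE, design = NULL) {
  m <- expr_matrix(sfpkm)
  if (ncol(m) < 2L || nrow(m) < 2L) abort("need >= 2 samples and >= 2 genes")
  x <- t(if (log_transform) log2(m) else m)
  keep <- apply(x, 2L, function(v) diff(range(v)) > 0)
  if (sum(keep) < 2L) abort("fewer than 2 non-constant genes")
  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    imax <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[imax, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- bind_cols(tibble(sample_id = rownames(pc$x)), as_tibble(pc$x))
  if (!is.null(design)) scores <- left_join(scores, validate_design(design), by = "sample_id")
  structure(list(scores = scores, rotation = pc$rotation, var_frac = var_frac),
            class = "expr_pca")
}

#' @export
print.expr_pca <- function(x, ...) {
  cat("Expression PCA:", nrow(x$scores), "samples;",
      "PC1", sprintf("%.1f%%", 100 * x$var_frac[1L]),
      "PC2", sprintf("%.1f%%", 100 * x$var_frac[2L]), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.expr_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.expr_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$var_frac)), var_fraction = x$var_frac)
}

#' @exportS3Method ggplot2::autoplot
autoplot.expr_pca <- function(object, colour = "species", shape = "sex", ...) {
  sc <- object$scores
  p <- ggplot(sc, aes(.data$PC1, .data$PC2))
  if (colour %in% names(sc) && shape %in% names(sc)) {
    p <- p + geom_point(aes(colour = .data[[colour]], shape = .data[[shape]]), size = 2.5)
  } else {
    p <- p + geom_point(size = 2.5)
  }
  p + labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$var_frac[1L]),
    y = sprintf("PC2 (%.1f%%)", 100 * object$var_frac[2L])
  ) + theme_minimal()
}
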