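#' Run the full comparative pipeline on synthetic or provided data
#'
#' Executes, in order: simulation (unless data are supplied), per-species
#' sex-bias classification, cross-species normalization and the low-
#' expression filter, expression phylogenies (NJ and balanced minimum
#' evolution with gene bootstrap) and PCA, codon-alignment simulation and
#' Ka/Ks estimation, the Dx/Vx/Sx/Rx statistics, the per-gene ANOVA
#' decomposition with variance classes, and the category-level report
#' (consistency classes, representation tests, correlation matrix, binned
#' summaries). Every intermediate is written as a plain-text file under
#' `out_dir` and a JSON manifest records seeds, filter counts and file
#' checksums; reruns with the same config are bit-identical.
#'
#' @param config A [sim_config()] (also carries the seed).
#' @param out_dir Output directory (created if missing).
#' @param data Optional pre-simulated data list (as from
#'   [simulate_expression()]); simulated from `config` when NULL.
#' @param bootstrap_reps Gene-bootstrap replicates for the tree (default
#'   100; 0 skips bootstrap).
#' @param fc,fdr DE thresholds (defaults 2-fold, 0.05).
#' @param min_bp Minimum ortholog alignment length in bp.
#' @param min_sfpkm sFPKM filter threshold.
#' @return Invisibly, a list of all in-memory results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir, data = NULL, bootstrap_reps = 100,
                         fc = 2, fdr = 0.05, min_bp = 150, min_sfpkm = 2) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  manifest <- list(seed = config$seed, n_genes = config$n_genes,
                   thresholds = list(fc = fc, fdr = fdr, min_bp = min_bp,
                                     min_sfpkm = min_sfpkm,
                                     pseudocount = 0.01))

  if (is.null(data)) data <- simulate_expression(config)
  write_expression(data$counts, pth("counts.tsv"))
  write_expression(data$fpkm, pth("fpkm.tsv"))
  write_design(data$design, pth("design.tsv"))
  write_orthologs(data$orthologs, pth("orthologs.tsv"))
  write_table(data$truth, pth("truth.tsv"))

  focal <- config$focal_species
  calls <- purrr::map(focal, function(sp) {
    call_sex_bias(data$counts, data$design, sp, fc = fc, alpha = fdr)
  }) |> bind_rows()
  write_table(calls, pth("sexbias.tsv"))

  fit <- fit_xnorm(data$fpkm, data$design)
  sfpkm <- to_sfpkm(data$fpkm, data$design, fit)
  write_expression(sfpkm, pth("sfpkm.tsv"))
  sfpkm_f <- filter_low_expression(sfpkm, min_sfpkm)
  write_expression(sfpkm_f, pth("sfpkm_filtered.tsv"))
  manifest$filters <- list(
    genes_in = nrow(sfpkm), genes_after_sfpkm_filter = nrow(sfpkm_f))
  write_table(tidy(fit), pth("scaling.tsv"))

  d <- spearman_distance(sfpkm_f)
  tree_nj <- nj_tree(d)
  tree_bme <- if (bootstrap_reps > 0) {
    bootstrap_support(sfpkm_f, bme_tree, n_reps = bootstrap_reps,
                      seed = config$seed + 7L)
  } else bme_tree(d)
  if (!is.null(config$outgroup)) {
    og <- grep(paste0("^", config$outgroup, "_"), tree_bme$tip.label, value = TRUE)
    if (length(og)) tree_bme <- root_tree(tree_bme, og)
  }
  write_newick(tree_nj, pth("tree_nj.nwk"))
  write_newick(tree_bme, pth("tree_bme.nwk"))
  pca <- pca_expression(sfpkm_f, design = data$design)
  write_table(tidy(pca), pth("pca_scores.tsv"))

  aln <- simulate_codon_alignments(config, seed = config$seed + 11L)
  kk <- kaks_table(aln, min_bp = min_bp, species = focal)
  avg <- average_kaks(kk)
  cats <- categorize_rates(avg)
  write_table(kk, pth("kaks_pairs.tsv"))
  write_table(cats, pth("kaks_avg.tsv"))
  manifest$filters$alignments_in <- length(aln)
  manifest$filters$alignments_after_length_filter <- length(unique(kk$ortholog_id))

  ev <- evo_stats(sfpkm_f, data$design, focal_species = focal,
                  pop_species = config$pop_species)
  write_table(ev, pth("evostats.tsv"))

  # one population per species keeps the two-way layout balanced
  anova_design <- filter(data$design, .data$population == "pop1")
  av <- gene_anova(sfpkm_f, anova_design, species = focal)
  classes <- classify_variance(av, fdr_threshold = fdr)
  write_table(as_tibble(av), pth("anova.tsv"))
  write_table(classes, pth("classes.tsv"))
  tk <- tukey_hsd_species(av)
  write_table(tk, pth("tukey.tsv"))

  analyzed <- sfpkm_f$gene_id
  cons <- classify_consistency(filter(calls, .data$gene_id %in% analyzed))
  write_table(cons, pth("consistency.tsv"))
  measures <- ev |>
    left_join(select(cats, "ortholog_id", KaKs = "avg_ratio"),
              by = c(gene_id = "ortholog_id"))
  cm <- correlation_matrix(select(measures, "Sx", "Vx", "Dx", "Rx", "KaKs"))
  write_table(tidy(cm), pth("correlations.tsv"))
  ref_calls <- filter(calls, .data$species == focal[1L], .data$gene_id %in% analyzed)
  grid_df <- ref_calls |>
    select("gene_id", "log2_fc") |>
    inner_join(measures, by = "gene_id")
  grid <- bin2d_summary(grid_df, x = "log2_fc", y = "Dx", value = "KaKs")
  write_table(grid, pth("bias_dx_grid.tsv"))

  manifest$counts <- list(
    sex_biased = as.list(table(calls$call)),
    variance_classes = as.list(table(classes$category)),
    consistency = as.list(table(cons$class)),
    rx_undefined = sum(is.na(ev$Rx))
  )
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(data = data, calls = calls, xnorm = fit, sfpkm = sfpkm_f,
                 tree_nj = tree_nj, tree_bme = tree_bme, pca = pca,
                 kaks = kk, kaks_avg = cats, evostats = ev, anova = av,
                 classes = classes, consistency = cons, correlations = cm,
                 grid = grid, manifest = manifest))
}
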