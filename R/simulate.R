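#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the whitefly study design: three focal *Bemisia* species (MEAM1, MED,
#' AsiaII3) plus a divergent greenhouse-whitefly outgroup (GW), two sexes,
#' two biological replicates per colony, and a second conspecific MEAM1
#' population -- five colonies x two sexes x two replicates = 20 samples.
#' Gene-level structure follows the two-way decomposition the downstream
#' ANOVA assumes: each gene belongs to one of five classes (non-variable,
#' sex, species, sex+species, interaction) with log2 effects applied on top
#' of a baseline log2-FPKM drawn from a normal distribution; counts are
#' negative-binomial around library-size-scaled means.
#'
#' @param n_genes Number of 1:1 orthologs to simulate.
#' @param focal_species Labels of the three focal species.
#' @param outgroup Outgroup species label (set `NULL` to omit).
#' @param pop_species Species with a second conspecific population.
#' @param n_reps Biological replicates per colony and sex.
#' @param baseline_mean,baseline_sd Normal parameters of baseline log2 FPKM.
#' @param sex_effect,species_effect,interaction_effect Absolute log2 effect
#'   sizes for the respective gene classes.
#' @param class_props Named proportions over
#'   `c("non_variable","sex_variable","species_variable","sex_and_species","interaction_variable")`;
#'   must sum to 1.
#' @param nb_dispersion Negative-binomial dispersion (0 gives Poisson).
#' @param pop_offset_sd Per-gene log2 offset s.d. between the two
#'   conspecific populations (intraspecific drift; makes Vx > 0).
#' @param outgroup_sd Per-gene log2 offset s.d. of the outgroup relative to
#'   the focal clade (its extra divergence).
#' @param library_sizes Optional named per-sample library sizes; by default
#'   drawn uniformly between 8 and 14 million fragments.
#' @param gene_length_kb Fixed gene length used in the FPKM link
#'   `fpkm = count / (library_size_millions * gene_length_kb)`.
#' @param n_codons Codons per simulated coding fragment.
#' @param omega_by_class Named dN/dS per gene class (all must be <= 1).
#' @param tree Rooted `phylo` species tree with branch lengths in expected
#'   nucleotide mutation proposals per site; default mirrors the focal
#'   clade with a distant outgroup.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       focal_species = c("MEAM1", "MED", "AsiaII3"),
                       outgroup = "GW",
                       pop_species = "MEAM1",
                       n_reps = 2,
                       baseline_mean = 5, baseline_sd = 2,
                       sex_effect = 2, species_effect = 2, interaction_effect = 2,
                       class_props = c(non_variable = 0.50, sex_variable = 0.20,
                                       species_variable = 0.15, sex_and_species = 0.10,
                                       interaction_variable = 0.05),
                       nb_dispersion = 0.05,
                       pop_offset_sd = 0.25,
                       outgroup_sd = 2,
                       library_sizes = NULL,
                       gene_length_kb = 1,
                       n_codons = 200,
                       omega_by_class = c(non_variable = 0.08, sex_variable = 0.05,
                                          species_variable = 0.30, sex_and_species = 0.15,
                                          interaction_variable = 0.15),
                       tree = NULL,
                       seed = 1L) {
  classes <- c("non_variable", "sex_variable", "species_variable",
               "sex_and_species", "interaction_variable")
  if (!setequal(names(class_props), classes)) {
    abort("class_props must be named over the five gene classes")
  }
  class_props <- class_props[classes]
  if (any(class_props < 0)) abort("class_props must be non-negative")
  if (abs(sum(class_props) - 1) > 1e-8) abort("class_props must sum to 1")
  if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (!setequal(names(omega_by_class), classes)) {
    abort("omega_by_class must be named over the five gene classes")
  }
  if (any(omega_by_class <= 0)) abort("omega must be > 0")
  if (any(omega_by_class > 1)) {
    abort("omega > 1 not supported by the thinning simulator")
  }
  if (is.null(tree)) {
    a <- focal_species[1L]; b <- focal_species[2L]; c3 <- focal_species[3L]
    nwk <- if (is.null(outgroup)) {
      sprintf("((%s:0.03,%s:0.03):0.03,%s:0.06);", a, b, c3)
    } else {
      sprintf("(((%s:0.03,%s:0.03):0.03,%s:0.06):0.12,%s:0.18);", a, b, c3, outgroup)
    }
    tree <- ape::read.tree(text = nwk)
  }
  structure(list(
    n_genes = as.integer(n_genes), focal_species = focal_species,
    outgroup = outgroup, pop_species = pop_species, n_reps = as.integer(n_reps),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    sex_effect = sex_effect, species_effect = species_effect,
    interaction_effect = interaction_effect,
    class_props = class_props, nb_dispersion = nb_dispersion,
    pop_offset_sd = pop_offset_sd, outgroup_sd = outgroup_sd,
    library_sizes = library_sizes, gene_length_kb = gene_length_kb,
    n_codons = as.integer(n_codons), omega_by_class = omega_by_class,
    tree = tree, seed = as.integer(seed)
  ), class = "sim_config")
}

sim_design <- function(config) {
  rows <- list()
  all_sp <- c(config$focal_species, config$outgroup)
  for (sp in all_sp) {
    pops <- if (identical(sp, config$pop_species)) c("pop1", "pop2") else "pop1"
    for (pop in pops) {
      for (sx in c("female", "male")) {
        for (r in seq_len(config$n_reps)) {
          rows[[length(rows) + 1L]] <- tibble(
            sample_id = paste(sp, pop, substr(sx, 1L, 1L), r, sep = "_"),
            species = sp, population = pop, sex = sx, replicate = r
          )
        }
      }
    }
  }
  validate_design(bind_rows(rows))
}

#' Simulate replicated expression data with known structure
#'
#' Draws per-gene classes, effects and baselines, then negative-binomial
#' counts with mean `library_size_millions * gene_length_kb * 2^eta`, where
#' `eta` is the gene's log2 "true FPKM" in that sample's group. FPKM is the
#' exact inverse of that link, so counts and FPKM are mutually consistent.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list: `counts` and `fpkm` (expression tibbles in ortholog
#'   space), `design`, `orthologs` (1:1 map with per-species gene ids) and
#'   `truth` (per-gene class, direction, affected species, omega, and the
#'   per-group true log2 FPKM as a nested matrix attribute `log2_means`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- sim_design(config)
  n <- config$n_genes
  classes <- names(config$class_props)
  gene_class <- sample(classes, n, replace = TRUE, prob = config$class_props)
  gene_id <- sprintf("OG%05d", seq_len(n))

  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  sex_dir <- sample(c(-1, 1), n, replace = TRUE)          # +1: male over female
  sp_idx <- sample(seq_along(config$focal_species), n, replace = TRUE)
  sp_dir <- sample(c(-1, 1), n, replace = TRUE)
  int_cell_sex <- sample(c("female", "male"), n, replace = TRUE)
  pop_off <- rnorm(n, 0, config$pop_offset_sd)            # pop2 minus pop1
  out_off <- rnorm(n, 0, config$outgroup_sd)

  has_sex <- gene_class %in% c("sex_variable", "sex_and_species")
  has_sp <- gene_class %in% c("species_variable", "sex_and_species")
  has_int <- gene_class == "interaction_variable"

  # per-gene true log2 FPKM for every (species, population, sex) group
  groups <- distinct(design, .data$species, .data$population, .data$sex)
  eta <- matrix(baseline, nrow = n, ncol = nrow(groups))
  colnames(eta) <- paste(groups$species, groups$population, groups$sex, sep = ".")
  for (k in seq_len(nrow(groups))) {
    sp <- groups$species[k]; pop <- groups$population[k]; sx <- groups$sex[k]
    col <- eta[, k]
    male <- sx == "male"
    col <- col + ifelse(has_sex & male, sex_dir * config$sex_effect / 2, 0) -
      ifelse(has_sex & !male, sex_dir * config$sex_effect / 2, 0)
    if (sp %in% config$focal_species) {
      affected <- has_sp & config$focal_species[sp_idx] == sp
      col <- col + ifelse(affected, sp_dir * config$species_effect, 0)
      int_hit <- has_int & config$focal_species[sp_idx] == sp & int_cell_sex == sx
      col <- col + ifelse(int_hit, sp_dir * config$interaction_effect, 0)
    }
    if (identical(sp, config$outgroup)) col <- col + out_off
    if (pop == "pop2") col <- col + pop_off
    eta[, k] <- col
  }

  lib <- config$library_sizes
  if (is.null(lib)) {
    lib <- setNames(runif(nrow(design), 8e6, 14e6), design$sample_id)
  } else if (is.null(names(lib)) || !all(design$sample_id %in% names(lib))) {
    abort("library_sizes must be named by sample_id")
  }

  counts <- matrix(0, nrow = n, ncol = nrow(design),
                   dimnames = list(gene_id, design$sample_id))
  grp_key <- paste(design$species, design$population, design$sex, sep = ".")
  for (j in seq_len(nrow(design))) {
    mu <- (lib[design$sample_id[j]] / 1e6) * config$gene_length_kb *
      2^eta[, grp_key[j]]
    counts[, j] <- if (config$nb_dispersion > 0) {
      rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    } else {
      rpois(n, mu)
    }
  }
  fpkm <- sweep(counts, 2L, (lib[design$sample_id] / 1e6) * config$gene_length_kb, "/")

  all_sp <- c(config$focal_species, config$outgroup)
  orth <- bind_cols(tibble(ortholog_id = gene_id),
                    as_tibble(setNames(
                      lapply(all_sp, function(sp) paste0(sp, "_g", sprintf("%05d", seq_len(n)))),
                      all_sp)))
  truth <- tibble(
    ortholog_id = gene_id, class = gene_class,
    sex_direction = ifelse(has_sex, ifelse(sex_dir > 0, "male_over", "female_over"), NA_character_),
    affected_species = ifelse(has_sp | has_int, config$focal_species[sp_idx], NA_character_),
    omega = unname(config$omega_by_class[gene_class])
  )
  attr(truth, "log2_means") <- eta
  list(counts = as_expr_tbl(counts, "counts"),
       fpkm = as_expr_tbl(fpkm, "fpkm"),
       design = design, orthologs = validate_orthologs(orth), truth = truth,
       library_sizes = lib)
}

#' Simulate codon alignments along a species tree at controlled dN/dS
#'
#' An ancestral sequence is drawn uniformly over sense codons and evolved
#' down the rooted tree: along a branch of length `t`, the number of
#' single-nucleotide mutation proposals is Poisson with mean
#' `t * 3 * n_codons`; each proposal picks a uniform site and a uniform
#' alternative base, is rejected if it would create a stop codon, accepted
#' when synonymous, and accepted with probability `omega` when
#' nonsynonymous (Gillespie-style thinning, so realized dN/dS is
#' approximately `omega`). `omega > 1` is rejected: the thinning scheme
#' caps acceptance probabilities at 1.
#'
#' @param config A [sim_config()] (supplies `n_codons`, per-class omega and
#'   the species tree); or pass `omega`/`tree`/`n_codons` explicitly.
#' @param omega Per-gene dN/dS vector (recycled); defaults to
#'   `config$omega_by_class` applied to freshly drawn classes.
#' @param n_genes Number of alignments; default `length(omega)`.
#' @param tree Rooted `phylo`; default `config$tree`.
#' @param n_codons Codons per gene; default `config$n_codons`.
#' @param seed Seed; default `config$seed + 1`.
#' @param ids Ortholog ids for the alignment names.
#' @return Named list of codon alignments (named character vectors keyed by
#'   species), suitable for [kaks_table()].
#' @export
simulate_codon_alignments <- function(config = NULL, omega = NULL, n_genes = NULL,
                                      tree = NULL, n_codons = NULL, seed = NULL,
                                      ids = NULL) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    tree <- tree %||% config$tree
    n_codons <- n_codons %||% config$n_codons
    seed <- seed %||% (config$seed + 1L)
  }
  if (is.null(tree) || is.null(n_codons)) abort("tree and n_codons are required")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(omega)) {
    if (is.null(config)) abort("omega required without a config")
    n_genes <- n_genes %||% config$n_genes
    cls <- sample(names(config$class_props), n_genes, replace = TRUE,
                  prob = config$class_props)
    omega <- unname(config$omega_by_class[cls])
  }
  n_genes <- n_genes %||% length(omega)
  omega <- rep_len(omega, n_genes)
  if (any(omega > 1)) abort("omega > 1 is not supported by the thinning simulator")
  if (any(omega < 0)) abort("omega must be >= 0")
  ids <- ids %||% sprintf("OG%05d", seq_len(n_genes))
  out <- vector("list", n_genes)
  names(out) <- ids
  for (g in seq_len(n_genes)) {
    anc <- sample(sense_codons(), n_codons, replace = TRUE)
    tips <- evolve_tree(anc, tree, omega[g])
    out[[g]] <- vapply(tips, function(x) paste(x, collapse = ""), character(1L))
  }
  out
}

# evolve a codon vector down every edge of a rooted phylo; returns tip states
evolve_tree <- function(anc_codons, tree, omega) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  states <- vector("list", n_tip + tree$Nnode)
  states[[root]] <- anc_codons
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1L]; child <- ord$edge[k, 2L]
    states[[child]] <- evolve_branch(states[[par]], ord$edge.length[k], omega)
  }
  setNames(states[seq_len(n_tip)], tree$tip.label)
}

evolve_branch <- function(codons, t, omega) {
  n_nt <- 3L * length(codons)
  n_events <- rpois(1L, t * n_nt)
  if (n_events == 0L) return(codons)
  aa <- codon_code()$aa
  nts <- c("A", "C", "G", "T")
  sites <- sample.int(n_nt, n_events, replace = TRUE)
  u <- runif(n_events)
  pick <- sample.int(3L, n_events, replace = TRUE)
  for (e in seq_len(n_events)) {
    i <- sites[e]
    cidx <- (i - 1L) %/% 3L + 1L
    pos <- (i - 1L) %% 3L + 1L
    old <- codons[cidx]
    oldch <- substr(old, pos, pos)
    newch <- setdiff(nts, oldch)[pick[e]]
    new <- old
    substr(new, pos, pos) <- newch
    if (aa[new] == "*") next
    if (aa[new] == aa[old] || u[e] <= omega) codons[cidx] <- new
  }
  codons
}
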