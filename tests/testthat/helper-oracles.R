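# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles, sharing no code path with the package.

.oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc), chartr("U", "T", names(gc)))
})
oracle_sense <- names(.oracle_code)[.oracle_code != "*"]

oracle_split_codons <- function(s) {
  s <- toupper(s)
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

# all 9 single-nucleotide mutants of a codon
oracle_mutants <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) != nt) {
        m <- codon
        substr(m, pos, pos) <- nt
        out <- c(out, m)
      }
    }
  }
  out
}

# permutations of a vector (tiny n)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# NG86 from scratch: sites by mutant enumeration, differences by explicit
# path enumeration, Jukes-Cantor conversion
oracle_ng86 <- function(s1, s2) {
  c1 <- oracle_split_codons(s1)
  c2 <- oracle_split_codons(s2)
  syn_sites_of <- function(cod) {
    mu <- oracle_mutants(cod)
    syn <- sum(.oracle_code[mu] == .oracle_code[cod] & .oracle_code[mu] != "*")
    3 * syn / 9
  }
  S <- (sum(vapply(c1, syn_sites_of, 0)) + sum(vapply(c2, syn_sites_of, 0))) / 2
  N <- 3 * length(c1) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(c1)) {
    if (c1[i] == c2[i]) next
    pos <- which(strsplit(c1[i], "")[[1]] != strsplit(c2[i], "")[[1]])
    counts <- NULL
    for (ord in oracle_perms(pos)) {
      cur <- c1[i]
      syn <- 0; non <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2[i], p, p)
        if (.oracle_code[nxt] == "*") blocked <- TRUE
        if (.oracle_code[nxt] == .oracle_code[cur]) syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      counts <- rbind(counts, c(syn, non, blocked))
    }
    ok <- counts[, 3] == 0
    if (!any(ok)) ok <- rep(TRUE, nrow(counts))
    Sd <- Sd + mean(counts[ok, 1])
    Nd <- Nd + mean(counts[ok, 2])
  }
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, ks = jc(Sd / S), ka = jc(Nd / N))
}

# random stop-free codon sequence
random_cds <- function(n_codons) {
  paste(sample(oracle_sense, n_codons, replace = TRUE), collapse = "")
}

# Benjamini-Hochberg by the step-up definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# median-of-ratios factors by direct enumeration
oracle_mor_factors <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  mp <- m[keep, , drop = FALSE]
  gm <- apply(mp, 1, function(r) prod(r)^(1 / length(r)))
  f <- apply(sweep(mp, 1, gm, "/"), 2, median)
  f / prod(f)^(1 / length(f))
}

# conditional NB exact test through unnormalized dnbinom products
oracle_nb_exact <- function(y1, y2, phi, mu = 7.3) {
  A <- sum(round(y1)); B <- sum(round(y2)); T <- A + B
  n1 <- length(y1); n2 <- length(y2)
  a <- 0:T
  w <- if (phi <= 0) {
    dpois(a, n1 * mu) * dpois(T - a, n2 * mu)
  } else {
    dnbinom(a, size = n1 / phi, mu = n1 * mu) *
      dnbinom(T - a, size = n2 / phi, mu = n2 * mu)
  }
  w <- w / sum(w)
  sum(w[w <= w[A + 1] * (1 + 1e-7)])
}

# random additive tree and its exact leaf-to-leaf distances
random_additive <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   tip.label = paste0("t", seq_len(n_leaves)))
  tr$edge.length <- runif(length(tr$edge.length), 0.5, 3)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# small expression tibble with uniform random values
random_expr <- function(n_genes, n_samples, units = "fpkm", min = 0, max = 100) {
  m <- matrix(runif(n_genes * n_samples, min, max), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  as_expr_tbl(m, units)
}

# fit + apply the cross-species scaling in one step
to_sfpkm_default <- function(fpkm, design) {
  to_sfpkm(fpkm, design, fit_xnorm(fpkm, design))
}

# the generator emits FPKM that is already commensurate across species
# (true scaling slopes are 1), so truth-scaled sFPKM is FPKM + pseudocount
sfpkm_true <- function(fpkm, pseudocount = 0.01) {
  as_expr_tbl(expr_matrix(fpkm) + pseudocount, "sfpkm")
}

# design matching sim_design() labels for hand-built examples
toy_design <- function(species = c("MEAM1", "MED", "AsiaII3"), pops = "pop1",
                       pop_species = "MEAM1", reps = 2) {
  rows <- list()
  for (sp in species) {
    pp <- if (sp == pop_species) pops else "pop1"
    for (pop in pp) for (sx in c("female", "male")) for (r in seq_len(reps)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste(sp, pop, substr(sx, 1, 1), r, sep = "_"),
        species = sp, population = pop, sex = sx, replicate = r)
    }
  }
  do.call(rbind, rows)
}
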