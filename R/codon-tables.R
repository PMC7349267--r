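# Codon bookkeeping shared by the NG86 estimator and the codon simulator.
# The universal genetic code is taken from Biostrings::GENETIC_CODE.

.codon_env <- new.env(parent = emptyenv())

codon_code <- function() {
  if (is.null(.codon_env$aa)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    codons <- chartr("U", "T", codons)
    aa <- setNames(unname(gc), codons)
    .codon_env$aa <- aa
    .codon_env$sense <- names(aa)[aa != "*"]
    .codon_env$stops <- names(aa)[aa == "*"]
  }
  .codon_env
}

#' Sense codons of the universal genetic code
#' @return Character vector of the 61 non-stop codons.
#' @keywords internal
sense_codons <- function() codon_code()$sense

is_stop_codon <- function(codon) unname(codon_code()$aa[codon] == "*")

codon_aa <- function(codon) unname(codon_code()$aa[codon])

# the 9 single-nucleotide neighbors of a codon
codon_neighbors <- function(codon) {
  nts <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1L]]
  out <- character(9L)
  k <- 0L
  for (pos in 1:3) {
    for (nt in setdiff(nts, ch[pos])) {
      new <- ch
      new[pos] <- nt
      k <- k + 1L
      out[k] <- paste(new, collapse = "")
    }
  }
  out
}

# NG86 synonymous site count of one codon: 3 * (fraction of the 9
# single-nucleotide changes that are synonymous); changes to stop codons
# count as nonsynonymous.
codon_syn_sites <- function() {
  env <- codon_code()
  if (is.null(env$syn_sites)) {
    s <- vapply(env$sense, function(cd) {
      nb <- codon_neighbors(cd)
      sum(env$aa[nb] == env$aa[cd] & env$aa[nb] != "*") / 3
    }, numeric(1L))
    env$syn_sites <- s
  }
  env$syn_sites
}

# Average synonymous/nonsynonymous difference counts between two codons,
# averaged over all orderings of the differing positions with equal weight;
# orderings passing through a stop codon are excluded and the weights
# renormalized (if every ordering is blocked, all are kept).
codon_path_counts <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  a <- strsplit(c1, "")[[1L]]
  b <- strsplit(c2, "")[[1L]]
  diff_pos <- which(a != b)
  aa <- codon_code()$aa
  perms <- switch(length(diff_pos),
    list(diff_pos),
    list(diff_pos, rev(diff_pos)),
    {
      p <- diff_pos
      list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)], p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
    })
  step_counts <- function(ord) {
    cur <- a
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b[pos]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (aa[to] == "*") blocked <- TRUE
      if (aa[from] == aa[to]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn, nonsyn, blocked)
  }
  res <- vapply(perms, step_counts, numeric(3L))
  keep <- res[3L, ] == 0
  if (!any(keep)) keep <- rep(TRUE, ncol(res))
  c(syn = mean(res[1L, keep]), nonsyn = mean(res[2L, keep]))
}

# Lazily cached 61x61 lookup of path-averaged difference counts.
codon_pair_tables <- function() {
  env <- codon_code()
  if (is.null(env$pair_syn)) {
    sense <- env$sense
    n <- length(sense)
    ps <- matrix(0, n, n, dimnames = list(sense, sense))
    pn <- ps
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        cnt <- codon_path_counts(sense[i], sense[j])
        ps[i, j] <- ps[j, i] <- cnt[["syn"]]
        pn[i, j] <- pn[j, i] <- cnt[["nonsyn"]]
      }
    }
    env$pair_syn <- ps
    env$pair_nonsyn <- pn
  }
  list(syn = env$pair_syn, nonsyn = env$pair_nonsyn)
}
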