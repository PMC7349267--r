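#' Pairwise Ka/Ks by Nei-Gojobori (1986) counting
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence as the
#' per-codon fraction of single-nucleotide changes that are synonymous
#' (changes to stop codons count as nonsynonymous), averages site counts
#' over the two sequences, counts observed synonymous/nonsynonymous
#' differences averaged over all shortest mutation paths between differing
#' codons (equal weights; paths through stop codons excluded and the
#' weights renormalized), and converts the proportions with the
#' Jukes-Cantor correction `d = -(3/4) log(1 - (4/3) p)`.
#'
#' @param seq1,seq2 Equal-length, gap-free, stop-free coding sequences
#'   (upper- or lower-case A/C/G/T), length divisible by 3.
#' @return A one-row tibble: `S`, `N` (site counts), `Sd`, `Nd` (difference
#'   counts), `pS`, `pN`, `ka`, `ks`, `ratio` (NA when `ks` is 0 or either
#'   class is saturated) and `saturated` (TRUE when a Jukes-Cantor argument
#'   is out of range).
#' @examples
#' ng86_kaks("ATGAAA", "ATGAAG")  # one synonymous third-position change
#' @export
ng86_kaks <- function(seq1, seq2) {
  c1 <- prepare_codons(seq1, "seq1")
  c2 <- prepare_codons(seq2, "seq2")
  if (length(c1) != length(c2)) abort("sequences differ in length")
  syn_sites <- codon_syn_sites()
  S <- (sum(syn_sites[c1]) + sum(syn_sites[c2])) / 2
  N <- 3 * length(c1) - S
  tabs <- codon_pair_tables()
  idx <- cbind(match(c1, rownames(tabs$syn)), match(c2, colnames(tabs$syn)))
  Sd <- sum(tabs$syn[idx])
  Nd <- sum(tabs$nonsyn[idx])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ks <- jc(pS)
  ka <- jc(pN)
  saturated <- is.na(ks) || is.na(ka)
  ratio <- if (!saturated && ks > 0) ka / ks else NA_real_
  tibble(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
         ka = ka, ks = ks, ratio = ratio, saturated = saturated)
}

prepare_codons <- function(s, what) {
  s <- toupper(s)
  if (nchar(s) %% 3L != 0L) abort(paste0(what, ": length not divisible by 3"))
  if (stringr::str_detect(s, "[^ACGT]")) abort(paste0(what, ": must be gap-free A/C/G/T"))
  cod <- seq_codons(s)
  if (any(is_stop_codon(cod))) abort(paste0(what, ": internal stop codon"))
  cod
}

#' Drop short ortholog alignments
#'
#' Alignments whose ungapped aligned length is below `min_bp` (default 150
#' bp, i.e. 50 codons) are excluded from rate estimation.
#'
#' @param alignments Named list of codon alignments.
#' @param min_bp Minimum aligned length in base pairs (kept when `>= min_bp`).
#' @return Filtered list.
#' @export
filter_short_fragments <- function(alignments, min_bp = 150) {
  keep <- vapply(alignments, function(aln) {
    cod <- lapply(aln, seq_codons)
    any_gap <- Reduce(`|`, lapply(cod, function(x) stringr::str_detect(x, "-")))
    3L * sum(!any_gap) >= min_bp
  }, logical(1L))
  alignments[keep]
}

#' Ka/Ks table for every ortholog and species pair
#'
#' Applies the short-fragment filter, drops codon columns gapped in any
#' sequence of a group, and runs [ng86_kaks()] on every pair of species in
#' each alignment.
#'
#' @param alignments Named list of codon alignments (names are ortholog ids).
#' @param min_bp Minimum ungapped aligned length in bp.
#' @param species Optional subset/order of species to compare (default: all
#'   species of each alignment).
#' @return Tibble with `ortholog_id`, `species_a`, `species_b` and the
#'   [ng86_kaks()] columns.
#' @export
kaks_table <- function(alignments, min_bp = 150, species = NULL) {
  alignments <- filter_short_fragments(alignments, min_bp = min_bp)
  rows <- purrr::imap(alignments, function(aln, oid) {
    if (!is.null(species)) aln <- aln[intersect(species, names(aln))]
    aln <- drop_gapped_codons(aln)
    sp <- names(aln)
    if (length(sp) < 2L) return(NULL)
    pairs <- combn(sp, 2L)
    purrr::map(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      bind_cols(tibble(ortholog_id = oid, species_a = a, species_b = b),
                ng86_kaks(aln[[a]], aln[[b]]))
    }) |> bind_rows()
  })
  bind_rows(rows)
}

# codon columns with a gap in ANY sequence are removed before counting
drop_gapped_codons <- function(aln) {
  cod <- lapply(aln, seq_codons)
  any_gap <- Reduce(`|`, lapply(cod, function(x) stringr::str_detect(x, "-")))
  vapply(cod, function(x) paste(x[!any_gap], collapse = ""), character(1L))
}

#' Average Ka/Ks over species pairs
#'
#' Arithmetic mean over the defined pairwise ratios of each ortholog;
#' orthologs with no defined pair are dropped with a warning.
#'
#' @param kaks Tibble from [kaks_table()].
#' @return Tibble `ortholog_id`, `n_pairs`, `avg_ratio`.
#' @export
average_kaks <- function(kaks) {
  out <- kaks |>
    group_by(.data$ortholog_id) |>
    summarise(n_pairs = sum(!is.na(.data$ratio)),
              avg_ratio = ifelse(.data$n_pairs[1L] > 0, mean(.data$ratio, na.rm = TRUE), NA_real_),
              .groups = "drop")
  dropped <- out$ortholog_id[out$n_pairs == 0L]
  if (length(dropped)) {
    warn(paste0(length(dropped), " ortholog(s) with no defined Ka/Ks ratio dropped"))
  }
  filter(out, .data$n_pairs > 0L)
}

#' Assign Ka/Ks rate categories
#'
#' `low` when the average ratio is below 0.1; `high` when strictly above
#' the empirical upper quartile of the analyzed set (type-7 linear
#' interpolation quantile); `mid` otherwise. A separate `positive` flag
#' marks ratios strictly above 1.
#'
#' @param avg Tibble from [average_kaks()] (needs `ortholog_id`, `avg_ratio`).
#' @param low_cut Threshold for the slow category.
#' @return Input with `category` (factor low/mid/high), `positive` (logical)
#'   and an `upper_quartile` attribute.
#' @export
categorize_rates <- function(avg, low_cut = 0.1) {
  q3 <- unname(quantile(avg$avg_ratio, 0.75, type = 7, na.rm = TRUE))
  out <- mutate(avg,
    category = factor(case_when(
      .data$avg_ratio < low_cut ~ "low",
      .data$avg_ratio > q3 ~ "high",
      TRUE ~ "mid"
    ), levels = c("low", "mid", "high")),
    positive = .data$avg_ratio > 1
  )
  attr(out, "upper_quartile") <- q3
  out
}
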