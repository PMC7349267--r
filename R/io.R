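#' Read a gene-by-sample expression table
#'
#' Expression tables are plain TSV: a header row of sample ids, a first
#' column of gene ids, and non-negative numeric values (raw counts, FPKM or
#' sFPKM depending on `units`). The returned tibble keeps `gene_id` as its
#' first column, one numeric column per sample, and records the unit kind in
#' the `"units"` attribute.
#'
#' @param path Path to a tab-separated file.
#' @param units One of `"counts"`, `"fpkm"`, `"sfpkm"`.
#' @return A validated expression tibble (`gene_id` + one column per sample).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' ex <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(0, 2), s2 = c(1, 3))
#' write_expression(ex, tf, units = "counts")
#' read_expression(tf, units = "counts")
#' @export
read_expression <- function(path, units = c("counts", "fpkm", "sfpkm")) {
  units <- match.arg(units)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2L) {
    abort("expression table needs a gene id column plus at least one sample")
  }
  names(tbl)[1L] <- "gene_id"
  tbl$gene_id <- as.character(tbl$gene_id)
  validate_expression(tbl, units = units)
}

#' Write an expression table to TSV
#'
#' @param x Expression tibble as returned by [read_expression()].
#' @param path Output path.
#' @param units Unit kind recorded for round-tripping (defaults to the
#'   table's own `"units"` attribute).
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path, units = expr_units(x)) {
  x <- validate_expression(x, units = units %||% "counts")
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' @rdname read_expression
#' @param x A data frame to validate in place of reading from disk.
#' @export
validate_expression <- function(x, units = c("counts", "fpkm", "sfpkm")) {
  units <- match.arg(units)
  x <- as_tibble(x)
  if (!"gene_id" %in% names(x)) {
    abort("expression table must have a 'gene_id' first column")
  }
  sample_ids <- setdiff(names(x), "gene_id")
  if (length(sample_ids) == 0L) abort("expression table has no sample columns")
  dup_g <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup_g)) {
    abort(paste0("duplicated gene id(s): ", paste(head(dup_g, 3L), collapse = ", ")))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    abort(paste0("duplicated sample id(s): ", paste(dup_s, collapse = ", ")))
  }
  for (s in sample_ids) {
    v <- x[[s]]
    if (!is.numeric(v)) abort(paste0("sample column '", s, "' is not numeric"))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      abort(paste0(
        "negative or non-finite value at gene '", x$gene_id[bad[1L]],
        "', sample '", s, "'"
      ))
    }
  }
  attr(x, "units") <- units
  x
}

#' @rdname read_expression
#' @export
expr_units <- function(x) attr(x, "units", exact = TRUE)

#' Convert an expression tibble to a numeric matrix (genes x samples)
#'
#' @param x Expression tibble.
#' @return Numeric matrix with gene ids as rownames.
#' @export
expr_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

#' Convert a genes-x-samples matrix to an expression tibble
#'
#' @param m Numeric matrix with rownames (gene ids) and colnames (samples).
#' @param units Unit kind.
#' @return Expression tibble.
#' @export
as_expr_tbl <- function(m, units = c("counts", "fpkm", "sfpkm")) {
  units <- match.arg(units)
  tbl <- bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
  validate_expression(tbl, units = units)
}

#' Read a sample design table
#'
#' The design maps each sample to its species, population, sex and
#' replicate. Sex labels are normalized to lowercase `"female"`/`"male"`
#' (initials `F`/`M` accepted).
#'
#' @param path TSV with columns `sample_id`, `species`, `population`, `sex`,
#'   `replicate`.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_design(tbl)
}

#' @rdname read_design
#' @param x A data frame to validate in place of reading from disk.
#' @export
validate_design <- function(x) {
  x <- as_tibble(x)
  need <- c("sample_id", "species", "population", "sex", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("design lacks column(s): ", paste(miss, collapse = ", ")))
  if (nrow(x) == 0L) abort("no samples in design")
  dup <- unique(x$sample_id[duplicated(x$sample_id)])
  if (length(dup)) abort(paste0("duplicated sample_id: ", paste(dup, collapse = ", ")))
  sex <- tolower(as.character(x$sex))
  sex[sex %in% c("f", "female")] <- "female"
  sex[sex %in% c("m", "male")] <- "male"
  bad <- setdiff(unique(sex), c("female", "male"))
  if (length(bad)) abort(paste0("unknown sex label(s): ", paste(bad, collapse = ", ")))
  rep_n <- suppressWarnings(as.integer(x$replicate))
  if (anyNA(rep_n) || any(rep_n < 1L)) abort("replicate must be a positive integer")
  mutate(x,
    sample_id = as.character(.data$sample_id),
    species = as.character(.data$species),
    population = as.character(.data$population),
    sex = !!sex, replicate = !!rep_n
  )
}

#' @rdname read_design
#' @export
write_design <- function(x, path) {
  readr::write_tsv(validate_design(x), path, progress = FALSE)
  invisible(x)
}

#' Read a 1:1 ortholog table
#'
#' One row per ortholog group: an `ortholog_id` column plus one column per
#' species holding that species' member gene id. The map must be strictly
#' 1:1 -- every species contributes exactly one gene per ortholog and no
#' gene occurs in two groups.
#'
#' @param path TSV path.
#' @return Ortholog tibble.
#' @export
read_orthologs <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_orthologs(tbl)
}

#' @rdname read_orthologs
#' @param x A data frame to validate in place of reading from disk.
#' @export
validate_orthologs <- function(x) {
  x <- as_tibble(x)
  if (!"ortholog_id" %in% names(x)) abort("ortholog table must have an 'ortholog_id' column")
  sp <- setdiff(names(x), "ortholog_id")
  if (length(sp) < 2L) abort("ortholog table needs at least two species columns")
  dup <- unique(x$ortholog_id[duplicated(x$ortholog_id)])
  if (length(dup)) abort(paste0("duplicated ortholog_id: ", paste(dup, collapse = ", ")))
  for (s in sp) {
    v <- as.character(x[[s]])
    if (anyNA(v) || any(v == "")) abort(paste0("species '", s, "' missing a gene in some ortholog"))
    d <- unique(v[duplicated(v)])
    if (length(d)) abort(paste0("gene '", d[1L], "' appears in two orthologs (species ", s, ")"))
  }
  x
}

#' @rdname read_orthologs
#' @export
write_orthologs <- function(x, path) {
  readr::write_tsv(validate_orthologs(x), path, progress = FALSE)
  invisible(x)
}

#' Read per-ortholog codon alignments from FASTA
#'
#' Headers follow the `"orthologID|species"` convention (delimiter
#' configurable). Sequences of one ortholog must share a common length
#' divisible by three, with gaps (if any) in whole codons. Codon columns
#' that are gapped in *any* sequence of the group are dropped before
#' downstream rate estimation; orthologs missing one of the expected
#' species are skipped with a warning.
#'
#' @param path FASTA path.
#' @param species Optional character vector: species expected per ortholog.
#' @param delim Header delimiter between ortholog id and species label.
#' @return Named list of codon alignments; each element is a named character
#'   vector (one upper-case sequence per species).
#' @export
read_codon_fasta <- function(path, species = NULL, delim = "|") {
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  parts <- stringr::str_split_fixed(headers, stringr::fixed(delim), 2L)
  if (any(parts[, 2L] == "")) {
    abort(paste0("FASTA header without '", delim, "' delimiter: ", headers[parts[, 2L] == ""][1L]))
  }
  tbl <- tibble(
    ortholog_id = parts[, 1L], species = parts[, 2L],
    seq = toupper(as.character(seqs))
  )
  out <- list()
  for (oid in unique(tbl$ortholog_id)) {
    sub <- tbl[tbl$ortholog_id == oid, ]
    if (anyDuplicated(sub$species)) {
      abort(paste0("ortholog ", oid, ": species repeated in FASTA"))
    }
    if (!is.null(species) && !all(species %in% sub$species)) {
      warn(paste0("ortholog ", oid, ": missing species ",
                  paste(setdiff(species, sub$species), collapse = ", "), "; skipped"))
      next
    }
    aln <- setNames(sub$seq, sub$species)
    out[[oid]] <- validate_codon_alignment(aln, oid)
  }
  out
}

#' @rdname read_codon_fasta
#' @param aln Named character vector of aligned sequences.
#' @param ortholog_id Id used in error messages.
#' @export
validate_codon_alignment <- function(aln, ortholog_id = "?") {
  lens <- unique(nchar(aln))
  if (length(lens) != 1L) abort(paste0("ortholog ", ortholog_id, ": unequal sequence lengths"))
  if (lens %% 3L != 0L) abort(paste0("ortholog ", ortholog_id, ": length ", lens, " not divisible by 3"))
  bad <- stringr::str_detect(aln, "[^ACGT-]")
  if (any(bad)) abort(paste0("ortholog ", ortholog_id, ": non-ACGT- character in ",
                             names(aln)[bad][1L]))
  cod <- lapply(aln, seq_codons)
  gap_unit_ok <- vapply(cod, function(x) all(x == "---" | !stringr::str_detect(x, "-")), logical(1L))
  if (!all(gap_unit_ok)) abort(paste0("ortholog ", ortholog_id, ": gaps not in whole codons"))
  # drop codon columns gapped in every sequence (alignment artefacts)
  n_cod <- lens %/% 3L
  all_gap <- rep(TRUE, n_cod)
  for (x in cod) all_gap <- all_gap & (x == "---")
  if (any(all_gap)) {
    aln <- vapply(cod, function(x) paste(x[!all_gap], collapse = ""), character(1L))
  }
  aln
}

#' Write codon alignments to FASTA
#'
#' @param alignments Named list as returned by [read_codon_fasta()].
#' @param path Output path.
#' @param delim Header delimiter.
#' @export
write_codon_fasta <- function(alignments, path, delim = "|") {
  seqs <- unlist(lapply(names(alignments), function(oid) {
    aln <- alignments[[oid]]
    setNames(unname(aln), paste0(oid, delim, names(aln)))
  }))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(alignments)
}

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are kept; integer bootstrap supports, when present as
#' `node.label`, are written as internal node labels.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(tree)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write any result tibble as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(x)
}

# split a sequence string into codons
seq_codons <- function(s) {
  n <- nchar(s)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}
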