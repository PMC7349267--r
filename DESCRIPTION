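Package: sexevol
Title: Evolution of Sex-Biased Gene Expression Across Closely Related Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative analysis of sex-biased gene
    expression and its evolution across closely related species, modelled on
    haplodiploid whitefly (Bemisia tabaci species complex) study designs.
    Classifies genes as female-, male- or non-sex-biased from replicated
    counts via a conditional negative-binomial exact test; normalizes FPKM
    across species to sFPKM by an origin-regression scaling model; builds
    expression phylogenies from Spearman distances (neighbor-joining and
    balanced minimum evolution) with gene bootstrap; estimates pairwise
    Ka/Ks by Nei-Gojobori (1986) counting with Jukes-Cantor correction;
    computes the interspecific (Dx), intraspecific (Vx), between-sex (Sx)
    expression-variation statistics and their ratio Rx = Dx/Vx; decomposes
    per-gene variance by sex and species with a two-way ANOVA and Tukey HSD;
    and runs the category-level statistics (hypergeometric representation
    tests, Mann-Whitney comparisons, consistency classes, correlation
    matrices, two-dimensional binned summaries). Ships a synthetic-data
    generator (negative-binomial expression with sex/species/interaction
    structure, codon alignments evolved at controllable dN/dS) that provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
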