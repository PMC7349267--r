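---
title: "Methods: sex-biased expression evolution across closely related species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-biased expression evolution across closely related species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexevol)
```

This vignette is the package's account of its own methods: the models and
their assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical conventions, and the
design choices we made where the underlying procedures left them open.

## The study design

The pipeline is organized around a small comparative design: three focal
congeneric species, each sampled for females and males with two biological
replicates; one focal species contributes a second conspecific population
(to separate intraspecific from interspecific expression variation); and a
divergent congener-family outgroup roots the expression phylogeny. That is
five colonies × two sexes × two replicates = 20 RNA-seq samples, with
expression summarized per gene as counts (for differential expression) and
FPKM (for cross-species statistics), plus a 1:1 ortholog map and codon
alignments for the molecular-evolution side.

## Differential expression between sexes

Within one species, each gene is tested for a difference between female and
male replicates.

**Normalization.** Per-sample factors are median-of-ratios: the median over
genes (restricted to genes positive in every sample) of
`count / geometric-mean-across-samples`, rescaled to geometric mean 1. The
estimator assumes the *majority of genes are not differentially expressed*;
when that fails, the per-sample ratio distribution turns bimodal and the
median can sit on either mode. This matters for simulation studies: a
configuration in which literally every gene is strongly sex-biased breaks
the reference and makes downstream power erratic, so our power checks embed
biased genes in a half-null background.

**Dispersion.** A single common negative-binomial dispersion φ is estimated
by moments: within each group with ≥ 2 replicates, the per-gene
`(variance − mean)/mean²` of scaled counts, pooled across genes and groups,
summarized by the median and floored at zero. The median is robust but
biased low at very small replicate numbers (roughly 25% low at 2–4
replicates, 8% at 16); since a smaller φ makes the exact test more liberal,
the test's observed false-positive rate is still held well under the
nominal level by the two-sided probability-ordering rule and the fold-change
gate (the null simulations below call < 1% of genes).

**Exact test.** Counts are equalized (divided by their factors, rounded),
and the test conditions on the total of the two group sums. Under the null
of equal means and common dispersion, the first group's sum given the total
follows `P(a) ∝ C(a + r1 − 1, a) · C(T − a + r2 − 1, T − a)` with
`r_g = n_g/φ` — a distribution free of the unknown mean, reducing to
binomial with `p = n1/(n1+n2)` in the Poisson limit φ = 0. The two-sided
p-value sums the probabilities of all splits no more probable than the
observed one, the same convention as the exact binomial test.

**Calling.** A gene is sex-biased when both gates pass: |log2FC| ≥ 1
(male-over-female orientation; fold changes use a 0.5 pseudocount on scaled
means, the test itself uses none) and BH-FDR < 0.05. Swapping the sex
labels provably mirrors the calls and negates the fold change.

## Cross-species normalization (sFPKM)

For each non-reference species, a slope β is fitted through the origin,
`β = Σx·y / Σx²`, with `x` that species' per-ortholog mean FPKM and `y` the
reference species' means; `sFPKM = β·FPKM + 0.01`, and orthologs with mean
sFPKM < 2 (strictly) are removed. The reference defaults to the first
species alphabetically; the pseudocount is added *after* scaling (the
procedure's description leaves the order open; adding after keeps the floor
identical for every species).

Two properties are worth stating plainly:

- *Self-consistency:* after scaling, regressing reference ortholog means on
  any scaled species' means through the origin returns slope 1 to machine
  precision. This is the invariant the tests assert.
- *Leverage sensitivity:* the unweighted origin regression is dominated by
  the highest-expressed orthologs (FPKM is heavy-tailed). If a large
  fraction of genes diverge multiplicatively with random sign, the linear
  scale is asymmetric (2^+2 and 2^−2 do not average to 1) and the fitted β
  drifts systematically from the true scale, shifting *every* gene of that
  species. In real data this is mitigated because highly expressed genes
  are typically conserved; in synthetic recovery studies of the ANOVA
  classifier we therefore evaluate on truth-scaled sFPKM (the generator's
  FPKM is already commensurate, true β = 1), and keep the fitted
  normalization in the end-to-end pipeline, where it mirrors what the
  procedure would do on real data.

## Expression phylogenies, bootstrap, PCA

Distances are `1 − ρ` with Spearman's ρ (average ranks on ties), computed
between sample profiles; the range is [0, 2] and a constant profile is an
error, not an NA. Trees come from neighbor joining and from balanced
minimum evolution (balanced FastME: greedy insertion minimizing the
balanced — Pauplin-weighted — tree length, then balanced NNI/SPR moves),
both via ape, with labels sorted first so input order cannot change the
result and negative branch lengths clamped to zero with a warning. Both
methods provably reconstruct additive matrices exactly; the test suite
checks topology and branch lengths against 50 random additive trees and,
at five leaves, verifies the balanced criterion against exhaustive
enumeration of all 15 topologies.

Bootstrap support resamples *genes* with replacement (default 100
replicates, seed required), rebuilds the tree, and labels each internal
bipartition of the reference tree with the percentage of replicates
containing it. Rooting uses the outgroup when one is configured.

PCA treats samples as observations and genes as variables, log2-transforms
(the sFPKM pseudocount keeps values positive), centers genes, does not
scale, and fixes each component's sign so its largest-magnitude loading is
positive (otherwise scores are only defined up to sign and would not be
reproducible across platforms).

## Ka/Ks by Nei–Gojobori counting

The coding-sequence side uses pairwise NG86 counting with Jukes–Cantor
correction rather than a maximum-likelihood codon model: the counting
method is fully specifiable and exhaustively checkable against a
brute-force oracle (every site count and path average is enumerable by
hand), which is what our acceptance tests do. The conventions:

- synonymous sites per codon = 3 × (fraction of the nine single-nucleotide
  changes that are synonymous); changes to stop codons count as
  nonsynonymous; site counts are averaged over the two sequences, so
  `S + N = 3 × codons` exactly;
- observed differences are averaged over all orderings of the differing
  positions with equal weights; orderings passing through a stop codon are
  excluded and the weights renormalized (if all are blocked, all are kept);
- `d = −(3/4)·ln(1 − (4/3)p)` per class; `p ≥ 3/4` is flagged saturated and
  the ratio is undefined rather than extrapolated; `Ks = 0` likewise leaves
  the ratio undefined;
- alignments shorter than 150 ungapped bp (50 codons) are excluded; codon
  columns gapped in any sequence of a group are dropped before counting;
- per-ortholog averages are the arithmetic mean over defined pairwise
  ratios; categories are `low` (< 0.1), `high` (strictly above the
  empirical upper quartile, linear-interpolation quantile), `mid`
  otherwise, with a separate `> 1` flag.

NG86 with JC correction is known to be biased at high divergence (it
ignores transition/transversion bias and codon frequencies); the recovery
tests therefore run at modest divergence (0.1 proposals/site between tips)
where the estimator lands within a few percent of the simulated dN/dS.

## Expression-variation statistics

With `X` a per-group mean of sFPKM, the four statistics are mean absolute
log2 ratios: `Vx` between the two conspecific populations (female term and
male term, averaged), `Dx` over the three species pairs within each sex
(six terms), `Sx` male/female within each species (three terms), and
`Rx = Dx/Vx`. Some printed variants of these formulas in the literature are
internally inconsistent (a population term that mixes sexes; a between-sex
term that is a ratio of a quantity to itself, identically zero); we
implement the symmetric forms of the original fire-ant formulation, the
only reading that makes `Vx` a pure population contrast and `Sx`
non-degenerate. `|log2(ratio)|` is used throughout (ratios are positive;
a signed sum would cancel variation rather than measure it).

`Rx` is undefined when `Vx = 0` (excluded from rank statistics and counted)
rather than infinite. Species means for `Dx` and `Sx` pool all samples of a
species including both populations — the design leaves this open; pooling
uses all the information and keeps the population contrast exclusively in
`Vx`. All four statistics are invariant to a global positive rescaling of
`X` and to the relabelings (populations for Vx, species for Dx, sexes for
Sx) the definitions imply; the tests assert these invariances on a thousand
random inputs.

## Variance decomposition and the five classes

Per gene, a two-way fixed-effects ANOVA on log2(sFPKM) with sex, species
and their interaction, requiring a *balanced* layout with ≥ 2 replicates
per cell (in the full design the second conspecific population is set
aside here so the focal 3 × 2 × 2 layout stays balanced). Balance makes the
sequential decomposition order-invariant and lets us compute all genes at
once from cell means (the implementation is cross-checked against `aov()`
gene by gene); `SS_total = SS_sex + SS_species + SS_int + SS_resid` holds
to 1e-8 relative. Genes with zero variance everywhere get p = 1 by
convention (no evidence of variation), and zero residual with a positive
effect gives p = 0. Tukey HSD contrasts on species marginal means use the
studentized range with the gene's ANOVA mean square error, matching
`stats::TukeyHSD` on balanced designs.

Classification applies BH-FDR at 0.05 per term across genes — the
procedure's own multiplicity handling is unstated, and 0.05 matches the DE
threshold — then: significant interaction ⇒ interaction-variable
(precedence: a crossing interaction makes marginal effects
uninterpretable); both mains ⇒ sex-and-species; one main ⇒ that class;
none ⇒ non-variable. Sex-variable genes carry a direction from the sign of
the sex coefficient (sum-to-zero coding).

## Category-level statistics

Representation uses hypergeometric tails in both directions
(`p_over = P(X ≥ k)`, `p_under = P(X ≤ k)`; the two share the point mass,
so their sum is ≥ 1); no multiplicity correction is applied across sets.
Mann–Whitney U is exact by full enumeration when `m + n ≤ 20` (ties
handled through average ranks inside the enumeration, which the standard
implementations refuse to do), otherwise a normal approximation with tie
and continuity corrections; all-tied inputs give p = 1 by convention.
Consistency classes of an ortholog's three per-species calls:
`switched_opposite` if both sexes' biases occur, else `female_vs_unbiased`
/ `male_vs_unbiased` if a bias co-occurs with unbiased, else `consistent`.
Correlation matrices are Spearman with pairwise-complete deletion
(undefined Rx or Ka/Ks drop per pair, with the per-pair n recorded);
p-values use the t approximation. The two-dimensional summaries bin genes
on log2FC (default [−8, 8]) × Dx (default [0, max]) into a 16 × 16 grid of
counts and indicator means; out-of-range values are clipped into the
boundary bins so counts are conserved.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions: 3 focal species + 1
outgroup, 2 sexes, 2 replicates, a second conspecific population of the
first focal species (20 samples); baseline log2-FPKM ~ N(5, 2); gene
classes in proportions (non-variable 0.50, sex 0.20, species 0.15,
sex-and-species 0.10, interaction 0.05) with |2| log2-unit effects of
random sign (sex effects split ± half between the sexes; species effects
hit one random focal species; interaction effects hit one random
species × sex cell); a per-gene population offset ~ N(0, 0.25) making Vx
positive; a per-gene outgroup offset ~ N(0, 2) for its extra divergence;
negative-binomial dispersion 0.05; library sizes ~ U(8, 14) million,
matching the per-sample read counts such experiments report. Counts have
mean `library-size-millions × gene-length-kb × 2^η` and
`FPKM = count/(library-size-millions × gene-length-kb)` with gene length
fixed at 1 kb, so the two units are exactly interconvertible.

Codon alignments evolve an ancestor (uniform over sense codons) down the
species tree; branch lengths are expected single-nucleotide *proposals*
per site, each proposal rejected if it creates a stop, accepted if
synonymous, and accepted with probability ω if nonsynonymous. This
thinning makes the realized dN/dS ≈ ω but caps ω at 1 — positive selection
(ω > 1) would need a different scheme and is out of scope. Per-class ω
defaults are all < 1 (0.05–0.30), with species-variable genes fastest,
mirroring the biological expectation that expression-conserved sex-biased
genes are also sequence-conserved. Note one subtlety: with ω = 0 the
*generator* introduces no amino-acid change (tip proteins are identical),
but the NG86 *estimate* of Ka can still be slightly positive when two
synonymous hits land in one codon, because path averaging then counts
fractional nonsynonymous steps.

What the generator does **not** emulate: read-level noise and mapping
(counts are drawn directly), gene-length variation (fixed 1 kb),
correlated expression between genes, expression-level-dependent divergence
(real high-expressed genes are more conserved — the reason the origin
regression behaves better on real data than on worst-case simulations),
indels in coding sequence, and ω > 1. Passing recovery tests on this
generator therefore demonstrates the estimators' correctness under the
model's assumptions, not robustness to everything real RNA-seq does.

## Problem sizes and determinism

The test-suite simulations use 1,500–5,000 genes for recovery studies,
10,000-codon pairs (20 replicates) for dN/dS recovery, 100 bootstrap
replicates for tree support, and a 500-gene end-to-end run; these sizes
keep every Monte-Carlo standard error comfortably below the asserted
margins while the whole suite runs in about a minute. Every stochastic
stage takes an explicit seed; `run_pipeline()` derives per-stage seeds
from the one root seed and writes MD5 checksums of every output into its
manifest, so reruns are verifiably bit-identical.

## Known limitations

- The common-dispersion estimator is biased low at 2 replicates; per-gene
  (tagwise) dispersion is out of scope.
- The origin-regression normalization has the leverage sensitivity
  described above; robust or rank-based cross-species normalizations are
  deliberate non-goals.
- NG86/JC underestimates divergence when transition/transversion bias is
  strong; the interface would accept a drop-in replacement estimator.
- Mann–Whitney p-values in the normal regime and Spearman p-values use
  asymptotic approximations.
- The ANOVA requires balance; unbalanced designs are rejected rather than
  approximated with Type-II/III sums of squares.
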