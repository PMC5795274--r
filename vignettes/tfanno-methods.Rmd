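---
title: "Methods: target-gene-based annotation of transcription factor function"
author: "tfanno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-gene-based annotation of transcription factor function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfanno)
```

# The model

A transcription factor (TF) has two kinds of function: the molecular
activity that lets it regulate transcription, and the biology carried out
by the genes it regulates. `tfanno` annotates the second kind — the
*target functions* — as the functional terms statistically
over-represented among a TF's target genes (TGs). The pipeline has five
statistical components, each with explicit assumptions.

## Target-gene calling

The input is a genes × bins matrix of ChIP-seq-derived binding intensity
in a window centred on each gene's transcription start site (TSS), bins
pre-oriented 5'→3'; strand handling, alignment and peak processing are
upstream of this package. The TF's *characteristic profile* is the
column-mean signal normalised to sum to one, and each gene's raw score is
the profile-weighted sum of its binned signal, so the score combines
binding *location* (through the weights, which concentrate near the TSS
when binding does) and binding *intensity*. Scores are standardised with
the sample (n − 1) standard deviation, converted to one-sided upper-tail
normal p-values — only an excess of binding is evidence of targeting — and
thresholded at a Benjamini–Hochberg FDR, default 0.01.

Assumptions worth stating: the normal null on z-scores is an
approximation to the bulk of non-target scores and is adequate when
targets are a small fraction of genes; the profile is estimated from *all*
genes (an optional refinement re-estimates it from called targets, off by
default because it can lock in early mistakes); and a single fixed window
(default 6,000 bp, with 20,000 bp as the configured alternative) means
distant enhancer-mediated regulation is out of reach by design. On
planted data the two window sizes call largely overlapping target sets
(Jaccard well above 0.5 in the test suite).

## Gene universes and enrichment

Every association test is conditioned on a *gene universe*, the allowed
set restricting both the TG set and the term's member genes. This choice
is not cosmetic: adding genes that are neither TGs nor term members
strictly increases the odds ratio (a property asserted on randomized
tables in the test suite), so an overly generous universe manufactures
enrichment. The package follows the rule that the universe should reflect
how the annotation was produced: curated catalogues can only annotate
genes the literature has studied, so they are tested against the
*literature-rich* universe (coding genes with at least one curated-source
annotation; annotated non-coding records are purged); machine-derived
annotations (GWAS-style) are tested against all coding genes.

Per TF × term, the 2×2 table is tested with Fisher's exact test
(one-tailed for enrichment, two-tailed for either direction) and the
G-test (`2 Σ O ln(O/E)`, 1 df) as its fast approximation. The phi
coefficient — the Pearson correlation of the two binary indicators —
gives a sample-size-independent effect size and the direction. Odds
ratios are reported raw; log2(OR) applies a Haldane–Anscombe 0.5
pseudo-count to all cells only when a cell is zero. BH q-values are
computed within each annotation source separately, since sources differ
drastically in term count and gene coverage. By default the two-tailed
p-value drives the q-values (both enrichment and depletion are real
phenomena; direction is read off phi), with the one-tailed variant
selectable; both are always reported. Terms with fewer than 3 universe
members are skipped as vacuous (configurable).

## The randomized-compendium null model

To ask whether the compendium carries functional signal at all, each real
TF is matched by a *fake* TF with the same number of TGs drawn uniformly
without replacement from the universe, and the association p-values are
paired per TF × term. Under the assumptions that (1) true associations of
real TFs always beat their fake counterparts and (2) false associations
fall symmetrically on either side, the number of true associations is
`n_upper − n_lower`; the empirical FDR at a p-value cutoff is the ratio
of fake to real associations passing it. Ties — common with discrete
exact-test p-values — are counted separately and excluded from both
triangles, which preserves the antisymmetry the estimator assumes (the
package's choice; the alternative of splitting ties half-half changes
nothing in expectation). G-test p-values drive the pairing by default,
with Fisher selectable. The fake-TF sampling universe defaults to the
coding universe so real and fake tests share a footing.

## Similarity networks and discordance

TF–TF similarity is measured by TG sharing (phi, Fisher, BH across all
pairs; *neighbors* at FDR 0.01), and in parallel by sharing of
significant target functions and of known functions over the respective
term spaces. "Low TG sharing" is odds ratio < 1, ties at exactly 1 going
to "high". The discordance analysis stratifies TF pairs by
(target-function sharing significant or not) × (TG sharing low or high)
and asks, within each TG stratum, whether function-sharing pairs are
enriched for known-function sharing — the interesting cell being pairs
that share functions *without* sharing targets. Function–function
regulator sharing flags term pairs with identical significant regulators
but lower-than-expected member-gene overlap (OR < 1): functions linked
through regulation rather than through shared genes. The significance
test for function-set sharing is Fisher's exact test over the term space,
chosen for consistency with every other overlap test in the package.

## Uniqueness-weighted diversity

Counting a TF's functions (or a gene's regulators) double-counts
redundant entries. The uniqueness of entity *t* is
`u_t = 1/Σ_{t'} φ²_{tt'}` (the self-term φ_tt = 1 guarantees
0 < u_t ≤ 1): 1 for an entity uncorrelated with all others, 1/k inside a
block of k perfectly correlated entities. The diversity of a member set
is `π = Σ u_t` — an effective number satisfying π ≤ n, monotone under
adding members, and exactly invariant to replacing a member by perfect
copies when that member is uncorrelated with the rest (the test suite
uses an orthogonal-bit construction to check this identity exactly). Phi
entries undefined from zero margins are treated as 0, i.e. no redundancy
contribution, which preserves u_t ≤ 1. Per-source diversities are summed
into the total. The TF–TF phi matrix uses TG sharing over the enrichment
universe (configurable). The pleiotropy analysis regresses function
diversity on regulator diversity by OLS with a Wald test, controlling for
the number of TGs per TF — the main confounder, since heavily studied TFs
have both more recorded targets and more recorded regulators. PageRank
(damping 0.85, exposed as an argument; the igraph implementation, checked
against a power-iteration oracle) serves as the network-position control.

# The synthetic-data generator

The generator defines the study conditions under which all stochastic
properties are asserted. Defaults: 2,000 genes, 85% coding, 20 TFs drawn
from the coding genes, six annotation sources emulating OMIM, GWAS,
PharmGKB, Reactome, GO-BP and GO-MF (12–15 terms each, sizes 10–60,
curated sources annotating only coding genes, GWAS the one
machine-derived source), 30 planted TF–term links, per-gene targeting
probability 0.6 inside a planted term against a 2% background, and a
6,000 bp / 100 bp-bin window with a Gaussian binding peak of height 10,
sd 300 bp, on unit-sd noise clipped at zero. These sizes keep a full
pipeline run in seconds while leaving every statistic comfortably
powered; the peak-to-noise ratio of 10 reflects a good ChIP-seq
experiment rather than a marginal one. Setting the background rate equal
to the in-term rate yields the structure-free negative control, under
which enrichment p-values are approximately uniform and the null model's
empirical FDR sits near 1.

What the generator deliberately does *not* emulate: read-level noise and
peak-caller artifacts, TG–TG correlation beyond term co-membership,
cell-type specificity, ontology structure among terms, and the strong
popularity biases of real literature-derived compendia. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to every pathology of real ChIP-seq data.

All randomness flows from one master seed, expanded into per-component
substreams keyed by a polynomial string hash, so adding a generator does
not perturb existing outputs and every artifact is byte-reproducible.

# Numerical choices and degenerate inputs

* One-sided Fisher p-values use the closed-form hypergeometric upper
  tail; two-sided calls `stats::fisher.test` and is clipped at 1 against
  floating-point overshoot of the exact-summation.
* Zero-margin tables: phi and the G-test raise errors at the low level;
  higher-level drivers record phi as `NA` (treated as 0 in uniqueness
  sums) and keep the p-values they can compute.
* Target calling refuses all-zero matrices (no profile), fewer than 3
  genes, and zero score variance, rather than returning fabricated
  statistics.
* BH is `stats::p.adjust(method = "BH")` behind a validating wrapper;
  ties are handled by the standard step-up on a stable sort.
* The empirical FDR returns 0 when no real association passes a cutoff;
  negative triangle estimates are reported as-is with a warning.

# Test problem sizes

Module tests run on a reduced scenario (600 genes, 8 TFs, 3 sources, 12
planted links) chosen to keep the default suite fast while preserving
every qualitative property; the acceptance suite exercises the full
default scenario above, a 1,000-gene target-calling simulation with 50
planted peaks, 100-seed pure-noise calling, 1,000 random tables for the
phi oracle, and a 146,096-edge compendium for the degree identities.

# Known limitations

* The enrichment model treats terms as flat sets; GO's hierarchy is
  neither propagated nor deduplicated beyond the uniqueness weighting.
* The TIP-style null is a convenient normal approximation; heavy-tailed
  binding-signal noise would call for an empirical null.
* The discordance analysis inherits whatever incompleteness the
  known-function catalogue has; on synthetic data that catalogue is the
  generator's own annotation sources.
* Expression-based diversity analyses are out of scope; the Spearman
  utility in `pleiotropyAssociation()` accepts user-supplied vectors.
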