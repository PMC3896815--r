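---
title: "Methods: network-based drug repositioning with reponet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based drug repositioning with reponet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reponet)
options(reponet.verbose = FALSE)
```

## The problem

Drug repositioning asks which approved or well-characterized drugs might
treat diseases they were not developed for. `reponet` approaches this by
giving every drug and every disease the same kind of molecular
representation — a prioritized set of genes — and then asking which drug
gene sets best explain which disease gene sets. Two independent evidence
streams feed the gene sets: literature co-occurrence (how often an entity
and a gene are mentioned in the same abstracts) and expression signatures
(how strongly a gene responds to drug treatment, or differs between disease
cases and controls). An interaction network refines both streams, the idea
being that disease- or drug-relevant genes act through network
neighborhoods rather than in isolation, and that the hubs of those
neighborhoods are their most informative representatives.

## Pipeline overview

For each entity (drug or disease) and each evidence source:

1. **Initial gene list.**
   *Literature:* co-mention counts below 5 abstracts are zeroed as likely
   false positives, the remaining counts are scored with a regularized
   log-odds connectivity measure, and genes with strictly positive score
   are kept.
   *Expression:* drugs are represented by replicate rank lists (rank 1 =
   most up-regulated of $n$ genes, rank $n$ = most down-regulated) merged
   into one list; diseases by a moderated two-sample statistic on
   case/control matrices. Either way, the 25 most up- and 25 most
   down-regulated genes form the 50-gene signature.
2. **Subnetwork induction.** The signature genes plus their direct
   neighbors in a source-specific reference network, with every edge among
   those nodes retained (the full induced subgraph).
3. **Centrality prioritization.** Degree, betweenness, or closeness
   centrality is computed on the subnetwork and only genes scoring strictly
   above the subnetwork mean are kept. This yields one Boolean
   entity-by-gene membership matrix per source and measure (six in all),
   plus combined-source matrices formed by element-wise OR.
4. **Association model.** For each disease, its Boolean gene vector is
   regressed on all drugs' Boolean gene vectors with an L1-penalized
   logistic regression; genes are the observations, drugs the predictors.
   The signed coefficient is the association score and strictly positive
   coefficients become predicted drug-disease calls.
5. **Evaluation.** Predictions are compared against a gold standard of
   known positives and sampled negatives (pairs with no literature
   co-occurrence) by ROC/AUC.

## The connectivity score

For entity $D$ and gene $G$ with co-mention count $A_{DG}$, marginal counts
$A_D$ and $A_G$, corpus size $N$ and regularizer $\lambda$, the original
log-odds form is

$$\mathrm{Connect}_{DG} = \ln(A_{DG} \, N + \lambda) - \ln(A_D \, A_G + \lambda).$$

Because the corpus-size term rewards any co-mention in a large corpus, the
default is the modified form, which replaces $N$ with the larger marginal
and the product of marginals with their sum:

$$\mathrm{Connect}_{DG} = \ln(A_{DG} \max(A_D, A_G) + \lambda) - \ln(A_D + A_G + \lambda).$$

With $\lambda = 1$ (the default everywhere), an all-zero cell scores
exactly 0, so "keep strictly positive scores" has a natural reading: zero
is the no-information point and is excluded. The modified score is
symmetric in the two marginals and strictly increasing in $A_{DG}$; both
properties are tested. Filtering (the `< 5` rule) is applied before
scoring, and a filtered cell can never re-enter a positive set.

## The moderated expression statistic

For a gene with case and control groups of sizes $n_1, n_2$, the score is

$$d = \frac{\bar{x}_{case} - \bar{x}_{control}}{s + s_0}, \qquad
s = \sqrt{\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)
\frac{\sum_{case}(x-\bar{x}_{case})^2 + \sum_{control}(x-\bar{x}_{control})^2}{n_1+n_2-2}},$$

a two-sample statistic moderated by the exchangeability constant $s_0$,
which damps genes whose tiny variance would otherwise produce huge scores.
`s0 = "auto"` (the default) uses the median of $s$ over genes — a simple,
scale-adaptive choice within the family of percentile rules commonly used
for this statistic. The full permutation/FDR machinery attached to this
statistic elsewhere is deliberately not implemented: only the ranking of
$d$ is consumed downstream.

Replicate drug rank lists are merged by mean rank (a Borda count) with
lexicographic gene-id tie-breaks. The published merging procedure this
stands in for is hierarchical and not fully recoverable from its
description; Borda aggregation has the same intent (consensus ranking of
replicates), is order-invariant, reduces to the identity on a single
replicate, and is isolated behind `merge_ranked_lists()` so an alternative
can be swapped in.

## Centrality conventions

Degree is the raw count of incident edges. Betweenness is unnormalized
shortest-path betweenness over unordered pairs. Closeness is computed
within connected components, $(c-1)/\sum d$ for a node in a component of
size $c \ge 2$, and 0 for isolated nodes — a finite, standard convention
for disconnected graphs. The selection rule ("keep genes with centrality
strictly above the average") is invariant under any uniform rescaling of a
measure within a subnetwork, so normalization choices cannot change which
genes are selected; this also makes the rule's two readings — above the
mean of all genes, or above the mean of all *other* genes — provably
identical, since $x > (S-x)/(n-1) \iff x > S/n$. Both facts are
property-tested, and betweenness/closeness are checked exhaustively
against a brute-force shortest-path oracle on every connected graph with up
to 6 nodes.

Two consequences of the strict rule are accepted rather than patched: a
regular subnetwork (all scores equal) selects nothing, and a single-node
subnetwork selects nothing. Such entities propagate as all-zero rows of the
membership matrix, which the regression handles (an all-zero response is a
degenerate fit with zero coefficients).

## The association model

The method's description mixes logistic and lasso regression; the
reconciliation adopted is L1-penalized logistic regression — a binary
response (disease gene membership) written as a sparse combination of drug
membership vectors. Fits use the coordinate-descent path algorithm of
glmnet: the full regularization path is computed with warm starts and the
coefficients are read off at the requested penalty, which is both more
robust than a cold single-penalty fit and deterministic. The penalty
default of 0.05 keeps a handful of drugs per disease at the package's
problem sizes; `penalty = "path"` instead selects the penalty from the
path by held-out deviance on an 80/20 gene split drawn from the
configuration seed. Negative coefficients are reported as scores but never
become calls: a drug whose gene set is *anti*-correlated with a disease
has no repositioning interpretation here.

Combining evidence sources is done at the selection level — the OR of the
two Boolean matrices for the same centrality measure — rather than by
unioning subnetworks before centrality. The selection-level reading matches
"combining the already-built networks"; the alternative would re-run
centrality on merged subnetworks and is intentionally out of scope.

## Evaluation

AUC uses the Mann-Whitney pair-counting form with ties counted 1/2, which
equals the trapezoidal area under the ROC curve; the suite cross-checks
both identities and an external ROC implementation. Negatives are sampled
uniformly (seeded) from pairs with no planted or literature signal; the
default sample size of 400 mirrors the scale of the published evaluation
protocol and is configurable.

## The synthetic world

Real inputs to this kind of pipeline (curated target databases, literature
co-mention counts, expression repositories) cannot be bundled or
downloaded at test time, so `generate_world()` builds a complete input
bundle with known ground truth:

* **Universe:** 2343 genes by default, matching the scale of the combined
  drug-target/disease-gene universe the method was designed around.
* **Reference networks:** two independent preferential-attachment graphs
  (3 edges per node), one per evidence source, giving the heavy-tailed
  degree structure of protein networks.
* **Planted associations:** 10 of the 50 drugs are each paired with one of
  8 diseases; each pair shares a 30-gene module drawn mostly (70%) from
  the top degree quintile, so that hub-biased centrality selection has
  planted signal to find — mirroring the premise that hub genes are the
  informative representation.
* **Literature counts:** negative-binomial background (mean 0.5, size 1)
  over every entity-gene cell; planted cells have their mean multiplied by
  the enrichment factor (default 40). Marginals are the row/column sums
  plus entity- and gene-level background mentions, and the corpus size
  dominates every marginal, so generated tables always satisfy the
  validators of the scoring module. With enrichment 1 the planted cells
  are distributed exactly as background.
* **Expression:** unit-variance Gaussian noise; planted modules are
  shifted by ±3 standard deviations (half the module up, half down) in the
  paired drug's replicate profiles and the paired disease's case samples.
* **Signal routing:** by default every planted pair carries both literature
  and expression signal; in the complementary scenario pairs alternate
  between literature-only and expression-only, the construction under
  which combining sources must beat either source alone.
* **Gold standard:** the planted pairs are the positives; negatives are
  sampled from the non-planted pairs.

Everything is a deterministic function of the configuration seed, and the
generated objects pass the consuming modules' validators unchanged.

What the world does *not* emulate: synonym/identifier ambiguity in
literature counts, probe-level artifacts or batch effects in expression,
correlated modules shared by several diseases, and the citation-bias
structure of real corpora. Passing the end-to-end tests therefore
demonstrates that the pipeline recovers the kind of signal it assumes —
co-mention enrichment and coherent expression shifts concentrated on
network modules — not that real databases contain such signal.

## Problem sizes and runtime choices

Unit tests exercise scaled-down worlds (300-400 genes, 12-15 drugs) where
the planted structure is still comfortably recoverable; the end-to-end and
null-world checks run the full default world (2343 genes, 50 drugs, 8
diseases), which completes in a few seconds per configuration on one core.
The exhaustive centrality verification enumerates all 27,475 connected
labeled graphs on 2-6 nodes. The null-world calibration averages five
seeds; a single world's AUC under no signal is noisy (8-10 positives
against 390 negatives), and the average is the quantity the chance-level
check constrains.

## Known limitations

* The co-occurrence table is consumed as given; building it (entity
  recognition, synonym aggregation) is upstream and out of scope.
* Per-disease fits are independent; no information is shared across
  diseases, and no stability selection or coefficient inference is
  offered.
* The expression path assumes gene-level matrices; probe summarization and
  normalization are upstream.
* Centrality conventions follow one fixed set of standard definitions;
  tools differ in normalization, but (see above) the selection rule is
  insensitive to that choice.
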