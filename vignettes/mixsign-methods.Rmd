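---
title: "Single-subject pathway analysis with functional signing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject pathway analysis with functional signing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixsign)
```

## The problem

Cohort methods for differential pathway analysis (limma followed by
enrichment, SAM, GSEA) need several biological replicates per condition.
In precision-medicine settings there is often exactly one pair of samples
per subject — a tumour and its margin, a pre- and post-treatment biopsy,
or paired isogenic animals on two diets. `mixsign` analyses that single
pair: it decides which transcripts are biologically altered between the
two conditions, which Gene Ontology Biological Process (GO-BP) terms are
overrepresented among them, and in which *functional* direction each
significant process moved.

## The mixture model on |log2FC|

For a paired profile the per-gene statistic is the absolute log2 fold
change $|log_2 FC_g| = |x^{case}_g - x^{control}_g|$ (log2 scale). The
package models these values as a two-component Gaussian mixture

$$ f(y) = \pi\,\mathcal{N}(y;\mu_A,\sigma_A^2) +
          (1-\pi)\,\mathcal{N}(y;\mu_U,\sigma_U^2), $$

where the $U$ component collects transcripts whose variation is noise and
the $A$ component the biologically altered transcripts. The fit is by
expectation–maximisation, and a gene is called a DEG when its posterior
probability of the altered component strictly exceeds 0.5. Fitting plain
Gaussians to folded (nonnegative) data is a deliberate reproduction of the
method as published; a folded-normal likelihood would match the generative
truth better but would be a different method. The practical consequence is
a mild downward bias of $\mu_A$ relative to the empirical altered-class
mean (the unaltered component absorbs part of the fold mass near zero) —
visible but harmless at realistic separations, as the parameter-recovery
tests show.

Numerical choices:

* **Initialisation.** One deterministic start ($\mu_U$ = median,
  $\mu_A$ = 95th percentile, pooled SD, $\pi = 0.1$) plus four seeded
  random perturbations; the best final log-likelihood wins. This makes
  results reproducible for a given seed while protecting against local
  optima.
* **Convergence.** Relative log-likelihood change below $10^{-8}$, at most
  1000 iterations. The E and M steps work in log space, so posteriors
  never underflow.
* **Degeneracy.** Component variances are floored at $10^{-6}$ and $\pi$
  is clamped to $[10^{-6}, 1-10^{-6}]$; components are relabelled so
  $\mu_U \le \mu_A$.
* **No-signal guard.** When $\mu_A - \mu_U < 0.5\,\sigma_U$ the two
  components describe one unimodal noise distribution, not signal; the
  DEG set is forced empty. The guard threshold is a qualitative
  separation criterion, not a tuned constant: it only has to distinguish
  "two interleaved components" from a genuine second mode.

## Enrichment

DEGs are tested per GO-BP term with a one-sided (enrichment) Fisher's
exact test on the 2×2 table of DEG × term membership over the universe of
measured, annotated genes. One-sided is the right alternative because the
question is overrepresentation; a two-sided test would conflate depletion
with enrichment. P-values are corrected with Benjamini–Yekutieli by
default — term overlap makes the tests strongly dependent, and B-Y is
valid under arbitrary dependence — with Benjamini–Hochberg available for
comparisons against DEG+FET reference pipelines. Significance is
inclusive, `fdr <= alpha`, with `alpha = 0.05`.

Odds ratios are the sample estimate $ad/bc$ ($\infty$ when $bc = 0$ with
$ad > 0$, 0 when $ad = 0$). For rank-based replicate comparisons a
Haldane–Anscombe estimate (0.5 added to each cell) is carried alongside so
that every term has a finite, rankable value.

The catalog is built by the true-path rule: a gene annotated to a term is
a member of every ancestor reachable through `is_a` and `part_of` edges
(regulates-family edges never propagate membership), and terms are kept
when their universe-restricted size is within [15, 500]. Sizes are
computed *after* intersecting with the measured universe so that every
margin of the contingency tables refers to the same gene population.

## Functional signing

GO encodes repressor biology as `negatively_regulates` edges: genes of
such a child term suppress the parent process, so an expression increase
of those genes is functional *repression* of the parent and an expression
decrease is de-repression. For each term the package therefore partitions
its DEGs into an "up-regulated and up-regulatory" side (expression-up
non-repressors plus expression-down repressors) and the mirror-image
"down-regulated and down-regulatory" side, using the repressor genes of
the term's *direct* `negatively_regulates` children only — transitive
negative regulation (odd/even path parity) is deliberately not chased.

Each side gets its own one-sided FET: successes are the genome-wide
functionally-concordant DEG pool for that term (the same repressor
flipping applied), the term column is the term's gene set extended by its
repressor genes, and the universe is the base universe. B-H FDR is
computed per direction across all tested terms, and the four-case rule
assigns the direction: **activated** (up significant at FDR ≤ 5%, down
not), **reduced activity** (the reverse), **bidirectional** (both),
**ambiguous** (neither). The rule is total and mutually exclusive, and
flipping every DEG's expression direction provably swaps activated and
reduced activity while leaving the other two categories fixed.

Two under-specified corners required decisions:

* A gene annotated both to a term and to one of its
  `negatively_regulates` children is treated as a repressor — the curated
  repressor role is the more specific claim about that gene's function in
  that context.
* Repressor genes are *not* added to the term's base gene set. The base
  enrichment statistics (p, OR, FDR from the full DEG set) are therefore
  bit-for-bit independent of repressor annotations; signing annotates, it
  never re-tests.

Known limitation: regulators with context-dependent (bidirectional)
capacity are all treated as repressors of their parent, which can
over-call reduced activity for terms dominated by dual-role transcription
factors.

## The synthetic-data generator

Real single-subject validation needs isogenic replicate pairs, which no
desk-scale dataset provides. The generator instead builds experiments in
which the truth is known by construction:

* **Ontology.** A root, ~250 core process terms attached by `is_a` (a
  quarter nested under another core term to exercise propagation), and a
  `negatively_regulates` child for 20% of core terms — the fraction of
  GO-BP-annotated mouse genes curated with negative regulatory roles.
  Direct annotation sizes are uniform on [15, 100]; repressor children
  are small specialised subterms (below the catalog floor), which also
  keeps the implant truth well defined: a repressor child's genes are
  genuinely altered, and if the child itself entered the catalog it would
  be a correct discovery that a naive truth list would miscount as a
  false positive. For the same reason implants are placed on terms whose
  only ancestor is the size-filtered root.
* **Expression.** Controls are $\mathcal{N}(8, 2^2)$ per gene (log2
  scale); each replicate adds the shared gene-level effect and
  independent $\mathcal{N}(0, 0.3^2)$ noise. Altered genes carry
  $|{\mathcal{N}(2, 0.4^2)}|$ effects signed by their implant: members of
  an activated term go up and its repressor genes go down, a reduced term
  is the mirror image, bidirectional terms split members 50/50. A further
  2% of genes are altered with random sign — the background
  inter-individual variation reported for isogenic mouse liver (0.8–11%
  of transcripts). Three replicates share the altered-gene assignment and
  differ only in noise, emulating isogenic replicate pairs of one
  genotype.
* **What it does not emulate.** Correlated gene-gene noise, platform
  effects, normalisation artefacts, and non-randomly distributed
  inter-individual variation. Passing tests on these fixtures demonstrate
  the *algorithmic* correctness and reproducibility of the pipeline, not
  its field performance on microarray or RNA-Seq data.

Default sizes (15,000 genes, 300 terms, 20 implants; null calibration at
4,000 genes × 120 terms × 50 repeats) were chosen as the smallest
configurations that are comfortably in the asymptotic regime of every
statistic involved; the full default experiment runs in seconds.

## Evaluation metrics

Candidate term lists are compared to a reference by exact term-id
matching (no semantic-similarity credit). ROC/AUC ranks terms by p-value
with tied scores grouped; the AUC is the tie-corrected Mann–Whitney
probability of ranking a random reference-positive above a random
negative. Precision is defined as 1 when nothing is called. Spearman rank
correlation of odds-ratio orderings uses average-rank ties and the
t-approximation for its p-value. Cross-replicate overlap is reported under
both denominators in use for such summaries — each replicate's own count
and the smallest input count.

## Reproducibility contract

Every stochastic step (generator, EM restarts) is driven by an explicit
seed, and identical configuration plus seed yields byte-identical fixture
files and identical results. The command-line entry point
(`inst/cli/mixsign.R`) writes its resolved configuration next to its
outputs.
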