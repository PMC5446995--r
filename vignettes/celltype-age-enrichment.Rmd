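---
title: "Cell-type enrichment of age-associated gene rankings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type enrichment of age-associated gene rankings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctenrich)
```

## The problem

Bulk-tissue expression studies of aging produce, for each gene, a p-value
and a direction of change, hence a total order from the most significantly
age-up-regulated gene to the most significantly age-down-regulated one.
Single-cell RNA-seq studies of the same tissue produce transcriptomic cell
types: clusters of cells with distinctive expression. ctenrich asks which
cell types the bulk age signal comes from: are the genes enriched in, say,
oligodendrocytes concentrated at the up-regulated end of the age ranking?

The statistic is deliberately threshold-free on the ranking side: the
**AUROC** of a gene set in a ranking is the probability that a set member
outranks a non-member,

$$\mathrm{AUROC} = \frac{U}{n_1 n_2}, \qquad
U = \sum_{g \in \text{set}} R_g - \frac{n_1(n_1+1)}{2},$$

where $R_g$ is the gene's midrank counted from the down-regulated end,
$n_1$ the set size within the ranking, and $n_2$ the complement size.
AUROC $> 0.5$ means the set leans toward age-up-regulation.

## The pipeline and its parameters

1. **Enriched-set derivation.** Expression values (RPKM or molecule
   counts — both pass through the identical path) are transformed as
   $\log(x+1)$ (natural log; standardization is scale-invariant, so the
   base only affects intermediates), standardized per gene across all
   cells with the sample (n−1) standard deviation, and averaged within
   each cell type, giving $\bar z_{gc}$. A gene is *enriched* in type $c$
   when $\bar z_{gc} > \tau$ and *non-specific* when
   $\max_c |\bar z_{gc}| < \tau$; both inequalities are strict, matching
   the "higher than" / "less than" definitions. The default $\tau = 2$ SD
   is the study convention. All-zero genes are removed first; genes
   constant across cells get $z = 0$ (they can never be enriched and fall
   in the non-specific class — the conservative outcome) rather than being
   dropped, which keeps gene universes aligned across stages.
2. **Orthology.** Mouse sets are converted to human symbols through a
   Homologene-style table reduced to 1:1 pairs (a homology group must
   contribute exactly one mouse and one human symbol; ambiguous groups are
   dropped and counted). The ranking background is restricted to mapped
   genes. Symbols are whitespace-trimmed but never case-folded: mouse
   Title-case and human UPPER-case conventions must be resolved by the map
   itself.
3. **Signed ranking.** Rows $(\text{gene}, p, \text{direction})$ become
   the score $s = \pm(-\log_{10} p)$ (up $= +$), ordered decreasingly;
   equal scores form tie groups stored lexicographically. All downstream
   statistics use midranks, so the within-tie order is immaterial. For
   direction-split sources the per-gene row with the strictly smaller p
   wins; an exact cross-direction tie is excluded (assigning a direction
   would invent information) and counted.
4. **Permutation calibration.** The cell-to-type labels are shuffled `B`
   times (default 10,000) and the *entire* derivation — profile,
   thresholding, non-specific set, mapping, AUROC — is recomputed per
   shuffle. Set sizes under the null are therefore emergent, and the
   non-specific set participates as an extra "type".
5. **GO dissection.** Within each enriched set, the ranking is subset to
   the set's genes and every GO term with a strict intersection size
   between the bounds (default $10 < n < 200$) is scored by AUROC and a
   two-sided Mann–Whitney p; Benjamini–Hochberg correction is applied once
   across all type-by-term tests jointly.

## Why the empirical null, and what the p-value is

On real data, permuted enriched sets do **not** score 0.5: broadly
expressed (non-specific) genes are consistently age-down-regulated, and by
construction an enriched set cannot contain them, so any enriched set —
even a label-shuffled one — sits above chance (the study observed permuted
baselines near 0.55, and 0.41 for the non-specific set). An analytic
Mann–Whitney test against 0.5 would therefore flag nearly everything.

The empirical p-value measures extremeness relative to the permuted mean
$m_c$, symmetrically:

$$p_c = \max\!\left(\frac{\#\{b : |A_{bc} - m_c| \ge |A^{\text{obs}}_c - m_c|\}}{B},\ \frac{1}{B}\right).$$

Ties count as extreme (conservative), and the floor is exactly $1/B$ with
no add-one correction. We note this two-sided distance-from-the-mean form
is the only reading consistent with published per-type p-values near 0.95
for observations sitting almost exactly at their permuted mean, and it
makes null p-values uniform — which the calibration tests verify.

The multiplicity correction is an empirical min-p FDR (plug-in,
Westfall–Young style): within each shuffle, every type's permuted AUROC is
converted to a p-value against its own null column by the same rule, and

$$q_c = \frac{1}{B}\,\#\{b : \min_{c'} p_{bc'} \le p_c\}.$$

With $C$ independent types and an observed p at the floor this gives
$q \approx 1 - (1 - 1/B)^C$, e.g. $\approx 0.005$ for 49 types at
$B = 10{,}000$ — the pairing seen in the study's headline table. Whether
the inner p should instead be leave-one-out is not determinable from the
description; the plug-in form is the default and the single largest
interpretive decision in the package. Shuffles in which a set is
degenerate (empty, or covering the whole ranking) record `NA` and are
dropped column-wise, with the effective `B` reported per type.

## The synthetic world

The generator emulates the statistical structure the analysis relies on,
not single-cell biochemistry:

* **Expression** is log-normal: per-gene baseline
  $\sim N(\mu_0, \sigma_0^2)$ (defaults 0 and 2), plus `marker_effect` for
  a marker gene in its own type, plus $N(0, \texttt{noise\_sd}^2)$; values
  are $\max(e^L - 1, 0)$. The heavy left tail of baselines yields genes
  detected in only a handful of cells after clipping — the sparse tail of
  real scRNA-seq, and the sole source of chance threshold crossings under
  label permutation. Dropout, library-size variation, batch structure and
  negative-binomial counts are deliberately out of scope, so a green test
  establishes correctness of the statistical machinery, not robustness to
  those artifacts.
* **Planted marker sets are disjoint** blocks, making recovery metrics
  unambiguous (overlapping enrichment is exercised by dedicated fixtures).
* **Age tables** draw a latent statistic $N(0,1)$, add `set_shift` (with
  sign) to injected types' markers and `nonspecific_shift` to all
  non-marker genes, then convert to two-sided p and direction.
* The **ortholog map is the identity** unless a mapping-stress fixture is
  requested, isolating orthology tests.

### A hard geometric constraint worth knowing

For a gene elevated in one of $C$ equal-size types ($k$ of $n$ cells), the
average standardized expression in that type is bounded:

$$\bar z \le \sqrt{\frac{n-k}{k}}\sqrt{\frac{n-1}{n}}.$$

With 5 balanced types of 20 cells the bound is **1.99 < 2**: at
$\tau = 2$, *no* effect size can make such a marker enriched. Real data
escapes the bound through many small types (49 types of 7–92 cells out of
1422 give bounds of roughly 3.8–14). The test suite asserts the bound
directly, and every world used for recovery or power uses paper-like
geometry (20–40 types of 3–4 cells). This bound is also why worlds differ
by purpose:

* **Null-calibration world** (25 types × 4 cells, 2000 genes, *no* planted
  effects): observed labels are exactly exchangeable with shuffles, so
  empirical p-values are uniform by construction — the strongest possible
  calibration statement, verified at [0.03, 0.07] for the fraction of
  $p \le 0.05$.
* **Power world** (20 types × 4 cells, 10,000 genes, one type's 300
  markers shifted 1 SD): detection power and min-p FDR behavior.
* **Inflated-baseline world** (40 types × 3 cells, 5000 genes, dense
  baseline $N(1.5, 1)$, `nonspecific_shift = −0.5`, no set shift):
  reproduces the above-0.5 permuted baseline. The dense baseline is chosen
  so permutation-derived sets are dominated by marker-structured genes —
  the mechanism behind the real phenomenon — rather than sparse
  singletons. In this world observed sets (~100 planted markers) are
  larger than permutation-derived ones (~8 genes), so the empirical test
  is *conservative*; the acceptance check asserts the absence of
  anti-conservatism (fraction of $p \le 0.05$ at most 0.07) rather than a
  two-sided band, which is exactly the control claim the procedure makes.

## Numerical choices

* Sample (n−1) SD for standardization; a population-SD toggle exists.
* Mann–Whitney p-values use the normal approximation with tie correction
  and a 0.5 continuity correction; at very small n (a 3-of-6 set) this is
  documented to sit within 0.15 of the exact enumeration, and the suite
  checks agreement with an exhaustive oracle there and with
  `wilcox.test` elsewhere.
* Tie comparisons in the empirical p use a $10^{-12}$ tolerance so exact
  floating-point ties count as extreme.
* The shuffle matrix is drawn up front from the master seed, making runs
  byte-reproducible and permutations parallelizable in principle.
* Exact p ties between directions in direction-split merges are excluded,
  not broken arbitrarily; midranks make any residual tie handling
  immaterial to AUROCs.

## Known limitations

* The permutation engine recomputes thresholding per shuffle but assumes
  the standardized matrix fits in memory as a dense matrix.
* GO annotations are used exactly as supplied; there is no ancestor
  propagation up the GO graph (a deliberate default, as annotation
  provenance rarely states propagation), and no term-size reweighting.
* The generator's balanced type sizes are a simplification; unbalanced
  designs only sharpen the geometric bound discussion above.
* Homology handling assumes pre-normalized symbols; live symbol updating
  against online services is out of scope.
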