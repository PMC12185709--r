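---
title: "Methods: models, parameters and design choices in interorgan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in interorgan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interorgan)
```

`interorgan` analyses multi-organ, FPKM-scale expression data from thermal
acclimation experiments. This vignette documents the statistical machinery,
the tunable parameters and the design decisions that were genuinely open —
the things a maintainer or a reviewer would want stated rather than
reverse-engineered from the code.

## The experimental design the package assumes

The target design is a reciprocal temperature transfer: animals reared from
the zygote stage at a cool or warm temperature either stay at their rearing
temperature (cool-acclimated `CA`, warm-acclimated `WA`) or are switched to
the other temperature at metamorphosis (cool-switched `CS` = warm-reared
then cooled; warm-switched `WS` = cool-reared then warmed). Each group has
6 animals, sexed 3:3 except `CS` at 4:2, and every animal contributes one
sample from each of seven organs (brain, heart, lung, liver, small
intestine, muscle, skin): 24 animals, 168 samples. `sim_design()` emits
exactly this layout; `read_metadata()` validates user data against the same
vocabulary.

## Biweight midcorrelation

The crosstalk screen rests on the biweight midcorrelation (`bicor()`), a
robust correlation that replaces means by medians and downweights points
far from the centre. For a vector $x$ with median $m_x$ and unscaled median
absolute deviation $d_x = \mathrm{median}|x_i - m_x|$, define

$$u_i = \frac{x_i - m_x}{9\,d_x}, \qquad
  w_i = (1-u_i^2)^2\,\mathbf{1}[|u_i|<1], \qquad
  \tilde x_i = (x_i - m_x)\,w_i,$$

and analogously for $y$; then

$$r = \frac{\sum_i \tilde x_i \tilde y_i}
           {\sqrt{\sum_i \tilde x_i^2\;\sum_i \tilde y_i^2}}.$$

Choices worth stating:

* **Tuning constant 9, unscaled MAD.** This is the canonical biweight
  midcorrelation parameterisation: points beyond nine MADs from the median
  get zero weight. The MAD is used raw (no 1.4826 normal-consistency
  factor); the factor would simply rescale $u$ and is not part of the
  canonical definition.
* **MAD-zero fallback.** When a gene's MAD is zero (more than half its
  values tie), the biweight is undefined. Rather than abort a screen over
  thousands of genes, that vector reverts to ordinary product-moment
  weighting (centred at the mean, unit weights) and the result is flagged
  `fallback_used`. Genes that are exactly constant are an error in the
  scalar API and an `NA` (treated as $p=1$ downstream) in the matrix
  screen.
* **p-value.** A two-sided p comes from $t = r\sqrt{(n-2)/(1-r^2)}$ on
  $n-2$ degrees of freedom. This is an approximation, adopted because it
  is the scale on which large screens are feasible. Its accuracy was
  quantified against a conditional permutation null during development:
  the absolute deviation between the t-based p and a $10^5$-permutation p
  is typically 0.004–0.015 at $n \le 30$, shrinking with $n$. That gap is
  a property of any t-based p against a conditional permutation null at
  these sample sizes — an exact-under-normality Pearson p shows the same
  order of deviation — so the package documents it rather than pretending
  the t p is exact. Power and calibration consequences are negligible for
  screening (the null rejection rate at $\alpha = 0.05$ is within $\pm
  0.01$ of nominal at $n = 24$; this is asserted by the test suite).

`bicor_screen()` computes all row pairs of two matrices by a vectorised
transform-then-crossproduct path and is tested to agree with the scalar
definition to $10^{-12}$.

## Inter-organ crosstalk scoring

`rank_regulators()` implements the secreted-protein screen between an
origin and a target organ:

1. **Pairing.** Correlation across organs needs paired observations; the
   animal is the experimental unit, so the origin-organ sample and the
   target-organ sample of the same animal are paired
   (`pair_by_animal()`). No other pairing is coherent for this design.
2. **Scale.** Correlations are computed on $\log_2(\mathrm{FPKM}+1)$ by
   default (`log_transform`). FPKM spans orders of magnitude; on the raw
   scale a screen at $n = 24$ is dominated by a few highly expressed
   samples, while on the log scale expression relationships are
   approximately linear. The robust weighting then guards against residual
   outliers rather than against the scale itself.
3. **Significance score.** Each secreted gene receives
   $S = \sum_j -\log_{10} p_j$ over *all* target-organ genes — not only
   the genes passing selection thresholds. Monotone-equivalent transforms
   would not change ranks; the sum is used because it accumulates evidence
   across the whole response transcriptome. P-values are floored at
   `p_floor = 1e-300` so the score stays finite.
4. **Ranking and ties.** Genes are ranked by descending score; exact ties
   break lexicographically by gene id so output is deterministic.
5. **Origin specificity.** A candidate passes when its mean FPKM in the
   origin organ strictly exceeds its mean FPKM in every other organ. The
   strict inequality makes exact ties fail, which is the conservative
   choice for a filter whose purpose is to exclude genes without a clear
   organ of origin. A strict max-mean criterion was chosen over graded
   specificity indices (e.g. tau) for transparency; a graded filter would
   be a config option, not a replacement.
6. **Target selection.** Per regulator, target genes with $r > 0.5$ and
   $p < 0.05$ (both strict) are reported, and can be passed to the
   enrichment module with the screened target-organ transcriptome as the
   background.

Scores are computed pooled across sexes by default; a per-sex screen is a
metadata subset away and needs no special support.

## Differential expression and sexual dimorphism

The DE stage is deliberately a *contract*: any procedure yielding per-gene
`log2fc`, `p`, `padj` can feed the downstream classifiers. The default,
`de_test()`, is a Welch two-sample t-test on $\log_2(\mathrm{FPKM}+1)$
with Benjamini–Hochberg adjustment across all tested genes. A
negative-binomial count model is intentionally not reimplemented — the
package consumes FPKM, on which count models are not defined — so absolute
DEG counts from this default are not comparable to count-based engines.
The `+1` pseudo-value bounds fold-changes for genes that are off in one
condition. Genes with zero variance on both sides and equal means get
`log2fc = 0, p = 1`; zero variance with unequal means yields `p = 0` (the
difference is exact). BH was chosen for multiplicity control because a
transcriptome-wide DEG screen controls the false discovery rate; FWER-type
corrections (Holm) answer a different question and are reserved for small
targeted comparisons.

Sex-biased genes are classified in the cool-acclimated reference with the
conventional thresholds $|\log_2 FC| > 1$ and $p_{adj} < 0.05$, both
strict, with the male-vs-female sign convention (positive = male-biased).

`attenuation_analysis()` quantifies directional attenuation of dimorphism
under warming: for each bias class within each sex it reports the median
warm-vs-cool fold-change, the fraction of genes moving toward the opposite
sex (male-biased genes falling in warm males and rising in warm females,
mirrored for female-biased genes), and a two-sided sign test against 0.5
(zero fold-changes dropped; a single-gene class legitimately returns
$p = 1$).

## Intron retention

Retention evidence is computed from per-base depth over the intron plus
the spliced-junction read count spanning it:

* `intron_depth` — the median per-base depth after discarding the lowest
  and highest 10% (floor) of positions. The trim approximates exclusion of
  exon-adjacent coverage bleed without read-level data; the fraction is a
  parameter (`trim`).
* `coverage` — fraction of intron bases with nonzero depth.
* `ir_ratio` — `intron_depth / (intron_depth + junction_reads)`, defined
  as 0 when both terms are 0.

The retention filter keeps introns with `ir_ratio > 0.5`,
`coverage > 0.9` and `intron_depth > 1.0` — all strict, mirroring the
printed ">" thresholds, so records sitting exactly at a threshold are
excluded. Per-intron results are reported; aggregation of multiple introns
to a per-gene call is left to the user because no principled default
exists. Coordinates are 0-based half-open throughout (BED convention),
which avoids off-by-one drift between interval and depth arithmetic.

## Enrichment

`hypergeom_enrich()` is the standard over-representation test: with $N$
background genes, $K$ in the set, $n$ in the foreground and $k$ hits, the
p-value is the upper tail including the observed count,
$p = P(X \ge k)$. Sets are intersected with the background first; sets
that vanish are skipped rather than tested at $K = 0$. Q-values are BH
(the usual reading of "q-value" in enrichment reporting; Storey's
estimator would be an alternative, not a correction of this one), with
$q < 0.05$ flagged. The background must be supplied explicitly — for
crosstalk targets it is the screened target-organ transcriptome, not the
genome — because background choice is the single largest silent bias in
enrichment analysis.

## The synthetic data generator

`sim_expression()` generates log-normal FPKM: Gaussian effects are summed
on the $\log_2$ scale and exponentiated. Per gene: a baseline
($\mathcal N(6, 1.5^2)$, log2-FPKM units), an organ effect
($\mathcal N(0, 2^2)$ per organ — organ identity dominates total variance,
as in real multi-organ data), planted effects, and residual noise
($\sigma = 0.25$). The parameters were fixed once, by the following
reasoning, and are not tuned to any test outcome:

* **Sex effect 4.0 log2 units** on planted biased genes ($\pm 2$ per
  sex). The within-group contrast has only 3 vs 3 animals; a Welch test at
  that size, with BH across 2,000 genes, reaches ~99% per-gene power at an
  effect of 4.0 with $\sigma = 0.25$ (computed by direct simulation of the
  Welch statistic — a fixed-df noncentral-t shortcut overstates power at
  these sizes because the estimated df ranges over 2–4). Biologically this
  is a vitellogenin-class liver dimorphism, not a subtle one: the
  generator's planted genes are meant to be the kind a 3-vs-3 design can
  legitimately find.
* **Temperature effect 2.0 log2 units** on responsive genes, applied in
  full in `WA`, not at all in `CA`, and at `switch_fraction` (default 0.5)
  in the switched groups — switching temperature at metamorphosis
  partially, not fully, remodels the transcriptome.
* **Attenuation.** A configurable fraction (default 0.8) of sex-biased
  genes has its sex effect multiplied by $(1 - w)$ where $w$ is the
  group's warmth (0, 0.5, 1): dimorphism shrinks from both sides as
  animals warm, which yields the mirrored sign pattern the attenuation
  module tests for.
* **Planted regulator.** One secreted gene in the origin organ shares a
  latent per-animal factor $z_a \sim \mathcal N(0,1)$ with each of its
  target genes in the target organ, with loading
  $\lambda = \sigma\sqrt{r/(1-r)}$ so the expected pairwise correlation is
  exactly the configured $r$ (default 0.7, 200 targets of 2,000 genes).
* **Secreted genes** (default 50, the regulator first) get a +8 log2
  origin-organ offset. The offset must dominate the $\mathcal N(0, 2^2)$
  organ effects for the generator's own guarantee — planted regulators are
  origin-specific by construction — to hold; at +8 the chance of another
  organ overtopping the origin is ~1%, and a 256-fold enrichment is
  typical of genuinely liver-restricted secreted genes.
* **Gene roles occupy fixed id blocks** (secreted, male-biased,
  female-biased, temperature-responsive, targets, in that order). Gene ids
  are labels; randomising them would only complicate the truth record.

Determinism: identical config + seed gives byte-identical output, and the
pipeline derives per-stage seeds from the global seed by a fixed
stage-name offset so stages are independently reproducible.

**What the generator does not emulate.** Library-size and GC biases,
count-level (negative-binomial) noise, dropout, correlated gene modules
beyond the planted regulator, batch effects, and unequal detection across
organs. Passing recovery tests on this generator therefore demonstrates
that the *procedures* are correct and well-calibrated under their stated
model — not that real tissue data will be as clean. In particular the DE
default will report different absolute DEG counts than a count-model
engine on real counts.

`sim_intron_fixtures()` builds retention fixtures by construction: truly
retained introns pass all three thresholds; rejected fixtures include, for
each threshold, one intron failing on that criterion alone, plus introns
sitting exactly at each threshold (excluded under strict inequality).

## Validation scale

The test suite and the acceptance script run entirely on generated data at
the design's native size (24 animals × 7 organs, 2,000 genes): regulator
recovery over 40 independent simulations, null calibration of the
correlation p over $10^4$ pairs at $n = 24$, oracle equivalence of the
correlation over 100 random pairs with a $10^5$-permutation p-value
cross-check, exhaustive enumeration of the hypergeometric tail for all
backgrounds up to $N = 12$, and byte-level reproducibility of two demo
pipeline runs. These sizes were chosen so the whole suite validates every
claim the package makes while staying comfortably runnable on a laptop.

## Known limitations

* The t-approximation p for bicor is approximate at small $n$ (quantified
  above); exact inference would need a permutation path, which is provided
  as a validation oracle, not a production mode.
* The DE default is a contract implementation on FPKM, not a count model.
* The specificity filter is binary; borderline origin-specificity is not
  graded.
* Per-gene aggregation of intron retention across introns is not defined.
* The enrichment test treats genes as exchangeable; length/expression bias
  corrections are out of scope.
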