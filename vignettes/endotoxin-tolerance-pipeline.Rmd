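---
title: "Methods: the endotol analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the endotol analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(endotol)
```

endotol analyzes the epigenetic and transcriptional remodelling that
accompanies endotoxin tolerance: monocytes exposed once to bacterial
lipopolysaccharide (LPS) respond to a second stimulus with blunted induction
of pro-inflammatory genes. The package links three layers of evidence —
array-based DNA methylation, RNA-seq expression, and genomic context (motifs,
histone-mark peaks, TSS proximity) — and every stage can be exercised against
synthetic data with known ground truth. This vignette is the package's
account of the statistics it implements, the tunable parameters, and the
design decisions taken where the methodology was genuinely open.

## Differential methylation on M values

Methylation at a CpG probe is summarized by the beta value, the fraction of
methylated signal, in [0, 1]. Betas are heteroscedastic (variance shrinks
toward the boundaries), so modelling is done on M values,

$$M = \log_2 \frac{\beta}{1 - \beta},$$

whose variance is closer to constant. `beta_to_m()` clips betas to
`[clip, 1 - clip]` first; the default clip of `1e-6` keeps boundary betas
finite without perturbing interior values (a beta of 0.001 maps to the same
M with or without the clip to 12 significant digits).

`diff_methylation()` fits, per probe, an ordinary least-squares model with an
intercept, a condition indicator (the tested coefficient, treated minus
reference) and donor indicator columns. The donor covariate absorbs the
between-donor methylation differences of a paired design, which are typically
much larger than the treatment effect. Residual variances are then moderated
empirically (`moderate_variances()`): the observed per-probe variances
$s^2_g$ with $d$ residual degrees of freedom are modelled as scaled-F draws
around a prior $(d_0, s_0^2)$ estimated by method of moments on $\log s^2$
(digamma/trigamma matching, with a Newton solver for the trigamma inverse),
and each probe's variance becomes the weighted combination

$$\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},$$

tested against a t distribution with $d_0 + d$ degrees of freedom. With
triplicate designs ($d$ as low as 2–4) this borrowing of strength is what
makes per-probe testing workable at all. When the spread of the observed
log-variances does not exceed what chi-square sampling alone produces, the
estimated $d_0$ is infinite and all probes share the common variance — the
correct limit, not an error.

Multiple testing uses the Benjamini–Hochberg step-up (`bh_fdr()`, implemented
from its definition and cross-checked in the tests against both exhaustive
enumeration and `p.adjust`). A probe is called differentially methylated
(`call_dmps()`) when `q < 0.05` and `|delta beta| > 0.2`, both strict; ties
at the threshold are excluded. The effect-size filter is computed on **raw**
betas (mean treated minus mean reference), not covariate-corrected ones,
because the threshold refers to actual group methylation differences;
covariate-corrected betas (`remove_covariate_effects()`, donor block coded
sum-to-zero so balanced group means are preserved) are for display only.
Probes with any missing beta are dropped before modelling rather than
imputed — the simplest defensible rule, reported via a message.

## Differential expression and the ranking metric

The expression stage is a deliberately documented divergence from
negative-binomial Wald testing: counts are normalized by median-of-ratios
size factors (`size_factors()`; factors rescaled to geometric mean 1),
shifted-log transformed as `log2(normalized + 0.5)`, and run through exactly
the same moderated linear model as the methylation stage, donor covariate
included. This trades some power at very low counts for a single, fully
specified, testable model; the synthetic acceptance surface (recovery of
planted two-fold-plus changes, false-discovery control) is defined for this
method, and the tests hold it to ≥80% sensitivity with observed FDP ≤ 0.10
at the standard thresholds. Genes are called differentially expressed with
strict `|logFC| > 1` and `q < 0.05`, optionally restricted to protein-coding
biotypes.

For gene set enrichment the list is ranked by
$\mathrm{score}_g = -\log_{10}(q_g) \cdot \mathrm{sign}(\mathrm{logFC}_g)$.
Two numerical choices: q values below the representable range are floored at
one tenth of the smallest positive q (the metric is undefined at zero and
the floor preserves the ordering), and ties are broken deterministically by
larger `|logFC|`, then lexicographic gene id, so the ranking — and therefore
every GSEA result — is bit-reproducible.

## The tolerization score

Given per-condition mean log2 expression of naive (untreated) and
LPS-pre-exposed cells before and after an LPS re-exposure, the score is

$$\mathrm{score} = (U_{re} - U) - (L_{re} - L).$$

A positive score means the gene mounts a weaker re-exposure response in
pre-exposed cells — it is tolerized. Gene-specific offsets (length,
mappability, baseline abundance) cancel exactly. `top_n_sets()` takes the
100 highest- and 100 lowest-scoring genes as the tolerized / non-tolerized
sets (boundary ties broken by gene id). When replicates exist, scores are
computed on per-condition means; the generator mirrors this with a
triplicate design.

## Preranked GSEA

`gsea_preranked()` implements the weighted Kolmogorov–Smirnov running sum:
walking down the ranked list, set members increment the sum by
$|score|^p / \sum_{hits} |score|^p$ (weight $p = 1$, the field's default)
and non-members decrement it by $1/(N - k)$. The enrichment score (ES) is
the extremal deviation; the leading edge is the set members at or before
(positive ES) or after (negative ES) the extremum.

Design decisions, each fixed and documented because the result depends on
them:

* **Gene-label permutation null.** A preranked list carries no phenotype
  labels, so the null is the ES distribution of random same-size gene sets
  drawn without replacement from the list.
* **Add-one nominal p** over the same-sign null, so p is never 0 and is
  bounded below by $1/(P+1)$.
* **Same-sign normalization**: NES = ES divided by the mean |ES| of the
  same-sign null — the only convention consistent with reporting signed NES
  alongside FDR.
* **Ratio-of-tails FDR** on the pooled normalized null across the
  collection, clamped to [0, 1].
* **One RNG stream**, seeded once and consumed in set order: identical seed
  and permutation count give bit-identical output.
* The permutation engine computes ES from hit positions in O(k) with the
  same first-extremum tie rule as the full running sum (the two routes are
  tested for exact agreement), and small `choose(N, k)` problems can be
  enumerated exhaustively instead of sampled.

With weight 0 the statistic reduces to the classical KS statistic on hit
positions, which the tests verify against a direct oracle.

## Enrichment around CpGs

Three CpG-centric analyses share one statistical core, the exact
two-sided Fisher test (`fisher_2x2()`: hypergeometric enumeration with the
conventional `1 + 1e-7` tie tolerance) with Haldane–Anscombe 0.5-corrected
odds ratios whenever a cell is zero:

* **Motif windows** (`motif_enrichment()`): ±250 bp windows around target
  CpGs vs background CpGs (all annotated CpGs minus the targets, keeping the
  2×2 cells disjoint). A window is a hit if any position on either strand
  scores at or above the threshold under log-odds PWM scanning
  (`pwm_scan()`; pseudocount 0.25 per cell, uniform background, both
  configurable). The default threshold is 80% of the motif's maximum
  achievable score — HOMER-like behavior expressed as a transparent,
  reproducible rule. BH correction runs across motifs.
* **Tile profiles** (`tile_peak_enrichment()`): the ±3 kb region around each
  CpG is divided into 10-bp tiles (600 tiles); at each offset a CpG is a hit
  if its tile overlaps ≥1 bp of any peak, and target vs background hits form
  the per-tile 2×2. The ≥1 bp overlap rule is the simplest stated choice;
  degenerate inputs (no peaks, saturating peaks) collapse to odds ratio 1
  under the correction rather than failing.
* **Category enrichment** (`category_enrichment()`): per-label 2×2 of
  genomic-feature or CpG-island-context annotations, reporting enrichment or
  depletion relative to OR = 1.

## Methylation–expression integration

`nearest_tss()` assigns each CpG the gene with the closest TSS (binary
search per chromosome, verified in the tests against the all-pairs brute
force), with ties broken by lexicographic gene id and a signed,
strand-aware distance (positive downstream of the TSS in the direction of
transcription). "Removing duplicate genes" is interpreted as keeping the
closest CpG per gene — the only distance-principled choice. The
delta-beta vs logFC association (`meth_expr_correlation()`) is a Pearson
correlation with a two-sided t-based p value, using one pair per gene by
default (the all-pairs mode is exposed via `one_per_gene = FALSE`).

Time-course trajectories of hypomethylation-associated genes are clustered
with `hier_cluster_timecourse()`: rows standardized to mean 0/sd 1,
Euclidean distance, complete linkage, tree cut at k = 3. Linkage and
distance are fixed and documented so the three-cluster behavior is
reproducible; cluster labels are ordered by the cluster mean at the final
timepoint, making C1..Ck deterministic. Constant rows cannot be standardized
and are dropped with a warning.

## The synthetic-data generators

Every stage is testable offline because `simulate_methylome()`,
`simulate_counts()`, `simulate_tolerance_timecourse()` and
`simulate_regions()` generate inputs with the statistical structure the
analysis assumes and a serialized ground truth. All are pure functions of
their parameter tuple including the seed, and `simulate_study()` derives all
four from one master seed.

What they emulate, and the defaults chosen as realistic study conditions:

* **Methylome**: bimodal baseline M values (array betas concentrate near 0
  and 1), donor random effects shared across a donor's samples (sd 0.5 M
  units), per-sample noise (sd 0.3 M units), triplicate paired design, and
  planted probes whose treated-arm beta is shifted by −0.3 from a mid-range
  baseline so the shift stays inside [0, 1].
* **Counts**: log-normal gene means (median ≈ 55 counts at desk scale),
  negative-binomial dispersion 0.1 (typical for biological replicates),
  mild library-size and donor lognormal effects, planted genes multiplied by
  $2^{\pm 2}$ in the treated arm.
* **Tolerance time course**: every gene mounts a re-exposure response in the
  naive arm; planted genes respond by 2 log2 units less in the pre-exposed
  arm; each reported condition value is the mean of 3 replicates with
  per-replicate noise sd 0.5 — a triplicate design matching how such tables
  are produced.
* **Regions**: an i.i.d. uniform 5-Mb contig; spaced CpGs so ±250 bp windows
  never overlap between CpGs; a sharp 9-bp GAS-like consensus
  (`stat_like_pwm()`) planted in 60% of target and 5% of background windows
  on a random strand; one peak per target CpG (half-width 100 bp, center
  jitter sd 20 bp); annotation labels drawn from different category
  distributions for targets vs background; stranded TSSs scattered
  uniformly.

What they deliberately do **not** emulate: probe-type chemistry and
normalization artifacts of real arrays, compositional CpG islands, GC bias,
read-level sequencing error, and correlated neighboring probes. Passing
tests therefore demonstrate the statistics are implemented and calibrated as
specified — not that upstream normalization of real data is handled, which
is outside this package (it consumes a normalized beta matrix and a count
matrix).

Desk-scale problem sizes are used throughout the suite and the acceptance
script — 20,000 probes, 5,000 genes, one 5-Mb contig with 2,200 CpGs —
chosen as the package's standard fixture sizes; full array scale changes
nothing statistically and can be requested through the generator arguments.

## Calibration and known limitations

Under a null methylome with donor effects the per-probe moderated test is
calibrated (type-I rate at p < 0.05 within Monte-Carlo error of 0.05, and
essentially no DMP calls at the double threshold), which the acceptance
suite verifies end to end. Known limitations, stated rather than hidden:

* No mean–variance trend is modelled in the moderation (no trend fitting);
  array data with strong trends would be slightly miscalibrated at the
  extremes.
* The shifted-log moderated-t expression stage loses power for genes with
  very low counts relative to exact NB machinery, and the post-hoc
  `|logFC|` filter means the realized false-discovery proportion among
  *called* DEGs is controlled only approximately.
* The FDR of the GSEA stage uses the classical pooled ratio-of-tails
  estimate, which is conservative for small collections.
* Strict inequalities are used at every published threshold; values exactly
  at a threshold are excluded by construction.
* Ranking uses FDR-adjusted q values everywhere, including the edge case
  q = 1 (score 0); nominal p is never substituted.

## A worked miniature

```{r example}
sim <- simulate_methylome(n_probes = 2000, n_dmp = 60, n_donors = 3, seed = 1)
dm <- diff_methylation(sim$beta, sim$sheet, contrast = c("LPS", "untreated"))
dmps <- call_dmps(dm, fdr = 0.05, delta = 0.2)
nrow(dmps)
mean(sim$truth$probe %in% dmps$probe) # sensitivity against the planted truth
glance(dm)
```
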