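---
title: "Nominating differentiation-associated lipid species: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating differentiation-associated lipid species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidisc)
```

## The problem and the data

Keratinocytes leaving the epidermal stem cell compartment remodel their
lipidome. Two experimental routes probe this: a suspension-culture time
course (0/4/8/12/24 h, duplicate, with a PKC-inhibitor arm that blocks
differentiation) and an siRNA knockdown time course (siScramble, siELOVL1,
siSLC27A1 at 24/48/72 h, triplicate). Shotgun lipidomics yields a samples ×
species table of picomole amounts; a companion 96-well siRNA screen of 258
lipid-enzyme knockdowns reads out the fraction of involucrin-positive cells
per well, in quadruplicate under two culture conditions. This package
implements the full downstream chain for these three designs and a generator
of synthetic datasets with planted ground truth.

## Models and procedures

### Normalization

Amounts are normalized per sample to mol% of total lipid
(`normalize_molpct()`), the scale on which class compositions, enrichment
tests and fold changes are defined. Missing (sample, species) pairs in long
input are zeros, not missing data: shotgun lipidomics reports only detected
species. Whether Z-scoring for the clustering heat map should operate on
mol% or raw picomoles is not uniquely determined by convention; mol% is used
here, consistent with everything downstream being defined on mol%, and the
input to `zscore_by_species()` is left to the caller.

### Near-zero-variance filter

Before PCA and sPLS-DA, species are removed when the ratio of the most to
second-most frequent value exceeds 95/5 **and** fewer than 10% of values are
distinct (zero-variance species always). Both inequalities are strict,
matching the multivariate toolchain this mirrors — a column equal in 19 of
20 samples with two distinct values sits exactly on both boundaries and is
*retained*. A plain variance-threshold mode is available.

### Sparse PLS-DA

`fit_splsda()` is written from scratch. Per component, a power iteration on
the cross-covariance of the centered/unit-scaled predictor block and the
centered one-hot class block alternates

1. `u ∝ Xᵀ(Yv)`, hard-threshold to the `keepX` largest |entries|, normalize;
2. `v ∝ Yᵀ(Xu)`, normalize;

until the relative change in `u` falls below 1e-9 (at most 500 iterations;
non-convergence keeps the last iterate with a warning). The score is
`t = Xu`; both blocks are deflated by regression on `t` (regression mode),
which makes scores mutually orthogonal and the residual predictor block
orthogonal to every extracted score. Numerical choices:

* **Initialization** — `v` starts from the first left singular vector of
  `YᵀX`: deterministic and seed-free.
* **Tie-break** — if the `keepX`-th and (`keepX`+1)-th |weights| tie
  exactly, the smaller column index is kept, so fits are reproducible across
  platforms and column orders.
* **Pure selection** — surviving weights keep their magnitude. Reference
  implementations soft-threshold (shrink) survivors; since the discriminant
  rules below depend on the *selection set* and a small magnitude cutoff,
  shrinkage would only move loadings near the 0.01 boundary. The dense-limit
  behavior (keepX = p) is identical either way and is verified against an
  SVD oracle in the tests.
* **keepX clamping** — `keepX = 250` is the published default and is kept
  even when fewer species survive filtering; it is clamped to p with a
  warning.
* **Scaling** — unit-variance scaling of predictor columns is on by default,
  mirroring the `scale = TRUE` convention of the published analysis.

### Discriminant rules

The published rules are stated with signed loadings (e.g. "loading <
−0.01"), but the sign of any PLS component is arbitrary and differs between
implementations. The canonical rule here is |loading| > 0.01 **plus** the
enrichment direction test, which is what the signed rule expresses once the
component is oriented; `orient_component()` fixes signs against a reference
class for reporting. The tests verify that flipping any component's sign
changes no discriminant set.

* **Suspension** (4-class model; classes assigned by
  `assign_suspension_classes()`): component 2 with strict class-median
  enrichment in "differentiated", united with component 3 and enrichment in
  "commitment". "Comparing the median of each sample class" is read as
  strict superiority over *every* other class median (a pooled-others mode
  is available).
* **Knockdown** (one model per timepoint, union over 48/72 h): components
  1–2 for siELOVL1, component 2 for siSLC27A1 — the extraction sentence
  read literally; a `components` argument overrides either. Enrichment is a
  mean fold change > 1 versus siScramble on mol%; fold changes are always
  reported on mol% even though the model may be fit on other scales. A
  species undetectable in the control with signal in the target reports the
  `Accumulated` sentinel, which also takes precedence in the maximum
  fold-change report.
* **Intersection** — sets from the two experiments intersect by canonical
  annotation (class + chains; aliases ignored), so structurally identical
  species match across annotation dialects.

### Screen scoring

Modified Z-scores use the raw MAD with the 0.6745 consistency constant
(configurable; it cancels everywhere except the volcano y-axis inputs). The
normalization unit is one culture condition across its plates — computing Z
within condition is what makes pooling the growth and serum arms valid;
per-plate normalization is available. Fold changes are per plate against
nontargeting controls on raw readouts (Z-scores can be negative, which would
break ratios). Significance is a two-sided Welch t of a target's pooled
Z-scores against same-plate control Z-scores, reported without
multiple-testing correction to match the published volcano convention; the
exact test behind the original figure is not documented, so this choice is
the package's own. Involucrin-siRNA wells are transfection QC and take no
part in control means or calling. Hit thresholds are strict: FC must exceed
2.5 (induction) or fall below 0.6 (inhibition) at p < 0.05.

## The synthetic-data generator

`simulate_suspension()`, `simulate_knockdown()` and `simulate_screen()`
reproduce the three design shapes with planted truth. Choices, made once:

* **Class composition** — PC-dominant with minor sphingolipid classes,
  loosely mimicking cultured-cell lipidomes; species base abundances are
  lognormal within class (sdlog 1, spanning ~2 orders of magnitude).
  No fidelity to any measured lipidome is claimed — only the statistical
  structure matters for testing.
* **Replicate noise** — multiplicative lognormal with sdlog 0.15 (~15% CV),
  a typical biological-replicate scatter for cultured cells.
* **Suspension truth** — besides the 20 commitment- and 20
  differentiation-enriched species (3×), 40 species respond 2.5× in *every*
  suspended sample. This broad suspension response reproduces the structure
  such experiments show — the adherent/suspended contrast dominating the
  first component — and pins the differentiation contrast to component 2 and
  commitment to component 3, as the discriminant rules assume. Per-sample
  totals vary ±30%.
* **Knockdown truth** — 20 siELOVL1- and 15 siSLC27A1-enriched species (3×
  at 48/72 h), 3 control-undetectable species exercising the `Accumulated`
  sentinel, and 30 species drifting over time in all arms (the dominant
  time effect real cultures show).
* **Screen** — plates of 86 targets + 2 nontargeting + 2 no-siRNA + 2
  positive-control wells; baselines 0.10 (growth) and 0.30 (serum); plate
  offsets 5%. Every target additionally carries a small lognormal true
  effect (sd 0.15): with pure well noise a replicate's correlation with the
  replicate mean cannot exceed ~0.5 plus the hits' contribution, so
  target-level heterogeneity is what makes replicate concordance realistic.
  At the default 15% well noise the synthetic screen is *cleaner* than a
  real one (r ≈ 0.96); the concordance check runs at 45% well noise, the
  regime in which r ≈ 0.8.
* **Seeding** — one seeded stream per dataset (`set.seed` at entry with
  fixed RNG kinds). Sub-stream hashing per entity was considered and
  rejected as needless machinery: determinism per seed is what the tests
  and the acceptance script rely on.

What passing tests on these data do **not** show: robustness to batch
effects, missing-value structure, heteroscedastic noise across abundance, or
annotation dialects beyond the grammar above — real shotgun data has all
four.

## Problem sizes used in validation

The packaged validation runs 20 seeds of each generator at the study's
design sizes (20-sample suspension course and 9-sample-per-timepoint
knockdown course over 300 species; 258-target screen in quadruplicate, two
conditions) plus a 1,000-target null screen for the type-I check; the full
suite completes in under two minutes on one core.

## Known limitations

* The loading threshold 0.01 on a unit-norm vector with ~250 nonzero
  entries (typical |loading| ≈ 1/√250 ≈ 0.063) excludes very little, and
  the knockdown enrichment rule is a bare fold change > 1. The combined
  rules are therefore a *permissive selection heuristic*, not a statistical
  test: on null data (no planted effects) the extracted sets are large, not
  empty — a null species passes the strict-median rule with probability
  roughly 1/(number of classes) and the mean rule with probability ~1/2.
  The package measures and reports this honestly rather than sharpening the
  published rules; users wanting specificity should treat the sets as
  candidates for downstream validation, exactly as the original study did.
* No cross-validated tuning of `ncomp`/`keepX`, no prediction of unseen
  samples, no multilevel variants, no batch correction, no imputation, no
  plate spatial-effect correction beyond per-plate control normalization.
* Significance testing of individual lipid fold changes is out of scope;
  the screen's Welch t applies to well readouts, not lipid species.
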