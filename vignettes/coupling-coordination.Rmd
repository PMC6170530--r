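---
title: "Assessing soil-vegetation co-development with the coupling coordination degree model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing soil-vegetation co-development with the coupling coordination degree model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdeval)
```

## The assessment problem

Revegetated mine dumps recover (or fail to recover) through the mutual
feedback of two subsystems: the planted vegetation and the reconstructed
soil. A reclamation pattern can look successful on one axis while the
other lags — the "short plank" that limits the whole ecosystem. ccdeval
implements a composite-index assessment of that co-development: each
plot receives a vegetation score $V_i$ and a soil score $S_i$, and the
pair is condensed into a coupling degree $C$ (how balanced the two
systems are) and a coupling coordination degree $D$ (how balanced *and*
how developed they are), plus a lag diagnosis from the ratio $V_i/S_i$.

The pipeline is a deterministic composition of standard multi-criteria
steps; the package's contribution is a tested, inspectable
implementation in which every intermediate (normalized matrix,
entropies, all three weight layers, scores, classifications) is retained
on the fitted object.

## The model

**Normalization.** Raw indicators arrive in incommensurable units and
are min-max standardized per indicator over the $m$ plots,

$$x'_{ij} = \frac{x_{ij} - \min_i x_{ij}}{\max_i x_{ij} - \min_i x_{ij}},$$

with the reflected form $(\max - x)/(\max - \min)$ for cost-type
indicators so that larger normalized values are always better. Every
non-constant column then attains both 0 and 1. A constant column carries
no ranking information; rather than failing, it is set to all zeros with
a warning, which makes the entropy stage assign it zero weight — the
policy that keeps the pipeline total on degenerate survey data.

**Entropy weights (objective layer).** Within each subsystem, indicator
$j$'s share vector is $P_{ij} = x'_{ij} / \sum_i x'_{ij}$, its
information entropy is

$$e_j = -\frac{1}{\ln m} \sum_i P_{ij} \ln P_{ij}, \qquad 0 \cdot \ln 0 := 0,$$

and its weight is $w_j = (1 - e_j) / \sum_j (1 - e_j)$ over the
subsystem's indicators. Indicators that differentiate the plots strongly
(low entropy) get high weight; a uniform column has $e_j = 1$ and weight
0. The $0\ln 0$ convention matters here because min-max output always
contains exact zeros; we deliberately do not epsilon-shift the data,
which would distort the weights. An all-zero column is treated as
maximally entropic ($e_j = 1$). If an entire block is uninformative the
weights fall back to equal shares with a warning.

**AHP weights (subjective layer).** Subsystems within a system are
weighted by the analytic hierarchy process: the principal right
eigenvector of a positive reciprocal pairwise-comparison matrix,
normalized to sum 1, computed by power iteration (tolerance $10^{-12}$,
at most 10,000 iterations). Consistency is judged by
$CI = (\lambda_{\max} - k)/(k - 1)$ and $CR = CI/RI(k)$ with Saaty's
random-index table ($k \le 10$); $CR > 0.1$ warns by default and can be
promoted to an error. The row-geometric-mean solution (`ahp_geomean()`)
is provided as an independent cross-check; the two coincide on perfectly
consistent matrices. Configs may also supply subsystem weights directly
(`direct_weights`), which is how the bundled fixture encodes weights
whose generating judgments were never published.

**Combination.** The combined weight of an indicator is the product of
its subsystem's AHP weight and its within-subsystem entropy weight.
Because each factor is normalized within its own scope, the products sum
to 1 within each system by construction — no renormalization is applied,
and the per-system weight blocks of the bundled fixture reproduce this.

**Scores and coupling.** Per plot,
$V_i = \sum_{j \in \text{veg}} w_j x'_{ij}$ and
$S_i = \sum_{j \in \text{soil}} w_j x'_{ij}$, both in $[0,1]$. The
coupling degree is

$$C = \sqrt{\frac{V S}{(V + S)^2}} \in [0, 0.5],$$

maximal exactly when $V = S > 0$; $V + S = 0$ is flagged degenerate with
$C := 0$. The coupling coordination degree is

$$D = \sqrt{C \cdot T}, \qquad T = \alpha V + \beta S,$$

with $\alpha = \beta = 0.5$ by default (equal importance of the two
systems; $\alpha + \beta = 1$ is enforced). With equal coefficients this
collapses to the closed form $D = (VS)^{1/4}/\sqrt 2$, which the test
suite uses as an exact oracle against the staged computation.

**A note on the radical.** Some presentations of the model print
$D = C \cdot T$ without the square root. The two forms are not
interchangeable: the radical-free variant systematically deflates $D$
(e.g. $V = 0.57$, $S = 0.74$ gives $0.32$ instead of $0.57$) and does
not reproduce published coordination tables computed with the standard
formulation. ccdeval defaults to the radical form, which is the standard
CCD formulation in the literature, and exposes the radical-free variant
behind `literal = TRUE` (CLI flag `--literal-eq-d`) for comparison
studies.

**Classification.** $D$ is banded into coordination classes and $V/S$
into lag classes with right-closed intervals: $D$ in $(0, 0.2]$ low,
$(0.2, 0.4]$ primary, $(0.4, 0.6]$ intermediate, $(0.6, 0.8]$ well,
$(0.8, 1]$ high coordination; $V/S \le 0.8$ vegetation lagging behind,
$(0.8, 1.2]$ synchronous development, $> 1.2$ soil lagging behind. Both
schemes are configurable (`classification_scheme()`, YAML override).
Note that with two systems $C \le 0.5$, so under equal coefficients
$D \le \sqrt{0.5} \approx 0.707$ and the bands above 0.707 are
unreachable; they are kept for completeness and for other coefficient
choices.

*Banding precision.* Published assessment tables report $D$ and $V/S$ to
two decimals and assign classes to those printed values, so a value that
rounds to a band edge (say $D = 0.4025 \to 0.40$) is classified with the
band containing 0.40. `classify()` therefore bands at reporting
precision by default (`digits = 2`); `digits = NULL` bands at full
precision. This is a presentation convention, not a change to the model:
the full-precision values are always retained on the fit.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha`, `beta` | 0.5, 0.5 | contribution coefficients of the two systems in $T$; must be nonnegative and sum to 1 |
| `cr_max`, `cr_action` | 0.1, `"warn"` | AHP consistency-ratio threshold and policy |
| `literal` | `FALSE` | radical-free $D = C T$ variant |
| `class_digits` | 2 | decimals at which $D$ and $V/S$ are banded |
| `direction` (per indicator) | `benefit` | min-max orientation |

The bundled 18-indicator mine-reclamation index system marks *all*
indicators as benefit-type, including pH and bulk density, which
soil-science convention would usually reverse-code. This mirrors the
arithmetic of the assessment the fixture reproduces (whose published
score tables are only consistent with uniform benefit coding); users
analysing their own surveys should set `direction: cost` for such
indicators in their index config.

## The synthetic-data generator

The original five-plot survey table is not publicly deposited, so the
generator makes the published results an executable fixture instead of
an untestable claim. Ground truth is injected at the normalized scale
and inverted through the min-max transform:
$x = \text{low} + x'(\text{high} - \text{low})$ for benefit columns
(reflected for cost), so `minmax_normalize(generate_matrix(s))`
reproduces the targets exactly provided every column attains an exact 0
and 1 — which two appended anchor plots (an all-0 and an all-1 row)
guarantee when the targets alone do not.

`scenario_from_scores()` goes one step further: setting every vegetation
column of plot $i$ to $V_i$ and every soil column to $S_i$ makes the
weighted system score equal $V_i$ (resp. $S_i$) for *any* weight set
summing to 1 per system, because a weighted mean of a constant row is
the constant. The whole downstream pipeline — weights included — can
therefore be exercised end to end against known $(V, S, C, D)$ without
the original data. Random scenarios (uniform draws within column ranges
plus optional Gaussian jitter) are seeded through a local RNG that never
touches the session's global random state.

What the generator does *not* emulate: realistic ecological correlation
structure among indicators (organic matter and total nitrogen co-vary in
real soils; here columns are independent unless targets say otherwise),
measurement error models, or spatial structure among plots. Passing
tests therefore demonstrate the correctness of the arithmetic and the
pipeline's contracts, not the field validity of any particular survey.

## Numerical choices and degenerate inputs

- Min-max with `max == min`: all zeros, warning, zero entropy weight.
- Entropy with $m = 1$: refused ($\ln m = 0$).
- All-zero share column: $e_j = 1$, weight 0; fully uninformative block:
  equal weights, warning.
- Power iteration from the uniform vector; reciprocity validated to a
  relative $10^{-9}$ before iterating; $k = 1$ short-circuits to weight 1.
- $V + S = 0$: $C = 0$ with a `degenerate` flag; $S = 0$: lag ratio `NA`,
  classified "soil lagging behind (extreme)" if $V > 0$, else
  "degenerate".
- Entropies are clamped to $[0, 1]$ against $10^{-16}$-scale round-off.
- Reports round the way assessment tables print (4 dp for $C$, 2 dp for
  $V$, $S$, $V/S$, $D$); all stored values are full precision.

## Worked example

```{r}
idx <- pingshuo_index()
t5 <- pingshuo_scores()
t5

sc <- scenario_from_scores(setNames(t5$V, t5$plot),
                           setNames(t5$S, t5$plot), idx)
fit <- ccd(generate_matrix(sc), idx, pingshuo_ahp(),
           exclude_plots = attr(sc, "anchor_plots"))
fit
```

The five plots are four 23-year-old reclaimed mine-dump plots under
different planting patterns (RUA broadleaved mixture, RP
broadleaf-conifer mixture, RM and PM monocultures) and an undisturbed
reference plot (OP). The fit recovers the published coupling degrees at
four decimals where the two-decimal $(V, S)$ inputs determine them, the
coordination degrees at two decimals (one plot's published value carries
visible input-rounding slack), and all ten class labels.

## Problem sizes

The assessment itself is desk-scale (five plots, eighteen indicators;
well under a second). The property-style checks in the test suite use
$10^4$ random $(V, S)$ pairs for the closed-form oracle, grids of
$20 \times 20$ for monotonicity, and a few dozen random matrices for the
normalization and round-trip invariants — sizes chosen so the whole
suite documents the claimed exactness ($10^{-12}$ for algebraic
identities, $10^{-8}$ for eigenvector recovery) while running in
seconds.

## Known limitations

- Exactly two systems are coupled; the hierarchy is limited to two
  levels (system / subsystem) above the indicators.
- The lag-ratio and band conventions follow the classification table
  shipped as the default; other traditions place band edges or lag
  directions differently, so cross-study comparisons should pin the
  scheme explicitly.
- Entropy weighting is sample-driven: with very few plots the weights
  are volatile, and a single outlier plot can dominate an indicator's
  information content. The method is honest about this (it is the
  point of the objective layer) but users should not over-interpret
  weights from $m < 5$.
- No missing-data handling: the matrix must be complete and finite.
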