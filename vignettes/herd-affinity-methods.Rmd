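---
title: "Sort-gate social affinity and milk yield: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sort-gate social affinity and milk yield: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions they rest on, the parameters that matter, the
design choices made where more than one defensible option existed, and
what the synthetic-herd validation does and does not demonstrate.

## 1. The measurement model

Each pen of an AMS barn is served by one sorting gate, and every voluntary
trip a cow makes from the resting area produces a timestamped gate
passage — on the order of ten per cow per day. The working assumption is
that **cows that pass the gate in close succession are moving together**,
and that repeated close succession over months indicates a social
affinity. The gate log cannot distinguish affiliative from agonistic
proximity, and it observes only one location in the barn; both caveats
are inherited by everything downstream (see §8).

### Affinity scores

Three pairwise scoring schemes are implemented over a pen's time-ordered
event sequence:

* **Lag sequence** (default): the cow at sequence position $i$ credits the
  cows at positions $i-k$, $k = 1 \dots \texttt{max\_lag}$ (default 4),
  with $\texttt{decay\_base}^{-(k-1)}$; with the default base 2 the lag
  weights are $1, \tfrac12, \tfrac14, \tfrac18$. Passages by the same cow
  at a lagged position are skipped without re-indexing. This scheme is
  purely order-based: it needs no time window and crosses day boundaries.
  The decay base is not dictated by anything in the problem; 2 is the
  simplest exponential decay over four lags and is configurable.
* **Fixed window**: time is cut into consecutive `window_minutes` bins
  (default 15) aligned to midnight; every unordered pair of distinct cows
  present in a bin gains one unit. Credit is presence-based, not
  event-count-based — all cows in a window hold a *uniform* relationship —
  and bins are fixed rather than sliding so a pair is counted once per
  window.
* **Inverse interval**: every pair of passages by distinct cows at most
  `window_minutes` apart contributes $1/\max(\Delta t,
  \texttt{epsilon\_seconds})$; the 1 s epsilon guards simultaneous
  passages recorded at the same second.

Two normalisations apply to any scheme:

* **Monthly traffic weights.** Logged gate traffic varies over the year
  for operational reasons unrelated to the cows' social structure, so each
  event contribution is multiplied by $C_{\min}/C_m$, the pen's minimum
  nonzero monthly passage count over the count of the event's month. The
  weighting is per event contribution, not a post-hoc matrix rescaling, so
  a pair's score remains a weighted sum of its co-occurrence events.
* **Residency normalisation.** Pair totals are divided by
  $\sqrt{T_a T_b}$, the geometric mean of the two cows' total days in the
  pen. The normalisation must be symmetric because the network is
  undirected; the geometric mean is the default, and a co-residency
  overlap denominator is available (`denominator = "overlap"`). Cows with
  fewer than 30 total residency days are removed entirely before scoring.

### Network metrics

Density is $2E/\!\left(N(N-1)\right)$ over strictly positive edges;
degree is the count of incident nonzero edges. For the path-based metrics
(weighted diameter, betweenness) **edge weights are used as distances**,
the default convention of common graph software on weighted graphs.
Under it a higher affinity means a *longer* edge — a semantic oddity that
we document rather than silently fix, because it reproduces the metric
definitions used in the field; reciprocal-score distances are available
via `distance = "inverse"`. On disconnected networks the diameter is the
maximum over connected pairs and the result is flagged.

## 2. Exclusive maximum-affinity pairs

Pairs are formed per pen, stepwise:

1. **Greedy** (non-exclusive): every cow gets its top-scoring partner;
   assignments may be asymmetric and are flagged.
2. **Stable roommates** (exclusive, default first step): preferences are
   each cow's partners by descending score, ties broken by ascending cow
   id, zero-score partners omitted. Irving's two-phase algorithm runs on
   these (possibly incomplete) lists; blocking pairs are defined over
   expressed preferences only and unmatched cows are allowed.
3. **Maximum-weight matching** (fallback): if no stable matching exists,
   a maximum-weight matching of the general graph is computed with the
   primal-dual blossom method, implemented in R in this package (no
   installed package provides general-graph weighted matching). Optimum
   ties are broken toward the lexicographically smallest pair set by an
   edge-fixing refinement.

A structural note: preferences derived from a *symmetric* score matrix
with deterministic tie-breaking always admit a stable matching — the
globally heaviest edge is mutually most-preferred, and induction on the
remaining cows completes the argument — so with network-derived
preferences step 3 never fires. It exists (and is tested against
exhaustive enumeration) for preference tables supplied from elsewhere.
Zero-score pairs are excluded throughout; with an odd number of matchable
cows one remains unmatched and is excluded from the effect analysis.

## 3. The expected-production baseline

Wood's lactation curve
$$Y(t) = \alpha\, t^{\beta} e^{-\gamma t}, \qquad t = \text{days in milk}$$
is fitted separately to every cow × lactation combination — deliberately
on the overfitting side, which makes the deviations attributed to broken
affinity *conservative*, since any slow within-cow trend is absorbed by
the curve. Numerical choices:

* bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM`),
  bounds $\alpha \in (0, 200]$, $\beta \in (0, 3]$, $\gamma \in [0, 0.5]$;
* initialisation from the ordinary least squares solution of the
  log-linearisation $\ln Y = \ln\alpha + \beta \ln t - \gamma t$ (zero
  yields excluded), clamped into the bounds;
* groups with fewer than `min_obs = 5` usable records are skipped —
  three-parameter fits need to stay overdetermined; DIM starts at 1
  because the curve is degenerate at $t = 0$;
* a fit that lands in the degenerate corner of the box (vanishing
  $\alpha$ with maximal $\beta, \gamma$) is reported as non-converged
  rather than used;
* optionally (`shrink_sparse`), groups under `shrink_n` records are refit
  with $(\beta, \gamma)$ pinned to the pen's mean converged values and
  $\alpha$ solved in closed form — a pragmatic stabiliser for thin
  windows, off by default to preserve the per-group estimand.

Parameters fitted on a *partial* DIM window are not individually
identifiable (a long flat stretch constrains only the curve's values, not
$\alpha$ vs $\beta$ vs $\gamma$ separately); the tests therefore validate
the fitted curve on the observed window, and full-lactation recovery of
the parameters themselves.

## 4. The affinity contrast

For each exclusively matched cow, each resident day is labelled
*affinity* (partner co-resident in the same pen) or *broken* (partner
absent). Per cow and period type we report the mean and SD of the daily
deviations from the cow's own expected curve; period types observed fewer
than `min_period_days = 7` days are suppressed to stabilise SDs. Each cow
with both period types contributes one within-cow difference
$d = \overline{\text{dev}}_{\text{aff}} - \overline{\text{dev}}_{\text{brk}}$;
per pen these are tested one-sided ($d > 0$: yields higher with the
partner present, the stated working hypothesis; two-sided by flag), and
raw p-values are Holm-adjusted across pens. Per-pen SDs are the SDs of
the *concatenated* daily deviations, reconstructed exactly from the
per-cow summaries; the SD of per-cow means is computable from the same
summaries if wanted. The pooled `Overall` row has no test (`NA`).

Because daily variability is much larger in early lactation, the
contrast is only identified if period labels are not confounded with
lactation stage; `dim_balance_check()` reports the per-type DIM quartiles
and the two-sample Kolmogorov–Smirnov statistic as an advisory
diagnostic. It never gates the analysis.

## 5. What the synthetic herd emulates

Defaults mirror the study farm the pipeline was designed around: 4 pens ×
54 cows × 365 days; gate passages Poisson with mean 10/cow/day at times
uniform over 24 h; 27% of passages diverted to milking (2.7
milkings/day); residency stay lengths drawn from the four observed
duration bands (30–90, 91–180, 181–270, >270 days, weighted by the
pooled observed cow counts); per-cow Wood parameters
$\alpha \sim \mathrm{LogNormal}(\ln 17, 0.2)$,
$\beta \sim N(0.25, 0.05)$ truncated above 0.05,
$\gamma \sim N(0.004, 0.001)$ truncated above 0.0005 (curves peaking
near 37 kg/day at DIM ≈ 60, matching the reported herd means of 36–42
kg); daily yield noise SD 0.8 kg/day during affinity periods and 2.6
kg/day with a −0.3 kg/day mean shift during broken periods — magnitudes
taken from the reported overall contrast.

**Planted pairs.** A fraction (default 0.4) of each pen's cows is
assigned to disjoint pairs. While co-resident, each gate passage by one
mate is answered by the other within `follow_gap_seconds` (default 30 s)
with probability `follow_prob` (default 0.8); the mates' baseline Poisson
rate during co-residence is `passes/(1 + follow_prob)` so the planted
structure does not inflate the observed daily passage rate.

**How pairs break.** By default 70% of pairs are broken by one or two
*temporary absences* of one mate (4–8 week windows with return — illness,
a management move) and 30% by a *terminal exit* (dry-off, sale), with the
exit day sampled mid-study. The mixture is a deliberate design choice:
with terminal exits only, every broken day falls late in the stayer's
series, so break status is collinear with lactation stage — exactly the
confounding the DIM-balance diagnostic warns about — and the per-cow
curve fit absorbs most of a terminal level shift into its decay
parameter. Temporary mid-residency absences leave the planted shift
identifiable. For the same reason the *effect-recovery validation* (in
the acceptance tests and `scripts/acceptance.R`) uses the
temporary-break-only condition: it checks the estimator where the
method's own identifying assumption holds. Recovery of the planted shift
is validated by the **paired within-cow difference**, not the difference
of the descriptive per-period means, which is diluted by affinity-only
cows (returning leavers).

Even so, the recovered shift is expected to sit slightly below the
planted −0.3 kg/day: the overfit per-cow baseline absorbs part of any
step — the conservative bias noted in §3 — and the acceptance tolerance
(±0.15 kg/day at 40 pairs, averaged over three fixed seeds) accommodates
that attenuation without hiding a sign or magnitude error.

**What it does not emulate.** No feed, weather, oestrus, disease or
milking-permission dynamics; no agonistic interactions; lactation number
is constant per cow (no calving mid-study); yields are Gaussian around
the curve rather than heavy-tailed; follower passages never cross pens.
Passing the validation suite therefore shows the *pipeline* recovers what
was planted under its own assumptions — it does not show that real
sort-gate data carries this much signal.

## 6. Problem sizes used in validation

The test suite runs the full pipeline at the study scale (4 × 54 × 365,
twice, for byte-identical reproducibility), planted-pair recovery at one
pen × 54 cows × 365 days for each follow probability in {0.2, 0.5, 0.8},
effect recovery at 40 pairs × 365 days for three seeds, test-size
calibration on 500 reduced null herds (24 cows × 120 days, true-curve
deviations, so the t-test's size is isolated from fitting noise), and
exhaustive matching oracles on 200 random graphs of up to 8 nodes.

## 7. Determinism and numerical conventions

All randomness flows from a single integer seed; identical configurations
produce byte-identical CSV artifacts. Ties are broken deterministically
everywhere: ascending cow id in preferences, partner lists and greedy
assignment; lexicographically smallest pair set among equal-weight
matchings; a day's first event for residency ties. Event timestamps
within a pen are made strictly increasing (minimal +1 s adjustments)
so sequence positions are well defined. Calendar days cut at midnight;
months are calendar months of the event's timestamp (the bin's start for
the window scheme). Degenerate inputs — empty pens, all-zero score rows,
pens with fewer than two testable cows, all-equal differences — are
flagged or excluded rather than silently propagated.

## 8. Known limitations

* Gate succession cannot separate affiliative from agonistic proximity;
  the affinity label is behavioural shorthand, not a welfare claim.
* Only symmetric, exclusive pairs are analysed; multi-partner structures
  (one cow central to several others) are out of scope because no clean
  affinity/broken period contrast exists for them.
* The diameter/betweenness distance convention follows the field's
  published metric definitions, with the documented oddity that stronger
  ties lengthen paths; use `distance = "inverse"` for the opposite
  convention.
* The Wood baseline absorbs part of any sustained yield shift
  (conservative attenuation); contrasts should be read as lower bounds
  on magnitude.
* With floating-point weights the blossom matching compares slacks
  exactly; pathological near-ties could in principle return a matching a
  hair below optimal, which the lexicographic refinement tolerance
  (1e-9 relative) absorbs in practice.
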