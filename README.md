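# herdaffinity

Social affinity between dairy cows, inferred from sort-gate traffic, and
its effect on milk production.

In barns with automatic milking systems (AMS), cows move voluntarily and
pass a preselection sorting gate on every trip from the resting area —
about 10 timestamped passages per cow per day. Cows that repeatedly pass
the gate in close succession are plausibly moving together, so the gate
log is a cheap, always-on proxy for social relationships. This package
turns a year of sort-gate events, daily milk records, and pen residency
into:

1. **pairwise affinity scores** per pen (three schemes; the default is an
   exponentially decaying *lag-sequence* score),
2. **weighted social networks** and their metrics (density, weighted
   diameter, degree, betweenness),
3. **exclusive maximum-affinity cow pairs** (greedy / Irving's
   stable-roommates / maximum-weight blossom matching, stepwise),
4. a per-cow **expected-production baseline** (Wood's lactation curve fit
   per cow × lactation), and
5. the **affinity contrast**: does a cow deviate from her own expected
   curve differently while her affinity partner is present (*affinity*
   period) versus absent (*broken* period)? Tested per pen with a paired
   *t*-test, Holm-corrected.

Because commercial farm data of this kind is proprietary, the package
ships a **synthetic herd generator** with planted affinity pairs, known
Wood parameters, and a known broken-affinity effect, so every stage of
the pipeline is verifiable against ground truth. It is aimed at
precision-livestock researchers who want to reuse the method or probe its
statistical behaviour before pointing it at their own AMS logs.

## The method in brief

**Lag-sequence affinity.** For the ordered passage sequence of one pen,
the cow at position *i* credits the distinct cows at positions
*i−1 … i−4* with `2^-(k-1)` (1, ½, ¼, ⅛). Contributions are weighted by
`C_min / C_month` (monthly gate traffic varies for operational reasons)
and pair totals are normalised by `sqrt(T_a T_b)`, the geometric mean of
the two cows' days of pen residency. Cows with under 30 days of residency
are dropped.

**Expected production.** Wood's gamma-shaped lactation curve,

```
Y(t) = α t^β exp(−γ t),   t = days in milk
```

is fitted per cow × lactation by bounded Levenberg–Marquardt least
squares from a log-linear start; daily deviations
`observed − expected` (kg/day) are the outcome of interest.

**The contrast.** For each exclusively matched cow with both period
types, the within-cow difference of mean deviations (affinity − broken)
enters a one-sided per-pen *t*-test (hypothesis: yields are higher with
the partner present); raw p-values are Holm-adjusted across pens, and
day-to-day deviation SDs are pooled per period type.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
herd; each is a thin driver over the package functions:

```sh
Rscript analysis/01_simulate_herd.R    # 4 pens x 54 cows x 365 days
Rscript analysis/02_score_networks.R
Rscript analysis/03_match_pairs.R
Rscript analysis/04_fit_lactation.R
Rscript analysis/05_affinity_effect.R
```

Output of stage 3 and stage 5 (seed 1):

```
matched 101 exclusive pairs across 4 pens (stable_roommates)
planted-pair recovery: 40 / 40 (100%)

Pen       MeanBrk  MeanAff    SDBrk    SDAff    p(Holm)
pen1        -0.11     0.01     2.15     0.80      0.063
pen2        -0.07     0.01     2.06     0.80      0.089
pen3        -0.02     0.01     2.22     0.79      0.212
pen4        -0.03     0.01     2.11     0.79      0.063
Overall     -0.06     0.01     2.13     0.79         NA
pooled day-to-day SD: 2.13 kg/day broken vs 0.79 kg/day affinity (2.7-fold)
```

Reading it: all 40 planted pairs were recovered exactly; day-to-day
variability of the deviation from each cow's own lactation curve is
nearly three-fold higher during broken-affinity periods (the planted
ratio is 3.25, diluted here because spuriously matched background pairs
carry no effect), and mean deviations are consistently more negative when
the partner is absent. In R the same run is one call:

```r
library(herdaffinity)
cfg <- synthetic_config(seed = 1)
res <- run_pipeline(run_config(synthetic = cfg, out_dir = "run"))
res$effects
```

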