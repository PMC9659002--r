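---
title: "Fuzzy-inference weighting of mortality risk factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-inference weighting of mortality risk factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fimrisk)
```

## The model

`fimrisk` ranks candidate risk factors for a mortality outcome observed as
country-level crude rates. The method is a fuzzy comprehensive evaluation:
rather than committing to a single weighting scheme, three candidate weight
groups are derived by unrelated principles — a data-driven contingency
statistic (chi-square), a rank-based ordinal score (RIDIT), and an
expert-elicited multi-criteria priority vector (AHP) — and the scheme whose
*composed membership vector* best matches a reference vector is selected by
a fuzzy similarity measure.

### Rates and risk levels

The crude rate of a variable in an observation unit is deaths divided by
population. The default observation unit is the country-year (each country
contributes one observation per year); a country unit (deaths and population
averaged over years before division) is available. With the default design
of 100 countries over 11 years minus 3 missing units, a panel has 1097
observations — deliberately the size at which all of the package's
reference tables were produced.

Each variable is then classified into five ordered risk levels by
quintiles: observations are ranked by rate and cut at ranks
$\lceil nk/5 \rceil$, $k = 1..4$. Ties are broken by original row order, so
classification is deterministic and seed-free; scaling a variable's deaths
by any positive constant leaves its levels unchanged. A constant column is
assigned level 1 throughout with a warning, since no ordering information
exists. We adopted the $\lceil nk/5 \rceil$ convention — the usual
"percentile rank" reading of quintile cuts — while noting that at
$n = 1097$ it yields level counts (220, 219, 220, 219, 219); published
frequencies from comparable analyses differ by a few units depending on tie
handling, which is immaterial downstream because every stage consumes the
levels, not the exact group sizes.

### Weight group A1: chi-square

For each factor $v$ a 2×5 table is built against the outcome levels: the
"$v$" row at outcome level $\ell$ is the sum, over observations at that
level, of $v$'s share of the observation's total crude rate across all
factors; the complement row makes the column totals equal the outcome level
frequencies. This construction conserves the observation count (grand total
$= n$) and uses only in-pipeline quantities; the table entries are
real-valued, and the Pearson formula
$\chi^2 = \sum (O - E)^2 / E$ (with $E$ the margin product and cells with
$E = 0$ contributing 0) is applied as-is. Weights are the statistics
normalized to sum 1.

The per-factor *p-value* reported by `chisq_stage()` deserves a note. The
rate-share table's entries are sums of small continuous shares, not
multinomial counts, so the statistic computed from it is **not**
$\chi^2_4$-distributed under independence (its scale is governed by the
variance-to-mean ratio of the shares and is strongly deflated). Attaching a
$\chi^2_4$ p-value to it would be wrong, and simulation confirms those
p-values pile up near 1 under the null. The stage therefore takes its
p-values from the standard count-based test of independence between the
factor's quintile level and the outcome level (5×5 contingency table,
`stats::chisq.test` without continuity correction), which is asymptotically
calibrated — the package's null-calibration test checks exactly this. The
*weights* keep the rate-share construction, whose worked example is
reproduced digit-for-digit in the test suite; `pearson_chisq()` itself is
validated against `stats::chisq.test` on random integer tables.

### Weight group A2: RIDIT

The outcome's pooled level frequencies $f_1..f_5$ define mid-rank (Bross)
ridits $r_\ell = (\sum_{j<\ell} f_j + f_\ell/2)/n$, which lie in (0, 1) and
have frequency-weighted mean exactly 0.5. Each observation carries the ridit
of its outcome level; a factor's score is

$$ S_v = \sum_g \frac{n_g}{n}\,\bigl|\bar r_g - 0.5\bigr|, $$

the frequency-weighted mean absolute deviation of the group-conditional mean
ridits from 0.5, over the factor's level groups $g$. $S_v$ is 0 when the
factor is independent of the outcome, at most 0.5, equals 0.24 for a factor
identical to a balanced outcome, and depends only on the grouping (not on
the labels of the factor's levels). This is a standard effect-size reading
of RIDIT analysis; per-variable RIDIT summaries in the applied literature
are often reported without their defining formula, so the package commits to
this one and documents it. Weights are the normalized scores.

### Weight group A3: AHP

An $n \times n$ positive pairwise-comparison matrix (entry $a_{ij}$ =
importance of factor $i$ over $j$, diagonal 1) yields a priority vector by
one of three standard methods: column-normalized mean (default), row
geometric means, or the principal right eigenvector by power iteration
(tolerance $10^{-10}$, at most 10,000 iterations, with an explicit
non-convergence error). For a perfectly consistent matrix
($a_{ij} = w_i/w_j$) all three recover $w$ exactly. The principal eigenvalue
is estimated as the mean of $(Aw)_i/w_i$, giving CI $= (\lambda_{max} -
n)/(n - 1)$ and CR $=$ CI$/$RI$(n)$ with Saaty's random indices for
$n \le 15$ and a linear extrapolation (slope 0.02 per step, warned) above.

Reciprocity ($a_{ij} a_{ji} = 1$) is *checked and reported, not enforced*:
real expert elicitations — including the packaged 30×30 matrix — violate it,
and silently "repairing" the matrix would hide the data problem while
changing the answer. The default prioritization method is the
column-normalized mean because the packaged matrix was published together
with its column sums, the signature intermediate of that variant. The
published priority vector for that matrix is treated as indicative only: no
standard method reproduces it exactly, so the package reports its own
priorities and never asserts agreement.

### Fuzzy composition and selection

The membership matrix $R$ has one row per factor: entry $(v, \ell)$ is the
fraction of observations at level $\ell$ of $v$ whose outcome level is also
$\ell$ (class-wise agreement), renormalized to a row sum of 1. It reduces to
a point mass when a single observation agrees at one level, to the uniform
row for a factor identical to a balanced outcome, and to near-uniform for an
independent factor. Each weight group is composed as $B = A R$, normalized
after composition (the convention consistent with composed vectors that sum
to ~100%).

The reference vector $C$ is the outcome's rate mass by level:
$C_\ell$ = (sum of outcome crude rates over observations at outcome level
$\ell$) / (total outcome crude rate). It is uniform for equal rates and
balanced quintiles and strictly increasing for monotone rate-to-level
assignments; it may alternatively be supplied directly in the pipeline
configuration (the packaged nearness table does exactly that). Similarity is
the lattice degree of nearness

$$ \sigma(B, C) = \tfrac12\bigl[(B \otimes C) + 1 - (B \odot C)\bigr], $$

with $B \otimes C = \max_\ell \min(B_\ell, C_\ell)$ and
$B \odot C = \min_\ell \max(B_\ell, C_\ell)$; $\sigma$ is symmetric, lies in
[0, 1], and the weight group with maximal $\sigma$ is selected (ties broken
by the fixed order chi-square, RIDIT, AHP, with a message). All internal
arithmetic is in proportions; percentages appear only in printed output.

### Random-forest stage

The forest classifies the 5-class outcome level from the factors' levels —
the 5-class target mirrors the five-level risk maps this analysis style
produces. Defaults are maximum depth 5, at least 10 cases in a node to
split, at least 5 per terminal node, and a 663/1097 training fraction with a
stratified, largest-remainder split so all five classes stay represented in
both folds. The number of trees is not part of the published design; the
default is 100 for stable impurity importances (a single-tree mode is one
configuration away). Tree growing is delegated to `ranger` (Gini split rule,
impurity importance, fixed seed, one thread); importances are normalized to
sum 1 and the ranking breaks ties alphabetically. Prediction seeds the vote
tie-break RNG, so reports are reproducible end to end.

## The synthetic generator

The generator emulates a GBD-style extract: long records (country, year,
variable, deaths, population). Each country has a latent severity
$z \sim N(0,1)$; log-rates are

$$ \log \mathrm{rate}_{v,it} = \beta_v + e_v z_i + \varepsilon_{v,it}, $$

with per-variable baselines $\beta_v \sim N(\log 10^{-4}, 0.5)$ (crude rates
of order 10 per 100,000, a realistic all-cause-attributable magnitude),
$e_v$ the planted effect (1.0 for the five informative factors by default, 0
otherwise, 1 for the outcome), and noise sd 0.5 (between-year variation of
the same order as between-variable baseline spread). Populations are
lognormal around $10^7$; deaths are `round(rate × population)`, so the
ingested rates recover the latent rates up to rounding. Three random
country-year units are deleted so the default design reproduces the
1097-observation panel.

What this emulates: monotone factor–outcome association through a shared
latent factor, heavy-tailed rates, and balanced quintile marginals. What it
does **not** emulate: real GBD marginals per country, temporal
autocorrelation, age structure, or correlated factor blocks. Passing the
parameter-recovery tests therefore shows the pipeline detects monotone
associations at realistic noise — not that it reproduces any particular
published ranking on real data.

## Problem sizes and numerical choices

The test suite runs the full default design (1097 × 30) for the
parameter-recovery and null-calibration checks, 20 seeds each — chosen as
the smallest replication at which a 90% recovery criterion is meaningful —
and small instances (5–500 observations, 2–9 criteria) elsewhere; the whole
suite completes in well under a minute on one CPU, and one full pipeline run
takes about two seconds. Weight vectors are validated to sum to 1 within
1e-9; membership reconstruction from printed percentage tables compares
entries with a 1e-9 tolerance after dividing by 100; zero expected cells
contribute 0 to the chi-square; all-zero weight vectors are errors, not
silent uniforms.

## Known limitations

- The rate-share observed-table construction and the membership-matrix
  definition are the package's own operationalizations of under-specified
  conventions in the applied literature; both are documented above, reduce
  to the expected degenerate cases, and are decoupled from the
  digit-level reproduction tests of the downstream arithmetic.
- AHP random indices beyond $n = 15$ are extrapolated.
- The RIDIT stage shares the outcome's *pooled* reference distribution
  across factors; multi-reference RIDIT comparisons are out of scope.
- No spatial or temporal modelling: observations are exchangeable units.
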