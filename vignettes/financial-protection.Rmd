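---
title: "Measuring financial protection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring financial protection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finprot)
```

# The problem

Out-of-pocket (OOP) payments at the point of health care use are the least
protective way to finance a health system: they arrive unpredictably, scale
with sickness rather than ability to pay, and can be large relative to a
household's budget. Two complementary summaries are standard. The
*catastrophic payment* measures ask how many households devote more than a
threshold share of their resources to health care, and by how much. The
*impoverishment* measures ask how many people an expenditure-based poverty
count misses because the money they spent on health care was unavailable
for everything else. `finprot` implements both, plus the quintile
descriptives that usually accompany them, for household-level survey data
such as Mongolia's Household Socio-Economic Survey (HSES).

# Catastrophic payment measures

For household $i$ with OOP payments $T_i$, total expenditure $x_i$ and
capacity to pay $nf(x_i) = x_i - \text{food}_i$, the budget share is
$T_i/x_i$ or $T_i/nf(x_i)$, and the household is catastrophic at threshold
$z$ when the share *strictly* exceeds $z$ ($E_i = 1$). Then

$$H = \frac{1}{N}\sum_i E_i, \qquad
  O_i = E_i\left(\frac{T_i}{x_i} - z\right), \qquad
  O = \frac{1}{N}\sum_i O_i, \qquad MPO = O/H.$$

$H$ is incidence, $O$ intensity, and $MPO$ the average excess among the
exceeders. All three treat rich and poor exceeders identically, so the
package also computes concentration indices of $E_i$ and $O_i$,

$$C = \frac{2\,\mathrm{cov}_w(y, r)}{\mu},$$

with $r$ the weighted fractional rank of the living-standard variable and
$\mu$ the weighted outcome mean, and the rank-weighted variants
$H^w = H(1 - C_E)$ and $O^w = O(1 - C_O)$. These are equivalent to
reweighting household $i$ by $2(1 - r_i)$ — weight 2 for the poorest
declining to 0 for the richest — and the package's tests assert that
equivalence directly (to $10^{-10}$) rather than trusting the closed form.

Conventions worth spelling out:

- **Strict exceedance.** A household exactly at the threshold is not
  catastrophic. With continuous expenditure data the boundary carries no
  mass; the choice only matters for constructed examples, and it is
  tested.
- **Ranking variable.** $C_E$ and $C_O$ are ranked by the same
  living-standard measure used as the share denominator (total expenditure
  for $T/x$, capacity to pay for $T/nf(x)$), at the household level,
  unadjusted for size. Nothing in the estimator forces that pairing — it
  is the internally consistent default, and `catastrophic_measures()`
  accepts a `rank_by` override.
- **Fractional ranks and ties.** Ranks are
  $r_i = (\text{cum. weight below} + w_i/2)/W$ after a stable ascending
  sort, so ties are resolved by input order deterministically;
  `tie_rank = "average"` assigns tie groups their midpoint rank instead.
  Expenditure is effectively continuous, so the two differ only on
  degenerate inputs.
- **Degenerate denominators.** A household with zero capacity to pay and
  zero OOP has share 0. Validation enforces $T \le x$ and
  $\text{food} \le x$ but cannot rule out $T > nf(x)$; such shares are
  clamped at 1 with a warning (a budget share above 1 is not
  interpretable). Clamping is silent within $10^{-9}$ relative of 1,
  where the only plausible cause is floating-point noise, e.g. a CSV
  round trip of a household capped exactly at its capacity.
- **$H = 0$.** The MPO is then $0/0$ and is reported as undefined
  (`mpo_defined = FALSE`), never as 0.
- **Weights.** The default counts every household once, matching the
  $1/N$ estimators above; `weights_mode = "sampling"` switches every sum
  to $\sum w_i \cdot (\cdot) / \sum w_i$. No survey-design variance
  estimation is attempted — weights affect point estimates only.

# Impoverishment measures

Poverty is measured on *per-capita* household expenditure
$y_i = x_i/s_i$ (raw household size, no adult-equivalence scale), gross
and net of health payments, against a per-person poverty line $PL$:

$$HP = \frac{\sum_i s_i p_i}{\sum_i s_i}, \qquad
  g_i = p_i (PL - y_i), \qquad
  G = \frac{\sum_i s_i g_i}{\sum_i s_i},$$

with $p_i = 1$ when $y_i < PL$ (strict: a person exactly at the line is
not poor). The net basis uses $y_i^{net} = (x_i - T_i)/s_i$, spreading
household OOP evenly over members — the standard construction when only
household-level OOP is observed. $NG = G/PL$ frees the gap from currency
units; $NMPG = NG/HP$ is the average shortfall among the poor. The
impoverishing effect of health payments is the net-minus-gross change in
each measure; since subtracting OOP can only lower expenditure, the net
measures dominate the gross ones, a property the test suite asserts on
random surveys.

Note the deliberate asymmetry, inherited from the estimators' standard
forms: catastrophic measures are household-weighted ($1/N$), poverty
measures person-weighted ($s_i$, times the sampling weight when enabled).
The person-weighted estimator is tested for exact equality against an
oracle that expands each household into $s_i$ identical individuals.

Two lines ship as presets for the Mongolian 2012 setting: the national
line (118,668 MNT per person per month) and the World Bank \$1.90/day
(2011 PPP) line, 34,769.6 MNT per month at 2012 prices. The MNT value of
the PPP line is taken as given — no days-per-month convention reproduces
it exactly from the dollar figure, and the package performs no PPP or
inflation adjustment of its own: poverty lines must be supplied in the
units and period of the expenditure data. By the same logic, net per-capita
expenditure is floored at zero only behind an explicit
`floor_net_at_zero` flag; under default validation ($T \le x$) negatives
cannot occur, and the flag exists only for permissive policies.

# Survey ingestion

`read_survey()` maps arbitrary CSV columns onto the canonical fields,
optionally rescaling a column at load time (`multiplier`), because
surveys mix recall periods (outpatient use in the past month, inpatient in
the past year) and harmonization is the caller's decision, not something
the reader can infer. Validation policies: `strict` errors on the first
violated rule; `drop` removes offending rows; `clamp` repairs what can be
repaired (negatives to 0, food and OOP capped at total, size floored at
1) and drops what cannot (non-positive totals or weights). Every drop and
clamp is tallied per rule in a retrievable load report, so a cleaned
analysis is still auditable.

# The synthetic generator

`generate_survey()` draws, from a single seeded stream in a documented
order (household size, per-capita expenditure, zero-OOP indicator, OOP
noise, urban stratum, service-use indicators):

- size $\sim 1 + \text{Poisson}(\bar{s} - 1)$;
- per-capita expenditure $\sim$ log-normal — the right skew every
  expenditure survey shows;
- food share $= \text{clamp}(a - b\,\log y_i,\ 0.05,\ 0.95)$, an Engel
  curve: poorer households devote a larger budget share to food (the
  share is deterministic given expenditure; the model carries no food
  noise term);
- OOP $= 0$ with probability $p_0$, else
  $\min(\lambda\, x_i^{\eta}\,\varepsilon_i \cdot m_{urban},\ x_i - \text{food}_i)$
  with mean-one log-normal noise $\varepsilon_i$. The cap at *non-food*
  expenditure (not just total) keeps both share denominators coherent, so
  every generated dataset passes strict validation by construction;
- utilization indicators with a logistic expenditure gradient.

An elasticity $\eta > 1$ makes OOP rise faster than expenditure, which is
what concentrates the catastrophic burden among the better-off (positive
$C_E$) and produces the steep richest-to-poorest OOP ratio observed in
the Mongolian data.

The `hses2012_like()` preset fixes these parameters, once, from the
published headline structure of HSES 2012: MNT-per-month units; log-normal
parameters (12.22, 0.70) chosen so the national poverty line sits near the
22% person-weighted quantile of per-capita expenditure; mean size 3.6;
Engel parameters (1.60, 0.10) giving food shares around 0.25–0.5;
$p_0 = 0.35$; $\eta = 1.15$ and $\lambda = 4.6\times10^{-3}$ jointly
matching a catastrophic head count near 5.5% at the 10%-of-total
threshold, a mean OOP near 25,000 MNT, a mildly pro-rich $C_E \approx
0.1$ and a roughly tenfold Q5/Q1 OOP gradient; 60% urban with a 1.3×
urban OOP multiplier. These are calibrations of a generating *process* to
published aggregates — the synthetic data share the real survey's broad
structure, not its microdata. In particular the generator draws
households independently (no stratified three-level sampling design, no
regional price variation, no item-level consumption structure), per-capita
expenditure is independent of household size, and OOP depends on
expenditure only through the elasticity — real OOP also depends on
illness shocks, insurance status and supply. Tests passing on synthetic
data therefore validate the *estimators* and their invariants, not any
substantive claim about Mongolia.

`generate_calibrated()` rescales $\lambda$ by bisection (same seed, so the
realized head count is a deterministic non-decreasing function of the
scale) until the head count at a chosen threshold hits a target within
tolerance, expanding the bracket upward first and failing loudly if the
target is unreachable (the head count saturates at the share of
households with positive OOP above the threshold cap).

# Numerical and testing choices

Rounding happens only at render time (`render_*(format = "text")`); the
data-frame and JSON outputs keep full precision, because identities like
$H^w = H(1 - C_E)$ and $NMPG \cdot HP = NG$ do not survive printed
rounding. The test suite checks the concentration index against a naive
$O(N^2)$ definitional double sum on datasets up to $N = 200$, the
rank-weighted closed forms against direct weighted sums to $10^{-10}$,
monotonicity of $H$ and $O$ in $z$, poverty dominance and line
monotonicity, and generator parameter recovery (the zero-OOP share at
$n = 50{,}000$ against a binomial confidence interval; preset calibration
at $n = 20{,}000$). These problem sizes keep the full suite to a few
seconds while leaving the $N^2$ oracle non-trivial.

# Limitations

No standard errors or confidence intervals are produced for $H$, $O$, the
concentration indices or the poverty measures; no decomposition of the
concentration index into contributors; no poverty-severity (squared-gap)
measures; no imputation of missing expenditure components. The chi-square
test attached to the utilization table is a Pearson independence test,
labelled as such — the appropriate test for survey-design-weighted
proportions would differ.
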