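---
title: "Online FDR control in group-sequential platform trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online FDR control in group-sequential platform trials: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gslond)
```

## The problem

In a platform trial, treatment arms enter (and leave) over the trial's
lifetime and are each compared against a shared control arm. The number of
hypotheses is not fixed in advance, and decisions must be taken as the data
arrive, without knowledge of future arms. Classical multiplicity adjustments
(Bonferroni, Benjamini-Hochberg) need the full set of p-values at once, so
they do not apply. *Online* FDR control replaces them: hypotheses
$H_1, H_2, \dots$ are tested in a prespecified order (here: order of entry
into the platform), the level $\alpha_i$ for $H_i$ may depend only on the
decisions for $H_1,\dots,H_{i-1}$, and after every decision the FDR

$$\mathrm{FDR}_i \;=\; \mathrm E\!\left[\frac{V(i)}{\max\left(\sum_{j\le i} R_j,\,1\right)}\right] \;\le\; \alpha$$

is controlled, where $R_j$ is the rejection indicator and $V(i)$ the number
of false rejections so far.

## The LOND procedure and its budgets

LOND ("significance Levels based On Number of Discoveries") fixes, before
the trial, non-negative budgets $\beta_i$ with $\sum_i \beta_i \le \alpha$,
and tests $H_i$ at

$$\alpha_i = \beta_i\Big(\textstyle\sum_{j<i} R_j + 1\Big).$$

Each discovery inflates all later levels. The *updated* variant
$\alpha_i = \beta_i \max(\sum_{j<i} R_j, 1)$ is the one with a proof of FDR
control under positive dependence (PRDS), which is the relevant regime here
because all arms share the control data; both are implemented
(`lond_level()`, `lond_level_updated()`, `lond()`).

Budget sequences (`beta_sequence()`):

* **descending**: $\beta_j = C\,\alpha\,\log(\max(j,2)) / (j\,e^{\sqrt{\log j}})$
  with $C = 0.07720838$ by default. This is the conventional published
  constant. It is *not* the exact normalizer of the series: the infinite sum
  of the unnormalized terms is 12.6451079 (partial sum to $10^6$ terms plus
  the analytic incomplete-gamma tail
  $2\,\Gamma(4,\sqrt{\log J})$; the series converges so slowly that the
  first million terms cover only about half of the total, so naive
  truncation is useless). The exact normalizer is therefore
  $1/12.6451 = 0.0790820$, computed by `lond_constant()`. With the
  conventional constant, $\sum_i\beta_i \approx 0.976\,\alpha$ — slightly
  conservative, and it reproduces the reference values
  $\beta_1 = 0.00134$, $\beta_2 = 0.00029$ at $\alpha = 0.025$. We keep the
  conventional constant as the default for comparability and expose the
  exact one for users who prefer self-consistency.
* **descending_truncated**: an a-priori bound $N$ on the number of
  hypotheses allows rescaling so that $\sum_{i\le N}\beta_i = \alpha$
  exactly. The rescale factor is $\alpha/\sum_{j\le N}\beta_j \ge 1$, so
  every budget grows; at $\alpha=0.025$, $N=1000$:
  $\beta_1' = 0.00446$, $\beta_2' = 0.00097$, $\beta_3' = 0.00083$.
  Choosing $N$ is the single most powerful design lever: the smaller $N$
  (down to the true number of arms $K$), the larger the budgets and the
  power.
* **equal**: $\beta_i = \alpha/N$ — best when alternatives arrive late,
  since the descending sequence starves late hypotheses.
* **dependent_adjusted**: $\beta_i / H_i$ with $H_i$ the harmonic number;
  gives FDR control under arbitrary dependence, at a substantial
  conservatism cost. Not used in the simulations, provided for completeness.

## Group-sequential testing and alpha spending

Each arm gets one interim analysis at information fraction $t_1$ (treatment
stage sizes $n^{(1)}, n^{(2)}$; default $t_1 = 0.5$), with early rejection
(efficacy) or a non-binding futility stop. The level $\alpha_i$ is split over
the two analyses by a Lan-DeMets spending function, either

* approximate O'Brien-Fleming:
  $\alpha^{OBF}(t) = 2\big(1-\Phi(\Phi^{-1}(1-\alpha_i/2)/\sqrt t)\big)$ —
  spends almost nothing early; or
* approximate Pocock: $\alpha^{PO}(t) = \alpha_i \ln(1 + (e-1)t)$ —
  spends roughly evenly.

The interim threshold on the one-sided p-value scale is
$a_1 = \mathrm{spend}(t_1, \alpha_i)$; the final threshold $a_2$ solves

$$P\big(p^{(1)} \le a_1\big) + P\big(p^{(1)} > a_1,\ p \le a_2\big) = \alpha_i$$

under the bivariate normal law of the interim and pooled-data final
z-statistics with correlation $\sqrt{t_1}$ (proportional per-stage
allocation; for pooled NCC+CC control sets the same boundaries are reused,
a deliberate conservative simplification since the actual correlation is
slightly different). The bivariate probabilities use `mvtnorm`'s
deterministic Miwa algorithm (absolute accuracy well below $10^{-9}$ in two
dimensions) and the root is found by `uniroot` to $10^{-12}$; boundaries are
cached by (spending, level, $t_1$), which matters in simulations where the
same handful of levels recurs thousands of times. At the default
$t_1 = 0.5$ and level $0.05/3$ the PO design gives $(a_1, a_2) =
(0.0103, 0.0089)$ and OBF gives $(0.0007, 0.0164)$ — the familiar pattern
that OBF defers its spending to the final analysis. Non-binding futility:
the efficacy boundaries ignore the futility bound, so stopping for futility
only makes the procedures more conservative.

## The group-sequential LOND variants

With overlapping arms, the rejection count relevant for $H_i$ can change
between its interim and final analysis. Writing "decided before" for a
strictly earlier event in the trial chronology:

* **gsLOND** counts rejections among earlier-entering hypotheses ($j < i$)
  decided before the current analysis, and rebuilds the full two-stage plan
  at the (possibly increased) level with the original spending function.
  Note the interim threshold actually used is never revisited.
* **gsLOND.II** addresses the level that gsLOND leaves on the table: if the
  level rose from $\alpha_i^{I(1)}$ to $\alpha_i^{I(2)}$ after the interim,
  the whole increment $\alpha_i^{I(2)} - a_1(\alpha_i^{I(1)})$ is allocated
  to the final analysis (`exhaust_increment_boundary()`), abandoning the
  spending-function shape but exhausting the level exactly. In the worked
  example this raises a final boundary from 0.0190 to 0.0279.
* **gsLOND.III** extends the counted set to later-entering hypotheses
  ($j \ne i$) already decided — heuristic, since it breaks the "past
  decisions only" requirement of the online framework, which is why it has
  no formal FDR guarantee; boundaries are recomputed with the original
  spending function.
* **gsLOND.II.III** combines both. The composition implemented (fixed by
  reproducing all cells of the worked example's outcome tables): the
  increment-exhaustion step is triggered *only* by an increase of the
  $j<i$ count after the interim; the exhausted target level is the
  all-hypotheses ($j \ne i$) level at the final analysis; and the stage-1
  spend subtracted is the interim boundary actually used. An increase
  caused only by a later-entering rejection recomputes the plan as in
  gsLOND.III.

The scheduler (`run_schedule()`) is event-driven: it consumes a strictly
totally ordered stream of interim/final events and forbids ties — the
simulator resolves simultaneous analyses by arm index (the predefined order
of entry, so the resolution is data-independent) and emits event ranks as
timestamps. "Decided before" always means strictly earlier in that order.
Decisions are never revisited; a futility-stopped arm contributes a
permanent $R_j = 0$. Comparators: the unadjusted level-$\alpha$ test and a
best-case Bonferroni ($\alpha/K$ with the true $K$), both with constant
levels.

## The platform-trial simulator

`sim_scenario()` / `run_replicates()` emulate the reference study design:
control patients accrue continuously (the control index is the time scale);
arm $i$ opens after $(i-1)\,n_\Delta$ controls; allocation is
1:1:$\cdots$:1 across control and open arms, so an arm's $k$-th patient
arrives with the $k$-th control after its opening; interim after
$n^{(1)}$ of its $n$ patients. Outcomes are $N(\Delta, 1)$ for alternative
arms, $N(0,1)$ otherwise; tests are one-sided pooled-variance two-sample
t-tests (consistent with the equal-variance generative model; p-values
computed in closed form and cross-checked against `t.test`). Control sets:
concurrent-only (CC; equal sizes by construction) or all controls so far
(NCC+CC). Defaults are the study conditions: $K=10$, $n=50$ split 25/25,
$n_\Delta = 20$, $\Delta = 0.6$, $\alpha = 0.025$ one-sided,
futility at 0.5, OBF spending, truncated descending budgets with $N = 100$,
NCC+CC controls, 5000 replicates.

Truth orderings: `random` (each arm null with probability $\pi_0$, so the
alternative count varies by replicate — power then averages over replicates
with at least one alternative), `alternatives_first`, `alternatives_last`
(blocks of $\mathrm{round}(K(1-\pi_0))$).

Replicate $r$ is seeded `seed + r`, and all randomness is drawn before any
analysis, so scenarios differing only in analysis settings (spending, N,
control set, variant) are paired by common random numbers — the paired
differences are what the qualitative-ordering tests use.

**Saved sample size** is reported as the percentage of the fixed-sample
design's total treatment sample size ($K\,n$) saved by interim stops (each
stop saves $n^{(2)}$). Under the global null with futility bound 0.5 the
interim-stop probability is almost exactly one half, giving the reference
headline of about 25% with equal stages. (Relative to the stage-2 maximum
$K\,n^{(2)}$ alone the same quantity would read ~50%; the total-sample
denominator is the one consistent with the reference value.)

**Budget mode** (`run_budget_mode()`) fixes the treatment budget at $K_0 n$:
an interim stop frees $n^{(2)}$ observations, and as soon as a whole arm's
worth is free a new arm opens immediately at the current control index,
entering the hypothesis stream with the next index. Added-arm truths follow
four scenarios (constant $\pi_0$/$\Delta$; effects drawn from
$\{0.4, 0.8, 1.2\}$; $\pi_0$ decreasing by $1/80$ per added arm, floored at
0; added alternatives with $\Delta = 1$). Arm additions are gated on the
treatment budget only — the pre-planned control accrual is unchanged — and
the invariant "treatment observations consumed $\le K_0 n$" holds per
replicate. The headline metric is the total number of rejected
alternatives.

What the simulator does *not* emulate: time trends in the control outcomes
(the main practical risk of NCC controls), binary or time-to-event
endpoints, delayed outcomes, response-adaptive allocation, and more than one
interim per arm. Passing operating-characteristic tests therefore speaks to
the procedures under a stable, normally distributed platform, not to
robustness against drift.

## Numerical and testing choices

* Boundary root-finding: bisection via `uniroot` on $(10^{-12}, \alpha_i)$,
  probability tolerance $10^{-12}$; plans exhaust their level to $10^{-6}$
  verified both analytically and against a $10^7$-draw Monte-Carlo oracle.
* p-values equal to a boundary reject (ties at machine precision follow the
  same $\le$ rule).
* The worked three-hypothesis example uses the exact equal split
  $\beta_i = 0.05/3$; printed reference tables round it to 0.0167, which is
  why a reproduced LOND level can read 0.0333 against a printed 0.0334 —
  table comparisons use an absolute $10^{-4}$ tolerance.
* Operating-characteristic problem sizes: the headline saved-sample-size
  run uses 5000 replicates (script) / 2500 (test suite); the FDR grid uses
  2000 replicates per cell over $\pi_0 \in \{0.2, 0.6, 1\}$, four
  procedures and both control sets; qualitative power orderings use 1200
  paired replicates per setting. FDR checks allow three Monte-Carlo
  standard errors above $\alpha$; ordering checks require the paired mean
  difference to exceed $-3$ standard errors of the difference.

## Worked example

```{r}
reproduce_table1()
```

```{r}
# boundaries for the middle hypothesis under all outcomes of its neighbours
reproduce_table2()
```

```{r, eval = FALSE}
# operating characteristics under the global null (about 15 s at 5000 reps)
sc <- sim_scenario(pi0 = 1, n_reps = 5000, seed = 11)
run_replicates(sc)
#> Platform-trial simulation: gsLOND, 5000 replicates
#>   fdr                      0.0122  (MC-SE 0.0016)
#>   saved_pct               24.9110  (MC-SE 0.1489)
```

## Known limitations

* gsLOND, gsLOND.II and gsLOND.III are heuristics; formal online FDR
  control is available for the fixed-sample (updated) LOND under PRDS and
  empirically supported for the group-sequential variants by the
  simulation suite here.
* The boundary correlation $\sqrt{t_1}$ is exact for CC controls with
  proportional allocation and an approximation (conservative in the cases
  examined) for NCC+CC.
* One interim per arm, a common endpoint and equal per-arm sample sizes are
  assumed throughout; the predefined hypothesis order must be
  data-independent for the online guarantee to be meaningful.
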