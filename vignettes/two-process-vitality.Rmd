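---
title: "The two-process vitality model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-process vitality model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the model it fits, the
numerical choices behind the implementation, and what the synthetic-data
based tests do and do not establish.

## The model

Vitality is a dimensionless, abstract survival capacity, normalized to 1 at
the clock origin. Two processes end a life:

* **Intrinsic (chronic) mortality.** Vitality follows a Wiener process with
  drift $-r$ and diffusion $s$; absorption at 0 is intrinsic death. The
  first-passage time is inverse-Gaussian, giving intrinsic survival
  $$l^i(x) = \Phi\!\Big(\frac{1-rx}{s\sqrt{x}}\Big) -
    e^{2r/s^2}\,\Phi\!\Big(-\frac{1+rx}{s\sqrt{x}}\Big).$$
* **Extrinsic (acute) mortality.** Challenges arrive in a Poisson stream of
  frequency $\lambda$ with magnitudes exponential with mean $\beta$
  (fractions of initial vitality); a challenge at or above current vitality
  kills. With vitality approximated by its deterministic path $1-rx$, the
  hazard is the Strehler–Mildvan form
  $\mu_e(x)=\lambda e^{-(1-rx)/\beta}$ and extrinsic survival its
  integrated exponential,
  $$l^e(x)=\exp\!\Big(-\tfrac{\lambda\beta}{r}e^{-1/\beta}
    \big(e^{rx/\beta}-1\big)\Big).$$

Total survival is the product $l = l^i\, l^e$. The four parameters and
their units:

| parameter | meaning | units | typical human-cohort scale |
|---|---|---|---|
| $r$ | mean rate of vitality loss | 1/year | ~0.013 |
| $s$ | variability of vitality loss | year$^{-1/2}$ | ~0.013 |
| $\lambda$ | extrinsic challenge frequency | 1/year | ~0.045 |
| $\beta$ | mean challenge magnitude | fraction of initial vitality | ~0.4 |

The reference set used throughout the package's tests and acceptance run is
$(r,s,\lambda,\beta) = (0.0135, 0.0126, 0.0449, 0.3999)$.

**The product form is an approximation.** In the full model challenges act
on each individual's *stochastic* vitality, so the two processes interact:
extrinsic deaths cull low-vitality individuals, and survivors near the mean
passage age $1/r$ have strictly positive vitality where the deterministic
path has none. The closed form is nevertheless what is fitted to data —
that is the point of the approximation — and the resulting parameter bias
is removed afterwards by simulation-based calibration (below). Evaluated
against the individual-based simulator at the reference parameters, the
closed-form total survival curve differs by up to ~0.026 in survival
proportion, peaking near age $1/r \approx 74$; the difference is stable
under step-size halving, i.e. it is approximation error, not simulation
error. Past $x = 1/r$ the deterministic vitality goes negative; the closed
form is evaluated as written there (it stays finite and integrable), which
is a documented model caveat rather than a numerical defect.

## Age origin and truncation

The model clock starts wherever vitality is normalized to 1. Data truncated
at an entry age (age 10 for the twin cohorts, where childhood mortality is
excluded by design) can be handled under two conventions, both supported:

* **conditioning** — the clock starts at birth and the fitted probabilities
  are $S(x)/S(x_0)$ (`surv_conditional()`; used whenever the first interval
  break is positive), or
* **re-anchoring** — the clock restarts at the truncation age with vitality
  1 (pass ages as `x - x0` with breaks from 0).

The analysis scripts use conditioning: the synthetic twin study is
simulated from birth, pairs where either member dies by 10 are dropped
(matching how a registry without childhood deaths is assembled), and the
likelihood conditions on survival to 10, so the generating and fitted
parameters share one clock.

## The individual-based simulator

`simulate_cohort()` advances each individual on an Euler grid of step `dt`
(default 0.05 years) with a fixed within-step order: diffusion update;
intrinsic-death check; challenge draws against the updated vitality. Two
details matter for accuracy and reproducibility:

* **Brownian-bridge crossing correction.** A step ending above the boundary
  may still have dipped below it in between; the crossing probability
  $\exp(-2 v_{\text{old}} v_{\text{new}} / (s^2 dt))$ is applied each step.
  Without it the Euler scheme overstates intrinsic survival by
  $O(\sqrt{dt})$; with it the intrinsic-only empirical curve matches the
  exact inverse-Gaussian survival to ~0.002 sup-norm at $n = 10^5$
  (Monte-Carlo noise), and halving `dt` moves the full-model curve by less
  than that noise.
* **RNG discipline.** One R RNG stream per cohort with a fixed iteration
  order (the C++ core draws through R's generator), so `set.seed()` gives
  bit-identical cohorts. Per-individual substreams were considered and
  rejected: R has no native substream API, and a single stream already
  delivers the reproducibility guarantee the design needs.

Challenge counts per step are Poisson($\lambda\,dt$) with per-challenge
exponential magnitudes — exact for the process and robust to coarser steps.
Survivors at the horizon (default 120 years on the model clock) are
recorded as censored, never dropped; they carry likelihood mass in the
open-ended interval.

## The synthetic twin study

`twin_study_config()` fixes the study conditions the generator emulates: a
late-19th-century national twin cohort. Group sizes follow the registry's
scale — about 1,050 monozygotic and 1,880 like-sex dizygotic pairs split
evenly by sex — with 10,000 per sex for the general population at desk
scale. Group parameters vary around the reference set: females face ~20%
fewer challenges than males (a known sex differential in risk exposure),
twins face smaller challenge magnitudes than the general population (DZ 10%
smaller, MZ a further 10%), and MZ males lose vitality ~10% more slowly.
These are plausible stand-ins chosen once to mirror the qualitative group
differences this framework is used to detect — **not** estimates from any
restricted registry data.

What the generator deliberately does *not* emulate: shared frailty or
genetically correlated co-twin lifespans (pair members are independent;
the tests verify within-pair correlation ~0), childhood mortality
(irrelevant past the age-10 entry), period shocks (wars, epidemics), and
cohort heterogeneity beyond the four parameters. Passing tests therefore
show that the pipeline recovers parameters from data generated by its own
model family under realistic sizes and censoring — not that real twin data
satisfy the model.

## Likelihood and fitting

With $S$ the (conditional) model survival, interval probabilities are
$p_j = S(b_j) - S(b_{j+1})$ and $p_{\text{last}} = S(b_K)$; the
log-likelihood is multinomial,
$\ell = \sum_j d_j \log p_j + n_{\text{surv}} \log p_{\text{last}}$, where
$n_{\text{surv}}$ pools open-ended-interval deaths with horizon-censored
individuals (both are known only to outlive the last break). Cells are
floored at $10^{-300}$ before the log so a zero cell cannot derail a line
search, while invalid parameters raise an error rather than $-\infty$.

`fit_vitality()` optimizes in log-parameter space (positivity for free, and
it tames the scale gap between $r \sim 0.01$ and $\beta \sim 0.4$):
Nelder-Mead at relative tolerance $10^{-8}$ on $\ell$, polished by
L-BFGS-B within a wide box. The data-driven start is
$r_0 = 1/(\text{median time from entry to death} + 1)$, $s_0 = r_0$,
$\lambda_0$ the crude death rate over the first tenth of the intervals and
$\beta_0 = 0.3$; a deterministic multi-start (x3 and /3 perturbations,
including intrinsic-vs-extrinsic swaps) guards against local optima. A fit
ending at the box boundary is flagged and reported unconverged — degenerate
data (e.g. all deaths in one interval) surface this way instead of
returning a silent bad fit.

The variance matrix is the inverse negative Hessian of $\ell$ at the
optimum, by central finite differences with per-parameter relative steps
($10^{-4}$), symmetrized; a non-positive-definite case falls back to the
eigenvalue pseudo-inverse and is flagged. Standard errors scale as
$1/\sqrt{n_{\text{entry}}}$ — which is why fits should be given the true
cohort size, not the life-table radix (`cohort_to_intervals(actual_n = )`).

## Bias correction

The closed form's estimates are systematically off relative to the full
interacting model: low for $r$ and $\beta$, high for $s$ and $\lambda$
(measured at the reference set, $n = 10^4$: roughly $-3\%$, $-3\%$, $+9\%$,
$+7\%$ respectively). Published polynomial correction formulas exist for
this model family but are not reproduced here; instead `bias_correct()`
calibrates against the package's own simulator, which reproduces the
documented intent (correction formulas "based on simulation with a
numerical form of the model") without guessing coefficients, and accepts
externally supplied formulas through the `formulas` hook.

Calibration seeks $\theta^*$ such that the mean closed-form estimate over
$B$ simulated cohorts generated at $\theta^*$ — same entry size, truncation
and binning as the data — equals the raw estimate. Numerical choices:

* $B = 50$ cohorts per round by default; per-parameter calibration noise
  (SE of the simulated mean) is then well under 2%.
* The multiplicative fixed-point step is damped with exponent 0.7: the mean
  estimate responds more than proportionally to the generating parameters
  (cross-coupling between the intrinsic and extrinsic blocks), so the
  undamped step over-corrects by roughly half and oscillates.
* Convergence requires the residual mismatch to fall below
  $\max(2\%, 2\,\text{SE})$ per parameter — tighter would chase Monte-Carlo
  noise — within 5 rounds; typically 2–3 suffice. Non-convergence returns
  the raw estimates, flagged and warned, never a half-corrected vector.
* Replicate fits inside calibration start at the generating parameters
  (single start): the optimum being sought is known to be nearby, and the
  full multi-start would only burn time.

## Subsample validation

`bootstrap_validation()` refits random 75% subsets of a twin group,
drawing whole twin pairs without replacement — subsampling, not a classical
bootstrap, and the pair is the sampling unit because co-twins enter the
data jointly. Unconverged replicates are excluded and counted, never
imputed. One deliberate economy: the full-sample calibration factors are
applied to every replicate's raw estimate instead of re-running the
simulation-based calibration inside each replicate. With closed-form
correction formulas the per-replicate correction would be free; re-running
a 50-cohort calibration 1,000 times is not, and the factors vary smoothly
in the parameters while replicates are 75% subsamples of one dataset, so
the factor is locally constant. The general population is not resampled:
it has no pair structure.

## Problem sizes in the tests

The test suite exercises the pipeline at sizes chosen to keep Monte-Carlo
noise well below the asserted tolerances while remaining desk-scale: the
simulator-vs-closed-form comparison at $n = 10^5$; parameter recovery as
five replicate studies of $n = 10^4$ with $B = 50$ calibration; the
standard-error coverage check over 60 cohorts of $n = 5{,}000$; the
subsample validation on a ~1,050-pair synthetic twin group with 50
replicates. All stochastic tests run under fixed seeds.

## Known limitations

* The closed form's deterministic-vitality approximation is the model's
  acknowledged weak point around and past $x = 1/r$; the calibration
  corrects the *parameters*, not the fitted curve's shape there.
* $\lambda$ and $\beta$ are weakly identified in cohorts of a few thousand:
  their sampling noise (5–10%) is of the same order as their biases, so
  bias correction improves them in expectation but not in every single
  cohort.
* Extrinsic parameters estimated from cohort data average over the periods
  the cohort lived through; the model fits them as constants.
* Heritability, shared frailty and correlated co-twin lifespans are out of
  scope throughout — the model treats each cohort marginally.
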