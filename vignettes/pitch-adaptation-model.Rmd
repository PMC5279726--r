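---
title: "A causal-inference model of vocal pitch adaptation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A causal-inference model of vocal pitch adaptation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchadapt)
```

## The behaviour being modelled

When the pitch of a vocalizer's auditory feedback is artificially shifted
— through miniature headphones on a singing bird, or earphones on a
speaking human — the vocalizer adapts its produced pitch in the direction
opposing the shift. Two robust regularities motivate this package:
compensation is *partial*, and relatively smaller for larger shifts; and
subjects with higher motor variability compensate *more*.

`pitchadapt` implements a normative account of both: the vocalizer treats
the question "was that sound me?" as Bayesian causal inference, and only
corrects errors to the extent they are credibly self-caused.

## Model

Pitch is measured in cents, $p = 1200\log_2 F - \kappa$; the reference
$\kappa$ is arbitrary and never enters any computation (all predictions
are invariant under translating the target, which is property-tested).

One vocalization ("rendition") unfolds as:

* produced pitch $p \sim N(\mu_m, \sigma_m^2)$, where the motor plan is
  the target plus a slowly learned corrective bias,
  $\mu_m = \mu^* + \epsilon$;
* pitch at the ear $p_{ear} = p + p_\Delta$ for an experimenter-imposed
  shift $p_\Delta$;
* encoded feedback $p_f \sim N(p_{ear}, \sigma_f^2)$ — the sensory system
  is itself noisy.

The perceptual stage knows $\mu_m$, $\sigma_m$, $\sigma_f$ but not $p$.
Marginalizing over the unknown production, feedback that *is* self-caused
is distributed

$$P(p_f \mid s) = N(\mu_m,\; \sigma_f^2 + \sigma_m^2),$$

while the alternative — another animal, the environment — is modelled as
uninformative, so its likelihood times its prior odds collapses into a
single constant $k$. Bayes' rule then gives the self-source posterior

$$P(s \mid p_f) = \frac{L}{L + k}, \qquad L = P(p_f \mid s).$$

If feedback were known to be self-caused, the optimal pitch estimate
would be the precision-weighted (one-step Kalman) combination
$p_{opt} = (\sigma_f^2\mu_m + \sigma_m^2 p_f)/(\sigma_f^2+\sigma_m^2)$.
Weighting by the source posterior yields the perceived deviation the
adaptive system acts on:

$$\Delta p = P(s \mid p_f)\,p_{opt} + P(e \mid p_f)\,\mu_m - \mu^*
           = \epsilon + (p_f - \mu_m)\,P(s \mid p_f)\,
             \frac{\sigma_m^2}{\sigma_f^2 + \sigma_m^2}.$$

Adaptation drives the *average* perceived deviation to zero by the
stochastic update $\epsilon \leftarrow \epsilon - \eta\langle\Delta
p\rangle_n$ over batches of $n$ renditions. The equilibrium $\epsilon$
— the corrective pitch bias — is the model's prediction for the adapted
state, summarized as percent compensation
$c = 100\,|\epsilon|/|p_\Delta|$.

## Parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `mu_target` | cents | 0 | pitch target $\mu^*$; pure reference |
| `sigma_m` | cents | 46 | motor SD; the songbird value obtained as MAD $31 \times 1.4826$ |
| `sigma_f` | cents | 23 | sensory SD; `Inf` = deaf limit |
| `k` | — | 1.5e-4 | external-source constant; larger = deviant feedback more readily ignored |
| `epsilon0` | cents | 0 | read-out offset added to $\epsilon$ after solving |
| `clamp_self` | flag | FALSE | pin $P(s \mid p_f) = 1$ (instructed subjects) |

The defaults are the best-fit regime for the songbird compensation
curve. `epsilon0` models a constant bias in how a study *measures* the
compensatory response (e.g. transient-peak read-outs); it is applied
after equilibrium solving and before the percent computation, never
inside the dynamics. `clamp_self` and `k = 0` are distinct code paths
proven equivalent by test; the clamp is the numerically safe canonical
form because $k = 0$ invites $0/0$ wherever the likelihood underflows.

## Numerical design

**Log-space posteriors.** At shifts of hundreds of cents the Gaussian
likelihood is of order $e^{-17}$ and smaller. The posterior is therefore
evaluated as $1/(1+e^{\log k - \log L})$ throughout; compensation curves
out to ±300 cents and beyond never touch a raw density.

**The deterministic solver is a single quadrature.** Because the
feedback residual $u = p_f - \mu_m \sim N(p_\Delta,
\sigma_m^2+\sigma_f^2)$ does not depend on $\epsilon$ (the motor plan
cancels), the expected deviation
$E[\Delta p] = \epsilon + w\,E[u\,P(s \mid u)]$ with
$w = \sigma_m^2/(\sigma_f^2+\sigma_m^2)$ is *exactly linear in
$\epsilon$ with unit slope*. Its root needs no iteration:
$\epsilon^* = -w\,E[u\,P(s \mid u)]$, one Gauss–Hermite quadrature
(80 nodes; the integrand is the Gaussian weight times a smooth logistic
factor, for which Gauss–Hermite is accurate to near machine precision —
cross-checked against adaptive quadrature at `rel.tol = 1e-12` in the
test suite). A bracket check ($|\epsilon| \le |p_\Delta| + 4\sigma_m$)
guards the result. This also makes curve prediction and fitting cheap:
a full random-search fit costs a few thousand quadratures.

In the same coordinates the stochastic solver draws each batch of
residuals $u$ directly from $N(p_\Delta, \sigma_m^2+\sigma_f^2)$ —
distributionally identical to drawing $p$ and then $p_f$, and one
`rnorm` cheaper.

**Convergence and honest uncertainty.** The stochastic iteration uses a
trailing window of 50 batches and declares convergence when consecutive
window means differ by under 0.05 cents, with a budget of 5,000 batches
(all configurable); the reported $\epsilon$ is the trailing-window mean,
and exhausting the budget flags `converged = FALSE` rather than failing
silently. Because the iteration relaxes toward the fixed point at rate
$\eta$ per batch, stopping on a window-mean change of $D$ leaves a
predictable residual drift of $D/\mathrm{expm1}(\eta W)$ (geometric
extrapolation) — up to about a cent at the defaults. The result's `se`
combines this drift estimate with autocorrelation-corrected sampling
noise of the window, so "stochastic agrees with deterministic within
3 `se`" is a fair, property-tested statement rather than an
underestimate that ignores early stopping.

**Deaf limit.** `sigma_f = Inf` is an exact sentinel: the feedback
weight $w$ is identically 0, the posterior is 0 (for $k > 0$), the
perceived deviation equals $\epsilon$, and both solvers return
$\epsilon = 0$ without ever forming $\infty \cdot 0$.

**Degenerate input policy.** $k = 0$ together with a zero likelihood
(deaf limit) raises a classed error; zero shifts yield `NA` percent
compensation, never $0/0$; single-point datasets can be generated but
refuse to fit.

## Fitting

`fit_random_search()` is a greedy random search: positive scale
parameters (`sigma_f`, `k`, `sigma_m`) are proposed multiplicatively,
log-uniform within a factor of $[0.1, 10]$ of the current best — "up to
one order of magnitude" made explicit — and `epsilon0` additively
(uniform ±20 cents by default, since it can be zero or negative).
Proposals are accepted only on strict residual decrease (mean absolute
error in percent-compensation points, weighted if the dataset carries
weights), so the accepted-residual sequence is provably monotone. `k`
is floored at $10^{-320}$ so the search can reach the essentially-zero
regime without leaving log space. The deterministic solver is the
default objective engine; the all-sampling loop is available behind
`method = "stochastic"` for fidelity.

Greedy acceptance can stall: on some seeds a single run walks into a
local minimum with $\sigma_f \to 0$ and moderate $k$ mimicking the
suppression that the data attribute to sensory noise. `fit_variants()`
therefore defaults to four restarts with random log-uniform
initializations ($\sigma_f \in [0.5, 100]$ cents,
$k \in [10^{-16}, 10^{-2}]$) and keeps the best run. A practical note
for variant comparisons: starting near $k = 10^{-3}$, matching an
essentially self-source dataset requires the search to walk $k$ down
tens of decades, roughly half a decade per accepted step, so budgets of
1,000–2,000 proposals per restart are appropriate there; simple
two-parameter recovery is reliable at the 500-proposal default.

Three variant masks mirror how such models are used: `full`
($\sigma_f, k$), `with_offset` (adds $\epsilon_0$, for read-out-biased
datasets), and `clamped_self` ($\sigma_f$ only, posterior pinned at 1).
`free_sigma_m = TRUE` adds the motor SD for datasets that did not
report it. No uncertainty is attached to fitted parameters; the full
proposal trace is exposed so users can bootstrap externally.

## What the synthetic generator does and does not emulate

`make_shift_curve_dataset()` and `make_motor_sd_curve_dataset()` run the
deterministic forward model over a grid and add i.i.d. Gaussian noise to
the percent-compensation values, emulating the measurement scatter of a
digitized published curve with known ground truth. The noise SD is a
required argument — it is part of the emulated conditions, not a hidden
default. The generators record truth, noise SD and seed as metadata, so
parameter-recovery experiments close the loop end-to-end.

They do **not** emulate: rendition-level sampling error in the underlying
experiments (points are noisy around the *exact* model curve),
between-subject heterogeneity, drift or session effects, non-Gaussian or
heteroskedastic digitization error, or any misspecification of the model
itself. Passing recovery tests therefore shows the fitting machinery is
correct and the model identifiable under its own assumptions — not that
real birds or speakers obey it.

Values chosen once for the recovery experiments: observation noise SD 1
percent point (realistic digitization error), shift grid
{10, 30, 50, 100, 150, 200, 300} cents, motor-SD grid 10–60 cents at a
fixed 100-cent shift (the source of such variability curves does not
state its shift; 100 cents is a typical magnitude).

## Behaviour worth knowing about

With $k > 0$, compensation versus sensory noise is non-monotonic:

```{r sensory-noise-curve, fig.width = 5, fig.height = 3.2, eval = FALSE}
p <- model_params(sigma_m = 32, sigma_f = 23, k = 1.5e-4)
sn <- compensation_vs_sensory_noise(p, exp(seq(log(0.5), log(300),
                                               length.out = 25)),
                                    p_shift = 100)
autoplot(sn) + ggplot2::scale_x_log10()
```

Very noisy sensors are distrusted (the Kalman weight vanishes), but very
*reliable* sensors reject deviant renditions as externally caused —
causal-inference outlier rejection — so compensation peaks at an
intermediate $\sigma_f$. Note that this shape strictly requires
$k > 0$: with $k = 0$ the posterior is identically 1 and the curve is
monotone, even though the non-monotonicity is sometimes illustrated with
nominally zero $k$; the package exposes both regimes and the tests pin
the non-monotonic one at $k = 1.5\times10^{-4}$.

The learning-time ratio
$\tau = q\,\langle P(e \mid p_f)\rangle / \langle P(s \mid p_f)\rangle$
is exposed in units of its scale $q$, which multiplies an unknown
per-study constant; under the clamp $\tau = 0$ identically.

## Problem sizes and limitations

The shipped tests and experiments use desk-scale settings — 20-triple
solver sweeps, 10-seed recovery with budget 500, variant comparisons at
budget 2,000 × 4 restarts — chosen as the package's own working sizes;
all are arguments, and larger studies only cost linearly more.

Known limitations: the model is stationary (no within-utterance dynamics,
no adaptation-speed modelling beyond the $\tau$ ratio); $\sigma_f$,
$\sigma_m$, $k$ are frequency-independent; the external-source
likelihood is collapsed into the single scalar $k$ with no support
structure; and fitted parameters come without standard errors. Extending
the source model (e.g. estimating the source priors iteratively) is
deliberately out of scope.
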