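# pitchadapt

Bayesian causal-inference modelling of vocal adaptation to pitch-shifted
auditory feedback.

When a songbird or a human hears their own voice pitch-shifted through
headphones, they shift their produced pitch in the opposing direction —
but only partially, and the larger the shift the smaller the *relative*
correction. `pitchadapt` implements a normative explanation: the
vocalizer performs causal inference on its feedback ("was that sound
me?") and corrects pitch errors only to the extent they are credibly
self-caused. The package is for computational neuroscientists and
speech/birdsong researchers who want to simulate this model, map its
predicted compensation curves, and fit its parameters to measured (or
digitized) compensation data.

## The model

Pitch is in cents ($1200\log_2 F$ minus an arbitrary reference). Each
rendition draws a produced pitch $p \sim N(\mu^*+\epsilon,\sigma_m^2)$
around the target $\mu^*$ plus a learned corrective bias $\epsilon$;
the ear receives $p_{ear}=p+p_\Delta$ under shift $p_\Delta$, encoded as
noisy feedback $p_f \sim N(p_{ear},\sigma_f^2)$. Marginalizing the
unknown production, self-caused feedback has likelihood
$L = N(p_f;\,\mu_m,\,\sigma_f^2+\sigma_m^2)$ with $\mu_m=\mu^*+\epsilon$,
and the self-source posterior is

$$P(s \mid p_f) = \frac{L}{L+k},$$

where the constant $k$ absorbs the prior odds and flat likelihood of an
external source. The perceived deviation weights the one-step Kalman
combination of plan and feedback by that posterior,

$$\Delta p \;=\; \epsilon + (p_f-\mu_m)\,P(s \mid p_f)\,
  \frac{\sigma_m^2}{\sigma_f^2+\sigma_m^2},$$

and adaptation relaxes $\epsilon \leftarrow \epsilon -
\eta\langle\Delta p\rangle_n$ until the average deviation vanishes. The
equilibrium bias yields the percent compensation
$c = 100|\epsilon|/|p_\Delta|$. Because deviant feedback is attributed
to the environment ($P(s\mid p_f)\!\to\!0$), large shifts are largely
ignored; because the Kalman weight grows with $\sigma_m^2$, variable
vocalizers compensate more; and a deaf vocalizer
($\sigma_f=\infty$) does not adapt at all.

## Worked example

```r
library(pitchadapt)

params <- model_params(sigma_m = 46, sigma_f = 23, k = 1.5e-4)
solve_equilibrium_deterministic(100, params)
#> <pitch_equilibrium>
#>   method : deterministic
#>   p_shift: 100 cents
#>   epsilon: -49.3253 cents
#>   percent compensation: 49.33%
```

A 100-cent upward shift is met by lowering the produced pitch 49.3
cents — about half the imposed error is corrected. Over a range of
shifts the *relative* correction shrinks and finally collapses:

```r
compensation_curve(params, shifts = c(10, 30, 100, 300))
#> # A tibble: 4 × 8
#>   variable_kind variable_value p_shift_cents epsilon_cents percent_compensation
#>   <chr>                  <dbl>         <dbl>         <dbl>                <dbl>
#> 1 shift_cents               10            10        -6.99                69.9
#> 2 shift_cents               30            30       -20.5                 68.4
#> 3 shift_cents              100           100       -49.3                 49.3
#> 4 shift_cents              300           300        -0.562                0.187
```

A 10-cent shift is ~70% compensated; a 300-cent shift is irreconcilable
with self-production and essentially ignored (0.19%). Fitting closes the
loop — here recovering parameters from a synthetic curve with known
ground truth ($\sigma_f = 23$, $k = 1.5\times10^{-4}$) and 1 point of
observation noise:

```r
truth <- params
d <- make_shift_curve_dataset(truth, c(10, 30, 50, 100, 150, 200, 300),
                              obs_noise_sd = 1, seed = 42)
fit_random_search(d, init = model_params(sigma_m = 46, sigma_f = 10, k = 1e-3),
                  free = c("sigma_f", "k"), budget = 500, seed = 1)
#> <pitch_fit>
#>   free    : sigma_f, k
#>   sigma_f : 20.772 cents
#>   k       : 0.000200347
#>   sigma_m : 46 cents (fixed)
#>   residual: 1.5760 percent points (4/500 proposals accepted)
```

The search lands within ~10% of the true sensory noise and within a
factor of ~1.3 of the true $k$ on this seed; `tidy()`, `glance()`,
`augment()` and `autoplot()` methods give broom/ggplot2-style access to
every result type. A stochastic solver
(`solve_equilibrium_stochastic()`), motor-variability and sensory-noise
curves, model variants (`fit_variants()`: read-out offset, clamped
self-source) and CSV round-tripping are documented in the help pages;
`vignette("pitch-adaptation-model")` explains the methods and design
choices. A command-line interface is installed at
`system.file("cli", "pitchadapt.R", package = "pitchadapt")` with
`solve`, `simulate` and `fit` subcommands.

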