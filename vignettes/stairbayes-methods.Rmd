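---
title: "Bayesian stairway-plot inference: model, priors and validation"
author: "stairbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian stairway-plot inference: model, priors and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stairbayes)
```

## The model

`stairbayes` infers the demographic history of a single panmictic
population from its site frequency spectrum (SFS): the counts
$\xi_i$ of SNPs at which $i$ of $n = 2m$ sampled haploid sequences carry
the derived allele.  The model is the stairway-plot composite likelihood:
sites are treated as independent draws from a multinomial distribution
over frequency classes, whose class probabilities follow from standard
coalescent theory under an infinite-sites mutation model.

One scaled population size $\theta_k = 4 N_k \mu$ is assigned to each
coalescent interval — the period during which exactly $k$ ancestral
lineages of the sample survive, $k = 2, \dots, n$.  Sizes are constant
within an interval and free to change between intervals, with interval
durations fixed at their coalescent expectations
$E[t_k] = 4N_k / (k(k-1))$.  This discretisation is a deliberate,
mildly inconsistent approximation (interval lengths depend on the sizes
being estimated) that is standard for skyline-type models and works well
in practice.

The probability that a site is polymorphic at derived count $i$ combines
the chance that a mutation lands on a lineage during interval $k$
(proportional to the lineage length, giving the weight
$\theta_k/(k-1)$) with the probability that a lineage present among $k$
ancestors subtends exactly $i$ of the $n$ samples,
$$
\Pr(k, i \mid n) = \binom{n-i-1}{k-2} \Big/ \binom{n-1}{k-1},
\qquad
p_i = \sum_{k=2}^{n} \Pr(k, i \mid n)\, \frac{\theta_k}{k-1}.
$$
For constant $\theta$ this collapses to the classical $p_i = \theta/i$
spectrum, which the test suite verifies to machine precision.  Because
at most one mutation may hit a site, parameter vectors with
$\sum_i p_i \ge 1$ are invalid and receive log-likelihood $-\infty$.

The monomorphic probability $p_0$ cannot be obtained the same way.  Two
derivations are provided: the *complement* $p_0 = 1 - \sum_i p_i$
(default), and the *tree-length* form
$p_0 = \exp(-\sum_k \theta_k/(k-1))$, the probability of no mutation on
a tree of expected total length; under the latter the polymorphic block
is rescaled to total $1 - p_0$.  The two agree to second order in the
expected tree length (a bound the tests check numerically) and lead to
virtually identical inferences at realistic $\theta$.

The likelihood is the multinomial log-probability of the observed
counts, with class probabilities renormalised by the chosen conditioning:

* `none` — model all classes including monomorphic sites;
* `noMonomorphic` — condition on polymorphism, $p_i^M = p_i/(1-p_0)$,
  for data sets without reliable invariant-site counts;
* `noMonoNoSingletons` — additionally drop the singleton classes
  ($i = 1$ and $i = n-1$), $p_i^S = p_i/(1-p_0-p_1-p_{n-1})$, for data
  where singletons are sequencing-error-prone.

Folded spectra (unknown ancestral state) merge classes $i$ and $n-i$;
the folded singleton correction removes the single merged class $i = 1$
and renormalises by $1 - p_0 - p_1^F$, the unique choice consistent with
the unfolded corrections.  The all-derived class $i = n$ would require
two mutations and is never modelled; its count is stored and a warning
is raised if it is positive.

Evaluation cost is $O(n^2)$ and independent of the number of SNPs: the
$\Pr(k,i\mid n)$ table is cached once per sample size, and a likelihood
evaluation is one table–vector product.

## Prior models

Nine priors on the vector $\theta_2, \dots, \theta_n$ are implemented,
spanning the spectrum from no shrinkage to strong adaptive shrinkage:

| family | structure | sampled hyperparameters |
|---|---|---|
| `IID_UNIFORM` | $\theta_i \sim U(0, 0.1)$ | — |
| `UCLN` | $\theta_i \sim \mathrm{LN}(\ln\hat\mu, \sigma)$ | $\hat\mu \sim \mathrm{LogUnif}(10^{-10}, 1)$, $\sigma \sim \mathrm{Exp}(\text{mean } 3H)$ |
| `IGR` | $\theta_i \sim \Gamma(m^2/v,\, m/v)$ | $m \sim \mathrm{LogUnif}(10^{-10}, 1)$, $v \sim \mathrm{Exp}(\text{mean } 0.01)$ |
| `BSP_GROUPED` | $b$ groups of equal values; autocorrelated exponential group means | group sizes (flat multinomial, offset 1), group values |
| `RJ` | each interval equals its predecessor w.p. $\beta = 0.5$, else fresh $U(0, 0.1)$ | equality indicators |
| `GMRF1/2` | $\ln\theta$ random walk (order 1/2), step SD $\xi$ | — (fixed $\xi$ by default) |
| `HSMRF1/2` | as GMRF with per-step SD $\gamma\,\xi_i$, $\xi_i \sim \mathrm{HalfCauchy}(0,1)$ | local scales $\xi_i$ |

$H = \ln 10 / (2 z_{0.975}) = 0.587405$ is the lognormal SD whose
central 95% interval spans one order of magnitude; it is the package's
unit of prior variation on log sizes.  The GMRF global scale defaults to
$\xi = H/\sqrt{n-2}$ so that the *end-to-end* log-size ratio spans about
one order of magnitude a priori; the HSMRF global scale defaults to
$\gamma = 0.021$ (equivalent to per-step HalfCauchy(0, 0.021) scales).
Both can instead be estimated under a half-Cauchy hyperprior
(`estimateScale = TRUE`).  Exponential hyperpriors are parameterised by
their mean throughout (3H and 0.01), and the loguniform upper bound is
$10^0$: $\theta = 4N\mu > 1$ has no biological meaning and the uniform
family caps at 0.1 for the same reason.

Design choices where the construction was genuinely open:

* **Chain orientation.**  The sequential priors (BSP, RJ, GMRF, HSMRF)
  need an anchor.  By default the chain starts at the most recent
  interval ($k = n$) and runs backward in time, matching the
  skyline-plot convention of present-anchored trajectories;
  `orientation = "past"` flips it.
* **Anchor distribution.**  The random-field equations only define
  increments; the anchor gets a proper $U(0, 0.1)$ base prior, matching
  the uniform family's support.
* **BSP group values.**  Group 1 is uniform on $(0, 0.1)$ and each later
  group is exponential with mean equal to its predecessor's value (the
  classical autocorrelated skyline construction).  The default group
  count is $b = \mathrm{round}(2m/4)$ (round-half-even), i.e. four
  intervals per group on average.
* **Second-order fields.**  The first increment of GMRF2/HSMRF2 has no
  second predecessor and uses the order-1 step.

### A numerical subtlety of the IGR prior

With $m$ as small as $10^{-10}$ and $v$ of order $0.01$, the gamma shape
$m^2/v$ reaches $10^{-18}$, and essentially all conditional mass of
$\theta$ lies *below the smallest positive double*: `rgamma()` returns
exact zeros for most hyperparameter draws.  A sampler whose state stores
$\theta$ as a double can therefore never visit most of this prior.
`stairbayes` carries the IGR $\theta$ coordinates in log space inside
the sampler (density with the exponential-map Jacobian, additive walks,
and exact log-scale gamma draws via
$\Gamma(a) \stackrel{d}{=} \Gamma(a+1)\, U^{1/a}$), which makes the
full support reachable.  Reported $\theta$ values may still underflow
to zero on output; they are exactly the values whose true magnitude is
below $10^{-308}$.

## MCMC

The sampler is single-site random-scan Metropolis-within-Gibbs.  One
*iteration* is one sweep: a multiplier proposal for every free scalar
parameter, a joint up–down scaling of all $\theta$ (with the location
hyperparameter for UCLN/IGR), the family's discrete moves (BSP
group-boundary shifts; RJ equality toggles, with dimension matching by
fresh uniform draws so the Jacobian is one), and three structural moves
that earn their keep in validation:

* *prior-conditional redraws* for the i.i.d. families (independence
  proposals from $p(\theta_j \mid \text{hypers})$, acceptance = bare
  likelihood ratio);
* *tail-scaling* block moves for the random fields (scale the chain from
  a position to its end, changing a single increment, so the old end of
  the chain mixes freely);
* a *prior refresh* independence move proposing the entire state from
  the prior's generative process (the prior cancels; acceptance is the
  likelihood ratio).  This is what lets the heavy hyperparameter
  funnels of UCLN/IGR mix in prior-dominated runs.

Multiplier step sizes are auto-tuned during burn-in only (targets: 0.44
acceptance for single-parameter moves, 0.23 for joint moves), preserving
ergodicity afterwards.  Defaults are 500,000 iterations and 4 replicate
runs for convergence assessment, 10% burn-in, and thinning chosen to
retain about 2000 samples per replicate.  Initial states are drawn from
the prior until the likelihood is finite, with a Watterson-style moment
estimate as fallback.  Convergence diagnostics are an
autocorrelation-based ESS (Geyer initial-monotone truncation) and the
across-replicate split potential scale reduction factor.

Alongside each retained sample the *conditioned site-class probability
vector* is stored.  An empty spectrum (zero sites) has log-likelihood
identically zero — the multinomial probability of observing nothing is
one — so zero-data runs sample the prior exactly; this is the
prior-recovery validation used in the test suite.

## Model selection: LPCV

Leave-one-out cross-validation is computed posthoc from the stored
probabilities.  Sites within a frequency class are exchangeable, so the
per-site sum collapses to a count-weighted sum over classes:
$$
\mathrm{LPCV} = \sum_i \xi_i \,
  \ln\!\left[\frac{1}{K}\sum_{k=1}^{K} \frac{1}{p_i^{(k)}}\right]^{-1},
$$
the log harmonic mean over MCMC samples of each class's probability,
evaluated with log-sum-exp stabilisation on $-\ln p$.  Replicates are
pooled for the final score and per-replicate scores reported as a
stability diagnostic.  `selectBest()` takes the arg-max across models
fitted to the same spectrum under the same conditioning; exact ties go
to the family with fewer sampled hyperparameters.

## Trajectories

$\theta$ samples transform to interval times
$T_i = \sum_{k=i}^{n} \theta_k / (k(k-1))$ (expected substitutions per
site; divided by $\mu$ for generations; multiplied by an explicit
generation time for years — never inferred) and sizes
$N_k = \theta_k / (4\mu)$.  Each sample defines a step function,
right-continuous, with interval $k$ on $[T_{k+1}, T_k)$, the most recent
interval extending to the present and times older than $T_2$ holding the
oldest size (the conventional flat tail).  Step functions are evaluated
on a common grid — 500 points by default, log-spaced because histories
span orders of magnitude, extending to the posterior 97.5% quantile of
the TMRCA — and summarised per grid point by the median and central 95%
interval.

## Synthetic scenarios

`demographicScenario()` ships six standard shapes (constant, two-epoch,
exponential growth with and without an ancient constant phase, a
multi-epoch complex expansion, and a bottleneck) with $\mu = 1.2\times
10^{-8}$ per bp per generation as the default rate.  The benchmark
parameter values behind the published versions of these scenarios are
not printed anywhere reusable, so the defaults here are documented
stand-ins chosen to exercise the same qualitative shapes (e.g. constant
$N = 10^4$; two-epoch $10^4 \to 10^5$ at $5\times 10^3$ generations;
bottleneck $10^4 \to 10^3 \to 10^4$); the scoring truth is always the
scenario's own configuration.

A continuous history is mapped to per-interval $\theta$ by fixed-point
iteration: starting from the present-day size, interval times are
computed from the current $\theta$ and each $\theta_k$ is reset to
$4\mu N(\text{interval midpoint})$ until the maximum relative change
falls below $10^{-10}$ (midpoints, not endpoints, to reduce
discretisation bias).  Sites are then drawn as one multinomial sample of
$l$ independent sites — exactly the model the likelihood assumes.  This
emulates the SFS of a large recombining genome (many effectively
independent sites); it does *not* emulate linkage, so passing tests
bound performance under the model's own assumptions and say nothing
about linked-site overdispersion.  Ancestral-allele miscalls are
modelled per class as binomial thinning into the mirror class $n-i$;
folding provably erases them, which the tests exploit.

## Validation settings and limitations

The shipped checks run at deliberately desk-sized problem scales,
stated here as the package's validation conditions: prior recovery at
$n = 6$ with 60,000 sweeps per family against $10^4$ direct prior
draws (KS < 0.05); constant-scenario recovery at $n = 20$, $l = 10^6$,
$\theta = 4.8\times10^{-4}$ over 20 seeds with 20,000 sweeps (95% bands
cover the truth at ≥ 90% of grid points); polarization-error ordering
on $\rho \in \{0, 0.005, 0.05\}$ with 5 coupled seeds at $l = 10^8$;
and a selection sanity check that HSMRF1 does not systematically beat
constant-capable families on constant-truth data (10 seeds, mean
advantage within two standard errors of zero).

Known limitations: no linkage or recombination modelling; no joint
multi-population spectra; the expected-interval-time discretisation
inherits the usual skyline bias for very rapid size changes; mutation
rate and generation time are fixed inputs, and mis-specifying them
rescales sizes and times reciprocally.
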