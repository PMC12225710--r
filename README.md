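# stairbayes

Bayesian inference of single-population demographic histories from site
frequency spectra (SFS), for population geneticists working with whole
genome SNP data.

The SFS — the count ξ_i of SNPs carried by i of n sampled chromosomes —
is summarised by a composite multinomial likelihood whose class
probabilities follow from coalescent expectations: one scaled size
θ_k = 4N_k μ per coalescent interval, and

    p_i = Σ_{k=2..n} Pr(k, i | n) · θ_k / (k−1),
    Pr(k, i | n) = C(n−i−1, k−2) / C(n−1, k−1),

with the monomorphic probability p₀ obtained either as 1 − Σp_i or as
exp(−Σ θ_k/(k−1)).  Posterior inference runs by Metropolis-within-Gibbs
MCMC under a choice of nine priors on the θ vector — independent
uniform/lognormal/gamma, grouped Bayesian skyline, reversible-jump
grouping, and first/second-order Gaussian and Horseshoe Markov random
fields — and competing priors are ranked by the leave-one-out
cross-validation score

    LPCV = Σ_i ξ_i · ln [ (1/K) Σ_k 1/p_i^(k) ]^(−1),

computed posthoc from stored per-sample class probabilities.  θ samples
transform to population-size trajectories N_k = θ_k/(4μ) against times
T_i = Σ_{k≥i} θ_k/(k(k−1)), summarised as a posterior median with a 95%
credible band on a plotting grid.  Folded spectra, unknown
monomorphic-site counts and ascertainment corrections (dropping
monomorphic and/or singleton classes) are supported, as is a
synthetic-data generator for standard demographic scenarios including
ancestral-allele polarization error.

## Worked example

Simulate a constant-size population (N = 10⁴, μ = 1.2×10⁻⁸, 20
haploids, 10⁶ sites), infer under a first-order Gaussian Markov random
field prior, and summarise:

```r
library(stairbayes)

sc    <- demographicScenario("constant", n = 20, l = 1e6)
truth <- scenarioToTheta(sc)
truth$theta[1]                     # 0.00048  (= 4 N mu)

sfs <- simulateSFS(truth$theta, sc@l, seed = 1)
sfs
#> SiteFrequencySpectrum: n = 20 haploids, unfolded
#>   polymorphic classes: 19, SNPs: 1,701
#>   monomorphic sites: 998,299

tr <- runMCMC(sfs, priorSpec("GMRF1"),
              mcmc = mcmcConfig(iterations = 12000, replicates = 2,
                                seed = 1))
effectiveSampleSize(tr, "theta_11")   # ~959, psrf ~1

traj <- summarizeTrajectories(tr, mu = sc@mu)
traj
#> DemographicTrajectory: 500 grid points, time in generations
#>   present-day N_e median: 1.101e+04 | oldest: 1.027e+04
plot(traj)
```

The present-day and oldest median sizes land within about 10% of the
true N = 10⁴, and the 95% band covers the flat truth across the grid.  Model comparison
against the no-shrinkage prior:

```r
trI <- runMCMC(sfs, priorSpec("IID_UNIFORM"),
               mcmc = mcmcConfig(iterations = 12000, replicates = 2,
                                 seed = 2))
selectBest(list(lpcv(tr, sfs), lpcv(trI, sfs)))
#> [1] "GMRF1"
```

The LPCV difference is small on constant-truth data (about +0.8 log
units for GMRF1 here): both families can represent a flat history, and
the smoothing prior wins by economy, not fit.

A command-line wrapper with `simulate`, `infer`, `select` and `plot`
subcommands is installed at `inst/scripts/stairbayes`:

```sh
Rscript inst/scripts/stairbayes simulate --scenario constant --n 20 \
    --l 1000000 --seed 1 --out sim
Rscript inst/scripts/stairbayes infer --sfs sim.sfs --prior GMRF1 \
    --iterations 12000 --seed 1 --out fit
```

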