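# Synthetic SFS generation with known truth: standard single-population
# demographic scenarios, the mapping from a continuous-time size history to
# per-interval theta under the model's own time discretisation, multinomial
# site sampling, and the ancestral-allele polarization-error experiment.

.SCENARIO_DEFAULTS <- list(
  constant = list(N0 = 1e4),
  two_epoch = list(NRecent = 1e4, NAncient = 1e5, changeTime = 5e3),
  exp_growth = list(N0 = 1e5, growthRate = 1e-3),
  exp_growth_constant = list(N0 = 1e5, NAncient = 1e3, duration = 5e3),
  complex_expansion = list(sizes = c(5e4, 5e3, 2e4), times = c(2e3, 2e4)),
  bottleneck = list(N0 = 1e4, NBottleneck = 1e3, start = 2e3, end = 4e3)
)

#' Construct a demographic scenario
#'
#' Six standard single-population shapes are available, with documented
#' default parameters chosen to exercise the same qualitative histories as
#' common simulation benchmarks (the exact benchmark parameters are not
#' published with the method, so these defaults are stand-ins; the truth
#' for scoring is always whatever the scenario says):
#' \itemize{
#'   \item \code{constant}: N0 = 1e4 at all times;
#'   \item \code{two_epoch}: N = 1e4 until 5000 generations ago, 1e5 before;
#'   \item \code{exp_growth}: N(t) = N0 exp(-r t), N0 = 1e5, r = 1e-3;
#'   \item \code{exp_growth_constant}: exponential growth from 1e3 to 1e5
#'     over the last 5000 generations, constant 1e3 before;
#'   \item \code{complex_expansion}: 5e4 / 5e3 / 2e4 with changes at 2000
#'     and 20000 generations (recent expansion after an older decline);
#'   \item \code{bottleneck}: 1e4, dropping to 1e3 between 2000 and 4000
#'     generations ago, 1e4 before.
#' }
#'
#' @param name scenario name (see above)
#' @param params named list overriding the scenario's default sizes/times
#'   (diploid N_e; times in generations)
#' @param mu per-site per-generation mutation rate (default 1.2e-8)
#' @param n haploid sample size (default 20)
#' @param l total number of sites (default 1e6)
#' @return a [DemographicScenario-class]
#' @examples
#' demographicScenario("constant", n = 20, l = 1e6)
#' @export
demographicScenario <- function(name, params = list(), mu = 1.2e-8,
                                n = 20L, l = 1e6) {
  name <- match.arg(name, names(.SCENARIO_DEFAULTS))
  p <- utils::modifyList(.SCENARIO_DEFAULTS[[name]], params)
  new("DemographicScenario", name = name, params = p, mu = mu,
      n = as.integer(n), l = as.numeric(l))
}

setMethod("show", "DemographicScenario", function(object) {
  cat(sprintf("DemographicScenario '%s': n = %d, l = %s, mu = %g\n",
              object@name, object@n, format(object@l, big.mark = ","),
              object@mu))
  ps <- vapply(object@params, function(x) paste(format(x), collapse = ","),
               character(1))
  cat("  ", paste(names(ps), ps, sep = " = ", collapse = "; "), "\n",
      sep = "")
})

#' Continuous-time size history of a scenario
#'
#' @param scenario a [DemographicScenario-class]
#' @return a vectorised function N(t), t in generations before present
#' @export
scenarioSizeFunction <- function(scenario) {
  stopifnot(is(scenario, "DemographicScenario"))
  p <- scenario@params
  switch(scenario@name,
    constant = function(t) rep(p$N0, length(t)),
    two_epoch = function(t) ifelse(t < p$changeTime, p$NRecent, p$NAncient),
    exp_growth = function(t) p$N0 * exp(-p$growthRate * t),
    exp_growth_constant = function(t) {
      r <- log(p$N0 / p$NAncient) / p$duration
      ifelse(t < p$duration, p$N0 * exp(-r * t), p$NAncient)
    },
    complex_expansion = function(t) {
      idx <- findInterval(t, p$times) + 1L
      p$sizes[idx]
    },
    bottleneck = function(t)
      ifelse(t >= p$start & t < p$end, p$NBottleneck, p$N0)
  )
}

#' Map a scenario to per-interval theta
#'
#' Finds the per-interval theta vector consistent with the continuous size
#' history under the model's own time discretisation (sizes constant within
#' expected coalescent intervals) by fixed-point iteration: starting from
#' the present-day size, interval times are computed from the current
#' theta, each theta_k is reset to 4 mu N(midpoint of interval k), and the
#' loop repeats until the maximum relative change is below \code{tol}.
#' Midpoints rather than endpoints are used to reduce discretisation bias.
#'
#' @param scenario a [DemographicScenario-class]
#' @param tol convergence tolerance on the relative change (default 1e-10)
#' @param maxIter iteration cap (default 100)
#' @return list with \code{theta} (oldest-first, k = 2..n), \code{times}
#'   (interval start times, generations), \code{sizes} (N_k), and
#'   \code{iterations} used
#' @export
scenarioToTheta <- function(scenario, tol = 1e-10, maxIter = 100L) {
  stopifnot(is(scenario, "DemographicScenario"))
  n <- scenario@n
  mu <- scenario@mu
  Nfun <- scenarioSizeFunction(scenario)
  theta <- rep(4 * mu * Nfun(0), n - 1L)
  for (iter in seq_len(maxIter)) {
    times <- intervalTimes(theta, mu)                # generations
    mids <- (times + c(times[-1L], 0)) / 2
    thetaNew <- 4 * mu * Nfun(mids)
    resid <- max(abs(thetaNew - theta) / theta)
    theta <- thetaNew
    if (resid < tol)
      return(list(theta = theta, times = intervalTimes(theta, mu),
                  sizes = theta / (4 * mu), iterations = iter))
  }
  stop(sprintf(
    "fixed-point mapping did not converge in %d iterations (last relative residual %.3g)",
    maxIter, resid))
}

#' Simulate a site frequency spectrum from theta
#'
#' One multinomial draw of \code{l} independent sites over the classes
#' {monomorphic, 1..n-1}, using the complement derivation of the
#' monomorphic probability.  Reproducible given \code{seed}.
#'
#' @param theta per-interval theta vector (oldest-first)
#' @param l number of sites
#' @param seed integer RNG seed
#' @return an unfolded [SiteFrequencySpectrum-class] with known
#'   monomorphic count
#' @export
simulateSFS <- function(theta, l, seed) {
  pp <- polymorphicProbs(theta)
  if (!pp$valid)
    stop("theta implies sum of polymorphic probabilities >= 1; ",
         "cannot simulate under the infinite-sites model")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw <- stats::rmultinom(1L, size = l, prob = c(1 - sum(pp$p), pp$p))[, 1L]
  siteFrequencySpectrum(draw[-1L], n = length(theta) + 1L,
                        monomorphicCount = draw[[1L]])
}

#' Polarization-error experiment
#'
#' For each miscall probability rho in \code{rhoGrid} and each seed:
#' simulate an unfolded spectrum from the scenario, mis-polarize each SNP
#' independently with probability rho, infer the demographic history, and
#' report the integrated absolute log10 deviation of the posterior-median
#' trajectory from the true size history over the plotting grid.  All rho
#' values for one seed share the same base spectrum and MCMC seed, so
#' rho = 0 reproduces the unperturbed baseline exactly.
#'
#' @param scenario a [DemographicScenario-class]
#' @param rhoGrid vector of miscall probabilities
#' @param prior a [PriorSpec-class]
#' @param mcmc an [MCMCConfig-class]
#' @param seeds integer vector of replicate seeds
#' @param gridPoints trajectory grid size for the deviation integral
#' @param folded also fold the perturbed spectrum before inference instead
#'   of using it unfolded
#' @return data.frame with columns rho, seed, deviation
#' @export
runPolarizationExperiment <- function(scenario, rhoGrid, prior, mcmc,
                                      seeds = 1:5, gridPoints = 101L,
                                      folded = FALSE) {
  stopifnot(is(scenario, "DemographicScenario"))
  truth <- scenarioToTheta(scenario)
  Nfun <- scenarioSizeFunction(scenario)
  maxT <- truth$times[[1L]]
  mu <- scenario@mu
  out <- list()
  for (s in seeds) {
    base <- simulateSFS(truth$theta, scenario@l, seed = s)
    for (rho in rhoGrid) {
      pert <- applyPolarizationError(base, rho, seed = s + 100000L)
      if (folded) pert <- foldSpectrum(pert)
      cfg <- mcmc
      cfg@seed <- as.integer(mcmc@seed + s)
      like <- likelihoodConfig()
      tr <- runMCMC(pert, prior, like, cfg)
      traj <- summarizeTrajectories(tr, mu, gridPoints = gridPoints,
                                    maxTime = maxT)
      dev <- mean(abs(log10(traj@median) - log10(Nfun(traj@time))))
      out[[length(out) + 1L]] <- data.frame(rho = rho, seed = s,
                                            deviation = dev)
    }
  }
  do.call(rbind, out)
}
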