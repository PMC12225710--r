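#' @import methods
#' @importFrom stats runif rnorm rexp rgamma rlnorm rcauchy rmultinom rbinom
#'   dnorm dexp dgamma dlnorm acf sd var quantile qnorm setNames
NULL

.PRIOR_FAMILIES <- c("IID_UNIFORM", "UCLN", "IGR", "BSP_GROUPED", "RJ",
                     "GMRF1", "GMRF2", "HSMRF1", "HSMRF2")

.CONDITIONINGS <- c("none", "noMonomorphic", "noMonoNoSingletons")
.P0_METHODS <- c("complement", "treeLength")

#' SiteFrequencySpectrum class
#'
#' Container for a single-population site frequency spectrum (SFS): the
#' number of SNPs observed with each derived-allele count among \code{n}
#' haploid samples (n = 2m for m diploid individuals).  Unfolded spectra
#' store classes i = 1..n-1; folded spectra store the merged classes
#' i = 1..floor(n/2).  The monomorphic (invariant-site) count may be unknown,
#' in which case the likelihood must condition on observing polymorphic
#' sites only and \code{"monomorphic"} must be listed among the masked
#' classes.  The all-derived class (i = n) cannot be modelled under the
#' infinite-sites assumption (it would require at least two mutations); its
#' count is recorded but never enters the likelihood.
#'
#' @slot n haploid sample size (integer, >= 2)
#' @slot counts numeric vector of non-negative integer SNP counts; index 1
#'   corresponds to derived-allele count i = 1 (unfolded) or minor-allele
#'   count i = 1 (folded)
#' @slot monomorphicCount number of invariant sites; \code{NA_real_} when
#'   unknown
#' @slot lastClassCount count of sites where all n samples carry the derived
#'   allele (unfolded only; excluded from the likelihood)
#' @slot folded logical, whether the spectrum is folded
#' @slot maskedClasses character subset of \code{c("monomorphic",
#'   "singletons")} excluded from the likelihood
#'
#' @seealso [siteFrequencySpectrum()], [readSFS()], [foldSpectrum()]
#' @export
setClass("SiteFrequencySpectrum",
  representation(
    n = "integer",
    counts = "numeric",
    monomorphicCount = "numeric",
    lastClassCount = "numeric",
    folded = "logical",
    maskedClasses = "character"
  ),
  prototype(
    n = 2L,
    counts = 0,
    monomorphicCount = NA_real_,
    lastClassCount = 0,
    folded = FALSE,
    maskedClasses = "monomorphic"
  )
)

setValidity("SiteFrequencySpectrum", function(object) {
  msg <- character()
  n <- object@n
  if (length(n) != 1L || is.na(n) || n < 2L)
    msg <- c(msg, "'n' must be a single integer >= 2")
  expected <- if (isTRUE(object@folded)) n %/% 2L else n - 1L
  if (length(object@counts) != expected)
    msg <- c(msg, sprintf("counts must have length %d (%s, n = %d), found %d",
                          expected, if (object@folded) "folded" else "unfolded",
                          n, length(object@counts)))
  if (any(is.na(object@counts)) || any(object@counts < 0) ||
      any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (!is.na(object@monomorphicCount) &&
      (object@monomorphicCount < 0 ||
       object@monomorphicCount != round(object@monomorphicCount)))
    msg <- c(msg, "monomorphicCount must be a non-negative integer or NA")
  if (is.na(object@monomorphicCount) &&
      !("monomorphic" %in% object@maskedClasses))
    msg <- c(msg,
      "unknown monomorphic count requires 'monomorphic' among maskedClasses")
  if (!all(object@maskedClasses %in% c("monomorphic", "singletons")))
    msg <- c(msg, "maskedClasses must be a subset of {monomorphic, singletons}")
  if (length(msg)) msg else TRUE
})

#' PriorSpec class
#'
#' Identity and hyperparameters of one of the nine prior models on the
#' per-interval scaled population sizes theta_k = 4 N_k mu.  Hyperparameters
#' not supplied are resolved to family defaults at the sample size in use
#' (see [resolvePrior()]).
#'
#' @slot family one of \code{IID_UNIFORM, UCLN, IGR, BSP_GROUPED, RJ, GMRF1,
#'   GMRF2, HSMRF1, HSMRF2}
#' @slot hyperparams named list of fixed hyperparameter overrides
#' @slot orientation \code{"present"} (Markov chain of the sequential priors
#'   anchored at the most recent interval, running backward in time) or
#'   \code{"past"}
#' @slot estimateScale logical; for GMRF/HSMRF, sample the global scale under
#'   a half-Cauchy hyperprior instead of fixing it
#'
#' @seealso [priorSpec()], [logPriorDensity()], [samplePrior()]
#' @export
setClass("PriorSpec",
  representation(
    family = "character",
    hyperparams = "list",
    orientation = "character",
    estimateScale = "logical"
  ),
  prototype(family = "GMRF1", hyperparams = list(),
            orientation = "present", estimateScale = FALSE)
)

setValidity("PriorSpec", function(object) {
  msg <- character()
  if (!(object@family %in% .PRIOR_FAMILIES))
    msg <- c(msg, sprintf("unknown prior family '%s'", object@family))
  if (!(object@orientation %in% c("present", "past")))
    msg <- c(msg, "orientation must be 'present' or 'past'")
  hp <- object@hyperparams
  if ("beta" %in% names(hp) && (hp$beta <= 0 || hp$beta >= 1))
    msg <- c(msg, "RJ equality probability beta must lie in (0, 1)")
  if ("groups" %in% names(hp) && hp$groups < 1)
    msg <- c(msg, "group count must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MCMCConfig class
#'
#' Settings for the Metropolis-within-Gibbs sampler.  One iteration is one
#' sweep: one proposal per free scalar parameter, plus one joint up-down
#' scaling move and one discrete move (group-boundary shift or
#' reversible-jump toggle) where the prior family has them.
#'
#' @slot iterations number of sweeps (default 500000)
#' @slot replicates number of independent replicate runs (default 4)
#' @slot burninFraction fraction of iterations discarded (in [0, 0.5])
#' @slot thin thinning interval; \code{NA} selects a value retaining about
#'   2000 samples per replicate
#' @slot seed integer RNG seed
#' @slot tuningWindow proposals per adaptation batch during burn-in
#'
#' @seealso [mcmcConfig()], [runMCMC()]
#' @export
setClass("MCMCConfig",
  representation(
    iterations = "integer",
    replicates = "integer",
    burninFraction = "numeric",
    thin = "integer",
    seed = "integer",
    tuningWindow = "integer"
  ),
  prototype(iterations = 500000L, replicates = 4L, burninFraction = 0.1,
            thin = NA_integer_, seed = 1L, tuningWindow = 50L)
)

setValidity("MCMCConfig", function(object) {
  msg <- character()
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (object@burninFraction < 0 || object@burninFraction > 0.5)
    msg <- c(msg, "burninFraction must lie in [0, 0.5]")
  if (!is.na(object@thin) && object@thin < 1L)
    msg <- c(msg, "thin must be >= 1")
  if (length(msg)) msg else TRUE
})

#' PosteriorTrace class
#'
#' Retained MCMC samples: per row the theta vector (columns
#' \code{theta_2..theta_n}), sampled hyperparameters, log-likelihood,
#' log-prior and log-posterior, with replicate id and iteration index.  The
#' matching conditioned site-class probability vectors are stored alongside
#' so the leave-one-out cross-validation score can be computed posthoc
#' without re-evaluating the model.
#'
#' @slot samples data.frame of retained samples
#' @slot probs numeric matrix, one row per retained sample, of conditioned
#'   site-class probabilities (columns named by frequency class)
#' @slot probClasses character labels of the modelled classes
#' @slot n haploid sample size
#' @slot folded logical
#' @slot conditioning conditioning scheme used by the likelihood
#' @slot p0Method monomorphic-probability derivation used
#' @slot family prior family sampled
#' @slot seed seed of the run
#'
#' @seealso [runMCMC()], [lpcv()], [summarizeTrajectories()]
#' @export
setClass("PosteriorTrace",
  representation(
    samples = "data.frame",
    probs = "matrix",
    probClasses = "character",
    n = "integer",
    folded = "logical",
    conditioning = "character",
    p0Method = "character",
    family = "character",
    seed = "integer"
  )
)

setValidity("PosteriorTrace", function(object) {
  msg <- character()
  if (nrow(object@samples) != nrow(object@probs))
    msg <- c(msg, "samples and probs must have the same number of rows")
  if (ncol(object@probs) != length(object@probClasses))
    msg <- c(msg, "probs columns must match probClasses")
  if (length(msg)) msg else TRUE
})

#' DemographicTrajectory class
#'
#' Posterior summary of the effective-population-size step function on a
#' plotting grid: per grid time the posterior median and the 2.5%/97.5%
#' quantiles.
#'
#' @slot time grid of times before present (increasing)
#' @slot median,lower,upper per-grid-point posterior summaries of N_e
#' @slot timeUnit \code{"substitutions"}, \code{"generations"} or
#'   \code{"years"}
#' @slot mu per-site per-generation mutation rate used (NA if none)
#'
#' @seealso [summarizeTrajectories()]
#' @export
setClass("DemographicTrajectory",
  representation(
    time = "numeric",
    median = "numeric",
    lower = "numeric",
    upper = "numeric",
    timeUnit = "character",
    mu = "numeric"
  )
)

setValidity("DemographicTrajectory", function(object) {
  k <- length(object@time)
  if (length(object@median) != k || length(object@lower) != k ||
      length(object@upper) != k)
    return("time, median, lower and upper must have equal length")
  if (any(diff(object@time) <= 0))
    return("grid times must be strictly increasing")
  TRUE
})

#' DemographicScenario class
#'
#' A synthetic-data scenario: a continuous-time effective population size
#' history N(t) (t in generations before present), a per-site mutation rate,
#' a haploid sample size and a total sequence length.  The shipped scenario
#' names mirror standard single-population simulation settings: constant
#' size, two-epoch change, exponential growth (with or without an older
#' constant phase), a multi-epoch complex expansion, and a bottleneck.
#'
#' @slot name scenario name
#' @slot params named list of sizes (diploid N_e) and change times
#'   (generations)
#' @slot mu per-site per-generation mutation rate (default 1.2e-8)
#' @slot n haploid sample size
#' @slot l total number of sites
#'
#' @seealso [demographicScenario()], [scenarioToTheta()], [simulateSFS()]
#' @export
setClass("DemographicScenario",
  representation(
    name = "character",
    params = "list",
    mu = "numeric",
    n = "integer",
    l = "numeric"
  )
)

setValidity("DemographicScenario", function(object) {
  msg <- character()
  if (object@mu <= 0) msg <- c(msg, "mu must be positive")
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@l < 0) msg <- c(msg, "l must be non-negative")
  num <- unlist(object@params[vapply(object@params, is.numeric, logical(1))])
  if (length(num) && any(num <= 0))
    msg <- c(msg, "scenario sizes and times must be positive")
  if (length(msg)) msg else TRUE
})

#' LPCVResult class
#'
#' Leave-one-out cross-validation score of one fitted model, with the
#' per-frequency-class contributions that sum to it.
#'
#' @slot score total LPCV score (log scale)
#' @slot perClass named vector of per-class contributions
#' @slot perReplicate per-replicate scores (stability diagnostic)
#' @slot K number of MCMC samples used
#' @slot model model identifier (prior family by default)
#' @slot conditioning conditioning under which probabilities were stored
#' @slot sfsFingerprint digest of the spectrum scored against
#'
#' @seealso [lpcv()], [selectBest()]
#' @export
setClass("LPCVResult",
  representation(
    score = "numeric",
    perClass = "numeric",
    perReplicate = "numeric",
    K = "integer",
    model = "character",
    conditioning = "character",
    sfsFingerprint = "character"
  )
)
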