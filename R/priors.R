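# The nine prior models on the per-interval theta vector.
#
# The sequential families (BSP, RJ, GMRF, HSMRF) are defined along a chain
# of intervals.  With orientation "present" (default) the chain is anchored
# at the most recent interval (k = n) and runs backward in time, matching
# the skyline-plot convention of present-anchored trajectories; "past"
# anchors at the oldest interval (k = 2).

#' Lognormal standard deviation spanning a given number of orders of magnitude
#'
#' The standard deviation sigma for which the central 95% interval of a
#' lognormal distribution spans \code{10^orders}:
#' \eqn{\sigma = \ln(10^{orders}) / (2 z_{0.975})}.  For one order of
#' magnitude this is H = 0.587405, used throughout as the unit of prior
#' variation on log population sizes.
#'
#' @param orders orders of magnitude spanned by the central 95% interval
#' @return the standard deviation
#' @examples
#' lognormalIntervalSD()  # 0.587405
#' @export
lognormalIntervalSD <- function(orders = 1) {
  log(10^orders) / (2 * qnorm(0.975))
}

#' Default number of Bayesian-skyline groups
#'
#' b = round(2m / 4) for m diploid individuals (i.e. on average four
#' coalescent intervals per group), floored at one group.  Uses R's
#' round-half-even rounding; seed-independent.
#'
#' @param m number of diploid individuals
#' @return integer group count
#' @examples
#' defaultGroupCount(20)  # 10
#' @export
defaultGroupCount <- function(m) {
  stopifnot(m >= 1)
  max(1L, as.integer(round(2 * m / 4)))
}

#' Construct a prior specification
#'
#' @param family one of \code{"IID_UNIFORM"}, \code{"UCLN"}, \code{"IGR"},
#'   \code{"BSP_GROUPED"}, \code{"RJ"}, \code{"GMRF1"}, \code{"GMRF2"},
#'   \code{"HSMRF1"}, \code{"HSMRF2"}
#' @param ... named hyperparameter overrides: \code{thetaMax} (uniform upper
#'   bound, default 0.1), \code{logunifMin}/\code{logunifMax} (loguniform
#'   bounds, default 1e-10 and 1), \code{sigmaMean} (UCLN exponential mean,
#'   default 3H), \code{vMean} (IGR exponential mean, default 0.01),
#'   \code{groups} (BSP group count, default round(n/4)), \code{beta} (RJ
#'   equality probability, default 0.5), \code{xi} (GMRF global scale,
#'   default H/sqrt(n-2) so the prior 95% interval of the end-to-end
#'   log-size ratio spans one order of magnitude), \code{gamma} (HSMRF
#'   global scale, default 0.021)
#' @param orientation \code{"present"} or \code{"past"} chain anchoring
#' @param estimateScale for GMRF/HSMRF, sample the global scale under a
#'   half-Cauchy hyperprior centred on the fixed default instead of fixing it
#' @return a [PriorSpec-class]
#' @examples
#' priorSpec("GMRF1")
#' priorSpec("RJ", beta = 0.3)
#' @export
priorSpec <- function(family, ..., orientation = "present",
                      estimateScale = FALSE) {
  family <- match.arg(family, .PRIOR_FAMILIES)
  new("PriorSpec", family = family, hyperparams = list(...),
      orientation = orientation, estimateScale = estimateScale)
}

#' Resolve prior hyperparameters at a given sample size
#'
#' Fills family defaults for hyperparameters not overridden in the spec.
#'
#' @param spec a [PriorSpec-class]
#' @param n haploid sample size
#' @return named list of concrete hyperparameter values
#' @export
resolvePrior <- function(spec, n) {
  stopifnot(is(spec, "PriorSpec"), n >= 2)
  H <- lognormalIntervalSD()
  hp <- spec@hyperparams
  pick <- function(name, default) if (!is.null(hp[[name]])) hp[[name]] else default
  out <- list(
    family = spec@family,
    n = as.integer(n),
    orientation = spec@orientation,
    estimateScale = spec@estimateScale,
    thetaMax = pick("thetaMax", 0.1),
    logunifMin = pick("logunifMin", 1e-10),
    logunifMax = pick("logunifMax", 1),
    sigmaMean = pick("sigmaMean", 3 * H),
    vMean = pick("vMean", 0.01),
    beta = pick("beta", 0.5),
    groups = as.integer(pick("groups", defaultGroupCount(n / 2))),
    xi = pick("xi", if (n > 2L) H / sqrt(n - 2) else H),
    gamma = pick("gamma", 0.021)
  )
  if (out$groups > n - 1L) stop("more groups than coalescent intervals")
  out
}

.toChain <- function(theta, orientation) {
  if (orientation == "present") rev(theta) else theta
}
.fromChain <- function(w, orientation) {
  if (orientation == "present") rev(w) else w
}

.dlogunif <- function(x, a, b) {
  ifelse(x >= a & x <= b, -log(x) - log(log(b / a)), -Inf)
}
.rlogunif <- function(k, a, b) exp(runif(k, log(a), log(b)))
.dhalfcauchy <- function(x, scale = 1) {
  ifelse(x > 0, log(2) - log(pi) - log(scale) - log1p((x / scale)^2), -Inf)
}
.rhalfcauchy <- function(k, scale = 1) abs(rcauchy(k, 0, scale))

# log of a Gamma(shape, rate) draw, exact for arbitrarily small shape via
# Gamma(a) = Gamma(a + 1) * U^(1/a); plain rgamma would underflow to 0
.rloggamma <- function(k, shape, rate) {
  log(rgamma(k, shape + 1, rate)) + log(runif(k)) / shape
}

# log-density of the flat (offset-1) multinomial on group sizes
.dGroupSizes <- function(sizes, b, nIntervals) {
  if (length(sizes) != b || any(sizes < 1) || sum(sizes) != nIntervals)
    return(-Inf)
  extra <- nIntervals - b
  lgamma(extra + 1) - sum(lgamma(sizes - 1 + 1)) + extra * log(1 / b)
}

#' Joint log prior density of a state
#'
#' Evaluates the joint log-density of the theta vector and the family's
#' sampled hyperparameters.  A state is a list with elements \code{theta}
#' (oldest-first, k = 2..n) and \code{hypers} (family-specific: UCLN
#' \code{mu}/\code{sigma}; IGR \code{m}/\code{v}; BSP \code{sizes}/
#' \code{values}; RJ \code{eq} equality indicators; HSMRF
#' \code{localScales}; optionally \code{globalScale}).  Returns \code{-Inf}
#' outside the support (e.g. theta above the uniform bound).
#'
#' @param spec a [PriorSpec-class]
#' @param state list with \code{theta} and \code{hypers}
#' @param n haploid sample size (default inferred from theta)
#' @return scalar log density
#' @export
logPriorDensity <- function(spec, state, n = length(state$theta) + 1L) {
  rp <- resolvePrior(spec, n)
  .priorLogDensity(rp, state)
}

.priorLogDensity <- function(rp, state) {
  theta <- state$theta
  hy <- state$hypers
  nInt <- rp$n - 1L
  if (length(theta) != nInt) stop("theta length must be n-1")
  if (is.null(state$lt)) {
    if (any(theta <= 0) || any(!is.finite(theta))) return(-Inf)
  } else if (any(!is.finite(state$lt))) {
    return(-Inf)  # log coordinates: theta itself may underflow to 0
  }
  tmax <- rp$thetaMax
  fam <- rp$family
  scaleTerm <- 0
  if (rp$estimateScale && fam %in% c("GMRF1", "GMRF2", "HSMRF1", "HSMRF2")) {
    gs <- hy$globalScale
    if (is.null(gs) || gs <= 0) return(-Inf)
    centre <- if (fam %in% c("GMRF1", "GMRF2")) rp$xi else rp$gamma
    scaleTerm <- .dhalfcauchy(gs, centre)
    if (fam %in% c("GMRF1", "GMRF2")) rp$xi <- gs else rp$gamma <- gs
  }

  if (fam == "IID_UNIFORM") {
    if (any(theta >= tmax)) return(-Inf)
    return(nInt * log(1 / tmax))
  }
  if (fam == "UCLN") {
    mu <- hy$mu; sigma <- hy$sigma
    if (is.null(mu) || is.null(sigma) || sigma <= 0) return(-Inf)
    lm <- .dlogunif(mu, rp$logunifMin, rp$logunifMax)
    if (!is.finite(lm)) return(-Inf)
    return(lm + dexp(sigma, 1 / rp$sigmaMean, log = TRUE) +
           sum(dlnorm(theta, log(mu), sigma, log = TRUE)))
  }
  if (fam == "IGR") {
    m <- hy$m; v <- hy$v
    if (is.null(m) || is.null(v) || v <= 0) return(-Inf)
    lm <- .dlogunif(m, rp$logunifMin, rp$logunifMax)
    if (!is.finite(lm)) return(-Inf)
    base <- lm + dexp(v, 1 / rp$vMean, log = TRUE)
    if (!is.null(state$lt)) {
      # log-theta coordinates (used by the sampler): the gamma shape m^2/v
      # can be so small that almost all theta mass lies below the smallest
      # positive double, so the chain walks in log space where that mass is
      # representable; density includes the exp Jacobian
      k <- m^2 / v; r <- m / v
      return(base + sum(k * state$lt - r * exp(state$lt)) +
             length(state$lt) * (k * log(r) - lgamma(k)))
    }
    return(base + sum(dgamma(theta, shape = m^2 / v, rate = m / v,
                             log = TRUE)))
  }
  if (fam == "BSP_GROUPED") {
    sizes <- hy$sizes; values <- hy$values
    if (is.null(sizes) || is.null(values)) return(-Inf)
    ld <- .dGroupSizes(sizes, rp$groups, nInt)
    if (!is.finite(ld)) return(-Inf)
    if (any(values <= 0)) return(-Inf)
    if (values[[1L]] >= tmax) return(-Inf)
    ld <- ld + log(1 / tmax)
    if (length(values) > 1L) {
      prev <- values[-length(values)]
      ld <- ld + sum(dexp(values[-1L], 1 / prev, log = TRUE))
    }
    # theta must be the expansion of the groups along the chain
    w <- rep(values, times = sizes)
    if (!isTRUE(all.equal(.toChain(theta, rp$orientation), w,
                          tolerance = 1e-12)))
      return(-Inf)
    return(ld)
  }
  if (fam == "RJ") {
    eq <- hy$eq
    if (is.null(eq) || length(eq) != nInt - 1L) return(-Inf)
    w <- .toChain(theta, rp$orientation)
    if (any(w >= tmax)) return(-Inf)
    ld <- log(1 / tmax)
    for (j in seq_len(nInt - 1L)) {
      if (eq[[j]]) {
        if (w[[j + 1L]] != w[[j]]) return(-Inf)
        ld <- ld + log(rp$beta)
      } else {
        ld <- ld + log(1 - rp$beta) + log(1 / tmax)
      }
    }
    return(ld)
  }
  # Markov random fields on log theta.  Each non-anchor value has a
  # lognormal-type conditional: the density over theta therefore carries the
  # change-of-variables term -log(theta) for every non-anchor position.
  w <- .toChain(theta, rp$orientation)
  if (w[[1L]] >= tmax) return(-Inf)
  ld <- log(1 / tmax) + scaleTerm - sum(log(w[-1L]))
  lw <- log(w)
  d <- diff(lw)
  if (fam == "GMRF1") {
    return(ld + sum(dnorm(d, 0, rp$xi, log = TRUE)))
  }
  if (fam == "GMRF2") {
    if (length(d) >= 1L) ld <- ld + dnorm(d[[1L]], 0, rp$xi, log = TRUE)
    if (length(d) >= 2L)
      ld <- ld + sum(dnorm(diff(d), 0, rp$xi, log = TRUE))
    return(ld)
  }
  ls <- hy$localScales
  if (is.null(ls) || length(ls) != length(d) || any(ls <= 0)) return(-Inf)
  ld <- ld + sum(.dhalfcauchy(ls, 1))
  if (fam == "HSMRF1") {
    return(ld + sum(dnorm(d, 0, rp$gamma * ls, log = TRUE)))
  }
  if (fam == "HSMRF2") {
    ld <- ld + dnorm(d[[1L]], 0, rp$gamma * ls[[1L]], log = TRUE)
    if (length(d) >= 2L)
      ld <- ld + sum(dnorm(diff(d), 0, rp$gamma * ls[-1L], log = TRUE))
    return(ld)
  }
  stop("unknown prior family: ", fam)
}

#' Draw a state from a prior model
#'
#' Exact ancestral (generative) draw from the family's hierarchical
#' description; reproducible given \code{seed}.  With \code{seed = NULL} the
#' current RNG stream is used (and advanced), which is how the MCMC
#' initialisation calls it.
#'
#' @param spec a [PriorSpec-class]
#' @param n haploid sample size
#' @param seed optional integer seed
#' @return a state list with \code{theta} (oldest-first) and \code{hypers}
#' @export
samplePrior <- function(spec, n, seed = NULL) {
  rp <- resolvePrior(spec, n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  .priorSample(rp)
}

.priorSample <- function(rp) {
  nInt <- rp$n - 1L
  fam <- rp$family
  tmax <- rp$thetaMax
  hypers <- list()
  if (rp$estimateScale && fam %in% c("GMRF1", "GMRF2", "HSMRF1", "HSMRF2")) {
    centre <- if (fam %in% c("GMRF1", "GMRF2")) rp$xi else rp$gamma
    hypers$globalScale <- .rhalfcauchy(1L, centre)
    if (fam %in% c("GMRF1", "GMRF2")) rp$xi <- hypers$globalScale
    else rp$gamma <- hypers$globalScale
  }
  if (fam == "IID_UNIFORM") {
    theta <- runif(nInt, 0, tmax)
    return(list(theta = theta, hypers = hypers))
  }
  if (fam == "UCLN") {
    hypers$mu <- .rlogunif(1L, rp$logunifMin, rp$logunifMax)
    hypers$sigma <- rexp(1L, 1 / rp$sigmaMean)
    theta <- rlnorm(nInt, log(hypers$mu), hypers$sigma)
    return(list(theta = theta, hypers = hypers))
  }
  if (fam == "IGR") {
    hypers$m <- .rlogunif(1L, rp$logunifMin, rp$logunifMax)
    hypers$v <- rexp(1L, 1 / rp$vMean)
    lt <- .rloggamma(nInt, shape = hypers$m^2 / hypers$v,
                     rate = hypers$m / hypers$v)
    return(list(theta = exp(lt), hypers = hypers, lt = lt))
  }
  if (fam == "BSP_GROUPED") {
    b <- rp$groups
    hypers$sizes <- as.integer(
      1L + rmultinom(1L, nInt - b, rep(1 / b, b))[, 1L])
    values <- numeric(b)
    values[[1L]] <- runif(1L, 0, tmax)
    for (j in seq_len(b - 1L))
      values[[j + 1L]] <- rexp(1L, 1 / values[[j]])
    hypers$values <- values
    w <- rep(values, times = hypers$sizes)
    return(list(theta = .fromChain(w, rp$orientation), hypers = hypers))
  }
  if (fam == "RJ") {
    w <- numeric(nInt)
    w[[1L]] <- runif(1L, 0, tmax)
    eq <- runif(nInt - 1L) < rp$beta
    for (j in seq_len(nInt - 1L))
      w[[j + 1L]] <- if (eq[[j]]) w[[j]] else runif(1L, 0, tmax)
    hypers$eq <- eq
    return(list(theta = .fromChain(w, rp$orientation), hypers = hypers))
  }
  # Markov random fields
  lw <- numeric(nInt)
  lw[[1L]] <- log(runif(1L, 0, tmax))
  if (fam %in% c("HSMRF1", "HSMRF2")) {
    hypers$localScales <- .rhalfcauchy(max(0L, nInt - 1L), 1)
  }
  sdStep <- function(j) {
    if (fam %in% c("GMRF1", "GMRF2")) rp$xi
    else rp$gamma * hypers$localScales[[j]]
  }
  order2 <- fam %in% c("GMRF2", "HSMRF2")
  for (j in seq_len(nInt - 1L)) {
    mean_j <- if (order2 && j >= 2L) 2 * lw[[j]] - lw[[j - 1L]] else lw[[j]]
    lw[[j + 1L]] <- rnorm(1L, mean_j, sdStep(j))
  }
  list(theta = .fromChain(exp(lw), rp$orientation), hypers = hypers)
}
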