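# Metropolis-within-Gibbs sampler over the prior state given the composite
# likelihood.  One iteration is one sweep: a multiplier proposal for every
# free scalar parameter, a joint up-down scaling of theta, and the family's
# discrete moves (group-boundary shifts for BSP, equality toggles for RJ).
# Multiplier tuning targets 0.44 acceptance for single-parameter moves and
# 0.23 for joint moves, adapting only during burn-in.

#' MCMC configuration
#'
#' @param iterations number of sweeps (default 500000)
#' @param replicates number of replicate runs for convergence checking
#'   (default 4)
#' @param burninFraction fraction discarded as burn-in (default 0.1)
#' @param thin thinning interval; \code{NA} (default) retains about 2000
#'   samples per replicate
#' @param seed integer RNG seed; replicate r uses seed + r - 1
#' @param tuningWindow proposals per adaptation batch during burn-in
#' @return an [MCMCConfig-class]
#' @export
mcmcConfig <- function(iterations = 500000L, replicates = 4L,
                       burninFraction = 0.1, thin = NA, seed = 1L,
                       tuningWindow = 50L) {
  new("MCMCConfig", iterations = as.integer(iterations),
      replicates = as.integer(replicates),
      burninFraction = as.numeric(burninFraction),
      thin = as.integer(thin), seed = as.integer(seed),
      tuningWindow = as.integer(tuningWindow))
}

.newMove <- function(type, idx = NA_integer_, lambda = 1, target = 0.44,
                     tunable = TRUE) {
  e <- new.env(parent = emptyenv())
  e$type <- type; e$idx <- idx; e$lambda <- lambda; e$target <- target
  e$tunable <- tunable; e$nTry <- 0L; e$nAcc <- 0L; e$batch <- 0L
  e
}

.moveSchedule <- function(rp) {
  nInt <- rp$n - 1L
  fam <- rp$family
  moves <- list()
  add <- function(m) moves[[length(moves) + 1L]] <<- m
  if (fam == "BSP_GROUPED") {
    for (j in seq_len(rp$groups)) add(.newMove("bspValue", j, lambda = 2))
    if (rp$groups > 1L) add(.newMove("bspBoundary", tunable = FALSE))
  } else if (fam == "RJ") {
    for (j in seq_len(nInt)) add(.newMove("rjValue", lambda = 2))
    for (j in seq_len(nInt - 1L)) add(.newMove("rjToggle", j, tunable = FALSE))
  } else {
    for (j in seq_len(nInt)) add(.newMove("thetaMult", j, lambda = 2))
  }
  if (fam %in% c("IID_UNIFORM", "UCLN", "IGR")) {
    # independence proposal from the conditional prior of theta_j given the
    # hyperparameters: Hastings cancels the prior, so acceptance is the
    # likelihood ratio alone (exact Gibbs under zero data)
    for (j in seq_len(nInt)) add(.newMove("priorRedraw", j, tunable = FALSE))
  }
  if (fam == "UCLN") {
    add(.newMove("hyperMult", idx = 1L, lambda = 2))  # mu
    add(.newMove("hyperMult", idx = 2L, lambda = 2))  # sigma
    add(.newMove("upDown", lambda = 1, target = 0.23))
  }
  if (fam == "IGR") {
    add(.newMove("hyperMult", idx = 1L, lambda = 2))  # m
    add(.newMove("hyperMult", idx = 2L, lambda = 2))  # v
    add(.newMove("upDown", lambda = 1, target = 0.23))
  }
  if (fam %in% c("GMRF1", "GMRF2", "HSMRF1", "HSMRF2")) {
    # block-scale the chain from a position to its end: changes a single
    # random-field increment, so the far end of the chain mixes freely
    for (j in 2:nInt) add(.newMove("tailScale", j, lambda = 1))
  }
  if (fam %in% c("HSMRF1", "HSMRF2")) {
    for (j in seq_len(nInt - 1L)) add(.newMove("localScale", j, lambda = 3))
  }
  if (rp$estimateScale && fam %in% c("GMRF1", "GMRF2", "HSMRF1", "HSMRF2"))
    add(.newMove("globalScale", lambda = 2))
  add(.newMove("jointScale", lambda = 1, target = 0.23))
  # independence proposal of the whole state from the prior's generative
  # process: the prior cancels in the Metropolis-Hastings ratio, so the
  # acceptance probability is the bare likelihood ratio.  Rarely accepted
  # in data-rich runs but guarantees irreducibility across the full prior
  # support (hyperparameter funnels included).
  add(.newMove("priorRefresh", tunable = FALSE))
  moves
}

.multFactor <- function(lambda) exp(lambda * (runif(1L) - 0.5))

# Propose from a move; returns list(state, lhr) or NULL for an
# out-of-support proposal (counted as a rejection).
.propose <- function(move, state, rp) {
  type <- move$type
  nInt <- rp$n - 1L
  lt <- !is.null(state$lt)  # IGR walks in log-theta coordinates
  if (type == "thetaMult") {
    f <- .multFactor(move$lambda)
    if (lt) {
      state$lt[[move$idx]] <- state$lt[[move$idx]] + log(f)
      state$theta[[move$idx]] <- exp(state$lt[[move$idx]])
      return(list(state = state, lhr = 0))  # additive walk is symmetric
    }
    state$theta[[move$idx]] <- state$theta[[move$idx]] * f
    return(list(state = state, lhr = log(f)))
  }
  if (type == "jointScale") {
    f <- .multFactor(move$lambda)
    if (lt) {
      state$lt <- state$lt + log(f)
      state$theta <- exp(state$lt)
      return(list(state = state, lhr = 0))
    }
    state$theta <- state$theta * f
    d <- nInt
    if (rp$family == "BSP_GROUPED") {
      state$hypers$values <- state$hypers$values * f
      d <- rp$groups
    } else if (rp$family == "RJ") {
      d <- 1L + sum(!state$hypers$eq)
    }
    return(list(state = state, lhr = d * log(f)))
  }
  if (type == "upDown") {
    f <- .multFactor(move$lambda)
    nm <- if (rp$family == "UCLN") "mu" else "m"
    state$hypers[[nm]] <- state$hypers[[nm]] * f
    if (lt) {
      state$lt <- state$lt + log(f)
      state$theta <- exp(state$lt)
      return(list(state = state, lhr = log(f)))
    }
    state$theta <- state$theta * f
    return(list(state = state, lhr = (nInt + 1L) * log(f)))
  }
  if (type == "hyperMult") {
    nm <- if (rp$family == "UCLN") c("mu", "sigma")[[move$idx]]
          else c("m", "v")[[move$idx]]
    f <- .multFactor(move$lambda)
    state$hypers[[nm]] <- state$hypers[[nm]] * f
    return(list(state = state, lhr = log(f)))
  }
  if (type == "priorRefresh") {
    newState <- .priorSample(rp)
    lhr <- .priorLogDensity(rp, state) - .priorLogDensity(rp, newState)
    if (!is.finite(lhr)) return(NULL)
    return(list(state = newState, lhr = lhr))
  }
  if (type == "priorRedraw") {
    j <- move$idx
    hy <- state$hypers
    if (lt) {  # IGR: exact conditional draw in log space
      k <- hy$m^2 / hy$v; r <- hy$m / hy$v
      old <- state$lt[[j]]
      new <- .rloggamma(1L, k, r)
      if (!is.finite(new)) return(NULL)
      state$lt[[j]] <- new
      state$theta[[j]] <- exp(new)
      lhr <- (k * old - r * exp(old)) - (k * new - r * exp(new))
      if (!is.finite(lhr)) return(NULL)
      return(list(state = state, lhr = lhr))
    }
    old <- state$theta[[j]]
    new <- switch(rp$family,
      IID_UNIFORM = runif(1L, 0, rp$thetaMax),
      UCLN = rlnorm(1L, log(hy$mu), hy$sigma))
    if (!is.finite(new) || new <= 0) return(NULL)
    state$theta[[j]] <- new
    lhr <- switch(rp$family,
      IID_UNIFORM = 0,
      UCLN = dlnorm(old, log(hy$mu), hy$sigma, log = TRUE) -
             dlnorm(new, log(hy$mu), hy$sigma, log = TRUE))
    if (!is.finite(lhr)) return(NULL)
    return(list(state = state, lhr = lhr))
  }
  if (type == "tailScale") {
    f <- .multFactor(move$lambda)
    w <- .toChain(state$theta, rp$orientation)
    idx <- move$idx:nInt
    w[idx] <- w[idx] * f
    state$theta <- .fromChain(w, rp$orientation)
    return(list(state = state, lhr = length(idx) * log(f)))
  }
  if (type == "localScale") {
    f <- .multFactor(move$lambda)
    state$hypers$localScales[[move$idx]] <-
      state$hypers$localScales[[move$idx]] * f
    return(list(state = state, lhr = log(f)))
  }
  if (type == "globalScale") {
    f <- .multFactor(move$lambda)
    state$hypers$globalScale <- state$hypers$globalScale * f
    return(list(state = state, lhr = log(f)))
  }
  if (type == "bspValue") {
    f <- .multFactor(move$lambda)
    state$hypers$values[[move$idx]] <- state$hypers$values[[move$idx]] * f
    state$theta <- .fromChain(
      rep(state$hypers$values, times = state$hypers$sizes), rp$orientation)
    return(list(state = state, lhr = log(f)))
  }
  if (type == "bspBoundary") {
    b <- rp$groups
    j <- sample.int(b - 1L, 1L)
    delta <- if (runif(1L) < 0.5) 1L else -1L
    s <- state$hypers$sizes
    s[[j]] <- s[[j]] + delta
    s[[j + 1L]] <- s[[j + 1L]] - delta
    if (s[[j]] < 1L || s[[j + 1L]] < 1L) return(NULL)
    state$hypers$sizes <- s
    state$theta <- .fromChain(rep(state$hypers$values, times = s),
                              rp$orientation)
    return(list(state = state, lhr = 0))
  }
  if (type == "rjValue") {
    w <- .toChain(state$theta, rp$orientation)
    eq <- state$hypers$eq
    free <- c(1L, which(!eq) + 1L)
    pos <- free[[sample.int(length(free), 1L)]]
    f <- .multFactor(move$lambda)
    w[[pos]] <- w[[pos]] * f
    w <- .rjPropagate(w, eq, pos)
    state$theta <- .fromChain(w, rp$orientation)
    return(list(state = state, lhr = log(f)))
  }
  if (type == "rjToggle") {
    j <- move$idx  # indicator for chain position j+1
    w <- .toChain(state$theta, rp$orientation)
    eq <- state$hypers$eq
    if (eq[[j]]) {
      eq[[j]] <- FALSE
      w[[j + 1L]] <- runif(1L, 0, rp$thetaMax)
      lhr <- log(rp$thetaMax)     # reverse (merge) is deterministic
    } else {
      eq[[j]] <- TRUE
      w[[j + 1L]] <- w[[j]]
      lhr <- -log(rp$thetaMax)    # reverse must redraw the abandoned value
    }
    w <- .rjPropagate(w, eq, j + 1L)
    state$hypers$eq <- eq
    state$theta <- .fromChain(w, rp$orientation)
    return(list(state = state, lhr = lhr))
  }
  stop("unknown move type: ", type)
}

# propagate a changed leader value through the following run of equalities
.rjPropagate <- function(w, eq, pos) {
  j <- pos
  while (j <= length(eq) && eq[[j]]) {
    w[[j + 1L]] <- w[[j]]
    j <- j + 1L
  }
  w
}

.tuneMove <- function(move, window) {
  move$batch <- move$batch + 1L
  acc <- move$nAcc / move$nTry
  delta <- min(0.25, 1 / sqrt(move$batch))
  move$lambda <- move$lambda * exp(if (acc > move$target) delta else -delta)
  move$lambda <- min(max(move$lambda, 1e-3), 20)
  move$nTry <- 0L; move$nAcc <- 0L
  invisible(move)
}

.fallbackState <- function(rp, thetaHat) {
  nInt <- rp$n - 1L
  th <- min(max(thetaHat, 1e-8), 0.9 * rp$thetaMax)
  theta <- rep(th, nInt)
  hypers <- list()
  fam <- rp$family
  if (rp$estimateScale && fam %in% c("GMRF1", "GMRF2", "HSMRF1", "HSMRF2"))
    hypers$globalScale <- if (fam %in% c("GMRF1", "GMRF2")) rp$xi else rp$gamma
  if (fam == "UCLN") {
    hypers$mu <- min(max(th, rp$logunifMin), rp$logunifMax)
    hypers$sigma <- rp$sigmaMean
  } else if (fam == "IGR") {
    hypers$m <- min(max(th, rp$logunifMin), rp$logunifMax)
    hypers$v <- rp$vMean
    return(list(theta = theta, hypers = hypers, lt = log(theta)))
  } else if (fam == "BSP_GROUPED") {
    b <- rp$groups
    base <- nInt %/% b
    sizes <- rep(base, b)
    extra <- nInt - base * b
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    hypers$sizes <- as.integer(sizes)
    hypers$values <- rep(th, b)
  } else if (fam == "RJ") {
    hypers$eq <- rep(FALSE, nInt - 1L)
  } else if (fam %in% c("HSMRF1", "HSMRF2")) {
    hypers$localScales <- rep(1, max(0L, nInt - 1L))
  }
  list(theta = theta, hypers = hypers)
}

.hyperColumns <- function(rp) {
  fam <- rp$family
  nInt <- rp$n - 1L
  cols <- character()
  if (fam == "UCLN") cols <- c("mu", "sigma")
  if (fam == "IGR") cols <- c("m", "v")
  if (fam == "BSP_GROUPED")
    cols <- c(paste0("groupSize_", seq_len(rp$groups)),
              paste0("groupValue_", seq_len(rp$groups)))
  if (fam == "RJ") cols <- "nGroups"
  if (fam %in% c("HSMRF1", "HSMRF2"))
    cols <- paste0("localScale_", seq_len(max(0L, nInt - 1L)))
  if (rp$estimateScale && fam %in% c("GMRF1", "GMRF2", "HSMRF1", "HSMRF2"))
    cols <- c(cols, "globalScale")
  cols
}

.hyperRow <- function(rp, state) {
  fam <- rp$family
  hy <- state$hypers
  out <- numeric()
  if (fam == "UCLN") out <- c(hy$mu, hy$sigma)
  if (fam == "IGR") out <- c(hy$m, hy$v)
  if (fam == "BSP_GROUPED") out <- c(hy$sizes, hy$values)
  if (fam == "RJ") out <- 1 + sum(!hy$eq)
  if (fam %in% c("HSMRF1", "HSMRF2")) out <- hy$localScales
  if (!is.null(hy$globalScale)) out <- c(out, hy$globalScale)
  out
}

#' Run the stairway-plot MCMC
#'
#' Samples the posterior of the per-interval theta vector (and the prior
#' family's hyperparameters) given a site frequency spectrum, by
#' Metropolis-within-Gibbs with auto-tuned multiplier moves, joint up-down
#' scaling, group-boundary shifts (BSP) and reversible-jump equality
#' toggles (RJ).  Replicate runs are kept separate in the trace (column
#' \code{run}) so convergence can be assessed.  Deterministic given the
#' seed in \code{mcmc}.
#'
#' When the spectrum carries no sites the likelihood is identically zero on
#' the log scale, so the sampler targets the prior exactly; this is the
#' standard prior-recovery validation of the sampling machinery.
#'
#' @param sfs a [SiteFrequencySpectrum-class]
#' @param prior a [PriorSpec-class]
#' @param likeConfig a [likelihoodConfig()] list
#' @param mcmc an [MCMCConfig-class] from [mcmcConfig()]
#' @return a [PosteriorTrace-class]
#' @examples
#' sfs <- siteFrequencySpectrum(c(60, 25, 14, 8, 5), n = 6,
#'                              monomorphicCount = 1e5)
#' tr <- runMCMC(sfs, priorSpec("IID_UNIFORM"),
#'               mcmc = mcmcConfig(iterations = 500, replicates = 1,
#'                                 seed = 7))
#' @export
runMCMC <- function(sfs, prior, likeConfig = likelihoodConfig(),
                    mcmc = mcmcConfig()) {
  stopifnot(is(sfs, "SiteFrequencySpectrum"), is(prior, "PriorSpec"),
            is(mcmc, "MCMCConfig"))
  n <- sfs@n
  rp <- resolvePrior(prior, n)
  frame <- .modelFrame(sfs, likeConfig)
  llFun <- .makeLogLik(frame)
  reps <- lapply(seq_len(mcmc@replicates), function(r) {
    set.seed(mcmc@seed + r - 1L)
    .runChain(rp, frame, llFun, mcmc, runId = r, sfs = sfs)
  })
  samples <- do.call(rbind, lapply(reps, `[[`, "samples"))
  probs <- do.call(rbind, lapply(reps, `[[`, "probs"))
  new("PosteriorTrace", samples = samples, probs = probs,
      probClasses = frame$classes, n = n, folded = sfs@folded,
      conditioning = frame$cond, p0Method = frame$p0Method,
      family = rp$family, seed = mcmc@seed)
}

.makeLogLik <- function(frame) {
  x <- frame$counts
  if (sum(x) == 0) return(function(theta) 0)
  const <- lgamma(sum(x) + 1) - sum(lgamma(x + 1))
  pos <- x > 0
  xp <- x[pos]
  function(theta) {
    p <- .condProbs(theta, frame)
    if (is.null(p)) return(-Inf)
    const + sum(xp * log(p[pos]))
  }
}

.initState <- function(rp, llFun, frame, sfs) {
  for (try in seq_len(1000L)) {
    st <- .priorSample(rp)
    lp <- .priorLogDensity(rp, st)
    if (is.finite(lp) && is.finite(llFun(st$theta))) return(st)
  }
  l <- totalSites(sfs)
  harm <- sum(1 / seq_len(rp$n - 1L))
  thetaHat <- if (!is.na(l) && l > 0) sum(sfs@counts) / (l * harm) else 1e-3
  st <- .fallbackState(rp, thetaHat)
  if (is.finite(.priorLogDensity(rp, st)) && is.finite(llFun(st$theta)))
    return(st)
  stop("could not find a valid starting state after 1000 prior draws; ",
       "the data may require a smaller starting theta (check the spectrum ",
       "scale and the prior support)")
}

.runChain <- function(rp, frame, llFun, mcmc, runId, sfs) {
  nIter <- mcmc@iterations
  burnin <- floor(nIter * mcmc@burninFraction)
  thin <- mcmc@thin
  if (is.na(thin)) thin <- max(1L, (nIter - burnin) %/% 2000L)
  window <- mcmc@tuningWindow

  state <- .initState(rp, llFun, frame, sfs)
  curLP <- .priorLogDensity(rp, state)
  curLL <- llFun(state$theta)
  moves <- .moveSchedule(rp)

  nInt <- rp$n - 1L
  hyperCols <- .hyperColumns(rp)
  keepIdx <- seq.int(burnin + thin, nIter, by = thin)
  nKeep <- length(keepIdx)
  thetaNames <- paste0("theta_", 2:rp$n)
  sampMat <- matrix(NA_real_, nKeep, 5L + nInt + length(hyperCols))
  colnames(sampMat) <- c("run", "iteration", "logPosterior", "logLikelihood",
                         "logPrior", thetaNames, hyperCols)
  probMat <- matrix(NA_real_, nKeep, length(frame$classes))
  colnames(probMat) <- paste0("p_", frame$classes)
  row <- 0L

  for (it in seq_len(nIter)) {
    for (mv in moves) {
      mv$nTry <- mv$nTry + 1L
      prop <- .propose(mv, state, rp)
      if (!is.null(prop)) {
        lp2 <- .priorLogDensity(rp, prop$state)
        if (is.finite(lp2)) {
          ll2 <- llFun(prop$state$theta)
          if (is.finite(ll2)) {
            a <- (lp2 + ll2) - (curLP + curLL) + prop$lhr
            if (a >= 0 || log(runif(1L)) < a) {
              state <- prop$state; curLP <- lp2; curLL <- ll2
              mv$nAcc <- mv$nAcc + 1L
            }
          }
        }
      }
      if (it <= burnin && mv$tunable && mv$nTry >= window)
        .tuneMove(mv, window)
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      row <- row + 1L
      p <- .condProbs(state$theta, frame)
      if (!is.null(p)) probMat[row, ] <- p
      sampMat[row, ] <- c(runId, it, curLP + curLL, curLL, curLP,
                          state$theta, .hyperRow(rp, state))
    }
  }
  list(samples = as.data.frame(sampMat[seq_len(row), , drop = FALSE]),
       probs = probMat[seq_len(row), , drop = FALSE])
}

setMethod("show", "PosteriorTrace", function(object) {
  runs <- unique(object@samples$run)
  cat(sprintf("PosteriorTrace: %d samples (%d replicate run%s), n = %d\n",
              nrow(object@samples), length(runs),
              if (length(runs) > 1) "s" else "", object@n))
  cat(sprintf("  prior: %s | conditioning: %s | p0: %s | %s\n",
              object@family, object@conditioning, object@p0Method,
              if (object@folded) "folded" else "unfolded"))
})

#' Write a posterior trace to a tab-separated file
#'
#' One header row; columns run, iteration, logPosterior, logLikelihood,
#' logPrior, theta_2..theta_n, hyperparameters, then the stored site-class
#' probabilities p_<class>.  Loadable by standard MCMC trace viewers.
#'
#' @param trace a [PosteriorTrace-class]
#' @param path output path
#' @param comment optional extra '#' comment line(s)
#' @return \code{path}, invisibly
#' @export
writeTrace <- function(trace, path, comment = NULL) {
  df <- cbind(trace@samples, as.data.frame(trace@probs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# stairbayes %s trace | prior=%s seed=%d",
                       as.character(utils::packageVersion("stairbayes")),
                       trace@family, trace@seed),
               if (!is.null(comment)) paste0("# ", comment)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace written by [writeTrace()]
#'
#' @param path file path
#' @param n haploid sample size of the spectrum the trace was sampled for
#' @param family prior family label
#' @param folded,conditioning,p0Method likelihood settings of the run
#' @return a [PosteriorTrace-class]
#' @export
readTrace <- function(path, n, family = "unknown", folded = FALSE,
                      conditioning = "none", p0Method = "complement") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  pCols <- grep("^p_", names(df))
  probs <- as.matrix(df[, pCols, drop = FALSE])
  new("PosteriorTrace", samples = df[, -pCols, drop = FALSE], probs = probs,
      probClasses = sub("^p_", "", names(df)[pCols]), n = as.integer(n),
      folded = folded, conditioning = conditioning, p0Method = p0Method,
      family = family, seed = NA_integer_)
}

# ---- convergence diagnostics ----

.essVector <- function(x) {
  N <- length(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    warning("degenerate (constant) trace; ESS reported as number of samples")
    return(as.numeric(N))
  }
  lagMax <- min(N - 1L, 2000L)
  rho <- as.vector(acf(x, lag.max = lagMax, plot = FALSE)$acf)[-1L]
  # Geyer initial monotone positive sequence on pair sums
  npair <- length(rho) %/% 2L
  if (npair < 1L) return(as.numeric(N))
  G <- rho[2 * seq_len(npair) - 1L] + rho[2 * seq_len(npair)]
  cut <- which(G <= 0)
  if (length(cut)) G <- G[seq_len(cut[[1L]] - 1L)]
  if (length(G)) G <- cummin(G)
  tau <- max(1, 1 + 2 * sum(G))
  N / tau
}

.splitRhat <- function(chains) {
  # chains: list of numeric vectors; split each in half
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2L
    if (h < 2L) return(list(x))
    list(x[seq_len(h)], x[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  len <- min(lengths(halves))
  if (len < 2L || length(halves) < 2L) return(NA_real_)
  M <- vapply(halves, function(x) x[seq_len(len)], numeric(len))
  W <- mean(apply(M, 2, var))
  B <- len * var(colMeans(M))
  if (W == 0) return(NA_real_)
  sqrt(((len - 1) / len * W + B / len) / W)
}

#' Effective sample size of a trace parameter
#'
#' Autocorrelation-based ESS (Geyer initial-monotone truncation of the
#' autocorrelation sum), computed per replicate run and summed.  The
#' across-replicate split potential scale reduction factor is attached as
#' attribute \code{"psrf"}.  A constant trace triggers a degeneracy warning
#' and reports the number of samples.
#'
#' @param trace a [PosteriorTrace-class], or a numeric vector of samples
#' @param param column name in the trace samples (e.g. \code{"theta_2"})
#' @return numeric ESS with attribute \code{psrf}
#' @export
setGeneric("effectiveSampleSize",
           function(trace, param) standardGeneric("effectiveSampleSize"))

#' @rdname effectiveSampleSize
setMethod("effectiveSampleSize", "numeric", function(trace, param) {
  .essVector(trace)
})

#' @rdname effectiveSampleSize
setMethod("effectiveSampleSize", "PosteriorTrace", function(trace, param) {
  df <- trace@samples
  if (!(param %in% names(df))) stop("no such parameter: ", param)
  if (nrow(df) < 100L) stop("need at least 100 retained samples")
  chains <- split(df[[param]], df$run)
  ess <- sum(vapply(chains, .essVector, numeric(1)))
  structure(ess, psrf = .splitRhat(chains))
})
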