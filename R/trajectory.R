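# Transform theta samples into interval times and population sizes, and
# summarise posterior trajectories on a plotting grid.
#
# Units: theta is in expected substitutions per site, so interval times
# T_i = sum_{k=i}^n theta_k/(k(k-1)) are in substitutions per site; dividing
# by the per-site per-generation mutation rate mu gives generations, and a
# generation time converts to years.  Year scaling always takes an explicit
# generation-time argument; it is never inferred.

#' Coalescent interval start times from theta
#'
#' \eqn{T_i = \sum_{k=i}^{n} \theta_k / (k(k-1))}: the expected time (going
#' back from the present) at which the number of ancestral lineages drops
#' to i - 1, i.e. the start of interval i.  In substitution units, or in
#' generations when \code{mu} is supplied.  Times are decreasing in i:
#' T_2 (the expected TMRCA) is the oldest.
#'
#' @param theta per-interval theta vector (element j is k = j+1)
#' @param mu optional per-site per-generation mutation rate
#' @return times T_2..T_n (oldest first, matching theta's ordering)
#' @examples
#' intervalTimes(0.004, mu = 1e-8)  # n = 2: theta/(2 mu) = 2N generations
#' @export
intervalTimes <- function(theta, mu = NULL) {
  .checkTheta(theta)
  ks <- seq_along(theta) + 1L
  times <- rev(cumsum(rev(theta / (ks * (ks - 1L)))))
  if (!is.null(mu)) {
    stopifnot(mu > 0)
    times <- times / mu
  }
  times
}

#' Per-interval effective population sizes from theta
#'
#' \eqn{N_k = \theta_k / (4\mu)}.
#'
#' @param theta per-interval theta vector
#' @param mu per-site per-generation mutation rate (> 0)
#' @return diploid effective sizes N_2..N_n
#' @examples
#' populationSizes(0.004, mu = 1e-8)  # 100000
#' @export
populationSizes <- function(theta, mu) {
  .checkTheta(theta)
  stopifnot(mu > 0)
  theta / (4 * mu)
}

# Evaluate one sampled step function at grid times (before present).
# Interval k occupies [T_{k+1}, T_k); the most recent interval extends to 0
# and times older than T_2 keep the oldest size (constant tail).
.stepSizes <- function(theta, grid, mu) {
  times <- intervalTimes(theta, mu)      # oldest first, length n-1
  sizes <- theta / (4 * mu)
  bounds <- rev(times)                   # increasing: T_n < ... < T_2
  idx <- findInterval(grid, bounds, left.open = FALSE) + 1L
  # idx 1 -> most recent interval (k = n); cap at oldest
  idx[idx > length(sizes)] <- length(sizes)
  rev(sizes)[idx]
}

#' Summarise posterior demographic trajectories on a grid
#'
#' Turns each retained theta sample into a step function of effective
#' population size versus time before present, evaluates all of them on a
#' common plotting grid (500 points by default, logarithmically spaced
#' because demographic histories span orders of magnitude), and reports the
#' per-grid-point posterior median and central 95% credible band.  The grid
#' extends to the posterior 97.5% quantile of the TMRCA T_2 by default.
#'
#' @param trace a [PosteriorTrace-class]
#' @param mu per-site per-generation mutation rate
#' @param gridPoints number of grid points (default 500)
#' @param generationTime optional generation time; when supplied, times are
#'   reported in years
#' @param logGrid logarithmic (default) or linear grid spacing
#' @param maxTime optional grid maximum (same units as the output)
#' @return a [DemographicTrajectory-class]
#' @export
summarizeTrajectories <- function(trace, mu, gridPoints = 500L,
                                  generationTime = NULL, logGrid = TRUE,
                                  maxTime = NULL) {
  stopifnot(is(trace, "PosteriorTrace"), mu > 0, gridPoints >= 2L)
  thetaCols <- grep("^theta_", names(trace@samples))
  Theta <- as.matrix(trace@samples[, thetaCols, drop = FALSE])
  if (nrow(Theta) < 1L) stop("empty trace")
  t2 <- apply(Theta, 1L, function(th) intervalTimes(th, mu)[[1L]])
  tn <- apply(Theta, 1L, function(th)
    intervalTimes(th, mu)[[ncol(Theta)]])
  upperT <- if (is.null(maxTime)) unname(stats::quantile(t2, 0.975))
            else maxTime
  lowerT <- max(min(tn) / 10, upperT * 1e-6)
  grid <- if (logGrid) exp(seq(log(lowerT), log(upperT),
                               length.out = gridPoints))
          else seq(lowerT, upperT, length.out = gridPoints)
  S <- apply(Theta, 1L, .stepSizes, grid = grid, mu = mu)  # grid x samples
  qs <- apply(S, 1L, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  unit <- "generations"
  if (!is.null(generationTime)) {
    stopifnot(generationTime > 0)
    grid <- grid * generationTime
    unit <- "years"
  }
  new("DemographicTrajectory", time = unname(grid),
      median = unname(qs[2L, ]), lower = unname(qs[1L, ]),
      upper = unname(qs[3L, ]), timeUnit = unit, mu = mu)
}

setMethod("show", "DemographicTrajectory", function(object) {
  cat(sprintf("DemographicTrajectory: %d grid points, time in %s\n",
              length(object@time), object@timeUnit))
  cat(sprintf("  present-day N_e median: %.4g | oldest: %.4g\n",
              object@median[[1L]], object@median[[length(object@median)]]))
})

#' @describeIn summarizeTrajectories export the grid summary as a data.frame
#'   (columns time, median, lower, upper)
#' @param trajectory a [DemographicTrajectory-class]
#' @export
trajectoryTable <- function(trajectory) {
  stopifnot(is(trajectory, "DemographicTrajectory"))
  data.frame(time = trajectory@time, median = trajectory@median,
             lower = trajectory@lower, upper = trajectory@upper)
}

#' Plot a posterior demographic trajectory
#'
#' Time before present on x, effective population size on y (both log
#' scale by default), shaded 95% credible band and posterior median line.
#'
#' @param x a [DemographicTrajectory-class]
#' @param y ignored
#' @param log axes log specification passed to [graphics::plot()]
#' @param truth optional function N(t) drawn as a reference line
#' @param main plot title
#' @param ... further graphical parameters
#' @export
setMethod("plot", signature(x = "DemographicTrajectory", y = "missing"),
  function(x, y, log = "xy", truth = NULL, main = "Demographic history",
           ...) {
    graphics::plot(x@time, x@median, type = "n", log = log,
                   xlab = sprintf("time before present (%s)", x@timeUnit),
                   ylab = expression(N[e]),
                   ylim = range(c(x@lower, x@upper)), main = main, ...)
    graphics::polygon(c(x@time, rev(x@time)), c(x@lower, rev(x@upper)),
                      col = grDevices::adjustcolor("darkgreen", 0.25),
                      border = NA)
    graphics::lines(x@time, x@median, col = "darkgreen", lwd = 2)
    if (!is.null(truth))
      graphics::lines(x@time, truth(x@time), col = "black", lty = 2)
    invisible(x)
  })
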