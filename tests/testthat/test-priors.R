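families <- c("IID_UNIFORM", "UCLN", "IGR", "BSP_GROUPED", "RJ",
              "GMRF1", "GMRF2", "HSMRF1", "HSMRF2")

test_that("closed-form prior densities evaluate as derived", {
  # uniform: density (1/0.1) per dimension
  expect_equal(
    logPriorDensity(priorSpec("IID_UNIFORM"),
                    list(theta = rep(0.01, 9), hypers = list())),
    9 * log(10))
  expect_identical(
    logPriorDensity(priorSpec("IID_UNIFORM"),
                    list(theta = c(rep(0.01, 8), 0.2), hypers = list())),
    -Inf)

  # GMRF1 with flat log-theta: two zero increments, plus the uniform anchor
  # and the lognormal Jacobian of the two non-anchor values
  th <- rep(exp(-6), 3)
  expect_equal(
    logPriorDensity(priorSpec("GMRF1", xi = 0.5), list(theta = th,
                                                       hypers = list())),
    log(10) + 2 * dnorm(0, 0, 0.5, log = TRUE) - 2 * log(exp(-6)))

  # RJ with all intervals equal: four equality events
  stRJ <- list(theta = rep(0.02, 5), hypers = list(eq = rep(TRUE, 4)))
  expect_equal(logPriorDensity(priorSpec("RJ"), stRJ),
               log(10) + 4 * log(0.5))

  # UCLN: product of lognormals plus hyperpriors parameterised by the mean
  H <- lognormalIntervalSD()
  st <- list(theta = c(0.01, 0.02), hypers = list(mu = 0.01, sigma = 0.5))
  expect_equal(
    logPriorDensity(priorSpec("UCLN"), st),
    -log(0.01) - log(log(1 / 1e-10)) +
      dexp(0.5, 1 / (3 * H), log = TRUE) +
      sum(dlnorm(c(0.01, 0.02), log(0.01), 0.5, log = TRUE)))

  # the spread unit: lognormal 95% interval of one order of magnitude
  expect_equal(H, log(10) / (2 * qnorm(0.975)))
  expect_equal(resolvePrior(priorSpec("UCLN"), 10)$sigmaMean, 3 * H)
})

test_that("prior densities integrate to one on low-dimensional slices", {
  # GMRF1 at n = 3: anchor uniform on (0, 0.1), second value lognormal
  spec <- priorSpec("GMRF1")
  inner <- function(t3) {
    vapply(t3, function(x) {
      stats::integrate(function(t2) vapply(t2, function(y)
        exp(logPriorDensity(spec, list(theta = c(y, x), hypers = list()))),
        numeric(1)), 0, Inf, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  total <- stats::integrate(inner, 1e-6, 0.1, rel.tol = 1e-7)$value
  expect_equal(total, 1, tolerance = 1e-4)

  # RJ at n = 3: sum over both indicator configurations
  specRJ <- priorSpec("RJ")
  dEq <- stats::integrate(function(t) vapply(t, function(x)
    exp(logPriorDensity(specRJ, list(theta = c(x, x),
                                     hypers = list(eq = TRUE)))),
    numeric(1)), 0, 0.1)$value
  dFree <- stats::integrate(function(t) vapply(t, function(x)
    exp(logPriorDensity(specRJ, list(theta = c(x, 0.05),
                                     hypers = list(eq = FALSE)))),
    numeric(1)), 0, 0.1)$value * 0.1  # second uniform integrates over 0.1
  expect_equal(dEq + dFree, 1, tolerance = 1e-6)
})

test_that("generative draws match their analytic moments", {
  set.seed(101)
  # uniform mean 0.05
  th <- replicate(5000, samplePrior(priorSpec("IID_UNIFORM"), 6)$theta)
  se <- 0.1 / sqrt(12) / sqrt(length(th))
  expect_lt(abs(mean(th) - 0.05), 4 * se)

  # RJ: distinct groups - 1 ~ Binomial(n-2, 1 - beta)
  g <- replicate(4000, {
    st <- samplePrior(priorSpec("RJ"), 6)
    sum(!st$hypers$eq)
  })
  expect_lt(abs(mean(g) - 4 * 0.5), 4 * sqrt(4 * 0.25 / length(g)))

  # GMRF1: end-to-end log variance (n-2) * xi^2
  xi <- resolvePrior(priorSpec("GMRF1"), 6)$xi
  d <- replicate(6000, {
    th <- samplePrior(priorSpec("GMRF1"), 6)$theta
    log(th[[1L]]) - log(th[[5L]])
  })
  expect_equal(var(d), 4 * xi^2, tolerance = 0.1)

  # loguniform median sqrt(ab)
  x <- stairbayes:::.rlogunif(20000, 1e-10, 1)
  expect_equal(median(log10(x)), log10(sqrt(1e-10)), tolerance = 0.15)
})

test_that("every family's density is finite at its own draws", {
  set.seed(202)
  for (f in families) {
    spec <- priorSpec(f)
    for (rep in 1:300) {
      st <- samplePrior(spec, 6)
      ld <- logPriorDensity(spec, st)
      if (f == "IGR" && any(st$theta == 0)) {
        # underflowed gamma draws carry their exact log coordinates
        expect_true(is.finite(logPriorDensity(spec, st)))
      } else {
        expect_true(is.finite(ld))
      }
    }
  }
})

test_that("HSMRF with unit local scales nests the GMRF", {
  th <- c(0.01, 0.012, 0.009, 0.011)
  gamma <- 0.021
  hs <- logPriorDensity(priorSpec("HSMRF1"),
                        list(theta = th,
                             hypers = list(localScales = rep(1, 3))))
  gm <- logPriorDensity(priorSpec("GMRF1", xi = gamma),
                        list(theta = th, hypers = list()))
  # the HSMRF adds only the half-Cauchy density of the local scales
  expect_equal(hs - 3 * stairbayes:::.dhalfcauchy(1, 1), gm)
})

test_that("the default group count follows round-half-even of 2m/4", {
  expect_identical(defaultGroupCount(20), 10L)
  expect_identical(defaultGroupCount(2), 1L)
  expect_identical(defaultGroupCount(3), 2L)   # round(1.5) = 2
  expect_identical(defaultGroupCount(5), 2L)   # round(2.5) = 2
  expect_identical(defaultGroupCount(1), 1L)   # floored at one group
})

test_that("BSP group sizes are positive and sum to the interval count", {
  set.seed(77)
  for (rep in 1:200) {
    st <- samplePrior(priorSpec("BSP_GROUPED"), 12)
    expect_true(all(st$hypers$sizes >= 1L))
    expect_identical(sum(st$hypers$sizes), 11L)
    expect_identical(length(st$theta), 11L)
  }
})

test_that("prior support violations give -Inf, not errors", {
  expect_identical(
    logPriorDensity(priorSpec("RJ"),
                    list(theta = c(0.2, 0.2), hypers = list(eq = TRUE))),
    -Inf)
  expect_identical(
    logPriorDensity(priorSpec("UCLN"),
                    list(theta = c(0.01, 0.01),
                         hypers = list(mu = 5, sigma = 1))),
    -Inf)  # mu outside the loguniform bounds
  expect_identical(
    logPriorDensity(priorSpec("GMRF1"),
                    list(theta = c(0.01, -0.01), hypers = list())),
    -Inf)
})
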