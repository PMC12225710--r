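test_that("interval times follow the telescoping coalescent sums", {
  # n = 2: T_2 = theta/2 substitutions = theta/(2 mu) = 2N generations
  expect_equal(intervalTimes(0.004), 0.002)
  expect_equal(intervalTimes(0.004, mu = 1e-8), 2e5)
  expect_equal(intervalTimes(0.004, mu = 1e-8),
               2 * populationSizes(0.004, 1e-8))

  # constant theta: T_2 = theta (1 - 1/n) by partial fractions
  for (n in c(5, 20, 200)) {
    times <- intervalTimes(rep(0.01, n - 1))
    expect_equal(times[[1L]], 0.01 * (1 - 1 / n), tolerance = 1e-14)
    # most recent interval is the single-term sum
    expect_equal(times[[n - 1L]], 0.01 / (n * (n - 1)))
    expect_true(all(diff(times) < 0))
  }
})

test_that("population sizes invert theta = 4 N mu", {
  expect_equal(populationSizes(0.004, 1e-8), 1e5)
  expect_equal(populationSizes(4.8e-4, 1.2e-8), 1e4)
  th <- c(0.001, 0.002, 0.003)
  expect_equal(populationSizes(th, 2e-8), populationSizes(th, 1e-8) / 2)
})

test_that("a single-sample trace summarises to its own step function", {
  theta <- c(0.004, 0.002, 0.001)  # n = 4, oldest first
  mu <- 1e-8
  samp <- data.frame(run = 1, iteration = 1, logPosterior = 0,
                     logLikelihood = 0, logPrior = 0,
                     theta_2 = theta[1], theta_3 = theta[2],
                     theta_4 = theta[3])
  tr <- new("PosteriorTrace", samples = samp,
            probs = matrix(1, 1, 1), probClasses = "0", n = 4L,
            folded = FALSE, conditioning = "none",
            p0Method = "complement", family = "IID_UNIFORM", seed = 1L)
  traj <- summarizeTrajectories(tr, mu, gridPoints = 200)
  expect_equal(traj@median, traj@lower)
  expect_equal(traj@median, traj@upper)
  times <- intervalTimes(theta, mu)
  sizes <- populationSizes(theta, mu)
  expected <- ifelse(traj@time < times[[3L]], sizes[[3L]],
              ifelse(traj@time < times[[2L]], sizes[[2L]], sizes[[1L]]))
  expect_equal(traj@median, expected)
})

test_that("constant-theta samples give flat bands", {
  samp <- data.frame(run = 1, iteration = 1:5, logPosterior = 0,
                     logLikelihood = 0, logPrior = 0,
                     theta_2 = rep(4e-4, 5), theta_3 = rep(4e-4, 5))
  tr <- new("PosteriorTrace", samples = samp, probs = matrix(1, 5, 1),
            probClasses = "0", n = 3L, folded = FALSE,
            conditioning = "none", p0Method = "complement",
            family = "IID_UNIFORM", seed = 1L)
  traj <- summarizeTrajectories(tr, 1e-8, gridPoints = 50)
  expect_true(all(traj@median == 1e4))
  expect_true(all(traj@lower == 1e4 & traj@upper == 1e4))
})

test_that("two known step functions give hand-computed grid quantiles", {
  mu <- 1e-8
  thA <- c(0.004, 0.001)  # n = 3
  thB <- c(0.002, 0.003)
  samp <- data.frame(run = 1, iteration = 1:2, logPosterior = 0,
                     logLikelihood = 0, logPrior = 0,
                     theta_2 = c(thA[1], thB[1]),
                     theta_3 = c(thA[2], thB[2]))
  tr <- new("PosteriorTrace", samples = samp, probs = matrix(1, 2, 1),
            probClasses = "0", n = 3L, folded = FALSE,
            conditioning = "none", p0Method = "complement",
            family = "IID_UNIFORM", seed = 1L)
  traj <- summarizeTrajectories(tr, mu, gridPoints = 64, logGrid = FALSE)
  stepAt <- function(th, t) {
    times <- intervalTimes(th, mu); sizes <- populationSizes(th, mu)
    ifelse(t < times[[2L]], sizes[[2L]], sizes[[1L]])
  }
  a <- stepAt(thA, traj@time); b <- stepAt(thB, traj@time)
  expect_equal(traj@median, (a + b) / 2)  # quantile type 7 midpoint of two
  expect_equal(traj@lower, pmin(a, b) + 0.025 * abs(a - b))
})

test_that("quantile bands are equivariant under monotone size transforms", {
  set.seed(9)
  samp <- data.frame(run = 1, iteration = 1:40, logPosterior = 0,
                     logLikelihood = 0, logPrior = 0,
                     theta_2 = runif(40, 1e-4, 1e-3),
                     theta_3 = runif(40, 1e-4, 1e-3))
  tr <- new("PosteriorTrace", samples = samp, probs = matrix(1, 40, 1),
            probClasses = "0", n = 3L, folded = FALSE,
            conditioning = "none", p0Method = "complement",
            family = "IID_UNIFORM", seed = 1L)
  t1 <- summarizeTrajectories(tr, 1e-8, gridPoints = 30)
  t2 <- summarizeTrajectories(tr, 2e-8, gridPoints = 30,
                              maxTime = max(t1@time) / 2)
  # halving via doubled mu: times and sizes both scale by 1/2
  expect_equal(t2@median, t1@median / 2, tolerance = 1e-10)
})

test_that("year scaling multiplies the grid by the generation time", {
  samp <- data.frame(run = 1, iteration = 1, logPosterior = 0,
                     logLikelihood = 0, logPrior = 0, theta_2 = 4e-4)
  tr <- new("PosteriorTrace", samples = samp, probs = matrix(1, 1, 1),
            probClasses = "0", n = 2L, folded = FALSE,
            conditioning = "none", p0Method = "complement",
            family = "IID_UNIFORM", seed = 1L)
  tg <- summarizeTrajectories(tr, 1e-8, gridPoints = 10)
  ty <- summarizeTrajectories(tr, 1e-8, gridPoints = 10, generationTime = 2)
  expect_equal(ty@time, tg@time * 2)
  expect_identical(ty@timeUnit, "years")
})
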