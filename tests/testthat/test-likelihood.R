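test_that("descendant-lineage probabilities match direct binomial evaluation", {
  expect_equal(lineageDescendantProb(2, 1, 4), 1 / 3)
  for (n in c(2, 5, 17, 40))
    expect_equal(lineageDescendantProb(n, 1, n), 1)
  expect_equal(lineageDescendantProb(3, 3, 4), 0)  # violates n-i+1 >= k
  expect_equal(lineageDescendantProb(1, 1, 5), 0)
  set.seed(1)
  for (rep in 1:30) {
    n <- sample(3:40, 1); k <- sample(2:n, 1); i <- sample(1:(n - 1), 1)
    expect_equal(lineageDescendantProb(k, i, n), oracleDescProb(k, i, n))
  }
})

test_that("each row of the descendant table is a probability distribution", {
  for (n in c(2, 7, 23, 50)) {
    P <- descendantProbTable(n)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  }
})

test_that("constant theta reproduces the 1/i spectrum at machine precision", {
  for (n in c(2, 10, 47, 100)) {
    theta <- 0.001
    pp <- polymorphicProbs(rep(theta, n - 1))
    expect_lt(max(abs(pp$p - theta / seq_len(n - 1))), 1e-12)
    expect_true(pp$valid)
  }
  # n = 2: single term, p_1 = theta_2
  expect_equal(polymorphicProbs(0.013)$p, 0.013)
})

test_that("varying theta matches the brute-force double loop", {
  set.seed(7)
  for (n in c(4, 9, 21)) {
    theta <- runif(n - 1, 1e-5, 1e-3)
    expect_equal(polymorphicProbs(theta)$p, oraclePolyProbs(theta, n),
                 tolerance = 1e-12)
  }
})

test_that("the infinite-sites constraint flags impossible theta", {
  pp <- polymorphicProbs(rep(1.0, 9))  # harmonic sum > 1
  expect_false(pp$valid)
  sfs <- siteFrequencySpectrum(rep(1, 9), n = 10, monomorphicCount = 10)
  expect_identical(logCompositeLikelihood(sfs, rep(1.0, 9)), -Inf)
})

test_that("both monomorphic-probability derivations behave as derived", {
  # n = 2 closed forms
  expect_equal(monomorphicProb(0.01), 0.99)
  expect_equal(monomorphicProb(0.01, "treeLength"), exp(-0.01))
  # no-mutation limit
  expect_equal(monomorphicProb(rep(1e-12, 9)), 1, tolerance = 1e-10)
  expect_equal(monomorphicProb(rep(1e-12, 9), "treeLength"), 1,
               tolerance = 1e-10)
  # second-order Taylor bound on the disagreement, for random small theta
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(3:25, 1)
    theta <- runif(n - 1, 1e-6, 2e-3)
    tl <- sum(theta / seq_len(n - 1))
    d <- abs(monomorphicProb(theta) - monomorphicProb(theta, "treeLength"))
    expect_lte(d, tl^2 / 2)
  }
})

test_that("probability folding merges mirror classes and conserves mass", {
  p <- c(0.03, 0.02, 0.01)
  expect_equal(foldProbs(p, 4), c(0.04, 0.02))
  theta <- 0.005
  p6 <- polymorphicProbs(rep(theta, 5))$p
  expect_equal(foldProbs(p6, 6),
               c(theta * (1 + 1 / 5), theta * (1 / 2 + 1 / 4), theta / 3),
               tolerance = 1e-14)
  set.seed(3)
  for (n in 3:12) {
    p <- runif(n - 1)
    expect_equal(sum(foldProbs(p, n)), sum(p))
  }
})

test_that("the composite likelihood equals an independent multinomial pmf", {
  sfs <- siteFrequencySpectrum(c(6, 3, 1), n = 4, monomorphicCount = 90)
  theta <- rep(0.02, 3)
  p <- oraclePolyProbs(theta, 4)
  expect_equal(p, c(0.02, 0.01, 0.02 / 3))
  expect_equal(logCompositeLikelihood(sfs, theta),
               dmultinom(c(90, 6, 3, 1), prob = c(1 - sum(p), p), log = TRUE))

  # conditioning on polymorphic sites only
  masked <- siteFrequencySpectrum(c(6, 3, 1), n = 4, monomorphicCount = 90,
                                  maskedClasses = "monomorphic")
  cfgM <- likelihoodConfig(conditioning = "noMonomorphic")
  expect_equal(logCompositeLikelihood(masked, theta, cfgM),
               dmultinom(c(6, 3, 1), prob = p / sum(p), log = TRUE))

  # conditioning away monomorphic and singleton classes (n = 6)
  theta6 <- rep(0.015, 5)
  p6 <- oraclePolyProbs(theta6, 6)
  maskedS <- siteFrequencySpectrum(c(6, 3, 2, 1, 1), n = 6,
                                   monomorphicCount = 90,
                                   maskedClasses = c("monomorphic",
                                                     "singletons"))
  cfgS <- likelihoodConfig(conditioning = "noMonoNoSingletons")
  expect_equal(logCompositeLikelihood(maskedS, theta6, cfgS),
               dmultinom(c(3, 2, 1), prob = p6[2:4] / sum(p6[2:4]),
                         log = TRUE))

  # folded spectrum
  folded <- foldSpectrum(sfs)
  pF <- c(p[1] + p[3], p[2])
  expect_equal(logCompositeLikelihood(folded, theta),
               dmultinom(c(90, 7, 3), prob = c(1 - sum(p), pF), log = TRUE))

  # tree-length p0 rescales the polymorphic block
  cfgT <- likelihoodConfig(p0Method = "treeLength")
  p0 <- exp(-sum(theta / 1:3))
  pT <- p * (1 - p0) / sum(p)
  expect_equal(logCompositeLikelihood(sfs, theta, cfgT),
               dmultinom(c(90, 6, 3, 1), prob = c(p0, pT), log = TRUE))
})

test_that("conditioned probability vectors renormalise to one", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:20, 1)
    theta <- runif(n - 1, 1e-5, 2e-3)
    for (p0m in c("complement", "treeLength"))
      for (cond in c("none", "noMonomorphic", "noMonoNoSingletons"))
        for (folded in c(FALSE, TRUE)) {
          counts <- rep(1, if (folded) n %/% 2 else n - 1)
          masked <- switch(cond, none = character(),
                           noMonomorphic = "monomorphic",
                           noMonoNoSingletons = c("monomorphic",
                                                  "singletons"))
          sfs <- siteFrequencySpectrum(
            counts, n = n, folded = folded, monomorphicCount = 5,
            maskedClasses = masked)
          frame <- stairbayes:::.modelFrame(
            sfs, likelihoodConfig(p0Method = p0m, conditioning = cond))
          p <- stairbayes:::.condProbs(theta, frame)
          expect_equal(sum(p), 1, tolerance = 1e-12)
        }
  }
})

test_that("empty data give log-likelihood zero", {
  sfs <- siteFrequencySpectrum(rep(0, 5), n = 6, monomorphicCount = 0)
  expect_identical(logCompositeLikelihood(sfs, rep(0.01, 5)), 0)
})

test_that("masking requirements are enforced", {
  sfs <- siteFrequencySpectrum(c(6, 3, 1), n = 4, monomorphicCount = 90)
  expect_error(
    logCompositeLikelihood(sfs, rep(0.01, 3),
                           likelihoodConfig(conditioning = "noMonomorphic")),
    "mask")
  unknown <- siteFrequencySpectrum(c(6, 3, 1), n = 4)
  expect_error(logCompositeLikelihood(unknown, rep(0.01, 3)), "noMonomorphic")
})

test_that("the multinomial likelihood peaks at the empirical frequencies", {
  # with n = 2 there is a single free class probability p1 = theta; the
  # maximising theta must be the empirical SNP fraction
  sfs <- siteFrequencySpectrum(7, n = 2, monomorphicCount = 93)
  grid <- seq(0.01, 0.2, by = 0.001)
  ll <- vapply(grid, function(th) logCompositeLikelihood(sfs, th), numeric(1))
  expect_equal(grid[which.max(ll)], 0.07, tolerance = 1e-6)
})
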