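# Independent brute-force oracles used to freeze expected values.  These
# deliberately re-derive quantities with naive loops and stats:: building
# blocks, independent of the package's vectorised implementations.

# Pr(k, i | n) by direct binomial evaluation
oracleDescProb <- function(k, i, n) {
  if (k >= 2 && k <= n - i + 1 && i >= 1 && i <= n) {
    choose(n - i - 1, k - 2) / choose(n - 1, k - 1)
  } else 0
}

# p_i by explicit double loop over k
oraclePolyProbs <- function(theta, n) {
  vapply(seq_len(n - 1L), function(i) {
    s <- 0
    for (k in 2:n) s <- s + oracleDescProb(k, i, n) * theta[[k - 1L]] / (k - 1)
    s
  }, numeric(1))
}

# LPCV by literal evaluation of the harmonic-mean formula
oracleLPCV <- function(probs, counts) {
  total <- 0
  for (j in seq_along(counts)) {
    if (counts[[j]] == 0) next
    hm <- 1 / mean(1 / probs[, j])
    total <- total + counts[[j]] * log(hm)
  }
  total
}

.mergedTestConfig <- function(over) {
  utils::modifyList(stairbayes:::.cliDefaults(), over)
}

# small deterministic SFS for reuse
toySFS <- function() {
  siteFrequencySpectrum(c(60, 25, 14, 8, 5), n = 6, monomorphicCount = 1e5)
}

makeTrace <- function(probs, classes, n, run = NULL, family = "IID_UNIFORM",
                      conditioning = "none") {
  K <- nrow(probs)
  if (is.null(run)) run <- rep(1, K)
  samp <- data.frame(run = run, iteration = seq_len(K),
                     logPosterior = 0, logLikelihood = 0, logPrior = 0)
  colnames(probs) <- paste0("p_", classes)
  new("PosteriorTrace", samples = samp, probs = probs,
      probClasses = classes, n = as.integer(n), folded = FALSE,
      conditioning = conditioning, p0Method = "complement",
      family = family, seed = 1L)
}
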