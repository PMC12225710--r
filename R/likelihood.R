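# Composite (multinomial) stairway-plot likelihood.
#
# theta vectors are stored with index j = 1..n-1 corresponding to the
# coalescent interval with k = j+1 ancestral lineages; j = n-1 (k = n) is the
# most recent interval, j = 1 (k = 2) the oldest.

.tableCache <- new.env(parent = emptyenv())

#' Probability that a lineage has i sampled descendants
#'
#' Under the standard coalescent, the probability that one of the k
#' ancestral lineages present during coalescent interval k subtends exactly
#' i of the n sampled lineages:
#' \deqn{\Pr(k,i \mid n) = \binom{n-i-1}{k-2} / \binom{n-1}{k-1}}
#' for \eqn{n-i+1 \ge k \ge 2} and \eqn{n \ge i \ge 1}, and 0 otherwise.
#' Evaluated in log space so large n stays exact to rounding.
#'
#' @param k number of ancestral lineages (vectorized)
#' @param i number of sampled descendants (vectorized)
#' @param n haploid sample size
#' @return probabilities (0 outside the valid range)
#' @examples
#' lineageDescendantProb(2, 1, 4)  # 1/3
#' @export
lineageDescendantProb <- function(k, i, n) {
  stopifnot(n >= 2)
  out <- exp(lchoose(n - i - 1, k - 2) - lchoose(n - 1, k - 1))
  out[!(k >= 2 & k <= n - i + 1 & i >= 1 & i <= n)] <- 0
  out
}

#' Descendant-probability table for sample size n
#'
#' Matrix of \eqn{\Pr(k,i\mid n)} with rows k = 2..n and columns
#' i = 1..n-1.  Depends only on n, so it is computed once and cached: the
#' likelihood is then an O(n^2) table-vector product per evaluation,
#' independent of the number of SNPs.
#'
#' @param n haploid sample size
#' @return an (n-1) x (n-1) matrix, dimnames k and i
#' @export
descendantProbTable <- function(n) {
  key <- as.character(n)
  hit <- .tableCache[[key]]
  if (!is.null(hit)) return(hit$P)
  ks <- 2:n
  is <- 1:(n - 1L)
  P <- outer(ks, is, lineageDescendantProb, n = n)
  dimnames(P) <- list(k = ks, i = is)
  # weights for p_i = sum_k Pr(k,i|n) * theta_k / (k-1)
  W <- P / (ks - 1L)
  assign(key, list(P = P, W = W), envir = .tableCache)
  P
}

.weightTable <- function(n) {
  descendantProbTable(n)
  .tableCache[[as.character(n)]]$W
}

.checkTheta <- function(theta) {
  if (length(theta) < 1L || any(!is.finite(theta)) || any(theta <= 0))
    stop("theta must be a vector of positive finite values (length n-1)")
  invisible(theta)
}

#' Expected site-class probabilities from per-interval theta
#'
#' The per-class expected mutation density
#' \eqn{p_i = \sum_{k=2}^{n} \Pr(k,i\mid n)\, \theta_k/(k-1)} for
#' i = 1..n-1: the lineage-length weight theta_k/(k-1) times the
#' descendant-count probability.  Under the infinite-sites assumption at
#' most one mutation hits a site, so the p_i must leave room for the
#' monomorphic class: the result is flagged invalid when
#' \eqn{\sum_i p_i \ge 1} (the sampler treats this as certain rejection).
#'
#' @param theta positive vector of scaled sizes theta_k = 4 N_k mu,
#'   element j corresponding to k = j+1 (so the last element is the most
#'   recent interval)
#' @return list with \code{p} (length n-1) and logical \code{valid}
#' @examples
#' polymorphicProbs(rep(0.001, 9))$p  # 0.001 / i, Fu's constant-size form
#' @export
polymorphicProbs <- function(theta) {
  .checkTheta(theta)
  n <- length(theta) + 1L
  p <- as.vector(theta %*% .weightTable(n))
  list(p = p, valid = sum(p) < 1)
}

#' Probability of a monomorphic site
#'
#' Two derivations: \code{"complement"} takes
#' \eqn{p_0 = 1 - \sum_{i=1}^{n-1} p_i} (the original stairway-plot
#' suggestion); \code{"treeLength"} takes the probability of no mutation on
#' the whole tree, \eqn{p_0 = \exp(-\sum_{k=2}^{n} \theta_k/(k-1))}, in
#' which case the polymorphic probabilities must be rescaled to total
#' \eqn{1 - p_0} (see [logCompositeLikelihood()], which does this
#' internally).  The two agree to second order in the expected tree length
#' and give virtually identical inferences for realistic theta.
#'
#' @param theta per-interval theta vector
#' @param method \code{"complement"} or \code{"treeLength"}
#' @return p0, or \code{NA} when the complement method is invalid
#'   (\eqn{\sum p_i \ge 1})
#' @export
monomorphicProb <- function(theta, method = c("complement", "treeLength")) {
  method <- match.arg(method)
  .checkTheta(theta)
  if (method == "treeLength") {
    exp(-sum(theta / seq_along(theta)))
  } else {
    pp <- polymorphicProbs(theta)
    if (!pp$valid) NA_real_ else 1 - sum(pp$p)
  }
}

#' Fold site-class probabilities
#'
#' Minor-allele class probabilities from unfolded ones:
#' \eqn{p^F_i = p_i + p_{n-i}} for i < n/2, with the middle class of an
#' even-n spectrum kept as-is.  Total probability mass is conserved.
#'
#' @param p unfolded class probabilities for i = 1..n-1
#' @param n haploid sample size
#' @return folded probabilities for i = 1..floor(n/2)
#' @export
foldProbs <- function(p, n) {
  stopifnot(length(p) == n - 1L)
  half <- n %/% 2L
  vapply(seq_len(half), function(i) {
    if (2L * i == n) p[[i]] else p[[i]] + p[[n - i]]
  }, numeric(1))
}

#' Likelihood configuration
#'
#' @param p0Method monomorphic-probability derivation, \code{"complement"}
#'   (default) or \code{"treeLength"}
#' @param conditioning ascertainment correction: \code{"none"} models all
#'   classes including monomorphic; \code{"noMonomorphic"} conditions on
#'   observing a polymorphic site (p_i / (1 - p_0)); \code{"noMonoNoSingletons"}
#'   additionally conditions away the singleton classes i = 1 and i = n-1
#'   (p_i / (1 - p_0 - p_1 - p_{n-1})).  For a folded spectrum the singleton
#'   correction removes the single merged class i = 1.
#' @return a list with validated entries
#' @export
likelihoodConfig <- function(p0Method = c("complement", "treeLength"),
                             conditioning = c("none", "noMonomorphic",
                                              "noMonoNoSingletons")) {
  list(p0Method = match.arg(p0Method), conditioning = match.arg(conditioning))
}

# Resolve the modeled classes/counts for an SFS + conditioning, with the
# consistency checks between masking and conditioning.
.modelFrame <- function(sfs, config) {
  n <- sfs@n
  folded <- sfs@folded
  half <- n %/% 2L
  cond <- config$conditioning
  masked <- sfs@maskedClasses
  monoExcluded <- cond %in% c("noMonomorphic", "noMonoNoSingletons")
  if (!monoExcluded) {
    if ("monomorphic" %in% masked || is.na(sfs@monomorphicCount))
      stop("conditioning 'none' models the monomorphic class, but it is ",
           "masked/unknown; use conditioning = 'noMonomorphic'")
  } else if (!is.na(sfs@monomorphicCount) && sfs@monomorphicCount > 0 &&
             !("monomorphic" %in% masked)) {
    stop("conditioning excludes the monomorphic class but its observed ",
         "count is nonzero; mask it first (maskedClasses)")
  }
  singIdx <- if (folded) 1L else c(1L, n - 1L)
  if (cond == "noMonoNoSingletons") {
    if (any(sfs@counts[singIdx] > 0) && !("singletons" %in% masked))
      stop("conditioning excludes singleton classes with nonzero observed ",
           "counts; mask them first (maskedClasses)")
  } else if ("singletons" %in% masked) {
    stop("singleton classes are masked; use conditioning = ",
         "'noMonoNoSingletons'")
  }
  polyIdx <- if (cond == "noMonoNoSingletons") {
    if (folded) setdiff(seq_len(half), 1L) else 2:(n - 2L)
  } else {
    if (folded) seq_len(half) else seq_len(n - 1L)
  }
  counts <- sfs@counts[polyIdx]
  classes <- as.character(polyIdx)
  if (!monoExcluded) {
    counts <- c(sfs@monomorphicCount, counts)
    classes <- c("0", classes)
  }
  list(n = n, folded = folded, half = half, cond = cond,
       p0Method = config$p0Method, polyIdx = polyIdx,
       counts = counts, classes = classes, monoModeled = !monoExcluded,
       W = .weightTable(n))
}

# Conditioned class probabilities for a theta vector under a model frame.
# Returns NULL when invalid (sum p_i >= 1).
.condProbs <- function(theta, frame) {
  n <- frame$n
  p <- as.vector(theta %*% frame$W)
  S <- sum(p)
  if (S >= 1 || any(p <= 0)) return(NULL)
  if (frame$p0Method == "treeLength") {
    p0 <- exp(-sum(theta / seq_along(theta)))
    p <- p * ((1 - p0) / S)
  } else {
    p0 <- 1 - S
  }
  if (frame$folded) p <- foldProbs(p, n)
  pm <- p[frame$polyIdx]
  if (frame$monoModeled) {
    c(p0, pm)
  } else {
    pm / (1 - p0 - (sum(p) - sum(pm)))
  }
}

#' Log composite likelihood of a site frequency spectrum
#'
#' The multinomial log-probability of the observed class counts given the
#' per-interval theta vector:
#' \eqn{\ln l! + \sum_i \xi_i \ln p_i - \sum_i \ln \xi_i!}, with the class
#' probabilities renormalised according to the conditioning scheme and
#' folded automatically when the spectrum is folded.  Factorials are
#' evaluated via log-gamma.  Returns \code{-Inf} when the theta vector is
#' invalid (\eqn{\sum_i p_i \ge 1}: more than one expected mutation per
#' site, violating the infinite-sites assumption).
#'
#' @param sfs a [SiteFrequencySpectrum-class]
#' @param theta per-interval theta vector of length n-1
#' @param config a [likelihoodConfig()] list
#' @return the log-likelihood (scalar; may be \code{-Inf})
#' @export
logCompositeLikelihood <- function(sfs, theta, config = likelihoodConfig()) {
  stopifnot(is(sfs, "SiteFrequencySpectrum"))
  .checkTheta(theta)
  if (length(theta) != sfs@n - 1L)
    stop(sprintf("theta must have length n-1 = %d, found %d",
                 sfs@n - 1L, length(theta)))
  frame <- .modelFrame(sfs, config)
  .frameLogLik(theta, frame)
}

.frameLogLik <- function(theta, frame) {
  x <- frame$counts
  if (sum(x) == 0) return(0)  # empty product: probability 1
  p <- .condProbs(theta, frame)
  if (is.null(p)) return(-Inf)
  pos <- x > 0
  lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + sum(x[pos] * log(p[pos]))
}
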