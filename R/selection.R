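# Leave-one-out cross-validation from stored per-sample site-class
# probabilities.  Sites within a frequency class are exchangeable, so the
# per-site sum over all l sites collapses to a count-weighted sum over the
# modelled classes, which is why the score can be computed posthoc from a
# trace in negligible time.

.sfsFingerprint <- function(sfs) {
  paste(sfs@n, sfs@folded, sfs@monomorphicCount,
        paste(sfs@counts, collapse = ","), sep = "|")
}

# family complexity used for tie-breaking (number of sampled hyperparameter
# blocks, roughly: simpler families first)
.FAMILY_COMPLEXITY <- c(IID_UNIFORM = 0, GMRF1 = 1, GMRF2 = 1,
                        UCLN = 2, IGR = 2, BSP_GROUPED = 3, RJ = 3,
                        HSMRF1 = 4, HSMRF2 = 4)

#' Leave-one-out cross-validation score (LPCV)
#'
#' Estimates the leave-one-out predictive log-probability of each site from
#' the MCMC samples: per site the harmonic mean over samples of its class
#' probability,
#' \deqn{LPCV = \sum_i \xi_i \ln\left[\frac{1}{K}\sum_{k=1}^{K}
#'   \frac{1}{p_i^{(k)}}\right]^{-1},}
#' computed with log-sum-exp stabilisation on \eqn{-\ln p}.  Replicate runs
#' are pooled for the total score; per-replicate scores are reported as a
#' stability diagnostic.  The spectrum must use the same conditioning as
#' the trace (the stored probabilities are the conditioned ones).
#'
#' @param trace a [PosteriorTrace-class]
#' @param sfs the [SiteFrequencySpectrum-class] the trace was sampled for
#' @param model model identifier for reporting (default the prior family)
#' @return an [LPCVResult-class]
#' @export
lpcv <- function(trace, sfs, model = trace@family) {
  stopifnot(is(trace, "PosteriorTrace"), is(sfs, "SiteFrequencySpectrum"))
  if (sfs@n != trace@n) stop("sample size mismatch between trace and SFS")
  counts <- .classCounts(trace, sfs)
  K <- nrow(trace@probs)
  if (K < 1L) stop("empty trace")
  perClass <- .lpcvContrib(trace@probs, counts)
  # per-replicate pass repeats the pooled one; its warnings are duplicates
  perRep <- vapply(split(seq_len(K), trace@samples$run), function(idx) {
    sum(suppressWarnings(
      .lpcvContrib(trace@probs[idx, , drop = FALSE], counts)))
  }, numeric(1))
  new("LPCVResult", score = sum(perClass),
      perClass = stats::setNames(perClass, colnames(trace@probs)),
      perReplicate = perRep, K = as.integer(K), model = model,
      conditioning = trace@conditioning,
      sfsFingerprint = .sfsFingerprint(sfs))
}

# observed counts aligned to the trace's modelled classes
.classCounts <- function(trace, sfs) {
  cls <- trace@probClasses
  vapply(cls, function(cl) {
    i <- as.integer(cl)
    if (i == 0L) {
      m <- sfs@monomorphicCount
      if (is.na(m)) stop("trace models the monomorphic class but the ",
                         "spectrum's monomorphic count is unknown")
      m
    } else sfs@counts[[i]]
  }, numeric(1))
}

.lpcvContrib <- function(probs, counts) {
  K <- nrow(probs)
  vapply(seq_along(counts), function(j) {
    xi <- counts[[j]]
    if (xi == 0) return(0)
    p <- probs[, j]
    if (any(is.na(p)) || any(p <= 0)) {
      warning("stored probability <= 0 for class ", colnames(probs)[j],
              " with nonzero count; LPCV is -Inf")
      return(-Inf)
    }
    # ln harmonic mean = ln K - logsumexp(-ln p)
    nlp <- -log(p)
    m <- max(nlp)
    xi * (log(K) - (m + log(sum(exp(nlp - m)))))
  }, numeric(1))
}

setMethod("show", "LPCVResult", function(object) {
  cat(sprintf("LPCVResult: model %s, score %.3f (K = %d samples)\n",
              object@model, object@score, object@K))
  if (length(object@perReplicate) > 1L)
    cat("  per-replicate: ",
        paste(sprintf("%.3f", object@perReplicate), collapse = ", "), "\n",
        sep = "")
})

#' Select the best model by LPCV
#'
#' Returns the model id with the highest LPCV score among results computed
#' on the same spectrum under the same conditioning.  Ties are broken
#' toward the family with fewer sampled hyperparameters, with a warning.
#'
#' @param results list of [LPCVResult-class] objects (at least two)
#' @return the winning model id (character)
#' @export
selectBest <- function(results) {
  if (!is.list(results) || length(results) < 2L)
    stop("need at least two LPCV results to compare")
  stopifnot(all(vapply(results, is, logical(1), "LPCVResult")))
  conds <- vapply(results, function(r) r@conditioning, character(1))
  fps <- vapply(results, function(r) r@sfsFingerprint, character(1))
  if (length(unique(conds)) > 1L)
    stop("LPCV scores under different conditioning schemes are not comparable")
  if (length(unique(fps)) > 1L)
    stop("LPCV results were computed on different spectra")
  scores <- vapply(results, function(r) r@score, numeric(1))
  models <- vapply(results, function(r) r@model, character(1))
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    cx <- .FAMILY_COMPLEXITY[models[best]]
    cx[is.na(cx)] <- Inf
    warning("LPCV tie between ", paste(models[best], collapse = ", "),
            "; choosing the simpler family")
    best <- best[which.min(cx)]
  }
  models[[best]]
}

#' Write a model-comparison report
#'
#' Tab-separated table ranked by LPCV: model id, score, K, per-replicate
#' scores.
#'
#' @param results list of [LPCVResult-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeComparison <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(model = r@model, LPCV = r@score, K = r@K,
               perReplicate = paste(sprintf("%.4f", r@perReplicate),
                                    collapse = ","))
  }))
  df <- df[order(-df$LPCV), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stairbayes %s model comparison (LPCV)",
                     as.character(utils::packageVersion("stairbayes"))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
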