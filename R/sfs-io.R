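#' Construct a site frequency spectrum
#'
#' @param counts non-negative integer SNP counts; for an unfolded spectrum
#'   the entries are the classes i = 1..n-1 (i = number of derived copies),
#'   for a folded spectrum the merged classes i = 1..floor(n/2)
#' @param n haploid sample size (n = 2m for m diploid individuals)
#' @param folded logical
#' @param monomorphicCount number of invariant sites, or \code{NA} when
#'   unknown (then \code{"monomorphic"} is added to the masked classes)
#' @param lastClassCount count of all-derived sites (xi_n); recorded but
#'   excluded from the likelihood, with a warning when positive
#' @param maskedClasses character subset of \code{c("monomorphic",
#'   "singletons")}
#' @return a [SiteFrequencySpectrum-class] object
#' @examples
#' sfs <- siteFrequencySpectrum(c(9, 4, 3), n = 4, monomorphicCount = 100)
#' totalSites(sfs)
#' @export
siteFrequencySpectrum <- function(counts, n, folded = FALSE,
                                  monomorphicCount = NA_real_,
                                  lastClassCount = 0,
                                  maskedClasses = character()) {
  if (is.na(monomorphicCount))
    maskedClasses <- union(maskedClasses, "monomorphic")
  if (!folded && lastClassCount > 0)
    warning("xi_n > 0: all-derived sites cannot be modelled under the ",
            "infinite-sites assumption and are excluded from the likelihood")
  new("SiteFrequencySpectrum", n = as.integer(n), counts = as.numeric(counts),
      monomorphicCount = as.numeric(monomorphicCount),
      lastClassCount = as.numeric(lastClassCount), folded = folded,
      maskedClasses = maskedClasses)
}

#' @describeIn siteFrequencySpectrum haploid sample size
#' @param x,object a \code{SiteFrequencySpectrum}
#' @export
sampleSize <- function(x) x@n

#' @describeIn siteFrequencySpectrum polymorphic class counts
#' @export
sfsCounts <- function(x) x@counts

#' @describeIn siteFrequencySpectrum invariant-site count (NA when unknown)
#' @export
monomorphicCount <- function(x) x@monomorphicCount

#' @describeIn siteFrequencySpectrum whether the spectrum is folded
#' @export
isFolded <- function(x) x@folded

#' @describeIn siteFrequencySpectrum classes excluded from the likelihood
#' @export
maskedClasses <- function(x) x@maskedClasses

#' @describeIn siteFrequencySpectrum total number of sites
#'   l = xi_0 + sum(xi_i) (NA when the monomorphic count is unknown)
#' @export
totalSites <- function(x) {
  if (is.na(x@monomorphicCount)) return(NA_real_)
  x@monomorphicCount + sum(x@counts) + x@lastClassCount
}

setMethod("show", "SiteFrequencySpectrum", function(object) {
  cat(sprintf("SiteFrequencySpectrum: n = %d haploids, %s\n", object@n,
              if (object@folded) "folded" else "unfolded"))
  cat(sprintf("  polymorphic classes: %d, SNPs: %s\n", length(object@counts),
              format(sum(object@counts), big.mark = ",")))
  cat(sprintf("  monomorphic sites: %s\n",
              if (is.na(object@monomorphicCount)) "unknown"
              else format(object@monomorphicCount, big.mark = ",")))
  if (length(object@maskedClasses))
    cat("  masked: ", paste(object@maskedClasses, collapse = ", "), "\n",
        sep = "")
})

#' Read a site frequency spectrum from a plain-text file
#'
#' The file holds '#' comment lines, one header line and one count line.
#' The header declares the haploid sample size and folding, e.g.
#' \code{"n=20 unfolded"}, optionally followed by \code{L=<total sites>}.
#' Two count-line dialects are accepted and disambiguated by length:
#' \itemize{
#'   \item full spectrum (dadi convention): n+1 entries for unfolded
#'     (xi_0 first, xi_n last) or floor(n/2)+1 entries for folded
#'     (xi_0 first);
#'   \item polymorphic-only: n-1 (unfolded) or floor(n/2) (folded) entries;
#'     the monomorphic count is then L minus the SNP total when \code{L=} is
#'     given, otherwise unknown.
#' }
#'
#' @param path file path
#' @return a [SiteFrequencySpectrum-class]
#' @seealso [writeSFS()]
#' @export
readSFS <- function(path) {
  if (!file.exists(path)) stop("SFS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L)
    stop("SFS file must contain a header line and a count line")
  header <- tolower(lines[[1L]])
  toks <- strsplit(header, "[[:space:];,]+")[[1L]]
  nTok <- grep("^n=", toks, value = TRUE)
  if (length(nTok) != 1L) stop("header must declare the sample size as n=<int>")
  n <- suppressWarnings(as.integer(sub("^n=", "", nTok)))
  if (is.na(n) || n < 2L) stop("invalid sample size in header: ", nTok)
  folded <- if (any(toks == "folded")) TRUE
            else if (any(toks == "unfolded")) FALSE
            else stop("header must declare 'folded' or 'unfolded'")
  lTok <- grep("^l=", toks, value = TRUE)
  totalL <- if (length(lTok)) as.numeric(sub("^l=", "", lTok[[1L]])) else NA

  raw <- strsplit(lines[[2L]], "[[:space:]]+")[[1L]]
  vals <- suppressWarnings(as.numeric(raw))
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("count line entries must be non-negative integers")
  nPoly <- if (folded) n %/% 2L else n - 1L
  nFull <- if (folded) nPoly + 1L else n + 1L
  if (length(vals) == nFull) {
    mono <- vals[[1L]]
    if (folded) {
      counts <- vals[-1L]
      last <- 0
    } else {
      counts <- vals[2:n]
      last <- vals[[n + 1L]]
    }
  } else if (length(vals) == nPoly) {
    counts <- vals
    last <- 0
    mono <- if (is.na(totalL)) NA_real_ else totalL - sum(counts)
    if (!is.na(mono) && mono < 0)
      stop("declared total length L is smaller than the SNP total")
  } else {
    stop(sprintf("expected %d or %d entries for n = %d (%s), found %d",
                 nPoly, nFull, n, if (folded) "folded" else "unfolded",
                 length(vals)))
  }
  siteFrequencySpectrum(counts, n = n, folded = folded,
                        monomorphicCount = mono, lastClassCount = last)
}

#' Write a site frequency spectrum to a plain-text file
#'
#' Writes the full-vector dialect when the monomorphic count is known and
#' the polymorphic-only dialect otherwise; [readSFS()] round-trips either.
#'
#' @param sfs a [SiteFrequencySpectrum-class]
#' @param path output file path
#' @param comment optional extra '#' comment line
#' @return \code{path}, invisibly
#' @export
writeSFS <- function(sfs, path, comment = NULL) {
  stopifnot(is(sfs, "SiteFrequencySpectrum"))
  hdr <- sprintf("n=%d %s", sfs@n, if (sfs@folded) "folded" else "unfolded")
  if (is.na(sfs@monomorphicCount)) {
    vec <- sfs@counts
  } else {
    vec <- if (sfs@folded) c(sfs@monomorphicCount, sfs@counts)
           else c(sfs@monomorphicCount, sfs@counts, sfs@lastClassCount)
  }
  lines <- c(sprintf("# stairbayes %s site frequency spectrum",
                     as.character(utils::packageVersion("stairbayes"))),
             if (!is.null(comment)) paste0("# ", comment),
             hdr,
             paste(format(vec, scientific = FALSE, trim = TRUE),
                   collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Fold an unfolded site frequency spectrum
#'
#' Merges derived-allele classes i and n-i into minor-allele classes:
#' xi_i^F = xi_i + xi_{n-i} for i < n/2, with the middle class kept as-is
#' when n is even.  The all-derived count xi_n is merged into the
#' monomorphic class (both are invariant in minor-allele terms).
#'
#' @param sfs an unfolded [SiteFrequencySpectrum-class]
#' @return the folded spectrum
#' @examples
#' foldSpectrum(siteFrequencySpectrum(c(9, 4, 3), n = 4,
#'                                    monomorphicCount = 100))
#' @export
foldSpectrum <- function(sfs) {
  stopifnot(is(sfs, "SiteFrequencySpectrum"))
  if (sfs@folded) stop("spectrum is already folded")
  n <- sfs@n
  half <- n %/% 2L
  xi <- sfs@counts
  folded <- vapply(seq_len(half), function(i) {
    if (2L * i == n) xi[[i]] else xi[[i]] + xi[[n - i]]
  }, numeric(1))
  mono <- if (is.na(sfs@monomorphicCount)) NA_real_
          else sfs@monomorphicCount + sfs@lastClassCount
  siteFrequencySpectrum(folded, n = n, folded = TRUE,
                        monomorphicCount = mono,
                        maskedClasses = sfs@maskedClasses)
}

#' Perturb an unfolded spectrum by ancestral-allele miscalls
#'
#' Each SNP in class i is independently mis-polarized (its derived and
#' ancestral alleles swapped, moving it to class n-i) with probability
#' \code{rho}.  Per class the number of moved SNPs is a binomial draw, so
#' the total SNP count is conserved; the middle class of an even-n spectrum
#' maps onto itself.  Folding erases the perturbation entirely.
#'
#' @param sfs an unfolded [SiteFrequencySpectrum-class]
#' @param rho miscall probability per SNP, in [0, 1]
#' @param seed integer RNG seed
#' @return the perturbed spectrum
#' @export
applyPolarizationError <- function(sfs, rho, seed) {
  stopifnot(is(sfs, "SiteFrequencySpectrum"))
  if (sfs@folded) stop("polarization error is undefined for a folded spectrum")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (rho == 0) return(sfs)
  n <- sfs@n
  xi <- sfs@counts
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  moved <- stats::rbinom(n - 1L, size = xi, prob = rho)
  out <- xi - moved
  # class i receives the movers of class n-i
  out <- out + moved[(n - 1L):1L]
  siteFrequencySpectrum(out, n = n, folded = FALSE,
                        monomorphicCount = sfs@monomorphicCount,
                        lastClassCount = sfs@lastClassCount,
                        maskedClasses = sfs@maskedClasses)
}
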