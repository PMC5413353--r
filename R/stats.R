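#' Automatic bin count by the Freedman-Diaconis rule
#'
#' Chooses the histogram bin width for the alignment (or difference)
#' values as \eqn{(Q_3 - Q_1)/n^{1/3}} and converts it to a bin count
#' \eqn{K = \lceil (domainHigh - domainLow)/width \rceil}, clamped to
#' \eqn{[3, 100]}. The rule is applied to the values being binned (the
#' alignment distribution), not to the raw marginals. Indices computed
#' with different K are not comparable, so when several datasets enter one
#' comparison the rule should be applied to their pooled alignment values
#' (the CLI's \code{--k auto} does exactly that).
#'
#' @param values numeric vector of alignment/difference values (at least
#'   4, with a positive interquartile range).
#' @param domainLow,domainHigh the quantization domain.
#' @return a [BinSelection-class].
#' @examples
#' cfg <- orientationSimConfig(n = 1000, seed = 3, sigmaX = 25)
#' sel <- selectBins(alignmentValues(simulateCoorientation(cfg)), 0, 90)
#' nBins(sel)
#' @export
selectBins <- function(values, domainLow = 0, domainHigh = 90) {
  if (length(values) < 4L)
    stop("need at least 4 values for Freedman-Diaconis bin selection",
         call. = FALSE)
  if (!(domainLow < domainHigh))
    stop("'domainLow' must be smaller than 'domainHigh'", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  if (iqr <= 0)
    stop(paste("interquartile range is zero; the Freedman-Diaconis rule",
               "is undefined -- supply K manually"), call. = FALSE)
  width <- iqr / length(values)^(1 / 3)
  k <- as.integer(min(max(ceiling((domainHigh - domainLow) / width), 3L),
                      100L))
  new("BinSelection", k = k, binWidth = width, q1 = q[1], q3 = q[2],
      n = length(values))
}

#' @describeIn BinSelection the selected bin count
#' @param object a BinSelection
#' @export
setMethod("nBins", "BinSelection", function(object) object@k)

setMethod("show", "BinSelection", function(object) {
  cat(sprintf(paste0("Freedman-Diaconis bin selection: K = %d ",
                     "(width %.4g; Q1 = %.4g, Q3 = %.4g, n = %d)\n"),
              object@k, object@binWidth, object@q1, object@q3, object@n))
})

#' Subsampling permutation test for an index contrast
#'
#' Tests whether the local (or global) index differs between two
#' conditions. The full-data indices fix the ordering; then for
#' \code{nIter} iterations a fraction of each condition's observations is
#' drawn without replacement, the index is recomputed on each subsample,
#' and the iteration counts as contradicting when the subsampled ordering
#' strictly reverses the full-data ordering (ties count as
#' non-contradicting, which is conservative). The p-value is the fraction
#' of contradicting iterations, floored at \code{1/nIter}: a fraction of 0
#' is reported as the attained bound, never as 0.
#'
#' Under the null of identical conditions the two subsampled indices are
#' exchangeable, so the contradiction fraction concentrates around 0.5;
#' well-separated conditions rarely if ever contradict.
#'
#' @param sampleA,sampleB [PairedSample-class] objects of the same mode.
#' @param k number of histogram bins, shared by every index computation.
#' @param statistic \code{"LI"} or \code{"GI"}.
#' @param nIter number of subsampling iterations.
#' @param subsampleFraction fraction of each condition drawn per iteration
#'   (without replacement), in (0, 1).
#' @param seed integer seed; identical inputs and seed give an identical
#'   p-value.
#' @return a [PermutationTestResult-class].
#' @examples
#' a <- simulateCoorientation(orientationSimConfig(500, 1, sigmaX = 25))
#' b <- simulateCoorientation(orientationSimConfig(500, 2, sigmaX = 25,
#'                                                 alpha = 0.5))
#' permutationTest(a, b, k = 15, nIter = 20, seed = 3)
#' @export
permutationTest <- function(sampleA, sampleB, k,
                            statistic = c("LI", "GI"), nIter = 100L,
                            subsampleFraction = 0.5, seed = NULL) {
  stopifnot(is(sampleA, "PairedSample"), is(sampleB, "PairedSample"))
  if (sampleMode(sampleA) != sampleMode(sampleB))
    stop("both conditions must share the analysis mode", call. = FALSE)
  statistic <- match.arg(statistic)
  k <- .assertCount(k, "k", min = 2L)
  nIter <- .assertCount(nIter, "nIter")
  if (subsampleFraction <= 0 || subsampleFraction >= 1)
    stop("'subsampleFraction' must lie in (0, 1)", call. = FALSE)
  seed <- .assertSeed(seed)
  mA <- floor(subsampleFraction * sampleSize(sampleA))
  mB <- floor(subsampleFraction * sampleSize(sampleB))
  if (mA < 2L || mB < 2L)
    stop("subsample size below 2; increase the fraction or the sample",
         call. = FALSE)
  stat <- function(s) {
    r <- computeDeBias(s, k = k)
    if (statistic == "LI") r@li else r@gi
  }
  sub <- function(s, m) {
    idx <- sample.int(sampleSize(s), m)
    PairedSample(s@x[idx], s@y[idx], mode = sampleMode(s))
  }
  res <- withSeed(seed, {
    fullA <- stat(sampleA)
    fullB <- stat(sampleB)
    aLess <- fullA < fullB
    contra <- 0L
    for (i in seq_len(nIter)) {
      sA <- stat(sub(sampleA, mA))
      sB <- stat(sub(sampleB, mB))
      if ((aLess && sA > sB) || (!aLess && sB > sA)) contra <- contra + 1L
    }
    list(fullA = fullA, fullB = fullB, aLess = aLess, contra = contra)
  })
  frac <- res$contra / nIter
  new("PermutationTestResult",
      pValue = max(frac, 1 / nIter), fractionContradicting = frac,
      nIter = nIter, subsampleFraction = subsampleFraction,
      direction = if (res$aLess) "a_less" else "b_less",
      statistic = statistic, statisticA = res$fullA,
      statisticB = res$fullB,
      seed = if (is.null(seed)) NA_integer_ else seed)
}

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf("Subsampling permutation test on %s\n", object@statistic))
  cat(sprintf("  full-data %s: A = %.4f, B = %.4f (%s)\n", object@statistic,
              object@statisticA, object@statisticB, object@direction))
  cat(sprintf("  contradicting fraction: %.3f over %d iterations (%.0f%% subsamples)\n",
              object@fractionContradicting, object@nIter,
              100 * object@subsampleFraction))
  cat(sprintf("  p-value: %s%.4g\n",
              if (object@fractionContradicting == 0) "<= " else "",
              object@pValue))
})

#' Group samples into a named condition
#'
#' @param name condition name.
#' @param samples list of [PairedSample-class] objects sharing one mode.
#' @param k bin count used for every index computed within the set.
#' @return a [ConditionSet-class].
#' @export
conditionSet <- function(name, samples, k) {
  if (is(samples, "PairedSample")) samples <- list(samples)
  new("ConditionSet", name = as.character(name), samples = samples,
      mode = sampleMode(samples[[1]]), k = .assertCount(k, "k", min = 2L))
}

#' Per-sample indices of a condition
#'
#' Computes the decomposition for every member sample with the set's
#' shared K and returns a flat table, one row per sample.
#'
#' @param set a [ConditionSet-class].
#' @param seed integer seed; member i uses \code{seed + i - 1}.
#' @param resampleReps passed to [computeDeBias()].
#' @return a data.frame with columns condition, label, n, gi, li.
#' @export
conditionIndices <- function(set, seed = NULL, resampleReps = 1L) {
  stopifnot(is(set, "ConditionSet"))
  seed <- .assertSeed(seed)
  rows <- lapply(seq_along(set@samples), function(i) {
    s <- set@samples[[i]]
    r <- computeDeBias(s, k = set@k,
                       seed = if (is.null(seed)) NULL else seed + i - 1L,
                       resampleReps = resampleReps)
    data.frame(condition = set@name, label = sampleLabel(s),
               n = sampleSize(s), gi = r@gi, li = r@li,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank-based comparison of per-sample indices between two conditions
#'
#' Convenience wrapper for replicated designs (one index per cell or field
#' of view): computes per-sample indices for both conditions and compares
#' them with a Wilcoxon rank-sum test. This is standard-issue group
#' statistics layered on top of the decomposition, complementary to the
#' subsampling [permutationTest()] which operates on pooled observations.
#' Both sets must share K (enforced).
#'
#' @param setA,setB [ConditionSet-class] objects with equal \code{k} and
#'   mode.
#' @param statistic \code{"LI"} or \code{"GI"}.
#' @param seed integer seed for the per-sample resampling.
#' @return a list with the per-condition index tables (\code{indicesA},
#'   \code{indicesB}) and the \code{htest} result (\code{test}).
#' @export
compareConditions <- function(setA, setB, statistic = c("LI", "GI"),
                              seed = NULL) {
  stopifnot(is(setA, "ConditionSet"), is(setB, "ConditionSet"))
  statistic <- match.arg(statistic)
  if (setA@k != setB@k)
    stop("conditions were binned with different K and cannot be compared",
         call. = FALSE)
  if (setA@mode != setB@mode)
    stop("conditions must share the analysis mode", call. = FALSE)
  ia <- conditionIndices(setA, seed = seed)
  ib <- conditionIndices(setB,
                         seed = if (is.null(seed)) NULL
                                else .assertSeed(seed) + length(setA@samples))
  col <- if (statistic == "LI") "li" else "gi"
  test <- stats::wilcox.test(ia[[col]], ib[[col]], exact = FALSE)
  list(indicesA = ia, indicesB = ib, test = test)
}

setMethod("show", "ConditionSet", function(object) {
  cat(sprintf("ConditionSet \"%s\": %d sample(s), %s mode, K = %d\n",
              object@name, length(object@samples), object@mode, object@k))
})
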