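#' Quantize values into an equal-width histogram on a fixed domain
#'
#' Bins \code{values} into \code{k} equal-width bins spanning
#' \code{[domainLow, domainHigh]}. Bins are half-open
#' \eqn{[e_j, e_{j+1})} except the last, which is closed, so the domain
#' maximum falls into bin \code{k} rather than being dropped. The histogram
#' stores frequencies (counts divided by N), making downstream distances
#' independent of sample size.
#'
#' @param values numeric vector; every value must lie inside the domain.
#' @param domainLow,domainHigh domain endpoints
#'   (\code{domainLow < domainHigh}).
#' @param k number of bins, at least 2.
#' @return a [CouplingHistogram-class].
#' @examples
#' quantize(c(5, 35, 65), 0, 90, 3)   # one observation per bin
#' @seealso [uniformReference()], [emd()]
#' @export
quantize <- function(values, domainLow, domainHigh, k) {
  k <- .assertCount(k, "k", min = 2L)
  stopifnot(is.numeric(domainLow), is.numeric(domainHigh),
            length(domainLow) == 1L, length(domainHigh) == 1L)
  if (!(domainLow < domainHigh))
    stop("'domainLow' must be smaller than 'domainHigh'", call. = FALSE)
  if (length(values) < 1L)
    stop("'values' must contain at least one observation", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite and free of missing values", call. = FALSE)
  out <- values < domainLow | values > domainHigh
  if (any(out))
    stop(sprintf("value %g lies outside the domain [%g, %g]",
                 values[which(out)[1L]], domainLow, domainHigh),
         call. = FALSE)
  idx <- floor((values - domainLow) / (domainHigh - domainLow) * k) + 1
  idx <- pmin(as.integer(idx), k)  # closed last bin
  counts <- tabulate(idx, nbins = k)
  new("CouplingHistogram", domainLow = domainLow, domainHigh = domainHigh,
      k = k, frequencies = counts / length(values),
      nSource = length(values))
}

#' Analytic uniform reference histogram
#'
#' The flat alignment histogram expected when neither global bias nor local
#' interaction is present; used as the baseline of both EMD comparisons.
#' Every frequency is exactly \code{1/k} -- the reference is analytic, not
#' sampled, so it adds no noise to the indices.
#'
#' @param k number of bins, at least 2.
#' @param domainLow,domainHigh the domain the reference lives on (defaults
#'   to the orientation alignment domain \code{[0, 90]} degrees; use
#'   \code{c(-1, 1)} for co-localization differences).
#' @return a [CouplingHistogram-class] with \code{nSource = 0}.
#' @examples
#' uniformReference(15)
#' @export
uniformReference <- function(k, domainLow = 0, domainHigh = 90) {
  k <- .assertCount(k, "k", min = 2L)
  if (!(domainLow < domainHigh))
    stop("'domainLow' must be smaller than 'domainHigh'", call. = FALSE)
  new("CouplingHistogram", domainLow = domainLow, domainHigh = domainHigh,
      k = k, frequencies = rep(1 / k, k), nSource = 0L)
}

# cumulative-sum L1 distance on frequency vectors
.emdFreq <- function(a, b) sum(abs(cumsum(a) - cumsum(b)))

#' @rdname emd
#' @export
setMethod("emd", signature(a = "CouplingHistogram", b = "CouplingHistogram"),
  function(a, b) {
    if (a@k != b@k)
      stop(sprintf(paste0("histograms with different bin counts (%d vs %d) ",
                          "cannot be compared; recompute with a shared K"),
                   a@k, b@k), call. = FALSE)
    if (abs(a@domainLow - b@domainLow) > 1e-9 ||
        abs(a@domainHigh - b@domainHigh) > 1e-9)
      stop("histograms live on different domains and cannot be compared",
           call. = FALSE)
    .emdFreq(a@frequencies, b@frequencies)
  })

#' @rdname meanAlignment
#' @export
setMethod("meanAlignment", "numeric", function(object) {
  if (length(object) < 1L)
    stop("cannot average an empty set of alignment values", call. = FALSE)
  mean(object)
})

#' @rdname meanAlignment
#' @export
setMethod("meanAlignment", "PairedSample", function(object) {
  mean(alignmentValues(object))
})

#' @describeIn CouplingHistogram number of bins
#' @param object a CouplingHistogram
#' @export
setMethod("nBins", "CouplingHistogram", function(object) object@k)

#' @describeIn CouplingHistogram bin frequencies (sum to 1)
#' @export
setMethod("frequencies", "CouplingHistogram", function(object)
  object@frequencies)

#' @describeIn CouplingHistogram the k + 1 bin edges
#' @export
setMethod("binEdges", "CouplingHistogram", function(object)
  seq(object@domainLow, object@domainHigh, length.out = object@k + 1L))

setMethod("show", "CouplingHistogram", function(object) {
  cat(sprintf("CouplingHistogram: %d bins on [%g, %g], from %d observations\n",
              object@k, object@domainLow, object@domainHigh, object@nSource))
  print(round(object@frequencies, 4))
})
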