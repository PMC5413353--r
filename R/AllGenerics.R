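#' @rdname accessors
#' @export
setGeneric("xValues", function(object) standardGeneric("xValues"))

#' @rdname accessors
#' @export
setGeneric("yValues", function(object) standardGeneric("yValues"))

#' @rdname accessors
#' @export
setGeneric("sampleMode", function(object) standardGeneric("sampleMode"))

#' @rdname accessors
#' @export
setGeneric("sampleLabel", function(object) standardGeneric("sampleLabel"))

#' @rdname accessors
#' @export
setGeneric("sampleSize", function(object) standardGeneric("sampleSize"))

#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))

#' @rdname accessors
#' @export
setGeneric("globalIndex", function(object) standardGeneric("globalIndex"))

#' @rdname accessors
#' @export
setGeneric("localIndex", function(object) standardGeneric("localIndex"))

#' Earth Mover's Distance between two same-K histograms
#'
#' For one-dimensional histograms on a shared domain with a shared number
#' of bins, the minimal-transport distance reduces to the L1 distance
#' between cumulative bin sums,
#' \deqn{EMD(A,B) = \sum_{i=1}^{K} \left| \sum_{j \le i} a_j -
#'   \sum_{j \le i} b_j \right|,}
#' measured in bin units. Histograms with different K or different domains
#' are not comparable and are rejected.
#'
#' @param a,b [CouplingHistogram-class] objects with identical \code{k} and
#'   domain.
#' @return a non-negative number; 0 if and only if the frequency vectors
#'   are identical.
#' @examples
#' a <- quantize(c(5, 35, 65), 0, 90, 3)
#' emd(a, uniformReference(3, 0, 90))
#' @export
setGeneric("emd", function(a, b) standardGeneric("emd"))

#' Mean alignment of a sample or of precomputed alignment values
#'
#' Arithmetic mean of the alignment values: for a numeric vector, its mean;
#' for a [PairedSample-class], the mean of its element-wise alignment
#' (alignment angle in degrees for orientation mode, normalized intensity
#' difference for co-localization mode).
#'
#' @param object numeric vector of alignment values, or a
#'   [PairedSample-class].
#' @return a single number.
#' @examples
#' meanAlignment(c(10, 30))
#' @export
setGeneric("meanAlignment", function(object) standardGeneric("meanAlignment"))
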