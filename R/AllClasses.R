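#' @import methods
NULL

.MODES <- c("orientation", "colocalization")

#' PairedSample: matched observations for one dataset
#'
#' Container for matched measurement pairs \eqn{(x_i, y_i)} from one
#' experiment or simulation. In \code{"orientation"} mode the two entries of
#' a pair are axial angles in degrees on \eqn{[-90, 90]} (values supplied on
#' \eqn{[0, 180)} are wrapped by mod-180 arithmetic); in
#' \code{"colocalization"} mode they are raw, non-negative fluorescence
#' intensities in arbitrary units.
#'
#' @slot x numeric vector of first-channel measurements.
#' @slot y numeric vector of second-channel measurements, matched to
#'   \code{x} element by element.
#' @slot mode character, either \code{"orientation"} or
#'   \code{"colocalization"}.
#' @slot label free-text label for the dataset.
#'
#' @seealso [PairedSample()] for the user-facing constructor,
#'   [computeDeBias()] for the decomposition.
#' @exportClass PairedSample
setClass("PairedSample",
  representation(x = "numeric", y = "numeric", mode = "character",
                 label = "character"),
  prototype(x = numeric(0), y = numeric(0), mode = "orientation", label = "")
)

setValidity("PairedSample", function(object) {
  msg <- NULL
  if (length(object@mode) != 1L || !object@mode %in% .MODES)
    msg <- c(msg, sprintf("'mode' must be one of: %s",
                          paste(.MODES, collapse = ", ")))
  if (length(object@x) != length(object@y))
    msg <- c(msg, "'x' and 'y' must have the same length")
  if (length(object@x) < 1L)
    msg <- c(msg, "a PairedSample needs at least one observation")
  if (anyNA(object@x) || anyNA(object@y) ||
      any(!is.finite(object@x)) || any(!is.finite(object@y)))
    msg <- c(msg, "'x' and 'y' must be finite and free of missing values")
  else if (identical(object@mode, "orientation")) {
    if (any(object@x < -90 | object@x > 90) || any(object@y < -90 | object@y > 90))
      msg <- c(msg, "orientation values must lie in [-90, 90] degrees")
  } else {
    if (any(object@x < 0) || any(object@y < 0))
      msg <- c(msg, "colocalization intensities must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' CouplingHistogram: a K-bin distribution on a fixed domain
#'
#' Equal-width histogram of alignment angles (domain \eqn{[0, 90]} degrees)
#' or normalized intensity differences (domain \eqn{[-1, 1]}), stored as
#' frequencies (fractions of observations) so that distances between
#' histograms do not depend on the number of source observations. Bins are
#' half-open \eqn{[e_j, e_{j+1})} except the last, which is closed so the
#' domain maximum is counted.
#'
#' @slot domainLow,domainHigh numeric, the domain endpoints
#'   (\code{domainLow < domainHigh}).
#' @slot k integer, number of bins (at least 2).
#' @slot frequencies numeric vector of length \code{k}; non-negative, sums
#'   to 1 when \code{nSource > 0}.
#' @slot nSource integer, the number of observations that were quantized
#'   (0 for analytic references).
#'
#' @seealso [quantize()], [uniformReference()], [emd()]
#' @exportClass CouplingHistogram
setClass("CouplingHistogram",
  representation(domainLow = "numeric", domainHigh = "numeric",
                 k = "integer", frequencies = "numeric", nSource = "integer")
)

setValidity("CouplingHistogram", function(object) {
  msg <- NULL
  if (length(object@k) != 1L || object@k < 2L)
    msg <- c(msg, "'k' must be a single integer >= 2")
  if (length(object@domainLow) != 1L || length(object@domainHigh) != 1L ||
      !(object@domainLow < object@domainHigh))
    msg <- c(msg, "'domainLow' must be smaller than 'domainHigh'")
  if (length(object@frequencies) != object@k)
    msg <- c(msg, "'frequencies' must have exactly 'k' entries")
  if (any(object@frequencies < 0))
    msg <- c(msg, "'frequencies' must be non-negative")
  if (object@nSource < 0L)
    msg <- c(msg, "'nSource' must be non-negative")
  if (object@nSource > 0L &&
      abs(sum(object@frequencies) - 1) > 1e-12)
    msg <- c(msg, "'frequencies' must sum to 1 (within 1e-12)")
  if (is.null(msg)) TRUE else msg
})

#' DeBiasResult: global and local indices for one sample
#'
#' Result of the global-bias/local-interaction decomposition: the global
#' index \eqn{GI = EMD(uniform, resampled)}, the local index
#' \eqn{LI = EMD(uniform, observed) - GI}, the two intermediate EMD values,
#' the observed and resampled histograms, and the full provenance (K, N,
#' mode, seed, number of resampling repetitions) needed to reproduce the
#' result bitwise.
#'
#' @slot gi,li numeric, the global and local indices. \code{gi >= 0};
#'   \code{li} may be negative (anti-alignment / anti-colocalization).
#' @slot emdObserved,emdResampled numeric, EMD(uniform, observed) and
#'   EMD(uniform, resampled).
#' @slot k integer, bins used. @slot n integer, observations used.
#' @slot mode character, analysis mode.
#' @slot seed integer, RNG seed used for the resampling.
#' @slot resampleReps integer, number of resampled histograms averaged.
#' @slot label character, carried over from the input sample.
#' @slot observed,resampled the two [CouplingHistogram-class] objects.
#'
#' @seealso [computeDeBias()], [globalIndex()], [localIndex()]
#' @exportClass DeBiasResult
setClass("DeBiasResult",
  representation(gi = "numeric", li = "numeric", emdObserved = "numeric",
                 emdResampled = "numeric", k = "integer", n = "integer",
                 mode = "character", seed = "integer",
                 resampleReps = "integer", label = "character",
                 observed = "CouplingHistogram",
                 resampled = "CouplingHistogram")
)

setValidity("DeBiasResult", function(object) {
  msg <- NULL
  if (abs(object@gi - object@emdResampled) > 1e-12)
    msg <- c(msg, "'gi' must equal 'emdResampled'")
  if (abs(object@li - (object@emdObserved - object@gi)) > 1e-12)
    msg <- c(msg, "'li' must equal 'emdObserved' - 'gi'")
  if (object@gi < 0)
    msg <- c(msg, "'gi' must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' OrientationSimConfig: parameters of the co-orientation generator
#'
#' Full parameterization of the synthetic co-orientation model: both
#' marginals are truncated normal on \eqn{(-90, 90)} degrees with common
#' mean \code{mu} and standard deviations \code{sigmaX}, \code{sigmaY}
#' (pre-truncation). A local interaction shifts one member of each pair
#' (chosen by a Bernoulli(0.5) draw) toward the other along the shorter
#' axial path, either by a fraction \code{alpha} of the current alignment
#' angle (\code{interaction = "proportional"}; negative \code{alpha} moves
#' away, i.e. anti-alignment) or by a constant \code{zeta} degrees capped
#' at the available gap (\code{interaction = "constant"}).
#'
#' @slot mu,sigmaX,sigmaY numeric, degrees.
#' @slot interaction character, \code{"proportional"} or \code{"constant"}.
#' @slot alpha numeric in \eqn{[-1, 1]} (proportional mode).
#' @slot zeta numeric \eqn{\ge 0} degrees (constant mode).
#' @slot n,seed integer.
#'
#' @seealso [orientationSimConfig()], [simulateCoorientation()]
#' @exportClass OrientationSimConfig
setClass("OrientationSimConfig",
  representation(mu = "numeric", sigmaX = "numeric", sigmaY = "numeric",
                 interaction = "character", alpha = "numeric",
                 zeta = "numeric", n = "integer", seed = "integer")
)

setValidity("OrientationSimConfig", function(object) {
  msg <- NULL
  if (object@sigmaX <= 0 || object@sigmaY <= 0)
    msg <- c(msg, "'sigmaX' and 'sigmaY' must be positive")
  if (!object@interaction %in% c("proportional", "constant"))
    msg <- c(msg, "'interaction' must be \"proportional\" or \"constant\"")
  if (identical(object@interaction, "proportional") && abs(object@alpha) > 1)
    msg <- c(msg, "'alpha' must lie in [-1, 1]")
  if (identical(object@interaction, "constant") && object@zeta < 0)
    msg <- c(msg, "'zeta' must be non-negative")
  if (object@n < 1L) msg <- c(msg, "'n' must be a positive integer")
  if (is.null(msg)) TRUE else msg
})

#' ColocSimConfig: parameters of the co-localization generator
#'
#' Synthetic co-localization model: \eqn{x_i} is truncated normal on
#' \eqn{[0, 1]} with mean \code{muX} and sd \code{sigmaX}; an interacting
#' subgroup (fraction \code{interactingFraction}, chosen by a seeded random
#' assignment) receives \eqn{y_i = x_i \zeta_i} with \eqn{\zeta_i} drawn
#' from Normal(\code{muZeta}, \code{sigmaZeta}) conditioned on
#' \eqn{y_i \in [0, 1]}; the remaining observations draw \eqn{y_i}
#' independently from a truncated normal on \eqn{(0, 1)} with mean
#' \code{muX} and sd \code{sigmaYNoninteracting}. A one-to-one interaction
#' corresponds to \code{muZeta = 1}; larger \code{sigmaZeta} weakens it.
#'
#' @slot muX numeric in (0, 1). @slot sigmaX numeric > 0.
#' @slot muZeta numeric. @slot sigmaZeta numeric >= 0.
#' @slot interactingFraction numeric in [0, 1].
#' @slot sigmaYNoninteracting numeric > 0.
#' @slot n,seed integer.
#'
#' @seealso [colocSimConfig()], [simulateColocalization()]
#' @exportClass ColocSimConfig
setClass("ColocSimConfig",
  representation(muX = "numeric", sigmaX = "numeric", muZeta = "numeric",
                 sigmaZeta = "numeric", interactingFraction = "numeric",
                 sigmaYNoninteracting = "numeric", n = "integer",
                 seed = "integer")
)

setValidity("ColocSimConfig", function(object) {
  msg <- NULL
  if (object@muX <= 0 || object@muX >= 1)
    msg <- c(msg, "'muX' must lie in (0, 1)")
  if (object@sigmaX <= 0) msg <- c(msg, "'sigmaX' must be positive")
  if (object@sigmaZeta < 0) msg <- c(msg, "'sigmaZeta' must be non-negative")
  if (object@interactingFraction < 0 || object@interactingFraction > 1)
    msg <- c(msg, "'interactingFraction' must lie in [0, 1]")
  if (object@sigmaYNoninteracting <= 0)
    msg <- c(msg, "'sigmaYNoninteracting' must be positive")
  if (object@n < 1L) msg <- c(msg, "'n' must be a positive integer")
  if (is.null(msg)) TRUE else msg
})

#' BinSelection: automatic histogram bin count
#'
#' Outcome of the Freedman-Diaconis bin selection: the bin width
#' \eqn{(Q_3 - Q_1)/n^{1/3}} and the resulting number of bins
#' \eqn{K = \lceil (domainHigh - domainLow)/width \rceil}, clamped to
#' \eqn{[3, 100]}.
#'
#' @slot k integer. @slot binWidth numeric.
#' @slot q1,q3 numeric, the quartiles used. @slot n integer.
#'
#' @seealso [selectBins()]
#' @exportClass BinSelection
setClass("BinSelection",
  representation(k = "integer", binWidth = "numeric", q1 = "numeric",
                 q3 = "numeric", n = "integer")
)

setValidity("BinSelection", function(object) {
  msg <- NULL
  if (object@k < 3L || object@k > 100L)
    msg <- c(msg, "'k' must lie in [3, 100]")
  if (object@binWidth <= 0) msg <- c(msg, "'binWidth' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' PermutationTestResult: subsampling test for an index contrast
#'
#' Outcome of the subsampling permutation test comparing the local (or
#' global) index of two conditions: the fraction of subsampling iterations
#' whose index ordering contradicts the full-data ordering, and the
#' reported p-value, floored at \code{1/nIter} so that a contradiction
#' count of zero is reported as the attained bound rather than zero.
#'
#' @slot pValue numeric in [0, 1].
#' @slot fractionContradicting numeric in [0, 1].
#' @slot nIter integer. @slot subsampleFraction numeric in (0, 1).
#' @slot direction character, \code{"a_less"} or \code{"b_less"} (full-data
#'   ordering).
#' @slot statistic character, \code{"LI"} or \code{"GI"}.
#' @slot statisticA,statisticB numeric, the full-data index per condition.
#' @slot seed integer.
#'
#' @seealso [permutationTest()]
#' @exportClass PermutationTestResult
setClass("PermutationTestResult",
  representation(pValue = "numeric", fractionContradicting = "numeric",
                 nIter = "integer", subsampleFraction = "numeric",
                 direction = "character", statistic = "character",
                 statisticA = "numeric", statisticB = "numeric",
                 seed = "integer")
)

setValidity("PermutationTestResult", function(object) {
  msg <- NULL
  if (object@nIter < 1L) msg <- c(msg, "'nIter' must be >= 1")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "'pValue' must lie in [0, 1]")
  if (object@fractionContradicting == 0 && object@pValue < 1 / object@nIter)
    msg <- c(msg, "'pValue' must be floored at 1/nIter")
  if (!object@direction %in% c("a_less", "b_less"))
    msg <- c(msg, "'direction' must be \"a_less\" or \"b_less\"")
  if (!object@statistic %in% c("LI", "GI"))
    msg <- c(msg, "'statistic' must be \"LI\" or \"GI\"")
  if (is.null(msg)) TRUE else msg
})

#' ConditionSet: a named group of samples analysed with one K
#'
#' Groups replicate [PairedSample-class] objects belonging to one
#' experimental condition. All members must share the analysis mode, and a
#' single bin count K is attached to the whole set because indices are
#' comparable only when evaluated with the same K.
#'
#' @slot name character. @slot samples list of PairedSample.
#' @slot mode character. @slot k integer.
#'
#' @seealso [conditionSet()], [conditionIndices()]
#' @exportClass ConditionSet
setClass("ConditionSet",
  representation(name = "character", samples = "list", mode = "character",
                 k = "integer")
)

setValidity("ConditionSet", function(object) {
  msg <- NULL
  if (length(object@samples) < 1L)
    msg <- c(msg, "a ConditionSet needs at least one sample")
  if (!all(vapply(object@samples, is, logical(1), class2 = "PairedSample")))
    msg <- c(msg, "'samples' must be a list of PairedSample objects")
  else if (!all(vapply(object@samples, sampleMode, character(1)) == object@mode))
    msg <- c(msg, "all member samples must share the set's mode")
  if (object@k < 2L) msg <- c(msg, "'k' must be >= 2")
  if (is.null(msg)) TRUE else msg
})
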