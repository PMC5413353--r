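#' Read a two-column paired table
#'
#' Reads matched pairs from a CSV or TSV file with exactly two numeric
#' columns (an optional header row is auto-detected). Rows with missing or
#' non-numeric entries are dropped with a logged count. Orientation values
#' are wrapped into \eqn{[-90, 90]} degrees.
#'
#' @param path file path.
#' @param mode \code{"orientation"} or \code{"colocalization"}.
#' @param dialect \code{"auto"} (by file extension; default comma),
#'   \code{"csv"} or \code{"tsv"}.
#' @param label optional label; defaults to the file name.
#' @return a [PairedSample-class].
#' @export
readPairedTable <- function(path, mode = c("orientation", "colocalization"),
                            dialect = c("auto", "csv", "tsv"),
                            label = NULL) {
  mode <- match.arg(mode)
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- switch(dialect,
                csv = ",", tsv = "\t",
                auto = if (grepl("\\.tsv$|\\.tab$|\\.txt$",
                                 tolower(path))) "\t" else ",")
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           strip.white = TRUE, fill = FALSE)
  if (ncol(raw) != 2L)
    stop(sprintf("%s: expected exactly 2 columns, found %d", path,
                 ncol(raw)), call. = FALSE)
  # header detection: a first row that does not parse as two numbers
  first <- suppressWarnings(as.numeric(raw[1L, ]))
  if (anyNA(first)) raw <- raw[-1L, , drop = FALSE]
  x <- suppressWarnings(as.numeric(raw[[1L]]))
  y <- suppressWarnings(as.numeric(raw[[2L]]))
  keep <- is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  if (dropped > 0L)
    .logmsg("%s: dropped %d row(s) with missing or non-numeric entries",
            path, dropped)
  if (!any(keep))
    stop(sprintf("%s: no valid data rows", path), call. = FALSE)
  PairedSample(x[keep], y[keep], mode = mode,
               label = if (is.null(label)) basename(path) else label)
}

#' Write a PairedSample as a two-column CSV
#'
#' The written file round-trips through [readPairedTable()].
#'
#' @param sample a [PairedSample-class].
#' @param path destination path.
#' @return the path, invisibly.
#' @export
writePairedTable <- function(sample, path) {
  stopifnot(is(sample, "PairedSample"))
  utils::write.csv(data.frame(x = sample@x, y = sample@y), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract matched pixel pairs from two single-channel TIFF images
#'
#' Reads two same-sized single-channel TIFF images (intensities are taken
#' as stored, with no rescaling) and pairs them pixel by pixel, optionally
#' restricted to the non-zero pixels of a mask image of the same shape and
#' optionally subsampled to a seeded random subset.
#'
#' @param pathX,pathY TIFF file paths.
#' @param mask optional TIFF mask path; non-zero pixels are included.
#' @param subsampleN optional cap on the number of pixel pairs.
#' @param seed integer seed for the subsampling.
#' @param mode analysis mode of the resulting sample; pixel intensities
#'   are co-localization data unless the images encode orientations.
#' @return a [PairedSample-class].
#' @export
readImagePair <- function(pathX, pathY, mask = NULL, subsampleN = NULL,
                          seed = NULL,
                          mode = c("colocalization", "orientation")) {
  mode <- match.arg(mode)
  img <- function(p) {
    a <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(a)) != 2L)
      stop(sprintf("%s: expected a single-channel image", p), call. = FALSE)
    a
  }
  ix <- img(pathX)
  iy <- img(pathY)
  if (!identical(dim(ix), dim(iy)))
    stop(sprintf("image shapes differ: %s vs %s",
                 paste(dim(ix), collapse = "x"),
                 paste(dim(iy), collapse = "x")), call. = FALSE)
  keep <- rep(TRUE, length(ix))
  if (!is.null(mask)) {
    im <- img(mask)
    if (!identical(dim(im), dim(ix)))
      stop("mask shape differs from the image shape", call. = FALSE)
    keep <- as.vector(im) != 0
    if (!any(keep)) stop("mask selects no pixels", call. = FALSE)
  }
  x <- as.vector(ix)[keep]
  y <- as.vector(iy)[keep]
  if (!is.null(subsampleN) && subsampleN < length(x)) {
    idx <- withSeed(.assertSeed(seed),
                    sample.int(length(x), .assertCount(subsampleN,
                                                       "subsampleN")))
    x <- x[idx]
    y <- y[idx]
  }
  .logmsg("image pair %s / %s: %d pixel pairs", basename(pathX),
          basename(pathY), length(x))
  PairedSample(x, y, mode = mode,
               label = sprintf("%s|%s", basename(pathX), basename(pathY)))
}

.resultToList <- function(result) {
  if (is(result, "DeBiasResult")) {
    list(type = "DeBiasResult", gi = result@gi, li = result@li,
         emd_observed = result@emdObserved,
         emd_resampled = result@emdResampled, k = result@k, n = result@n,
         mode = result@mode, seed = result@seed,
         resample_reps = result@resampleReps, label = result@label,
         observed_frequencies = result@observed@frequencies,
         resampled_frequencies = result@resampled@frequencies,
         domain = c(result@observed@domainLow, result@observed@domainHigh))
  } else if (is(result, "PermutationTestResult")) {
    list(type = "PermutationTestResult", p_value = result@pValue,
         fraction_contradicting = result@fractionContradicting,
         n_iter = result@nIter,
         subsample_fraction = result@subsampleFraction,
         direction = result@direction, statistic = result@statistic,
         statistic_a = result@statisticA, statistic_b = result@statisticB,
         seed = result@seed)
  } else stop("unsupported result type", call. = FALSE)
}

.resultFlatRow <- function(result) {
  l <- .resultToList(result)
  l$observed_frequencies <- NULL
  l$resampled_frequencies <- NULL
  l$domain <- NULL
  as.data.frame(l, stringsAsFactors = FALSE)
}

#' Write a result to JSON or CSV
#'
#' JSON round-trips every field, including the seed, so re-running the
#' computation from the recorded inputs and seed reproduces the result
#' bitwise ([readResult()] restores the object). CSV writes one flat row
#' with a header (histograms omitted).
#'
#' @param result a [DeBiasResult-class] or [PermutationTestResult-class].
#' @param path destination path.
#' @param format \code{"json"} or \code{"csv"}.
#' @return the path, invisibly.
#' @export
writeResult <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    # I(17) significant digits: doubles survive the round-trip exactly
    jsonlite::write_json(.resultToList(result), path, auto_unbox = TRUE,
                         digits = I(17), null = "null", na = "null")
  } else {
    utils::write.csv(.resultFlatRow(result), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read a result written by [writeResult()]
#'
#' @param path a JSON file written by [writeResult()].
#' @return the restored [DeBiasResult-class] or
#'   [PermutationTestResult-class].
#' @export
readResult <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  asint <- function(v) if (is.null(v) || is.na(v)) NA_integer_ else
    as.integer(v)
  if (identical(l$type, "DeBiasResult")) {
    dom <- as.numeric(l$domain)
    mk <- function(f) new("CouplingHistogram", domainLow = dom[1],
                          domainHigh = dom[2], k = asint(l$k),
                          frequencies = as.numeric(f),
                          nSource = asint(l$n))
    new("DeBiasResult", gi = l$gi, li = l$li,
        emdObserved = l$emd_observed, emdResampled = l$emd_resampled,
        k = asint(l$k), n = asint(l$n), mode = l$mode,
        seed = asint(l$seed), resampleReps = asint(l$resample_reps),
        label = if (is.null(l$label)) "" else l$label,
        observed = mk(l$observed_frequencies),
        resampled = mk(l$resampled_frequencies))
  } else if (identical(l$type, "PermutationTestResult")) {
    new("PermutationTestResult", pValue = l$p_value,
        fractionContradicting = l$fraction_contradicting,
        nIter = asint(l$n_iter),
        subsampleFraction = l$subsample_fraction,
        direction = l$direction, statistic = l$statistic,
        statisticA = l$statistic_a, statisticB = l$statistic_b,
        seed = asint(l$seed))
  } else stop(sprintf("%s: not a recognised result file", path),
              call. = FALSE)
}

.configToList <- function(config) {
  if (is(config, "OrientationSimConfig")) {
    list(type = "OrientationSimConfig", mu = config@mu,
         sigma_x = config@sigmaX, sigma_y = config@sigmaY,
         interaction = config@interaction, alpha = config@alpha,
         zeta = config@zeta, n = config@n, seed = config@seed)
  } else {
    list(type = "ColocSimConfig", mu_x = config@muX,
         sigma_x = config@sigmaX, mu_zeta = config@muZeta,
         sigma_zeta = config@sigmaZeta,
         interacting_fraction = config@interactingFraction,
         sigma_y_noninteracting = config@sigmaYNoninteracting,
         n = config@n, seed = config@seed)
  }
}

#' Read a simulation sidecar config
#'
#' Restores the generator configuration written next to a simulated CSV by
#' [writeSimulation()]; re-running the matching simulator on it reproduces
#' the dataset exactly.
#'
#' @param path JSON sidecar path.
#' @return an [OrientationSimConfig-class] or [ColocSimConfig-class].
#' @export
readSimConfig <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(l$type, "OrientationSimConfig")) {
    orientationSimConfig(n = l$n, seed = l$seed, sigmaX = l$sigma_x,
                         sigmaY = l$sigma_y, mu = l$mu,
                         interaction = l$interaction, alpha = l$alpha,
                         zeta = l$zeta)
  } else if (identical(l$type, "ColocSimConfig")) {
    colocSimConfig(n = l$n, seed = l$seed, muX = l$mu_x,
                   sigmaX = l$sigma_x, muZeta = l$mu_zeta,
                   sigmaZeta = l$sigma_zeta,
                   interactingFraction = l$interacting_fraction,
                   sigmaYNoninteracting = l$sigma_y_noninteracting)
  } else stop(sprintf("%s: not a simulation config", path), call. = FALSE)
}

#' Run a simulator and write its dataset plus a config sidecar
#'
#' Writes the simulated pairs as a two-column CSV (the package's canonical
#' interchange format) and the full configuration as a JSON sidecar at
#' \code{<path>.json}, so the dataset is exactly reproducible.
#'
#' @param config an [OrientationSimConfig-class] or
#'   [ColocSimConfig-class].
#' @param path CSV destination path.
#' @return the simulated [PairedSample-class], invisibly.
#' @export
writeSimulation <- function(config, path) {
  sample <- if (is(config, "OrientationSimConfig"))
    simulateCoorientation(config) else simulateColocalization(config)
  writePairedTable(sample, path)
  jsonlite::write_json(.configToList(config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sample)
}
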