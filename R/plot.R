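#' Diagnostic histogram plot for a decomposition
#'
#' Plots the observed and resampled alignment histograms side by side with
#' the uniform reference line. A large gap between the resampled bars and
#' the uniform line is global bias; an additional gap between observed and
#' resampled bars is local interaction.
#'
#' @param result a [DeBiasResult-class].
#' @param main plot title.
#' @return invisibly, the matrix of plotted frequencies.
#' @export
plotDeBias <- function(result, main = NULL) {
  stopifnot(is(result, "DeBiasResult"))
  freq <- rbind(observed = result@observed@frequencies,
                resampled = result@resampled@frequencies)
  centers <- (binEdges(result@observed)[-1] +
              binEdges(result@observed)[-(result@k + 1L)]) / 2
  colnames(freq) <- signif(centers, 3)
  if (is.null(main))
    main <- sprintf("GI = %.3f, LI = %.3f (K = %d, N = %d)",
                    result@gi, result@li, result@k, result@n)
  graphics::barplot(freq, beside = TRUE, col = c("grey25", "grey70"),
                    border = NA, main = main,
                    xlab = if (result@mode == "orientation")
                      "alignment angle (degrees)"
                    else "normalized intensity difference",
                    ylab = "frequency")
  graphics::abline(h = 1 / result@k, lty = 2)
  graphics::legend("topright", bty = "n",
                   fill = c("grey25", "grey70", NA),
                   border = NA, lty = c(NA, NA, 2),
                   legend = c("observed", "resampled", "uniform"))
  invisible(freq)
}
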