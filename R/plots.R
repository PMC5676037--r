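# Minimal base-graphics views of the main results.

#' Histogram of apparent diffusion coefficients
#'
#' Two-colour D* histogram with the immobile/diffusing cutoff marked.
#'
#' @param stats data.frame with `dStar` (e.g. from [trackStats()]).
#' @param dThreshold classification cutoff drawn as a vertical line.
#' @param breaks passed to [graphics::hist()].
#' @return invisibly, the histogram object.
#' @export
plotDstarHistogram <- function(stats, dThreshold, breaks = 40) {
    h <- graphics::hist(stats$dStar, breaks = breaks, plot = FALSE)
    cols <- ifelse(h$mids < dThreshold, "firebrick", "steelblue")
    graphics::plot(h, col = cols, border = "white",
                   xlab = expression(D * "*" ~ (mu * m^2 / s)),
                   main = "Apparent diffusion coefficients")
    graphics::abline(v = dThreshold, lty = 2)
    invisible(h)
}

#' Peak density along the chromosome
#'
#' Inverse inter-peak distance (bars) and peak length (points) by genomic
#' position, the compact view of binding-site density and clustering.
#'
#' @param dens result of [densityProfile()].
#' @return `NULL`, invisibly.
#' @export
plotPeakDensity <- function(dens) {
    pp <- dens$perPeak
    graphics::plot(pp$midpoint, pp$invGap, type = "h",
                   xlab = "chromosome position (bp)",
                   ylab = "1 / distance to next peak (1/bp)",
                   main = "Binding-site density")
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(pp$midpoint, pp$lengthBp, col = "red", pch = 16,
                   cex = 0.5, axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "red")
    graphics::mtext("peak length (bp)", side = 4, line = 2, col = "red")
    invisible(NULL)
}

#' Mean long-axis fluorescence profile with confidence band
#'
#' @param avg result of [averageProfiles()].
#' @return `NULL`, invisibly.
#' @export
plotMeanProfile <- function(avg) {
    graphics::plot(avg$position, avg$mean, type = "l", lwd = 2,
                   ylim = range(c(avg$lower, avg$upper, avg$mean),
                                na.rm = TRUE),
                   xlab = "position along the long axis (fraction)",
                   ylab = "fluorescence (a.u.)",
                   main = sprintf("Mean profile (n = %d)", avg$n[1]))
    if (!all(is.na(avg$lower)))
        graphics::polygon(c(avg$position, rev(avg$position)),
                          c(avg$lower, rev(avg$upper)),
                          col = grDevices::adjustcolor("steelblue", 0.3),
                          border = NA)
    invisible(NULL)
}
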