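# nucleoid_profiles: long-axis fluorescence profiles, condensation extent,
# cohort averaging, colocalization and time-lapse summaries.

.poleBackground <- function(position, value, poleFraction = 0.05) {
    nearPole <- position <= poleFraction | position >= 1 - poleFraction
    if (!any(nearPole)) return(0)
    stats::median(value[nearPole])
}

#' Long-axis intensity profile from a 2D image
#'
#' Samples the mean intensity of an image in stripes perpendicular to the
#' pole-to-pole axis at `nSamples` equally spaced fractional positions,
#' restricted to pixels within half a cell width of the axis. Pixel centres
#' are taken at (column, row) coordinates.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param geom one-row data.frame (or list) with `ax`, `ay`, `bx`, `by`,
#'   `width` in pixel units.
#' @param nSamples number of positions along the axis (default 100).
#' @return data.frame with columns `position` (stripe centres in `[0, 1]`)
#'   and `value` (mean stripe intensity; `NA` for empty stripes).
#' @export
profileFromImage <- function(image, geom, nSamples = 100L) {
    stopifnot(is.matrix(image), nSamples >= 2L)
    g <- as.list(geom)
    ux <- g$bx - g$ax; uy <- g$by - g$ay
    len <- sqrt(ux^2 + uy^2)
    if (len <= 0) .stopf("cell axis has zero length")
    inX <- c(g$ax, g$bx) >= 0.5 & c(g$ax, g$bx) <= ncol(image) + 0.5
    inY <- c(g$ay, g$by) >= 0.5 & c(g$ay, g$by) <= nrow(image) + 0.5
    if (!all(inX & inY))
        .stopf("cell axis lies outside the image bounds")
    ux <- ux / len; uy <- uy / len
    px <- rep(seq_len(ncol(image)), each = nrow(image))
    py <- rep(seq_len(nrow(image)), times = ncol(image))
    rx <- px - g$ax; ry <- py - g$ay
    l <- (rx * ux + ry * uy) / len
    wPerp <- abs(rx * uy - ry * ux)
    keep <- l >= 0 & l <= 1 & wPerp <= g$width / 2
    bin <- pmin(pmax(ceiling(l[keep] * nSamples), 1L), nSamples)
    v <- as.vector(image)[keep]
    mean_by <- tapply(v, factor(bin, levels = seq_len(nSamples)), mean)
    data.frame(position = (seq_len(nSamples) - 0.5) / nSamples,
               value = as.numeric(mean_by))
}

#' Average intensity profiles across a cohort of cells
#'
#' Resamples every cell's profile onto a common fractional grid by linear
#' interpolation and returns the pointwise mean with a t-based 95% (by
#' default) confidence interval.
#'
#' @param profiles data.frame with columns `cell_id`, `position`, `value`
#'   (and optionally `channel`; use `channel` to select one).
#' @param channel optional channel name to subset on.
#' @param nGrid number of grid points (default 100).
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns `position`, `mean`, `lower`, `upper`,
#'   `n`. With a single cell the CI columns are `NA` and a warning is
#'   raised.
#' @export
averageProfiles <- function(profiles, channel = NULL, nGrid = 100L,
                            conf = 0.95) {
    stopifnot(is.data.frame(profiles),
              all(c("cell_id", "position", "value") %in% names(profiles)))
    if (!is.null(channel)) profiles <- profiles[profiles$channel == channel, ]
    cells <- unique(profiles$cell_id)
    if (!length(cells)) .stopf("no profiles to average")
    grid <- (seq_len(nGrid) - 0.5) / nGrid
    mat <- vapply(cells, function(cid) {
        p <- profiles[profiles$cell_id == cid, ]
        p <- p[order(p$position), ]
        stats::approx(p$position, p$value, xout = grid, rule = 2)$y
    }, numeric(nGrid))
    mat <- matrix(mat, nrow = nGrid)
    n <- length(cells)
    m <- rowMeans(mat)
    if (n < 2L) {
        .warnf("confidence interval undefined for a single profile")
        return(data.frame(position = grid, mean = m, lower = NA_real_,
                          upper = NA_real_, n = n))
    }
    s <- apply(mat, 1, stats::sd)
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
    data.frame(position = grid, mean = m, lower = m - half,
               upper = m + half, n = n)
}

#' Nucleoid condensation extent of one profile
#'
#' Measures the fraction of the cell length occupied by the fluorescence
#' signal: the profile is background-subtracted (background = median value
#' over the 5% of positions nearest each pole), and the extent is the
#' distance between the outermost positions where the signal reaches
#' `relThreshold` times its maximum — outermost crossings rather than the
#' largest contiguous run, so a two-lobed nucleoid is spanned whole. The
#' default threshold is 0.5 (full width at half maximum), which for
#' symmetric edge shapes is first-order unbiased in the edge softness. When
#' the profile has no pole-to-interior contrast (flat positive signal) the
#' raw profile is thresholded instead and the extent spans the whole cell.
#'
#' @param position positions in `[0, 1]` (fractions of cell length from the
#'   distant pole), strictly increasing.
#' @param value non-negative intensities, same length as `position`.
#' @param relThreshold relative threshold in (0, 1), default 0.5.
#' @param poleFraction fraction of cell length at each pole used for the
#'   background estimate (default 0.05).
#' @return list with `extentFraction`, `thresholdUsed` (absolute threshold
#'   on the background-subtracted scale) and `background`.
#' @examples
#' x <- (1:100 - 0.5) / 100
#' v <- as.numeric(x >= 0.1 & x <= 0.9)   # top-hat over the central 80%
#' condensationExtent(x, v)$extentFraction
#' @export
condensationExtent <- function(position, value, relThreshold = 0.5,
                               poleFraction = 0.05) {
    if (relThreshold <= 0 || relThreshold >= 1)
        .stopf("'relThreshold' must lie strictly between 0 and 1")
    stopifnot(length(position) == length(value))
    if (all(value == 0)) {
        .warnf("all-zero profile; extent is zero")
        return(list(extentFraction = 0, thresholdUsed = 0, background = 0))
    }
    bg <- .poleBackground(position, value, poleFraction)
    signal <- value - bg
    m <- max(signal)
    if (m <= 0) {
        # flat profile: the signal fills the cell, threshold the raw values
        signal <- value
        m <- max(signal)
        bg <- 0
    }
    thr <- relThreshold * m
    above <- which(signal >= thr)
    lo <- min(above); hi <- max(above)
    # linear interpolation of the outermost crossings removes the half-grid
    # discretization bias of taking the sampled positions themselves
    left <- position[lo]
    if (lo > 1L && signal[lo - 1L] < thr && signal[lo] > signal[lo - 1L])
        left <- position[lo - 1L] + (position[lo] - position[lo - 1L]) *
            (thr - signal[lo - 1L]) / (signal[lo] - signal[lo - 1L])
    right <- position[hi]
    if (hi < length(signal) && signal[hi + 1L] < thr &&
        signal[hi] > signal[hi + 1L])
        right <- position[hi] + (position[hi + 1L] - position[hi]) *
            (signal[hi] - thr) / (signal[hi] - signal[hi + 1L])
    extent <- right - left
    list(extentFraction = extent, thresholdUsed = thr, background = bg)
}

#' Condensation extent for every cell in a profile table
#'
#' @param profiles data.frame with columns `cell_id`, `position`, `value`
#'   (optionally `channel`).
#' @param channel optional channel to subset on.
#' @param ... passed to [condensationExtent()].
#' @return data.frame with columns `cell_id`, `extentFraction`,
#'   `thresholdUsed`.
#' @export
condensationByCell <- function(profiles, channel = NULL, ...) {
    stopifnot(is.data.frame(profiles))
    if (!is.null(channel)) profiles <- profiles[profiles$channel == channel, ]
    cells <- unique(profiles$cell_id)
    res <- lapply(cells, function(cid) {
        p <- profiles[profiles$cell_id == cid, ]
        p <- p[order(p$position), ]
        ce <- condensationExtent(p$position, p$value, ...)
        data.frame(cell_id = cid, extentFraction = ce$extentFraction,
                   thresholdUsed = ce$thresholdUsed)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Two-channel colocalization of intensity profiles
#'
#' Pearson correlation of two background-subtracted profiles after
#' resampling onto a common grid: 1 for perfectly overlapping signals, near
#' 0 for independent ones.
#'
#' @param p1,p2 data.frames with columns `position`, `value`.
#' @param nGrid resampling grid size (default 100).
#' @return correlation in `[-1, 1]`, or `NA` with a warning when either
#'   channel has zero variance.
#' @export
colocalizationOverlap <- function(p1, p2, nGrid = 100L) {
    grid <- (seq_len(nGrid) - 0.5) / nGrid
    res <- lapply(list(p1, p2), function(p) {
        p <- p[order(p$position), ]
        v <- stats::approx(p$position, p$value, xout = grid, rule = 2)$y
        v - .poleBackground(grid, v)
    })
    if (any(vapply(res, stats::sd, numeric(1)) == 0)) {
        .warnf("zero-variance channel; colocalization undefined")
        return(NA_real_)
    }
    stats::cor(res[[1]], res[[2]])
}

#' Time-lapse condensation between division events
#'
#' Computes the condensation extent of every frame of a single-cell lineage
#' and summarises it per segment, where segments are the intervals between
#' consecutive sister-chromosome separation (division) events. With fewer
#' than two recorded events the whole series forms one segment. Each
#' segment gets a mean extent and a t-based 95% confidence interval.
#'
#' @param profiles data.frame with columns `frame`, `position`, `value` for
#'   one lineage (one channel).
#' @param divisionFrames sorted integer frames at which divisions occurred.
#' @param relThreshold passed to [condensationExtent()].
#' @param conf confidence level (default 0.95).
#' @return list with `perFrame` (data.frame `frame`, `extentFraction`) and
#'   `segments` (data.frame `segment`, `startFrame`, `endFrame`, `mean`,
#'   `lower`, `upper`, `n`).
#' @export
timelapseCondensation <- function(profiles, divisionFrames,
                                  relThreshold = 0.5, conf = 0.95) {
    stopifnot(is.data.frame(profiles),
              all(c("frame", "position", "value") %in% names(profiles)))
    divisionFrames <- sort(divisionFrames)
    frames <- sort(unique(profiles$frame))
    perFrame <- do.call(rbind, lapply(frames, function(f) {
        p <- profiles[profiles$frame == f, ]
        p <- p[order(p$position), ]
        ce <- condensationExtent(p$position, p$value,
                                 relThreshold = relThreshold)
        data.frame(frame = f, extentFraction = ce$extentFraction)
    }))
    if (length(divisionFrames) < 2L) {
        bounds <- data.frame(startFrame = min(frames),
                             endFrame = max(frames))
    } else {
        bounds <- data.frame(
            startFrame = divisionFrames[-length(divisionFrames)],
            endFrame = divisionFrames[-1])
    }
    segs <- lapply(seq_len(nrow(bounds)), function(i) {
        inSeg <- perFrame$frame >= bounds$startFrame[i] &
            perFrame$frame < bounds$endFrame[i] |
            (i == nrow(bounds) & perFrame$frame == bounds$endFrame[i])
        e <- perFrame$extentFraction[inSeg]
        if (!length(e)) {
            .warnf("segment %d contains no frames; skipped", i)
            return(NULL)
        }
        m <- mean(e)
        if (length(e) > 1L) {
            half <- stats::qt(1 - (1 - conf) / 2, df = length(e) - 1) *
                stats::sd(e) / sqrt(length(e))
        } else half <- NA_real_
        data.frame(segment = i, startFrame = bounds$startFrame[i],
                   endFrame = bounds$endFrame[i], mean = m,
                   lower = m - half, upper = m + half, n = length(e))
    })
    segs <- do.call(rbind, segs)
    list(perFrame = perFrame, segments = segs)
}
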