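# spt: track linking, mean squared displacement, apparent diffusion
# coefficient D* and normalized intracellular coordinates.

#' Link localizations into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking: for every pair of
#' consecutive frames, candidate (track head, new localization) pairs within
#' `rMax` are assigned in order of increasing distance; ties break
#' deterministically on the lower localization row index, then the lower
#' track id. There is no gap closing, so a blinking gap terminates a track
#' and starts a new one. Linking is performed independently per cell when a
#' `cell_id` column is present.
#'
#' @param locs data.frame with columns `frame`, `x`, `y` and optionally
#'   `cell_id`.
#' @param rMax maximum linking radius (same length units as `x`, `y`).
#' @param minSteps minimum number of steps a track must have to be kept
#'   (default 4, i.e. at least 5 localizations).
#' @return data.frame with columns `track_id`, `frame`, `x`, `y`,
#'   `cell_id`, ordered by track then frame.
#' @export
linkTracks <- function(locs, rMax, minSteps = 4L) {
    stopifnot(is.data.frame(locs), all(c("frame", "x", "y") %in% names(locs)))
    if (!is.numeric(rMax) || rMax <= 0) .stopf("'rMax' must be positive")
    if (minSteps < 1) .stopf("'minSteps' must be at least 1")
    if (!"cell_id" %in% names(locs)) locs$cell_id <- "cell_1"
    locs <- locs[order(locs$cell_id, locs$frame), , drop = FALSE]
    locs$.row <- seq_len(nrow(locs))
    out <- lapply(split(locs, locs$cell_id), .linkOneCell, rMax = rMax)
    out <- do.call(rbind, out)
    if (is.null(out) || !nrow(out)) {
        return(data.frame(track_id = character(0), frame = integer(0),
                          x = numeric(0), y = numeric(0),
                          cell_id = character(0)))
    }
    nLoc <- table(out$track_id)
    keep <- names(nLoc)[nLoc >= minSteps + 1L]
    out <- out[out$track_id %in% keep, , drop = FALSE]
    out <- out[order(out$track_id, out$frame), , drop = FALSE]
    rownames(out) <- NULL
    out[, c("track_id", "frame", "x", "y", "cell_id")]
}

.linkOneCell <- function(locs, rMax) {
    frames <- sort(unique(locs$frame))
    byFrame <- split(locs, factor(locs$frame, levels = frames))
    trackOf <- integer(nrow(locs))       # index into local rows
    nextId <- 0L
    # track id per localization, keyed by local row order
    ids <- rep(NA_integer_, nrow(locs))
    rowIndex <- seq_len(nrow(locs))
    loc2local <- stats::setNames(rowIndex, rownames(locs))
    heads <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        row = integer(0))
    for (fi in seq_along(frames)) {
        cur <- byFrame[[fi]]
        curIdx <- loc2local[rownames(cur)]
        assigned <- rep(NA_integer_, nrow(cur))
        consecutive <- fi > 1L && frames[fi] == frames[fi - 1L] + 1L
        if (consecutive && nrow(heads) && nrow(cur)) {
            dx <- outer(heads$x, cur$x, `-`)
            dy <- outer(heads$y, cur$y, `-`)
            d <- sqrt(dx^2 + dy^2)
            d[d > rMax] <- NA
            usedHead <- rep(FALSE, nrow(heads))
            repeat {
                if (all(is.na(d))) break
                m <- min(d, na.rm = TRUE)
                cand <- which(d == m, arr.ind = TRUE)
                if (nrow(cand) > 1L) {
                    # tie-break: lower localization original index, then
                    # lower track id
                    ordc <- order(cur$.row[cand[, 2]], heads$id[cand[, 1]])
                    cand <- cand[ordc[1], , drop = FALSE]
                }
                hi <- cand[1, 1]; ci <- cand[1, 2]
                assigned[ci] <- heads$id[hi]
                usedHead[hi] <- TRUE
                d[hi, ] <- NA
                d[, ci] <- NA
            }
        }
        new <- which(is.na(assigned))
        if (length(new)) {
            assigned[new] <- nextId + seq_along(new)
            nextId <- nextId + length(new)
        }
        ids[curIdx] <- assigned
        heads <- data.frame(id = assigned, x = cur$x, y = cur$y,
                            row = cur$.row)
    }
    data.frame(track_id = sprintf("%s_t%04d", locs$cell_id[1], ids),
               frame = locs$frame, x = locs$x, y = locs$y,
               cell_id = locs$cell_id)
}

#' Mean squared displacement of one trajectory
#'
#' With `lagAveraged = FALSE` (default) returns the mean of the first
#' `nSteps` single-frame squared displacements,
#' `(1/n) * sum_i ||r_i - r_(i-1)||^2` — the four-step, lag-1 MSD used to
#' form the apparent diffusion coefficient. With `lagAveraged = TRUE`
#' returns the average of the time-averaged MSDs at lags `1..nSteps`.
#'
#' @param xy numeric matrix (n x 2) of positions ordered by frame, with
#'   consecutive frames.
#' @param nSteps number of steps entering the estimate (default 4).
#' @param lagAveraged average over lags 1..`nSteps` instead of the first
#'   `nSteps` lag-1 displacements.
#' @return MSD in squared length units.
#' @export
trackMSD <- function(xy, nSteps = 4L, lagAveraged = FALSE) {
    xy <- as.matrix(xy)
    nstep <- nrow(xy) - 1L
    if (nstep < nSteps)
        .stopf("track has %d step(s); %d required", nstep, nSteps)
    if (!lagAveraged) {
        d <- diff(xy[seq_len(nSteps + 1L), , drop = FALSE])
        return(mean(rowSums(d^2)))
    }
    msdLag <- vapply(seq_len(nSteps), function(lag) {
        d <- xy[-seq_len(lag), , drop = FALSE] -
            xy[seq_len(nrow(xy) - lag), , drop = FALSE]
        mean(rowSums(d^2))
    }, numeric(1))
    mean(msdLag)
}

#' Apparent diffusion coefficient from an MSD
#'
#' `D* = MSD / (4 * dt)` for two-dimensional tracks, where `dt` is the frame
#' interval. "Apparent" because confinement, motion blur and localization
#' error bias it relative to the true diffusion coefficient; in particular
#' immobile particles have a noise floor of `sigma^2 / dt` driven by the
#' localization error `sigma`.
#'
#' @param msd mean squared displacement (length^2).
#' @param dt frame interval in seconds.
#' @return D* in length^2 per second.
#' @examples
#' apparentDiffusion(0.04, 0.01)  # 1 um^2/s for msd in um^2
#' @export
apparentDiffusion <- function(msd, dt) {
    if (!is.numeric(dt) || any(dt <= 0))
        .stopf("'dt' must be a positive frame interval in seconds")
    if (any(msd < 0)) .stopf("'msd' must be non-negative")
    msd / (4 * dt)
}

#' Per-track MSD and D* for a table of trajectories
#'
#' Vectorised companion to [trackMSD()]/[apparentDiffusion()]: computes the
#' four-step lag-1 MSD and D* for every track in a long-format table. Tracks
#' with fewer than `nSteps` steps are dropped (their count is reported via a
#' message).
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x`, `y`.
#' @param dt frame interval in seconds.
#' @param nSteps number of steps entering each MSD (default 4).
#' @return data.frame with columns `track_id`, `nSteps`, `msd`, `dStar`.
#' @export
trackStats <- function(tracks, dt, nSteps = 4L) {
    stopifnot(is.data.frame(tracks),
              all(c("track_id", "frame", "x", "y") %in% names(tracks)))
    if (!is.numeric(dt) || dt <= 0) .stopf("'dt' must be positive")
    ord <- order(tracks$track_id, tracks$frame)
    tid <- as.character(tracks$track_id)[ord]
    x <- tracks$x[ord]; y <- tracks$y[ord]
    same <- tid[-1] == tid[-length(tid)]
    sq <- (diff(x)^2 + diff(y)^2)[same]
    stepTrack <- tid[-1][same]
    # step index within track
    stepIdx <- sequence(rle(stepTrack)$lengths)
    use <- stepIdx <= nSteps
    nPer <- tapply(use, stepTrack, sum)
    full <- names(nPer)[nPer == nSteps]
    dropped <- length(unique(tid)) - length(full)
    if (dropped > 0)
        message(dropped, " track(s) shorter than ", nSteps,
                " steps were dropped")
    sel <- use & stepTrack %in% full
    msd <- rowsum(sq[sel], stepTrack[sel])[, 1] / nSteps
    data.frame(track_id = names(msd), nSteps = nSteps, msd = as.numeric(msd),
               dStar = apparentDiffusion(as.numeric(msd), dt),
               row.names = NULL)
}

#' Classify particle mobility from apparent diffusion coefficients
#'
#' Labels each track `immobile` when `dStar < dThreshold` and `diffusing`
#' otherwise, and summarises the immobile fraction and the
#' diffusing:immobile ratio (the two-population summary used to contrast a
#' DNA-bound NAP, roughly 2:1, with its non-binding truncation, roughly
#' 20:1).
#'
#' @param stats data.frame with a `dStar` column (e.g. from [trackStats()]).
#' @param dThreshold D* cutoff in length^2/s separating bound from
#'   diffusing particles; see [mobilityThreshold()] for a data-driven
#'   choice.
#' @return list with `results` (input plus `label`), `fractionImmobile`,
#'   `ratioDiffusingToImmobile`, `dThreshold`, `n`.
#' @export
classifyMobility <- function(stats, dThreshold) {
    stopifnot(is.data.frame(stats), "dStar" %in% names(stats))
    if (!is.numeric(dThreshold) || dThreshold < 0)
        .stopf("'dThreshold' must be non-negative")
    if (!nrow(stats)) {
        .warnf("no tracks to classify")
        return(list(results = cbind(stats, label = character(0)),
                    fractionImmobile = NA_real_,
                    ratioDiffusingToImmobile = NA_real_,
                    dThreshold = dThreshold, n = 0L))
    }
    label <- ifelse(stats$dStar < dThreshold, "immobile", "diffusing")
    nImm <- sum(label == "immobile")
    nDiff <- nrow(stats) - nImm
    list(results = cbind(stats, label = label),
         fractionImmobile = nImm / nrow(stats),
         ratioDiffusingToImmobile = if (nImm > 0) nDiff / nImm else Inf,
         dThreshold = dThreshold, n = nrow(stats))
}

#' Data-driven D* threshold at the histogram antimode
#'
#' Finds the minimum of a kernel density estimate of `log10(dStar)` between
#' its two highest modes — the valley separating the immobile
#' (localization-error floor) and diffusing populations. D* histograms are
#' conventionally log-binned because both populations are scale
#' distributions; the antimode on the log axis is far more stable than on
#' the linear one. Falls back to the median with a warning when the density
#' has a single mode or the valley is too shallow to separate populations.
#'
#' @param dStar numeric vector of apparent diffusion coefficients.
#' @return threshold value (length^2/s).
#' @export
mobilityThreshold <- function(dStar) {
    dStar <- dStar[is.finite(dStar) & dStar > 0]
    if (length(dStar) < 10L)
        .stopf("at least 10 positive D* values are needed to locate an antimode")
    de <- stats::density(log10(dStar), n = 512)
    y <- de$y
    isMax <- which(diff(sign(diff(y))) == -2) + 1L
    isMax <- isMax[y[isMax] >= 0.05 * max(y)]  # ignore negligible tail bumps
    if (length(isMax) < 2L) {
        .warnf("D* density looks unimodal; falling back to the median")
        return(stats::median(dStar))
    }
    top2 <- sort(isMax[order(y[isMax], decreasing = TRUE)][1:2])
    valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
    # the valley must dip well below the weaker mode, otherwise the two
    # populations are not separable at this localization precision
    if (y[valley] > 0.85 * min(y[top2])) {
        .warnf("D* populations are not separable (shallow antimode); %s",
               "falling back to the median")
        return(stats::median(dStar))
    }
    10^de$x[valley]
}

#' Normalize localizations into the cell coordinate frame
#'
#' Projects each localization into a rod-cell frame defined by the two pole
#' coordinates and the cell width: `l` in `[0, 1]` is the fractional
#' position along the pole-to-pole axis measured from pole A (the designated
#' distant/old pole when the geometry table encodes one), `w` in `[-1, 1]`
#' is the signed perpendicular offset relative to the half-width, and
#' `lFolded = |l - 0.5|` is the pole-symmetric coordinate used for pooled
#' histograms. Points outside the cell footprint beyond `tol` are excluded;
#' the exclusion count is messaged and attached as attribute `nExcluded`.
#'
#' @param locs data.frame with columns `cell_id`, `x`, `y` (plus any
#'   carried-through columns such as `frame`, `track_id`).
#' @param geom data.frame with columns `cell_id`, `ax`, `ay`, `bx`, `by`,
#'   `width` (pole A, pole B, cell width, in the units of `x`/`y`).
#' @param tol footprint tolerance as a fraction of the normalized
#'   coordinates (default 0.05).
#' @return `locs` restricted to in-footprint points, with added columns
#'   `l`, `w`, `lFolded`; attribute `nExcluded` counts dropped points.
#' @export
normalizePositions <- function(locs, geom, tol = 0.05) {
    stopifnot(is.data.frame(locs), is.data.frame(geom),
              all(c("cell_id", "x", "y") %in% names(locs)),
              all(c("cell_id", "ax", "ay", "bx", "by", "width") %in%
                      names(geom)))
    idx <- match(locs$cell_id, geom$cell_id)
    if (anyNA(idx))
        .stopf("no geometry for cell '%s'", locs$cell_id[which(is.na(idx))[1]])
    g <- geom[idx, , drop = FALSE]
    ux <- g$bx - g$ax; uy <- g$by - g$ay
    len <- sqrt(ux^2 + uy^2)
    if (any(len <= 0)) .stopf("cell length must be positive")
    ux <- ux / len; uy <- uy / len
    rx <- locs$x - g$ax; ry <- locs$y - g$ay
    l <- (rx * ux + ry * uy) / len
    w <- (rx * uy - ry * ux) / (g$width / 2)
    inside <- l >= -tol & l <= 1 + tol & abs(w) <= 1 + tol
    nExcluded <- sum(!inside)
    if (nExcluded > 0)
        message(nExcluded, " localization(s) outside the cell footprint ",
                "were excluded")
    out <- locs[inside, , drop = FALSE]
    out$l <- pmin(pmax(l[inside], 0), 1)
    out$w <- pmin(pmax(w[inside], -1), 1)
    out$lFolded <- abs(out$l - 0.5)
    rownames(out) <- NULL
    attr(out, "nExcluded") <- nExcluded
    out
}
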