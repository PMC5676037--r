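# synthetic_data: seeded generators for every input the pipeline consumes —
# replicate/control peak sets with an ori-proximal density gradient,
# two-population particle tracks in rod cells, and plateau-shaped nucleoid
# intensity profiles.

#' Build a synthetic-data configuration
#'
#' Returns a [SimConfig-class] whose defaults define the study conditions
#' the generators emulate:
#' \itemize{
#'   \item `peaks`: `nPeaks = 600` true binding sites whose density falls
#'     linearly with circular distance from oriC
#'     (`lambda(d) = lambda0 * (1 - beta * d / (L/2))`, `beta = 0.6`);
#'     lognormal widths (median 400 bp, `sdlog = 0.8`, so a heavy tail
#'     reaches >= 1,000 bp); replicate intervals jittered by 50 bp with 1%
#'     per-replicate dropout; uniform control peaks at rate 0.05 per true
#'     peak; lognormal fold enrichments (median 5.3, `sdlog = 0.6`) with
#'     15% replicate scatter.
#'   \item `tracks`: `nTracks = 384` particles, an immobile fraction of 1/3
#'     (exact composition, not binomially drawn), mobile diffusion
#'     `dMobile = 1.5` um^2/s confined to the cell footprint, localization
#'     error `sigma = 0.02` um, frame interval `dt = 0.01` s, geometric
#'     track-length tail beyond the 5-localization minimum, rod cells of
#'     length ~ N(4, 0.5) um and width 0.7 um, immobile anchors clustered
#'     at the cell quarters.
#'   \item `profiles`: `nCells = 100` cells on a 100-point grid, nucleoid
#'     occupancy 0.75 of cell length with logistic edges (softness 0.01),
#'     additive Gaussian noise (sd 0.05 on unit amplitude), second channel
#'     coupled at 0.9.
#' }
#' Any field can be overridden via the `peaks`, `tracks`, `profiles` lists.
#' Identical configurations (including the seed) produce bit-identical
#' outputs.
#'
#' @param seed integer RNG seed.
#' @param genome a [GenomeContext-class] (default: 7-Mbp circular
#'   chromosome, oriC at 0, ter at the antipode).
#' @param peaks,tracks,profiles named lists overriding individual model
#'   parameters.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, genome = GenomeContext(7e6),
                      peaks = list(), tracks = list(), profiles = list()) {
    peakDefaults <- list(
        nPeaks = 600L, gradientShape = "linear", gradientStrength = 0.6,
        widthMeanlog = log(400), widthSdlog = 0.8, minWidth = 100,
        jitterBp = 50, dropout = 0.01, controlRate = 0.05,
        controlDisjoint = TRUE, foldMeanlog = log(5.3), foldSdlog = 0.6,
        foldReplicateSd = 0.15)
    sptDefaults <- list(
        nTracks = 384L, immobileFraction = 1 / 3, dMobile = 1.5,
        sigma = 0.02, dt = 0.01, extraStepP = 0.3, minLocs = 5L,
        nCells = 20L, cellLengthMean = 4, cellLengthSd = 0.5,
        cellWidth = 0.7, quarterSd = 0.05, confined = TRUE)
    profileDefaults <- list(
        nCells = 100L, nPositions = 100L, occupancy = 0.75, occupancySd = 0,
        centerJitter = 0.02, edgeSoftness = 0.01, amplitude = 1,
        background = 0.05, noiseSd = 0.05, coupling = 0.9)
    merge <- function(def, user) {
        unknown <- setdiff(names(user), names(def))
        if (length(unknown))
            .stopf("unknown generator parameter(s): %s",
                   paste(unknown, collapse = ", "))
        def[names(user)] <- user
        def
    }
    new("SimConfig", seed = as.integer(seed), genome = genome,
        peakModel = merge(peakDefaults, peaks),
        sptModel = merge(sptDefaults, tracks),
        profileModel = merge(profileDefaults, profiles))
}

# Rejection-sample n midpoints from the circular intensity
# lambda(d) = 1 - beta * d/(L/2) (linear) or exp(-beta * d/(L/2)).
.sampleBiasedMidpoints <- function(n, ctx, shape, beta) {
    L <- genomeLength(ctx)
    out <- numeric(0)
    while (length(out) < n) {
        m <- stats::runif(2L * (n - length(out)), 0, L)
        d <- circularDistance(floor(m) %% L, oricPos(ctx), ctx)
        acc <- switch(shape,
            linear = 1 - beta * d / (L / 2),
            exponential = exp(-beta * d / (L / 2)),
            .stopf("unknown gradient shape '%s'", shape))
        if (any(acc < 0))
            .stopf("gradient strength makes the intensity negative")
        out <- c(out, m[stats::runif(length(m)) < acc])
    }
    out[seq_len(n)]
}

#' Simulate replicate and control ChIP-Seq peak sets
#'
#' Draws true peak midpoints from an inhomogeneous point process on the
#' circle whose intensity decreases with circular distance from oriC, with
#' lognormal widths and fold enrichments. Each replicate observes the truth
#' with positional jitter, replicate-specific fold scatter, and independent
#' dropout; control peaks are placed uniformly (disjoint from the truth by
#' default). The truth table enables recovery tests.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `rep1`, `rep2`, `control` (`GRanges` as returned by
#'   [readPeaks()]) and `truth` (data.frame: `peak`, `midpoint`, `widthBp`,
#'   `fold`).
#' @export
simulatePeaks <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    pm <- cfg@peakModel
    ctx <- cfg@genome
    if (pm$nPeaks < 1) .stopf("'nPeaks' must be at least 1")
    if (pm$gradientShape == "linear" && pm$gradientStrength > 1)
        .stopf("gradient strength makes the intensity negative")
    .withSeed(cfg@seed, {
        mid <- .sampleBiasedMidpoints(pm$nPeaks, ctx, pm$gradientShape,
                                      pm$gradientStrength)
        width <- pmax(pm$minWidth,
                      stats::rlnorm(pm$nPeaks, pm$widthMeanlog, pm$widthSdlog))
        fold <- stats::rlnorm(pm$nPeaks, pm$foldMeanlog, pm$foldSdlog)
        reps <- lapply(c("rep1", "rep2"), function(rid) {
            keep <- stats::runif(pm$nPeaks) >= pm$dropout
            jm <- mid[keep] + stats::rnorm(sum(keep), 0, pm$jitterBp)
            jw <- pmax(pm$minWidth / 2,
                       width[keep] + stats::rnorm(sum(keep), 0, pm$jitterBp))
            jf <- fold[keep] * exp(stats::rnorm(sum(keep), 0,
                                                pm$foldReplicateSd))
            .peaksFromTruth(ctx, jm %% genomeLength(ctx), jw, jf, rid)
        })
        L <- genomeLength(ctx)
        nCtrl <- stats::rpois(1, pm$controlRate * pm$nPeaks)
        ctrlMid <- numeric(0)
        ctrlWidth <- pmax(pm$minWidth,
                          stats::rlnorm(nCtrl, pm$widthMeanlog, pm$widthSdlog))
        if (nCtrl > 0) {
            ctrlMid <- stats::runif(nCtrl, 0, L)
            if (isTRUE(pm$controlDisjoint)) {
                # keep each control peak clear of every jittered truth peak
                minSep <- (max(width) + ctrlWidth) / 2 + 4 * pm$jitterBp
                for (i in seq_len(100)) {
                    near <- vapply(seq_len(nCtrl), function(j)
                        any(circularDistance(floor(ctrlMid[j]) %% L,
                                             floor(mid) %% L,
                                             ctx) < minSep[j]), logical(1))
                    if (!any(near)) break
                    ctrlMid[near] <- stats::runif(sum(near), 0, L)
                }
            }
        }
        control <- .peaksFromTruth(ctx, ctrlMid, ctrlWidth,
                                   rep(1, nCtrl), "control")
        list(rep1 = reps[[1]], rep2 = reps[[2]], control = control,
             truth = data.frame(peak = sprintf("true_%04d",
                                               seq_len(pm$nPeaks)),
                                midpoint = mid, widthBp = width,
                                fold = fold))
    })
}

# Reflect points into the spherocylindrical cell footprint: distance from
# the pole-to-pole axis segment must not exceed the half width.
.reflectIntoCell <- function(x, y, len, halfW) {
    for (i in 1:8) {
        qx <- pmin(pmax(x, 0), len)   # nearest point on the axis segment
        d <- sqrt((x - qx)^2 + y^2)
        out <- d > halfW
        if (!any(out)) break
        over <- d[out] - halfW
        x[out] <- x[out] - 2 * over * (x[out] - qx[out]) / d[out]
        y[out] <- y[out] - 2 * over * y[out] / d[out]
    }
    list(x = x, y = y)
}

#' Simulate two-population single-particle tracks in rod cells
#'
#' Generates localization and geometry tables for a mixture of immobile
#' particles (fixed anchor plus per-frame Gaussian localization error;
#' anchors clustered at the cell quarters along the long axis) and mobile
#' particles (2D Brownian motion with diffusion coefficient `dMobile`,
#' reflected at the spherocylindrical cell boundary when `confined`).
#' The immobile/diffusing composition is exact
#' (`round(immobileFraction * nTracks)` immobile tracks). Track lengths are
#' `minLocs` plus a geometric tail (photobleaching). Tracks within a cell
#' are staggered in time so at most one molecule is visible per frame,
#' matching sparse photoactivation.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `localizations` (data.frame: `track_id`, `cell_id`,
#'   `frame`, `x`, `y` in um), `geometry` (data.frame: `cell_id`, `ax`,
#'   `ay`, `bx`, `by`, `width`), `truth` (data.frame: `track_id`, `label`,
#'   `dTrue`) and `dt`.
#' @export
simulateTracks <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    sm <- cfg@sptModel
    if (sm$nTracks < 1) .stopf("'nTracks' must be at least 1")
    if (sm$dMobile <= 0 || sm$sigma < 0)
        .stopf("'dMobile' must be positive and 'sigma' non-negative")
    .withSeed(cfg@seed, {
        nImm <- round(sm$immobileFraction * sm$nTracks)
        labels <- rep(c("immobile", "diffusing"),
                      c(nImm, sm$nTracks - nImm))
        nCells <- max(1L, as.integer(sm$nCells))
        cellLen <- pmax(2, stats::rnorm(nCells, sm$cellLengthMean,
                                        sm$cellLengthSd))
        geometry <- data.frame(
            cell_id = sprintf("cell_%03d", seq_len(nCells)),
            ax = 0, ay = (seq_len(nCells) - 1) * 10,
            bx = cellLen, by = (seq_len(nCells) - 1) * 10,
            width = sm$cellWidth)
        cellOf <- sample(seq_len(nCells), sm$nTracks, replace = TRUE)
        nLocs <- sm$minLocs + stats::rgeom(sm$nTracks, sm$extraStepP)
        halfW <- sm$cellWidth / 2
        stepSd <- sqrt(2 * sm$dMobile * sm$dt)
        loc <- vector("list", sm$nTracks)
        frameOffset <- integer(nCells)  # next free frame per cell
        for (i in seq_len(sm$nTracks)) {
            ci <- cellOf[i]
            len <- cellLen[ci]
            n <- nLocs[i]
            if (labels[i] == "immobile") {
                q <- sample(c(0.225, 0.775), 1)
                ax0 <- pmin(pmax(q * len + stats::rnorm(1, 0, sm$quarterSd *
                                                            len), 0), len)
                ay0 <- pmin(pmax(stats::rnorm(1, 0, halfW / 3), -halfW),
                            halfW)
                tx <- rep(ax0, n)
                ty <- rep(ay0, n)
            } else {
                tx <- numeric(n); ty <- numeric(n)
                repeat {  # uniform start inside the footprint
                    sx <- stats::runif(1, -halfW, len + halfW)
                    sy <- stats::runif(1, -halfW, halfW)
                    qx <- min(max(sx, 0), len)
                    if ((sx - qx)^2 + sy^2 <= halfW^2) break
                }
                tx[1] <- sx; ty[1] <- sy
                for (k in seq_len(n - 1L)) {
                    px <- tx[k] + stats::rnorm(1, 0, stepSd)
                    py <- ty[k] + stats::rnorm(1, 0, stepSd)
                    if (isTRUE(sm$confined)) {
                        r <- .reflectIntoCell(px, py, len, halfW)
                        px <- r$x; py <- r$y
                    }
                    tx[k + 1L] <- px; ty[k + 1L] <- py
                }
            }
            ox <- tx + stats::rnorm(n, 0, sm$sigma)
            oy <- ty + stats::rnorm(n, 0, sm$sigma)
            frames <- frameOffset[ci] + seq_len(n) - 1L
            frameOffset[ci] <- frameOffset[ci] + n + 2L  # dark gap
            loc[[i]] <- data.frame(
                track_id = sprintf("track_%05d", i),
                cell_id = geometry$cell_id[ci],
                frame = frames,
                x = ox, y = oy + geometry$ay[ci])
        }
        localizations <- do.call(rbind, loc)
        rownames(localizations) <- NULL
        truth <- data.frame(track_id = sprintf("track_%05d",
                                               seq_len(sm$nTracks)),
                            cell_id = geometry$cell_id[cellOf],
                            label = labels,
                            dTrue = ifelse(labels == "immobile", 0,
                                           sm$dMobile))
        list(localizations = localizations, geometry = geometry,
             truth = truth, dt = sm$dt)
    })
}

.plateau <- function(x, e1, e2, softness) {
    stats::plogis((x - e1) / softness) * stats::plogis((e2 - x) / softness)
}

#' Simulate two-channel nucleoid intensity profiles
#'
#' Per cell, a plateau of width `occupancy * cellLength` (logistic edges,
#' random centre offset) on a fractional 100-point grid, plus additive
#' Gaussian noise over a small uniform background. Channel 2 shares the
#' structural component scaled by `coupling` and carries independent noise,
#' supporting colocalization tests. The per-cell true occupancy is
#' returned.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `profiles` (data.frame: `cell_id`, `channel`,
#'   `position`, `value`) and `truth` (data.frame: `cell_id`, `occupancy`,
#'   `center`).
#' @export
simulateProfiles <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    fm <- cfg@profileModel
    if (fm$nCells < 1) .stopf("'nCells' must be at least 1")
    if (fm$occupancy <= 0 || fm$occupancy > 1)
        .stopf("'occupancy' must lie in (0, 1]")
    .withSeed(cfg@seed, {
        grid <- (seq_len(fm$nPositions) - 0.5) / fm$nPositions
        out <- vector("list", fm$nCells)
        truth <- vector("list", fm$nCells)
        for (i in seq_len(fm$nCells)) {
            occ <- fm$occupancy
            if (fm$occupancySd > 0)
                occ <- min(1, max(0.05, stats::rnorm(1, occ, fm$occupancySd)))
            maxOff <- max(0, min(fm$centerJitter, (1 - occ) / 2))
            center <- 0.5 + stats::runif(1, -maxOff, maxOff)
            shape <- .plateau(grid, center - occ / 2, center + occ / 2,
                              fm$edgeSoftness)
            ch1 <- fm$background + fm$amplitude * shape +
                stats::rnorm(fm$nPositions, 0, fm$noiseSd)
            ch2 <- fm$background + fm$coupling * fm$amplitude * shape +
                stats::rnorm(fm$nPositions, 0, fm$noiseSd)
            cid <- sprintf("cell_%04d", i)
            out[[i]] <- data.frame(
                cell_id = cid,
                channel = rep(c("ch1", "ch2"), each = fm$nPositions),
                position = rep(grid, 2L),
                value = pmax(0, c(ch1, ch2)))
            truth[[i]] <- data.frame(cell_id = cid, occupancy = occ,
                                     center = center)
        }
        list(profiles = do.call(rbind, out),
             truth = do.call(rbind, truth))
    })
}

#' Simulate a single-lineage condensation time course
#'
#' Emits per-frame profiles for one cell lineage with an optionally
#' drifting occupancy, together with the division frames and per-frame
#' truth, for exercising [timelapseCondensation()].
#'
#' @param cfg a [SimConfig-class] (profile model parameters are reused).
#' @param nFrames number of frames.
#' @param divisionFrames integer frames of the division events.
#' @param occupancyDrift occupancy change per frame (default 0).
#' @return list with `profiles` (data.frame: `frame`, `position`, `value`),
#'   `divisionFrames` and `truth` (data.frame: `frame`, `occupancy`).
#' @export
simulateLineageProfiles <- function(cfg, nFrames = 30L,
                                    divisionFrames = c(0L, nFrames),
                                    occupancyDrift = 0) {
    stopifnot(is(cfg, "SimConfig"))
    fm <- cfg@profileModel
    .withSeed(cfg@seed + 1L, {
        grid <- (seq_len(fm$nPositions) - 0.5) / fm$nPositions
        out <- vector("list", nFrames)
        occ <- pmin(0.95, pmax(0.05,
            fm$occupancy + occupancyDrift * (seq_len(nFrames) - 1L)))
        for (f in seq_len(nFrames)) {
            shape <- .plateau(grid, 0.5 - occ[f] / 2, 0.5 + occ[f] / 2,
                              fm$edgeSoftness)
            out[[f]] <- data.frame(
                frame = f - 1L, position = grid,
                value = pmax(0, fm$background + fm$amplitude * shape +
                                 stats::rnorm(fm$nPositions, 0, fm$noiseSd)))
        }
        list(profiles = do.call(rbind, out),
             divisionFrames = divisionFrames,
             truth = data.frame(frame = seq_len(nFrames) - 1L,
                                occupancy = occ))
    })
}

#' Simulate a gene/operon annotation track
#'
#' Tiles the chromosome with non-overlapping features of lognormal length
#' separated by exponential gaps, with random strands — enough structure to
#' exercise promoter/gene-body annotation.
#'
#' @param cfg a [SimConfig-class].
#' @param meanLengthBp mean feature length (default 2000 bp).
#' @param meanGapBp mean intergenic gap (default 300 bp).
#' @return stranded `GRanges` with `featureId` and `kind` metadata.
#' @export
simulateFeatures <- function(cfg, meanLengthBp = 2000, meanGapBp = 300) {
    stopifnot(is(cfg, "SimConfig"))
    ctx <- cfg@genome
    L <- genomeLength(ctx)
    .withSeed(cfg@seed + 2L, {
        starts <- numeric(0); ends <- numeric(0)
        pos <- stats::rexp(1, 1 / meanGapBp)
        while (pos < L - meanLengthBp) {
            len <- max(200, stats::rlnorm(1, log(meanLengthBp), 0.5))
            if (pos + len >= L) break
            starts <- c(starts, pos); ends <- c(ends, pos + len)
            pos <- pos + len + 2 + stats::rexp(1, 1 / meanGapBp)
        }
        n <- length(starts)
        gr <- .granges0(ctx, round(starts), round(ends),
                        meta = S4Vectors::DataFrame(
                            featureId = sprintf("op_%05d", seq_len(n)),
                            kind = "operon",
                            strand = sample(c("+", "-"), n, replace = TRUE)))
        GenomicRanges::strand(gr) <- S4Vectors::mcols(gr)$strand
        S4Vectors::mcols(gr)$strand <- NULL
        gr
    })
}
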