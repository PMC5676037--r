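# Track linking, MSD / apparent diffusion coefficient, mobility
# classification and normalized cell coordinates.

test_that("linkTracks links one drifting molecule into a four-step track", {
    locs <- data.frame(frame = 0:4, x = seq(0, 0.4, by = 0.1), y = 0)
    tr <- linkTracks(locs, rMax = 0.5, minSteps = 4)
    expect_equal(length(unique(tr$track_id)), 1L)
    expect_equal(nrow(tr), 5L)
    expect_equal(tr$frame, 0:4)
})

test_that("molecules beyond rMax are never merged", {
    locs <- data.frame(frame = rep(0:4, each = 2),
                       x = rep(c(0, 10), times = 5) + rep(0:4, each = 2) * 0.05,
                       y = 0)
    tr <- linkTracks(locs, rMax = 1, minSteps = 4)
    expect_equal(length(unique(tr$track_id)), 2L)
    for (tid in unique(tr$track_id)) {
        xs <- tr$x[tr$track_id == tid]
        expect_true(all(xs < 5) || all(xs > 5))
    }
})

test_that("a blinking gap splits a molecule into two tracks", {
    locs <- data.frame(frame = c(0:2, 6:8), x = 0, y = 0)
    tr <- linkTracks(locs, rMax = 0.5, minSteps = 1)
    expect_equal(length(unique(tr$track_id)), 2L)
    # at the four-step default both fragments are discarded
    expect_equal(nrow(linkTracks(locs, rMax = 0.5, minSteps = 4)), 0L)
})

test_that("equidistant candidates break ties on the lower row index", {
    # one head at origin, two candidates at distance 1 in frame 1
    locs <- data.frame(frame = c(0, 1, 1), x = c(0, 0, 0), y = c(0, 1, -1))
    tr <- linkTracks(locs, rMax = 2, minSteps = 1)
    cont <- tr[tr$frame == 1 & tr$track_id == tr$track_id[tr$frame == 0], ]
    expect_equal(cont$y, 1)  # the earlier row wins
})

test_that("linkTracks agrees with the sorted-assignment oracle", {
    set.seed(31)
    for (rep in 1:40) {
        nFrames <- sample(3:6, 1)
        locs <- do.call(rbind, lapply(seq_len(nFrames) - 1, function(f) {
            n <- sample(1:5, 1)
            data.frame(frame = f, x = round(runif(n, 0, 4), 3),
                       y = round(runif(n, 0, 4), 3))
        }))
        got <- linkTracks(locs, rMax = 1.2, minSteps = 1)
        want <- bruteLink(locs, rMax = 1.2)
        keepW <- ave(want$track, want$track, FUN = length) >= 2
        sigGot <- linkSignature(got$frame, got$x, got$y, got$track_id)
        sigWant <- linkSignature(want$frame[keepW], want$x[keepW],
                                 want$y[keepW], want$track[keepW])
        expect_equal(sigGot, sigWant)
    }
})

test_that("trackMSD has the stated closed forms", {
    expect_equal(trackMSD(cbind(rep(1, 5), rep(2, 5))), 0)
    d <- 0.3
    straight <- cbind(seq(0, by = d, length.out = 5), 0)
    expect_equal(trackMSD(straight), d^2)
    expect_error(trackMSD(straight[1:3, ]), "step")
    # lag-averaged variant on a ballistic track: mean over lags of (lag*d)^2
    expect_equal(trackMSD(straight, lagAveraged = TRUE),
                 mean((1:4 * d)^2))
})

test_that("mean MSD of simulated Brownian steps converges to 4*D*dt", {
    cfg <- simConfig(seed = 41, tracks = list(
        nTracks = 3000L, immobileFraction = 0, sigma = 0, confined = FALSE,
        dMobile = 1.5, dt = 0.01))
    sim <- simulateTracks(cfg)
    st <- trackStats(sim$localizations, dt = sim$dt)
    expect_equal(nrow(st), 3000L)
    # per-track D* ~ (D/8) chi2_8, so sd = D/2 and se = D/(2 sqrt(n))
    se <- 1.5 / (2 * sqrt(3000))
    expect_lt(abs(mean(st$dStar) - 1.5), 3 * se)
    expect_lt(abs(mean(st$msd) - 4 * 1.5 * 0.01), 3 * se * 4 * 0.01)
})

test_that("apparentDiffusion is MSD/(4 dt) with guarded inputs", {
    expect_equal(apparentDiffusion(0.04, 0.01), 1.0)
    expect_equal(apparentDiffusion(0, 0.01), 0)
    expect_error(apparentDiffusion(0.04, 0), "dt")
    expect_error(apparentDiffusion(-1, 0.01), "msd")
})

test_that("trackStats equals per-track trackMSD", {
    set.seed(43)
    locs <- do.call(rbind, lapply(1:6, function(i) {
        n <- sample(5:9, 1)
        data.frame(track_id = sprintf("t%02d", i), frame = seq_len(n) - 1,
                   x = cumsum(rnorm(n, 0, 0.1)), y = cumsum(rnorm(n, 0, 0.1)))
    }))
    st <- trackStats(locs, dt = 0.02)
    for (i in seq_len(nrow(st))) {
        tr <- locs[locs$track_id == st$track_id[i], ]
        expect_equal(st$msd[i], trackMSD(cbind(tr$x, tr$y)))
    }
    expect_equal(st$dStar, st$msd / (4 * 0.02))
})

test_that("classifyMobility labels, summarises and stays monotone", {
    st <- data.frame(track_id = paste0("t", 1:6),
                     dStar = c(0.01, 0.02, 0.05, 0.5, 0.8, 1.2))
    all_imm <- classifyMobility(st, 2)
    expect_equal(all_imm$fractionImmobile, 1)
    none <- classifyMobility(st, 0)
    expect_equal(none$fractionImmobile, 0)
    expect_equal(none$ratioDiffusingToImmobile, Inf)
    half <- classifyMobility(st, 0.1)
    expect_equal(half$fractionImmobile, 0.5)
    expect_equal(half$ratioDiffusingToImmobile, 1)
    # monotone in the threshold
    fr <- vapply(seq(0, 2, by = 0.1), function(th)
        classifyMobility(st, th)$fractionImmobile, numeric(1))
    expect_true(all(diff(fr) >= 0))
    expect_warning(res <- classifyMobility(st[0, ], 0.1), "no tracks")
    expect_true(is.na(res$fractionImmobile))
})

test_that("two-population recovery at the experiment's track count", {
    errs <- vapply(1:5, function(s) {
        cfg <- simConfig(seed = 100 + s)
        sim <- simulateTracks(cfg)
        st <- trackStats(sim$localizations, dt = sim$dt)
        cls <- classifyMobility(st, 0.3)
        abs(cls$fractionImmobile - 1 / 3)
    }, numeric(1))
    expect_true(all(errs <= 0.05))
})

test_that("normalizePositions maps the rod-cell frame correctly", {
    geom <- data.frame(cell_id = "c1", ax = 1, ay = 1, bx = 5, by = 1,
                       width = 1)
    locs <- data.frame(cell_id = "c1",
                       x = c(1, 3, 2), y = c(1, 1, 1.25))
    np <- normalizePositions(locs, geom)
    expect_equal(np$l, c(0, 0.5, 0.25))
    expect_equal(np$w[1:2], c(0, 0))
    expect_equal(abs(np$w[3]), 0.5)
    expect_equal(np$lFolded, c(0.5, 0, 0.25))
})

test_that("points far outside the footprint are excluded and counted", {
    geom <- data.frame(cell_id = "c1", ax = 0, ay = 0, bx = 4, by = 0,
                       width = 1)
    locs <- data.frame(cell_id = "c1", x = c(2, 20), y = c(0, 5))
    expect_message(np <- normalizePositions(locs, geom), "excluded")
    expect_equal(nrow(np), 1L)
    expect_equal(attr(np, "nExcluded"), 1L)
})

test_that("pooled folded-coordinate histogram is mirror symmetric", {
    geom <- data.frame(cell_id = "c1", ax = 0, ay = 0, bx = 4, by = 0,
                       width = 1)
    set.seed(51)
    xs <- runif(300, 0, 4)
    locs <- data.frame(cell_id = "c1", x = xs, y = 0)
    refl <- data.frame(cell_id = "c1", x = 4 - xs, y = 0)
    h1 <- hist(normalizePositions(locs, geom)$lFolded,
               breaks = seq(0, 0.5, by = 0.05), plot = FALSE)$counts
    h2 <- hist(normalizePositions(refl, geom)$lFolded,
               breaks = seq(0, 0.5, by = 0.05), plot = FALSE)$counts
    expect_equal(h1, h2)
})

test_that("immobile particles concentrate at the cell quarters", {
    cfg <- simConfig(seed = 61, tracks = list(nTracks = 600L))
    sim <- simulateTracks(cfg)
    np <- suppressMessages(
        normalizePositions(sim$localizations, sim$geometry))
    imm <- merge(np, sim$truth[, c("track_id", "label")], by = "track_id")
    l <- imm$l[imm$label == "immobile"]
    inQuarters <- mean((l >= 0.15 & l <= 0.35) | (l >= 0.65 & l <= 0.85))
    expect_gt(inQuarters, 0.8)
})
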