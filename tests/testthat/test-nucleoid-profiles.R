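# Long-axis profiles, condensation extent, cohort averaging,
# colocalization and time-lapse summaries.

test_that("profileFromImage recovers constructed intensity structure", {
    geom <- list(ax = 0.5, ay = 10, bx = 100.5, by = 10, width = 10)
    flat <- profileFromImage(matrix(3, 20, 100), geom, nSamples = 50)
    expect_equal(unique(flat$value), 3)

    band <- matrix(0, 20, 100); band[, 48:53] <- 5
    pb <- profileFromImage(band, geom, nSamples = 50)
    expect_equal(pb$position[which.max(pb$value)], 0.5, tolerance = 0.03)

    lobes <- matrix(0, 20, 100); lobes[, 23:28] <- 5; lobes[, 73:78] <- 5
    pl <- profileFromImage(lobes, geom, nSamples = 50)
    top <- order(pl$value, decreasing = TRUE)[1:6]
    expect_true(any(abs(pl$position[top] - 0.25) < 0.05))
    expect_true(any(abs(pl$position[top] - 0.75) < 0.05))

    out <- list(ax = -50, ay = 10, bx = 200, by = 10, width = 10)
    expect_error(profileFromImage(band, out, 50), "outside")
})

test_that("averageProfiles returns exact means and calibrated CIs", {
    grid <- (1:100 - 0.5) / 100
    one <- data.frame(cell_id = rep(sprintf("c%02d", 1:50), each = 100),
                      position = rep(grid, 50),
                      value = rep(sin(grid * pi), 50))
    avg <- averageProfiles(one)
    expect_equal(avg$mean, sin(grid * pi))
    expect_equal(avg$upper - avg$lower, rep(0, 100))
    expect_equal(avg$n, rep(50L, 100))

    # iid noise: t CI half-width ~ 1.96 * sigma / sqrt(n) for n = 50
    set.seed(71)
    sigma <- 0.2; n <- 50
    noisy <- data.frame(cell_id = rep(sprintf("c%02d", 1:n), each = 100),
                        position = rep(grid, n),
                        value = rnorm(100 * n, 1, sigma))
    avgN <- averageProfiles(noisy)
    half <- mean((avgN$upper - avgN$lower) / 2)
    expect_equal(half, qt(0.975, n - 1) * sigma / sqrt(n), tolerance = 0.1)

    expect_warning(single <- averageProfiles(one[one$cell_id == "c01", ]),
                   "single")
    expect_true(all(is.na(single$lower)))
})

test_that("mismatched grids are resampled; symmetric input, symmetric mean", {
    g1 <- seq(0, 1, length.out = 60)
    g2 <- seq(0, 1, length.out = 90)
    sym <- function(x) exp(-((x - 0.5) / 0.2)^2)
    two <- rbind(data.frame(cell_id = "a", position = g1, value = sym(g1)),
                 data.frame(cell_id = "b", position = g2, value = sym(g2)))
    avg <- averageProfiles(two)
    expect_equal(avg$mean, rev(avg$mean), tolerance = 1e-6)
})

test_that("condensationExtent matches closed-form profiles", {
    x <- (1:100 - 0.5) / 100
    tophat <- as.numeric(x >= 0.1 & x <= 0.9)
    expect_equal(condensationExtent(x, tophat)$extentFraction, 0.8)

    grid01 <- seq(0, 1, length.out = 101)
    expect_equal(condensationExtent(grid01, rep(2, 101))$extentFraction, 1.0)

    expect_warning(zero <- condensationExtent(x, rep(0, 100)), "zero")
    expect_equal(zero$extentFraction, 0)
    expect_error(condensationExtent(x, tophat, relThreshold = 1.2),
                 "relThreshold")
})

test_that("extent is invariant to positive rescaling of the profile", {
    set.seed(72)
    pr <- simulateProfiles(simConfig(seed = 72,
                                     profiles = list(nCells = 5L)))$profiles
    for (cid in unique(pr$cell_id)) {
        p <- pr[pr$cell_id == cid & pr$channel == "ch1", ]
        e1 <- condensationExtent(p$position, p$value)$extentFraction
        e2 <- condensationExtent(p$position, 7.3 * p$value)$extentFraction
        expect_equal(e1, e2)
    }
})

test_that("extent shrinks as the relative threshold rises", {
    x <- (1:200 - 0.5) / 200
    v <- plogis((x - 0.15) / 0.02) * plogis((0.85 - x) / 0.02)
    ext <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(th)
        condensationExtent(x, v, relThreshold = th)$extentFraction,
        numeric(1))
    expect_true(all(diff(ext) < 0))
    expect_equal(ext[3], 0.7, tolerance = 0.01)  # FWHM of the 0.70 plateau
})

test_that("generator occupancy is recovered from noisy synthetic cells", {
    pr <- simulateProfiles(simConfig(seed = 73,
                                     profiles = list(nCells = 100L)))
    ext <- condensationByCell(pr$profiles, channel = "ch1")
    expect_equal(mean(ext$extentFraction), 0.75, tolerance = 0.03)
    expect_lt(sd(ext$extentFraction), 0.05)
})

test_that("colocalization is 1 for identical, <1 for mirrored, ~0 for noise", {
    x <- (1:100 - 0.5) / 100
    v <- plogis((x - 0.2) / 0.05) * plogis((0.7 - x) / 0.05)  # asymmetric
    p1 <- data.frame(position = x, value = v)
    expect_equal(colocalizationOverlap(p1, p1), 1)
    pm <- data.frame(position = x, value = rev(v))
    expect_lt(colocalizationOverlap(p1, pm), 1)
    set.seed(74)
    n1 <- data.frame(position = x, value = rnorm(100))
    n2 <- data.frame(position = x, value = rnorm(100))
    expect_lt(abs(colocalizationOverlap(n1, n2)), 0.3)
    flat <- data.frame(position = x, value = rep(1, 100))
    expect_warning(r <- colocalizationOverlap(p1, flat), "variance")
    expect_true(is.na(r))
})

test_that("timelapse condensation segments between division events", {
    cfg <- simConfig(seed = 75, profiles = list(noiseSd = 0.02))
    tl <- simulateLineageProfiles(cfg, nFrames = 30,
                                  divisionFrames = c(0, 15, 30))
    res <- timelapseCondensation(tl$profiles, tl$divisionFrames)
    expect_equal(nrow(res$segments), 2L)
    expect_equal(res$segments$mean, rep(0.75, 2), tolerance = 0.03)
    expect_true(all(res$segments$upper - res$segments$lower < 0.05))

    # single division event -> one segment over the whole series
    one <- timelapseCondensation(tl$profiles, divisionFrames = 15)
    expect_equal(nrow(one$segments), 1L)
    expect_equal(one$segments$n, 30L)

    # drifting occupancy is tracked
    dr <- simulateLineageProfiles(cfg, nFrames = 25, occupancyDrift = 0.005)
    resD <- timelapseCondensation(dr$profiles, c(0, 25))
    trend <- coef(lm(extentFraction ~ frame, data = resD$perFrame))[2]
    expect_gt(trend, 0.003)

    expect_warning(
        timelapseCondensation(tl$profiles, divisionFrames = c(0, 40, 45)),
        "no frames")
})
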