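# Replicate confirmation, spacing/density statistics, ori->ter bias and
# promoter/gene-body annotation.

ctx <- GenomeContext(7e6)

test_that("confirmPeaks applies the intersection-and-control policy", {
    small <- tinyContext()
    r1 <- peaksFromCoords(small, 100, 200, fold = 6, replicateId = "rep1")
    r2 <- peaksFromCoords(small, 150, 250, fold = 5, replicateId = "rep2")

    cps <- confirmPeaks(r1, r2, ctx = small)
    expect_equal(nConfirmed(cps), 1L)
    se <- data.frame(start = GenomicRanges::start(consensusPeaks(cps)) - 1,
                     end = GenomicRanges::end(consensusPeaks(cps)))
    expect_equal(se$start, 150)
    expect_equal(se$end, 200)
    expect_setequal(provenance(cps)[[1]]$replicate, c("rep1", "rep2"))

    ctrl <- peaksFromCoords(small, 180, 300)
    expect_equal(nConfirmed(confirmPeaks(r1, r2, ctrl, small)), 0L)

    far <- peaksFromCoords(small, 500, 600, replicateId = "rep2")
    expect_equal(nConfirmed(confirmPeaks(r1, far, ctx = small)), 0L)

    expect_warning(
        empty <- confirmPeaks(r1, peaksFromCoords(small, numeric(0),
                                                  numeric(0)), ctx = small),
        "empty")
    expect_equal(nConfirmed(empty), 0L)
})

test_that("confirmPeaks matches the position-occupancy oracle", {
    L <- 5000L
    small <- GenomeContext(L)
    set.seed(101)
    for (rep in 1:60) {
        n1 <- sample(0:20, 1); n2 <- sample(0:20, 1); nc <- sample(0:5, 1)
        d1 <- randomIntervals(max(n1, 1), L, 150)[seq_len(n1), , drop = FALSE]
        d2 <- randomIntervals(max(n2, 1), L, 150)[seq_len(n2), , drop = FALSE]
        dc <- randomIntervals(max(nc, 1), L, 150)[seq_len(nc), , drop = FALSE]
        if (n1 == 0 || n2 == 0) next
        g1 <- peaksFromCoords(small, d1$start, d1$end, replicateId = "rep1")
        g2 <- peaksFromCoords(small, d2$start, d2$end, replicateId = "rep2")
        gc <- peaksFromCoords(small, dc$start, dc$end)
        got <- consensusPeaks(confirmPeaks(g1, g2, gc, small))
        want <- bruteConfirm(d1, d2, dc, L)
        expect_equal(length(got), nrow(want))
        if (nrow(want)) {
            expect_equal(GenomicRanges::start(got) - 1, want$start)
            expect_equal(GenomicRanges::end(got), want$end)
        }
    }
})

test_that("union policy keeps the full supported extent", {
    small <- tinyContext()
    r1 <- peaksFromCoords(small, 100, 200, replicateId = "rep1")
    r2 <- peaksFromCoords(small, 150, 250, replicateId = "rep2")
    cps <- confirmPeaks(r1, r2, ctx = small, method = "union")
    expect_equal(GenomicRanges::start(consensusPeaks(cps)) - 1, 100)
    expect_equal(GenomicRanges::end(consensusPeaks(cps)), 250)
})

test_that("filterByEnrichment keeps peaks meeting the fold threshold", {
    small <- tinyContext()
    r1 <- peaksFromCoords(small, c(100, 500), c(200, 600),
                          fold = c(6.0, 6.0), replicateId = "rep1")
    r2 <- peaksFromCoords(small, c(120, 520), c(220, 620),
                          fold = c(5.2, 4.9), replicateId = "rep2")
    cps <- confirmPeaks(r1, r2, ctx = small)
    expect_equal(nConfirmed(cps), 2L)

    kept <- filterByEnrichment(cps, minFold = 5, requireBoth = TRUE)
    expect_equal(nConfirmed(kept), 1L)   # (6.0, 4.9) dropped
    either <- filterByEnrichment(cps, minFold = 5, requireBoth = FALSE)
    expect_equal(nConfirmed(either), 2L)
    expect_equal(nConfirmed(filterByEnrichment(cps, 0)), 2L)  # identity

    noFold <- confirmPeaks(peaksFromCoords(small, 100, 200),
                           peaksFromCoords(small, 150, 250), ctx = small)
    expect_error(filterByEnrichment(noFold, 5), "missing")
})

test_that("mean inter-peak spacing is L/n with circular midpoint gaps", {
    mids <- seq(0, 6999000, length.out = 626)
    gr <- peaksFromCoords(ctx, mids, mids + 200)
    sp <- meanInterpeakSpacing(gr, ctx)
    expect_equal(sp$meanBp, 7e6 / 626)
    expect_equal(round(sp$meanBp), 11182)  # the ~11,000-bp dispersal

    one <- peaksFromCoords(ctx, 1000, 2000)
    expect_equal(meanInterpeakSpacing(one, ctx)$meanBp, 7e6)
    expect_equal(meanInterpeakSpacing(one, ctx)$gapsBp, 7e6)

    small <- GenomeContext(1000)
    four <- peaksFromCoords(small, c(0, 250, 500, 750) - 5 + 5,
                            c(0, 250, 500, 750) + 10)
    gaps <- meanInterpeakSpacing(four, small)$gapsBp
    expect_equal(gaps, rep(250, 4))

    expect_error(
        meanInterpeakSpacing(peaksFromCoords(ctx, numeric(0), numeric(0)),
                             ctx), "empty")
})

test_that("spacing is invariant under rotation of all coordinates", {
    set.seed(7)
    mids <- sort(sample.int(7e6, 200) - 1)
    gr <- peaksFromCoords(ctx, mids, mids + 100)
    base <- meanInterpeakSpacing(gr, ctx)
    for (shift in c(12345, 3.1e6, 6.9e6)) {
        rot <- peaksFromCoords(ctx, (mids + shift) %% 7e6,
                               (mids + shift) %% 7e6 + 100)
        rotated <- meanInterpeakSpacing(rot, ctx)
        expect_equal(rotated$meanBp, base$meanBp)
        expect_equal(sort(round(rotated$gapsBp, 6)),
                     sort(round(base$gapsBp, 6)))
    }
})

test_that("densityProfile reports lengths and inverse midpoint gaps", {
    small <- GenomeContext(1e5)
    two <- peaksFromCoords(small, c(1000, 2000), c(1100, 2100))
    dp <- densityProfile(two, small, binBp = 1e4)
    expect_equal(dp$perPeak$invGap[1], 1 / 1000)

    long <- peaksFromCoords(ctx, 500, 1500)
    expect_equal(densityProfile(long, ctx)$perPeak$lengthBp, 1000)
    expect_true(all(densityProfile(long, ctx)$perPeak$lengthBp >= 1000))

    # 100 peaks on a regular grid, 10 bins -> exactly 10 per bin
    g <- GenomeContext(1e5)
    mids <- seq(0, 1e5 - 1000, by = 1000)
    grid <- peaksFromCoords(g, mids, mids + 10)
    dp2 <- densityProfile(grid, g, binBp = 1e4)
    expect_equal(dp2$binCounts, rep(10L, 10))
    expect_equal(sum(dp2$binCounts), 100L)

    expect_error(densityProfile(two, small, binBp = 0), "binBp")
})

test_that("ori->ter bias is detected, null-calibrated and sign-symmetric", {
    # all peaks in the oriC-proximal 10% of the circle
    set.seed(11)
    mids <- c(runif(150, 0, 3.5e5), runif(150, 6.65e6, 7e6)) %% 7e6
    gr <- peaksFromCoords(ctx, mids, mids + 100)
    bias <- oriTerBias(gr, ctx, nPerm = 1000, seed = 5)
    expect_lt(bias$statistic, 0)
    expect_lt(bias$pValue, 0.05)
    expect_equal(sum(bias$binCounts), 300)

    # mirror image (reflect through the quarter point swaps oriC/ter ends)
    mirrored <- (3.5e6 - mids) %% 7e6
    grM <- peaksFromCoords(ctx, mirrored, mirrored + 100)
    biasM <- oriTerBias(grM, ctx, nPerm = 1000, seed = 5)
    expect_gt(biasM$statistic, 0)
    expect_gt(biasM$pValue, 0.5)

    # uniform null: statistic near zero
    set.seed(12)
    u <- runif(500, 0, 7e6)
    biasU <- oriTerBias(peaksFromCoords(ctx, u, u + 100), ctx,
                        nPerm = 1000, seed = 5)
    expect_lt(abs(biasU$statistic), 0.35)

    expect_error(oriTerBias(gr, ctx, nPerm = 10), "nPerm")
    few <- peaksFromCoords(ctx, c(100, 200), c(150, 250))
    expect_error(oriTerBias(few, ctx, binBp = 7e6 / 2), "bins")
})

test_that("annotatePeaks applies the literal promoter/gene-body rules", {
    f <- withr::local_tempfile()
    writeLines("opA\t1000\t2000\t+", f)
    feats <- readFeatures(f, ctx)
    # promoter window for opA is [850, 1000)
    prom <- annotatePeaks(peaksFromCoords(ctx, 900, 940), feats, ctx)
    expect_equal(prom$annotations$category, "promoter")
    expect_equal(prom$annotations$featureId, "opA")

    body <- annotatePeaks(peaksFromCoords(ctx, 1200, 1300), feats, ctx)
    expect_equal(body$annotations$category, "gene_body")

    # overlaps window and body but not contained in body -> promoter
    both <- annotatePeaks(peaksFromCoords(ctx, 900, 1300), feats, ctx)
    expect_equal(both$annotations$category, "promoter")

    away <- annotatePeaks(peaksFromCoords(ctx, 5000, 5100), feats, ctx)
    expect_equal(away$annotations$category, "intergenic")
})

test_that("minus-strand promoters sit downstream of the end coordinate", {
    f <- withr::local_tempfile()
    writeLines("opB\t1000\t2000\t-", f)
    feats <- readFeatures(f, ctx)
    # promoter window is [2000, 2150)
    res <- annotatePeaks(peaksFromCoords(ctx, 2100, 2140), feats, ctx)
    expect_equal(res$annotations$category, "promoter")
    res2 <- annotatePeaks(peaksFromCoords(ctx, 900, 990), feats, ctx)
    expect_equal(res2$annotations$category, "intergenic")
})

test_that("promoter windows wrap circularly at the genome edge", {
    f <- withr::local_tempfile()
    writeLines("opE\t50\t900\t+", f)     # window wraps to [L-100, L) + [0, 50)
    feats <- readFeatures(f, ctx)
    res <- annotatePeaks(peaksFromCoords(ctx, 7e6 - 80, 7e6 - 60), feats, ctx)
    expect_equal(res$annotations$category, "promoter")
})

test_that("annotation categories are exhaustive, exclusive and tally to 1", {
    L <- 50000L
    small <- GenomeContext(L)
    set.seed(21)
    nf <- 12
    fs <- sort(sample.int(L - 3000, nf))
    fdf <- data.frame(id = sprintf("f%02d", seq_len(nf)), start = fs,
                      end = fs + sample(500:2500, nf, replace = TRUE),
                      strand = sample(c("+", "-"), nf, replace = TRUE))
    ff <- withr::local_tempfile()
    utils::write.table(fdf, ff, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    feats <- readFeatures(ff, small)
    pk <- randomIntervals(80, L, 400)
    gr <- peaksFromCoords(small, pk$start, pk$end)
    res <- annotatePeaks(gr, feats, small)
    expect_equal(nrow(res$annotations), 80L)
    expect_true(all(res$annotations$category %in%
                    c("promoter", "gene_body", "intergenic", "mixed")))
    expect_equal(sum(res$tally), 1)
    # agree with the literal-predicate oracle, peak by peak
    s0 <- GenomicRanges::start(gr) - 1
    e0 <- GenomicRanges::end(gr)
    want <- vapply(seq_along(gr), function(i)
        bruteAnnotate(s0[i], e0[i], fdf, L), character(1))
    expect_equal(res$annotations$category, want)
})
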