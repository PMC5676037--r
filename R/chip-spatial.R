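# chip_spatial: replicate confirmation, ori->ter bias, density/spacing
# statistics and promoter/gene-body annotation of peaks on a circular
# chromosome.

.emptyPeakSet <- function(ctx) {
    new("ConfirmedPeakSet",
        peaks = .granges0(ctx, numeric(0), numeric(0)),
        provenance = list(), genome = ctx)
}

#' Confirm peaks across replicates against a control strain
#'
#' Builds the consensus peak set: regions supported by both
#' immunoprecipitation replicates (>= 1 bp overlap) and not overlapping any
#' peak called in the control strain. Under the default `"intersection"`
#' policy a consensus peak is the merged intersection of overlapping
#' replicate intervals; `"union"` instead merges the full extent of the
#' supporting intervals. Consensus peaks overlapping a control interval are
#' dropped whole. Per-peak provenance records every contributing replicate
#' interval with its fold enrichment.
#'
#' @param rep1,rep2 `GRanges` of peaks from the two replicates (as returned
#'   by [readPeaks()]).
#' @param control `GRanges` of control-strain peaks (may be empty).
#' @param ctx a [GenomeContext-class].
#' @param method overlap policy, `"intersection"` (default) or `"union"`.
#' @return A [ConfirmedPeakSet-class].
#' @examples
#' ctx <- GenomeContext(1e4)
#' r1 <- peaksFromCoords(ctx, 100, 200, fold = 6, replicateId = "rep1")
#' r2 <- peaksFromCoords(ctx, 150, 250, fold = 5, replicateId = "rep2")
#' confirmPeaks(r1, r2, ctx = ctx)   # one consensus peak [150, 200)
#' @export
confirmPeaks <- function(rep1, rep2, control = NULL, ctx,
                         method = c("intersection", "union")) {
    method <- match.arg(method)
    stopifnot(is(ctx, "GenomeContext"))
    if (length(rep1) == 0L || length(rep2) == 0L) {
        .warnf("a replicate peak list is empty; returning an empty set")
        return(.emptyPeakSet(ctx))
    }
    r1 <- GenomicRanges::reduce(rep1)
    r2 <- GenomicRanges::reduce(rep2)
    if (method == "intersection") {
        cons <- GenomicRanges::reduce(
            GenomicRanges::intersect(r1, r2, ignore.strand = TRUE))
    } else {
        both <- GenomicRanges::reduce(c(r1, r2))
        h1 <- IRanges::overlapsAny(both, r1)
        h2 <- IRanges::overlapsAny(both, r2)
        cons <- both[h1 & h2]
    }
    if (!is.null(control) && length(control) && length(cons)) {
        cons <- cons[!IRanges::overlapsAny(cons, control)]
    }
    if (!length(cons)) {
        out <- .emptyPeakSet(ctx)
        return(out)
    }
    names(cons) <- sprintf("peak_%04d", seq_along(cons))
    provPiece <- function(r, cp, label) {
        r <- r[IRanges::overlapsAny(r, cp)]
        se <- .startEnd0(r)
        fold <- S4Vectors::mcols(r)$foldEnrichment
        if (is.null(fold)) fold <- rep(NA_real_, length(r))
        rid <- S4Vectors::mcols(r)$replicateId
        rid <- if (is.null(rid)) rep(NA_character_, length(r))
               else as.character(rid)
        rid[is.na(rid)] <- label
        data.frame(replicate = rid, start = se$start, end = se$end,
                   foldEnrichment = as.numeric(fold))
    }
    prov <- lapply(seq_along(cons), function(i) {
        out <- rbind(provPiece(rep1, cons[i], "rep1"),
                     provPiece(rep2, cons[i], "rep2"))
        rownames(out) <- NULL
        out
    })
    names(prov) <- names(cons)
    new("ConfirmedPeakSet", peaks = cons, provenance = prov, genome = ctx)
}

#' Build a small peak GRanges from coordinate vectors
#'
#' Convenience constructor used in examples, tests and simulations:
#' 0-based half-open coordinates plus optional fold enrichments.
#'
#' @param ctx a [GenomeContext-class].
#' @param start0,end0 0-based half-open interval coordinates.
#' @param fold fold-enrichment values (recycled).
#' @param replicateId replicate label (recycled).
#' @return `GRanges` with `foldEnrichment` and `replicateId` metadata.
#' @export
peaksFromCoords <- function(ctx, start0, end0, fold = NA_real_,
                            replicateId = NA_character_) {
    n <- length(start0)
    .granges0(ctx, start0, end0,
              meta = S4Vectors::DataFrame(
                  foldEnrichment = rep_len(as.numeric(fold), n),
                  replicateId = rep_len(as.character(replicateId), n)))
}

#' Filter a confirmed peak set by fold enrichment
#'
#' Keeps consensus peaks whose supporting replicate intervals reach a minimum
#' fold enrichment. With `requireBoth = TRUE` (default) every contributing
#' interval from both replicates must satisfy `foldEnrichment >= minFold`,
#' reproducing a "highest enrichment in both biological replicates"
#' selection; otherwise a single qualifying interval suffices.
#'
#' @param x a [ConfirmedPeakSet-class].
#' @param minFold minimum fold enrichment (`0` keeps everything).
#' @param requireBoth require the threshold in both replicates.
#' @return A filtered [ConfirmedPeakSet-class].
#' @export
filterByEnrichment <- function(x, minFold, requireBoth = TRUE) {
    stopifnot(is(x, "ConfirmedPeakSet"), is.numeric(minFold))
    if (minFold < 0) .stopf("'minFold' must be non-negative")
    if (!length(x)) return(x)
    folds <- lapply(x@provenance, `[[`, "foldEnrichment")
    if (any(vapply(folds, function(f) any(is.na(f)), logical(1))))
        .stopf("fold enrichment values are missing from the provenance; %s",
               "supply peaks with a fold column before filtering")
    keep <- vapply(seq_along(folds), function(i) {
        f <- folds[[i]]
        if (requireBoth) all(f >= minFold) else any(f >= minFold)
    }, logical(1))
    new("ConfirmedPeakSet", peaks = x@peaks[keep],
        provenance = x@provenance[keep], genome = x@genome)
}

.peakMidpoints <- function(x) {
    gr <- if (is(x, "ConfirmedPeakSet")) consensusPeaks(x) else x
    .mid0(gr)
}

#' Mean inter-peak spacing on the circular chromosome
#'
#' For `n` peaks on a circle of length `L` the midpoint-to-midpoint gaps sum
#' to `L`, so the mean spacing is exactly `L / n`; the individual circular
#' gaps (successor distances of the sorted midpoints, including the
#' wrap-around gap) are returned alongside.
#'
#' @param x a [ConfirmedPeakSet-class] or a peak `GRanges`.
#' @param ctx a [GenomeContext-class].
#' @return list with `meanBp` (`L / n`) and `gapsBp` (numeric vector of
#'   midpoint gaps, one per peak).
#' @examples
#' ctx <- GenomeContext(7e6)
#' gr <- peaksFromCoords(ctx, seq(0, 6.99e6, length.out = 626),
#'                       seq(0, 6.99e6, length.out = 626) + 200)
#' meanInterpeakSpacing(gr, ctx)$meanBp  # ~11,182 bp
#' @export
meanInterpeakSpacing <- function(x, ctx) {
    stopifnot(is(ctx, "GenomeContext"))
    mid <- .peakMidpoints(x)
    if (!length(mid))
        .stopf("inter-peak spacing is undefined for an empty peak set")
    L <- genomeLength(ctx)
    mid <- sort(mid %% L)
    gaps <- if (length(mid) == 1L) L else diff(c(mid, mid[1] + L))
    list(meanBp = L / length(mid), gapsBp = gaps)
}

.binCounts <- function(mid, L, binBp) {
    edges <- seq(0, L, by = binBp)
    if (edges[length(edges)] < L) edges <- c(edges, L)  # truncated last bin
    counts <- tabulate(findInterval(mid, edges, rightmost.closed = TRUE),
                       nbins = length(edges) - 1L)
    list(edges = edges, counts = counts)
}

#' Peak density profile along the chromosome
#'
#' Bins peak midpoints into fixed-width genomic bins and reports, per peak,
#' its length and the inverse of the circular gap to the next peak midpoint
#' (large values mark tight clusters, mirroring a density plot in which the
#' bar height is 1/distance and a dot marks the peak length).
#'
#' @param x a [ConfirmedPeakSet-class] or peak `GRanges`.
#' @param ctx a [GenomeContext-class].
#' @param binBp bin width in bp (default 1e5); the last bin is truncated if
#'   `binBp` does not divide the genome length.
#' @return list with `binEdges`, `binCounts` and `perPeak` (data.frame:
#'   `midpoint`, `lengthBp`, `gapBp`, `invGap`).
#' @export
densityProfile <- function(x, ctx, binBp = 1e5) {
    stopifnot(is(ctx, "GenomeContext"))
    if (!is.numeric(binBp) || binBp <= 0)
        .stopf("'binBp' must be a positive number of base pairs")
    gr <- if (is(x, "ConfirmedPeakSet")) consensusPeaks(x) else x
    L <- genomeLength(ctx)
    mid <- .mid0(gr) %% L
    bc <- .binCounts(mid, L, binBp)
    ord <- order(mid)
    gaps <- if (length(mid) == 1L) L else diff(c(mid[ord], mid[ord][1] + L))
    perPeak <- data.frame(midpoint = mid[ord],
                          lengthBp = GenomicRanges::width(gr)[ord],
                          gapBp = gaps, invGap = 1 / gaps)
    list(binEdges = bc$edges, binCounts = bc$counts, perPeak = perPeak)
}

#' Permutation test for an oriC-to-ter binding bias
#'
#' Quantifies whether peak density decreases with circular distance from
#' oriC. Peak midpoints are binned along the chromosome; the statistic is the
#' Spearman rank correlation between each bin's count and the circular
#' distance of the bin midpoint from oriC (negative = density falls toward
#' ter). The null distribution is built by re-placing the same number of
#' midpoints uniformly on the circle `nPerm` times; the p-value is the
#' one-sided lower-tail probability, so small p together with a negative
#' statistic indicates ori-proximal clustering.
#'
#' @param x a [ConfirmedPeakSet-class] or peak `GRanges`.
#' @param ctx a [GenomeContext-class].
#' @param binBp bin width in bp (default 1e5).
#' @param nPerm number of permutations (>= 100).
#' @param seed seed for the permutation draws (the caller's RNG state is
#'   left untouched).
#' @return list with `statistic`, `pValue`, `nPerm`, `binEdges`,
#'   `binCounts`, `nPeaks`.
#' @export
oriTerBias <- function(x, ctx, binBp = 1e5, nPerm = 1000, seed = 1L) {
    stopifnot(is(ctx, "GenomeContext"))
    if (nPerm < 100) .stopf("'nPerm' must be at least 100")
    mid <- .peakMidpoints(x)
    L <- genomeLength(ctx)
    mid <- mid %% L
    bc <- .binCounts(mid, L, binBp)
    if (sum(bc$counts > 0) < 3L)
        .stopf("fewer than 3 non-empty bins; use a smaller 'binBp' or more peaks")
    binMid <- (bc$edges[-length(bc$edges)] + bc$edges[-1]) / 2
    dOri <- circularDistance(binMid, oricPos(ctx), ctx)
    dRank <- rank(dOri)
    stat <- stats::cor(rank(bc$counts), dRank)
    n <- length(mid)
    edges <- bc$edges
    nb <- length(edges) - 1L
    permStat <- .withSeed(seed, {
        vapply(seq_len(nPerm), function(i) {
            m <- stats::runif(n, 0, L)
            cnt <- tabulate(findInterval(m, edges, rightmost.closed = TRUE),
                            nbins = nb)
            stats::cor(rank(cnt), dRank)
        }, numeric(1))
    })
    p <- (1 + sum(permStat <= stat)) / (nPerm + 1)
    list(statistic = stat, pValue = p, nPerm = nPerm,
         binEdges = bc$edges, binCounts = bc$counts, nPeaks = n)
}

# Promoter windows (0-based half-open), strand aware, wrapped circularly:
# + strand: [start - 150, start); - strand: [end, end + 150).
.promoterWindows <- function(features, ctx, upstream = 150L) {
    se <- .startEnd0(features)
    str <- as.character(GenomicRanges::strand(features))
    L <- genomeLength(ctx)
    s0 <- ifelse(str == "-", se$end, se$start - upstream)
    e0 <- ifelse(str == "-", se$end + upstream, se$start)
    neg <- which(s0 < 0)         # wrap leftward overhang onto the circle
    s0[neg] <- s0[neg] + L
    e0[neg] <- e0[neg] + L       # .granges0 splits intervals with end > L
    fid <- S4Vectors::mcols(features)$featureId
    .granges0(ctx, s0, e0, meta = S4Vectors::DataFrame(featureId = fid))
}

#' Annotate peaks to promoters and gene/operon bodies
#'
#' Applies window rules to place each peak in exactly one category:
#' \describe{
#'   \item{promoter}{the peak intersects the region from 150 bp upstream to
#'     1 bp upstream of a feature's strand-aware start (upstream of the end
#'     coordinate for minus-strand features); windows extending past the
#'     linear genome edge wrap circularly.}
#'   \item{gene_body}{the peak begins and ends within a single feature body.}
#'   \item{mixed}{both predicates hold.}
#'   \item{intergenic}{neither holds.}
#' }
#' The two predicates are evaluated literally (no precedence rule), so the
#' categories are exhaustive and mutually exclusive by construction.
#'
#' @param x a [ConfirmedPeakSet-class] or peak `GRanges`.
#' @param features stranded feature `GRanges` from [readFeatures()].
#' @param ctx a [GenomeContext-class].
#' @param upstream promoter window size in bp (default 150).
#' @return list with `annotations` (data.frame: `peak`, `category`,
#'   `featureId`) and `tally` (named fractions over the four categories).
#' @export
annotatePeaks <- function(x, features, ctx, upstream = 150L) {
    stopifnot(is(ctx, "GenomeContext"))
    gr <- if (is(x, "ConfirmedPeakSet")) consensusPeaks(x) else x
    if (!length(gr))
        return(list(annotations = data.frame(peak = character(0),
                                             category = character(0),
                                             featureId = character(0)),
                    tally = c(promoter = NA_real_, gene_body = NA_real_,
                              intergenic = NA_real_, mixed = NA_real_)))
    prom <- .promoterWindows(features, ctx, upstream)
    promHit <- GenomicRanges::findOverlaps(gr, prom, ignore.strand = TRUE)
    bodyHit <- GenomicRanges::findOverlaps(gr, features, type = "within",
                                           ignore.strand = TRUE)
    isProm <- seq_along(gr) %in% S4Vectors::queryHits(promHit)
    isBody <- seq_along(gr) %in% S4Vectors::queryHits(bodyHit)
    category <- ifelse(isProm & isBody, "mixed",
                ifelse(isProm, "promoter",
                ifelse(isBody, "gene_body", "intergenic")))
    fid <- rep(NA_character_, length(gr))
    pf <- S4Vectors::mcols(prom)$featureId
    bf <- S4Vectors::mcols(features)$featureId
    first <- function(hits, ids) {
        out <- rep(NA_character_, length(gr))
        q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
        keep <- !duplicated(q)
        out[q[keep]] <- as.character(ids[s[keep]])
        out
    }
    fromBody <- first(bodyHit, bf)
    fromProm <- first(promHit, pf)
    fid <- ifelse(isBody, fromBody, ifelse(isProm, fromProm, NA_character_))
    nm <- names(gr) %||% paste0("peak_", seq_along(gr))
    ann <- data.frame(peak = nm, category = category, featureId = fid)
    lv <- c("promoter", "gene_body", "intergenic", "mixed")
    tally <- table(factor(category, levels = lv)) / length(gr)
    list(annotations = ann, tally = c(tally))
}
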