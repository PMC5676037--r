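# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Build a GRanges on the context's circular seqinfo from 0-based half-open
# coordinates; intervals running past the linear end (end0 > L) are split into
# two sub-intervals sharing the same name.
.granges0 <- function(ctx, start0, end0, meta = NULL, names = NULL) {
    L <- genomeLength(ctx)
    stopifnot(length(start0) == length(end0))
    wraps <- which(end0 > L)
    idx <- seq_along(start0)
    if (length(wraps)) {
        s2 <- rep(0, length(wraps))
        e2 <- end0[wraps] - L
        end0[wraps] <- L
        start0 <- c(start0, s2)
        end0 <- c(end0, e2)
        idx <- c(idx, wraps)
    }
    si <- GenomeInfoDb::Seqinfo(seqnames = chromName(ctx), seqlengths = L,
                                isCircular = TRUE)
    gr <- GenomicRanges::GRanges(
        seqnames = rep(chromName(ctx), length(start0)),
        ranges = IRanges::IRanges(start = start0 + 1, end = end0),
        seqinfo = si)
    if (!is.null(meta)) S4Vectors::mcols(gr) <- meta[idx, , drop = FALSE]
    if (!is.null(names)) names(gr) <- names[idx]
    BiocGenerics::sort(gr)
}

# 0-based continuous midpoints of a GRanges (internal 1-based storage).
.mid0 <- function(gr) {
    (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
}

# 0-based half-open (start, end) of a GRanges.
.startEnd0 <- function(gr) {
    data.frame(start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr))
}

.peaksFromTruth <- function(ctx, mid, width, fold = NULL, replicateId = NULL) {
    start0 <- round(mid - width / 2)
    end0 <- start0 + pmax(1, round(width))
    L <- genomeLength(ctx)
    neg <- which(start0 < 0)
    if (length(neg)) {  # rotate leftward overhang onto the circle
        start0[neg] <- start0[neg] + L
        end0[neg] <- end0[neg] + L
    }
    n <- length(start0)
    meta <- S4Vectors::DataFrame(
        foldEnrichment = rep_len(if (is.null(fold)) NA_real_ else fold, n),
        replicateId = rep_len(if (is.null(replicateId)) NA_character_
                              else replicateId, n))
    .granges0(ctx, start0, end0, meta = meta)
}
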