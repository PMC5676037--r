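# Independent brute-force oracles and fixture builders used across tests.

# Shortest arc by explicit enumeration of both directions.
bruteCircularDistance <- function(a, b, L) {
    min((a - b) %% L, (b - a) %% L)
}

# Position-occupancy oracle for replicate confirmation (intersection
# policy): mark every integer position covered by each set, intersect,
# extract maximal runs, drop runs touching control coverage.
# Intervals are data.frames with 0-based half-open columns start, end.
bruteConfirm <- function(rep1, rep2, control, L) {
    coverIt <- function(df) {
        v <- logical(L)
        for (i in seq_len(nrow(df))) {
            s <- df$start[i]; e <- df$end[i]
            if (e > s) v[(s + 1):e] <- TRUE  # 1-indexed positions s+1..e
        }
        v
    }
    both <- coverIt(rep1) & coverIt(rep2)
    ctrl <- if (nrow(control)) coverIt(control) else logical(L)
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
    if (!nrow(runs)) return(runs)
    keep <- vapply(seq_len(nrow(runs)), function(i) {
        !any(ctrl[(runs$start[i] + 1):runs$end[i]])
    }, logical(1))
    runs[keep, , drop = FALSE]
}

# Literal-predicate annotation oracle over integer position sets mod L.
bruteAnnotate <- function(peakStart, peakEnd, features, L, upstream = 150) {
    peakPos <- seq(peakStart, peakEnd - 1) %% L
    isProm <- FALSE
    isBody <- FALSE
    for (i in seq_len(nrow(features))) {
        fs <- features$start[i]; fe <- features$end[i]
        if (features$strand[i] == "+") {
            win <- seq(fs - upstream, fs - 1) %% L
        } else {
            win <- seq(fe, fe + upstream - 1) %% L
        }
        if (length(intersect(peakPos, win))) isProm <- TRUE
        if (peakStart >= fs && peakEnd <= fe) isBody <- TRUE
    }
    if (isProm && isBody) "mixed"
    else if (isProm) "promoter"
    else if (isBody) "gene_body"
    else "intergenic"
}

# Greedy nearest-neighbour linker written independently: sorts all
# candidate pairs of one frame transition by (distance, localization row,
# head id) and assigns greedily.
bruteLink <- function(locs, rMax) {
    locs <- locs[order(locs$frame), , drop = FALSE]
    locs$idx <- seq_len(nrow(locs))
    frames <- sort(unique(locs$frame))
    track <- integer(nrow(locs))
    nextId <- 0L
    prevRows <- integer(0)
    for (fi in seq_along(frames)) {
        rows <- locs$idx[locs$frame == frames[fi]]
        assigned <- rep(NA_integer_, length(rows))
        if (fi > 1 && frames[fi] == frames[fi - 1] + 1 && length(prevRows)) {
            cand <- expand.grid(pi = seq_along(prevRows),
                                ci = seq_along(rows))
            cand$d <- sqrt(
                (locs$x[prevRows[cand$pi]] - locs$x[rows[cand$ci]])^2 +
                (locs$y[prevRows[cand$pi]] - locs$y[rows[cand$ci]])^2)
            cand <- cand[cand$d <= rMax, , drop = FALSE]
            cand <- cand[order(cand$d, rows[cand$ci],
                               track[prevRows[cand$pi]]), , drop = FALSE]
            usedP <- logical(length(prevRows))
            usedC <- logical(length(rows))
            for (k in seq_len(nrow(cand))) {
                p <- cand$pi[k]; c <- cand$ci[k]
                if (!usedP[p] && !usedC[c]) {
                    assigned[c] <- track[prevRows[p]]
                    usedP[p] <- TRUE; usedC[c] <- TRUE
                }
            }
        }
        for (c in which(is.na(assigned))) {
            nextId <- nextId + 1L
            assigned[c] <- nextId
        }
        track[rows] <- assigned
        prevRows <- rows
    }
    data.frame(frame = locs$frame, x = locs$x, y = locs$y, track = track)
}

# Canonical partition signature of a linking result: sorted tracks as
# strings of member row keys, for comparing linkers that label differently.
linkSignature <- function(frame, x, y, track) {
    key <- paste(frame, signif(x, 10), signif(y, 10), sep = ":")
    unname(sort(vapply(split(key, track), function(k)
        paste(sort(k), collapse = "|"), character(1)), method = "radix"))
}

tinyContext <- function(L = 10000) GenomeContext(L)

randomIntervals <- function(n, L, maxLen = 200) {
    s <- sample.int(L - maxLen, n, replace = TRUE) - 1L
    data.frame(start = s, end = s + sample.int(maxLen, n, replace = TRUE))
}
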