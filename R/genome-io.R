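# genome_io: tabular input/output and circular-coordinate arithmetic.

#' Circular distance between chromosomal coordinates
#'
#' Shortest arc length between two positions on a circular chromosome,
#' `min(|a - b|, L - |a - b|)`. Vectorised over `a` and `b`; always in
#' `[0, L/2]` and symmetric in its arguments.
#'
#' @param a,b 0-based coordinates in `[0, lengthBp)`.
#' @param ctx a [GenomeContext-class].
#' @return numeric vector of distances in bp.
#' @examples
#' ctx <- GenomeContext(7e6)
#' circularDistance(0, 6999999, ctx)      # 1, wrapping past the origin
#' circularDistance(1e6, 5e6, ctx)        # 3e6, the shorter arc
#' @export
circularDistance <- function(a, b, ctx) {
    stopifnot(is(ctx, "GenomeContext"))
    L <- genomeLength(ctx)
    if (any(a < 0 | a >= L) || any(b < 0 | b >= L))
        .stopf("coordinates must lie in [0, %s)", format(L, big.mark = ","))
    d <- abs(a - b)
    pmin(d, L - d)
}

#' Read a BED-like peak file
#'
#' Parses a tab-separated BED-like file (>= 3 columns: chrom, start, end;
#' coordinates 0-based half-open) into a `GRanges` of peaks. An optional
#' numeric column is interpreted as the fold enrichment; peak callers differ
#' in which column carries it, so the column index is an argument. Intervals
#' that extend past the declared chromosome length wrap around the circle and
#' are split into two sub-intervals sharing a name.
#'
#' @param path file path.
#' @param ctx a [GenomeContext-class]; coordinates are validated against it.
#' @param foldColumn 1-based index of the column holding fold enrichment
#'   (default 5, matching [writePeaks()] output of
#'   chrom/start/end/name/fold); `NA` or a missing column yields `NA` folds.
#' @param replicateId label stored in the `replicateId` metadata column.
#' @return `GRanges` sorted by position with metadata columns
#'   `foldEnrichment` and `replicateId`.
#' @seealso [writePeaks()], [readFeatures()]
#' @export
readPeaks <- function(path, ctx, foldColumn = 5L,
                      replicateId = NA_character_) {
    stopifnot(is(ctx, "GenomeContext"))
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        return(.granges0(ctx, numeric(0), numeric(0),
                         meta = S4Vectors::DataFrame(
                             foldEnrichment = numeric(0),
                             replicateId = character(0))))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    # tolerate space-separated input
    one <- lengths(fields) == 1L
    fields[one] <- strsplit(lines[one], "[[:space:]]+")
    n <- lengths(fields)
    bad <- which(n < 3L)
    if (length(bad))
        .stopf("malformed line %d in '%s': fewer than 3 columns",
               lineNo[bad[1]], path)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad))
        .stopf("malformed line %d in '%s': non-numeric coordinates",
               lineNo[bad[1]], path)
    bad <- which(start0 >= end0)
    if (length(bad))
        .stopf("invalid interval on line %d in '%s': start (%s) >= end (%s)",
               lineNo[bad[1]], path, start0[bad[1]], end0[bad[1]])
    L <- genomeLength(ctx)
    bad <- which(start0 < 0 | start0 >= L | end0 > 2 * L)
    if (length(bad))
        .stopf("coordinates out of range on line %d in '%s'",
               lineNo[bad[1]], path)
    fold <- rep(NA_real_, length(lines))
    if (!is.na(foldColumn) && any(n >= foldColumn)) {
        has <- n >= foldColumn
        fold[has] <- suppressWarnings(as.numeric(
            vapply(fields[has], `[`, "", as.integer(foldColumn))))
    }
    nm <- ifelse(n >= 4L, vapply(fields, function(f) f[4L], ""),
                 paste0("peak_", seq_along(lines)))
    .granges0(ctx, start0, end0,
              meta = S4Vectors::DataFrame(foldEnrichment = fold,
                                          replicateId = replicateId),
              names = nm)
}

#' Write peaks to a BED-like file
#'
#' Emits chrom, start, end (0-based half-open), name and fold enrichment as
#' tab-separated columns; [readPeaks()] on the result reproduces the
#' intervals bit-exactly.
#'
#' @param gr `GRanges` with optional `foldEnrichment` metadata column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(gr, path) {
    se <- .startEnd0(gr)
    nm <- names(gr) %||% paste0("peak_", seq_along(gr))
    if (is.null(nm)) nm <- paste0("peak_", seq_along(gr))
    fold <- S4Vectors::mcols(gr)$foldEnrichment
    if (is.null(fold)) fold <- rep(NA_real_, length(gr))
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = format(se$start, scientific = FALSE, trim = TRUE),
                     end = format(se$end, scientific = FALSE, trim = TRUE),
                     name = nm, fold = fold)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a feature (gene/operon) annotation table
#'
#' Reads a tab-separated table with columns `id`, `start`, `end`, `strand`
#' (and optionally `kind`) into a stranded `GRanges`. The coordinate base of
#' the table is declared by `base` and converted to the internal 0-based
#' half-open convention on read. Duplicate ids are kept with a warning.
#'
#' @param path file path.
#' @param ctx a [GenomeContext-class].
#' @param base 0 if the table is already 0-based half-open, 1 if it uses
#'   1-based inclusive coordinates.
#' @param header whether the file has a header row.
#' @return `GRanges` sorted by start, with metadata columns `featureId` and
#'   `kind`.
#' @export
readFeatures <- function(path, ctx, base = 0, header = FALSE) {
    stopifnot(is(ctx, "GenomeContext"), base %in% c(0, 1))
    df <- utils::read.table(path, sep = "\t", header = header,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L)
        .stopf("feature table '%s' needs columns id, start, end, strand", path)
    names(df)[1:4] <- c("id", "start", "end", "strand")
    if (!all(df$strand %in% c("+", "-")))
        .stopf("unknown strand symbol '%s' in '%s' (expected + or -)",
               setdiff(df$strand, c("+", "-"))[1], path)
    start0 <- if (base == 1) df$start - 1 else df$start
    end0 <- df$end  # 1-based inclusive end == 0-based half-open end
    if (any(start0 >= end0))
        .stopf("invalid feature interval in '%s': start >= end", path)
    if (anyDuplicated(df$id))
        .warnf("duplicate feature ids in '%s'; all rows kept", path)
    kind <- if (ncol(df) >= 5L) as.character(df[[5L]]) else "operon"
    gr <- .granges0(ctx, start0, end0,
                    meta = S4Vectors::DataFrame(featureId = df$id, kind = kind,
                                                strand = df$strand))
    GenomicRanges::strand(gr) <- S4Vectors::mcols(gr)$strand
    S4Vectors::mcols(gr)$strand <- NULL
    gr
}
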