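#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' Circular chromosome context
#'
#' Describes the coordinate frame every interval computation runs in: a single
#' circular chromosome of known length with declared origin of replication
#' (oriC) and terminus (ter) positions. Coordinates are 0-based and live in
#' `[0, lengthBp)`; intervals are 0-based half-open on input/output (BED
#' convention).
#'
#' @slot chromName single chromosome name.
#' @slot lengthBp chromosome length in base pairs.
#' @slot oricPos 0-based coordinate of oriC.
#' @slot terPos 0-based coordinate of ter.
#'
#' @seealso [GenomeContext()] for the user constructor,
#'   [circularDistance()] for the induced metric.
#' @export
setClass("GenomeContext",
    slots = c(
        chromName = "character",
        lengthBp  = "numeric",
        oricPos   = "numeric",
        terPos    = "numeric"
    )
)

setValidity("GenomeContext", function(object) {
    msg <- character()
    if (length(object@chromName) != 1L || is.na(object@chromName) ||
        !nzchar(object@chromName))
        msg <- c(msg, "'chromName' must be a single non-empty string")
    if (length(object@lengthBp) != 1L || is.na(object@lengthBp) ||
        object@lengthBp <= 0)
        msg <- c(msg, "'lengthBp' must be a single positive number")
    for (s in c("oricPos", "terPos")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v < 0 || v >= object@lengthBp)
            msg <- c(msg, sprintf("'%s' must lie in [0, lengthBp)", s))
    }
    if (length(msg) == 0L && object@oricPos == object@terPos)
        msg <- c(msg, "'oricPos' and 'terPos' must differ")
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeContext
#'
#' @param lengthBp chromosome length in bp (e.g. 7e6 for a ~7-Mbp
#'   mycobacterial chromosome).
#' @param chromName chromosome name used in interval containers.
#' @param oricPos 0-based oriC coordinate; defaults to 0 so that oriC anchors
#'   the map.
#' @param terPos 0-based ter coordinate; defaults to the antipode
#'   `floor(lengthBp / 2)`.
#'
#' @return A [GenomeContext-class] object.
#' @examples
#' ctx <- GenomeContext(7e6)
#' circularDistance(0, 6999999, ctx)
#' @export
GenomeContext <- function(lengthBp, chromName = "chr",
                          oricPos = 0, terPos = floor(lengthBp / 2)) {
    new("GenomeContext", chromName = as.character(chromName),
        lengthBp = as.numeric(lengthBp), oricPos = as.numeric(oricPos),
        terPos = as.numeric(terPos))
}

setMethod("show", "GenomeContext", function(object) {
    cat("GenomeContext:", object@chromName,
        sprintf("(%s bp, circular)\n", format(object@lengthBp, big.mark = ",")))
    cat("  oriC:", format(object@oricPos, big.mark = ","),
        " ter:", format(object@terPos, big.mark = ","), "\n")
})

#' Replicate-confirmed ChIP-Seq peak set
#'
#' The consensus peak set obtained by requiring support from two
#' immunoprecipitation replicates and absence from a control strain
#' ([confirmPeaks()]). Consensus peaks are stored as a non-overlapping
#' `GRanges`; per-peak provenance records the contributing replicate
#' intervals and their fold enrichments, which downstream enrichment
#' filtering ([filterByEnrichment()]) consumes.
#'
#' @slot peaks `GRanges` of consensus intervals, sorted, non-overlapping.
#' @slot provenance list (one element per consensus peak) of data.frames with
#'   columns `replicate`, `start`, `end`, `foldEnrichment` (0-based half-open
#'   coordinates).
#' @slot genome the [GenomeContext-class] the peaks live on.
#'
#' @export
setClass("ConfirmedPeakSet",
    slots = c(
        peaks      = "GRanges",
        provenance = "list",
        genome     = "GenomeContext"
    )
)

setValidity("ConfirmedPeakSet", function(object) {
    msg <- character()
    if (length(object@provenance) != length(object@peaks))
        msg <- c(msg, "one provenance entry is required per consensus peak")
    if (length(object@peaks) > 1L) {
        red <- GenomicRanges::reduce(object@peaks)
        if (length(red) != length(object@peaks))
            msg <- c(msg, "consensus peaks must be non-overlapping after merge")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ConfirmedPeakSet", function(object) {
    cat("ConfirmedPeakSet with", length(object@peaks),
        "consensus peaks on", object@genome@chromName, "\n")
    if (length(object@peaks)) {
        w <- GenomicRanges::width(object@peaks)
        cat(sprintf("  width: median %d bp, %d peak(s) >= 1,000 bp\n",
                    as.integer(stats::median(w)), sum(w >= 1000L)))
    }
})

#' @describeIn ConfirmedPeakSet number of consensus peaks.
#' @param x a `ConfirmedPeakSet`.
#' @export
setMethod("length", "ConfirmedPeakSet", function(x) length(x@peaks))

#' Synthetic-data generator configuration
#'
#' Bundles the seed, the genome and the three generator models (peaks,
#' tracks, profiles). Construct with [simConfig()], which fills in the
#' default study conditions; identical configurations (including the seed)
#' yield bit-identical simulated data.
#'
#' @slot seed integer RNG seed.
#' @slot genome [GenomeContext-class] used by the peak generator.
#' @slot peakModel,sptModel,profileModel named lists of generator
#'   parameters; see [simConfig()] for fields and defaults.
#'
#' @export
setClass("SimConfig",
    slots = c(
        seed         = "integer",
        genome       = "GenomeContext",
        peakModel    = "list",
        sptModel     = "list",
        profileModel = "list"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    pm <- object@peakModel; sm <- object@sptModel; fm <- object@profileModel
    chkFrac <- function(v, nm) {
        if (!is.null(v) && (!is.numeric(v) || is.na(v) || v < 0 || v > 1))
            sprintf("'%s' must be a fraction in [0, 1]", nm) else character()
    }
    chkPos <- function(v, nm) {
        if (!is.null(v) && (!is.numeric(v) || is.na(v) || v <= 0))
            sprintf("'%s' must be positive", nm) else character()
    }
    msg <- c(msg,
        chkFrac(pm$gradientStrength, "peaks$gradientStrength"),
        chkFrac(pm$dropout, "peaks$dropout"),
        chkFrac(pm$controlRate, "peaks$controlRate"),
        chkPos(pm$nPeaks, "peaks$nPeaks"),
        chkPos(pm$jitterBp, "peaks$jitterBp"),
        chkFrac(sm$immobileFraction, "tracks$immobileFraction"),
        chkPos(sm$dMobile, "tracks$dMobile"),
        chkPos(sm$dt, "tracks$dt"),
        chkPos(sm$cellWidth, "tracks$cellWidth"),
        chkPos(fm$occupancy, "profiles$occupancy"),
        chkFrac(fm$coupling, "profiles$coupling"))
    if (!is.null(sm$sigma) && (!is.numeric(sm$sigma) || sm$sigma < 0))
        msg <- c(msg, "'tracks$sigma' must be non-negative")
    if (!is.null(fm$occupancy) && fm$occupancy > 1)
        msg <- c(msg, "'profiles$occupancy' must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig (seed", object@seed, ")\n")
    cat("  peaks:   n =", object@peakModel$nPeaks,
        ", gradient", object@peakModel$gradientShape,
        object@peakModel$gradientStrength, "\n")
    cat("  tracks:  n =", object@sptModel$nTracks,
        ", immobile fraction", signif(object@sptModel$immobileFraction, 3), "\n")
    cat("  profiles: n =", object@profileModel$nCells,
        ", occupancy", object@profileModel$occupancy, "\n")
})

#' Densitometry standard curve
#'
#' Linear calibration of band intensity against known protein amounts,
#' fitted by ordinary least squares ([fitStandardCurve()]) and used to
#' convert sample band intensities into protein mass and copies per cell
#' ([moleculesPerCell()]).
#'
#' @slot amounts known amounts loaded (ng).
#' @slot intensities measured band intensities (arbitrary units).
#' @slot slope,intercept fitted line `intensity = slope * amount + intercept`.
#' @slot r2 coefficient of determination of the fit.
#'
#' @export
setClass("StandardCurve",
    slots = c(
        amounts     = "numeric",
        intensities = "numeric",
        slope       = "numeric",
        intercept   = "numeric",
        r2          = "numeric"
    )
)

setValidity("StandardCurve", function(object) {
    msg <- character()
    if (length(object@amounts) < 3L)
        msg <- c(msg, "a standard curve needs at least 3 calibration points")
    if (length(object@amounts) != length(object@intensities))
        msg <- c(msg, "'amounts' and 'intensities' must have equal length")
    if (any(object@amounts <= 0))
        msg <- c(msg, "'amounts' must be strictly positive")
    if (length(msg)) msg else TRUE
})

setMethod("show", "StandardCurve", function(object) {
    cat(sprintf("StandardCurve: intensity = %.4g * ng %+.4g (r2 = %.4f, n = %d)\n",
                object@slope, object@intercept, object@r2,
                length(object@amounts)))
})
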