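#' @rdname GenomeContext-class
#' @param x a `GenomeContext`.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname GenomeContext-class
#' @export
setGeneric("oricPos", function(x) standardGeneric("oricPos"))

#' @rdname GenomeContext-class
#' @export
setGeneric("terPos", function(x) standardGeneric("terPos"))

#' @rdname GenomeContext-class
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @describeIn GenomeContext-class chromosome length in bp.
#' @export
setMethod("genomeLength", "GenomeContext", function(x) x@lengthBp)

#' @describeIn GenomeContext-class 0-based oriC coordinate.
#' @export
setMethod("oricPos", "GenomeContext", function(x) x@oricPos)

#' @describeIn GenomeContext-class 0-based ter coordinate.
#' @export
setMethod("terPos", "GenomeContext", function(x) x@terPos)

#' @describeIn GenomeContext-class chromosome name.
#' @export
setMethod("chromName", "GenomeContext", function(x) x@chromName)

#' @rdname ConfirmedPeakSet-class
#' @export
setGeneric("consensusPeaks", function(x) standardGeneric("consensusPeaks"))

#' @rdname ConfirmedPeakSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ConfirmedPeakSet-class
#' @export
setGeneric("nConfirmed", function(x) standardGeneric("nConfirmed"))

#' @describeIn ConfirmedPeakSet-class consensus intervals as a `GRanges`.
#' @export
setMethod("consensusPeaks", "ConfirmedPeakSet", function(x) x@peaks)

#' @describeIn ConfirmedPeakSet-class per-peak contributing replicate
#'   intervals (list of data.frames).
#' @export
setMethod("provenance", "ConfirmedPeakSet", function(x) x@provenance)

#' @describeIn ConfirmedPeakSet-class number of confirmed peaks.
#' @export
setMethod("nConfirmed", "ConfirmedPeakSet", function(x) length(x@peaks))
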