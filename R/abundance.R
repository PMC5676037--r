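# abundance: standard-curve quantification of fusion-protein copies per
# cell and the genome-wide binding-interval arithmetic.

.AVOGADRO <- 6.02214076e23

#' Fit a densitometry standard curve
#'
#' Ordinary least-squares line `intensity = slope * amount + intercept`
#' through known amounts of purified reference protein and their measured
#' band intensities. A non-positive slope is allowed but warned about.
#'
#' @param amounts known protein amounts (ng), >= 3 strictly positive values.
#' @param intensities band intensities (arbitrary units).
#' @return A [StandardCurve-class].
#' @examples
#' fitStandardCurve(c(1, 2, 4), c(10, 20, 40))
#' @export
fitStandardCurve <- function(amounts, intensities) {
    if (length(amounts) < 3L)
        .stopf("at least 3 calibration points are required")
    fit <- stats::lm(intensities ~ amounts)
    slope <- unname(stats::coef(fit)[2])
    if (is.na(slope)) slope <- 0
    r2 <- if (stats::var(intensities) == 0) NA_real_
          else suppressWarnings(summary(fit)$r.squared)  # exact fits warn
    if (slope <= 0)
        .warnf("standard-curve slope is not positive (%.4g)", slope)
    new("StandardCurve", amounts = as.numeric(amounts),
        intensities = as.numeric(intensities), slope = slope,
        intercept = unname(stats::coef(fit)[1]), r2 = r2)
}

#' Protein copies per cell from a band intensity
#'
#' Converts a sample band intensity into nanograms via the standard curve,
#' into molecule counts via the monomer mass, and into copies per cell by
#' standardisation to the CFU count loaded in the lane:
#' `molecules = ng * 1e-9 / monomerMassDa * N_A`, `perCell = molecules /
#' laneCfu`.
#'
#' @param sampleIntensity band intensity (a.u.).
#' @param curve a [StandardCurve-class].
#' @param laneCfu number of colony-forming units loaded in the lane.
#' @param monomerMassDa monomer mass in daltons (default 48000, a
#'   ~48-kDa GFP fusion; use 47000 for the mCherry fusion).
#' @return list with `ngInLane`, `molecules`, `moleculesPerCell`.
#' @export
moleculesPerCell <- function(sampleIntensity, curve, laneCfu,
                             monomerMassDa = 48000) {
    stopifnot(is(curve, "StandardCurve"))
    if (!is.numeric(laneCfu) || laneCfu <= 0)
        .stopf("'laneCfu' must be a positive cell count")
    if (curve@slope == 0)
        .stopf("standard curve has zero slope; cannot invert")
    ng <- (sampleIntensity - curve@intercept) / curve@slope
    if (any(ng <= .Machine$double.eps^0.5))
        .stopf("sample intensity maps to a non-positive protein amount")
    molecules <- ng * 1e-9 / monomerMassDa * .AVOGADRO
    list(ngInLane = ng, molecules = molecules,
         moleculesPerCell = molecules / laneCfu)
}

#' Expected genome-wide binding interval
#'
#' If a chromosome of length `L` is shared evenly among `n` binding units,
#' each unit accounts for `L / n` bp. `copiesPerCell` is interpreted in
#' binding units (dimers for a HU-family NAP) divided by `stoichiometry`:
#' pass monomer counts with `stoichiometry = 2`, or dimer counts with the
#' default `stoichiometry = 1`. 30,000 dimers on a 7-Mbp chromosome give
#' one binding unit every ~233 bp.
#'
#' @param copiesPerCell protein copies per cell (> 0).
#' @param ctx a [GenomeContext-class].
#' @param stoichiometry copies per binding unit (default 1).
#' @return expected bp of chromosome per binding unit.
#' @examples
#' expectedBindingInterval(30000, GenomeContext(7e6))
#' @export
expectedBindingInterval <- function(copiesPerCell, ctx, stoichiometry = 1) {
    stopifnot(is(ctx, "GenomeContext"))
    if (!is.numeric(copiesPerCell) || copiesPerCell <= 0)
        .stopf("'copiesPerCell' must be positive")
    if (stoichiometry <= 0) .stopf("'stoichiometry' must be positive")
    units <- copiesPerCell / stoichiometry
    genomeLength(ctx) / units
}
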