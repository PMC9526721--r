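#' Sciatic function index (SFI)
#'
#' Walking-track gait metric from paired hindlimb footprints:
#' `SFI = -38.3*(EPL - NPL)/NPL + 109.5*(ETS - NTS)/NTS
#'        + 13.3*(EITS - NITS)/NITS - 8.8`,
#' where PL is the print length (heel to third toe), TS the toe spread
#' (first to fifth toe) and ITS the intermediary toe spread (second to
#' fourth toe); `E` marks the experimental (injured) side, `N` the naive
#' contralateral side. Values near 0 indicate normal gait; values near
#' -100 severe impairment. The formula uses only within-pair ratios and is
#' therefore invariant to a common rescaling of all measurements.
#'
#' @param EPL,NPL experimental / naive print length (> 0, same unit).
#' @param ETS,NTS experimental / naive toe spread.
#' @param EITS,NITS experimental / naive intermediary toe spread.
#' @return The SFI value (vectorized over its arguments).
#' @examples
#' sciaticFunctionIndex(10, 10, 5, 5, 2, 2)  # symmetric prints: -8.8
#' @export
sciaticFunctionIndex <- function(EPL, NPL, ETS, NTS, EITS, NITS) {
  vals <- cbind(EPL, NPL, ETS, NTS, EITS, NITS)
  if (any(vals <= 0))
    stop("all footprint measurements must be positive")
  -38.3 * (EPL - NPL) / NPL + 109.5 * (ETS - NTS) / NTS +
    13.3 * (EITS - NITS) / NITS - 8.8
}

#' Total regenerating axons at a distance
#'
#' Estimated total number of regenerating axons extending to a distance
#' along the nerve: `pi * r^2 * axonsPerMm / t`, with `r` the nerve
#' cross-sectional radius, `axonsPerMm` the average count of labeled axons
#' per mm of nerve width at that distance, and `t` the optical-section
#' thickness (default 0.010 mm, i.e. 10 um). `r` and `t` must carry the
#' same length unit tag; the count is per the same unit.
#'
#' @param r nerve radius (> 0).
#' @param axonsPerMm average axons per unit nerve width (>= 0).
#' @param t section thickness (> 0; default 0.010).
#' @param rUnit,tUnit unit tags (default `"mm"`); a mismatch is an error.
#' @return Estimated axon count (unrounded).
#' @examples
#' totalRegeneratingAxons(0.2, 50)  # 200 * pi
#' @export
totalRegeneratingAxons <- function(r, axonsPerMm, t = 0.010,
                                   rUnit = "mm", tUnit = "mm") {
  if (!identical(rUnit, tUnit))
    stop("unit mismatch: r in ", rUnit, ", t in ", tUnit)
  stopifnot(r > 0, t > 0, axonsPerMm >= 0)
  pi * r^2 * axonsPerMm / t
}

#' @rdname totalRegeneratingAxons
#' @param d nerve cross-sectional width (diameter); halved to the radius.
#' @param dUnit unit tag of the diameter.
#' @export
totalRegeneratingAxonsFromDiameter <- function(d, axonsPerMm, t = 0.010,
                                               dUnit = "mm", tUnit = "mm") {
  totalRegeneratingAxons(d / 2, axonsPerMm, t, rUnit = dUnit,
                         tUnit = tUnit)
}

#' Pupillary constriction percentage
#'
#' Percentage change in pupil area between a dark-adapted baseline and the
#' reading after a light stimulus: `100 * (baseline - stimulated) /
#' baseline`. Dilation (stimulated area above baseline) yields a negative
#' value and a warning. `pupilConstrictionFromDiameter()` squares diameters
#' into areas first.
#'
#' @param baselineArea,stimulatedArea pupil areas (> 0).
#' @return Constriction percentage.
#' @export
pupilConstrictionPercent <- function(baselineArea, stimulatedArea) {
  if (any(baselineArea <= 0)) stop("baseline area must be positive")
  out <- 100 * (baselineArea - stimulatedArea) / baselineArea
  if (any(out < 0)) warning("pupil dilation: negative constriction")
  out
}

#' @rdname pupilConstrictionPercent
#' @param baselineDiameter,stimulatedDiameter pupil diameters (> 0).
#' @export
pupilConstrictionFromDiameter <- function(baselineDiameter,
                                          stimulatedDiameter) {
  pupilConstrictionPercent(baselineDiameter^2, stimulatedDiameter^2)
}

#' qPCR relative fold change (2^-ddCt)
#'
#' Delta-delta-Ct method: `dCt = Ct_target - Ct_reference` within each
#' condition, `ddCt = dCt_test - dCt_control`, fold change `2^-ddCt`.
#'
#' @param ctTargetTest,ctRefTest target and reference-gene Ct in the test
#'   condition.
#' @param ctTargetControl,ctRefControl same in the control condition.
#' @return Fold change of the target relative to control.
#' @examples
#' ddctFoldChange(20, 18, 23, 18)  # 2^3 = 8
#' @export
ddctFoldChange <- function(ctTargetTest, ctRefTest,
                           ctTargetControl, ctRefControl) {
  cts <- cbind(ctTargetTest, ctRefTest, ctTargetControl, ctRefControl)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("Ct values must be finite and positive")
  ddct <- (ctTargetTest - ctRefTest) - (ctTargetControl - ctRefControl)
  2^(-ddct)
}

#' Paired percent recovery
#'
#' A measurement normalized to its within-animal reference (contralateral
#' side or pre-injury baseline): `100 * injured / reference`.
#'
#' @param injured measurement on the injured/treated side (>= 0).
#' @param reference paired reference measurement (> 0).
#' @return Percentage.
#' @export
pairedPercentRecovery <- function(injured, reference) {
  if (any(reference <= 0)) stop("reference measurement must be positive")
  100 * injured / reference
}
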