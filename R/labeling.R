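#' Label GM / WM / GWB from tissue probability images
#'
#' The working label volume of the width pipeline: a voxel is GM when
#' `pGM >= tProb`, else WM when `pWM >= tProb`, else the gray/white boundary
#' (GWB) when both probabilities are strictly positive and strictly below
#' `tProb`; everything else is background. The threshold defaults to 0.9.
#' GM/WM certainty takes precedence over junction membership, and the strict
#' positivity is honored exactly: a voxel with `pGM = 0` can never be GWB.
#' CSF probability does not participate.
#'
#' @param pGm,pWm Probability-role [BrainVolume-class]s of identical geometry.
#' @param tProb Threshold in (0, 1].
#' @return Label-role [BrainVolume-class] over
#'   {background = 0, GM = 2, WM = 3, GWB = 4}.
#' @examples
#' pg <- brainVolume(array(c(0.95, 0.5, 0, 0.2, 0.95, 0.5, 0, 0.2), c(2, 2, 2)),
#'                   role = "probability")
#' pw <- brainVolume(array(c(0.03, 0.4, 0, 0.92, 0.03, 0.4, 0, 0.92), c(2, 2, 2)),
#'                   role = "probability")
#' countLabels(labelRegions(pg, pw))
#' @export
labelRegions <- function(pGm, pWm, tProb = 0.9) {
  stopifnot(is(pGm, "BrainVolume"), is(pWm, "BrainVolume"))
  checkSameGeometry(pGm, pWm, "probability volumes")
  if (!(tProb > 0 && tProb <= 1)) stop("domain error: tProb must be in (0, 1]")
  g <- pGm@data; w <- pWm@data
  lab <- array(0L, dim = dim(g))
  isGm <- g >= tProb
  isWm <- !isGm & w >= tProb
  isGwb <- !isGm & !isWm & g > 0 & g < tProb & w > 0 & w < tProb
  lab[isGm] <- labelCodes()[["gm"]]
  lab[isWm] <- labelCodes()[["wm"]]
  lab[isGwb] <- labelCodes()[["gwb"]]
  brainVolume(lab, spacing = pGm@spacing, affine = pGm@affine, role = "label")
}

#' Count voxels per label
#'
#' @param labels Label-role [BrainVolume-class].
#' @return Named integer vector over the codes of [labelCodes()] (all five
#'   names present; counts sum to the voxel count).
#' @export
countLabels <- function(labels) {
  stopifnot(is(labels, "BrainVolume"))
  codes <- labelCodes()
  out <- vapply(codes, function(cd) sum(labels@data == cd), integer(1))
  names(out) <- names(codes)
  out
}
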