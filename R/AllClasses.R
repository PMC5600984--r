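#' @useDynLib ldpo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Label codes used throughout the package
#'
#' Volumes with role `"label"` use a fixed integer code table:
#' 0 = background, 1 = CSF, 2 = GM, 3 = WM, 4 = GWB (the gray/white matter
#' boundary band).
#'
#' @return Named integer vector of label codes.
#' @examples
#' labelCodes()
#' @export
labelCodes <- function() {
  c(background = 0L, csf = 1L, gm = 2L, wm = 3L, gwb = 4L)
}

#' Status codes for traced gray/white boundary paths
#'
#' Per-voxel outcome of the greedy potential-field trace: 0 = not a GWB voxel,
#' 1 = ok (both endpoints found), 2 = the GM-ward descent stalled,
#' 3 = the WM-ward ascent stalled, 4 = a voxel repeated (defensive guard).
#'
#' @return Named integer vector of status codes.
#' @export
statusCodes <- function() {
  c(none = 0L, ok = 1L, gm_unreachable = 2L, wm_unreachable = 3L,
    cycle_detected = 4L)
}

.volumeRoles <- c("intensity", "probability", "potential", "width", "label", "mask")

#' BrainVolume: a 3D scalar grid with voxel geometry
#'
#' The carrier type of the package: a 3D array together with its voxel
#' spacing (mm), a 4x4 voxel-to-world affine (NIfTI convention, mapping
#' 0-based voxel indices to world mm), and a `role` declaring what the values
#' mean. Validity constraints depend on the role: probability volumes must lie
#' in \[0, 1\], width volumes must be non-negative, label volumes must only use
#' the codes of [labelCodes()], and mask volumes are binary.
#'
#' @slot data 3D numeric or integer array.
#' @slot spacing Numeric length-3, mm per voxel along each axis, all > 0.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot role One of `"intensity"`, `"probability"`, `"potential"`, `"width"`,
#'   `"label"`, `"mask"`.
#' @export
setClass("BrainVolume",
  representation(data = "array", spacing = "numeric", affine = "matrix",
                 role = "character"))

setValidity("BrainVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must have exactly 3 dimensions")
  if (any(dim(d) < 1L)) return("all dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    return("spacing must be 3 positive finite values (mm/voxel)")
  }
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (length(object@role) != 1L || !object@role %in% .volumeRoles) {
    return(sprintf("role must be one of: %s", paste(.volumeRoles, collapse = ", ")))
  }
  v <- as.vector(d)
  switch(object@role,
    probability = if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      return("probability-role values must lie in [0, 1]"),
    width = if (any(v < 0, na.rm = TRUE))
      return("width-role values must be >= 0"),
    label = if (!all(v %in% labelCodes()))
      return("label-role values must be in {0 (background), 1 (CSF), 2 (GM), 3 (WM), 4 (GWB)}"),
    mask = if (!all(v %in% c(0, 1)))
      return("mask-role values must be 0/1"),
    NULL)
  TRUE
})

#' Construct a BrainVolume
#'
#' @param data 3D array.
#' @param spacing Voxel spacing in mm (length 3).
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing` (0-based voxel convention).
#' @param role Value semantics; see [BrainVolume-class].
#' @return A [BrainVolume-class] object.
#' @examples
#' v <- brainVolume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1.2))
#' dim(v)
#' @export
brainVolume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                        role = "intensity") {
  if (is.null(dim(data))) stop("data must be a 3D array")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  if (role %in% c("label", "mask")) storage.mode(data) <- "integer"
  new("BrainVolume", data = data, spacing = as.numeric(spacing),
      affine = affine, role = role)
}

#' TissueModel: per-class Gaussian parameters of the HMRF model
#'
#' Gaussian intensity parameters for the ordered classes CSF < GM < WM
#' (T1 ordering), plus the Potts pairwise weight `beta` and the per-iteration
#' parameter history recorded by [emFit()].
#'
#' @slot mu Named numeric length-3 class means, strictly increasing
#'   (csf, gm, wm).
#' @slot sigma Named numeric length-3 class standard deviations, all > 0.
#' @slot beta Non-negative MRF pairwise weight (the clique potential is
#'   `0.5 * beta` for a discordant neighbor pair).
#' @slot history List of per-iteration `(mu, sigma)` sets.
#' @export
setClass("TissueModel",
  representation(mu = "numeric", sigma = "numeric", beta = "numeric",
                 history = "list"))

setValidity("TissueModel", function(object) {
  if (length(object@mu) != 3L || length(object@sigma) != 3L)
    return("mu and sigma must each have length 3 (CSF, GM, WM)")
  if (any(object@sigma <= 0)) return("all sigma must be > 0")
  if (is.unsorted(object@mu, strictly = TRUE))
    return("means must satisfy mu_CSF < mu_GM < mu_WM")
  if (length(object@beta) != 1L || object@beta < 0) return("beta must be >= 0")
  TRUE
})

#' @rdname TissueModel-class
#' @param mu,sigma,beta,history See slots.
#' @return A [TissueModel-class] object.
#' @export
tissueModel <- function(mu, sigma, beta = 1, history = list()) {
  names(mu) <- names(sigma) <- c("csf", "gm", "wm")
  new("TissueModel", mu = mu, sigma = sigma, beta = beta, history = history)
}

#' SegmentationResult: labels and tissue posteriors from HMRF-EM
#'
#' @slot labels Label-role [BrainVolume-class] over {background, CSF, GM, WM}.
#' @slot pCsf,pGm,pWm Probability-role volumes; at every in-mask voxel the
#'   three posteriors sum to 1 (within 1e-6) and are 0 outside the mask.
#' @slot model Fitted [TissueModel-class].
#' @slot emIterations Number of EM iterations performed.
#' @slot converged Whether the parameter-change norm fell below tolerance.
#' @export
setClass("SegmentationResult",
  representation(labels = "BrainVolume", pCsf = "BrainVolume",
                 pGm = "BrainVolume", pWm = "BrainVolume",
                 model = "TissueModel", emIterations = "integer",
                 converged = "logical"))

#' PotentialField: converged Laplace solution over the GWB band
#'
#' @slot psi Potential-role [BrainVolume-class]; `NA` outside the field
#'   (CSF/background), exact Dirichlet constants on GM and WM.
#' @slot psiGm,psiGwb,psiWm Boundary / initialization constants,
#'   `psiGm < psiGwb < psiWm`.
#' @slot energyTrace Total field-energy value after each Jacobi sweep.
#' @slot iterations Number of sweeps performed.
#' @slot converged Whether the relative energy change fell below tolerance.
#' @export
setClass("PotentialField",
  representation(psi = "BrainVolume", psiGm = "numeric", psiGwb = "numeric",
                 psiWm = "numeric", energyTrace = "numeric",
                 iterations = "integer", converged = "logical"))

setValidity("PotentialField", function(object) {
  if (!(object@psiGm < object@psiGwb && object@psiGwb < object@psiWm))
    return("boundary constants must satisfy psiGm < psiGwb < psiWm")
  TRUE
})

#' WidthMap: per-voxel gray/white boundary width in mm
#'
#' @slot width Width-role [BrainVolume-class] (mm); 0 outside the GWB band and
#'   at voxels whose trace failed.
#' @slot statusMap Volume of [statusCodes()] per voxel.
#' @slot stats Summary list (mean, sd, max, min, mode, n) over all GWB voxels
#'   with a successfully measured width.
#' @export
setClass("WidthMap",
  representation(width = "BrainVolume", statusMap = "BrainVolume",
                 stats = "list"))

#' FeatureMap: a scalar lesion-detection feature with polarity
#'
#' @slot data Scalar [BrainVolume-class].
#' @slot featureName Identifier, e.g. `"gradient_magnitude"` or `"gwb_width"`.
#' @slot polarity `"high_is_positive"` (width map) or `"low_is_positive"`
#'   (gradient map: a blurred junction has a *small* gradient).
#' @slot backgroundRule Threshold below which voxels are excluded from
#'   evaluation entirely (`NA_real_` for none; 5 for the gradient map).
#' @export
setClass("FeatureMap",
  representation(data = "BrainVolume", featureName = "character",
                 polarity = "character", backgroundRule = "numeric"))

setValidity("FeatureMap", function(object) {
  if (!object@polarity %in% c("high_is_positive", "low_is_positive"))
    return("polarity must be 'high_is_positive' or 'low_is_positive'")
  TRUE
})

#' @rdname FeatureMap-class
#' @param data,featureName,polarity,backgroundRule See slots.
#' @return A [FeatureMap-class] object.
#' @export
featureMap <- function(data, featureName, polarity,
                       backgroundRule = NA_real_) {
  new("FeatureMap", data = data, featureName = featureName,
      polarity = polarity, backgroundRule = backgroundRule)
}

#' EvalCurve: threshold sweep of voxelwise detection metrics
#'
#' @slot curve data.frame with columns threshold, tp, tn, fp, fn, tpr, fpr,
#'   precision, recall, f_score (thresholds ascending).
#' @slot polarity Polarity of the evaluated feature.
#' @slot nEval Number of voxels entering the confusion counts (constant
#'   across thresholds).
#' @export
setClass("EvalCurve",
  representation(curve = "data.frame", polarity = "character",
                 nEval = "integer"))

#' PhantomBundle: a synthetic volume with ground truth
#'
#' @slot image Intensity-role [BrainVolume-class].
#' @slot truthLabels Label-role volume from the generating geometry.
#' @slot truthWidth Width-role volume: the generating band thickness (mm) on
#'   band voxels, 0 elsewhere.
#' @slot lesionMask Mask-role volume of the thickened ("lesional") band voxels.
#' @slot spec List of the generating parameters.
#' @export
setClass("PhantomBundle",
  representation(image = "BrainVolume", truthLabels = "BrainVolume",
                 truthWidth = "BrainVolume", lesionMask = "BrainVolume",
                 spec = "list"))
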