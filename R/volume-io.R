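#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI-1 image (optionally gzip-compressed) into a
#' [BrainVolume-class], taking the voxel spacing from the header. No
#' resampling or reorientation is performed; the data array is in the file's
#' native voxel order.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param role Value semantics of the volume (see [BrainVolume-class]);
#'   `"label"` and `"mask"` volumes are coerced to integer.
#' @return A [BrainVolume-class].
#' @seealso [writeVolume()], [rescaleIntensity()]
#' @export
readVolume <- function(path, role = "intensity") {
  if (!file.exists(path)) stop(sprintf("I/O error: file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("dimensionality error: expected a 3D image, got %dD", length(d)))
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("geometry error: non-positive voxel spacing in header")
  }
  aff <- tryCatch(unclass(RNifti::xform(img))[1:4, 1:4], error = function(e) NULL)
  if (is.null(aff) || !all(is.finite(aff))) aff <- diag(c(sp, 1))
  dat <- array(as.vector(img), dim = d)
  if (role %in% c("label", "mask")) storage.mode(dat) <- "integer"
  brainVolume(dat, spacing = sp, affine = aff, role = role)
}

#' Write a BrainVolume as NIfTI-1
#'
#' Integer roles (label, mask) are written as uint8 and round-trip exactly;
#' other roles are written as float32 (round-trip within float32 rounding).
#'
#' @param vol A [BrainVolume-class].
#' @param path Output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "BrainVolume"))
  if (!dir.exists(dirname(path))) {
    stop(sprintf("I/O error: directory does not exist: %s", dirname(path)))
  }
  dat <- vol@data
  dtype <- if (vol@role %in% c("label", "mask")) "uint8" else "float"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Rescale intensities to a working range
#'
#' Affine-linear global min-max rescaling (the pipeline's working range is
#' \[0, 255\]): the image minimum maps to `lo`, the maximum to `hi`, and the
#' voxel value order is preserved. Applying it twice is the identity within
#' floating-point rounding.
#'
#' @param vol Intensity-role [BrainVolume-class] with at least two distinct
#'   values.
#' @param lo,hi Target range, `hi > lo`.
#' @return Rescaled intensity [BrainVolume-class].
#' @examples
#' v <- brainVolume(array(c(10, 20, 30, 10, 20, 30, 10, 20), c(2, 2, 2)))
#' range(volData(rescaleIntensity(v)))
#' @export
rescaleIntensity <- function(vol, lo = 0, hi = 255) {
  stopifnot(is(vol, "BrainVolume"))
  if (vol@role != "intensity") stop("rescaleIntensity expects an intensity-role volume")
  if (hi <= lo) stop("domain error: hi must be > lo")
  r <- range(vol@data, finite = TRUE)
  if (r[1] == r[2]) {
    stop("degenerate-range error: constant image cannot be rescaled")
  }
  dat <- (vol@data - r[1]) / (r[2] - r[1]) * (hi - lo) + lo
  brainVolume(dat, spacing = vol@spacing, affine = vol@affine,
              role = "intensity")
}
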