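#' Slab phantom with a gray/white boundary band of known thickness
#'
#' Builds a layered 3D volume along a chosen axis: a CSF base layer, a GM
#' slab, a partial-volume intensity ramp of controllable physical thickness
#' (the constructed GWB band), and a WM slab. Optionally the band is locally
#' thickened inside a cylindrical "lesion" footprint, emulating the broadened
#' junction of a focal cortical dysplasia. Per-class Gaussian noise is added
#' with a seeded generator, so identical specs reproduce identical volumes.
#'
#' The CSF layer exists because the segmentation model is three-class; set
#' `csfMm = 0` for a pure GM/band/WM slab (suitable for testing the width
#' machinery on constructed labels, but not for running the full pipeline).
#'
#' @param shape Voxel counts, length 3.
#' @param spacing Voxel spacing mm, length 3.
#' @param gwbThicknessMm Physical thickness of the transition band (mm); the
#'   band occupies `max(1, round(thickness/spacing[axis]))` voxel layers.
#' @param tissueMeans Intensities (CSF, GM, WM), strictly increasing
#'   (T1 ordering).
#' @param tissueSds Per-class Gaussian noise SD; 0 for a noiseless phantom.
#'   Band voxels use the GM/WM SDs interpolated along the ramp.
#' @param csfMm Thickness of the CSF base layer (mm).
#' @param lesion `NULL`, or `list(center = c(i, j) in-plane voxel indices
#'   (default: volume center), radiusMm, multiplier > 1)`: columns whose
#'   in-plane world distance to the center is at most `radiusMm` get a band
#'   `multiplier` times thicker.
#' @param profile Ramp shape: `"linear"` (default) or `"smoothstep"`.
#' @param axis Slab normal (1, 2 or 3).
#' @param seed Integer seed for the noise generator.
#' @return A [PhantomBundle-class] with image, truth labels, truth width and
#'   lesion mask.
#' @examples
#' ph <- slabPhantom(shape = c(16, 16, 24), gwbThicknessMm = 3,
#'                   tissueSds = c(0, 0, 0))
#' table(volData(ph@truthLabels))
#' @export
slabPhantom <- function(shape = c(40, 40, 40), spacing = c(1, 1, 1),
                        gwbThicknessMm = 3,
                        tissueMeans = c(csf = 50, gm = 110, wm = 170),
                        tissueSds = c(10, 10, 10), csfMm = 5, lesion = NULL,
                        profile = c("linear", "smoothstep"), axis = 3,
                        seed = 1) {
  profile <- match.arg(profile)
  stopifnot(length(shape) == 3, length(spacing) == 3, gwbThicknessMm > 0)
  if (is.unsorted(tissueMeans, strictly = TRUE)) {
    stop("tissue means must be strictly increasing (CSF < GM < WM)")
  }
  if (!is.null(lesion)) {
    if (is.null(lesion$multiplier) || lesion$multiplier <= 1) {
      stop("lesion multiplier must be > 1")
    }
    if (is.null(lesion$radiusMm)) stop("lesion needs a radiusMm")
  }
  perm <- c(setdiff(1:3, axis), axis)   # build with the normal as axis 3
  shp <- shape[perm]; sp <- spacing[perm]
  nx <- shp[1]; ny <- shp[2]; nz <- shp[3]; dz <- sp[3]

  nCsf <- round(csfMm / dz)
  nb0 <- max(1L, round(gwbThicknessMm / dz))
  kc <- floor((nCsf + 1 + nz) / 2)

  bandIdx <- function(nb) {
    k0 <- kc - floor(nb / 2)
    c(k0, k0 + nb - 1L)
  }
  nbL <- if (is.null(lesion)) nb0 else max(1L, round(gwbThicknessMm * lesion$multiplier / dz))
  b0 <- bandIdx(nb0); bL <- bandIdx(max(nb0, nbL))
  if (bL[1] <= nCsf + 1 || bL[2] >= nz) {
    stop("geometry error: band thicker than the volume allows")
  }

  inLesionCol <- matrix(FALSE, nx, ny)
  if (!is.null(lesion)) {
    ctr <- if (is.null(lesion$center)) c((nx + 1) / 2, (ny + 1) / 2) else lesion$center
    xs <- (seq_len(nx) - ctr[1]) * sp[1]
    ys <- (seq_len(ny) - ctr[2]) * sp[2]
    inLesionCol <- outer(xs^2, ys^2, "+") <= lesion$radiusMm^2
  }

  img <- array(0, dim = shp)
  lab <- array(0L, dim = shp)
  wid <- array(0, dim = shp)
  les <- array(0L, dim = shp)
  sdv <- array(0, dim = shp)

  rampF <- function(f) if (profile == "linear") f else 3 * f^2 - 2 * f^3
  muC <- tissueMeans[1]; muG <- tissueMeans[2]; muW <- tissueMeans[3]
  sdC <- tissueSds[1]; sdG <- tissueSds[2]; sdW <- tissueSds[3]

  fillColumns <- function(cols, nb) {
    bi <- bandIdx(nb)
    for (k in seq_len(nz)) {
      if (k <= nCsf) {
        img[, , k][cols] <<- muC; lab[, , k][cols] <<- 1L
        sdv[, , k][cols] <<- sdC
      } else if (k < bi[1]) {
        img[, , k][cols] <<- muG; lab[, , k][cols] <<- 2L
        sdv[, , k][cols] <<- sdG
      } else if (k > bi[2]) {
        img[, , k][cols] <<- muW; lab[, , k][cols] <<- 3L
        sdv[, , k][cols] <<- sdW
      } else {
        f <- rampF((k - bi[1] + 0.5) / nb)
        img[, , k][cols] <<- muG + (muW - muG) * f
        lab[, , k][cols] <<- 4L
        wid[, , k][cols] <<- nb * dz
        sdv[, , k][cols] <<- (1 - f) * sdG + f * sdW
      }
    }
  }
  fillColumns(!inLesionCol, nb0)
  if (any(inLesionCol)) {
    fillColumns(inLesionCol, nbL)
    les <- array(0L, dim = shp)
    lesCols <- array(rep(inLesionCol, nz), dim = shp)
    les[lesCols & lab == 4L] <- 1L
  }

  img <- img + withSeed(seed, array(stats::rnorm(length(img)), dim = shp)) * sdv

  iperm <- order(perm)
  mk <- function(a, role) brainVolume(aperm(a, iperm), spacing = spacing, role = role)
  new("PhantomBundle",
      image = mk(img, "intensity"), truthLabels = mk(lab, "label"),
      truthWidth = mk(wid, "width"), lesionMask = mk(les, "mask"),
      spec = list(geometry = "slab", shape = shape, spacing = spacing,
                  gwbThicknessMm = nb0 * dz, requestedThicknessMm = gwbThicknessMm,
                  tissueMeans = unname(tissueMeans), tissueSds = unname(tissueSds),
                  csfMm = csfMm, lesion = lesion, hasLesion = !is.null(lesion),
                  profile = profile, axis = axis, seed = seed))
}

#' Spherical-shell phantom: curved gray/white boundary of known thickness
#'
#' Concentric geometry around the volume center: a WM core, a transition
#' shell of stated physical thickness (the GWB band, ramping from the WM to
#' the GM intensity), a GM mantle, and CSF outside.
#'
#' @inheritParams slabPhantom
#' @param wmRadiusMm Radius of the WM core (mm).
#' @param gmThicknessMm Thickness of the GM mantle outside the band (mm).
#' @return A [PhantomBundle-class]; the lesion mask is empty (shell lesions
#'   are not modelled).
#' @export
shellPhantom <- function(shape = c(40, 40, 40), spacing = c(1, 1, 1),
                         wmRadiusMm = 8, gwbThicknessMm = 2,
                         gmThicknessMm = 6,
                         tissueMeans = c(csf = 50, gm = 110, wm = 170),
                         tissueSds = c(10, 10, 10),
                         profile = c("linear", "smoothstep"), seed = 1) {
  profile <- match.arg(profile)
  stopifnot(gwbThicknessMm >= 0, wmRadiusMm > 0)
  if (is.unsorted(tissueMeans, strictly = TRUE)) {
    stop("tissue means must be strictly increasing (CSF < GM < WM)")
  }
  ctr <- (shape + 1) / 2
  r3 <- wmRadiusMm + gwbThicknessMm + gmThicknessMm
  maxFit <- min((shape - ctr) * spacing)
  if (r3 > maxFit) stop("geometry error: shell radii do not fit inside shape")

  xs <- (seq_len(shape[1]) - ctr[1]) * spacing[1]
  ys <- (seq_len(shape[2]) - ctr[2]) * spacing[2]
  zs <- (seq_len(shape[3]) - ctr[3]) * spacing[3]
  r <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))

  r1 <- wmRadiusMm; r2 <- wmRadiusMm + gwbThicknessMm
  rampF <- function(f) if (profile == "linear") f else 3 * f^2 - 2 * f^3
  muC <- tissueMeans[1]; muG <- tissueMeans[2]; muW <- tissueMeans[3]

  img <- array(muC, dim = shape)
  lab <- array(1L, dim = shape)
  wid <- array(0, dim = shape)
  sdv <- array(tissueSds[1], dim = shape)

  core <- r < r1
  band <- r >= r1 & r < r2
  mantle <- r >= r2 & r < r3
  img[core] <- muW; lab[core] <- 3L; sdv[core] <- tissueSds[3]
  if (any(band)) {
    f <- rampF((r[band] - r1) / max(gwbThicknessMm, .Machine$double.eps))
    img[band] <- muW + (muG - muW) * f
    lab[band] <- 4L
    wid[band] <- gwbThicknessMm
    sdv[band] <- f * tissueSds[2] + (1 - f) * tissueSds[3]
  }
  img[mantle] <- muG; lab[mantle] <- 2L; sdv[mantle] <- tissueSds[2]

  img <- img + withSeed(seed, array(stats::rnorm(length(img)), dim = shape)) * sdv

  mk <- function(a, role) brainVolume(a, spacing = spacing, role = role)
  new("PhantomBundle",
      image = mk(img, "intensity"), truthLabels = mk(lab, "label"),
      truthWidth = mk(wid, "width"),
      lesionMask = mk(array(0L, dim = shape), "mask"),
      spec = list(geometry = "spherical_shell", shape = shape,
                  spacing = spacing, gwbThicknessMm = gwbThicknessMm,
                  wmRadiusMm = wmRadiusMm, gmThicknessMm = gmThicknessMm,
                  tissueMeans = unname(tissueMeans),
                  tissueSds = unname(tissueSds), hasLesion = FALSE,
                  profile = profile, seed = seed))
}

#' Write a phantom bundle to a directory
#'
#' Emits `image.nii.gz`, `truth_labels.nii.gz`, `truth_width.nii.gz`,
#' `lesion_mask.nii.gz` and a `spec.yaml` sidecar of the generating
#' parameters.
#'
#' @param bundle A [PhantomBundle-class].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writePhantom <- function(bundle, dir) {
  stopifnot(is(bundle, "PhantomBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVolume(bundle@image, file.path(dir, "image.nii.gz"))
  writeVolume(bundle@truthLabels, file.path(dir, "truth_labels.nii.gz"))
  writeVolume(bundle@truthWidth, file.path(dir, "truth_width.nii.gz"))
  writeVolume(bundle@lesionMask, file.path(dir, "lesion_mask.nii.gz"))
  spec <- bundle@spec
  spec$lesion <- if (is.null(spec$lesion)) NULL else lapply(spec$lesion, as.numeric)
  yaml::write_yaml(spec, file.path(dir, "spec.yaml"))
  invisible(dir)
}
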