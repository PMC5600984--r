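# Laplace potential field over the GWB band.
#
# The band is treated as an electric potential field with GM and WM as
# Dirichlet boundaries (psi_GM on GM, psi_WM on WM, fixed); band voxels start
# at psi_GWB and relax by synchronous Jacobi averaging of the six face
# neighbors. Where a neighbor is undefined (CSF/background/volume edge) a
# mirror (zero-flux) condition substitutes the center's own previous value,
# so the potential — and hence the measured width — runs only between GM and
# WM, never toward CSF.

.inFieldArr <- function(labArr) {
  labArr == labelCodes()[["gm"]] | labArr == labelCodes()[["wm"]] |
    labArr == labelCodes()[["gwb"]]
}

#' Initialize the potential field from a label volume
#'
#' GM voxels get `psiGm`, WM voxels `psiWm`, GWB voxels `psiGwb`
#' (`psiGm < psiGwb < psiWm` so every band voxel has a path from GM to WM);
#' CSF and background are excluded from the field (`NA` sentinel).
#'
#' @param labels Label-role [BrainVolume-class] containing at least one GWB
#'   voxel.
#' @param psiGm,psiGwb,psiWm Boundary / initialization constants
#'   (defaults 50 / 100 / 150).
#' @return A [PotentialField-class] (0 sweeps, not converged).
#' @export
initializePotential <- function(labels, psiGm = 50, psiGwb = 100,
                                psiWm = 150) {
  stopifnot(is(labels, "BrainVolume"))
  if (!(psiGm < psiGwb && psiGwb < psiWm)) {
    stop("domain error: constants must satisfy psiGm < psiGwb < psiWm")
  }
  lab <- labels@data
  cd <- labelCodes()
  if (!any(lab == cd[["gwb"]])) {
    stop("empty-region error: label volume contains no GWB voxels")
  }
  psi <- array(NA_real_, dim = dim(lab))
  psi[lab == cd[["gm"]]] <- psiGm
  psi[lab == cd[["wm"]]] <- psiWm
  psi[lab == cd[["gwb"]]] <- psiGwb
  new("PotentialField",
      psi = brainVolume(psi, spacing = labels@spacing, affine = labels@affine,
                        role = "potential"),
      psiGm = psiGm, psiGwb = psiGwb, psiWm = psiWm,
      energyTrace = numeric(0), iterations = 0L, converged = FALSE)
}

# Core synchronous update on raw arrays (returns the new psi array).
.jacobiStep <- function(psi, inField, gwb) {
  acc <- array(0, dim = dim(psi))
  for (axis in 1:3) {
    for (delta in c(-1L, 1L)) {
      nb <- shift3d(psi, axis, delta, fill = NA_real_)
      valid <- shift3d(inField, axis, delta, fill = FALSE)
      nb[!valid | is.na(nb)] <- psi[!valid | is.na(nb)]
      acc <- acc + nb
    }
  }
  out <- psi
  out[gwb] <- acc[gwb] / 6
  out
}

#' One synchronous Jacobi sweep
#'
#' Replaces every GWB voxel by the mean of its six face neighbors' previous
#' values (mirror condition where a neighbor is outside the field); GM and WM
#' values are left untouched. Being synchronous, the result is independent of
#' voxel visitation order.
#'
#' @param field A [PotentialField-class].
#' @param labels The label volume the field was built from.
#' @return Updated [PotentialField-class] (iteration count incremented; the
#'   energy trace is extended by [fieldEnergy()] of the new state).
#' @export
jacobiSweep <- function(field, labels) {
  stopifnot(is(field, "PotentialField"), is(labels, "BrainVolume"))
  lab <- labels@data
  inF <- .inFieldArr(lab)
  gwb <- lab == labelCodes()[["gwb"]]
  psi <- .jacobiStep(field@psi@data, inF, gwb)
  out <- field
  out@psi <- brainVolume(psi, spacing = field@psi@spacing,
                         affine = field@psi@affine, role = "potential")
  out@iterations <- field@iterations + 1L
  out@energyTrace <- c(field@energyTrace, fieldEnergy(out, labels))
  out
}

#' Total field energy over the GWB band
#'
#' Sum over band voxels of the gradient magnitude
#' `sqrt((dpsi/dx)^2 + (dpsi/dy)^2 + (dpsi/dz)^2)`, with central differences
#' `(psi(x+1) - psi(x-1))/2` where both axial neighbors are in the field,
#' one-sided differences where only one is, and 0 where neither is.
#'
#' @param field A [PotentialField-class].
#' @param labels The label volume the field was built from.
#' @return Scalar energy (0 for a constant field).
#' @export
fieldEnergy <- function(field, labels) {
  stopifnot(is(field, "PotentialField"), is(labels, "BrainVolume"))
  lab <- labels@data
  psi <- field@psi@data
  inF <- .inFieldArr(lab)
  gwb <- lab == labelCodes()[["gwb"]]
  if (!any(gwb)) stop("empty-region error: no GWB voxels")
  sq <- array(0, dim = dim(psi))
  for (axis in 1:3) {
    fwd <- shift3d(psi, axis, -1L, fill = NA_real_)   # value at x+1
    bwd <- shift3d(psi, axis, 1L, fill = NA_real_)    # value at x-1
    fOk <- shift3d(inF, axis, -1L, fill = FALSE) & !is.na(fwd)
    bOk <- shift3d(inF, axis, 1L, fill = FALSE) & !is.na(bwd)
    g <- array(0, dim = dim(psi))
    both <- fOk & bOk
    g[both] <- (fwd[both] - bwd[both]) / 2
    fonly <- fOk & !bOk
    g[fonly] <- fwd[fonly] - psi[fonly]
    bonly <- bOk & !fOk
    g[bonly] <- psi[bonly] - bwd[bonly]
    sq <- sq + g^2
  }
  sum(sqrt(sq[gwb]))
}

#' Solve the Laplace equation over the GWB band
#'
#' Repeats synchronous Jacobi sweeps until the absolute relative change of
#' the total field energy falls below `relTol` or `maxIter` sweeps are
#' reached. The relative-change test starts at the second computed energy.
#' At convergence the converged band values obey the discrete maximum
#' principle: strictly inside (`psiGm`, `psiWm`) for every band voxel
#' connected to both boundaries.
#'
#' @inheritParams initializePotential
#' @param relTol Relative energy-change tolerance (default 1e-5).
#' @param maxIter Sweep cap (default 2000).
#' @return A converged [PotentialField-class] with the per-sweep energy trace.
#' @examples
#' lab <- array(0L, c(3, 3, 5))
#' lab[2, 2, ] <- c(2L, 4L, 4L, 4L, 3L)
#' f <- solveLaplace(brainVolume(lab, role = "label"))
#' volData(potential(f))[2, 2, 2:4]   # ~ (75, 100, 125)
#' @export
solveLaplace <- function(labels, psiGm = 50, psiGwb = 100, psiWm = 150,
                         relTol = 1e-5, maxIter = 2000) {
  field <- initializePotential(labels, psiGm, psiGwb, psiWm)
  lab <- labels@data
  inF <- .inFieldArr(lab)
  gwb <- lab == labelCodes()[["gwb"]]
  psi <- field@psi@data
  # the trace starts with the initialized field's energy, so the relative
  # change is first tested at the second computed energy (after one sweep)
  trace <- fieldEnergy(field, labels)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    psi <- .jacobiStep(psi, inF, gwb)
    field@psi@data <- psi
    e <- fieldEnergy(field, labels)
    trace <- c(trace, e)
    n <- length(trace)
    if (trace[n - 1] > 0 &&
        abs(trace[n] - trace[n - 1]) / trace[n - 1] < relTol) {
      converged <- TRUE
      break
    }
  }
  field@psi <- brainVolume(psi, spacing = labels@spacing,
                           affine = labels@affine, role = "potential")
  field@energyTrace <- trace
  field@iterations <- it
  field@converged <- converged
  field
}
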