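# Greedy tracing of the potential field: from each GWB voxel, descend to the
# corresponding GM voxel (minimum-potential neighbor steps) and ascend to the
# corresponding WM voxel (maximum-potential steps); the two endpoints define
# the local GM-to-WM direction, and the boundary width is their world-mm
# separation.

# Single half-trace on raw arrays. direction "gm": strictly decreasing steps,
# stop at a GM-labeled voxel; "wm": strictly increasing, stop at WM.
# Ties among equal-potential neighbors resolve to the lexicographically
# smallest offset (offset rows are pre-sorted; which.min/max picks the first).
# A visited-set guard flags revisits defensively, although the strict
# monotonicity of accepted steps makes a cycle impossible.
.traceHalf <- function(psiArr, labArr, inF, origin, direction, off, maxSteps) {
  d <- dim(psiArr)
  stopLabel <- if (direction == "gm") labelCodes()[["gm"]] else labelCodes()[["wm"]]
  failStatus <- if (direction == "gm") "gm_unreachable" else "wm_unreachable"
  pick <- if (direction == "gm") which.min else which.max
  better <- if (direction == "gm") `<` else `>`

  cur <- as.integer(origin)
  lin <- function(v) v[1] + (v[2] - 1L) * d[1] + (v[3] - 1L) * d[1] * d[2]
  visited <- lin(cur)
  path <- list(cur)
  steps <- 0L
  status <- failStatus
  repeat {
    if (labArr[cur[1], cur[2], cur[3]] == stopLabel) {
      status <- "ok"
      break
    }
    if (steps >= maxSteps) break
    nb <- sweep(off, 2, cur, "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    if (!any(ok)) break
    nb <- nb[ok, , drop = FALSE]
    nlin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    fieldOk <- inF[nlin]
    if (!any(fieldOk)) break
    nb <- nb[fieldOk, , drop = FALSE]
    nlin <- nlin[fieldOk]
    psiN <- psiArr[nlin]
    j <- pick(psiN)
    if (!better(psiN[j], psiArr[cur[1], cur[2], cur[3]])) break  # no strict step
    if (nlin[j] %in% visited) {
      status <- "cycle_detected"
      break
    }
    cur <- nb[j, ]
    visited <- c(visited, nlin[j])
    path[[length(path) + 1L]] <- cur
    steps <- steps + 1L
  }
  list(endpoint = if (status == "ok") cur else NULL,
       path = do.call(rbind, path), status = status, steps = steps)
}

.traceCommon <- function(field, labels, origin, direction, neighborhood,
                         maxSteps) {
  stopifnot(is(field, "PotentialField"), is(labels, "BrainVolume"))
  lab <- labels@data
  origin <- as.integer(origin)
  if (length(origin) != 3L || any(origin < 1L) || any(origin > dim(lab))) {
    stop("index error: origin out of bounds")
  }
  if (lab[origin[1], origin[2], origin[3]] != labelCodes()[["gwb"]]) {
    stop("contract error: origin must be a GWB voxel")
  }
  if (is.null(maxSteps)) maxSteps <- sum(dim(lab))
  off <- nbhdOffsets(neighborhood)
  res <- .traceHalf(field@psi@data, lab, .inFieldArr(lab), origin, direction,
                    off, maxSteps)
  res$psiTrace <- field@psi@data[res$path]
  res
}

#' Trace a GWB voxel to its corresponding GM voxel
#'
#' Starting at a GWB voxel, repeatedly steps to the neighbor with the
#' smallest potential within the search neighborhood (26-connected by
#' default) and stops as soon as a GM-labeled voxel is reached. Only strictly
#' decreasing steps are taken: on a converged harmonic field the discrete
#' maximum principle guarantees such a step exists until the GM boundary, so
#' a stalled trace (status `"gm_unreachable"`) indicates a band voxel not
#' connected to GM.
#'
#' @param field Converged [PotentialField-class].
#' @param labels Label volume the field was solved on.
#' @param origin 1-based index triple of a GWB voxel.
#' @param neighborhood 26 (default) or 6.
#' @param maxSteps Step cap; defaults to `sum(dim)` of the volume.
#' @return List with `endpoint` (index triple or `NULL`), `path` (matrix of
#'   visited voxels, origin first), `psiTrace` (potential along the path,
#'   strictly monotone), `status`, `steps`.
#' @export
traceToGM <- function(field, labels, origin, neighborhood = 26,
                      maxSteps = NULL) {
  .traceCommon(field, labels, origin, "gm", neighborhood, maxSteps)
}

#' Trace a GWB voxel to its corresponding WM voxel
#'
#' Symmetric to [traceToGM()]: strictly increasing maximum-potential steps,
#' stopping at a WM-labeled voxel.
#'
#' @inheritParams traceToGM
#' @return As [traceToGM()], with status `"wm_unreachable"` on a stall.
#' @export
traceToWM <- function(field, labels, origin, neighborhood = 26,
                      maxSteps = NULL) {
  .traceCommon(field, labels, origin, "wm", neighborhood, maxSteps)
}

#' Boundary width from traced endpoints
#'
#' `mode = "endpoint"` (default): the world-mm Euclidean distance between the
#' GM and WM endpoints — the literal mean of the width definition's two
#' terms, which share the same endpoint pair. `mode = "halfpath-mean"`: the
#' mean of the origin-to-GM and origin-to-WM distances, which can fall below
#' one voxel diagonal for a band voxel adjacent to both boundaries.
#'
#' @param origin,gmEndpoint,wmEndpoint 1-based index triples; the two
#'   endpoints must be distinct.
#' @param spacing Voxel spacing (mm), used when `affine` is `NULL`.
#' @param mode `"endpoint"` or `"halfpath-mean"`.
#' @param affine Optional 4x4 voxel-to-world matrix (0-based voxel
#'   convention); overrides `spacing`.
#' @return Width in mm (> 0).
#' @examples
#' widthAt(c(1, 1, 2), c(1, 1, 1), c(1, 1, 3))                    # 2
#' widthAt(c(1, 1, 2), c(1, 1, 1), c(1, 1, 3), mode = "halfpath-mean")  # 1
#' @export
widthAt <- function(origin, gmEndpoint, wmEndpoint, spacing = c(1, 1, 1),
                    mode = c("endpoint", "halfpath-mean"), affine = NULL) {
  mode <- match.arg(mode)
  if (all(gmEndpoint == wmEndpoint)) {
    stop("degenerate-geometry error: coincident endpoints")
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  w <- function(idx) as.numeric((c(idx - 1, 1) %*% t(affine))[1:3])
  if (mode == "endpoint") {
    sqrt(sum((w(gmEndpoint) - w(wmEndpoint))^2))
  } else {
    (sqrt(sum((w(origin) - w(gmEndpoint))^2)) +
       sqrt(sum((w(origin) - w(wmEndpoint))^2))) / 2
  }
}

#' Compute the GWB width map
#'
#' Traces every GWB voxel to its GM and WM endpoints over the converged
#' potential field and fills the width map (mm) where both traces succeed;
#' elsewhere the width is 0 and the failure is recorded in the status map
#' (per-voxel failures never abort the run). Distances are taken in world
#' coordinates, honoring anisotropic spacing.
#'
#' @inheritParams traceToGM
#' @param mode Width convention, see [widthAt()].
#' @return A [WidthMap-class]; its `stats` summarize all measured widths.
#' @export
computeWidthMap <- function(field, labels, neighborhood = 26,
                            mode = c("endpoint", "halfpath-mean"),
                            maxSteps = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(field, "PotentialField"), is(labels, "BrainVolume"))
  lab <- labels@data
  d <- dim(lab)
  if (is.null(maxSteps)) maxSteps <- sum(d)
  off <- nbhdOffsets(neighborhood)
  psiArr <- field@psi@data
  inF <- .inFieldArr(lab)
  aff <- labels@affine

  width <- array(0, dim = d)
  status <- array(0L, dim = d)
  gwbIdx <- which(lab == labelCodes()[["gwb"]], arr.ind = TRUE)
  sc <- statusCodes()
  if (nrow(gwbIdx) > 0) {
    for (r in seq_len(nrow(gwbIdx))) {
      v <- gwbIdx[r, ]
      gm <- .traceHalf(psiArr, lab, inF, v, "gm", off, maxSteps)
      if (gm$status != "ok") {
        status[v[1], v[2], v[3]] <- sc[[gm$status]]
        next
      }
      wm <- .traceHalf(psiArr, lab, inF, v, "wm", off, maxSteps)
      if (wm$status != "ok") {
        status[v[1], v[2], v[3]] <- sc[[wm$status]]
        next
      }
      status[v[1], v[2], v[3]] <- sc[["ok"]]
      width[v[1], v[2], v[3]] <- widthAt(v, gm$endpoint, wm$endpoint,
                                         mode = mode, affine = aff)
    }
  }
  wvol <- brainVolume(width, spacing = labels@spacing, affine = aff,
                      role = "width")
  # status codes share the 0..4 range of the label code table, so the volume
  # rides on the label role (written as uint8)
  svol <- brainVolume(status, spacing = labels@spacing, affine = aff,
                      role = "label")
  stats <- tryCatch(.widthSummary(width[width > 0]),
                    error = function(e) list(mean = NA_real_, sd = NA_real_,
                                             max = NA_real_, min = NA_real_,
                                             mode = NA_real_, n = 0L))
  new("WidthMap", width = wvol, statusMap = svol, stats = stats)
}

.widthSummary <- function(w) {
  if (!length(w)) stop("empty-region error: no positive widths")
  rounded <- round(w, 2)
  tab <- table(rounded)
  modeVal <- as.numeric(names(tab)[which.max(tab)])
  list(mean = mean(w), sd = stats::sd(w), max = max(w), min = min(w),
       mode = modeVal, n = length(w))
}

#' Width statistics over a region
#'
#' Mean, SD, max, min and mode (values rounded to 0.01 mm) over the strictly
#' positive widths inside the region mask; voxels outside the region are
#' ignored.
#'
#' @param widthMap A [WidthMap-class].
#' @param region Mask-role [BrainVolume-class] or logical/0-1 array of the
#'   same shape; `NULL` means the whole volume.
#' @return List with mean, sd, max, min, mode, n.
#' @export
regionStats <- function(widthMap, region = NULL) {
  stopifnot(is(widthMap, "WidthMap"))
  w <- widthMap@width@data
  m <- asMaskArray(region, dim(w))
  vals <- w[m & w > 0]
  if (!length(vals)) {
    stop("empty-region error: region contains no positive widths")
  }
  .widthSummary(vals)
}
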