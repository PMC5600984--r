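# Internal helpers shared across modules.

# Shift a 3D array by `delta` voxels along `axis`, filling vacated entries
# with `fill`. shift3d(a, 1, +1)[i,j,k] == a[i-1,j,k].
shift3d <- function(a, axis, delta, fill = NA) {
  d <- dim(a)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (abs(delta) >= n) return(out)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  if (delta > 0) {
    dst[[axis]] <- (delta + 1L):n
    src[[axis]] <- 1L:(n - delta)
  } else if (delta < 0) {
    dst[[axis]] <- 1L:(n + delta)
    src[[axis]] <- (1L - delta):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Evaluate expr with a local RNG state seeded by `seed`; the caller's RNG
# stream is untouched.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' World coordinates of voxel indices
#'
#' Maps 1-based voxel index triples to world mm through the volume's affine
#' (NIfTI convention: the affine acts on 0-based indices).
#'
#' @param vol A [BrainVolume-class].
#' @param idx Integer vector of length 3, or an n x 3 matrix of index triples.
#' @return An n x 3 matrix of world coordinates (mm).
#' @export
worldCoords <- function(vol, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  h <- cbind(idx - 1, 1)
  w <- h %*% t(vol@affine)
  w[, 1:3, drop = FALSE]
}

# 26- or 6-neighborhood offsets, ordered by offset magnitude (face before
# edge before corner), then lexicographically, so which.min/which.max
# tie-breaks among equal-potential neighbors prefer the shortest step and are
# fully deterministic. Magnitude-first ordering keeps descent axis-aligned on
# planar (tied) potential fields, where a purely lexicographic rule would
# drift diagonally and systematically overestimate widths.
nbhdOffsets <- function(neighborhood = 26) {
  if (neighborhood == 6) {
    off <- rbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1),
                 c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  } else if (neighborhood == 26) {
    g <- as.matrix(expand.grid(dk = -1:1, dj = -1:1, di = -1:1))
    off <- g[, c("di", "dj", "dk")]
    off <- off[order(rowSums(off^2), off[, 1], off[, 2], off[, 3]), ,
               drop = FALSE]
    off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  } else {
    stop("neighborhood must be 6 or 26")
  }
  dimnames(off) <- NULL
  storage.mode(off) <- "integer"
  off
}

# Geometry agreement between two volumes.
checkSameGeometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a@data), dim(b@data))) {
    stop(sprintf("geometry error: %s have different shapes (%s vs %s)", what,
                 paste(dim(a@data), collapse = "x"),
                 paste(dim(b@data), collapse = "x")))
  }
  if (max(abs(a@spacing - b@spacing)) > 1e-6) {
    stop(sprintf("geometry error: %s have different spacing", what))
  }
  invisible(TRUE)
}

# Coerce a mask argument (BrainVolume, array, or NULL -> all TRUE) to logical.
asMaskArray <- function(mask, dims) {
  if (is.null(mask)) return(array(TRUE, dim = dims))
  m <- if (is(mask, "BrainVolume")) mask@data else mask
  if (!identical(dim(m), dims)) {
    stop("geometry error: mask shape does not match volume")
  }
  array(as.logical(m != 0), dim = dims)
}
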