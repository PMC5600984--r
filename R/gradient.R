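#' Local gradient-magnitude feature map
#'
#' The classical comparator feature for the blurred gray/white junction: the
#' magnitude of the first-order intensity derivative estimated within a
#' local window (5 x 5 x 5 by default), per mm. A *blurred* junction has a
#' gradual intensity ramp and therefore a *small* gradient, so the feature's
#' polarity is `low_is_positive`, and voxels with values below 5 are treated
#' as background and excluded from evaluations.
#'
#' The default estimator is an unweighted least-squares plane fit of the
#' intensities over the window (separable centered-moment filter), chosen
#' for isotropy and noise robustness; `estimator = "central"` gives plain
#' central differences. Near the volume edge the largest centered window
#' that fits is used (minimum 3); face voxels fall back to one-sided
#' differences.
#'
#' @param y Intensity-role [BrainVolume-class].
#' @param window Odd window size >= 3 and no larger than any image dimension.
#' @param estimator `"ls"` (least-squares plane fit, default) or
#'   `"central"`.
#' @return A [FeatureMap-class] (`polarity = "low_is_positive"`,
#'   `backgroundRule = 5`).
#' @examples
#' ramp <- brainVolume(array(rep(3 * (0:8), each = 81), c(9, 9, 9)))
#' g <- gradientMap(ramp)
#' volData(g@data)[5, 5, 5]   # 3 (per mm, along the third axis)
#' @export
gradientMap <- function(y, window = 5, estimator = c("ls", "central")) {
  estimator <- match.arg(estimator)
  stopifnot(is(y, "BrainVolume"))
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  d <- dim(y@data)
  if (any(window > d)) {
    stop("geometry error: window larger than an image dimension")
  }
  h <- (window - 1L) %/% 2L
  if (estimator == "central") h <- 1L

  meanLine <- function(v, hmax) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      hi <- min(hmax, i - 1L, n - i)
      out[i] <- mean(v[(i - hi):(i + hi)])
    }
    out
  }
  derivLine <- function(v, hmax) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      hi <- min(hmax, i - 1L, n - i)
      if (hi >= 1L) {
        dd <- -hi:hi
        out[i] <- sum(dd * v[(i - hi):(i + hi)]) / sum(dd^2)
      } else if (i == 1L) {
        out[i] <- v[2L] - v[1L]
      } else {
        out[i] <- v[n] - v[n - 1L]
      }
    }
    out
  }
  alongAxis <- function(a, axis, f) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    m <- apply(m, 2, f)
    aperm(array(m, dim = dp), order(perm))
  }

  sq <- array(0, dim = d)
  for (axis in 1:3) {
    g <- y@data
    if (estimator == "ls" && h >= 1L) {
      for (other in setdiff(1:3, axis)) {
        g <- alongAxis(g, other, function(v) meanLine(v, h))
      }
    }
    g <- alongAxis(g, axis, function(v) derivLine(v, h))
    sq <- sq + (g / y@spacing[axis])^2
  }
  featureMap(brainVolume(sqrt(sq), spacing = y@spacing, affine = y@affine,
                         role = "intensity"),
             featureName = "gradient_magnitude",
             polarity = "low_is_positive", backgroundRule = 5)
}

#' Wrap a width map as a detection feature
#'
#' @param widthMap A [WidthMap-class].
#' @return A [FeatureMap-class] with `polarity = "high_is_positive"` (a wide
#'   boundary flags a blurred junction) and no background rule.
#' @export
widthFeature <- function(widthMap) {
  stopifnot(is(widthMap, "WidthMap"))
  v <- widthMap@width
  featureMap(brainVolume(v@data, spacing = v@spacing, affine = v@affine,
                         role = "intensity"),
             featureName = "gwb_width", polarity = "high_is_positive")
}
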