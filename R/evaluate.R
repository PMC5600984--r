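# Voxelwise evaluation of feature maps against a lesion ground-truth mask:
# confusion counts at a threshold, full threshold sweeps (ROC / PR / F),
# and the best-F operating point.

.featureValues <- function(feature) {
  stopifnot(is(feature, "FeatureMap"))
  feature@data@data
}

#' Confusion counts at one threshold
#'
#' Positivity follows the feature's polarity: value strictly greater than `t`
#' for `high_is_positive` features (width map), strictly less than `t` for
#' `low_is_positive` ones (gradient map). When the feature carries a
#' background rule, voxels with values below it are excluded from all four
#' counts. Counts are restricted to `evalMask`.
#'
#' @param feature A [FeatureMap-class].
#' @param truth Binary lesion mask ([BrainVolume-class] or array) of the same
#'   shape.
#' @param t Threshold.
#' @param evalMask Evaluation mask (`NULL` = whole volume).
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusionAt <- function(feature, truth, t, evalMask = NULL) {
  v <- .featureValues(feature)
  tr <- if (is(truth, "BrainVolume")) truth@data else truth
  if (!identical(dim(tr), dim(v))) {
    stop("geometry error: truth shape does not match feature")
  }
  m <- asMaskArray(evalMask, dim(v))
  if (!any(m)) stop("contract error: empty evaluation mask")
  if (!is.na(feature@backgroundRule)) {
    m <- m & v >= feature@backgroundRule
  }
  pos <- if (feature@polarity == "high_is_positive") v > t else v < t
  tr <- tr != 0
  c(tp = sum(m & pos & tr), tn = sum(m & !pos & !tr),
    fp = sum(m & pos & !tr), fn = sum(m & !pos & tr))
}

#' Threshold sweep: ROC, precision/recall and F-score
#'
#' Thresholds are `nThresholds` evenly spaced values spanning the included
#' in-mask feature range. Conventions for empty denominators:
#' precision = 0 when tp + fp = 0, recall = tp/(tp + fn), and
#' F = 2PR/(P + R) = 0 when P + R = 0.
#'
#' @inheritParams confusionAt
#' @param nThresholds Number of thresholds (>= 2; default 256).
#' @return An [EvalCurve-class].
#' @export
thresholdSweep <- function(feature, truth, evalMask = NULL,
                           nThresholds = 256) {
  if (nThresholds < 2) stop("contract error: nThresholds must be >= 2")
  v <- .featureValues(feature)
  m <- asMaskArray(evalMask, dim(v))
  if (!any(m)) stop("contract error: empty evaluation mask")
  mIncl <- m
  if (!is.na(feature@backgroundRule)) mIncl <- m & v >= feature@backgroundRule
  vals <- v[mIncl]
  if (!length(vals)) stop("contract error: background rule excludes every voxel")
  ts <- seq(min(vals), max(vals), length.out = nThresholds)
  counts <- t(vapply(ts, function(t) confusionAt(feature, truth, t, m),
                     integer(4)))
  tp <- counts[, "tp"]; tn <- counts[, "tn"]
  fp <- counts[, "fp"]; fn <- counts[, "fn"]
  tpr <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  fpr <- ifelse(fp + tn > 0, fp / (fp + tn), 0)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- tpr
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  new("EvalCurve",
      curve = data.frame(threshold = ts, tp = tp, tn = tn, fp = fp, fn = fn,
                         tpr = tpr, fpr = fpr, precision = prec, recall = rec,
                         f_score = f),
      polarity = feature@polarity, nEval = as.integer(sum(mIncl)))
}

#' Best F-score operating point
#'
#' @param curve An [EvalCurve-class].
#' @return Named numeric `c(threshold, f_score)`; ties resolve to the
#'   smallest threshold.
#' @export
bestFScore <- function(curve) {
  stopifnot(is(curve, "EvalCurve"))
  cv <- curve@curve
  if (!nrow(cv)) stop("contract error: empty curve")
  i <- which.max(cv$f_score)
  c(threshold = cv$threshold[i], f_score = cv$f_score[i])
}

#' Randomly select axial slices containing lesion
#'
#' Evaluation helper mirroring slice-restricted F-score computation: returns
#' a mask covering `nSlices` randomly chosen slices (along `axis`) that
#' intersect the lesion mask.
#'
#' @param truth Binary lesion mask volume.
#' @param nSlices Number of slices to keep (capped at the number of lesion
#'   slices).
#' @param seed Integer seed.
#' @param axis Slice axis (default 3, axial).
#' @return Mask-role [BrainVolume-class].
#' @export
selectLesionSlices <- function(truth, nSlices, seed = 1, axis = 3) {
  tr <- if (is(truth, "BrainVolume")) truth@data else truth
  hasLesion <- which(apply(tr != 0, axis, any))
  if (!length(hasLesion)) stop("empty-region error: no lesion slices")
  keep <- withSeed(seed, sample(hasLesion, min(nSlices, length(hasLesion))))
  m <- array(0L, dim = dim(tr))
  idx <- list(seq_len(dim(tr)[1]), seq_len(dim(tr)[2]), seq_len(dim(tr)[3]))
  idx[[axis]] <- keep
  m[idx[[1]], idx[[2]], idx[[3]]] <- 1L
  sp <- if (is(truth, "BrainVolume")) truth@spacing else c(1, 1, 1)
  brainVolume(m, spacing = sp, role = "mask")
}

#' Write an evaluation curve to CSV
#'
#' @param curve An [EvalCurve-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path) {
  utils::write.csv(curve@curve, path, row.names = FALSE)
  invisible(path)
}
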