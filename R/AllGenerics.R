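#' @name accessors
#' @title Accessors for package containers
#' @description Slot accessors: use these rather than `@`.
#' @param x Object.
#' @return The corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))
#' @rdname accessors
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))
#' @rdname accessors
#' @export
setGeneric("volRole", function(x) standardGeneric("volRole"))

#' @rdname accessors
#' @export
setMethod("volData", "BrainVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("volSpacing", "BrainVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("volAffine", "BrainVolume", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("volRole", "BrainVolume", function(x) x@role)

#' @export
setMethod("dim", "BrainVolume", function(x) dim(x@data))

setMethod("show", "BrainVolume", function(object) {
  cat(sprintf("BrainVolume [%s] %s, spacing %s mm, range [%g, %g]\n",
              object@role, paste(dim(object@data), collapse = " x "),
              paste(signif(object@spacing, 4), collapse = " x "),
              suppressWarnings(min(object@data, na.rm = TRUE)),
              suppressWarnings(max(object@data, na.rm = TRUE))))
})

#' @rdname accessors
#' @export
setGeneric("tissueMeans", function(x) standardGeneric("tissueMeans"))
#' @rdname accessors
#' @export
setGeneric("tissueSds", function(x) standardGeneric("tissueSds"))
#' @rdname accessors
#' @export
setGeneric("mrfBeta", function(x) standardGeneric("mrfBeta"))

#' @rdname accessors
#' @export
setMethod("tissueMeans", "TissueModel", function(x) x@mu)
#' @rdname accessors
#' @export
setMethod("tissueSds", "TissueModel", function(x) x@sigma)
#' @rdname accessors
#' @export
setMethod("mrfBeta", "TissueModel", function(x) x@beta)

setMethod("show", "TissueModel", function(object) {
  cat("TissueModel (Gaussian per class, Potts pairwise weight)\n")
  print(rbind(mu = object@mu, sigma = object@sigma))
  cat(sprintf("beta = %g; %d recorded iterations\n",
              object@beta, length(object@history)))
})

#' @rdname accessors
#' @export
setGeneric("segLabels", function(x) standardGeneric("segLabels"))
#' @rdname accessors
#' @export
setGeneric("tissueProb", function(x, tissue) standardGeneric("tissueProb"))
#' @rdname accessors
#' @export
setGeneric("tissueModelOf", function(x) standardGeneric("tissueModelOf"))

#' @rdname accessors
#' @export
setMethod("segLabels", "SegmentationResult", function(x) x@labels)
#' @rdname accessors
#' @param tissue One of "csf", "gm", "wm".
#' @export
setMethod("tissueProb", "SegmentationResult", function(x, tissue) {
  switch(match.arg(tissue, c("csf", "gm", "wm")),
         csf = x@pCsf, gm = x@pGm, wm = x@pWm)
})
#' @rdname accessors
#' @export
setMethod("tissueModelOf", "SegmentationResult", function(x) x@model)

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %s, %d EM iterations (%s)\n",
              paste(dim(object@labels@data), collapse = " x "),
              object@emIterations,
              if (object@converged) "converged" else "not converged"))
  show(object@model)
})

#' @rdname accessors
#' @export
setGeneric("potential", function(x) standardGeneric("potential"))
#' @rdname accessors
#' @export
setGeneric("energyTrace", function(x) standardGeneric("energyTrace"))

#' @rdname accessors
#' @export
setMethod("potential", "PotentialField", function(x) x@psi)
#' @rdname accessors
#' @export
setMethod("energyTrace", "PotentialField", function(x) x@energyTrace)

setMethod("show", "PotentialField", function(object) {
  cat(sprintf(
    "PotentialField: psi (GM/GWB/WM) = %g/%g/%g, %d sweeps (%s)\n",
    object@psiGm, object@psiGwb, object@psiWm, object@iterations,
    if (object@converged) "converged" else "not converged"))
})

#' @rdname accessors
#' @export
setGeneric("widthVolume", function(x) standardGeneric("widthVolume"))
#' @rdname accessors
#' @export
setGeneric("statusVolume", function(x) standardGeneric("statusVolume"))
#' @rdname accessors
#' @export
setGeneric("widthStats", function(x) standardGeneric("widthStats"))

#' @rdname accessors
#' @export
setMethod("widthVolume", "WidthMap", function(x) x@width)
#' @rdname accessors
#' @export
setMethod("statusVolume", "WidthMap", function(x) x@statusMap)
#' @rdname accessors
#' @export
setMethod("widthStats", "WidthMap", function(x) x@stats)

setMethod("show", "WidthMap", function(object) {
  s <- object@stats
  if (length(s) && is.finite(s$mean)) {
    cat(sprintf(
      "WidthMap: %d measured GWB voxels; mean %.2f mm (sd %.2f), range [%.2f, %.2f], mode %.2f\n",
      s$n, s$mean, s$sd, s$min, s$max, s$mode))
  } else {
    cat("WidthMap: no measured GWB voxels\n")
  }
})

#' @rdname accessors
#' @export
setGeneric("curveData", function(x) standardGeneric("curveData"))
#' @rdname accessors
#' @export
setMethod("curveData", "EvalCurve", function(x) x@curve)

setMethod("show", "EvalCurve", function(object) {
  cat(sprintf("EvalCurve: %d thresholds over %d voxels (%s); max F = %.3f\n",
              nrow(object@curve), object@nEval, object@polarity,
              max(object@curve$f_score)))
})

setMethod("show", "FeatureMap", function(object) {
  cat(sprintf("FeatureMap '%s' (%s%s)\n", object@featureName, object@polarity,
              if (is.na(object@backgroundRule)) ""
              else sprintf(", background < %g excluded", object@backgroundRule)))
  show(object@data)
})

setMethod("show", "PhantomBundle", function(object) {
  cat(sprintf("PhantomBundle (%s): %s, band thickness %g mm%s\n",
              object@spec$geometry,
              paste(dim(object@image@data), collapse = " x "),
              object@spec$gwbThicknessMm,
              if (isTRUE(object@spec$hasLesion))
                sprintf(", lesion x%g", object@spec$lesion$multiplier) else ""))
})
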