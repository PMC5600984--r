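# Hidden Markov random field EM segmentation of CSF/GM/WM.
#
# Model: per-voxel Gaussian class likelihoods G(y; mu_l, sigma_l) combined
# with a Potts prior over 6-connected neighbor pairs (clique potential
# 0.5*beta for a discordant pair). MAP labels are estimated by sequential
# raster-order ICM; (mu_l, sigma_l) are re-estimated from posterior-weighted
# moments; per-tissue posterior probabilities are the per-voxel normalization
# of likelihood x local Gibbs prior across the three classes.

.tissueSet <- c(csf = 1L, gm = 2L, wm = 3L)

.asTissueLabel <- function(x) {
  if (is.character(x)) x <- .tissueSet[match(x, names(.tissueSet))]
  x <- suppressWarnings(as.integer(x))
  if (any(is.na(x)) || any(!x %in% .tissueSet)) {
    stop("domain error: label must be CSF (1), GM (2) or WM (3)")
  }
  x
}

#' Potts clique potential for a neighbor pair
#'
#' `0` for concordant labels, `0.5 * beta` for discordant labels.
#'
#' @param labelA,labelB Tissue labels: 1/2/3 or "csf"/"gm"/"wm" (vectorized).
#' @param beta Non-negative pairwise weight.
#' @return Numeric clique potential(s).
#' @examples
#' cliquePotential("gm", "gm")   # 0
#' cliquePotential("gm", "wm")   # 0.5
#' @export
cliquePotential <- function(labelA, labelB, beta = 1) {
  a <- .asTissueLabel(labelA); b <- .asTissueLabel(labelB)
  if (beta < 0) stop("domain error: beta must be >= 0")
  ifelse(a == b, 0, 0.5 * beta)
}

#' Normalized local Gibbs prior at one voxel
#'
#' `exp(-sum_q V_c(candidate, labels(q)))` over the 6-neighborhood, normalized
#' so the three candidate priors sum to 1. Neighbors outside the volume or not
#' carrying a tissue label (background/GWB) do not contribute; with no valid
#' neighbor the prior is uniform (1/3).
#'
#' @param labels Label-role [BrainVolume-class] or integer array.
#' @param voxel 1-based index triple.
#' @param candidate Tissue label (1/2/3 or name).
#' @param beta Pairwise weight.
#' @return The normalized prior probability of `candidate` at `voxel`.
#' @export
localPrior <- function(labels, voxel, candidate, beta = 1) {
  lab <- if (is(labels, "BrainVolume")) labels@data else labels
  d <- dim(lab)
  if (any(voxel < 1) || any(voxel > d)) stop("index error: voxel out of bounds")
  cand <- .asTissueLabel(candidate)
  off <- nbhdOffsets(6)
  nb <- sweep(off, 2, as.integer(voxel), "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  nbl <- lab[nb[ok, , drop = FALSE]]
  nbl <- nbl[nbl %in% .tissueSet]
  u <- vapply(.tissueSet, function(l) sum(0.5 * beta * (nbl != l)), numeric(1))
  pr <- exp(-(u - min(u)))
  pr <- pr / sum(pr)
  unname(pr[cand])
}

#' Initialize the tissue model by k-means
#'
#' k-means on the in-mask intensities; components are sorted by ascending
#' mean and assigned CSF/GM/WM in that order (T1 ordering). Deterministic
#' given `seed`.
#'
#' @param y Intensity-role [BrainVolume-class].
#' @param mask Brain mask ([BrainVolume-class], array, or `NULL` for all
#'   voxels); must select at least `10 * k` voxels.
#' @param k Number of classes (3).
#' @param seed Integer seed.
#' @param beta Pairwise weight stored in the model.
#' @return A [TissueModel-class].
#' @export
initializeModel <- function(y, mask = NULL, k = 3, seed = 1, beta = 1) {
  stopifnot(is(y, "BrainVolume"))
  m <- asMaskArray(mask, dim(y@data))
  vals <- y@data[m]
  if (length(vals) < 10 * k) {
    stop("initialization error: mask selects fewer than 10*k voxels")
  }
  if (length(unique(vals)) < k) {
    stop("initialization error: fewer distinct intensities than classes")
  }
  km <- withSeed(seed, stats::kmeans(vals, centers = k, nstart = 5, iter.max = 100))
  ord <- order(km$centers)
  mu <- as.numeric(km$centers[ord])
  sigma <- vapply(ord, function(cl) stats::sd(vals[km$cluster == cl]), numeric(1))
  sigma[!is.finite(sigma) | sigma <= 0] <- max(diff(range(vals)) / 100, 1e-6)
  # guarantee strictly increasing means even for near-degenerate clusters
  eps <- max(diff(range(vals)), 1) * 1e-9
  mu <- mu + seq_len(k) * eps
  tissueModel(mu, sigma, beta = beta)
}

# Per-label count of discordant labeled 6-neighbors, as the Gibbs energy
# U_l(v) = 0.5 * beta * #{q in N6(v): labels(q) in L, labels(q) != l}.
.gibbsEnergies <- function(labArr, beta) {
  d <- dim(labArr)
  nLab <- array(0, d)
  cnt <- list(array(0, d), array(0, d), array(0, d))
  for (axis in 1:3) {
    for (delta in c(-1L, 1L)) {
      sh <- shift3d(labArr, axis, delta, fill = 0L)
      nLab <- nLab + (sh > 0L)
      for (l in 1:3) cnt[[l]] <- cnt[[l]] + (sh == l)
    }
  }
  lapply(1:3, function(l) 0.5 * beta * (nLab - cnt[[l]]))
}

# Posterior probabilities p_l(v) normalized over the three labels:
# p_l ∝ G(y; theta_l) * exp(-U_l(v)). Zero outside the mask.
.posteriors <- function(yArr, labArr, maskArr, mu, sigma, beta) {
  U <- .gibbsEnergies(labArr, beta)
  lp <- lapply(1:3, function(l) {
    stats::dnorm(yArr, mu[l], sigma[l], log = TRUE) - U[[l]]
  })
  mx <- pmax(lp[[1]], lp[[2]], lp[[3]])
  e <- lapply(lp, function(x) exp(x - mx))
  z <- e[[1]] + e[[2]] + e[[3]]
  lapply(e, function(x) {
    p <- x / z
    p[!maskArr] <- 0
    p
  })
}

# Total posterior energy: Gaussian negative log-likelihood over in-mask
# voxels plus the Potts energy over unordered in-mask neighbor pairs.
# Used to assert that sequential ICM sweeps never increase the energy.
mrfEnergy <- function(yArr, labArr, maskArr, mu, sigma, beta) {
  idx <- which(maskArr & labArr > 0L)
  l <- labArr[idx]
  lik <- log(sigma[l]) + (yArr[idx] - mu[l])^2 / (2 * sigma[l]^2)
  pair <- 0
  for (axis in 1:3) {
    sh <- shift3d(labArr, axis, 1L, fill = 0L)
    both <- labArr > 0L & sh > 0L
    pair <- pair + sum(0.5 * beta * (labArr[both] != sh[both]))
  }
  sum(lik) + pair
}

#' One sequential ICM sweep of the MAP labeling
#'
#' Visits every in-mask voxel in raster order and assigns the label
#' maximizing Gaussian likelihood times the local Gibbs prior, reading
#' already-updated neighbors (so the total posterior energy never increases).
#' With `beta = 0` this reduces to per-voxel Gaussian classification.
#'
#' @param y Intensity-role [BrainVolume-class].
#' @param labels Label-role [BrainVolume-class] (1/2/3 in mask, 0 outside).
#' @param model A [TissueModel-class].
#' @param mask Brain mask, or `NULL` for all voxels.
#' @return Updated label-role [BrainVolume-class].
#' @export
icmUpdate <- function(y, labels, model, mask = NULL) {
  stopifnot(is(y, "BrainVolume"), is(labels, "BrainVolume"),
            is(model, "TissueModel"))
  m <- asMaskArray(mask, dim(y@data))
  lab <- icm_sweep_cpp(as.double(y@data), as.integer(labels@data),
                       as.logical(m), dim(y@data),
                       as.double(model@mu), as.double(model@sigma),
                       model@beta)
  brainVolume(array(lab, dim = dim(y@data)), spacing = y@spacing,
              affine = y@affine, role = "label")
}

#' Fit the hidden-MRF EM segmentation
#'
#' Alternates MAP label estimation (sequential ICM sweeps) with
#' posterior-weighted M-step updates of the class means and standard
#' deviations, stopping when the largest absolute parameter change drops
#' below `tol` or after `maxEmIter` iterations. Class order CSF < GM < WM is
#' enforced by sorting after every M-step. Deterministic given `seed`.
#'
#' @param y Intensity-role [BrainVolume-class].
#' @param mask Brain mask; voxels outside carry zero probability for every
#'   tissue and never enter parameter updates. `NULL` means all voxels.
#' @param beta Potts pairwise weight (default 1).
#' @param maxEmIter,maxIcmIter Iteration caps (EM outer loop; ICM sweeps per
#'   EM iteration).
#' @param tol Convergence tolerance on the max absolute change over all
#'   (mu_l, sigma_l).
#' @param seed Seed for the k-means initialization.
#' @return A [SegmentationResult-class].
#' @examples
#' ph <- slabPhantom(shape = c(12, 12, 20), gwbThicknessMm = 2, seed = 2)
#' seg <- emFit(ph@image, maxEmIter = 3)
#' tissueMeans(tissueModelOf(seg))
#' @export
emFit <- function(y, mask = NULL, beta = 1, maxEmIter = 30, maxIcmIter = 10,
                  tol = 1e-4, seed = 1) {
  stopifnot(is(y, "BrainVolume"))
  if (tol <= 0) stop("contract error: tol must be > 0")
  m <- asMaskArray(mask, dim(y@data))
  if (!any(m)) stop("contract error: empty mask")
  yArr <- y@data
  model <- initializeModel(y, m, k = 3, seed = seed, beta = beta)
  mu <- model@mu; sigma <- model@sigma

  # initial labels: per-voxel Gaussian classification
  classify <- function(mu, sigma) {
    ll <- vapply(1:3, function(l) stats::dnorm(as.vector(yArr), mu[l], sigma[l],
                                               log = TRUE),
                 numeric(length(yArr)))
    lab <- array(max.col(ll, ties.method = "first"), dim = dim(yArr))
    lab[!m] <- 0L
    storage.mode(lab) <- "integer"
    lab
  }
  labArr <- classify(mu, sigma)

  runIcm <- function(labArr, mu, sigma) {
    for (s in seq_len(maxIcmIter)) {
      new <- icm_sweep_cpp(as.double(yArr), labArr, as.logical(m),
                           dim(yArr), mu, sigma, beta)
      new <- array(new, dim = dim(yArr)); storage.mode(new) <- "integer"
      if (identical(new, labArr)) break
      labArr <- new
    }
    labArr
  }

  history <- list()
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(maxEmIter)) {
    iter <- t
    labArr <- runIcm(labArr, mu, sigma)
    post <- .posteriors(yArr, labArr, m, mu, sigma, beta)
    muNew <- numeric(3); sigNew <- numeric(3)
    for (l in 1:3) {
      w <- post[[l]][m]
      sw <- sum(w)
      if (sw < 1e-8) {
        stop(sprintf("degenerate-class error: label %s lost all posterior mass",
                     names(.tissueSet)[l]))
      }
      muNew[l] <- sum(w * yArr[m]) / sw
      sigNew[l] <- sqrt(sum(w * (yArr[m] - muNew[l])^2) / sw)
      if (sigNew[l] <= 0) sigNew[l] <- .Machine$double.eps^0.25
    }
    ord <- order(muNew)
    if (!identical(ord, 1:3)) {
      muNew <- muNew[ord]; sigNew <- sigNew[ord]
      remap <- match(1:3, ord)
      labArr <- array(c(0L, remap)[labArr + 1L], dim = dim(yArr))
      storage.mode(labArr) <- "integer"
    }
    delta <- max(abs(c(muNew - mu, sigNew - sigma)))
    mu <- muNew; sigma <- sigNew
    history[[t]] <- list(mu = mu, sigma = sigma, delta = delta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  labArr <- runIcm(labArr, mu, sigma)
  post <- .posteriors(yArr, labArr, m, mu, sigma, beta)

  mkVol <- function(a, role) brainVolume(a, spacing = y@spacing,
                                         affine = y@affine, role = role)
  finalLab <- labArr
  finalLab[!m] <- 0L
  new("SegmentationResult",
      labels = mkVol(finalLab, "label"),
      pCsf = mkVol(pmin(pmax(post[[1]], 0), 1), "probability"),
      pGm = mkVol(pmin(pmax(post[[2]], 0), 1), "probability"),
      pWm = mkVol(pmin(pmax(post[[3]], 0), 1), "probability"),
      model = tissueModel(mu, sigma, beta = beta, history = history),
      emIterations = iter, converged = converged)
}
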