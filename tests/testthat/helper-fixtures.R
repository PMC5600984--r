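# Fixtures and independent oracles, built in code at test time.

# 3x3x(n+2) volume with a single in-field column: GM cap, n GWB voxels, WM cap.
columnLabels <- function(n = 3) {
  lab <- array(0L, c(3, 3, n + 2))
  lab[2, 2, ] <- c(2L, rep(4L, n), 3L)
  brainVolume(lab, role = "label")
}

# Full-plane slab labels: GM below, `bandLayers` GWB layers, WM above.
slabLabels <- function(nx = 8, ny = 8, bandLayers = 3, gmLayers = 3,
                       wmLayers = 3, spacing = c(1, 1, 1)) {
  nz <- gmLayers + bandLayers + wmLayers
  lab <- array(0L, c(nx, ny, nz))
  lab[, , seq_len(gmLayers)] <- 2L
  lab[, , gmLayers + seq_len(bandLayers)] <- 4L
  lab[, , gmLayers + bandLayers + seq_len(wmLayers)] <- 3L
  brainVolume(lab, spacing = spacing, role = "label")
}

# Random label volume over {background, CSF, GM, WM, GWB} with >= 1 GWB voxel.
randomLabels <- function(dims = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  repeat {
    lab <- array(sample(0:4, prod(dims), replace = TRUE,
                        prob = c(0.1, 0.1, 0.25, 0.25, 0.3)), dim = dims)
    storage.mode(lab) <- "integer"
    if (any(lab == 4L)) break
  }
  brainVolume(lab, role = "label")
}

# Independent direct linear solve of the Jacobi fixed point: for every GWB
# voxel in a boundary-connected component, 6 psi_v = sum over face neighbors
# of (in-field neighbor value, or psi_v itself when the neighbor is outside
# the field). GWB components not connected to GM/WM stay at the init value.
denseLaplaceOracle <- function(labels, psiGm = 50, psiGwb = 100, psiWm = 150) {
  lab <- volData(labels)
  d <- dim(lab)
  idx <- which(lab == 4L)
  arr <- which(lab == 4L, arr.ind = TRUE)
  pos <- setNames(seq_along(idx), idx)
  off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  lin <- function(v) v[1] + (v[2] - 1) * d[1] + (v[3] - 1) * d[1] * d[2]
  nbrs <- lapply(seq_along(idx), function(r) {
    nb <- sweep(off, 2, arr[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb[ok, , drop = FALSE]
  })
  # boundary-connected GWB set (BFS through GWB adjacency from GM/WM contact)
  touches <- vapply(nbrs, function(nb) any(lab[nb] %in% c(2L, 3L)), logical(1))
  conn <- touches
  repeat {
    grew <- FALSE
    for (r in which(!conn)) {
      nb <- nbrs[[r]]
      nbGwb <- nb[lab[nb] == 4L, , drop = FALSE]
      if (nrow(nbGwb) && any(conn[pos[as.character(apply(nbGwb, 1, lin))]])) {
        conn[r] <- TRUE; grew <- TRUE
      }
    }
    if (!grew) break
  }
  psi <- array(NA_real_, dim = d)
  psi[lab == 2L] <- psiGm
  psi[lab == 3L] <- psiWm
  psi[lab == 4L] <- psiGwb
  sIdx <- which(conn)
  if (length(sIdx)) {
    A <- matrix(0, length(sIdx), length(sIdx))
    b <- numeric(length(sIdx))
    rowOf <- setNames(seq_along(sIdx), idx[sIdx])
    for (q in seq_along(sIdx)) {
      r <- sIdx[q]
      nb <- nbrs[[r]]
      m <- 0
      for (t in seq_len(nrow(nb))) {
        l <- lab[nb[t, , drop = FALSE]]
        if (l == 2L) { m <- m + 1; b[q] <- b[q] + psiGm }
        else if (l == 3L) { m <- m + 1; b[q] <- b[q] + psiWm }
        else if (l == 4L) {
          m <- m + 1
          A[q, rowOf[as.character(lin(nb[t, ]))]] <- -1
        }
      }
      A[q, q] <- m
    }
    psi[idx[sIdx]] <- solve(A, b)
  }
  psi
}

# Independent equal-weight three-component Gaussian EM on the flattened
# intensities (the beta = 0 limit of the hidden-MRF model has a uniform label
# prior, i.e. fixed mixing weights 1/3).
gmmOracle <- function(vals, mu, sigma, tol = 1e-8, maxIter = 500) {
  for (it in seq_len(maxIter)) {
    ll <- vapply(1:3, function(l) stats::dnorm(vals, mu[l], sigma[l]),
                 numeric(length(vals)))
    p <- ll / rowSums(ll)
    muN <- colSums(p * vals) / colSums(p)
    sgN <- sqrt(colSums(p * (vals - rep(muN, each = length(vals)))^2) /
                  colSums(p))
    delta <- max(abs(c(muN - mu, sgN - sigma)))
    ord <- order(muN)
    mu <- muN[ord]; sigma <- sgN[ord]
    if (delta < tol) break
  }
  list(mu = mu, sigma = sigma)
}

# Brute-force least-squares plane fit of intensities over a full centered
# window at one interior voxel; returns the gradient magnitude per mm.
planeFitOracle <- function(arr, v, h, spacing) {
  rng <- lapply(1:3, function(a) (v[a] - h):(v[a] + h))
  g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  X <- cbind(1, (g$x - v[1]) * spacing[1], (g$y - v[2]) * spacing[2],
             (g$z - v[3]) * spacing[3])
  yv <- arr[as.matrix(g)]
  beta <- solve(crossprod(X), crossprod(X, yv))
  sqrt(sum(beta[2:4]^2))
}

# Hand re-enumeration of the confusion rules at one threshold.
confusionOracle <- function(vals, truth, t, polarity, backgroundRule = NA) {
  keep <- rep(TRUE, length(vals))
  if (!is.na(backgroundRule)) keep <- vals >= backgroundRule
  pos <- if (polarity == "high_is_positive") vals > t else vals < t
  c(tp = sum(keep & pos & truth), tn = sum(keep & !pos & !truth),
    fp = sum(keep & pos & !truth), fn = sum(keep & !pos & truth))
}

# Per-voxel re-evaluation of the labeling rule.
labelOracle <- function(g, w, tProb) {
  out <- array(0L, dim = dim(g))
  for (i in seq_along(g)) {
    out[i] <- if (g[i] >= tProb) 2L
      else if (w[i] >= tProb) 3L
      else if (g[i] > 0 && g[i] < tProb && w[i] > 0 && w[i] < tProb) 4L
      else 0L
  }
  out
}
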