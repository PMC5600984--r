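test_that("k-means initialization recovers well-separated clusters deterministically", {
  set.seed(0)
  vals <- c(rnorm(1000, 50, 5), rnorm(1000, 110, 5), rnorm(1000, 170, 5))
  trueMeans <- tapply(vals, rep(1:3, each = 1000), mean)
  dims <- c(30, 10, 10)
  y <- brainVolume(array(vals, dims))
  m1 <- initializeModel(y, seed = 0)
  expect_lt(max(abs(tissueMeans(m1) - trueMeans)), 2)
  expect_true(all(diff(tissueMeans(m1)) > 0))
  m2 <- initializeModel(y, seed = 0)
  expect_identical(tissueMeans(m1), tissueMeans(m2))
  expect_identical(tissueSds(m1), tissueSds(m2))
  # too-small mask
  small <- array(FALSE, dims); small[1:10] <- TRUE
  expect_error(initializeModel(y, small), "initialization error")
})

test_that("clique potential is the scaled Potts pair energy", {
  expect_equal(cliquePotential("gm", "gm"), 0)
  expect_equal(cliquePotential("gm", "wm"), 0.5)
  expect_equal(cliquePotential("gm", "wm", beta = 2), 1.0)
  expect_equal(cliquePotential(2, 2, beta = 7), 0)
  expect_error(cliquePotential(5, 2), "domain")
})

test_that("local prior is the normalized Gibbs ratio over candidates", {
  lab <- array(0L, c(3, 3, 3))
  lab[2, 2, ] <- 2L; lab[2, c(1, 3), 2] <- 2L; lab[c(1, 3), 2, 2] <- 2L
  # all six neighbors GM: exp(0) / (exp(0) + 2 exp(-3))
  expect_equal(localPrior(brainVolume(lab, role = "label"), c(2, 2, 2), "gm"),
               exp(0) / (exp(0) + 2 * exp(-3)), tolerance = 1e-12)
  # isolated voxel: uniform over the three candidates
  iso <- brainVolume(array(0L, c(3, 3, 3)), role = "label")
  for (cand in c("csf", "gm", "wm")) {
    expect_equal(localPrior(iso, c(2, 2, 2), cand), 1 / 3)
  }
  # 3 GM / 3 WM split: GM and WM priors equal by symmetry
  lab2 <- array(0L, c(3, 3, 3))
  lab2[2, 2, 1] <- 2L; lab2[2, 1, 2] <- 2L; lab2[1, 2, 2] <- 2L
  lab2[2, 2, 3] <- 3L; lab2[2, 3, 2] <- 3L; lab2[3, 2, 2] <- 3L
  v2 <- brainVolume(lab2, role = "label")
  expect_equal(localPrior(v2, c(2, 2, 2), "gm"),
               localPrior(v2, c(2, 2, 2), "wm"))
  expect_error(localPrior(v2, c(9, 2, 2), "gm"), "index")
})

test_that("ICM reduces to Gaussian classification at beta = 0 and respects a strong prior", {
  model <- tissueModel(c(50, 110, 170), c(10, 10, 10), beta = 0)
  set.seed(2)
  y <- array(c(rnorm(500, 110, 10), rnorm(500, 170, 10)), c(10, 10, 10))
  yv <- brainVolume(y)
  lab0 <- brainVolume(array(2L, c(10, 10, 10)), role = "label")
  got <- icmUpdate(yv, lab0, model)
  ll <- sapply(1:3, function(l) dnorm(as.vector(y), c(50, 110, 170)[l], 10, log = TRUE))
  expect_identical(as.vector(volData(got)), max.col(ll, ties.method = "first"))

  # salt voxel: GM-valued voxel inside a WM slab flips to WM under a large beta
  y2 <- array(170, c(5, 5, 5)); y2[3, 3, 3] <- 110
  lab2 <- array(3L, c(5, 5, 5)); lab2[3, 3, 3] <- 2L
  strong <- tissueModel(c(50, 110, 170), c(10, 10, 10), beta = 50)
  got2 <- icmUpdate(brainVolume(y2), brainVolume(lab2, role = "label"), strong)
  # oracle: exhaustive evaluation of the three candidate posteriors there
  cost <- sapply(1:3, function(l) {
    -dnorm(110, c(50, 110, 170)[l], 10, log = TRUE) + 0.5 * 50 * sum(l != rep(3, 6))
  })
  expect_equal(which.min(cost), 3L)
  expect_identical(volData(got2)[3, 3, 3], 3L)
})

test_that("sequential ICM sweeps never increase the posterior energy", {
  ph <- slabPhantom(shape = c(12, 12, 20), gwbThicknessMm = 2, seed = 4)
  y <- ph@image
  model <- initializeModel(y, seed = 1)
  m <- array(TRUE, dim(y))
  ll <- sapply(1:3, function(l) {
    dnorm(as.vector(volData(y)), tissueMeans(model)[l], tissueSds(model)[l], log = TRUE)
  })
  lab <- brainVolume(array(max.col(ll, ties.method = "first"), dim(y)),
                     role = "label")
  e <- ldpo:::mrfEnergy(volData(y), volData(lab), m, tissueMeans(model),
                        tissueSds(model), 1)
  for (s in 1:5) {
    lab <- icmUpdate(y, lab, model)
    e2 <- ldpo:::mrfEnergy(volData(y), volData(lab), m, tissueMeans(model),
                           tissueSds(model), 1)
    expect_lte(e2, e + 1e-8)
    e <- e2
  }
})

test_that("EM recovers generating parameters on a three-class phantom", {
  ph <- slabPhantom(shape = c(30, 30, 30), gwbThicknessMm = 2,
                    tissueMeans = c(50, 110, 170), tissueSds = c(10, 10, 10),
                    seed = 6)
  seg <- emFit(ph@image, seed = 1)
  mu <- tissueMeans(tissueModelOf(seg))
  sg <- tissueSds(tissueModelOf(seg))
  expect_lt(max(abs(mu - c(50, 110, 170)) / c(50, 110, 170)), 0.02)
  expect_lt(max(abs(sg - 10) / 10), 0.10)
  expect_true(all(diff(mu) > 0))
  # posteriors: sum to one in-mask, zero outside, argmax agrees with labels
  ps <- volData(tissueProb(seg, "csf")) + volData(tissueProb(seg, "gm")) +
    volData(tissueProb(seg, "wm"))
  expect_lt(max(abs(ps - 1)), 1e-6)
  stack <- cbind(as.vector(volData(tissueProb(seg, "csf"))),
                 as.vector(volData(tissueProb(seg, "gm"))),
                 as.vector(volData(tissueProb(seg, "wm"))))
  expect_identical(max.col(stack, ties.method = "first"),
                   as.vector(volData(segLabels(seg))))
})

test_that("EM respects the mask and the stopping rule", {
  ph <- slabPhantom(shape = c(12, 12, 20), gwbThicknessMm = 2, seed = 8)
  m <- array(TRUE, dim(ph@image)); m[1:3, , ] <- FALSE
  seg <- emFit(ph@image, m, maxEmIter = 5)
  expect_true(all(volData(tissueProb(seg, "gm"))[!m] == 0))
  expect_true(all(volData(segLabels(seg))[!m] == 0L))
  segOne <- emFit(ph@image, tol = Inf)
  expect_identical(segOne@emIterations, 1L)
  expect_true(segOne@converged)
  expect_error(emFit(ph@image, array(FALSE, dim(ph@image))), "empty mask")
})

test_that("beta = 0 EM equals an independent equal-weight Gaussian mixture fit", {
  ph <- slabPhantom(shape = c(16, 16, 24), gwbThicknessMm = 2, seed = 5)
  seg <- emFit(ph@image, beta = 0, tol = 1e-8, maxEmIter = 200, seed = 2)
  init <- initializeModel(ph@image, seed = 2)
  orc <- gmmOracle(as.vector(volData(ph@image)), tissueMeans(init),
                   tissueSds(init), tol = 1e-8)
  expect_lt(max(abs(tissueMeans(tissueModelOf(seg)) - orc$mu)), 1e-3)
})

test_that("EM is deterministic given the seed", {
  ph <- slabPhantom(shape = c(12, 12, 20), gwbThicknessMm = 2, seed = 9)
  a <- emFit(ph@image, seed = 3, maxEmIter = 5)
  b <- emFit(ph@image, seed = 3, maxEmIter = 5)
  expect_identical(volData(segLabels(a)), volData(segLabels(b)))
  expect_identical(volData(tissueProb(a, "gm")), volData(tissueProb(b, "gm")))
  expect_identical(tissueMeans(tissueModelOf(a)), tissueMeans(tissueModelOf(b)))
})
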