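test_that("SIMPLISMA finds the pure directions", {
  ## rank-1 data: the first selected spectrum is collinear with the truth
  tgrid <- seq(0, 6, by = 0.05)
  s <- fixtureSpectrum(c(250, 340), c(15, 25))
  X <- (exp(-0.5 * ((tgrid - 3) / 0.5)^2)) %o% s
  sel <- simplisma(X, 1)
  expect_gt(abs(cor(sel$spectra[, 1], s)), 0.999)
  ## two components confined to disjoint time blocks: one pick per block
  s2 <- fixtureSpectrum(c(290, 380), c(20, 10))
  C <- cbind(exp(-0.5 * ((tgrid - 1.5) / 0.3)^2),
             exp(-0.5 * ((tgrid - 4.5) / 0.3)^2))
  X2 <- C %*% t(cbind(s, s2))
  sel2 <- simplisma(X2, 2)
  picks <- tgrid[sel2$indices]
  expect_true(any(abs(picks - 1.5) < 1) && any(abs(picks - 4.5) < 1))
  ## purity scores are non-increasing over the selection order
  set.seed(31)
  X3 <- abs(matrix(rnorm(600), 30, 20)) + 0.1
  sel3 <- simplisma(X3, 5)
  expect_true(all(diff(sel3$purity) <= 1e-9))
  expect_error(simplisma(matrix(0, 4, 4), 2), "all-zero")
})

test_that("MCR-ALS recovers a noiseless bilinear rank-2 cluster", {
  tgrid <- seq(0, 8, by = 0.04)
  sA <- fixtureSpectrum(c(250, 330), c(15, 25))
  sB <- fixtureSpectrum(c(280, 390), c(25, 12))
  expect_lt(abs(cor(sA, sB)), 0.6)
  C <- cbind(exp(-0.5 * ((tgrid - 3.4) / 0.45)^2),
             0.6 * exp(-0.5 * ((tgrid - 4.2) / 0.45)^2))
  X <- C %*% t(cbind(sA, sB))
  fit <- mcrALS(X, simplisma(X, 2)$spectra)
  expect_lt(fit$lof, 0.1)
  ## permutation-matched spectral correlation
  cr <- abs(cor(fit$S, cbind(sA, sB)))
  expect_gt(max(cr[, 1]), 0.999)
  expect_gt(max(cr[, 2]), 0.999)
  ## constraint contract holds exactly
  expect_gte(min(fit$C), 0)
  expect_gte(min(fit$S), 0)
  for (j in 1:2) {
    prof <- fit$C[, j]
    m <- which.max(prof)
    expect_true(all(diff(prof[seq_len(m)]) >= -1e-9))
    expect_true(all(diff(prof[m:length(prof)]) <= 1e-9))
  }
  ## lof trajectory of accepted states is non-increasing
  expect_true(all(diff(fit$lofTrace) <= 1e-12))
  ## unit-norm spectra
  expect_equal(colSums(fit$S^2), c(1, 1))
})

test_that("rank-1 fits reproduce rank-1 data and reconstruction is near-SVD", {
  tgrid <- seq(0, 5, by = 0.05)
  s <- fixtureSpectrum(c(260, 350), c(18, 22))
  c0 <- exp(-0.5 * ((tgrid - 2.5) / 0.4)^2)
  X <- c0 %o% s
  fit <- mcrALS(X, simplisma(X, 1)$spectra)
  expect_lt(fit$lof, 1e-6)
  expect_gt(cor(fit$C[, 1], c0), 0.99999)
  ## rank-2 constrained fit is close to the unconstrained truncation error
  sB <- fixtureSpectrum(c(300, 240), c(20, 15))
  X2 <- X + (0.5 * exp(-0.5 * ((tgrid - 3.2) / 0.4)^2)) %o% sB +
    matrix(abs(rnorm(length(tgrid) * length(s), sd = 1e-4)),
           length(tgrid))
  fit2 <- mcrALS(X2, simplisma(X2, 2)$spectra)
  sv <- svd(X2)
  Xr <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
  errSvd <- sqrt(sum((X2 - Xr)^2))
  errMcr <- sqrt(sum(fit2$E^2))
  expect_lt(errMcr, errSvd * 1.5)
  expect_error(mcrALS(X, matrix(1, length(s), 50)), "rank")
})

test_that("rank estimation respects the six-component cap", {
  ## ten heavily overlapping components in one window
  set.seed(17)
  tgrid <- seq(0, 4, by = 1 / 60)
  specs <- randomSpectra(10, fixtureChannels, maxR = 0.95)
  C <- vapply(seq_len(10), function(i)
    exp(-0.5 * ((tgrid - (1.4 + 0.12 * i)) / 0.12)^2), numeric(length(tgrid)))
  X <- C %*% t(specs) + matrix(abs(rnorm(length(tgrid) * 39, sd = 1e-4)),
                               length(tgrid))
  r <- estimateRank(X, cap = 6)
  expect_lte(r, 6)
  expect_gte(r, 1)
  expect_warning(estimateRank(X, cap = 8), "cap")
  ## clean rank-2 cluster
  sA <- fixtureSpectrum(c(250, 330), c(15, 25))
  sB <- fixtureSpectrum(c(280, 390), c(25, 12))
  C2 <- cbind(exp(-0.5 * ((tgrid - 1.5) / 0.2)^2),
              0.7 * exp(-0.5 * ((tgrid - 2) / 0.2)^2))
  expect_equal(estimateRank(C2 %*% t(cbind(sA, sB))), 2L)
  ## pure noise is rank 0
  set.seed(18)
  expect_equal(estimateRank(matrix(abs(rnorm(800, sd = 1e-3)), 40, 20)), 0L)
})

test_that("the MS 0.1 percent rule counts noise signals above threshold", {
  expect_equal(msNoiseCount(c(100, 0.05, 0.2)), 1L)
  expect_equal(msNoiseCount(c(100, 50, 20)), 2L)
  expect_equal(msNoiseCount(c(7)), 0L)
  expect_equal(msNoiseCount(numeric(0)), 0L)
})

test_that("extracted components carry apex, purity screen and flags", {
  tgrid <- seq(0, 5, by = 0.05)
  s <- fixtureSpectrum(c(260, 350), c(18, 22))
  c0 <- exp(-0.5 * ((tgrid - 2.5) / 0.4)^2)
  X <- c0 %o% s
  cl <- structure(list(runId = "r1", clusterId = "r1_c01", time = tgrid),
                  class = "PeakCluster")
  fit <- mcrALS(X, simplisma(X, 1)$spectra)
  comps <- extractComponents(fit, cl, purity = 1)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$apexTime, 2.5, tolerance = 0.05)
  expect_true(comps[[1]]$pure)
  expect_false(comps[[1]]$truncated)
  ## truncated peak: maximum on the boundary is retained but flagged
  Xt <- X[tgrid >= 2.5, ]
  clt <- structure(list(runId = "r1", clusterId = "r1_c02",
                        time = tgrid[tgrid >= 2.5]), class = "PeakCluster")
  fitT <- mcrALS(Xt, simplisma(Xt, 1)$spectra)
  compsT <- extractComponents(fitT, clt, purity = 1)
  expect_length(compsT, 1)
  expect_true(compsT[[1]]$truncated)
})

test_that("strong two-component overlap resolves where the apex spectrum cannot", {
  ## the apex scan of a strongly overlapped pair is a mixture; the resolved
  ## spectra match the truth while the raw apex spectrum matches neither
  tgrid <- seq(0, 6, by = 0.02)
  sA <- fixtureSpectrum(c(245, 330), c(14, 22))
  sB <- fixtureSpectrum(c(285, 385), c(22, 14))
  C <- cbind(exp(-0.5 * ((tgrid - 3.0) / 0.3)^2),
             0.9 * exp(-0.5 * ((tgrid - 3.35) / 0.3)^2))
  X <- C %*% t(cbind(sA, sB))
  fit <- mcrALS(X, simplisma(X, 2)$spectra)
  cr <- abs(cor(fit$S, cbind(sA, sB)))
  expect_gt(max(cr[, 1]), 0.99)
  expect_gt(max(cr[, 2]), 0.99)
  apexSpec <- X[which.max(rowSums(X)), ]
  expect_lt(abs(cor(apexSpec, sA)), 0.99)
  expect_lt(abs(cor(apexSpec, sB)), 0.99)
})
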