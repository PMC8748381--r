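## Small design + programs used throughout: 3 factors, 8 + 1 runs.
.retSetup <- function(seed = 1) {
  spec <- referenceCampaign(1, seed = seed)
  list(spec = spec,
       programs = campaignPrograms(spec),
       runs = data.frame(runId = spec$design$runIds,
                         role = spec$design$roles))
}

test_that("noiseless LSS retention is recovered to high accuracy", {
  su <- .retSetup()
  true <- lssParams(2.0, 4.0, tempCoef = -0.004, tRef = 35)
  tRs <- vapply(su$programs, function(p)
    simulateGradient(true, p, dt = p@t0 / 100)$tR, numeric(1))
  m <- fitComponent(tRs, su$runs, su$programs, mode = "lss",
                    componentId = "synthA")
  predAll <- c(m$calibration$predicted, m$validation$predicted)
  obsAll <- c(m$calibration$observed, m$validation$observed)
  expect_true(all(abs(predAll - obsAll) < 0.01))
  expect_equal(m$params$S, 4.0, tolerance = 0.01)
  expect_equal(m$params$logK0, 2.0, tolerance = 0.01)
})

test_that("validation runs never influence the fitted model", {
  su <- .retSetup()
  true <- lssParams(1.8, 5.0)
  tRs <- vapply(su$programs, function(p)
    simulateGradient(true, p)$tR, numeric(1))
  m1 <- fitComponent(tRs, su$runs, su$programs, mode = "lss")
  tRs2 <- tRs
  tRs2[su$runs$runId[su$runs$role == "validation"]] <- NA
  m2 <- fitComponent(tRs2, su$runs, su$programs, mode = "lss")
  expect_equal(m1$params$S, m2$params$S)
  expect_equal(m1$params$logK0, m2$params$logK0)
})

test_that("a mis-assigned retention time surfaces as an outlying residual", {
  ## a +1 min bad assignment in any single run must rank among the top two
  ## absolute residuals (a high-leverage design corner can drag a neighbour
  ## up with it), and be the single largest in most positions
  dm <- addValidationRuns(screeningDesign(list(
    factorDef("tG", "gradient_time", 5, 15),
    factorDef("phiF", "phi_final", 0.6, 1.0))), 1)
  spec <- campaignSpec(list(), dm)
  programs <- campaignPrograms(spec)
  runs <- data.frame(runId = dm$runIds, role = dm$roles)
  true <- lssParams(2.0, 4.0)
  tRs0 <- vapply(programs, function(p)
    simulateGradient(true, p)$tR, numeric(1))
  calIds <- runs$runId[runs$role == "calibration"]
  hits <- logical(length(calIds))
  for (k in seq_along(calIds)) {
    tRs <- tRs0
    tRs[calIds[k]] <- tRs[calIds[k]] + 1
    m <- fitComponent(tRs, runs, programs, mode = "lss")
    calPairs <- goodnessOfFit(m)$pairs
    calPairs <- calPairs[calPairs$role == "calibration", ]
    ord <- calPairs$run[order(-abs(calPairs$residual))]
    expect_true(calIds[k] %in% ord[1:2])
    hits[k] <- ord[1] == calIds[k]
  }
  expect_gt(mean(hits), 0.5)
})

test_that("goodness of fit reports exact r2 and recomputable RMSE", {
  su <- .retSetup()
  true <- lssParams(2.0, 4.0)
  tRs <- vapply(su$programs, function(p)
    simulateGradient(true, p, dt = p@t0 / 100)$tR, numeric(1))
  m <- fitComponent(tRs, su$runs, su$programs, mode = "lss",
                    dt = su$spec$t0 / 100)
  expect_equal(m$r2Cal, 1.0, tolerance = 1e-6)
  gof <- goodnessOfFit(m)
  calPairs <- gof$pairs[gof$pairs$role == "calibration", ]
  expect_equal(gof$rmse, sqrt(mean(calPairs$residual^2)))
  expect_setequal(unique(gof$pairs$role), c("calibration", "validation"))
})

test_that("PLS mode interpolates the design region", {
  su <- .retSetup()
  true <- lssParams(2.0, 4.5)
  tRs <- vapply(su$programs, function(p)
    simulateGradient(true, p)$tR, numeric(1))
  m <- fitComponent(tRs, su$runs, su$programs, mode = "pls",
                    coded = su$spec$design$coded)
  expect_gt(m$r2Cal, 0.99)
  expect_lte(m$latentVariables, sum(su$runs$role == "calibration") - 2)
  ## validation prediction stays reasonable for an interior test point
  expect_lt(abs(m$validation$observed - m$validation$predicted), 0.5)
})

test_that("too few assigned runs is a clear error naming the component", {
  su <- .retSetup()
  tRs <- setNames(rep(NA_real_, 9), su$runs$runId)
  tRs[su$runs$runId[1]] <- 5
  expect_error(fitComponent(tRs, su$runs, su$programs, mode = "lss",
                            componentId = "P07"), "P07")
})

test_that("LSS parameters are recoverable from two isocratic runs", {
  progs <- list(r1 = elutionProgram(0.2, t0 = 1),
                r2 = elutionProgram(0.4, t0 = 1))
  runs <- data.frame(runId = c("r1", "r2"),
                     role = c("calibration", "calibration"))
  ## k = 10 at phi 0.2, k = 1 at phi 0.4  =>  S = 5, log k0 = 2
  tRs <- c(r1 = 11, r2 = 2)
  m <- fitComponent(tRs, runs, progs, mode = "lss")
  lss <- invertToLSS(m)
  expect_equal(lss$S, 5, tolerance = 1e-4)
  expect_equal(lss$logK0, 2, tolerance = 1e-4)
  ## the empirical-mode path inverts from isocratic observations
  progs3 <- list(r1 = elutionProgram(0.2, t0 = 1),
                 r2 = elutionProgram(0.3, t0 = 1),
                 r3 = elutionProgram(0.4, t0 = 1))
  runs3 <- data.frame(runId = c("r1", "r2", "r3"), role = "calibration")
  k3 <- 10^(2 - 5 * c(0.2, 0.3, 0.4))
  tRs3 <- setNames(1 + k3, c("r1", "r2", "r3"))
  mP <- fitComponent(tRs3, runs3, progs3, mode = "pls",
                     coded = matrix(c(-1, 0, 1), 3, 1,
                                    dimnames = list(NULL, "x1")))
  lssP <- invertToLSS(mP, t0 = 1, programs = progs3)
  expect_equal(lssP$S, 5, tolerance = 1e-4)
  expect_equal(lssP$logK0, 2, tolerance = 1e-4)
  ## no phi variation: not identifiable
  progsSame <- list(r1 = elutionProgram(0.3, t0 = 1),
                    r2 = elutionProgram(0.3, t0 = 1),
                    r3 = elutionProgram(0.3, t0 = 1))
  mS <- fitComponent(setNames(c(5, 5.02, 5.04), c("r1", "r2", "r3")),
                     runs3, progsSame, mode = "pls",
                     coded = matrix(c(-1, 0, 1), 3, 1,
                                    dimnames = list(NULL, "x1")))
  expect_error(invertToLSS(mS, t0 = 1, programs = progsSame),
               "phi variation")
})

test_that("recovered S is accurate across noisy seeded campaigns", {
  ## apex-time noise of up to half a sampling interval on every run
  errs <- numeric(0)
  for (seed in 1:5) {
    su <- .retSetup(seed = seed)
    set.seed(100 + seed)
    sInt <- 1 / (su$spec$samplingRate * 60)
    for (comp in 1:2) {
      true <- lssParams(runif(1, 1.5, 2.8), runif(1, 3, 8))
      tRs <- vapply(su$programs, function(p)
        simulateGradient(true, p)$tR, numeric(1))
      tRs <- tRs + runif(length(tRs), -0.5, 0.5) * sInt
      m <- fitComponent(tRs, su$runs, su$programs, mode = "lss")
      errs <- c(errs, abs(m$params$S - true$S) / true$S)
    }
  }
  expect_lt(median(errs), 0.05)
})
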