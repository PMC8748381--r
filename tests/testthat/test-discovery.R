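## Engineered spectra with controlled correlations for catalog tests.
.mkSpec <- function(seedShift) {
  unitVec(fixtureSpectrum(c(240 + seedShift, 340 - seedShift), c(16, 24)))
}

test_that("a component pure in every run collapses to one catalog entry", {
  s <- .mkSpec(0)
  comps <- lapply(sprintf("run%02d", 1:8), function(r)
    fixtureComponent(r, s + rnorm(length(s), sd = 1e-4), apexTime = 5))
  cat0 <- buildCatalog(comps)
  expect_length(cat0$entries, 1)
  expect_length(cat0$entries[[1]]$runs, 8)
})

test_that("identical UV but different MS base peaks stay separate entries", {
  set.seed(41)
  s <- .mkSpec(0)
  s2 <- unitVec(s + rnorm(length(s), sd = 0.01))
  expect_gt(cor(s, s2), 0.99)
  a <- fixtureComponent("run01", s, 5, msSpectrum = c(`154` = 100, `77` = 10))
  b <- fixtureComponent("run02", s2, 6, msSpectrum = c(`182` = 100, `91` = 8))
  expect_length(buildCatalog(list(a, b), msMode = TRUE)$entries, 2)
  ## without MS evidence they merge
  expect_length(buildCatalog(list(a, b), msMode = FALSE)$entries, 1)
})

test_that("pure in exactly one run still seeds a catalog entry", {
  sA <- .mkSpec(0); sB <- .mkSpec(30)
  comps <- c(list(fixtureComponent("run01", sA, 4, pure = TRUE)),
             lapply(sprintf("run%02d", 2:4), function(r)
               fixtureComponent(r, sA, 4, pure = FALSE)),
             list(fixtureComponent("run01", sB, 6, pure = TRUE)))
  cat0 <- buildCatalog(comps)
  expect_length(cat0$entries, 2)
})

test_that("assignment respects the 0.95 limit and the 0.8 alert band", {
  base <- .mkSpec(0)
  n <- length(base)
  mk <- function(target) {
    ## vector with a prescribed correlation to `base`
    v <- rnorm(n)
    v <- residuals(lm(v ~ base))
    unitVec(target * scale(base)[, 1] + sqrt(1 - target^2) * scale(v)[, 1])
  }
  cat0 <- buildCatalog(list(fixtureComponent("run00", base, 5)))
  for (case in list(c(0.96, NA), c(0.85, NA), c(0.50, NA))) {
    r <- case[1]
    extr <- list(fixtureComponent("run01", mk(r), 5.2, pure = FALSE))
    tab <- assignComponents(cat0, extr, runIds = "run01")
    flag <- tab$flags[1, 1]
    if (r >= 0.95) {
      expect_equal(flag, "assigned")
      expect_equal(unname(tab$tR[1, 1]), 5.2)
    } else if (r > 0.8) {
      expect_equal(flag, "alert")
      expect_true(is.na(tab$tR[1, 1]))
    } else {
      expect_equal(flag, "unassigned")
    }
    expect_equal(unname(tab$bestR[1, 1]), r, tolerance = 1e-6)
  }
})

test_that("competing entries resolve by descending correlation", {
  sA <- .mkSpec(0); sB <- .mkSpec(40)
  ## one extracted component resembling A strongly, B moderately
  mix <- unitVec(0.95 * sA + 0.31 * sB)
  cat0 <- buildCatalog(list(fixtureComponent("r0", sA, 3),
                            fixtureComponent("r0", sB, 7)))
  extr <- list(fixtureComponent("run01", mix, 5, pure = FALSE))
  rA <- cor(cat0$entries[[1]]$spectrum, mix)
  rB <- cor(cat0$entries[[2]]$spectrum, mix)
  thr <- max(rA, rB) - 0.01      # the stronger match clears the limit
  tab <- assignComponents(cat0, extr, runIds = "run01", thrUV = thr,
                          alertFloor = 0.1)
  winner <- which.max(c(rA, rB))
  expect_equal(unname(tab$flags[winner, 1]), "assigned")
  expect_false(tab$flags[-winner, 1] == "assigned")
  ## no extracted component is consumed twice
  expect_equal(sum(tab$flags[, 1] == "assigned"), 1)
})

test_that("catalog membership is stable under run ordering", {
  set.seed(42)
  specs <- lapply(c(0, 25, 50), .mkSpec)
  mkRun <- function(r) lapply(seq_along(specs), function(i)
    fixtureComponent(r, unitVec(specs[[i]] + rnorm(39, sd = 1e-3)),
                     apexTime = i))
  runs <- lapply(sprintf("run%02d", 1:5), mkRun)
  fwd <- buildCatalog(do.call(c, runs))
  rev_ <- buildCatalog(do.call(c, rev(runs)))
  expect_equal(length(fwd$entries), length(rev_$entries))
  crossR <- sapply(fwd$entries, function(a)
    max(sapply(rev_$entries, function(b) cor(a$spectrum, b$spectrum))))
  expect_true(all(crossR > 0.9999))
})

test_that("background-correlated entries are flagged, not deleted", {
  set.seed(43)
  tgrid <- seq(1 / 300, 6, by = 1 / 300)
  drift <- chromdev:::.driftSpectrum(fixtureChannels)
  X <- (0.02 + 0.01 * tgrid / 6) %o% drift +
    matrix(rnorm(length(tgrid) * 39, sd = 5e-4), length(tgrid))
  peak <- 0.2 * exp(-0.5 * ((tgrid - 3) / 0.05)^2)
  sA <- .mkSpec(10)
  X <- X + peak %o% as.numeric(sA)
  ch <- chromatogram("run01", tgrid, fixtureChannels, X, "UV")
  cat0 <- buildCatalog(list(
    fixtureComponent("run01", unitVec(drift), 0.5),
    fixtureComponent("run01", sA, 3)))
  filt <- backgroundFilter(cat0, list(ch))
  art <- vapply(filt$entries, `[[`, logical(1), "artifact")
  drifty <- which.max(sapply(filt$entries, function(e)
    abs(cor(e$spectrum, drift))))
  expect_true(art[drifty])
  expect_false(all(art))
  expect_length(filt$entries, 2)   # flagged, never removed
})

test_that("diagnostics expose redundancy and sum-spectrum patterns", {
  sA <- .mkSpec(0); sB <- .mkSpec(45)
  sSum <- unitVec(sA + sB)
  mkTab <- function(entries, tR, flags) {
    ## strict merge threshold keeps near-duplicate entries distinct, as a
    ## drifted consensus would in a real campaign
    cat0 <- buildCatalog(entries, thrUV = 0.99999)
    ord <- order(sapply(cat0$entries, function(e) e$members[[1]]$apexTime))
    tab <- assignComponents(cat0, list(), runIds = colnames(tR))
    tab$tR[] <- tR
    tab$flags[] <- flags
    tab
  }
  ## redundancy: duplicate entry, identical assigned times
  set.seed(51)
  e1 <- fixtureComponent("r1", sA, 5)
  e2 <- fixtureComponent("r2", unitVec(sA + rnorm(39, sd = 0.01)), 5.001)
  tR <- matrix(c(5, 5.001, 5.5, 5.501), 2, 2,
               dimnames = list(NULL, c("r1", "r2")))
  tab <- mkTab(list(e1, e2), tR, "assigned")
  d <- assignmentDiagnostics(tab, thr = 0.95, deltaTol = 0.01)
  expect_equal(nrow(d$redundancy), 1)
  ## sum-spectrum: entry matching the sum of two co-eluting entries
  e3 <- fixtureComponent("r1", sA, 4)
  e4 <- fixtureComponent("r1", sB, 4.001)
  e5 <- fixtureComponent("r2", sSum, 4.0005)
  tR3 <- matrix(c(4, 4.001, 4.0005, 6, 6.001, 6.0005), 3, 2,
                dimnames = list(NULL, c("r1", "r2")))
  tab3 <- mkTab(list(e3, e4, e5), tR3, "assigned")
  d3 <- assignmentDiagnostics(tab3, deltaTol = 0.01)
  expect_gte(nrow(d3$sumSpectrum), 1)
  ## a clean two-entry table reports nothing
  eC <- fixtureComponent("r1", sA, 3)
  eD <- fixtureComponent("r1", sB, 7)
  tRc <- matrix(c(3, 7, 3.5, 7.5), 2, 2,
                dimnames = list(NULL, c("r1", "r2")))
  tabC <- mkTab(list(eC, eD), tRc, "assigned")
  dC <- assignmentDiagnostics(tabC, deltaTol = 0.01)
  expect_equal(nrow(dC$redundancy), 0)
  expect_equal(nrow(dC$sumSpectrum), 0)
})

test_that("edits apply and the alert gate blocks fitting until resolved", {
  sA <- .mkSpec(0); sB <- .mkSpec(45)
  cat0 <- buildCatalog(list(fixtureComponent("r1", sA, 3),
                            fixtureComponent("r1", sB, 7)))
  tab <- assignComponents(cat0, list(), runIds = c("r1", "r2"))
  tab$flags[1, 1] <- "alert"
  expect_true(hasAlerts(tab))
  runs <- data.frame(runId = c("r1", "r2"),
                     role = c("calibration", "calibration"))
  progs <- list(r1 = elutionProgram(0.3, t0 = 1),
                r2 = elutionProgram(0.5, t0 = 1))
  expect_error(fitRetentionModels(tab, runs, progs), "alert")
  ## manual assignment clears the alert
  tab2 <- applyEdits(tab, list(list(action = "set_tR", entry = rownames(tab$tR)[1],
                                    run = "r1", tR = 3.2)))
  expect_equal(unname(tab2$flags[1, 1]), "manual")
  expect_false(hasAlerts(tab2))
  ## deletion shrinks the catalog and the table together
  tab3 <- applyEdits(tab2, list(list(action = "delete",
                                     entry = rownames(tab2$tR)[2])))
  expect_equal(nrow(tab3$tR), 1)
  expect_length(tab3$catalog$entries, 1)
  expect_error(applyEdits(tab3, list(list(action = "delete", entry = "nope"))),
               "no catalog entry")
})
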