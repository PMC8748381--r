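test_that("differential evolution solves the sphere and is reproducible", {
  fn <- function(x) sum(x^2)
  r1 <- deMinimize(fn, rep(-5, 5), rep(5, 5), pop = 40, gens = 200, seed = 3)
  expect_lt(r1$value, 1e-6)
  r2 <- deMinimize(fn, rep(-5, 5), rep(5, 5), pop = 40, gens = 200, seed = 3)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trace, r2$trace)
})

test_that("bound handling keeps every candidate inside the box", {
  ## objective rewards leaving the box: any excursion would win
  fn <- function(x) -sum(pmax(abs(x) - 1, 0)) + sum((x - 0.9)^2)
  r <- deMinimize(fn, rep(-1, 3), rep(1, 3), pop = 20, gens = 50, seed = 5)
  expect_true(all(r$par >= -1 & r$par <= 1))
})

test_that("non-finite objective values are rejected, not fatal", {
  fn <- function(x) if (x[1] > 0) NaN else sum(x^2)
  r <- deMinimize(fn, c(-2, -2), c(2, 2), pop = 10, gens = 30, seed = 7)
  expect_true(is.finite(r$value))
  expect_gt(r$nonFinite, 0)
})

test_that("pareto filter equals brute-force dominance", {
  expect_equal(paretoFilter(matrix(c(1, 2), 1)), 1L)
  expect_setequal(paretoFilter(rbind(c(1, 2), c(2, 1), c(2, 2))), c(1L, 2L))
  expect_equal(paretoFilter(matrix(numeric(0), 0, 2)), integer())
  ## duplicates of a non-dominated point are all retained
  expect_setequal(paretoFilter(rbind(c(1, 1), c(1, 1), c(2, 2))), c(1L, 2L))
  set.seed(13)
  pts <- matrix(runif(200), 100, 2)
  got <- sort(paretoFilter(pts))
  brute <- which(!vapply(seq_len(100), function(i)
    any(vapply(seq_len(100), function(j)
      j != i && all(pts[j, ] <= pts[i, ]) && any(pts[j, ] < pts[i, ]),
      logical(1))), logical(1)))
  expect_equal(got, brute)
  ## 3-objective fallback path agrees with brute force too
  set.seed(14)
  pts3 <- matrix(runif(90), 30, 3)
  got3 <- sort(paretoFilter(pts3))
  brute3 <- which(!vapply(seq_len(30), function(i)
    any(vapply(seq_len(30), function(j)
      j != i && all(pts3[j, ] <= pts3[i, ]) && any(pts3[j, ] < pts3[i, ]),
      logical(1))), logical(1)))
  expect_equal(got3, brute3)
})

test_that("two crossing LSS lines are separated away from the crossing", {
  ## log k equal at phi = 0.3: isocratic elution there gives Rs = 0
  pA <- lssParams(2.0, 4.0)
  pB <- lssParams(2.3, 5.0)
  sp <- searchSpace(data.frame(name = c("phi_initial", "phi_final", "t_G"),
                               low = c(0.05, 0.05, 0.5),
                               high = c(0.6, 0.6, 0.6)), t0 = 1)
  front <- optimizeSeparation(list(pA, pB), sp, mode = "pareto", pop = 20,
                              gens = 40, seed = 2, plates = 5000,
                              overtime = 100)
  best <- front$members[which.max(front$members$criticalRs), ]
  ## grid-search oracle over near-isocratic programs in the same space
  grid <- expand.grid(phiI = seq(0.05, 0.6, length.out = 50),
                      phiF = seq(0.05, 0.6, length.out = 50))
  gridBest <- max(vapply(seq_len(nrow(grid)), function(i) {
    prg <- elutionProgram(data.frame(time = c(0, 0.55),
                                     phi = c(grid$phiI[i], grid$phiF[i])),
                          t0 = 1)
    sim <- simulateSeparation(list(pA, pB), prg, plates = 5000,
                              overtime = 100)
    if (any(!sim$components$eluted)) 0 else sim$criticalRs
  }, numeric(1)))
  expect_gte(best$criticalRs, 0.98 * gridBest)
  ## no optimal member sits at the zero-selectivity crossing
  expect_false(any(abs(front$members$phi_initial - 0.3) < 0.01 &
                     abs(front$members$phi_final - 0.3) < 0.01 &
                     front$members$criticalRs < 0.1))
})

test_that("a single component reduces to runtime minimization", {
  p <- lssParams(2.5, 4)
  sp <- searchSpace(data.frame(name = c("phi_initial", "phi_final", "t_G"),
                               low = c(0.05, 0.5, 2),
                               high = c(0.5, 1, 15)), t0 = 1)
  front <- optimizeSeparation(list(p), sp, mode = "pareto", pop = 15,
                              gens = 25, seed = 4)
  expect_equal(nrow(front$members), 1)  # one objective left: fastest wins
  res <- optimizeSeparation(list(p), sp, mode = "threshold_time",
                            targetRs = 0, pop = 15, gens = 25, seed = 4)
  expect_lt(res$runtime, 4)
})

test_that("a returned front is itself non-dominated", {
  pA <- lssParams(2.0, 4.0); pB <- lssParams(2.4, 5.5)
  sp <- searchSpace(data.frame(name = c("phi_initial", "phi_final", "t_G"),
                               low = c(0.02, 0.5, 2),
                               high = c(0.5, 1, 15)), t0 = 1)
  front <- optimizeSeparation(list(pA, pB), sp, mode = "pareto", pop = 15,
                              gens = 20, seed = 6)
  obj <- cbind(-front$members$criticalRs, front$members$runtime)
  expect_length(paretoFilter(obj), nrow(obj))
})
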