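## Second-order predictor expansion of coded design rows (no intercept;
## PLS centres internally).
.secondOrderPredictors <- function(coded) {
  mm <- secondOrderModelMatrix(coded)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

## Simulate tR for one (logK0, S[, aT]) vector under a list of programs.
.lssPredict <- function(par, programs, useTemp, tRef, dt) {
  vapply(programs, function(prg) {
    pp <- list(logK0 = par[1], S = par[2],
               tempCoef = if (useTemp) par[3] else 0, tRef = tRef)
    class(pp) <- "LSSParams"
    step <- if (is.null(dt)) prg@t0 / 50 else dt
    simulateGradient(pp, prg, dt = step, overtime = 50)$tR
  }, numeric(1))
}

#' Fit a retention model for one catalog component
#'
#' Two modes are offered. `"lss"` (default) fits the linear solvent strength
#' parameters directly: `log10 k = log10 k0 - S phi [+ a (T - Tref)]`, by
#' nonlinear least squares on the observed retention times, with each
#' candidate parameter set pushed through the stepwise gradient simulator
#' under every run's own elution program; the fitted parameters are
#' immediately usable for simulating arbitrary programs. `"pls"` fits a
#' standard partial least squares regression of retention time on the coded
#' design factors expanded to second order, with the number of latent
#' variables chosen by leave-one-out cross-validation on the calibration
#' runs (capped at calibration runs minus 2); it interpolates empirically
#' within the design region. In both modes only calibration-role runs with
#' assigned retention times enter the fit; validation runs are predicted,
#' never fitted.
#'
#' @param tRs named numeric vector of assigned retention times (minutes) per
#'   run id; NA = unassigned (excluded).
#' @param runs data.frame with columns `runId` and `role`
#'   (`"calibration"`/`"validation"`), one row per run.
#' @param programs named list of [ElutionProgram-class], one per run id.
#' @param mode `"lss"` or `"pls"`.
#' @param componentId identifier stored in the model.
#' @param coded coded design matrix (rows matching `runs`); required for
#'   `"pls"` mode.
#' @param dt gradient-integration step for `"lss"` mode, minutes (default
#'   `t0/50`).
#' @return A `"RetentionModel"` list: `componentId`, `mode`, `params`
#'   (`"LSSParams"`, lss mode), `latentVariables` and `plsFit` (pls mode),
#'   `calibration`/`validation` data.frames (run, observed, predicted),
#'   `r2Cal`, `rmseCal`.
#' @export
fitComponent <- function(tRs, runs, programs, mode = c("lss", "pls"),
                         componentId = "component", coded = NULL,
                         dt = NULL) {
  mode <- match.arg(mode)
  runIds <- runs$runId
  obs <- tRs[runIds]
  cal <- runs$role == "calibration" & !is.na(obs)
  val <- runs$role == "validation"
  temps <- vapply(runIds, function(r) programs[[r]]@temperature, numeric(1))
  useTemp <- mode == "lss" && length(unique(temps[cal])) > 1
  p <- if (mode == "lss") 2 + useTemp else 3
  if (sum(cal) < p)
    stop("component '", componentId, "': only ", sum(cal),
         " assigned calibration runs for ", p, " model terms")
  tRef <- mean(range(temps[cal]))
  calIds <- runIds[cal]
  calProgs <- programs[calIds]
  out <- list(componentId = componentId, mode = mode, useTemp = useTemp)

  if (mode == "lss") {
    ## multistart grid, refined by Levenberg-Marquardt
    t0 <- calProgs[[1]]@t0
    resFun <- function(par)
      obs[calIds] - .lssPredict(par, calProgs, useTemp, tRef, dt)
    starts <- expand.grid(logK0 = c(1, 2, 3), S = c(3, 5, 8, 15))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      par0 <- c(starts$logK0[i], starts$S[i], if (useTemp) 0)
      ss <- sum(resFun(par0)^2)
      if (is.null(best) || ss < best$ss) best <- list(par = par0, ss = ss)
    }
    fit <- minpack.lm::nls.lm(par = best$par, fn = resFun,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200, ptol = 1e-10))
    par <- fit$par
    out$params <- lssParams(par[1], par[2],
                            tempCoef = if (useTemp) par[3] else 0,
                            tRef = tRef)
    predAll <- .lssPredict(par, programs[runIds], useTemp, tRef, dt)
  } else {
    if (is.null(coded)) stop("pls mode requires the coded design matrix")
    X <- .secondOrderPredictors(coded)
    Xcal <- X[cal, , drop = FALSE]
    ycal <- obs[calIds]
    keep <- apply(Xcal, 2, function(v) stats::sd(v) > 0)
    Xcal <- Xcal[, keep, drop = FALSE]
    maxLV <- max(1, min(sum(cal) - 2, ncol(Xcal)))
    ## mixOmics warns about centering stability below 5 samples per fold;
    ## fold sizes here are fixed by the design, so the notices carry no
    ## actionable information
    looRmse <- vapply(seq_len(maxLV), function(nc) {
      errs <- vapply(seq_len(sum(cal)), function(k) suppressWarnings({
        f <- mixOmics::pls(Xcal[-k, , drop = FALSE], ycal[-k], ncomp = nc,
                           mode = "regression")
        pr <- stats::predict(f, Xcal[k, , drop = FALSE])$predict[1, 1, nc]
        pr - ycal[k]
      }), numeric(1))
      sqrt(mean(errs^2))
    }, numeric(1))
    nc <- which.min(looRmse)
    plsFit <- suppressWarnings(
      mixOmics::pls(Xcal, ycal, ncomp = nc, mode = "regression"))
    out$latentVariables <- nc
    out$plsFit <- plsFit
    out$plsKeep <- keep
    predAll <- suppressWarnings(
      stats::predict(plsFit, X[, keep, drop = FALSE])$predict[, 1, nc])
  }
  calDf <- data.frame(run = calIds, observed = obs[calIds],
                      predicted = predAll[cal], role = "calibration")
  valDf <- if (any(val))
    data.frame(run = runIds[val], observed = obs[runIds[val]],
               predicted = predAll[val], role = "validation")
  else data.frame(run = character(), observed = numeric(),
                  predicted = numeric(), role = character())
  out$calibration <- calDf
  out$validation <- valDf
  res <- calDf$observed - calDf$predicted
  out$rmseCal <- sqrt(mean(res^2))
  sst <- sum((calDf$observed - mean(calDf$observed))^2)
  out$r2Cal <- if (sst > 0) 1 - sum(res^2) / sst else 1
  class(out) <- "RetentionModel"
  out
}

#' @export
print.RetentionModel <- function(x, ...) {
  cat(sprintf("RetentionModel '%s' [%s]: r2(cal) = %.4f, RMSE = %.4g min\n",
              x$componentId, x$mode, x$r2Cal, x$rmseCal))
  if (x$mode == "lss")
    cat(sprintf("  log10 k0 = %.3f, S = %.3f, tempCoef = %.4g (Tref %.1f)\n",
                x$params$logK0, x$params$S, x$params$tempCoef,
                x$params$tRef))
  else
    cat(sprintf("  %d latent variable(s)\n", x$latentVariables))
  invisible(x)
}

#' Goodness-of-fit summary for a retention model
#'
#' Observed-vs-predicted pairs for calibration and validation runs (kept
#' distinct, as validation runs never enter the fit), r-squared, RMSE and
#' per-run standardized residuals; runs whose standardized residual exceeds
#' 3 in magnitude are flagged -- bad component-to-peak assignments surface
#' as exactly such outlying residuals.
#'
#' @param model a `"RetentionModel"`.
#' @return list with `pairs` (data.frame run, observed, predicted, role,
#'   residual, stdResidual, flagged), `r2`, `rmse`.
#' @export
goodnessOfFit <- function(model) {
  df <- rbind(model$calibration, model$validation)
  df$residual <- df$observed - df$predicted
  s <- stats::sd(model$calibration$observed -
                   model$calibration$predicted)
  if (!is.finite(s) || s == 0) s <- .Machine$double.eps
  df$stdResidual <- df$residual / s
  df$flagged <- abs(df$stdResidual) > 3
  list(pairs = df, r2 = model$r2Cal, rmse = model$rmseCal)
}

#' Recover linear solvent strength parameters from a fitted model
#'
#' For models fitted in `"lss"` mode this is the identity on the stored
#' parameters. For empirical (`"pls"`) models fitted on isocratic runs the
#' LSS line is recovered from the observations themselves: each run gives
#' `k = tR / t0 - 1`, and `log10 k` is regressed on phi. Designs without
#' phi variation are not invertible.
#'
#' @param model a `"RetentionModel"`.
#' @param t0 dead time, minutes (isocratic inversion).
#' @param programs named list of per-run [ElutionProgram-class] (isocratic
#'   inversion; phi is read from each program).
#' @return An `"LSSParams"` object.
#' @export
invertToLSS <- function(model, t0 = NULL, programs = NULL) {
  if (model$mode == "lss") return(model$params)
  if (is.null(t0) || is.null(programs))
    stop("isocratic inversion needs t0 and the run programs")
  df <- model$calibration
  phis <- vapply(df$run, function(r) {
    prg <- programs[[r]]
    if (nrow(prg@nodes) > 1 && stats::sd(prg@nodes$phi) > 0)
      stop("invertToLSS: run '", r, "' is not isocratic")
    prg@nodes$phi[1]
  }, numeric(1))
  if (stats::sd(phis) == 0)
    stop("no phi variation across runs: LSS parameters not identifiable")
  k <- df$observed / t0 - 1
  if (any(k <= 0)) stop("non-positive retention factor encountered")
  fit <- stats::lm(log10(k) ~ phis)
  lssParams(unname(stats::coef(fit)[1]), -unname(stats::coef(fit)[2]))
}

#' Fit retention models for every catalog component
#'
#' Gate and loop: refuses to fit while unresolved alert cells remain in the
#' assignment table (unless `allowAlerts`), skips artifact-flagged entries,
#' and fits each remaining entry with [fitComponent()]. Entries with too few
#' assigned calibration runs are reported and skipped.
#'
#' @param table an `"AssignmentTable"`.
#' @param runs data.frame with `runId`, `role` per run.
#' @param programs named list of per-run [ElutionProgram-class].
#' @param mode `"lss"` or `"pls"` (see [fitComponent()]).
#' @param coded coded design matrix for `"pls"` mode.
#' @param allowAlerts waive the unresolved-alert gate.
#' @param dt integration step for `"lss"` mode.
#' @return named list of `"RetentionModel"` objects.
#' @export
fitRetentionModels <- function(table, runs, programs,
                               mode = c("lss", "pls"), coded = NULL,
                               allowAlerts = FALSE, dt = NULL) {
  mode <- match.arg(mode)
  if (hasAlerts(table) && !allowAlerts)
    stop("unresolved alert cells remain in the assignment table; ",
         "resolve them (applyEdits) or set allowAlerts = TRUE")
  models <- list()
  ids <- rownames(table$tR)
  for (i in seq_along(ids)) {
    if (isTRUE(table$catalog$entries[[i]]$artifact)) next
    tRs <- table$tR[i, ]
    tRs[!table$flags[i, ] %in% c("assigned", "manual")] <- NA
    m <- tryCatch(
      fitComponent(tRs, runs, programs, mode = mode,
                   componentId = ids[i], coded = coded, dt = dt),
      error = function(e) {
        message("skipping ", ids[i], ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(m)) models[[ids[i]]] <- m
  }
  models
}
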