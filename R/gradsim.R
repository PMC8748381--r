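#' Linear solvent strength parameters
#'
#' The retention factor of a solute in reversed phase follows
#' `log10 k = log10 k0 - S * phi + a * (T - Tref)`, where `phi` is the
#' organic-modifier fraction, `S` the solute-specific solvent-strength slope,
#' `k0` the extrapolated retention factor in pure water, and `a` an optional
#' van't-Hoff-like linear temperature coefficient about a reference
#' temperature `Tref`.
#'
#' @param logK0 log10 retention factor at phi = 0 (and T = Tref).
#' @param S solvent-strength slope (positive in reversed phase; a warning is
#'   issued otherwise).
#' @param tempCoef temperature coefficient per degree Celsius (default 0).
#' @param tRef reference temperature, degrees Celsius.
#' @return An object of class `"LSSParams"` (a list).
#' @examples
#' p <- lssParams(logK0 = 2, S = 4)
#' retentionFactor(p, phi = 0.25)  # k = 10
#' @export
lssParams <- function(logK0, S, tempCoef = 0, tRef = 25) {
  stopifnot(is.finite(logK0), is.finite(S))
  if (S <= 0)
    warning("S <= 0 is unusual for reversed-phase retention")
  structure(list(logK0 = logK0, S = S, tempCoef = tempCoef, tRef = tRef),
            class = "LSSParams")
}

#' @rdname lssParams
#' @param params an `"LSSParams"` object.
#' @param phi modifier fraction(s).
#' @param temperature column temperature, degrees Celsius.
#' @export
retentionFactor <- function(params, phi, temperature = params$tRef) {
  10^(params$logK0 - params$S * phi +
        params$tempCoef * (temperature - params$tRef))
}

#' Modifier fraction at the column inlet
#'
#' Evaluates the elution program at time `t`, as experienced by the column
#' inlet: the programmed composition is delayed by the dwell time, linearly
#' interpolated between nodes, and held constant before the first and after
#' the last node.
#'
#' @param program an [ElutionProgram-class].
#' @param t time(s) in minutes (>= 0).
#' @return numeric vector of phi values.
#' @export
phiAt <- function(program, t) {
  nd <- program@nodes
  tEff <- t - program@tDwell
  if (nrow(nd) == 1L) return(rep(nd$phi, length(t)))
  stats::approx(nd$time, nd$phi, xout = pmin(pmax(tEff, nd$time[1]),
                                             nd$time[nrow(nd)]),
                ties = "ordered")$y
}

## Internal: vectorized stepwise-isocratic migration for several solutes.
## Returns data.frame(tR, kElution, eluted). The program is integrated
## numerically while the inlet composition changes; once it is constant
## (isocratic, or past the last node + dwell) the remaining migration is
## finished in closed form, so isocratic retention is exact: tR = t0 (1 + k).
.simulateGradientMany <- function(paramsList, program, dt = program@t0 / 50,
                                  overtime = 3) {
  stopifnot(dt > 0)
  t0 <- program@t0
  temp <- program@temperature
  n <- length(paramsList)
  logK0 <- vapply(paramsList, `[[`, numeric(1), "logK0")
  S <- vapply(paramsList, `[[`, numeric(1), "S")
  aT <- vapply(paramsList, function(p) {
    a <- p$tempCoef; if (is.null(a)) 0 else a
  }, numeric(1))
  tRefs <- vapply(paramsList, function(p) {
    r <- p$tRef; if (is.null(r)) 25 else r
  }, numeric(1))
  kAt <- function(phi) {
    ## phi scalar or vector; returns n x length(phi) matrix
    ex <- outer(-S, phi) + (logK0 + aT * (temp - tRefs))
    10^ex
  }
  nd <- program@nodes
  tFlat <- program@tDwell + nd$time[nrow(nd)]  # inlet constant beyond this
  tG <- nd$time[nrow(nd)]

  x <- numeric(n)          # migrated fraction
  tauEl <- rep(NA_real_, n)
  kEl <- rep(NA_real_, n)
  tau <- 0
  if (tFlat > 0) {
    nSteps <- ceiling(tFlat / dt)
    mids <- (seq_len(nSteps) - 0.5) * dt
    phiMid <- phiAt(program, mids)
    kMat <- kAt(phiMid)                       # n x nSteps
    rate <- matrix(1 / (t0 * kMat), nrow = n) # fraction migrated per minute
    cum <- if (nSteps > 1) t(apply(rate * dt, 1, cumsum)) else rate * dt
    cum <- matrix(cum, nrow = n)
    for (i in seq_len(n)) {
      hit <- which(cum[i, ] >= 1)
      if (length(hit)) {
        s <- hit[1]
        prev <- if (s > 1) cum[i, s - 1] else 0
        tauEl[i] <- (s - 1) * dt + (1 - prev) / rate[i, s]
        kEl[i] <- kMat[i, s]
      } else {
        x[i] <- cum[i, nSteps]
      }
    }
    ## account for the partial last step beyond tFlat
    over <- nSteps * dt - tFlat
    if (over > 0) {
      notEl <- is.na(tauEl)
      x[notEl] <- x[notEl] - rate[notEl, nSteps] * over
    }
    tau <- tFlat
  }
  ## closed-form finish under constant final composition
  notEl <- is.na(tauEl)
  if (any(notEl)) {
    phiEnd <- phiAt(program, tFlat + 1e-9)
    kEnd <- as.numeric(kAt(phiEnd))
    tauEl[notEl] <- tau + (1 - x[notEl]) * t0 * kEnd[notEl]
    kEl[notEl] <- kEnd[notEl]
  }
  tR <- t0 + tauEl
  eluted <- rep(TRUE, n)
  if (tG > 0) {
    limit <- t0 + tFlat + overtime * tG
    eluted <- tR <= limit
  }
  eluted <- eluted & is.finite(tR)
  data.frame(tR = tR, kElution = kEl, eluted = eluted)
}

#' Simulate gradient retention by small isocratic steps
#'
#' Integrates solute migration under an arbitrary elution program: in each
#' small time step the solute advances a fraction `dt / (t0 * k(phi(t)))` of
#' the column, with `k` from the linear solvent strength relation at the
#' composition currently at the inlet (dwell-delayed); the solute elutes when
#' the accumulated fraction reaches 1, with linear interpolation inside the
#' final step. Once the program composition is constant the remaining
#' migration is completed in closed form, so isocratic retention is exact:
#' `tR = t0 * (1 + k)`.
#'
#' @param params an `"LSSParams"` object (see [lssParams()]), or a list of
#'   them.
#' @param program an [ElutionProgram-class].
#' @param dt integration step in minutes (default `t0 / 50`).
#' @param overtime multiple of the gradient time for which elution is allowed
#'   to continue under final-node conditions before a solute is flagged
#'   non-eluting (default 3).
#' @return For a single parameter set, a list with `tR` (minutes),
#'   `kElution` (retention factor at the moment of elution) and `eluted`
#'   (logical). For a list of sets, a data.frame with one row per solute.
#' @examples
#' p <- lssParams(logK0 = 2, S = 4)
#' simulateGradient(p, elutionProgram(0.25, t0 = 1))$tR  # 1 * (1 + 10) = 11
#' @export
simulateGradient <- function(params, program, dt = program@t0 / 50,
                             overtime = 3) {
  single <- inherits(params, "LSSParams")
  pl <- if (single) list(params) else params
  res <- .simulateGradientMany(pl, program, dt = dt, overtime = overtime)
  if (single) as.list(res[1, ]) else res
}

#' Gaussian peak standard deviation from the plate model
#'
#' `sigma_t = t0 * (1 + kElution) / sqrt(plates)`: the isocratic plate-count
#' width at the retention factor prevailing when the solute leaves the
#' column. Gradient peak compression is not modelled.
#'
#' @param kElution retention factor at elution.
#' @param t0 dead time, minutes.
#' @param plates column plate number (> 0).
#' @return peak standard deviation in minutes.
#' @export
peakSigma <- function(kElution, t0, plates) {
  stopifnot(plates > 0)
  t0 * (1 + kElution) / sqrt(plates)
}

#' Pairwise and critical resolution
#'
#' Scores adjacent-in-time peak pairs with the 4-sigma baseline-width
#' convention `Rs = (tR_j - tR_i) / (2 * (sigma_i + sigma_j))` and reports
#' the critical (minimum) resolution. A single peak yields `criticalRs =
#' Inf`.
#'
#' @param tR retention times, minutes.
#' @param sigma peak standard deviations, minutes.
#' @return list with `pairs` (data.frame `i`, `j`, `Rs` in elution order,
#'   indices referring to the input order) and `criticalRs`.
#' @export
resolutions <- function(tR, sigma) {
  stopifnot(length(tR) == length(sigma), length(tR) >= 1)
  ord <- order(tR)
  if (length(tR) == 1L)
    return(list(pairs = data.frame(i = integer(), j = integer(),
                                   Rs = numeric()),
                criticalRs = Inf))
  i <- ord[-length(ord)]
  j <- ord[-1]
  Rs <- (tR[j] - tR[i]) / (2 * (sigma[i] + sigma[j]))
  list(pairs = data.frame(i = i, j = j, Rs = Rs), criticalRs = min(Rs))
}

#' Simulate a full separation and score it
#'
#' Runs [simulateGradient()] for every component, converts retention factors
#' at elution into Gaussian peak widths via [peakSigma()], and scores the
#' separation with [resolutions()]. Non-eluting components are reported but
#' excluded from the resolution scoring.
#'
#' @param paramsList list of `"LSSParams"` objects (optionally named).
#' @param program an [ElutionProgram-class].
#' @param plates column plate number.
#' @param dt integration step, minutes.
#' @param overtime see [simulateGradient()].
#' @return list with `components` (data.frame name, tR, sigma, kElution,
#'   eluted, sorted by tR), `pairs`, `criticalRs`, and `runtime` (elution
#'   time of the last eluting component, minutes).
#' @export
simulateSeparation <- function(paramsList, program, plates = 10000,
                               dt = program@t0 / 50, overtime = 3) {
  res <- .simulateGradientMany(paramsList, program, dt = dt,
                               overtime = overtime)
  nm <- names(paramsList)
  if (is.null(nm)) nm <- paste0("C", seq_along(paramsList))
  comp <- data.frame(name = nm, tR = res$tR, kElution = res$kElution,
                     sigma = peakSigma(res$kElution, program@t0, plates),
                     eluted = res$eluted)
  comp <- comp[order(comp$tR), ]
  el <- comp[comp$eluted, ]
  if (nrow(el) == 0)
    return(list(components = comp,
                pairs = data.frame(i = integer(), j = integer(),
                                   Rs = numeric()),
                criticalRs = 0, runtime = Inf))
  rs <- resolutions(el$tR, el$sigma)
  list(components = comp, pairs = rs$pairs, criticalRs = rs$criticalRs,
       runtime = max(el$tR))
}
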