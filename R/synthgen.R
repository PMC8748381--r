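#' Define a ground-truth mixture component
#'
#' @param name component name.
#' @param lss `"LSSParams"` from [lssParams()].
#' @param uvSpectrum non-negative spectrum on the campaign's UV channel
#'   axis; normalized to unit maximum.
#' @param msSpectrum optional named numeric vector (names = integer m/z) of
#'   relative intensities in (0, 100], base peak = 100.
#' @param amount injected amount in arbitrary response units (> 0); the
#'   flow-corrected peak area of the component in every run.
#' @return A `"TrueComponent"` list.
#' @export
trueComponent <- function(name, lss, uvSpectrum, msSpectrum = NULL,
                          amount = 1) {
  stopifnot(inherits(lss, "LSSParams"), all(uvSpectrum >= 0), amount > 0)
  if (max(uvSpectrum) <= 0) stop("uvSpectrum must have a positive maximum")
  uvSpectrum <- uvSpectrum / max(uvSpectrum)
  if (!is.null(msSpectrum)) {
    stopifnot(all(msSpectrum > 0), !is.null(names(msSpectrum)))
    msSpectrum <- msSpectrum / max(msSpectrum) * 100
  }
  structure(list(name = name, lss = lss, uvSpectrum = uvSpectrum,
                 msSpectrum = msSpectrum, amount = amount),
            class = "TrueComponent")
}

#' Random smooth UV spectra with bounded pairwise correlation
#'
#' Draws spectra as sums of 2-4 Gaussian absorption bands over the channel
#' axis, unit-maximum normalized, resampling until all pairwise Pearson
#' correlations are below `maxR`.
#'
#' @param n number of spectra.
#' @param channels wavelength axis (nm).
#' @param maxR maximum allowed pairwise correlation.
#' @param maxTries resampling budget.
#' @return matrix `length(channels)` x `n`.
#' @export
randomSpectra <- function(n, channels, maxR = 0.9, maxTries = 200) {
  draw <- function() {
    nb <- sample(2:4, 1)
    ctr <- stats::runif(nb, min(channels), max(channels))
    wid <- stats::runif(nb, 0.03, 0.15) * diff(range(channels))
    amp <- stats::runif(nb, 0.3, 1)
    s <- colSums(amp * t(vapply(seq_len(nb), function(b)
      exp(-0.5 * ((channels - ctr[b]) / wid[b])^2),
      numeric(length(channels)))))
    s / max(s)
  }
  out <- matrix(0, length(channels), n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(maxTries)) {
      cand <- draw()
      if (i == 1 ||
          max(abs(stats::cor(cand, out[, seq_len(i - 1), drop = FALSE]))) <
            maxR) { ok <- TRUE; break }
    }
    if (!ok) stop("could not draw ", n, " spectra with pairwise |r| < ", maxR)
    out[, i] <- cand
  }
  out
}

#' Specify a synthetic screening campaign
#'
#' Bundles the ground-truth components, the experimental design and the
#' acquisition/noise model that [simulateCampaign()] realizes. Defaults are
#' the package's reference screening conditions: 5 points/s sampling, column
#' plate number 5000, dead time 1 min, amounts spanning up to 10x and
#' detector noise giving an apex signal-to-noise near 100 when left at
#' `noiseSD = 1e-3` with unit amounts.
#'
#' @param components list of [trueComponent()] objects.
#' @param design a `"DesignMatrix"` (see [screeningDesign()]).
#' @param channels UV channel axis, nm.
#' @param plates column plate number.
#' @param noiseSD iid Gaussian detector noise, absorbance units per cell.
#' @param baselineAmp amplitude of the low-order polynomial baseline drift
#'   (0 disables).
#' @param injectionAmp amplitude of the broad early-eluting injection hump
#'   that emulates maxplot artifact peaks (0 disables).
#' @param samplingRate detector sampling rate, points per second.
#' @param t0 dead time, minutes.
#' @param tDwell dwell time, minutes.
#' @param flow flow rate, mL/min.
#' @param columnId column identifier.
#' @param phiInitDefault,phiFinalDefault,tGDefault,tempDefault program
#'   parameters used when the corresponding role is absent from the design.
#' @param withMS also emit binned MS chromatograms for components carrying
#'   MS spectra.
#' @param seed integer seed; a fixed seed makes the campaign bit-identical.
#' @return A `"CampaignSpec"` list.
#' @export
campaignSpec <- function(components, design, channels = seq(210, 400, by = 5),
                         plates = 5000, noiseSD = 1e-3, baselineAmp = 0,
                         injectionAmp = 0, samplingRate = 5, t0 = 1,
                         tDwell = 0, flow = 1, columnId = "colA",
                         phiInitDefault = 0.05, phiFinalDefault = 0.95,
                         tGDefault = 10, tempDefault = 25, withMS = FALSE,
                         seed = 1) {
  stopifnot(samplingRate > 0, noiseSD >= 0, inherits(design, "DesignMatrix"))
  structure(list(components = components, design = design,
                 channels = channels, plates = plates, noiseSD = noiseSD,
                 baselineAmp = baselineAmp, injectionAmp = injectionAmp,
                 samplingRate = samplingRate, t0 = t0, tDwell = tDwell,
                 flow = flow, columnId = columnId,
                 phiInitDefault = phiInitDefault,
                 phiFinalDefault = phiFinalDefault, tGDefault = tGDefault,
                 tempDefault = tempDefault, withMS = withMS, seed = seed),
            class = "CampaignSpec")
}

#' Elution program for one design run
#'
#' Maps the design row's factor roles onto a single-segment linear program:
#' `gradient_time` sets the ramp duration, `phi_initial`/`phi_final` its end
#' points, `temperature` the column temperature; spec defaults fill any
#' missing role.
#'
#' @param spec a `"CampaignSpec"`.
#' @param runIndex row of the design.
#' @return An [ElutionProgram-class].
#' @export
programForRun <- function(spec, runIndex) {
  dm <- spec$design
  stopifnot(runIndex >= 1, runIndex <= nrow(dm$real))
  roles <- vapply(dm$factors, `[[`, character(1), "role")
  val <- function(role, default) {
    i <- which(roles == role)
    if (length(i)) dm$real[runIndex, i[1]] else default
  }
  phiI <- val("phi_initial", spec$phiInitDefault)
  phiF <- val("phi_final", spec$phiFinalDefault)
  tG <- val("gradient_time", spec$tGDefault)
  temp <- val("temperature", spec$tempDefault)
  elutionProgram(data.frame(time = c(0, tG), phi = c(phiI, phiF)),
                 temperature = temp, t0 = spec$t0, tDwell = spec$tDwell,
                 flow = spec$flow)
}

## Smooth fixed pseudo-spectrum used for baseline drift / injection hump;
## deterministic in the channel axis so artifacts are reproducible.
.driftSpectrum <- function(channels) {
  x <- (channels - min(channels)) / diff(range(channels))
  s <- 0.6 + 0.4 * cos(2.2 * x) + 0.25 * x
  s / max(s)
}

#' Simulate one screening run
#'
#' Each component elutes as a Gaussian centred at the retention time given
#' by [simulateGradient()] under the run's program, with plate-model width
#' and area equal to its amount divided by the flow rate; the data matrix is
#' the bilinear sum of profile x spectrum outer products plus optional
#' baseline drift, injection hump, and iid Gaussian noise (which may leave
#' slightly negative values, as real autozeroed detectors do).
#'
#' @param spec a `"CampaignSpec"`.
#' @param runIndex design row to simulate.
#' @return list with `uv` (a UV [Chromatogram-class]), `ms` (an MS
#'   [Chromatogram-class] or NULL), and `truth` (data.frame component, tR,
#'   sigma, eluted, truncated).
#' @export
simulateRun <- function(spec, runIndex) {
  prog <- programForRun(spec, runIndex)
  n <- length(spec$components)
  dtSamp <- 1 / (spec$samplingRate * 60)   # minutes between points
  tGend <- prog@nodes$time[nrow(prog@nodes)]
  if (n > 0) {
    sim <- simulateGradient(lapply(spec$components, `[[`, "lss"), prog,
                            dt = spec$t0 / 100)
    sig <- peakSigma(sim$kElution, spec$t0, spec$plates)
    tEnd <- max(spec$t0 + tGend + 2 * spec$t0,
                max(sim$tR[sim$eluted] + 6 * sig[sim$eluted],
                    -Inf, na.rm = TRUE))
  } else {
    sim <- NULL
    tEnd <- spec$t0 + tGend + 2 * spec$t0
  }
  time <- seq(dtSamp, tEnd, by = dtSamp)
  nm <- vapply(spec$components, `[[`, character(1), "name")
  X <- matrix(0, length(time), length(spec$channels))
  truth <- data.frame(component = character(), tR = numeric(),
                      sigma = numeric(), eluted = logical(),
                      truncated = logical())
  C <- NULL
  if (n > 0) {
    C <- matrix(0, length(time), n)
    for (i in seq_len(n)) {
      if (!is.finite(sim$tR[i]) || !is.finite(sig[i])) next
      comp <- spec$components[[i]]
      area <- comp$amount / spec$flow
      prof <- area / (sig[i] * sqrt(2 * pi)) *
        exp(-0.5 * ((time - sim$tR[i]) / sig[i])^2)
      C[, i] <- prof
      X <- X + prof %o% comp$uvSpectrum
    }
    truth <- data.frame(component = nm, tR = sim$tR, sigma = sig,
                        eluted = sim$eluted,
                        truncated = sim$tR + 3 * sig > tEnd | !sim$eluted)
  }
  runSeed <- spec$seed * 1000L + runIndex
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(runSeed)
  if (spec$baselineAmp > 0) {
    u <- time / max(time)
    drift <- spec$baselineAmp * (0.3 + 0.7 * u - 0.4 * u^2)
    X <- X + drift %o% .driftSpectrum(spec$channels)
  }
  if (spec$injectionAmp > 0) {
    hump <- spec$injectionAmp *
      exp(-0.5 * ((time - spec$t0) / (0.4 * spec$t0))^2)
    X <- X + hump %o% rev(.driftSpectrum(spec$channels))
  }
  if (spec$noiseSD > 0)
    X <- X + matrix(stats::rnorm(length(X), sd = spec$noiseSD), nrow(X))
  dmRoles <- spec$design$roles
  meta <- list(program = prog, temperature = prog@temperature,
               flow = spec$flow, columnId = spec$columnId,
               role = dmRoles[runIndex])
  rid <- spec$design$runIds[runIndex]
  uv <- chromatogram(rid, time, spec$channels, X, detector = "UV",
                     meta = meta)
  ms <- NULL
  if (isTRUE(spec$withMS) && n > 0) {
    allMz <- sort(unique(as.numeric(unlist(lapply(spec$components, function(co)
      names(co$msSpectrum))))))
    if (length(allMz)) {
      ## MS sampled on a coarser grid (1 scan/s)
      msTime <- seq(1 / 60, tEnd, by = 1 / 60)
      M <- matrix(0, length(msTime), length(allMz))
      for (i in seq_len(n)) {
        comp <- spec$components[[i]]
        if (is.null(comp$msSpectrum)) next
        area <- comp$amount / spec$flow
        prof <- area / (sig[i] * sqrt(2 * pi)) *
          exp(-0.5 * ((msTime - sim$tR[i]) / sig[i])^2)
        idx <- match(as.numeric(names(comp$msSpectrum)), allMz)
        M[, idx] <- M[, idx] + prof %o% (comp$msSpectrum / 100)
      }
      if (spec$noiseSD > 0)
        M <- M + matrix(stats::rnorm(length(M), sd = spec$noiseSD), nrow(M))
      ms <- chromatogram(rid, msTime, allMz, M, detector = "MS",
                         axisKind = "mz", meta = meta)
    }
  }
  list(uv = uv, ms = ms, truth = truth)
}

#' Simulate a complete screening campaign
#'
#' One chromatogram per design row (UV, plus MS when configured), with a
#' ground-truth table of every component's true retention time in every run.
#'
#' @param spec a `"CampaignSpec"`.
#' @return list with `chromatograms` (list of UV [Chromatogram-class]),
#'   `msChromatograms` (list or NULL entries), and `groundTruth`
#'   (data.frame run, component, tR, sigma, eluted, truncated).
#' @export
simulateCampaign <- function(spec) {
  nRuns <- nrow(spec$design$real)
  uv <- vector("list", nRuns)
  ms <- vector("list", nRuns)
  gt <- list()
  for (r in seq_len(nRuns)) {
    res <- simulateRun(spec, r)
    uv[[r]] <- res$uv
    ms[[r]] <- res$ms
    if (nrow(res$truth))
      gt[[r]] <- cbind(run = spec$design$runIds[r], res$truth)
  }
  names(uv) <- spec$design$runIds
  list(chromatograms = uv, msChromatograms = ms,
       groundTruth = if (length(gt)) do.call(rbind, gt)
                     else data.frame(run = character(),
                                     component = character(),
                                     tR = numeric(), sigma = numeric(),
                                     eluted = logical(),
                                     truncated = logical()))
}

#' Reference synthetic campaign
#'
#' Builds the package's standard test campaign: `n` components with random
#' smooth UV spectra (pairwise |r| < `maxR`), LSS parameters drawn from
#' ranges typical for small phenolics in acetonitrile/water (log10 k0 in
#' 1.2-3, S in 3-8), amounts spanning 10x (0.1 to 1), under a 3-factor
#' (gradient time 5-15 min, final modifier fraction 0.6-1.0, temperature
#' 25-45 degC) 8-run screening design plus one intermediate validation run.
#' The default detector noise (0.013 response units per cell) puts the apex
#' signal-to-noise of the smallest component near 100 for typical peak
#' widths: discovery is nontrivial but solvable.
#'
#' @param n number of components.
#' @param seed integer seed.
#' @param maxR maximum pairwise spectral correlation.
#' @param withMS attach simple MS spectra (1-4 ions) and emit MS runs.
#' @param noiseSD detector noise standard deviation.
#' @param ... passed on to [campaignSpec()].
#' @return A `"CampaignSpec"`.
#' @export
referenceCampaign <- function(n = 6, seed = 1, maxR = 0.9, withMS = FALSE,
                              noiseSD = 0.013, ...) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  channels <- seq(210, 400, by = 5)
  specs <- randomSpectra(n, channels, maxR = maxR)
  logK0 <- stats::runif(n, 1.2, 3)
  S <- stats::runif(n, 3, 8)
  aT <- stats::runif(n, -0.008, -0.002)
  amounts <- 10^stats::runif(n, -1, 0)
  comps <- lapply(seq_len(n), function(i) {
    msSpec <- NULL
    if (withMS) {
      nIon <- sample(1:4, 1)
      mz <- sample(80:500, nIon)
      inten <- c(100, stats::runif(nIon - 1, 5, 80))
      msSpec <- stats::setNames(inten, mz)
    }
    trueComponent(sprintf("comp%02d", i),
                  lssParams(logK0[i], S[i], tempCoef = aT[i], tRef = 35),
                  specs[, i], msSpectrum = msSpec, amount = amounts[i])
  })
  dm <- screeningDesign(list(
    factorDef("tG", "gradient_time", 5, 15),
    factorDef("phiFinal", "phi_final", 0.6, 1.0),
    factorDef("T", "temperature", 25, 45)))
  dm <- addValidationRuns(dm, 1, "intermediate")
  campaignSpec(comps, dm, channels = channels, withMS = withMS, seed = seed,
               noiseSD = noiseSD, ...)
}
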