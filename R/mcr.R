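## Fast non-negative least squares for many right-hand sides.
## min ||A %*% b - y||^2 s.t. b >= 0, columnwise over Y. The unconstrained
## normal-equation solution is used wherever it is already feasible; only
## offending columns fall back to Lawson-Hanson active sets on the (tiny,
## r <= 6) normal equations.
.nnlsMulti <- function(A, Y) {
  AtA <- crossprod(A)
  AtY <- crossprod(A, Y)
  r <- ncol(A)
  ridge <- diag(1e-12 * max(diag(AtA), 1), r)
  B <- tryCatch(solve(AtA + ridge, AtY),
                error = function(e) matrix(0, r, ncol(Y)))
  bad <- which(apply(B < -1e-12, 2, any))
  for (j in bad)
    B[, j] <- .nnlsOne(AtA, AtY[, j])
  B[B < 0] <- 0
  B
}

## Lawson-Hanson NNLS on precomputed normal equations.
.nnlsOne <- function(AtA, Aty, tol = 1e-10, maxIter = 200) {
  r <- length(Aty)
  P <- logical(r)
  x <- numeric(r)
  w <- Aty
  it <- 0
  while (any(!P) && any(w[!P] > tol * max(abs(Aty), 1)) && it < maxIter) {
    it <- it + 1
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(r)
      s[P] <- tryCatch(
        solve(AtA[P, P, drop = FALSE] +
                diag(1e-12 * max(diag(AtA), 1), sum(P)), Aty[P]),
        error = function(e) rep(0, sum(P)))
      if (all(s[P] > tol)) { x <- s; break }
      neg <- P & (s <= tol)
      alpha <- suppressWarnings(min(x[neg] / (x[neg] - s[neg]), na.rm = TRUE))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (s - x)
      P[P & (x <= tol)] <- FALSE
      x[!P] <- 0
      if (!any(P)) break
    }
    w <- Aty - AtA %*% x
  }
  pmax(x, 0)
}

## Unimodal projection of a non-negative profile: monotone rise up to the
## column maximum, monotone fall after it (isotonic regression each side).
.unimodalProfile <- function(y) {
  m <- which.max(y)
  n <- length(y)
  out <- y
  if (m > 1)
    out[1:m] <- stats::isoreg(seq_len(m), y[1:m])$yf
  if (m < n)
    out[m:n] <- rev(stats::isoreg(seq_len(n - m + 1), rev(y[m:n]))$yf)
  pmax(out, 0)
}

#' SIMPLISMA pure-variable selection
#'
#' Selects the "purest" time points of a cluster matrix as initial spectral
#' estimates for alternating least squares. Purity of a time point is
#' `p_i = sigma_i / (mu_i + alpha)` (mean and standard deviation across
#' channels), with `alpha` set to `alphaPct` percent of the maximum of the
#' mean spectrum to keep low-signal noise rows from scoring high. After
#' each selection, candidate purities are down-weighted by the determinant
#' of the correlation-around-origin matrix of the candidate together with
#' the rows already selected, which drives successive selections toward
#' directions independent of those found before.
#'
#' @param X non-negative cluster matrix (time x channel).
#' @param nMax maximum number of pure variables to select (>= 1).
#' @param alphaPct noise offset, percent of the mean-spectrum maximum
#'   (default 3; literature-typical range 1-5).
#' @return list with `spectra` (channel x nSelected matrix, the rows of `X`
#'   at the selected time points, unit-Euclidean-normalized), `purity`
#'   (weighted purity score at each selection, non-increasing), `indices`
#'   (selected row indices).
#' @export
simplisma <- function(X, nMax, alphaPct = 3) {
  stopifnot(nMax >= 1, alphaPct > 0)
  X <- as.matrix(X)
  if (all(X <= 0)) stop("simplisma: all-zero cluster matrix")
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  alpha <- alphaPct / 100 * max(colMeans(X))
  p1 <- sdv / (mu + alpha)
  lam <- sqrt(mu^2 + (sdv + alpha)^2)
  Z <- X / lam                        # length-corrected rows
  Zn <- Z / sqrt(rowSums(Z^2))        # COO-normalized rows
  sel <- integer()
  pur <- numeric()
  for (s in seq_len(nMax)) {
    w <- vapply(seq_len(nrow(X)), function(i) {
      idx <- c(i, sel)
      G <- tcrossprod(Zn[idx, , drop = FALSE])
      det(G)
    }, numeric(1))
    w[sel] <- -Inf
    score <- w * p1
    j <- which.max(score)
    if (!is.finite(score[j]) || score[j] <= 0) break
    sel <- c(sel, j)
    pur <- c(pur, score[j])
  }
  Sp <- t(X[sel, , drop = FALSE])
  nrm <- sqrt(colSums(Sp^2))
  nrm[nrm == 0] <- 1
  list(spectra = sweep(Sp, 2, nrm, `/`), purity = pur, indices = sel)
}

#' MCR-ALS bilinear curve resolution
#'
#' Alternating least squares for the bilinear model `X = C S^T + E`, with
#' non-negativity on concentration profiles `C` and spectra `S` and
#' (optionally) unimodality on each profile column, starting from initial
#' spectral estimates (typically [simplisma()] output). Iterations stop when
#' the relative change of the lack of fit
#' `lof = 100 * sqrt(sum(E^2) / sum(X^2))` falls below `tol`, or after
#' `maxIter` iterations; a fit whose lof rises for more than 10 consecutive
#' iterations is flagged non-converged. The best (lowest-lof) accepted state
#' is returned, so the lof of the returned trajectory is non-increasing.
#'
#' @param X cluster matrix (time x channel); negative entries are clipped
#'   to zero first (noise/autozero artifacts).
#' @param initSpectra channel x rank matrix of initial spectra.
#' @param constraints character subset of `c("nonneg", "unimodal")`.
#' @param tol relative lof-change tolerance (default 1e-6).
#' @param maxIter maximum iterations (default 500).
#' @return A `"BilinearFit"` list: `C` (time x rank), `S` (channel x rank,
#'   unit-Euclidean columns), `E`, `lof` (percent), `nIter`, `converged`,
#'   `lofTrace` (accepted-state lof values).
#' @export
mcrALS <- function(X, initSpectra, constraints = c("nonneg", "unimodal"),
                   tol = 1e-6, maxIter = 500) {
  X <- as.matrix(X)
  X[X < 0] <- 0
  r <- ncol(initSpectra)
  if (r > min(dim(X)))
    stop("rank ", r, " exceeds cluster dimensions ", paste(dim(X),
         collapse = "x"))
  S <- as.matrix(initSpectra)
  ssx <- sum(X^2)
  unimodal <- "unimodal" %in% constraints
  best <- NULL
  bestLof <- Inf
  lofPrev <- Inf
  rising <- 0
  lofTrace <- numeric()
  converged <- FALSE
  it <- 0
  while (it < maxIter) {
    it <- it + 1
    C <- t(.nnlsMulti(S, t(X)))
    if (unimodal)
      for (j in seq_len(r)) C[, j] <- .unimodalProfile(C[, j])
    St <- .nnlsMulti(C, X)            # rank x channel
    S <- t(St)
    nrm <- sqrt(colSums(S^2))
    nrm[nrm == 0] <- 1
    S <- sweep(S, 2, nrm, `/`)
    C <- sweep(C, 2, nrm, `*`)
    E <- X - tcrossprod(C, S)
    lof <- 100 * sqrt(sum(E^2) / ssx)
    if (lof <= bestLof) {
      best <- list(C = C, S = S, E = E, lof = lof)
      bestLof <- lof
      lofTrace <- c(lofTrace, lof)
      rising <- 0
    } else rising <- rising + 1
    if (is.finite(lofPrev) &&
        abs(lofPrev - lof) / max(lofPrev, .Machine$double.eps) < tol) {
      converged <- TRUE
      break
    }
    if (rising > 10) break
    lofPrev <- lof
  }
  structure(c(best, list(nIter = it, converged = converged,
                         lofTrace = lofTrace)),
            class = "BilinearFit")
}

#' Estimate the chemical rank of a peak cluster
#'
#' A candidate rank is taken from the singular values of the (clipped)
#' cluster matrix that exceed a noise floor estimated from the cluster's
#' edge rows, capped at `cap` components per cluster. Constrained fits of
#' ranks 1..candidate are then computed and the smallest rank whose lack of
#' fit falls below `lofThreshold` percent is returned.
#'
#' @param X cluster matrix (time x channel).
#' @param cap maximum admitted rank (default 6); raising it triggers a
#'   warning, since overfitting past six components per cluster mostly
#'   produces false positives.
#' @param lofThreshold percent lof below which a rank is accepted
#'   (default 2).
#' @param alphaPct SIMPLISMA offset for the trial fits.
#' @param maxIter ALS iteration cap for the trial fits.
#' @return integer rank (0 for a cluster indistinguishable from noise).
#' @export
estimateRank <- function(X, cap = 6, lofThreshold = 2, alphaPct = 3,
                         maxIter = 100) {
  if (cap > 6)
    warning("rank cap above 6: expect false-positive components")
  X <- as.matrix(X)
  X[X < 0] <- 0
  m <- nrow(X)
  edge <- unique(c(seq_len(max(2, floor(0.1 * m))),
                   seq(m - max(2, floor(0.1 * m)) + 1, m)))
  noise <- stats::sd(X[edge, ] - rowMeans(X[edge, , drop = FALSE]))
  if (!is.finite(noise)) noise <- 0
  sv <- svd(X, nu = 0, nv = 0)$d
  floorSv <- max(noise * (sqrt(nrow(X)) + sqrt(ncol(X))),
                 1e-12 * sv[1])
  cand <- min(sum(sv > floorSv), cap, min(dim(X)))
  if (cand == 0) return(0L)
  ## signal gate: the cluster maximum must stand clear of the baseline by
  ## more than the expected extreme of the cell noise over all cells
  kDet <- 2 + sqrt(2 * log(2 * length(X)))
  if (max(X) - stats::median(X) <= kDet * noise) return(0L)
  for (r in seq_len(cand)) {
    init <- simplisma(X, r, alphaPct)
    if (ncol(init$spectra) < r) next
    fit <- mcrALS(X, init$spectra, maxIter = maxIter)
    if (fit$lof < lofThreshold) return(r)
  }
  as.integer(cand)
}

#' Count MS noise signals above the 0.1 percent rule
#'
#' Number of signals, base peak excluded, exceeding 0.1 percent of the base
#' peak in the normalized ESI spectrum; a crowded small-signal spectrum
#' marks a noise component.
#'
#' @param msSpectrum numeric vector of intensities (any scale).
#' @param thresholdPct relative threshold, percent of base peak
#'   (default 0.1).
#' @return integer count.
#' @export
msNoiseCount <- function(msSpectrum, thresholdPct = 0.1) {
  if (length(msSpectrum) == 0) return(0L)
  rel <- msSpectrum / max(msSpectrum) * 100
  sum(rel > thresholdPct) - 1L   # base peak always passes; exclude it
}

#' Extract per-component results from a cluster fit
#'
#' Turns a [mcrALS()] fit of one peak cluster into a list of extracted
#' components: elution profile, unit spectrum, apex time, SIMPLISMA purity
#' (lenient screen: components below `uvPurityMin` times the cluster's top
#' purity are dropped, so true components are not lost at this stage), a
#' coelution flag (`pure` iff the cluster fit has rank 1), and a truncation
#' flag when the profile maximum sits on the cluster boundary.
#'
#' @param fit a `"BilinearFit"`.
#' @param cluster the `"PeakCluster"` the fit came from (must carry `time`).
#' @param purity numeric purity scores from [simplisma()], one per
#'   component (recycled as NA if absent).
#' @param uvPurityMin relative purity floor (default 0.05).
#' @param msNoiseMax drop components whose attached MS spectrum has
#'   [msNoiseCount()] above this (default Inf = no MS screen here).
#' @return list of `"ExtractedComponent"` lists.
#' @export
extractComponents <- function(fit, cluster, purity = NULL,
                              uvPurityMin = 0.05, msNoiseMax = Inf) {
  r <- ncol(fit$C)
  if (is.null(purity)) purity <- rep(NA_real_, r)
  purity <- rep_len(purity, r)
  keep <- if (all(is.na(purity))) rep(TRUE, r)
          else purity >= uvPurityMin * max(purity, na.rm = TRUE)
  out <- list()
  for (j in seq_len(r)) {
    if (!keep[j]) next
    prof <- fit$C[, j]
    if (max(prof) <= 0) next
    apexIdx <- which.max(prof)
    out[[length(out) + 1]] <- structure(list(
      runId = cluster$runId,
      clusterId = if (is.null(cluster$clusterId)) NA_character_
                  else cluster$clusterId,
      profile = prof,
      spectrum = fit$S[, j],
      apexTime = cluster$time[apexIdx],
      purity = purity[j],
      pure = (r == 1L),
      truncated = apexIdx == 1L || apexIdx == length(prof),
      msSpectrum = NULL,
      noiseCount = NA_integer_), class = "ExtractedComponent")
  }
  out
}

#' Resolve every cluster of a chromatogram
#'
#' Runs rank estimation, SIMPLISMA initialization and constrained MCR-ALS on
#' each peak cluster of a chromatogram and collects the surviving extracted
#' components.
#'
#' @param chrom a [Chromatogram-class].
#' @param rankCap maximum components per cluster (default 6).
#' @param lofThreshold rank-selection lof threshold, percent.
#' @param alphaPct SIMPLISMA offset percent.
#' @param uvPurityMin relative purity floor for [extractComponents()].
#' @param ... passed to [peakClusters()].
#' @return list with `components` (list of `"ExtractedComponent"`),
#'   `clusters`, `fits`.
#' @export
resolveChromatogram <- function(chrom, rankCap = 6, lofThreshold = 2,
                                alphaPct = 3, uvPurityMin = 0.05, ...) {
  cls <- peakClusters(chrom, ...)
  comps <- list()
  fits <- list()
  for (cl in cls) {
    X <- pmax(cl$submatrix, 0)
    if (all(X <= 0)) next
    r <- estimateRank(X, cap = rankCap, lofThreshold = lofThreshold,
                      alphaPct = alphaPct)
    if (r == 0) next
    init <- simplisma(X, r, alphaPct)
    r <- ncol(init$spectra)
    fit <- mcrALS(X, init$spectra)
    cc <- extractComponents(fit, cl, purity = init$purity,
                            uvPurityMin = uvPurityMin)
    comps <- c(comps, cc)
    fits[[length(fits) + 1]] <- fit
  }
  list(components = comps, clusters = cls, fits = fits)
}
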