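#' Summary traces: maxplot and TIC
#'
#' `maxplot` is the per-time-point maximum of the DAD absorbance over all
#' wavelengths (clipped at zero), a wavelength-agnostic trace that avoids
#' false negatives from an unlucky single-channel choice. `tic` is the
#' total ion chromatogram, the per-scan sum of MS intensities.
#'
#' @param chrom a [Chromatogram-class] (`UV` for `maxplot`, `MS` for `tic`).
#' @return A `"SummaryTrace"` list with `time`, `value`, `kind`.
#' @export
maxplot <- function(chrom) {
  stopifnot(is(chrom, "Chromatogram"))
  if (chrom@detector != "UV") stop("maxplot requires a UV chromatogram")
  v <- pmax(apply(chrom@intensity, 1, max), 0)
  structure(list(time = chrom@time, value = v, kind = "maxplot"),
            class = "SummaryTrace")
}

#' @rdname maxplot
#' @export
tic <- function(chrom) {
  stopifnot(is(chrom, "Chromatogram"))
  if (chrom@detector != "MS") stop("tic requires an MS chromatogram")
  structure(list(time = chrom@time, value = rowSums(chrom@intensity),
                 kind = "tic"), class = "SummaryTrace")
}

## Savitzky-Golay smoothing and second derivative of a trace value vector.
.sgSmooth <- function(v, window = 11, order = 3, deriv = 0) {
  window <- min(window, if (length(v) %% 2 == 0) length(v) - 1 else length(v))
  if (window %% 2 == 0) window <- window - 1
  if (window <= order) return(if (deriv == 0) v else rep(0, length(v)))
  as.numeric(signal::sgolayfilt(v, p = order, n = window, m = deriv))
}

## Robust noise level from the most quiescent fraction of the trace:
## 1.4826 * MAD of the first difference over baseline candidates, scaled by
## 1/sqrt(2) because differencing doubles the variance.
.noiseLevel <- function(value) {
  q <- stats::quantile(value, 0.25)
  idx <- which(value <= q)
  d <- diff(value[idx])
  d <- d[is.finite(d)]
  n <- 1.4826 * stats::median(abs(d)) / sqrt(2)
  if (!is.finite(n) || n == 0) n <- max(1.4826 * stats::median(abs(diff(value))) /
                                          sqrt(2), .Machine$double.eps)
  n
}

## Baseline model of a summary trace: the quiescent level b0 (the maxplot
## baseline rides at a positive offset, the expected maximum of the channel
## noise), the raw noise, and the residual ripple left in the smoothed
## trace. Baseline points are those with sm <= b0 + noiseK * ripple.
.baselineModel <- function(v, sm, noiseK) {
  idx <- which(v <= stats::median(v))
  b0 <- stats::median(sm[idx])
  noise <- .noiseLevel(v)
  ripple <- stats::sd(sm[idx])
  if (!is.finite(ripple) || ripple == 0) ripple <- noise
  amp <- max(noise, ripple)
  list(b0 = b0, noise = noise, amp = amp,
       threshold = b0 + noiseK * amp,
       mask = sm <= b0 + noiseK * amp)
}

#' Segment a summary trace into baseline-delimited peak clusters
#'
#' Negative trace values are clipped to zero, the trace is smoothed by
#' Savitzky-Golay local polynomial regression, a robust noise level is
#' estimated from the most quiescent trace fraction, and stretches whose
#' smoothed value stays at or below `noiseK * noise` for at least
#' `minPoints` consecutive samples are declared baseline. Maximal
#' non-baseline stretches become clusters, extended to the adjacent
#' baseline sample on each side; apexes are local maxima of the smoothed
#' trace where its smoothed second derivative is negative.
#'
#' @param trace a `"SummaryTrace"`.
#' @param smoothWindow Savitzky-Golay window (points, odd; default 11).
#' @param noiseK baseline threshold in noise units (default 3).
#' @param minPoints minimum consecutive baseline samples (default 5).
#' @return list of `"PeakCluster"` objects, each with `runId` (NA here,
#'   filled by [peakClusters()]), `idxStart`/`idxEnd` (half-open indices
#'   into the time axis), `startTime`/`endTime`, `apexTimes`, `noiseLevel`.
#'   An all-baseline trace gives an empty list.
#' @export
segmentTrace <- function(trace, smoothWindow = 11, noiseK = 3,
                         minPoints = 5) {
  stopifnot(length(trace$value) > smoothWindow)
  v <- pmax(trace$value, 0)
  sm <- pmax(.sgSmooth(v, smoothWindow), 0)
  bm <- .baselineModel(v, sm, noiseK)
  noise <- bm$amp
  low <- bm$mask
  ## only stretches of >= minPoints low samples count as baseline
  r <- rle(low)
  isBase <- rep(r$values & r$lengths >= minPoints, r$lengths)
  ## trace ends act as baseline so edge clusters are delimited
  d2 <- .sgSmooth(v, smoothWindow, deriv = 2)
  n <- length(v)
  sig <- !isBase
  rs <- rle(sig)
  ends <- cumsum(rs$lengths)
  starts <- ends - rs$lengths + 1
  out <- list()
  for (s in seq_along(rs$values)) {
    if (!rs$values[s]) next
    i0 <- max(starts[s] - 1, 1)        # adjacent baseline sample
    i1 <- min(ends[s] + 1, n)          # half-open end
    seg <- i0:(i1 - 1)
    ## a real peak spans many samples; above-threshold blips shorter than
    ## the baseline run length are detector noise excursions
    if (length(seg) < minPoints + 2) next
    smSeg <- sm[seg]
    apexIdx <- seg[which(diff(sign(diff(smSeg))) == -2) + 1]
    apexIdx <- apexIdx[d2[apexIdx] < 0 &
                         sm[apexIdx] > bm$b0 + 2 * noiseK * bm$amp]
    apexIdx <- .prominentApexes(sm, apexIdx, noiseK * noise)
    if (length(apexIdx) == 0) next     # no real apex: noise blip
    out[[length(out) + 1]] <- structure(
      list(runId = NA_character_, idxStart = i0, idxEnd = i1,
           startTime = trace$time[i0], endTime = trace$time[i1 - 1],
           apexTimes = trace$time[apexIdx], noiseLevel = noise,
           baseLevel = bm$b0),
      class = "PeakCluster")
  }
  out
}

## Keep only local maxima whose valley to the nearest taller accepted apex
## is deeper than `depth` (peak prominence against detector ripple).
.prominentApexes <- function(sm, cand, depth) {
  if (length(cand) <= 1) return(cand)
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  acc <- cand[1]
  for (i in cand[-1]) {
    ok <- TRUE
    for (a in acc) {
      rng <- if (a < i) a:i else i:a
      valley <- min(sm[rng])
      if (sm[i] - valley <= depth) { ok <- FALSE; break }
    }
    if (ok) acc <- c(acc, i)
  }
  sort(acc)
}

#' Split a composite cluster at profile minima
#'
#' Inspects interior local minima of the smoothed trace inside the cluster;
#' where the valley value drops below `valleyRatio` times the smaller of
#' the two adjacent apex values, the cluster is cut there. The pieces tile
#' the parent index range exactly and inherit its run id and noise level.
#'
#' @param cluster a `"PeakCluster"` from [segmentTrace()].
#' @param trace the `"SummaryTrace"` it was segmented from.
#' @param valleyRatio depth criterion (default 0.5).
#' @param smoothWindow Savitzky-Golay window, as in [segmentTrace()].
#' @return list of `"PeakCluster"` pieces (the input unchanged if no valley
#'   qualifies).
#' @export
splitAtMinima <- function(cluster, trace, valleyRatio = 0.5,
                          smoothWindow = 11) {
  v <- pmax(trace$value, 0)
  sm <- pmax(.sgSmooth(v, smoothWindow), 0)
  seg <- cluster$idxStart:(cluster$idxEnd - 1)
  smSeg <- sm[seg]
  ## prominent maxima within the cluster; candidate valleys sit between
  ## adjacent ones
  maxIdx <- which(diff(sign(diff(smSeg))) == -2) + 1
  depth <- 3 * cluster$noiseLevel
  maxIdx <- sort(match(.prominentApexes(smSeg, maxIdx, depth),
                       seq_along(smSeg)))
  b0 <- if (is.null(cluster$baseLevel)) 0 else cluster$baseLevel
  cuts <- integer()
  if (length(maxIdx) >= 2) {
    for (a in seq_len(length(maxIdx) - 1)) {
      i0 <- maxIdx[a]; i1 <- maxIdx[a + 1]
      m <- i0 + which.min(smSeg[i0:i1]) - 1
      lower <- min(smSeg[i0], smSeg[i1]) - b0
      if (smSeg[m] - b0 < valleyRatio * lower) cuts <- c(cuts, seg[m])
    }
  }
  if (!length(cuts)) return(list(cluster))
  bounds <- c(cluster$idxStart, sort(cuts), cluster$idxEnd)
  out <- vector("list", length(bounds) - 1)
  for (i in seq_len(length(bounds) - 1)) {
    i0 <- bounds[i]; i1 <- bounds[i + 1]
    ap <- cluster$apexTimes[cluster$apexTimes >= trace$time[i0] &
                              cluster$apexTimes < trace$time[i1 - 1] +
                              .Machine$double.eps]
    out[[i]] <- structure(
      list(runId = cluster$runId, idxStart = i0, idxEnd = i1,
           startTime = trace$time[i0], endTime = trace$time[i1 - 1],
           apexTimes = ap, noiseLevel = cluster$noiseLevel,
           baseLevel = cluster$baseLevel),
      class = "PeakCluster")
  }
  out
}

#' Segment a chromatogram into peak clusters with data submatrices
#'
#' Convenience wrapper: computes the summary trace ([maxplot()] for UV,
#' [tic()] for MS), segments it, optionally splits composite clusters at
#' qualifying minima, and attaches each cluster's slice of the data matrix
#' (all channels) with negative entries preserved.
#'
#' @param chrom a [Chromatogram-class].
#' @param smoothWindow,noiseK,minPoints see [segmentTrace()].
#' @param valleyRatio see [splitAtMinima()]; `NA` disables splitting.
#' @return list of `"PeakCluster"` objects, each additionally carrying
#'   `submatrix`, `time` (cluster time axis) and `channels`.
#' @export
peakClusters <- function(chrom, smoothWindow = 11, noiseK = 3,
                         minPoints = 5, valleyRatio = 0.5) {
  tr <- if (chrom@detector == "UV") maxplot(chrom) else tic(chrom)
  cl <- segmentTrace(tr, smoothWindow, noiseK, minPoints)
  if (!is.na(valleyRatio)) {
    cl <- do.call(c, c(lapply(cl, splitAtMinima, trace = tr,
                              valleyRatio = valleyRatio,
                              smoothWindow = smoothWindow), list(list())))
  }
  lapply(seq_along(cl), function(i) {
    c0 <- cl[[i]]
    c0$runId <- chrom@runId
    c0$clusterId <- sprintf("%s_c%02d", chrom@runId, i)
    seg <- c0$idxStart:(c0$idxEnd - 1)
    c0$submatrix <- chrom@intensity[seg, , drop = FALSE]
    c0$time <- chrom@time[seg]
    c0$channels <- chrom@channels
    c0
  })
}

#' Export a cluster table
#'
#' @param clusters list of `"PeakCluster"` objects.
#' @return data.frame (run_id, cluster_id, start_time, end_time, n_apexes).
#' @export
clusterTable <- function(clusters) {
  data.frame(
    run_id = vapply(clusters, `[[`, character(1), "runId"),
    cluster_id = vapply(clusters, function(x)
      if (is.null(x$clusterId)) NA_character_ else x$clusterId, character(1)),
    start_time = vapply(clusters, `[[`, numeric(1), "startTime"),
    end_time = vapply(clusters, `[[`, numeric(1), "endTime"),
    n_apexes = vapply(clusters, function(x) length(x$apexTimes), integer(1)))
}
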