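#' Differential evolution minimizer (DE/rand/1/bin)
#'
#' Classic differential evolution: for each parent, a mutant
#' `v = a + F (b - c)` is built from three distinct random population
#' members, crossed binomially with the parent (at least one mutated gene),
#' reflected back into bounds, and kept only if it improves the objective.
#' Fully reproducible under a seed. Trials on which the objective returns a
#' non-finite value are rejected and counted.
#'
#' @param fn objective function of a numeric vector, to minimize.
#' @param lower,upper bound vectors (same length).
#' @param pop population size (>= 4, default 40).
#' @param gens number of generations (default 200).
#' @param F differential weight in (0, 2) (default 0.7).
#' @param CR crossover rate in \[0, 1\] (default 0.9).
#' @param seed integer seed (NULL leaves the RNG alone, with a warning:
#'   unseeded optimizations are not reproducible).
#' @return list with `par`, `value`, `nonFinite` (rejected trial count),
#'   `trace` (best value per generation).
#' @export
deMinimize <- function(fn, lower, upper, pop = 40, gens = 200, F = 0.7,
                       CR = 0.9, seed = NULL) {
  stopifnot(pop >= 4, F > 0, F < 2, CR >= 0, CR <= 1,
            length(lower) == length(upper), all(lower < upper))
  if (is.null(seed)) warning("unseeded optimization: results not reproducible")
  else set.seed(seed)
  d <- length(lower)
  P <- t(replicate(pop, stats::runif(d, lower, upper)))
  raw <- apply(P, 1, fn)
  nonFinite <- sum(!is.finite(raw))
  fvals <- ifelse(is.finite(raw), raw, Inf)
  trace <- numeric(gens)
  for (g in seq_len(gens)) {
    for (i in seq_len(pop)) {
      idx <- sample(setdiff(seq_len(pop), i), 3)
      v <- P[idx[1], ] + F * (P[idx[2], ] - P[idx[3], ])
      ## reflection into bounds
      for (rep in 1:5) {
        below <- v < lower; v[below] <- 2 * lower[below] - v[below]
        above <- v > upper; v[above] <- 2 * upper[above] - v[above]
        if (!any(v < lower | v > upper)) break
      }
      v <- pmin(pmax(v, lower), upper)
      cross <- stats::runif(d) < CR
      cross[sample(d, 1)] <- TRUE
      trial <- ifelse(cross, v, P[i, ])
      fv <- fn(trial)
      if (!is.finite(fv)) { nonFinite <- nonFinite + 1; next }
      if (fv <= fvals[i]) { P[i, ] <- trial; fvals[i] <- fv }
    }
    trace[g] <- min(fvals)
  }
  b <- which.min(fvals)
  list(par = P[b, ], value = fvals[b], nonFinite = nonFinite, trace = trace)
}

#' Non-dominated subset of objective points
#'
#' All objectives are minimized. A point is dominated if another point is
#' no worse in every objective and strictly better in at least one;
#' duplicates of a non-dominated point are all retained. Two-objective
#' input uses an O(n log n) sweep; higher dimensions fall back to pairwise
#' checks.
#'
#' @param points numeric matrix (rows = points) or list of numeric vectors.
#' @return integer indices of the non-dominated points, in input order.
#' @export
paretoFilter <- function(points) {
  if (is.list(points)) points <- do.call(rbind, points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (n == 0) return(integer())
  if (ncol(points) == 1)
    return(which(points[, 1] == min(points[, 1])))
  if (ncol(points) == 2) {
    ord <- order(points[, 1], points[, 2])
    keep <- logical(n)
    best2 <- Inf
    i <- 1
    while (i <= n) {
      ## block of ties in objective 1
      j <- i
      while (j < n && points[ord[j + 1], 1] == points[ord[i], 1]) j <- j + 1
      blockMin <- min(points[ord[i:j], 2])
      if (blockMin < best2) {
        keep[ord[i:j][points[ord[i:j], 2] == blockMin]] <- TRUE
        best2 <- blockMin
      } else if (blockMin == best2)
        keep[ord[i:j][points[ord[i:j], 2] == blockMin]] <- TRUE
      i <- j + 1
    }
    return(which(keep))
  }
  dominated <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(points[j, ] <= points[i, ]) && any(points[j, ] < points[i, ])) {
        dominated[i] <- TRUE
        break
      }
    }
  }
  which(!dominated)
}

#' Define the elution-program search space
#'
#' @param parameters data.frame (or list of lists) with `name`, `low`,
#'   `high`. Recognized names: `phi_initial`, `phi_final`, `t_G`,
#'   `temperature`, `t_mid_frac`, `phi_mid` (the last two enable a
#'   2-segment profile).
#' @param t0 dead time of the target method, minutes.
#' @param tDwell dwell time, minutes.
#' @param flow flow rate, mL/min.
#' @return a `"SearchSpace"` list.
#' @export
searchSpace <- function(parameters, t0 = 1, tDwell = 0, flow = 1) {
  if (is.list(parameters) && !is.data.frame(parameters))
    parameters <- do.call(rbind, lapply(parameters, as.data.frame))
  stopifnot(all(c("name", "low", "high") %in% names(parameters)),
            all(parameters$low < parameters$high))
  structure(list(parameters = parameters, t0 = t0, tDwell = tDwell,
                 flow = flow), class = "SearchSpace")
}

#' Decode a search vector into an elution program
#'
#' Phi values are clipped to \[0, 1\] and node times sorted, so every decoded
#' vector is a valid program.
#'
#' @param space a `"SearchSpace"`.
#' @param vec numeric vector, one entry per space parameter.
#' @param temperature fallback temperature when not searched.
#' @return an [ElutionProgram-class].
#' @export
decodeProgram <- function(space, vec, temperature = 25) {
  p <- stats::setNames(as.numeric(vec), space$parameters$name)
  g <- function(nm, default) if (nm %in% names(p)) unname(p[nm]) else default
  phiI <- min(max(g("phi_initial", 0.05), 0), 1)
  phiF <- min(max(g("phi_final", 0.95), 0), 1)
  tG <- max(g("t_G", 10), 1e-3)
  temp <- g("temperature", temperature)
  if ("phi_mid" %in% names(p)) {
    tMid <- min(max(g("t_mid_frac", 0.5), 0.01), 0.99) * tG
    phiM <- min(max(g("phi_mid", (phiI + phiF) / 2), 0), 1)
    nodes <- data.frame(time = sort(c(0, tMid, tG)),
                        phi = c(phiI, phiM, phiF))
  } else {
    nodes <- data.frame(time = c(0, tG), phi = c(phiI, phiF))
  }
  elutionProgram(nodes, temperature = temp, t0 = space$t0,
                 tDwell = space$tDwell, flow = space$flow)
}

## Objective evaluation shared by all optimizer modes. Returns
## c(negCritRs, runtime); non-eluting components are penalized.
.sepObjectives <- function(paramsList, space, vec, plates, dt, overtime,
                           rsCap = 1e3) {
  prg <- decodeProgram(space, vec)
  sim <- simulateSeparation(paramsList, prg, plates = plates,
                            dt = if (is.null(dt)) prg@t0 / 50 else dt,
                            overtime = overtime)
  pen <- sum(!sim$components$eluted)
  crit <- min(sim$criticalRs, rsCap)
  if (pen > 0) crit <- -pen          # strictly worse than any feasible value
  rt <- if (is.finite(sim$runtime)) sim$runtime else 1e6
  c(-crit, rt + pen * 1e3)
}

#' Optimize a separation by differential evolution
#'
#' Searches the elution-program space for programs that maximize the
#' critical resolution and minimize the analysis time (elution time of the
#' last component, not the programmed gradient time). Three modes:
#' `"pareto"` (recommended) evolves the population under dominance
#' replacement -- a trial replaces its parent only when it dominates it --
#' while an external archive accumulates every non-dominated program found;
#' `"weighted"` scalarizes the two objectives; `"threshold_time"` minimizes
#' runtime subject to the critical resolution reaching `targetRs`.
#'
#' @param paramsList list of `"LSSParams"` (or `"RetentionModel"` objects in
#'   `lss` mode, whose parameters are taken).
#' @param space a `"SearchSpace"`.
#' @param mode `"pareto"`, `"weighted"`, or `"threshold_time"`.
#' @param pop,gens,F,CR differential evolution settings.
#' @param seed integer seed (mandatory for reproducibility).
#' @param plates column plate number for peak widths.
#' @param dt integration step (default `t0/50`).
#' @param overtime see [simulateGradient()].
#' @param weight weight on resolution in `"weighted"` mode (0..1).
#' @param targetRs resolution target in `"threshold_time"` mode.
#' @return `"pareto"` mode: a `"ParetoFront"` list with `members`
#'   (data.frame of decoded parameters + `criticalRs`, `runtime`) and
#'   `vectors`; other modes: list with `par`, `program`, `criticalRs`,
#'   `runtime`, `value`.
#' @export
optimizeSeparation <- function(paramsList, space,
                               mode = c("pareto", "weighted",
                                        "threshold_time"),
                               pop = 40, gens = 200, F = 0.7, CR = 0.9,
                               seed = 1, plates = 10000, dt = NULL,
                               overtime = 3, weight = 0.7, targetRs = 1.5) {
  mode <- match.arg(mode)
  paramsList <- lapply(paramsList, function(p)
    if (inherits(p, "RetentionModel")) {
      if (p$mode != "lss")
        stop("optimization needs LSS-mode models (or raw LSSParams)")
      p$params
    } else p)
  lower <- space$parameters$low
  upper <- space$parameters$high
  obj2 <- function(vec) .sepObjectives(paramsList, space, vec, plates, dt,
                                       overtime)
  if (mode == "weighted") {
    res <- deMinimize(function(v) {
      o <- obj2(v); weight * o[1] + (1 - weight) * o[2]
    }, lower, upper, pop, gens, F, CR, seed)
  } else if (mode == "threshold_time") {
    res <- deMinimize(function(v) {
      o <- obj2(v)
      short <- max(targetRs - (-o[1]), 0)
      o[2] + 1e3 * short
    }, lower, upper, pop, gens, F, CR, seed)
  } else {
    set.seed(seed)
    d <- length(lower)
    P <- t(replicate(pop, stats::runif(d, lower, upper)))
    Fv <- t(apply(P, 1, obj2))
    archV <- P
    archF <- Fv
    for (g in seq_len(gens)) {
      for (i in seq_len(pop)) {
        idx <- sample(setdiff(seq_len(pop), i), 3)
        v <- P[idx[1], ] + F * (P[idx[2], ] - P[idx[3], ])
        for (rep in 1:5) {
          below <- v < lower; v[below] <- 2 * lower[below] - v[below]
          above <- v > upper; v[above] <- 2 * upper[above] - v[above]
          if (!any(v < lower | v > upper)) break
        }
        v <- pmin(pmax(v, lower), upper)
        cross <- stats::runif(d) < CR
        cross[sample(d, 1)] <- TRUE
        trial <- ifelse(cross, v, P[i, ])
        ft <- obj2(trial)
        if (any(!is.finite(ft))) next
        dominates <- all(ft <= Fv[i, ]) && any(ft < Fv[i, ])
        if (dominates) { P[i, ] <- trial; Fv[i, ] <- ft }
        archV <- rbind(archV, trial)
        archF <- rbind(archF, ft)
      }
      keep <- paretoFilter(archF)
      archV <- archV[keep, , drop = FALSE]
      archF <- archF[keep, , drop = FALSE]
    }
    mem <- as.data.frame(archV)
    names(mem) <- space$parameters$name
    mem$criticalRs <- -archF[, 1]
    mem$runtime <- archF[, 2]
    ord <- order(-mem$criticalRs)
    front <- structure(list(members = mem[ord, , drop = FALSE],
                            vectors = archV[ord, , drop = FALSE],
                            space = space),
                       class = "ParetoFront")
    return(front)
  }
  o <- obj2(res$par)
  list(par = stats::setNames(res$par, space$parameters$name),
       program = decodeProgram(space, res$par),
       criticalRs = -o[1], runtime = o[2], value = res$value)
}

#' @export
print.ParetoFront <- function(x, ...) {
  cat(sprintf("ParetoFront: %d non-dominated program(s)\n", nrow(x$members)))
  print(utils::head(x$members, 10), row.names = FALSE)
  if (nrow(x$members) > 10) cat("  ...\n")
  invisible(x)
}
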