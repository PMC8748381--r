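## Pearson correlation between two spectra on the common channel grid.
.specCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

## Cosine similarity of two sparse MS spectra given as named vectors
## (names = integer m/z bins).
.msCosine <- function(a, b) {
  if (is.null(a) || is.null(b)) return(NA_real_)
  bins <- union(names(a), names(b))
  va <- stats::setNames(numeric(length(bins)), bins)
  vb <- va
  va[names(a)] <- a
  vb[names(b)] <- b
  s <- sqrt(sum(va^2) * sum(vb^2))
  if (s == 0) return(0)
  sum(va * vb) / s
}

.msBasePeak <- function(ms) {
  if (is.null(ms) || length(ms) == 0) return(NA_real_)
  as.numeric(names(ms)[which.max(ms)])
}

#' Build the cross-run component catalog
#'
#' Components flagged pure (extracted alone from a rank-1 cluster in at
#' least one run) are greedily merged into unique catalog entries when their
#' UV spectra correlate at `thrUV` or better -- unless MS evidence is in use
#' and their MS base peaks differ, in which case they remain separate
#' entries (identical UV, different MS distinguishes e.g. positional
#' isomers). Each entry's consensus spectrum is the unit-normalized mean of
#' its members. Spectra of components that never eluted pure form the mixed
#' set; mixed spectra correlating at `thrUV` with a pure entry are credited
#' to that entry's provenance, the remainder stay unassigned mixed spectra.
#'
#' @param extracted flat list of `"ExtractedComponent"` objects from all
#'   runs (see [resolveChromatogram()]).
#' @param thrUV UV spectral correlation threshold (default 0.95).
#' @param msMode use MS base peaks to separate UV-identical entries.
#' @param thrMS MS cosine threshold used when comparing MS spectra
#'   (default 0.9).
#' @return A `"ComponentCatalog"` list with `entries`, `mixedSet`,
#'   `thrUV`, `msMode`.
#' @export
buildCatalog <- function(extracted, thrUV = 0.95, msMode = FALSE,
                         thrMS = 0.9) {
  entries <- list()
  if (length(extracted)) {
    isPure <- vapply(extracted, `[[`, logical(1), "pure")
    ## a profile peaking on its cluster boundary is a split fragment or a
    ## truncated peak: unreliable as a catalog anchor, still assignable
    trunc <- vapply(extracted, `[[`, logical(1), "truncated")
    isPure <- isPure & !trunc
    pureIdx <- which(isPure)
    ## most intense first: stable consensus anchors
    ord <- pureIdx[order(vapply(extracted[pureIdx], function(x)
      max(x$profile), numeric(1)), decreasing = TRUE)]
    for (i in ord) {
      comp <- extracted[[i]]
      placed <- FALSE
      for (e in seq_along(entries)) {
        r <- .specCor(entries[[e]]$spectrum, comp$spectrum)
        if (r >= thrUV) {
          if (msMode) {
            bpE <- entries[[e]]$msBasePeak
            bpC <- .msBasePeak(comp$msSpectrum)
            if (!is.na(bpE) && !is.na(bpC) && abs(bpE - bpC) > 0.5)
              next                      # same UV, different MS: keep apart
          }
          en <- entries[[e]]
          en$members <- c(en$members, list(comp))
          sp <- rowMeans(vapply(en$members, `[[`,
                                numeric(length(comp$spectrum)), "spectrum"))
          en$spectrum <- sp / sqrt(sum(sp^2))
          en$runs <- union(en$runs, comp$runId)
          if (is.na(en$msBasePeak))
            en$msBasePeak <- .msBasePeak(comp$msSpectrum)
          if (is.null(en$msSpectrum)) en$msSpectrum <- comp$msSpectrum
          entries[[e]] <- en
          placed <- TRUE
          break
        }
      }
      if (!placed)
        entries[[length(entries) + 1]] <- list(
          id = NA_character_, spectrum = comp$spectrum,
          members = list(comp), runs = comp$runId,
          msSpectrum = comp$msSpectrum,
          msBasePeak = .msBasePeak(comp$msSpectrum), artifact = FALSE)
    }
    ## order entries by median apex time for stable, readable ids
    med <- vapply(entries, function(e)
      stats::median(vapply(e$members, `[[`, numeric(1), "apexTime")),
      numeric(1))
    entries <- entries[order(med)]
    for (e in seq_along(entries)) entries[[e]]$id <- sprintf("P%02d", e)
    ## mixed set: credit provenance or keep as leftover spectra
    mixed <- list()
    for (i in which(!isPure)) {
      comp <- extracted[[i]]
      rs <- vapply(entries, function(e) .specCor(e$spectrum, comp$spectrum),
                   numeric(1))
      if (length(rs) && max(rs) >= thrUV) {
        e <- which.max(rs)
        entries[[e]]$runs <- union(entries[[e]]$runs, comp$runId)
      } else mixed[[length(mixed) + 1]] <- comp
    }
  } else mixed <- list()
  structure(list(entries = entries, mixedSet = mixed, thrUV = thrUV,
                 msMode = msMode, thrMS = thrMS),
            class = "ComponentCatalog")
}

#' @export
print.ComponentCatalog <- function(x, ...) {
  cat(sprintf("ComponentCatalog: %d pure entries, %d mixed spectra (thrUV = %g)\n",
              length(x$entries), length(x$mixedSet), x$thrUV))
  for (e in x$entries)
    cat(sprintf("  %s: %d member(s), runs {%s}%s%s\n", e$id,
                length(e$members), paste(e$runs, collapse = ","),
                if (!is.na(e$msBasePeak)) sprintf(", base peak %g",
                                                  e$msBasePeak) else "",
                if (isTRUE(e$artifact)) " [artifact]" else ""))
  invisible(x)
}

#' Assign catalog components to retention times in every run
#'
#' Per run, catalog entries are matched one-to-one to that run's extracted
#' components by greedy descending spectral correlation (ties within 1e-9
#' broken toward the smaller retention-time distance to the entry's median
#' assigned time). A match at `thrUV` or better assigns the extracted apex
#' time; a best correlation between `alertFloor` and `thrUV` leaves the cell
#' unassigned with an alert flag (significant but below the acceptance
#' limit); anything lower is plainly unassigned.
#'
#' @param catalog a `"ComponentCatalog"`.
#' @param extracted flat list of `"ExtractedComponent"` from the same
#'   campaign.
#' @param runIds run identifiers defining the table columns (default: all
#'   runs seen in `extracted`).
#' @param thrUV acceptance threshold (default: the catalog's, 0.95).
#' @param alertFloor alert band floor (default 0.8).
#' @return An `"AssignmentTable"` list: `tR` and `bestR` (entry x run
#'   matrices), `flags` (character matrix `"assigned"`/`"alert"`/
#'   `"unassigned"`/`"manual"`), `catalog`, `runIds`.
#' @export
assignComponents <- function(catalog, extracted, runIds = NULL,
                             thrUV = catalog$thrUV, alertFloor = 0.8) {
  if (is.null(runIds))
    runIds <- unique(vapply(extracted, `[[`, character(1), "runId"))
  nE <- length(catalog$entries)
  tR <- matrix(NA_real_, nE, length(runIds),
               dimnames = list(vapply(catalog$entries, `[[`, character(1),
                                      "id"), runIds))
  bestR <- tR
  flags <- matrix("unassigned", nE, length(runIds),
                  dimnames = dimnames(tR))
  for (ri in seq_along(runIds)) {
    comps <- extracted[vapply(extracted, `[[`, character(1), "runId") ==
                         runIds[ri]]
    if (!length(comps) || !nE) next
    R <- matrix(0, nE, length(comps))
    for (e in seq_len(nE)) for (j in seq_along(comps))
      R[e, j] <- .specCor(catalog$entries[[e]]$spectrum, comps[[j]]$spectrum)
    medT <- vapply(catalog$entries, function(en)
      stats::median(vapply(en$members, `[[`, numeric(1), "apexTime")),
      numeric(1))
    apex <- vapply(comps, `[[`, numeric(1), "apexTime")
    usedE <- logical(nE)
    usedC <- logical(length(comps))
    repeat {
      Rm <- R
      Rm[usedE, ] <- -Inf
      Rm[, usedC] <- -Inf
      top <- max(Rm)
      if (!is.finite(top) || top < alertFloor) break
      cand <- which(Rm > top - 1e-9, arr.ind = TRUE)
      if (nrow(cand) > 1) {
        dts <- abs(apex[cand[, 2]] - medT[cand[, 1]])
        cand <- cand[which.min(dts), , drop = FALSE]
      }
      e <- cand[1, 1]; j <- cand[1, 2]
      bestR[e, ri] <- R[e, j]
      if (R[e, j] >= thrUV) {
        tR[e, ri] <- apex[j]
        flags[e, ri] <- "assigned"
      } else flags[e, ri] <- "alert"
      usedE[e] <- TRUE
      usedC[j] <- TRUE
    }
    ## record best correlation for entries that got nothing
    for (e in which(!usedE)) bestR[e, ri] <- if (length(comps))
      max(R[e, ]) else NA_real_
  }
  structure(list(tR = tR, bestR = bestR, flags = flags, catalog = catalog,
                 runIds = runIds),
            class = "AssignmentTable")
}

#' @export
print.AssignmentTable <- function(x, ...) {
  cat(sprintf("AssignmentTable: %d component(s) x %d run(s); %d assigned, %d alert, %d unassigned\n",
              nrow(x$tR), ncol(x$tR), sum(x$flags %in% c("assigned", "manual")),
              sum(x$flags == "alert"),
              sum(x$flags == "unassigned")))
  print(round(x$tR, 3))
  invisible(x)
}

#' Flag catalog entries correlated with run backgrounds
#'
#' The maxplot trace tends to produce artifact "peaks" early in runs whose
#' extracted spectra track the baseline drift. Each run's background
#' spectrum is estimated as the mean spectrum over its baseline points;
#' catalog entries whose spectrum correlates (positively or negatively) at
#' `thr` or beyond with any run's background are flagged `artifact`. They
#' are reported and excluded from retention modelling, never silently
#' deleted.
#'
#' @param catalog a `"ComponentCatalog"`.
#' @param chromatograms list of UV [Chromatogram-class] runs.
#' @param thr absolute correlation threshold (default 0.95).
#' @param noiseK,minPoints,smoothWindow baseline detection settings (see
#'   [segmentTrace()]).
#' @return the catalog with `artifact` flags updated.
#' @export
backgroundFilter <- function(catalog, chromatograms, thr = 0.95,
                             noiseK = 3, minPoints = 5, smoothWindow = 11) {
  bgs <- list()
  for (ch in chromatograms) {
    tr <- maxplot(ch)
    v <- pmax(tr$value, 0)
    sm <- pmax(.sgSmooth(v, smoothWindow), 0)
    base <- .baselineModel(v, sm, noiseK)$mask
    X <- ch@intensity
    idx <- if (sum(base) >= minPoints) which(base)
           else order(sm)[seq_len(min(length(sm), 20))]
    bg <- colMeans(X[idx, , drop = FALSE])
    ## drift shape: remove the flat offset so the correlation probes shape
    if (stats::sd(bg) > 0) bgs[[length(bgs) + 1]] <- bg
  }
  for (e in seq_along(catalog$entries)) {
    sp <- catalog$entries[[e]]$spectrum
    for (bg in bgs) {
      if (abs(.specCor(sp, bg)) >= thr) {
        catalog$entries[[e]]$artifact <- TRUE
        break
      }
    }
  }
  catalog
}

#' False-positive diagnostics on an assignment table
#'
#' Advisory report of the patterns that betray spurious catalog entries:
#' \describe{
#'   \item{redundancy}{entry pairs with spectral correlation at or above
#'     the threshold whose assigned retention times agree within `deltaTol`
#'     in every co-assigned run -- two extractions of one mixture
#'     component.}
#'   \item{sumSpectrum}{an entry whose spectrum matches the normalized sum
#'     of two co-eluting entries -- the apex spectrum of a fully overlapped
#'     pair masquerading as a component.}
#'   \item{columnInconsistency}{entries assigned in the runs of one column
#'     but never in another's -- typically background interference specific
#'     to one column.}
#' }
#' Nothing is deleted automatically; the chromatographer reviews the report
#' and applies [applyEdits()].
#'
#' @param table an `"AssignmentTable"`.
#' @param thr spectral correlation threshold (default: catalog's).
#' @param deltaTol retention-time agreement tolerance, minutes (default
#'   twice the median sampling interval implied by assigned times, or 0.05
#'   min if that cannot be estimated).
#' @param runColumns optional named character vector run id -> column id;
#'   defaults to the single-column case (no inconsistency checks).
#' @return list with data.frames `redundancy`, `sumSpectrum`,
#'   `columnInconsistency`.
#' @export
assignmentDiagnostics <- function(table, thr = table$catalog$thrUV,
                                  deltaTol = NULL, runColumns = NULL) {
  cat0 <- table$catalog
  nE <- length(cat0$entries)
  if (is.null(deltaTol)) deltaTol <- 0.05
  red <- data.frame(entryA = character(), entryB = character(),
                    specCor = numeric(), maxDeltaT = numeric())
  ids <- vapply(cat0$entries, `[[`, character(1), "id")
  if (nE >= 2) {
    for (a in seq_len(nE - 1)) for (b in (a + 1):nE) {
      r <- .specCor(cat0$entries[[a]]$spectrum, cat0$entries[[b]]$spectrum)
      if (r < thr) next
      co <- which(table$flags[a, ] == "assigned" &
                    table$flags[b, ] == "assigned")
      if (!length(co)) next
      dmax <- max(abs(table$tR[a, co] - table$tR[b, co]))
      if (dmax <= deltaTol)
        red <- rbind(red, data.frame(entryA = ids[a], entryB = ids[b],
                                     specCor = r, maxDeltaT = dmax))
    }
  }
  ss <- data.frame(entry = character(), partA = character(),
                   partB = character(), specCor = numeric())
  if (nE >= 3) {
    for (e in seq_len(nE)) {
      for (a in seq_len(nE - 1)) for (b in (a + 1):nE) {
        if (e %in% c(a, b)) next
        co <- which(table$flags[a, ] == "assigned" &
                      table$flags[b, ] == "assigned")
        if (!length(co)) next
        if (max(abs(table$tR[a, co] - table$tR[b, co])) > deltaTol) next
        sumSp <- cat0$entries[[a]]$spectrum + cat0$entries[[b]]$spectrum
        r <- .specCor(cat0$entries[[e]]$spectrum, sumSp / sqrt(sum(sumSp^2)))
        if (r >= thr)
          ss <- rbind(ss, data.frame(entry = ids[e], partA = ids[a],
                                     partB = ids[b], specCor = r))
      }
    }
  }
  ci <- data.frame(entry = character(), assignedColumn = character(),
                   missingColumn = character())
  if (!is.null(runColumns)) {
    cols <- unique(runColumns[table$runIds])
    if (length(cols) >= 2) {
      for (e in seq_len(nE)) {
        rate <- vapply(cols, function(cc) {
          rr <- table$runIds[runColumns[table$runIds] == cc]
          mean(table$flags[e, rr] %in% c("assigned", "manual"))
        }, numeric(1))
        if (any(rate >= 0.5) && any(rate == 0))
          ci <- rbind(ci, data.frame(
            entry = ids[e],
            assignedColumn = cols[which.max(rate)],
            missingColumn = paste(cols[rate == 0], collapse = ",")))
      }
    }
  }
  list(redundancy = red, sumSpectrum = ss, columnInconsistency = ci)
}

#' Apply user edits to an assignment table
#'
#' Supported actions: `list(action = "delete", entry = id)` removes a
#' catalog entry and its row; `list(action = "merge", keep = id, drop =
#' id)` merges one entry into another (the kept entry's assignments win in
#' conflicts, the dropped entry fills its gaps); `list(action = "set_tR",
#' entry = id, run = runId, tR = minutes)` assigns a cell manually (flag
#' `"manual"`), clearing its alert.
#'
#' @param table an `"AssignmentTable"`.
#' @param edits list of edit actions.
#' @return the edited `"AssignmentTable"`.
#' @export
applyEdits <- function(table, edits) {
  for (ed in edits) {
    ids <- rownames(table$tR)
    act <- ed$action
    if (act == "delete") {
      i <- match(ed$entry, ids)
      if (is.na(i)) stop("no catalog entry '", ed$entry, "'")
      table$tR <- table$tR[-i, , drop = FALSE]
      table$bestR <- table$bestR[-i, , drop = FALSE]
      table$flags <- table$flags[-i, , drop = FALSE]
      table$catalog$entries <- table$catalog$entries[-i]
    } else if (act == "merge") {
      k <- match(ed$keep, ids); d <- match(ed$drop, ids)
      if (is.na(k) || is.na(d)) stop("merge references unknown entry")
      fill <- table$flags[k, ] == "unassigned" &
        table$flags[d, ] %in% c("assigned", "manual")
      table$tR[k, fill] <- table$tR[d, fill]
      table$flags[k, fill] <- table$flags[d, fill]
      table$bestR[k, fill] <- table$bestR[d, fill]
      table$catalog$entries[[k]]$runs <-
        union(table$catalog$entries[[k]]$runs,
              table$catalog$entries[[d]]$runs)
      table$tR <- table$tR[-d, , drop = FALSE]
      table$bestR <- table$bestR[-d, , drop = FALSE]
      table$flags <- table$flags[-d, , drop = FALSE]
      table$catalog$entries <- table$catalog$entries[-d]
    } else if (act == "set_tR") {
      i <- match(ed$entry, ids)
      if (is.na(i)) stop("no catalog entry '", ed$entry, "'")
      j <- match(ed$run, colnames(table$tR))
      if (is.na(j)) stop("no run '", ed$run, "' in table")
      table$tR[i, j] <- ed$tR
      table$flags[i, j] <- "manual"
    } else stop("unknown edit action '", act, "'")
  }
  table
}

#' Are unresolved alerts present?
#'
#' Retention-model fitting refuses to run while alert cells remain
#' unresolved (unless explicitly waived), mirroring the rule that the model
#' may not be built before critical alerts have been addressed.
#'
#' @param table an `"AssignmentTable"`.
#' @return logical.
#' @export
hasAlerts <- function(table) any(table$flags == "alert")

#' Export an assignment table as a data.frame
#'
#' @param table an `"AssignmentTable"`.
#' @return data.frame with component, run, tR, flag, bestR.
#' @export
assignmentFrame <- function(table) {
  df <- expand.grid(component = rownames(table$tR),
                    run = colnames(table$tR), stringsAsFactors = FALSE)
  df$tR <- as.vector(table$tR)
  df$flag <- as.vector(table$flags)
  df$bestR <- as.vector(table$bestR)
  df
}

#' Attach MS spectra to UV-extracted components
#'
#' Resolves each run's MS chromatogram with the same cluster/MCR machinery,
#' then attaches to every UV-extracted component the MS spectrum of the
#' MS-resolved component whose apex lies closest in time (within
#' `tolerance`); where no resolved MS component is near, the raw scan at the
#' UV apex is used. Attached spectra are base-peak-normalized sparse vectors
#' named by m/z bin, and the 0.1 percent noise count is filled in.
#'
#' @param extracted flat list of `"ExtractedComponent"` (UV).
#' @param msChromatograms list of MS [Chromatogram-class] runs, named or
#'   ordered by run id.
#' @param tolerance apex matching tolerance, minutes (default 0.1).
#' @param ... passed to [resolveChromatogram()] for the MS data.
#' @return the component list with `msSpectrum` and `noiseCount` filled.
#' @export
attachMSSpectra <- function(extracted, msChromatograms, tolerance = 0.1,
                            ...) {
  byRun <- list()
  for (ms in msChromatograms) {
    if (is.null(ms)) next
    byRun[[ms@runId]] <- list(chrom = ms,
                              res = resolveChromatogram(ms, ...))
  }
  sparsify <- function(v, channels) {
    keep <- which(v > 0.001 * max(v))
    sp <- v[keep] / max(v) * 100
    stats::setNames(sp, round(channels[keep]))
  }
  for (i in seq_along(extracted)) {
    comp <- extracted[[i]]
    run <- byRun[[comp$runId]]
    if (is.null(run)) next
    msComps <- run$res$components
    spec <- NULL
    if (length(msComps)) {
      d <- abs(vapply(msComps, `[[`, numeric(1), "apexTime") - comp$apexTime)
      if (min(d) <= tolerance)
        spec <- sparsify(msComps[[which.min(d)]]$spectrum,
                         run$res$components[[which.min(d)]]$spectrum * 0 +
                           channelValues(run$chrom))
    }
    if (is.null(spec)) {
      row <- which.min(abs(chromTime(run$chrom) - comp$apexTime))
      v <- pmax(intensityMatrix(run$chrom)[row, ], 0)
      if (max(v) > 0) spec <- sparsify(v, channelValues(run$chrom))
    }
    if (!is.null(spec) && length(spec)) {
      extracted[[i]]$msSpectrum <- spec
      extracted[[i]]$noiseCount <- msNoiseCount(spec)
    }
  }
  extracted
}
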