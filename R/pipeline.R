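#' Per-run elution programs of a campaign spec
#'
#' @param spec a `"CampaignSpec"`.
#' @return named list of [ElutionProgram-class], one per design run.
#' @export
campaignPrograms <- function(spec) {
  n <- nrow(spec$design$real)
  stats::setNames(lapply(seq_len(n), function(r) programForRun(spec, r)),
                  spec$design$runIds)
}

#' Run component discovery over a whole campaign
#'
#' Segments and curve-resolves every run, pools the extracted components,
#' optionally fuses MS spectra, builds the catalog, filters
#' background-correlated entries, assigns retention times, and computes the
#' false-positive diagnostics.
#'
#' @param chromatograms list of UV [Chromatogram-class] runs.
#' @param msChromatograms optional list of MS runs (NULL entries allowed).
#' @param thrUV acceptance correlation (default 0.95).
#' @param alertFloor alert band floor (default 0.8).
#' @param rankCap maximum components per cluster (default 6).
#' @param backgroundThr artifact-correlation threshold (default 0.95).
#' @param ... passed to [resolveChromatogram()].
#' @return list with `extracted`, `catalog`, `table`, `diagnostics`.
#' @export
discoverComponents <- function(chromatograms, msChromatograms = NULL,
                               thrUV = 0.95, alertFloor = 0.8, rankCap = 6,
                               backgroundThr = 0.95, ...) {
  extracted <- list()
  for (ch in chromatograms)
    extracted <- c(extracted,
                   resolveChromatogram(ch, rankCap = rankCap, ...)$components)
  msMode <- FALSE
  if (!is.null(msChromatograms) &&
      any(!vapply(msChromatograms, is.null, logical(1)))) {
    extracted <- attachMSSpectra(extracted, msChromatograms)
    msMode <- TRUE
  }
  catalog <- buildCatalog(extracted, thrUV = thrUV, msMode = msMode)
  catalog <- backgroundFilter(catalog, chromatograms, thr = backgroundThr)
  runIds <- vapply(chromatograms, runId, character(1))
  table <- assignComponents(catalog, extracted, runIds = runIds,
                            thrUV = thrUV, alertFloor = alertFloor)
  diag <- assignmentDiagnostics(table)
  list(extracted = extracted, catalog = catalog, table = table,
       diagnostics = diag)
}

#' End-to-end synthetic campaign pipeline
#'
#' Convenience driver used by the command-line interface and the examples:
#' simulate a campaign, discover its components, fit retention models and
#' optimize the separation.
#'
#' @param spec a `"CampaignSpec"`.
#' @param mode retention model mode (`"lss"` or `"pls"`).
#' @param optimize run the Pareto optimization stage.
#' @param space optional `"SearchSpace"`; a default
#'   (phi_initial 0.02-0.5, phi_final 0.5-1, t_G 2-20 min) is built when
#'   omitted.
#' @param pop,gens differential evolution budget.
#' @param allowAlerts waive the alert gate before fitting.
#' @param seed seed for the optimizer (defaults to the spec's).
#' @return list with `simulation`, `discovery`, `models`, `front`.
#' @export
runPipeline <- function(spec, mode = "lss", optimize = TRUE, space = NULL,
                        pop = 40, gens = 60, allowAlerts = FALSE,
                        seed = spec$seed) {
  sim <- simulateCampaign(spec)
  disc <- discoverComponents(sim$chromatograms, sim$msChromatograms)
  programs <- campaignPrograms(spec)
  runs <- data.frame(runId = spec$design$runIds, role = spec$design$roles)
  models <- fitRetentionModels(disc$table, runs, programs, mode = mode,
                               coded = spec$design$coded,
                               allowAlerts = allowAlerts)
  front <- NULL
  if (optimize && length(models)) {
    if (is.null(space))
      space <- searchSpace(data.frame(
        name = c("phi_initial", "phi_final", "t_G"),
        low = c(0.02, 0.5, 2), high = c(0.5, 1.0, 20)),
        t0 = spec$t0, tDwell = spec$tDwell, flow = spec$flow)
    front <- optimizeSeparation(models, space, mode = "pareto", pop = pop,
                                gens = gens, seed = seed,
                                plates = spec$plates)
  }
  list(simulation = sim, discovery = disc, models = models, front = front)
}

## ---- command-line interface -------------------------------------------

.cliDefaults <- function() list(
  seed = 1, outdir = "chromdev_out", n_components = 6,
  thr_uv = 0.95, alert_floor = 0.8, rank_cap = 6, noise_k = 3,
  valley_ratio = 0.5, mode = "lss", pop = 40, gens = 60,
  allow_alerts = FALSE)

#' Read a campaign configuration (YAML, JSON fallback)
#'
#' @param path config file; NULL gives the documented defaults.
#' @return named list of settings.
#' @export
readCampaignConfig <- function(path = NULL) {
  cfg <- .cliDefaults()
  if (!is.null(path)) {
    user <- tryCatch(yaml::read_yaml(path),
                     error = function(e) jsonlite::fromJSON(path))
    cfg[names(user)] <- user
  }
  cfg
}

.writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")

#' Command-line entry point
#'
#' Dispatches the subcommands `design`, `simulate`, `discover`, `fit`,
#' `optimize` and `report` onto the package functions, reading and writing
#' stage artifacts in the output directory. The resolved configuration and
#' seed are serialized next to the outputs for provenance. `discover`
#' returns exit code 2 when unresolved alerts remain and `--allow-alerts`
#' was not given; `fit` refuses to run in the same situation.
#'
#' @param argv character vector of arguments, e.g.
#'   `c("simulate", "--seed", "7", "--outdir", "out")`.
#' @return integer exit code (invisibly).
#' @export
chromdevMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    cat("usage: chromdev <design|simulate|discover|fit|optimize|report>",
        "[--config FILE] [--seed N] [--outdir DIR] [--allow-alerts]\n")
    return(invisible(1L))
  }
  cmd <- argv[1]
  args <- argv[-1]
  getOpt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1] else default
  }
  cfg <- readCampaignConfig(getOpt("--config"))
  if (!is.null(getOpt("--seed"))) cfg$seed <- as.integer(getOpt("--seed"))
  if (!is.null(getOpt("--outdir"))) cfg$outdir <- getOpt("--outdir")
  if ("--allow-alerts" %in% args) cfg$allow_alerts <- TRUE
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  .writeJSON(cfg, file.path(cfg$outdir, "config_used.json"))
  code <- switch(cmd,
    design = .cmdDesign(cfg),
    simulate = .cmdSimulate(cfg),
    discover = .cmdDiscover(cfg),
    fit = .cmdFit(cfg),
    optimize = .cmdOptimize(cfg),
    report = .cmdReport(cfg),
    { message("unknown command '", cmd, "'"); 1L })
  invisible(code)
}

.cfgSpec <- function(cfg)
  referenceCampaign(n = cfg$n_components, seed = cfg$seed)

.cmdDesign <- function(cfg) {
  spec <- .cfgSpec(cfg)
  writeDesignCSV(spec$design, file.path(cfg$outdir, "design.csv"))
  message("design: ", nrow(spec$design$real), " runs written")
  0L
}

.cmdSimulate <- function(cfg) {
  spec <- .cfgSpec(cfg)
  sim <- simulateCampaign(spec)
  for (ch in sim$chromatograms) {
    base <- file.path(cfg$outdir, runId(ch))
    writeUVMatrix(ch, paste0(base, "_uv.tsv"), paste0(base, "_meta.json"))
  }
  utils::write.csv(sim$groundTruth,
                   file.path(cfg$outdir, "ground_truth.csv"),
                   row.names = FALSE)
  writeDesignCSV(spec$design, file.path(cfg$outdir, "design.csv"))
  message("simulate: ", length(sim$chromatograms), " runs written")
  0L
}

.cmdLoadRuns <- function(cfg) {
  dm <- readDesignCSV(file.path(cfg$outdir, "design.csv"))
  chroms <- lapply(dm$runIds, function(rid) {
    base <- file.path(cfg$outdir, rid)
    if (!file.exists(paste0(base, "_uv.tsv")))
      stop("missing run artifact '", base, "_uv.tsv'; run `simulate` first")
    readUVMatrix(paste0(base, "_uv.tsv"), paste0(base, "_meta.json"),
                 runId = rid)
  })
  list(design = dm, chromatograms = chroms)
}

.cmdDiscover <- function(cfg) {
  runs <- .cmdLoadRuns(cfg)
  disc <- discoverComponents(runs$chromatograms, thrUV = cfg$thr_uv,
                             alertFloor = cfg$alert_floor,
                             rankCap = cfg$rank_cap, noiseK = cfg$noise_k,
                             valleyRatio = cfg$valley_ratio)
  utils::write.csv(assignmentFrame(disc$table),
                   file.path(cfg$outdir, "assignments.csv"),
                   row.names = FALSE)
  spectra <- vapply(disc$catalog$entries, `[[`,
                    numeric(length(disc$catalog$entries[[1]]$spectrum)),
                    "spectrum")
  utils::write.csv(spectra, file.path(cfg$outdir, "catalog_spectra.csv"),
                   row.names = FALSE)
  .writeJSON(disc$diagnostics, file.path(cfg$outdir, "diagnostics.json"))
  message("discover: ", length(disc$catalog$entries), " catalog entries")
  if (hasAlerts(disc$table) && !isTRUE(cfg$allow_alerts)) {
    message("unresolved alerts remain; rerun with --allow-alerts or edit")
    return(2L)
  }
  0L
}

.cmdFit <- function(cfg) {
  runs <- .cmdLoadRuns(cfg)
  disc <- discoverComponents(runs$chromatograms, thrUV = cfg$thr_uv,
                             alertFloor = cfg$alert_floor,
                             rankCap = cfg$rank_cap, noiseK = cfg$noise_k,
                             valleyRatio = cfg$valley_ratio)
  programs <- stats::setNames(lapply(runs$chromatograms,
                                     function(ch) runMeta(ch)$program),
                              runs$design$runIds)
  rdf <- data.frame(runId = runs$design$runIds, role = runs$design$roles)
  if (hasAlerts(disc$table) && !isTRUE(cfg$allow_alerts)) {
    message("fit refused: unresolved alerts (use --allow-alerts)")
    return(2L)
  }
  models <- fitRetentionModels(disc$table, rdf, programs, mode = cfg$mode,
                               coded = runs$design$coded,
                               allowAlerts = isTRUE(cfg$allow_alerts))
  reg <- lapply(models, function(m) c(
    list(component = m$componentId, mode = m$mode, r2 = m$r2Cal,
         rmse = m$rmseCal),
    if (m$mode == "lss") unclass(m$params)))
  .writeJSON(reg, file.path(cfg$outdir, "models.json"))
  gof <- do.call(rbind, lapply(models, function(m)
    cbind(component = m$componentId, goodnessOfFit(m)$pairs)))
  utils::write.csv(gof, file.path(cfg$outdir, "goodness_of_fit.csv"),
                   row.names = FALSE)
  message("fit: ", length(models), " retention models")
  0L
}

.cmdOptimize <- function(cfg) {
  mj <- file.path(cfg$outdir, "models.json")
  if (!file.exists(mj)) stop("missing models.json; run `fit` first")
  reg <- jsonlite::fromJSON(mj, simplifyDataFrame = FALSE)
  params <- lapply(reg, function(m)
    lssParams(m$logK0, m$S, tempCoef = m$tempCoef, tRef = m$tRef))
  sp <- searchSpace(data.frame(name = c("phi_initial", "phi_final", "t_G"),
                               low = c(0.02, 0.5, 2),
                               high = c(0.5, 1.0, 20)))
  front <- optimizeSeparation(params, sp, mode = "pareto", pop = cfg$pop,
                              gens = cfg$gens, seed = cfg$seed)
  utils::write.csv(front$members, file.path(cfg$outdir, "pareto_front.csv"),
                   row.names = FALSE)
  best <- front$members[which.max(front$members$criticalRs), ]
  prg <- decodeProgram(sp, as.numeric(best[seq_len(nrow(sp$parameters))]))
  .writeJSON(list(nodes = prg@nodes, temperature = prg@temperature,
                  t0 = prg@t0, t_dwell = prg@tDwell, flow = prg@flow,
                  criticalRs = best$criticalRs, runtime = best$runtime),
             file.path(cfg$outdir, "optimal_program.json"))
  message("optimize: front of ", nrow(front$members), " programs")
  0L
}

.cmdReport <- function(cfg) {
  out <- list()
  fa <- file.path(cfg$outdir, "assignments.csv")
  if (file.exists(fa)) {
    a <- utils::read.csv(fa)
    out$n_components <- length(unique(a$component))
    out$n_assigned <- sum(a$flag %in% c("assigned", "manual"))
    out$n_alerts <- sum(a$flag == "alert")
  }
  fm <- file.path(cfg$outdir, "models.json")
  if (file.exists(fm)) {
    reg <- jsonlite::fromJSON(fm, simplifyDataFrame = FALSE)
    out$n_models <- length(reg)
    out$median_r2 <- stats::median(vapply(reg, `[[`, numeric(1), "r2"))
  }
  fp <- file.path(cfg$outdir, "pareto_front.csv")
  if (file.exists(fp)) {
    fr <- utils::read.csv(fp)
    out$front_size <- nrow(fr)
    out$best_critical_Rs <- max(fr$criticalRs)
  }
  .writeJSON(out, file.path(cfg$outdir, "report.json"))
  message("report: ", file.path(cfg$outdir, "report.json"))
  0L
}
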