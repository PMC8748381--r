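## Sniff the delimiter of a delimited text file from its first line.
.sniffDelim <- function(line) {
  counts <- c(`\t` = lengths(regmatches(line, gregexpr("\t", line))),
              `,` = lengths(regmatches(line, gregexpr(",", line))),
              `;` = lengths(regmatches(line, gregexpr(";", line))))
  names(counts)[which.max(counts)]
}

#' Read run metadata from a JSON sidecar
#'
#' The sidecar carries, per run: the elution program as a list of
#' `{time, phi}` nodes, `temperature` (degC), `flow` (mL/min), `column_id`,
#' `role` (`calibration` or `validation`), `t0` (dead time, min) and
#' optionally `t_dwell` (min) and `time_unit` (`"min"`, the default, or
#' `"s"`; second-based programs are converted to minutes on load).
#'
#' @param path path to the JSON file.
#' @return metadata list with element `program` an [ElutionProgram-class].
#' @export
readRunMeta <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (f in c("program", "temperature", "flow", "column_id", "role", "t0"))
    if (is.null(m[[f]]))
      stop("metadata file '", path, "' is missing required field '", f, "'")
  if (!m$role %in% c("calibration", "validation"))
    stop("metadata field 'role' must be 'calibration' or 'validation'")
  fac <- 1
  if (!is.null(m$time_unit)) {
    if (m$time_unit == "s") fac <- 1 / 60
    else if (m$time_unit != "min")
      stop("time_unit must be 'min' or 's'")
  }
  nodes <- as.data.frame(m$program)
  nodes$time <- nodes$time * fac
  prog <- elutionProgram(nodes, temperature = m$temperature,
                         t0 = m$t0 * fac,
                         tDwell = if (is.null(m$t_dwell)) 0
                                  else m$t_dwell * fac,
                         flow = m$flow)
  list(program = prog, temperature = m$temperature, flow = m$flow,
       columnId = m$column_id, role = m$role, timeUnitFactor = fac)
}

#' @rdname readRunMeta
#' @param meta metadata list as stored in a [Chromatogram-class] (`meta`
#'   slot with `program`, `temperature`, `flow`, `columnId`, `role`).
#' @export
writeRunMeta <- function(meta, path) {
  prog <- meta$program
  out <- list(program = prog@nodes, temperature = meta$temperature,
              flow = meta$flow, column_id = meta$columnId, role = meta$role,
              t0 = prog@t0, t_dwell = prog@tDwell, time_unit = "min")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a DAD-UV matrix exported as delimited text
#'
#' Expected layout: first row = channel (wavelength) values, first column =
#' acquisition times; delimiter (tab, comma or semicolon) is sniffed.
#' Negative intensities are preserved as read; clipping to non-negative
#' values happens later, immediately before curve resolution.
#'
#' @param path data file.
#' @param metaPath JSON metadata sidecar (see [readRunMeta()]).
#' @param runId run identifier; defaults to the file name without extension.
#' @return A [Chromatogram-class] with `detector = "UV"`.
#' @export
readUVMatrix <- function(path, metaPath, runId = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("UV matrix file '", path, "' is empty")
  delim <- .sniffDelim(lines[1])
  parts <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != nf[1]))
    stop("ragged rows in '", path, "': row ", which(nf != nf[1])[1],
         " has ", nf[which(nf != nf[1])[1]], " fields, expected ", nf[1])
  header <- suppressWarnings(as.numeric(parts[[1]]))
  channels <- header[-1]
  if (anyNA(channels)) stop("non-numeric channel header in '", path, "'")
  body <- matrix(suppressWarnings(as.numeric(unlist(parts[-1]))),
                 ncol = nf[1], byrow = TRUE)
  if (anyNA(body)) stop("non-numeric data values in '", path, "'")
  time <- body[, 1]
  if (any(diff(time) <= 0))
    stop("non-monotonic time axis in '", path, "'")
  meta <- readRunMeta(metaPath)
  time <- time * meta$timeUnitFactor
  meta$timeUnitFactor <- NULL
  if (is.null(runId)) runId <- sub("\\.[^.]*$", "", basename(path))
  chromatogram(runId, time, channels, body[, -1, drop = FALSE],
               detector = "UV", meta = meta)
}

#' Write a DAD-UV chromatogram as tab-delimited text
#'
#' Layout mirrors [readUVMatrix()]: first row channel values, first column
#' times (minutes), full double precision, so a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param chrom a UV [Chromatogram-class].
#' @param path output file.
#' @param metaPath optional path for the JSON metadata sidecar.
#' @export
writeUVMatrix <- function(chrom, path, metaPath = NULL) {
  stopifnot(is(chrom, "Chromatogram"))
  if (chrom@detector != "UV") stop("writeUVMatrix requires a UV chromatogram")
  if (length(chrom@time) == 0 || length(chrom@channels) == 0)
    stop("refusing to write an empty chromatogram")
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time", fmt(chrom@channels)), collapse = "\t"), con)
  rows <- cbind(fmt(chrom@time),
                matrix(fmt(chrom@intensity), nrow = length(chrom@time)))
  writeLines(apply(rows, 1, paste, collapse = "\t"), con)
  if (!is.null(metaPath)) writeRunMeta(chrom@meta, metaPath)
  invisible(path)
}

#' Read long-format MS full-scan data and bin onto an m/z grid
#'
#' Input is a CSV with header `time,mz,intensity`, one row per recorded ion.
#' Intensities are accumulated into half-open, left-inclusive bins
#' `[mz0 + i*bin, mz0 + (i+1)*bin)` anchored at the floor of the smallest
#' observed m/z; one matrix row per distinct scan time. Binning conserves
#' total ion current exactly.
#'
#' @param path CSV file.
#' @param metaPath JSON metadata sidecar.
#' @param mzBin bin width in Da (> 0); default 1 (unit-resolution
#'   quadrupole data).
#' @param runId run identifier; defaults to the file name.
#' @return A [Chromatogram-class] with `detector = "MS"`; channel values are
#'   bin centres.
#' @export
readMSScans <- function(path, metaPath, mzBin = 1, runId = NULL) {
  if (mzBin <= 0) stop("mzBin must be > 0")
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("MS scan file '", path, "' is empty")
  if (!all(c("time", "mz", "intensity") %in% names(df)))
    stop("MS scan file must have columns time, mz, intensity")
  meta <- readRunMeta(metaPath)
  times <- sort(unique(df$time)) * meta$timeUnitFactor
  mz0 <- floor(min(df$mz))
  binIdx <- floor((df$mz - mz0) / mzBin)
  nBins <- max(binIdx) + 1
  rowIdx <- match(df$time * meta$timeUnitFactor, times)
  X <- matrix(0, nrow = length(times), ncol = nBins)
  for (r in seq_len(nrow(df)))
    X[rowIdx[r], binIdx[r] + 1] <- X[rowIdx[r], binIdx[r] + 1] +
      df$intensity[r]
  centres <- mz0 + (seq_len(nBins) - 0.5) * mzBin
  meta$timeUnitFactor <- NULL
  if (is.null(runId)) runId <- sub("\\.[^.]*$", "", basename(path))
  chromatogram(runId, times, centres, X, detector = "MS", meta = meta)
}
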