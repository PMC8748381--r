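#' @import methods
NULL

#' Elution program
#'
#' Describes a (multi-)linear gradient elution program as a sequence of
#' `(time, phi)` nodes, where `phi` is the volume fraction of organic
#' modifier (\%B in decimal form), together with the operational context
#' needed to simulate retention: column temperature, dead time `t0`
#' (elution time of an unretained solute), dwell time `tDwell` (delay
#' between the pump mixer and the column inlet) and flow rate.
#'
#' Between nodes the composition is interpolated linearly; before the first
#' and after the last node it is held constant. All times are minutes.
#'
#' @slot nodes data.frame with numeric columns `time` (min, non-decreasing,
#'   starting at 0) and `phi` (fraction in \[0, 1\]).
#' @slot temperature column temperature, degrees Celsius.
#' @slot t0 dead time, minutes (> 0).
#' @slot tDwell dwell time, minutes (>= 0).
#' @slot flow flow rate, mL/min (> 0).
#' @export
setClass("ElutionProgram",
  representation(
    nodes = "data.frame",
    temperature = "numeric",
    t0 = "numeric",
    tDwell = "numeric",
    flow = "numeric"
  )
)

setValidity("ElutionProgram", function(object) {
  msgs <- character()
  nd <- object@nodes
  if (!all(c("time", "phi") %in% names(nd)))
    msgs <- c(msgs, "nodes must have columns 'time' and 'phi'")
  else {
    if (nrow(nd) < 1) msgs <- c(msgs, "at least one program node required")
    if (nrow(nd) >= 1 && nd$time[1] != 0)
      msgs <- c(msgs, "first node time must be 0")
    if (is.unsorted(nd$time)) msgs <- c(msgs, "node times must be non-decreasing")
    if (any(nd$phi < 0 | nd$phi > 1)) msgs <- c(msgs, "phi must lie in [0, 1]")
  }
  if (length(object@t0) != 1 || object@t0 <= 0) msgs <- c(msgs, "t0 must be > 0")
  if (object@tDwell < 0) msgs <- c(msgs, "tDwell must be >= 0")
  if (object@flow <= 0) msgs <- c(msgs, "flow must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct an elution program
#'
#' @param nodes data.frame (or matrix) with columns `time` (min) and `phi`,
#'   or a single phi value for an isocratic program.
#' @param temperature column temperature in degrees Celsius.
#' @param t0 dead time in minutes.
#' @param tDwell dwell time in minutes.
#' @param flow flow rate in mL/min.
#' @return An [ElutionProgram-class] object.
#' @examples
#' elutionProgram(data.frame(time = c(0, 10), phi = c(0.05, 0.95)), t0 = 1)
#' elutionProgram(0.3, t0 = 1)   # isocratic at 30 % B
#' @export
elutionProgram <- function(nodes, temperature = 25, t0 = 1, tDwell = 0,
                           flow = 1) {
  if (is.numeric(nodes) && length(nodes) == 1L)
    nodes <- data.frame(time = 0, phi = nodes)
  nodes <- as.data.frame(nodes)[, c("time", "phi")]
  new("ElutionProgram", nodes = nodes, temperature = temperature,
      t0 = t0, tDwell = tDwell, flow = flow)
}

setMethod("show", "ElutionProgram", function(object) {
  nd <- object@nodes
  cat(sprintf("ElutionProgram: %d node(s), phi %.3g -> %.3g over %.3g min\n",
              nrow(nd), nd$phi[1], nd$phi[nrow(nd)], nd$time[nrow(nd)]))
  cat(sprintf("  T = %g degC, t0 = %g min, tDwell = %g min, flow = %g mL/min\n",
              object@temperature, object@t0, object@tDwell, object@flow))
})

#' Chromatogram: one run's time x channel intensity matrix
#'
#' Container for second-order chromatographic raw data: a matrix of detector
#' responses over a strictly increasing time axis (minutes) and a strictly
#' increasing channel axis (wavelengths in nm for DAD-UV, m/z bin centres
#' for full-scan MS), plus acquisition metadata.
#'
#' @slot runId run identifier.
#' @slot time numeric vector of acquisition times, minutes, strictly
#'   increasing.
#' @slot axisKind `"wavelength_nm"` or `"mz"`.
#' @slot channels numeric vector of channel values, strictly increasing.
#' @slot intensity numeric matrix, `length(time)` x `length(channels)`.
#' @slot detector `"UV"` or `"MS"`.
#' @slot meta list with elements `program` ([ElutionProgram-class]),
#'   `temperature`, `flow`, `columnId`, `role` (`"calibration"` or
#'   `"validation"`).
#' @export
setClass("Chromatogram",
  representation(
    runId = "character",
    time = "numeric",
    axisKind = "character",
    channels = "numeric",
    intensity = "matrix",
    detector = "character",
    meta = "list"
  )
)

setValidity("Chromatogram", function(object) {
  msgs <- character()
  if (length(object@time) < 1) msgs <- c(msgs, "empty time axis")
  if (any(diff(object@time) <= 0))
    msgs <- c(msgs, "time axis must be strictly increasing")
  if (length(object@channels) < 1) msgs <- c(msgs, "empty channel axis")
  if (any(diff(object@channels) <= 0))
    msgs <- c(msgs, "channel axis must be strictly increasing")
  if (!object@axisKind %in% c("wavelength_nm", "mz"))
    msgs <- c(msgs, "axisKind must be 'wavelength_nm' or 'mz'")
  if (object@axisKind == "wavelength_nm" && any(object@channels <= 0))
    msgs <- c(msgs, "wavelength channels must be positive")
  if (nrow(object@intensity) != length(object@time))
    msgs <- c(msgs, "intensity rows must match time length")
  if (ncol(object@intensity) != length(object@channels))
    msgs <- c(msgs, "intensity columns must match channel length")
  if (anyNA(object@intensity)) msgs <- c(msgs, "intensity contains NA")
  if (!object@detector %in% c("UV", "MS"))
    msgs <- c(msgs, "detector must be 'UV' or 'MS'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Chromatogram
#'
#' @param runId run identifier string.
#' @param time acquisition times (minutes), strictly increasing.
#' @param channels channel values (nm or m/z), strictly increasing.
#' @param intensity matrix `length(time)` x `length(channels)`.
#' @param detector `"UV"` or `"MS"`.
#' @param axisKind channel axis kind; defaults to `"wavelength_nm"` for UV
#'   and `"mz"` for MS.
#' @param meta metadata list (see [Chromatogram-class]).
#' @return A [Chromatogram-class] object.
#' @export
chromatogram <- function(runId, time, channels, intensity,
                         detector = c("UV", "MS"), axisKind = NULL,
                         meta = list()) {
  detector <- match.arg(detector)
  if (is.null(axisKind))
    axisKind <- if (detector == "UV") "wavelength_nm" else "mz"
  new("Chromatogram", runId = as.character(runId), time = as.numeric(time),
      axisKind = axisKind, channels = as.numeric(channels),
      intensity = as.matrix(intensity), detector = detector, meta = meta)
}

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf("Chromatogram '%s' [%s]: %d time points x %d channels\n",
              object@runId, object@detector, length(object@time),
              length(object@channels)))
  cat(sprintf("  time %.3g..%.3g min, channels %.4g..%.4g (%s)\n",
              min(object@time), max(object@time), min(object@channels),
              max(object@channels), object@axisKind))
  if (!is.null(object@meta$role))
    cat(sprintf("  role: %s, column: %s\n", object@meta$role,
                if (is.null(object@meta$columnId)) "?" else object@meta$columnId))
})

#' Accessors for Chromatogram objects
#'
#' @param x a [Chromatogram-class].
#' @return `intensityMatrix` the intensity matrix; `chromTime` the time axis
#'   (minutes); `channelValues` the channel axis; `detectorType` `"UV"` or
#'   `"MS"`; `runId` the run identifier; `runMeta` the metadata list.
#' @name chromatogram-accessors
NULL

#' @rdname chromatogram-accessors
#' @export
intensityMatrix <- function(x) x@intensity
#' @rdname chromatogram-accessors
#' @export
chromTime <- function(x) x@time
#' @rdname chromatogram-accessors
#' @export
channelValues <- function(x) x@channels
#' @rdname chromatogram-accessors
#' @export
detectorType <- function(x) x@detector
#' @rdname chromatogram-accessors
#' @export
runId <- function(x) x@runId
#' @rdname chromatogram-accessors
#' @export
runMeta <- function(x) x@meta
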