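#' Define a screening factor
#'
#' @param name factor name.
#' @param role one of `"gradient_time"`, `"phi_initial"`, `"phi_final"`,
#'   `"temperature"`, `"other"`.
#' @param low,high factor range (low < high). For `gradient_time` the ratio
#'   `high/low` must be at least 3 so that the gradient runs carry enough
#'   solvent-strength information for the retention model; a smaller ratio
#'   triggers a warning (or automatic widening, see [screeningDesign()]).
#' @return A `"FactorDef"` list.
#' @export
factorDef <- function(name, role = c("other", "gradient_time", "phi_initial",
                                     "phi_final", "temperature"),
                      low, high) {
  role <- match.arg(role)
  stopifnot(is.numeric(low), is.numeric(high))
  if (low >= high) stop("factor '", name, "': low must be < high")
  structure(list(name = name, role = role, low = low, high = high),
            class = "FactorDef")
}

## Coded three-level irregular fractions with the economical run counts
## 2 / 6 / 8 / 18 for 1..4 factors. Entries chosen so the second-order model
## matrix has maximal rank (full column rank for 1, 2 and 4 factors; for 3
## factors the 8 runs span 8 of the 10 second-order terms, the design's
## saturation limit).
.hokeTables <- list(
  `1` = matrix(c(-1, 1), ncol = 1),
  `2` = matrix(c(-1, -1,
                  1, -1,
                 -1,  1,
                  1,  1,
                  1,  0,
                  0,  1), ncol = 2, byrow = TRUE),
  `3` = matrix(c(-1, -1, -1,
                  1,  1, -1,
                  1, -1,  1,
                 -1,  1,  1,
                  1,  0,  0,
                  0,  1,  0,
                  0,  0,  1,
                  0,  0,  0), ncol = 3, byrow = TRUE),
  `4` = matrix(c(-1, -1, -1, -1,
                  1,  1, -1, -1,
                  1, -1,  1, -1,
                  1, -1, -1,  1,
                 -1,  1,  1, -1,
                 -1,  1, -1,  1,
                 -1, -1,  1,  1,
                  1,  1,  1,  1,
                  1,  1,  0,  0,
                  1,  0,  1,  0,
                  1,  0,  0,  1,
                  1,  0,  0,  0,
                 -1,  0,  0,  0,
                  0,  1,  0,  0,
                  0, -1,  0,  0,
                  0,  0,  1,  0,
                  0,  0,  0,  1,
                  0,  0,  0,  0), ncol = 4, byrow = TRUE)
)

#' Hoke-sized coded screening design
#'
#' Returns an economical coded design matrix (levels in \[-1, 1\]) for 1 to 4
#' factors with the run counts 2, 6, 8 and 18 of the Hoke D6 family of
#' irregular second-order fractions. Rows are unique and the second-order
#' model matrix built on the rows has maximal rank.
#'
#' @param nFactors number of factors, 1..4.
#' @return coded matrix with one row per calibration run.
#' @examples
#' nrow(hokeD6(3))  # 8
#' @export
hokeD6 <- function(nFactors) {
  if (length(nFactors) != 1 || !nFactors %in% 1:4)
    stop("nFactors must be an integer in 1..4")
  m <- .hokeTables[[as.character(nFactors)]]
  colnames(m) <- paste0("x", seq_len(nFactors))
  m
}

#' Expand coded factors to a second-order model matrix
#'
#' Intercept, linear, two-way interaction and quadratic terms on coded
#' levels.
#'
#' @param coded coded design matrix.
#' @return model matrix.
#' @export
secondOrderModelMatrix <- function(coded) {
  coded <- as.matrix(coded)
  k <- ncol(coded)
  out <- cbind(`(Intercept)` = 1, coded)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      v <- coded[, i] * coded[, j]
      out <- cbind(out, v)
      colnames(out)[ncol(out)] <- paste0(colnames(coded)[i], ":",
                                         colnames(coded)[j])
    }
  }
  sq <- coded^2
  colnames(sq) <- paste0(colnames(coded), "^2")
  cbind(out, sq)
}

#' Map coded levels to real factor units
#'
#' Affine map per column: -1 to `low`, +1 to `high`.
#'
#' @param coded coded matrix with entries in \[-1, 1\].
#' @param factors list of [factorDef()] objects, one per column.
#' @return matrix in factor units.
#' @export
scaleToReal <- function(coded, factors) {
  coded <- as.matrix(coded)
  stopifnot(ncol(coded) == length(factors))
  if (any(coded < -1 - 1e-12 | coded > 1 + 1e-12))
    stop("coded entries must lie in [-1, 1]")
  lows <- vapply(factors, `[[`, numeric(1), "low")
  highs <- vapply(factors, `[[`, numeric(1), "high")
  out <- sweep(sweep((coded + 1) / 2, 2, highs - lows, `*`), 2, lows, `+`)
  colnames(out) <- vapply(factors, `[[`, character(1), "name")
  out
}

#' Map real factor values back to coded levels
#'
#' Inverse of [scaleToReal()].
#' @inheritParams scaleToReal
#' @param real matrix in factor units.
#' @export
scaleToCoded <- function(real, factors) {
  real <- as.matrix(real)
  lows <- vapply(factors, `[[`, numeric(1), "low")
  highs <- vapply(factors, `[[`, numeric(1), "high")
  out <- sweep(sweep(real, 2, lows, `-`), 2, (highs - lows) / 2, `/`) - 1
  colnames(out) <- paste0("x", seq_along(factors))
  out
}

#' Build a screening design for a campaign
#'
#' Combines the coded Hoke-sized design with factor ranges, enforcing the
#' gradient-time level ratio (>= 3:1) and the rule that pH may not be used as
#' a factor under UV-only detection (pH shifts UV spectra, which would defeat
#' spectral component tracking; it is allowed, with a warning, when MS
#' detection is present).
#'
#' @param factors list of [factorDef()] objects (1 to 4).
#' @param widenGradient if TRUE, a gradient-time range with `high/low < 3` is
#'   widened (low reduced) to reach the 3:1 ratio instead of only warning.
#' @param msPresent logical; is MS detection configured?
#' @return A `"DesignMatrix"` list with elements `factors`, `coded`,
#'   `real`, `roles` (all `"calibration"`), `runIds`.
#' @export
screeningDesign <- function(factors, widenGradient = FALSE,
                            msPresent = FALSE) {
  if (inherits(factors, "FactorDef")) factors <- list(factors)
  nms <- tolower(vapply(factors, `[[`, character(1), "name"))
  if (any(nms %in% c("ph", "p.h.")) && !msPresent)
    stop("pH is not accepted as a factor under UV-only detection: ",
         "it alters component UV spectra")
  if (any(nms %in% c("ph", "p.h.")) && msPresent)
    warning("pH as a factor: UV spectra may shift across runs; ",
            "component tracking will rely on MS spectra")
  for (i in seq_along(factors)) {
    f <- factors[[i]]
    if (f$role == "gradient_time" && f$high / f$low < 3) {
      if (widenGradient) {
        factors[[i]]$low <- f$high / 3
        warning("gradient-time range widened to reach the 3:1 level ratio")
      } else {
        warning("gradient-time levels in ratio < 3:1; ",
                "retention model quality will suffer")
      }
    }
  }
  coded <- hokeD6(length(factors))
  real <- scaleToReal(coded, factors)
  dm <- list(factors = factors, coded = coded, real = real,
             roles = rep("calibration", nrow(coded)),
             runIds = sprintf("run%02d", seq_len(nrow(coded))))
  class(dm) <- "DesignMatrix"
  dm
}

#' Append validation runs to a design
#'
#' Validation runs never enter the retention-model calculation; they assess
#' its predictive ability. Strategy `"extreme"` places them at the range
#' bounds of the gradient-time factor (slowest and fastest gradients, outside
#' the calibration settings where possible); `"intermediate"` places them at
#' interior points not coincident with any calibration row, which also aids
#' the discovery process.
#'
#' @param dm a `"DesignMatrix"` from [screeningDesign()].
#' @param n number of validation runs (>= 1).
#' @param strategy `"intermediate"` or `"extreme"`.
#' @return the augmented `"DesignMatrix"`.
#' @export
addValidationRuns <- function(dm, n = 1,
                              strategy = c("intermediate", "extreme")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(dm, "DesignMatrix"), n >= 1)
  k <- length(dm$factors)
  gtCol <- which(vapply(dm$factors, `[[`, character(1), "role") ==
                   "gradient_time")
  rows <- matrix(0, nrow = n, ncol = k)
  if (strategy == "extreme") {
    for (i in seq_len(n)) {
      rows[i, ] <- 0
      if (length(gtCol)) rows[i, gtCol[1]] <- if (i %% 2 == 1) 1 else -1
      else rows[i, 1] <- if (i %% 2 == 1) 1 else -1
    }
  } else {
    ## interior points off the coded lattice used for calibration
    levs <- c(0.5, -0.5, 0.25, -0.25, 0.75, -0.75)
    for (i in seq_len(n))
      rows[i, ] <- rep(levs[(i - 1) %% length(levs) + 1], k)
  }
  ## never duplicate a calibration row; under the extreme strategy the
  ## gradient-time bound is kept and the other factors are displaced
  free <- if (strategy == "extreme" && length(gtCol) && k > 1)
    setdiff(seq_len(k), gtCol[1]) else seq_len(k)
  for (i in seq_len(n)) {
    tries <- 0
    while (any(apply(dm$coded, 1, function(r)
      all(abs(r - rows[i, ]) < 1e-9)))) {
      rows[i, free] <- pmin(rows[i, free] * 0.9 + 0.15, 1)
      tries <- tries + 1
      if (tries > 50) stop("could not place a distinct validation run")
    }
  }
  colnames(rows) <- colnames(dm$coded)
  dm$coded <- rbind(dm$coded, rows)
  dm$real <- rbind(dm$real, scaleToReal(rows, dm$factors))
  dm$roles <- c(dm$roles, rep("validation", n))
  dm$runIds <- c(dm$runIds,
                 sprintf("val%02d", seq_len(n)))
  dm
}

#' @export
print.DesignMatrix <- function(x, ...) {
  cat(sprintf("DesignMatrix: %d factor(s), %d calibration + %d validation run(s)\n",
              length(x$factors), sum(x$roles == "calibration"),
              sum(x$roles == "validation")))
  df <- as.data.frame(x$real)
  df <- cbind(run = x$runIds, role = x$roles, df)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write / read a design as CSV
#'
#' One row per run: `run_id`, `role`, then one column per factor in real
#' units. Factor definitions travel in a JSON header comment line.
#'
#' @param dm a `"DesignMatrix"`.
#' @param path file path.
#' @export
writeDesignCSV <- function(dm, path) {
  hdr <- jsonlite::toJSON(lapply(dm$factors, unclass), auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#factors ", hdr), con)
  df <- data.frame(run_id = dm$runIds, role = dm$roles,
                   as.data.frame(dm$real), check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDesignCSV
#' @export
readDesignCSV <- function(path) {
  if (!file.exists(path))
    stop("missing design file '", path,
         "': run the design or simulate stage first")
  lines <- readLines(path)
  if (!startsWith(lines[1], "#factors "))
    stop("missing #factors header line in design file")
  fl <- jsonlite::fromJSON(sub("^#factors ", "", lines[1]),
                           simplifyDataFrame = FALSE)
  factors <- lapply(fl, function(f)
    factorDef(f$name, f$role, f$low, f$high))
  df <- utils::read.csv(textConnection(lines[-1]), check.names = FALSE)
  real <- as.matrix(df[, -(1:2), drop = FALSE])
  dm <- list(factors = factors, coded = scaleToCoded(real, factors),
             real = real, roles = df$role, runIds = df$run_id)
  class(dm) <- "DesignMatrix"
  dm
}
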