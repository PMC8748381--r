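## Shared fixtures, built in code.

## Two smooth, moderately correlated reference spectra on a coarse UV axis.
fixtureChannels <- seq(210, 400, by = 5)

fixtureSpectrum <- function(centers, widths, amps = rep(1, length(centers)),
                            channels = fixtureChannels) {
  s <- rowSums(vapply(seq_along(centers), function(b)
    amps[b] * exp(-0.5 * ((channels - centers[b]) / widths[b])^2),
    numeric(length(channels))))
  s / max(s)
}

## Bilinear cluster matrix from Gaussian profiles and given spectra.
fixtureCluster <- function(tR, sigma, amounts, spectra,
                           tgrid = seq(0, 10, by = 1 / 30)) {
  C <- vapply(seq_along(tR), function(i)
    amounts[i] * exp(-0.5 * ((tgrid - tR[i]) / sigma[i])^2),
    numeric(length(tgrid)))
  list(X = C %*% t(spectra), C = C, time = tgrid)
}

## An ExtractedComponent stub for discovery tests.
fixtureComponent <- function(runId, spectrum, apexTime, pure = TRUE,
                             msSpectrum = NULL, truncated = FALSE) {
  structure(list(runId = runId, clusterId = NA_character_,
                 profile = c(0.5, 1, 0.5), spectrum = spectrum,
                 apexTime = apexTime, purity = 1, pure = pure,
                 truncated = truncated, msSpectrum = msSpectrum,
                 noiseCount = NA_integer_),
            class = "ExtractedComponent")
}

## Deterministic vector with unit Euclidean norm.
unitVec <- function(x) x / sqrt(sum(x^2))
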