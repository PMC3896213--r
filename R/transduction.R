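# Transduction: SED -> receptor current per spike-initiation zone.
#
# Each cluster of M Merkel cell-neurite complexes feeds one spike-initiation
# zone with current
#     I(t) = beta + M * (alpha * eps(t) + lambda * d eps/dt) + omega(t)
# where omega(t) is a 7-point moving average of Box-Muller Gaussian noise,
# drawn independently per cluster and not scaled by M.

#' Transduction parameters
#'
#' @param beta Offset current, mA.
#' @param alpha Static gain, mA/Pa, applied to SED.
#' @param lambda Dynamic gain, mA.ms/Pa, applied to the SED rate of change
#'   (backward difference on the 1-ms grid, Pa/ms, so no unit conversion is
#'   needed).
#'
#' The defaults are the values fitted for the four-zone \{8,5,3,1\}
#' reference arbor.
#'
#' @return An object of class `transduction_parameters`.
#' @export
transduction_parameters <- function(beta = 5.643e-8,
                                    alpha = 2.539e-14,
                                    lambda = 5.833e-11) {
  if (!all(is.finite(c(beta, alpha, lambda))))
    stop("transduction parameters must be finite", call. = FALSE)
  if (alpha < 0 || lambda < 0)
    stop("alpha and lambda must be non-negative", call. = FALSE)
  structure(list(beta = beta, alpha = alpha, lambda = lambda),
            class = "transduction_parameters")
}

#' Current-noise configuration
#'
#' The noise term is generated as i.i.d. Gaussian deviates (Box-Muller
#' transform of uniform variates), standard deviation `sigma`, smoothed with
#' a centred moving average of width `window` (shrinking at the edges).  The
#' moving average reduces the interior-sample variance to `sigma^2 / window`
#' and introduces autocorrelation up to lag `window - 1`.
#'
#' @param sigma Standard deviation of the underlying (pre-averaging) Gaussian
#'   deviates, mA.  The default is calibrated so that static-phase
#'   normalized-interspike-interval variability falls in the range seen in
#'   slowly adapting type I afferents (coefficient of variation roughly
#'   0.3-0.8).
#' @param window Moving-average width, odd, >= 1.
#' @param enabled Set `FALSE` for deterministic simulations.
#' @param shared If `TRUE` one noise series is shared by all clusters of an
#'   afferent; the default draws an independent series per cluster.
#'
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(sigma = 5e-9, window = 7, enabled = TRUE,
                         shared = FALSE) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (window < 1 || window %% 2 == 0)
    stop("window must be odd and >= 1", call. = FALSE)
  structure(list(sigma = sigma, window = as.integer(window),
                 enabled = isTRUE(enabled), shared = isTRUE(shared)),
            class = "noise_config")
}

#' Smoothed Gaussian noise series
#'
#' Draws `n` i.i.d. N(0, sigma^2) deviates via the Box-Muller transform and
#' applies a centred `window`-point moving average, with a shrinking window
#' at the edges.  Uses R's random number stream, so results are reproducible
#' under [set.seed()].
#'
#' @param n Number of samples.
#' @param noise A [noise_config()] object.
#' @return Numeric vector of length `n`, mA.
#' @export
noise_series <- function(n, noise = noise_config()) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!noise$enabled || noise$sigma == 0) return(numeric(n))
  bm_noise_cpp(as.integer(n), noise$sigma, noise$window)
}

#' Transduce an SED trace into per-zone receptor currents
#'
#' Evaluates the cluster transduction function for every zone of an arbor:
#' `I_z(t) = beta + M_z * (alpha * eps + lambda * d eps/dt) + omega_z(t)`.
#' The SED derivative is a per-sample backward difference in Pa/ms (first
#' sample 0).  One independent noise series is added per cluster (or one
#' shared series if so configured); the noise is not scaled by cluster size.
#'
#' @param sed A `sed_trace` (or numeric SED vector on a 1-ms grid).
#' @param M Integer vector of cluster sizes, one per zone, all >= 1.
#' @param params A [transduction_parameters()] object.
#' @param noise A [noise_config()] object.
#' @return A matrix (samples x zones) of currents in mA, with attribute
#'   `"time_ms"`.
#' @export
transduce <- function(sed, M, params = transduction_parameters(),
                      noise = noise_config()) {
  eps <- if (inherits(sed, "sed_trace")) sed$sed_pa else as.numeric(sed)
  time_ms <- if (inherits(sed, "sed_trace")) sed$time_ms
             else seq_along(eps) - 1
  M <- as.integer(M)
  if (any(M < 1)) stop("configuration error: cluster sizes must be >= 1",
                       call. = FALSE)
  n <- length(eps)
  deps <- c(0, diff(eps))                       # Pa per 1-ms sample
  base <- params$alpha * eps + params$lambda * deps
  I <- matrix(params$beta, n, length(M))
  for (z in seq_along(M)) I[, z] <- I[, z] + M[z] * base
  if (noise$enabled && noise$sigma > 0) {
    if (noise$shared) {
      w <- noise_series(n, noise)
      I <- I + w
    } else {
      for (z in seq_along(M)) I[, z] <- I[, z] + noise_series(n, noise)
    }
  }
  attr(I, "time_ms") <- time_ms
  I
}
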