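# Skin mechanics: ramp-and-hold indentation -> strain energy density (SED).
#
# The full finite-element skin model is replaced by a reduced-order uniaxial
# surrogate: an incompressible Mooney-Rivlin tissue column in series with a
# linear-elastic substrate column, followed by a quasi-linear viscoelastic
# (Prony series) hereditary integral.  An import path for externally computed
# SED traces (e.g. from a finite-element solver) is provided so the surrogate
# can be bypassed.

#' Skin material and geometry parameters
#'
#' Material constants for the uniaxial skin surrogate: a Mooney-Rivlin
#' (incompressible, hyperelastic) tissue column representing the epidermis,
#' dermis and subcutaneous layers, in series with a linear-elastic substrate
#' column, plus a two-term Prony relaxation series applied quasi-linearly to
#' the elastic strain energy density.
#'
#' @param C10,C01 Mooney-Rivlin coefficients of the tissue, Pa.
#' @param substrate_modulus Young's modulus of the elastic substrate, Pa.
#' @param prony_g1,prony_g2 Dimensionless Prony relaxation weights; their sum
#'   must be below 1 so the long-time modulus `g_inf = 1 - g1 - g2` stays
#'   positive.
#' @param prony_tau1,prony_tau2 Prony relaxation time constants, s
#'   (`tau2 > tau1 > 0`).
#' @param tissue_thickness Total thickness of the tissue column, micrometres.
#'   The default sums a 17 um epidermis, 224 um dermis and 101 um
#'   subcutaneous layer.
#' @param substrate_thickness Substrate column thickness, micrometres.
#'   Commanded depths can exceed the tissue stack, so series substrate
#'   compliance is required for the surrogate to remain physical.
#' @param friction_coefficient Probe-skin friction; recorded for provenance,
#'   unused by the uniaxial surrogate.
#' @param probe_diameter_mm Probe tip diameter, mm; provenance only.
#'
#' @return An object of class `skin_parameters`.
#' @export
skin_parameters <- function(C10 = 14847, C01 = 41410,
                            substrate_modulus = 906098,
                            prony_g1 = 0.391, prony_tau1 = 0.25,
                            prony_g2 = 0.226, prony_tau2 = 9.371,
                            tissue_thickness = 342,
                            substrate_thickness = 2000,
                            friction_coefficient = 0.3,
                            probe_diameter_mm = 3) {
  if (C10 <= 0 || C01 <= 0 || substrate_modulus <= 0)
    stop("all moduli must be positive", call. = FALSE)
  if (prony_g1 < 0 || prony_g2 < 0 || prony_g1 + prony_g2 >= 1)
    stop("Prony weights must be non-negative with g1 + g2 < 1", call. = FALSE)
  if (!(prony_tau2 > prony_tau1 && prony_tau1 > 0))
    stop("Prony time constants must satisfy tau2 > tau1 > 0", call. = FALSE)
  if (tissue_thickness <= 0 || substrate_thickness <= 0)
    stop("thicknesses must be positive", call. = FALSE)
  structure(list(
    C10 = C10, C01 = C01,
    substrate_modulus = substrate_modulus,
    prony_g1 = prony_g1, prony_tau1 = prony_tau1,
    prony_g2 = prony_g2, prony_tau2 = prony_tau2,
    g_inf = 1 - prony_g1 - prony_g2,
    tissue_thickness = tissue_thickness,
    substrate_thickness = substrate_thickness,
    friction_coefficient = friction_coefficient,
    probe_diameter_mm = probe_diameter_mm
  ), class = "skin_parameters")
}

#' Ramp-and-hold displacement stimulus
#'
#' Builds a constant-acceleration ramp from skin contact to the commanded
#' depth followed by a hold, sampled on a uniform grid.  The ramp duration is
#' `sqrt(2 * depth / acceleration)`; the trajectory equals the commanded
#' depth exactly from the end of the ramp onwards.
#'
#' @param depth Commanded indentation depth, mm (0 to 0.5).
#' @param acceleration Ramp acceleration, mm/s^2 (> 0).
#' @param hold Hold duration at commanded depth, s (> 0).
#' @param fs Sampling rate, Hz.
#'
#' @return An object of class `displacement_stimulus` with elements
#'   `time_ms`, `displacement_mm`, `ramp_ms`, plus the call parameters.
#' @export
make_ramp_hold <- function(depth, acceleration, hold = 5, fs = 1000) {
  if (!is.finite(depth) || depth < 0 || depth > 0.5)
    stop("invalid stimulus: depth must lie in [0, 0.5] mm", call. = FALSE)
  if (!is.finite(acceleration) || acceleration <= 0)
    stop("invalid stimulus: ramp acceleration must be positive", call. = FALSE)
  if (!is.finite(hold) || hold <= 0)
    stop("invalid stimulus: hold duration must be positive", call. = FALSE)
  t_ramp <- sqrt(2 * depth / acceleration)            # s
  n <- round((t_ramp + hold) * fs) + 1L
  t <- (seq_len(n) - 1L) / fs                          # s
  d <- 0.5 * acceleration * t^2
  d[t >= t_ramp] <- depth
  d[n] <- depth
  structure(list(
    time_ms = t * 1000,
    displacement_mm = d,
    ramp_ms = t_ramp * 1000,
    depth = depth, acceleration = acceleration,
    hold = hold, fs = fs
  ), class = "displacement_stimulus")
}

# Uniaxial Cauchy stress of an incompressible Mooney-Rivlin solid at
# stretch lam (compressive for lam < 1); sign follows the stretch.
.mr_uniaxial_stress <- function(lam, C10, C01) {
  2 * (lam^2 - 1 / lam) * (C10 + C01 / lam)
}

# Mooney-Rivlin strain energy density at uniaxial stretch lam.
.mr_sed <- function(lam, C10, C01) {
  I1 <- lam^2 + 2 / lam
  I2 <- 1 / lam^2 + 2 * lam
  C10 * (I1 - 3) + C01 * (I2 - 3)
}

#' Instantaneous (elastic) strain energy density at a given depth
#'
#' Partitions the commanded depth between the Mooney-Rivlin tissue column and
#' the linear-elastic substrate column by uniaxial force balance, then returns
#' the strain energy density of the tissue column.  This is the elastic
#' response before viscoelastic relaxation.
#'
#' @param depth Indentation depth, mm.
#' @param params A [skin_parameters()] object.
#' @return Strain energy density, Pa (0 at zero depth, strictly increasing).
#' @export
instantaneous_sed <- function(depth, params = skin_parameters()) {
  if (length(depth) > 1L)
    return(vapply(depth, instantaneous_sed, numeric(1), params = params))
  if (depth < 0) stop("depth must be non-negative", call. = FALSE)
  if (depth == 0) return(0)
  h_t <- params$tissue_thickness / 1000   # mm
  h_s <- params$substrate_thickness / 1000
  if (depth >= h_t + h_s)
    stop("mechanics error: depth exceeds total column capacity", call. = FALSE)
  # residual(d_t): compressive tissue stress minus substrate stress
  resid <- function(d_t) {
    lam <- 1 - d_t / h_t
    s_t <- -.mr_uniaxial_stress(lam, params$C10, params$C01)  # > 0 in compression
    s_s <- params$substrate_modulus * (depth - d_t) / h_s
    s_t - s_s
  }
  upper <- min(depth, h_t * 0.999999)
  sol <- tryCatch(
    stats::uniroot(resid, c(0, upper), tol = 1e-12),
    error = function(e) stop(sprintf(
      "mechanics error: force-balance solver failed at depth %g mm (%s)",
      depth, conditionMessage(e)), call. = FALSE)
  )
  lam <- 1 - sol$root / h_t
  .mr_sed(lam, params$C10, params$C01)
}

#' Quasi-linear viscoelastic convolution of an elastic SED series
#'
#' Applies the reduced relaxation function
#' `G(t) = g_inf + g1 exp(-t/tau1) + g2 exp(-t/tau2)` to the elastic strain
#' energy density series via the hereditary integral
#' `eps(t) = integral G(t - s) dW/ds ds`, discretized with the standard
#' recursive exponential update (exact for piecewise-linear W), so cost is
#' linear in the number of samples.
#'
#' @param W Elastic SED series, Pa, on a uniform grid with `W[1] = 0`.
#' @param params A [skin_parameters()] object.
#' @param fs Sampling rate of the grid, Hz.
#' @return Relaxed SED series, Pa, same length as `W`.
#' @export
qlv_convolve <- function(W, params = skin_parameters(), fs = 1000) {
  n <- length(W)
  if (n == 0L) stop("empty series", call. = FALSE)
  dt <- 1 / fs                                   # s
  g_inf <- params$g_inf
  out <- numeric(n)
  out[1] <- W[1]
  q1 <- 0; q2 <- 0
  e1 <- exp(-dt / params$prony_tau1)
  e2 <- exp(-dt / params$prony_tau2)
  # exact update for W linear over each step
  a1 <- params$prony_g1 * params$prony_tau1 / dt * (1 - e1)
  a2 <- params$prony_g2 * params$prony_tau2 / dt * (1 - e2)
  if (n > 1L) {
    dW <- diff(W)
    for (k in 2:n) {
      q1 <- e1 * q1 + a1 * dW[k - 1L]
      q2 <- e2 * q2 + a2 * dW[k - 1L]
      out[k] <- g_inf * W[k] + q1 + q2
    }
  }
  pmax(out, 0)
}

#' Strain energy density trace for a ramp-and-hold stimulus
#'
#' Runs the full skin surrogate: instantaneous Mooney-Rivlin/substrate force
#' balance per sample during the ramp, then quasi-linear viscoelastic
#' relaxation over the whole trace.
#'
#' @param stim A [make_ramp_hold()] stimulus.
#' @param params A [skin_parameters()] object.
#' @return An object of class `sed_trace` with `time_ms`, `sed_pa` and the
#'   source stimulus.
#' @export
sed_trace <- function(stim, params = skin_parameters()) {
  stopifnot(inherits(stim, "displacement_stimulus"))
  d <- stim$displacement_mm
  W <- numeric(length(d))
  ramp_idx <- which(d < stim$depth)
  if (length(ramp_idx)) W[ramp_idx] <- instantaneous_sed(d[ramp_idx], params)
  if (stim$depth > 0) {
    W_hold <- instantaneous_sed(stim$depth, params)
    W[d >= stim$depth] <- W_hold
  }
  eps <- qlv_convolve(W, params, fs = stim$fs)
  structure(list(time_ms = stim$time_ms, sed_pa = eps, stimulus = stim),
            class = "sed_trace")
}

#' Read / write SED traces as CSV
#'
#' The on-disk format is a two-column CSV with header `time_ms, sed_pa` on a
#' uniform time grid; this is the interchange point for externally computed
#' finite-element SED output.
#'
#' @param path File path.
#' @return `read_sed_trace` returns a `sed_trace`; `write_sed_trace`
#'   invisibly returns `path`.
#' @export
read_sed_trace <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("format error: empty SED trace file", call. = FALSE)
  if (!all(c("time_ms", "sed_pa") %in% names(df)))
    stop("format error: SED trace CSV needs columns time_ms, sed_pa",
         call. = FALSE)
  bad <- which(df$sed_pa < 0)
  if (length(bad))
    stop(sprintf("format error: negative SED at row %d", bad[1]), call. = FALSE)
  if (nrow(df) > 2L) {
    dts <- diff(df$time_ms)
    if (max(abs(dts - dts[1])) > 1e-6 * max(dts[1], 1))
      stop(sprintf("format error: non-uniform time grid near row %d",
                   which.max(abs(dts - dts[1])) + 1L), call. = FALSE)
  }
  structure(list(time_ms = df$time_ms, sed_pa = df$sed_pa, stimulus = NULL),
            class = "sed_trace")
}

#' @rdname read_sed_trace
#' @param trace A `sed_trace` object.
#' @export
write_sed_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sed_trace"))
  utils::write.csv(
    data.frame(time_ms = trace$time_ms, sed_pa = trace$sed_pa),
    path, row.names = FALSE)
  invisible(path)
}
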