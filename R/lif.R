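# Spike initiation: an array of leaky integrate-and-fire zones with
# antidromic cross-zone resetting.
#
# Each spike-initiation zone obeys  R C du/dt = -u(t) + R I(t)  and fires
# when u reaches the threshold; the spike resets every zone in the afferent
# and starts a shared absolute refractory period, so the fastest-driven zone
# acts as the driver for the merged train.

#' Leaky integrate-and-fire parameters
#'
#' @param tau Membrane time constant, ms.
#' @param capacitance Membrane capacitance, mF.  The resistance is derived as
#'   `R = tau / capacitance` (5e8 Ohm with the defaults, so mA-scale currents
#'   map onto tens of mV, commensurate with the threshold).
#' @param threshold Spike-initiation threshold, mV.
#' @param refractory Absolute refractory period, ms.
#' @param reset Reset potential, mV (resting potential of the membrane
#'   equation).
#' @param step Integrator output step, ms; must divide the 1-ms current grid.
#'   Substeps below 1 ms sharpen spike-time resolution.
#' @param clamp_refractory If `TRUE` (default) integration is suspended and
#'   the membrane clamped at the reset potential during refractoriness;
#'   if `FALSE` zones keep integrating but cannot fire.
#'
#' @return An object of class `lif_parameters`.
#' @export
lif_parameters <- function(tau = 5, capacitance = 1e-8, threshold = 30,
                           refractory = 1, reset = 0, step = 1,
                           clamp_refractory = TRUE) {
  if (tau <= 0 || capacitance <= 0 || threshold <= 0 || refractory <= 0)
    stop("tau, capacitance, threshold and refractory must be positive",
         call. = FALSE)
  if (step <= 0) stop("integrator step must be positive", call. = FALSE)
  structure(list(tau = tau, capacitance = capacitance,
                 threshold = threshold, refractory = refractory,
                 reset = reset, step = step,
                 resistance = tau / capacitance,
                 clamp_refractory = isTRUE(clamp_refractory)),
            class = "lif_parameters")
}

#' Integrate an afferent's spike-initiation-zone array
#'
#' Runs the coupled leaky integrate-and-fire array by classical
#' fourth-order Runge-Kutta with the current held constant over each input
#' sample.  A spike in any zone antidromically resets all zones and starts a
#' 1-ms (by default) absolute refractory period; simultaneous crossings are
#' resolved by largest overshoot, then lowest zone id.
#'
#' @param currents A samples x zones matrix of currents in mA (as returned
#'   by [transduce()]), on a uniform grid.
#' @param params A [lif_parameters()] object.
#' @param dt_ms Grid spacing of `currents`, ms.
#' @return An object of class `spike_train`: a data frame with columns
#'   `time_ms` and `zone`, sorted by time.
#' @export
integrate_afferent <- function(currents, params = lif_parameters(),
                               dt_ms = 1) {
  if (is.null(dim(currents))) currents <- matrix(currents, ncol = 1)
  if (ncol(currents) < 1L) stop("at least one zone is required", call. = FALSE)
  n_sub <- round(dt_ms / params$step)
  if (n_sub < 1L) n_sub <- 1L
  res <- lif_integrate_cpp(currents, params$tau, params$capacitance,
                           params$threshold, params$refractory, params$reset,
                           dt_ms, as.integer(n_sub), params$clamp_refractory)
  spike_train(res$time_ms, res$zone)
}

#' Construct / validate a spike train
#'
#' @param time_ms Spike times in ms, strictly increasing.
#' @param zone Originating zone id per spike.
#' @param refractory Minimum allowed spacing used for validation, ms.
#' @return A `spike_train` data frame.
#' @export
spike_train <- function(time_ms, zone = rep(1L, length(time_ms)),
                        refractory = NULL) {
  time_ms <- as.numeric(time_ms)
  if (is.unsorted(time_ms, strictly = TRUE))
    stop("spike times must be strictly increasing", call. = FALSE)
  if (!is.null(refractory) && length(time_ms) > 1L &&
      any(diff(time_ms) < refractory - 1e-9))
    stop("spikes closer than the refractory period", call. = FALSE)
  structure(data.frame(time_ms = time_ms, zone = as.integer(zone)),
            class = c("spike_train", "data.frame"))
}

#' Closed-form interspike interval under constant drive
#'
#' For a single zone under constant current `I`, the steady interspike
#' interval is `refractory + tau * log(RI / (RI - threshold))`; used as the
#' analytic oracle for the numerical integrator.
#'
#' @param I Constant current, mA.
#' @param params A [lif_parameters()] object.
#' @return Interval in ms, or `Inf` if the drive is subthreshold.
#' @export
lif_isi_exact <- function(I, params = lif_parameters()) {
  RI <- params$resistance * I
  if (RI <= params$threshold) return(Inf)
  params$refractory + params$tau * log(RI / (RI - params$threshold))
}

#' Check that the offset current alone is subthreshold
#'
#' With zero strain energy density the only deterministic drive is the offset
#' `beta`; spiking at rest is ruled out if `R * beta < threshold`.
#'
#' @param params A [lif_parameters()] object.
#' @param trans A [transduction_parameters()] object.
#' @return A list with `pass` (logical), `drive_mV` (R*beta) and `margin_mV`
#'   (threshold minus drive).
#' @export
baseline_subthreshold_check <- function(params = lif_parameters(),
                                        trans = transduction_parameters()) {
  drive <- params$resistance * trans$beta
  list(pass = drive < params$threshold,
       drive_mV = drive,
       margin_mV = params$threshold - drive)
}

#' Read / write spike trains as CSV
#'
#' Two-column CSV `time_ms, zone`; the reader validates sortedness and
#' refractory spacing.
#'
#' @param path File path.
#' @param refractory Minimum spacing enforced on read, ms (`NULL` to skip).
#' @return `read_spike_train` returns a `spike_train`.
#' @export
read_spike_train <- function(path, refractory = 1) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "zone") %in% names(df)))
    stop("format error: spike train CSV needs columns time_ms, zone",
         call. = FALSE)
  spike_train(df$time_ms, df$zone, refractory = refractory)
}

#' @rdname read_spike_train
#' @param train A `spike_train` object.
#' @export
write_spike_train <- function(train, path) {
  utils::write.csv(as.data.frame(train), path, row.names = FALSE)
  invisible(path)
}
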