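# Stimulation protocol and response statistics: ramp/static firing rates,
# exponential displacement-response fits and their comparison, percent
# firing-rate change, normalized interspike intervals, first-spike latency.

#' Stimulation protocol
#'
#' The standard protocol crosses five displacement depths with three ramp
#' accelerations (15 unique stimulations) and repeats each five times,
#' giving 75 indexed simulations.
#'
#' @param depths Displacement depths, mm.
#' @param accelerations Ramp accelerations, mm/s^2.
#' @param hold Hold duration, s.
#' @param repetitions Repetitions per unique stimulation.
#' @return An object of class `stimulus_protocol`; its `table` element is a
#'   data frame with one row per indexed simulation (`index`, `stim_id`,
#'   `depth`, `acceleration`, `rep`).
#' @export
stimulus_protocol <- function(depths = c(0.04, 0.12, 0.20, 0.28, 0.36),
                              accelerations = c(20, 81, 1143),
                              hold = 5, repetitions = 5) {
  if (any(depths < 0.01 - 1e-12) || any(depths > 0.36 + 1e-12))
    stop("depths must lie within [0.01, 0.36] mm", call. = FALSE)
  grid <- expand.grid(depth = depths, acceleration = accelerations,
                      KEEP.OUT.ATTRS = FALSE)
  grid$stim_id <- seq_len(nrow(grid))
  tab <- grid[rep(seq_len(nrow(grid)), each = repetitions), ]
  tab$rep <- rep(seq_len(repetitions), times = nrow(grid))
  tab$index <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(depths = depths, accelerations = accelerations,
                 hold = hold, repetitions = repetitions,
                 table = tab[, c("index", "stim_id", "depth",
                                 "acceleration", "rep")]),
            class = "stimulus_protocol")
}

#' Ramp-phase firing rate
#'
#' Number of spikes during the ramp (stimulus onset to commanded depth)
#' divided by the ramp duration.
#'
#' @param train A `spike_train` aligned to stimulus onset at t = 0.
#' @param stim The [make_ramp_hold()] stimulus.
#' @return Rate in Hz.
#' @export
ramp_rate <- function(train, stim) {
  if (stim$ramp_ms <= 0) stop("undefined rate: zero ramp duration",
                              call. = FALSE)
  n <- sum(train$time_ms >= 0 & train$time_ms < stim$ramp_ms)
  n / (stim$ramp_ms / 1000)
}

#' Static-phase firing rate
#'
#' Number of spikes in the final 2.5 s of the hold divided by 2.5 s; this
#' window excludes the period of rapid adaptation that follows the ramp.
#'
#' @inheritParams ramp_rate
#' @param window Static analysis window, s.
#' @return Rate in Hz.
#' @export
static_rate <- function(train, stim, window = 2.5) {
  if (stim$hold < window)
    stop(sprintf("hold (%g s) shorter than the %g-s static window",
                 stim$hold, window), call. = FALSE)
  t_end <- stim$ramp_ms + stim$hold * 1000
  t_start <- t_end - window * 1000
  sum(train$time_ms >= t_start & train$time_ms <= t_end) / window
}

#' First-spike latency
#'
#' @inheritParams ramp_rate
#' @return Latency of the first spike after onset, ms; `NA` if no spike.
#' @export
first_spike_latency <- function(train, stim = NULL) {
  t <- train$time_ms[train$time_ms >= 0]
  if (length(t) == 0L) return(NA_real_)
  t[1]
}

#' Single-exponential displacement-response fit
#'
#' Fits `rate = Y0 * exp(kappa * depth)` by nonlinear least squares;
#' `Y0` (Hz) is the threshold firing rate (y-intercept) and `kappa` (1/mm)
#' the mechanical sensitivity.
#'
#' @param depths Depths, mm (>= 3 distinct values).
#' @param rates Static firing rates, Hz, same length.
#' @return A list with `Y0`, `kappa`, `r_squared`, `ssr` and the `nls` fit.
#' @export
fit_displacement_response <- function(depths, rates) {
  if (length(unique(depths)) < 3L)
    stop("need at least 3 distinct depths", call. = FALSE)
  df <- data.frame(D = depths, r = rates)
  # log-linear start values (guard zero rates)
  pos <- df$r > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(r) ~ D, data = df[pos, ])
    start <- list(Y0 = exp(unname(stats::coef(lf)[1])),
                  kappa = unname(stats::coef(lf)[2]))
  } else {
    start <- list(Y0 = max(mean(df$r), 0.1), kappa = 1)
  }
  ss_tot <- sum((df$r - mean(df$r))^2)
  # a start that already reproduces the data exactly (e.g. constant rates)
  # makes the least-squares step degenerate; return it directly
  ssr0 <- sum((df$r - start$Y0 * exp(start$kappa * df$D))^2)
  if (ssr0 <= 1e-20 * max(1, sum(df$r^2))) {
    return(list(Y0 = start$Y0, kappa = start$kappa,
                r_squared = 1, ssr = ssr0, fit = NULL))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ Y0 * exp(kappa * D), data = df, start = start,
                      lower = c(Y0 = 0, kappa = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf(
      "fit error (start Y0=%.3g, kappa=%.3g): %s",
      start$Y0, start$kappa, conditionMessage(e)), call. = FALSE)
  )
  co <- stats::coef(fit)
  ssr <- sum(stats::residuals(fit)^2)
  list(Y0 = unname(co["Y0"]), kappa = unname(co["kappa"]),
       r_squared = if (ss_tot > 0) 1 - ssr / ss_tot else 1,
       ssr = ssr, fit = fit)
}

# SSR of the exponential model fitted with one parameter shared across two
# datasets ("kappa" or "Y0"), or with all parameters shared ("both").
.shared_exp_ssr <- function(dA, rA, dB, rB, share) {
  df <- data.frame(D = c(dA, dB), r = c(rA, rB),
                   grp = rep(c(0, 1), c(length(dA), length(dB))))
  fA <- fit_displacement_response(dA, rA)
  fB <- fit_displacement_response(dB, rB)
  start <- switch(share,
    kappa = list(kappa = (fA$kappa + fB$kappa) / 2, Y0a = fA$Y0, Y0b = fB$Y0),
    Y0    = list(Y0 = (fA$Y0 + fB$Y0) / 2, ka = fA$kappa, kb = fB$kappa),
    both  = list(Y0 = (fA$Y0 + fB$Y0) / 2, kappa = (fA$kappa + fB$kappa) / 2))
  form <- switch(share,
    kappa = r ~ (Y0a * (1 - grp) + Y0b * grp) * exp(kappa * D),
    Y0    = r ~ Y0 * exp((ka * (1 - grp) + kb * grp) * D),
    both  = r ~ Y0 * exp(kappa * D))
  fit <- minpack.lm::nlsLM(form, data = df, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  list(ssr = sum(stats::residuals(fit)^2), n_par = length(start),
       n = nrow(df))
}

#' Compare two exponential displacement-response fits
#'
#' Extra sum-of-squares F test of whether a parameter (`kappa`, `Y0`, or
#' both) differs between two datasets: the nested model shares the
#' parameter(s), the full model fits each dataset separately.
#'
#' @param depthsA,ratesA First dataset.
#' @param depthsB,ratesB Second dataset.
#' @param share Which parameter the nested model shares.
#' @return A list with `F`, `p_value`, `df1`, `df2`, and the separate and
#'   shared SSRs.
#' @export
compare_exponential_fits <- function(depthsA, ratesA, depthsB, ratesB,
                                     share = c("kappa", "Y0", "both")) {
  share <- match.arg(share)
  fA <- fit_displacement_response(depthsA, ratesA)
  fB <- fit_displacement_response(depthsB, ratesB)
  ssr_full <- fA$ssr + fB$ssr
  sh <- .shared_exp_ssr(depthsA, ratesA, depthsB, ratesB, share)
  n <- sh$n
  p_full <- 4
  df1 <- p_full - sh$n_par
  df2 <- n - p_full
  if (df1 < 1 || df2 < 1) stop("degenerate degrees of freedom", call. = FALSE)
  Fstat <- max(0, (sh$ssr - ssr_full) / df1) / (ssr_full / df2)
  list(F = Fstat, p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, ssr_separate = ssr_full, ssr_shared = sh$ssr)
}

#' Percent firing-rate change between two configurations
#'
#' The difference in summed firing rates across all stimulations divided by
#' the lower of the two sums, expressed in percent.  The unsigned statistic
#' always places the larger-sum configuration in the numerator and is
#' therefore non-negative and invariant to argument order; set
#' `signed = TRUE` to keep the direction (positive when `ratesA` sums
#' higher).
#'
#' @param ratesA,ratesB Aligned firing-rate vectors, equal length.
#' @param signed Report the signed variant?
#' @return Percent change.
#' @export
percent_fr_change <- function(ratesA, ratesB, signed = FALSE) {
  if (length(ratesA) != length(ratesB))
    stop("rate vectors must have equal length", call. = FALSE)
  sA <- sum(ratesA); sB <- sum(ratesB)
  lo <- min(sA, sB)
  if (lo <= 0) stop("undefined: lower summed rate is zero", call. = FALSE)
  val <- abs(sA - sB) / lo * 100
  if (signed && sA < sB) val <- -val
  val
}

#' Pooled normalized interspike intervals
#'
#' Each static-phase interspike interval is divided by the mean interval of
#' its own stimulus, then pooled; the pooled sample mean is 1 by
#' construction up to unequal interval counts per stimulus.
#'
#' @param isi_by_stimulus A list of numeric vectors, one per stimulus, of
#'   static-phase interspike intervals (ms); entries with fewer than one
#'   interval are dropped.
#' @return Numeric vector of normalized intervals.
#' @export
normalized_isi <- function(isi_by_stimulus) {
  keep <- Filter(function(v) length(v) >= 1, isi_by_stimulus)
  if (length(keep) == 0L) stop("no interspike intervals", call. = FALSE)
  unlist(lapply(keep, function(v) v / mean(v)), use.names = FALSE)
}

#' Static-phase interspike intervals of a train
#'
#' @inheritParams static_rate
#' @return Numeric vector of intervals, ms (empty if fewer than two
#'   static-phase spikes).
#' @export
static_isi <- function(train, stim, window = 2.5) {
  t_end <- stim$ramp_ms + stim$hold * 1000
  t_start <- t_end - window * 1000
  t <- train$time_ms[train$time_ms >= t_start & train$time_ms <= t_end]
  if (length(t) < 2L) return(numeric(0))
  diff(t)
}
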