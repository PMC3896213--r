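# Synthetic inputs: the prototypical target response (from linear
# regressions of ramp- and static-phase rates against depth) and synthetic
# arbor populations spanning the observed morphometric ranges.

#' Prototypical response regressions
#'
#' Linear regressions of firing rate against displacement depth that define
#' the prototypical slowly adapting type I response: one ramp-phase
#' regression per ramp acceleration and a single pooled static-phase
#' regression.  The default coefficients are synthetic values chosen to be
#' qualitatively consistent with published displacement-response data for
#' mouse afferents; they are configuration values, not measurements.
#'
#' @param ramp_slopes Ramp-rate slopes, Hz/mm, one per acceleration.
#' @param ramp_intercepts Ramp-rate intercepts, Hz.
#' @param accelerations Accelerations the ramp regressions belong to,
#'   mm/s^2, ascending.
#' @param static_slope,static_intercept Pooled static-phase regression.
#' @return An object of class `prototypical_regression`.
#' @export
prototypical_regression <- function(ramp_slopes = c(150, 300, 700),
                                    ramp_intercepts = c(5, 10, 20),
                                    accelerations = c(20, 81, 1143),
                                    static_slope = 30,
                                    static_intercept = 1) {
  stopifnot(length(ramp_slopes) == length(accelerations),
            length(ramp_intercepts) == length(accelerations))
  structure(list(ramp_slopes = ramp_slopes,
                 ramp_intercepts = ramp_intercepts,
                 accelerations = accelerations,
                 static_slope = static_slope,
                 static_intercept = static_intercept),
            class = "prototypical_regression")
}

#' Evaluate the prototypical target response over a protocol
#'
#' Evaluates the regressions at every indexed simulation of the protocol and
#' clips negative predictions to zero.
#'
#' @param reg A [prototypical_regression()].
#' @param protocol A [stimulus_protocol()].
#' @return The protocol table with added columns `rfr_target` and
#'   `hfr_target` (Hz).
#' @export
make_prototypical_response <- function(reg = prototypical_regression(),
                                       protocol = stimulus_protocol()) {
  tab <- protocol$table
  ai <- match(tab$acceleration, reg$accelerations)
  if (anyNA(ai))
    stop("protocol acceleration missing from the regression set",
         call. = FALSE)
  tab$rfr_target <- pmax(0, reg$ramp_slopes[ai] * tab$depth +
                              reg$ramp_intercepts[ai])
  tab$hfr_target <- pmax(0, reg$static_slope * tab$depth +
                              reg$static_intercept)
  tab
}

#' Arbor population model
#'
#' Ranges for sampling synthetic arbor configurations: the number of
#' spike-initiation zones, total transduction units, and cluster-skew
#' magnitude spanning what is observed in reconstructed touch-dome
#' afferents.
#'
#' @param zone_range Inclusive range of zone counts.
#' @param unit_range Inclusive range of total transduction units.
#' @param skew_range Inclusive range of skew magnitudes (units per rank).
#' @param max_attempts Rejection-sampling cap before declaring the ranges
#'   infeasible.
#' @return An object of class `arbor_population_model`.
#' @export
arbor_population_model <- function(zone_range = c(3, 5),
                                   unit_range = c(13, 20),
                                   skew_range = c(0.6, 4.5),
                                   max_attempts = 1e4) {
  structure(list(zone_range = zone_range, unit_range = unit_range,
                 skew_range = skew_range, max_attempts = max_attempts),
            class = "arbor_population_model")
}

#' Sample a synthetic arbor configuration
#'
#' Draws the zone count and total units uniformly from the model ranges,
#' partitions the units uniformly at random among zones (each cluster >= 1)
#' and accepts the draw if the skew magnitude falls in the requested range;
#' rejection sampling is capped at `max_attempts`.
#'
#' @param model An [arbor_population_model()].
#' @return An [arbor_configuration()].
#' @export
sample_arbor <- function(model = arbor_population_model()) {
  pick <- function(rng) {
    x <- seq.int(rng[1], rng[2])
    if (length(x) == 1L) x else sample(x, 1)
  }
  for (i in seq_len(model$max_attempts)) {
    nz <- pick(model$zone_range)
    total <- pick(model$unit_range)
    if (total < nz) next
    # uniform random composition of total into nz positive parts
    if (nz == 1) {
      parts <- total
    } else {
      cuts <- sort(sample(seq_len(total - 1L), nz - 1L))
      parts <- diff(c(0L, cuts, total))
    }
    cfg <- arbor_configuration(parts)
    if (cfg$n_zones < 2) next
    sk <- skew_slope(cfg)$skew
    if (sk >= model$skew_range[1] - 1e-9 &&
        sk <= model$skew_range[2] + 1e-9)
      return(cfg)
  }
  stop("infeasible arbor ranges: no configuration found within the attempt cap",
       call. = FALSE)
}
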