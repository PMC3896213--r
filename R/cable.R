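# Closed-form cable-theory and conduction-delay calculations that justify
# abstracting each spike-initiation zone as a point neuron with zero
# inter-zone delay.

#' Cable parameters
#'
#' @param Rm Specific membrane resistance, Ohm.cm^2.
#' @param Ri Axial resistivity, Ohm.cm.
#' @param diameter Neurite diameter, micrometres.
#' @param neurite_velocity Conduction velocity in unmyelinated neurites, m/s.
#' @param myelinated_velocity Conduction velocity in myelinated branches, m/s.
#' @param refractory Nodal refractory period, ms.
#' @param na_inactivation Sodium-channel inactivation timescale, ms.  Cited
#'   but not printed in the source literature; 1 ms is assumed and the
#'   report states the assumption.
#' @return An object of class `cable_parameters`.
#' @export
cable_parameters <- function(Rm = 15000, Ri = 125, diameter = 1,
                             neurite_velocity = 0.7,
                             myelinated_velocity = 13,
                             refractory = 1, na_inactivation = 1) {
  vals <- c(Rm, Ri, diameter, neurite_velocity, myelinated_velocity,
            refractory, na_inactivation)
  if (any(vals <= 0)) stop("all cable parameters must be positive",
                           call. = FALSE)
  structure(list(Rm = Rm, Ri = Ri, diameter = diameter,
                 neurite_velocity = neurite_velocity,
                 myelinated_velocity = myelinated_velocity,
                 refractory = refractory,
                 na_inactivation = na_inactivation),
            class = "cable_parameters")
}

#' Passive length constant of a neurite
#'
#' `lambda = sqrt(Rm * d / (4 * Ri))` with `Rm` in Ohm.cm^2, `Ri` in Ohm.cm
#' and the diameter converted to cm; returned in micrometres.
#'
#' @param params A [cable_parameters()] object.
#' @return Length constant, micrometres.
#' @export
length_constant <- function(params = cable_parameters()) {
  d_cm <- params$diameter * 1e-4
  lambda_cm <- sqrt(params$Rm * d_cm / (4 * params$Ri))
  lambda_cm * 1e4
}

#' Conduction delay along a path
#'
#' @param path_length Path length, micrometres.
#' @param velocity Conduction velocity, m/s.
#' @return Delay, ms.
#' @export
conduction_delay <- function(path_length, velocity) {
  if (any(path_length < 0) || any(velocity <= 0))
    stop("path length must be non-negative and velocity positive",
         call. = FALSE)
  (path_length * 1e-6) / velocity * 1e3
}

#' Point-neuron justification report
#'
#' Evaluates the three criteria under which neurite and branch geometry can
#' be abstracted away: (1) neurite path lengths are much shorter than the
#' passive length constant, so receptor current spreads efficiently to the
#' heminodes; (2) conduction delays along neurites are much shorter than the
#' sodium-channel inactivation timescale; (3) conduction delays along
#' myelinated branches are much shorter than the nodal refractory period, so
#' travel-time differences cannot create competitive interactions between
#' zones.
#'
#' @param neurite_paths Neurite path lengths (tips to heminodes),
#'   micrometres.
#' @param branch_paths Myelinated branch path lengths (heminodes to the
#'   convergence node), micrometres.
#' @param params A [cable_parameters()] object.
#' @param factor How many times smaller the compared quantity must be to
#'   count as "much" smaller.
#' @return A list with per-criterion pass flags and margins (ratio of the
#'   limiting scale to the worst-case value) and an overall `pass`.
#' @export
point_neuron_report <- function(neurite_paths, branch_paths,
                                params = cable_parameters(), factor = 5) {
  lam <- length_constant(params)
  worst_neurite <- max(neurite_paths)
  c1_margin <- lam / worst_neurite
  neurite_delay <- conduction_delay(worst_neurite, params$neurite_velocity)
  c2_margin <- params$na_inactivation / neurite_delay
  branch_delay <- conduction_delay(max(branch_paths),
                                   params$myelinated_velocity)
  c3_margin <- params$refractory / branch_delay
  crit <- c(electrotonic = c1_margin >= factor,
            neurite_delay = c2_margin >= factor,
            branch_delay = c3_margin >= factor)
  list(pass = all(crit),
       criteria = crit,
       margins = c(electrotonic = c1_margin,
                   neurite_delay = c2_margin,
                   branch_delay = c3_margin),
       length_constant_um = lam,
       na_inactivation_assumed_ms = params$na_inactivation)
}
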