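# End-to-end orchestration: skin -> transduction -> spike-initiation array
# -> response statistics, and the structural experiments built on top
# (grouping perturbations, cluster fill-up surveys, small-vs-large
# comparisons).

#' Precompute SED traces for a protocol
#'
#' The skin stage does not depend on the transduction parameters, so the
#' strain-energy-density trace of each unique stimulation can be computed
#' once and reused across configurations and fitting evaluations.
#'
#' @param protocol A [stimulus_protocol()].
#' @param skin A [skin_parameters()] object.
#' @return A list, indexed by `stim_id`, of `list(stim, sed)` pairs.
#' @export
precompute_sed <- function(protocol, skin = skin_parameters()) {
  tab <- protocol$table
  ids <- unique(tab$stim_id)
  out <- vector("list", max(ids))
  for (id in ids) {
    row <- tab[match(id, tab$stim_id), ]
    stim <- make_ramp_hold(row$depth, row$acceleration, hold = protocol$hold)
    out[[id]] <- list(stim = stim, sed = sed_trace(stim, skin))
  }
  out
}

#' Simulate an afferent over a full protocol
#'
#' Runs every indexed simulation of the protocol through the pipeline
#' (SED -> per-cluster currents -> coupled leaky integrate-and-fire array ->
#' merged spike train) and summarizes each as ramp rate, static rate and
#' first-spike latency.
#'
#' Reproducibility: either give `seed` (per-repetition noise seeds are then
#' drawn once from it) or pass `rep_seeds` explicitly.  Reusing one
#' `rep_seeds` vector across two configurations yields paired comparisons
#' with common noise.
#'
#' @param arbor An [arbor_configuration()].
#' @param trans [transduction_parameters()] for this configuration.
#' @param protocol A [stimulus_protocol()].
#' @param skin,lif,noise Stage parameter objects.
#' @param seed Integer master seed (ignored when `rep_seeds` given).
#' @param rep_seeds Optional integer vector, one seed per indexed
#'   simulation.
#' @param sed_cache Optional result of [precompute_sed()].
#' @param collect_isi If `TRUE`, attach static-phase interspike intervals
#'   per indexed simulation as attribute `"isi"`.
#' @return The protocol table with columns `rfr` (Hz), `hfr` (Hz) and
#'   `latency_ms` appended.
#' @export
simulate_protocol <- function(arbor, trans = transduction_parameters(),
                              protocol = stimulus_protocol(),
                              skin = skin_parameters(),
                              lif = lif_parameters(),
                              noise = noise_config(),
                              seed = NULL, rep_seeds = NULL,
                              sed_cache = NULL, collect_isi = FALSE) {
  tab <- protocol$table
  n <- nrow(tab)
  if (is.null(rep_seeds)) {
    if (!is.null(seed)) {
      set.seed(seed)
      rep_seeds <- sample.int(.Machine$integer.max, n)
    }
  } else if (length(rep_seeds) != n) {
    stop("rep_seeds must have one entry per indexed simulation",
         call. = FALSE)
  }
  if (is.null(sed_cache)) sed_cache <- precompute_sed(protocol, skin)
  rfr <- hfr <- lat <- numeric(n)
  isis <- if (collect_isi) vector("list", n)
  for (i in seq_len(n)) {
    entry <- sed_cache[[tab$stim_id[i]]]
    if (!is.null(rep_seeds)) set.seed(rep_seeds[i])
    I <- transduce(entry$sed, arbor$clusters, trans, noise)
    train <- integrate_afferent(I, lif)
    rfr[i] <- ramp_rate(train, entry$stim)
    hfr[i] <- static_rate(train, entry$stim)
    lat[i] <- first_spike_latency(train)
    if (collect_isi) isis[[i]] <- static_isi(train, entry$stim)
  }
  tab$rfr <- rfr
  tab$hfr <- hfr
  tab$latency_ms <- lat
  if (collect_isi) attr(tab, "isi") <- isis
  tab
}

#' Model runner for response-surface fitting
#'
#' Wraps [simulate_protocol()] into the `(beta, alpha, lambda) ->
#' data.frame(rfr, hfr)` closure that [rsm_fit()] evaluates.  The SED cache
#' and per-repetition noise seeds are frozen at construction so every
#' candidate parameter set sees identical stimuli and noise.
#'
#' @inheritParams simulate_protocol
#' @param seed Master seed used to freeze the per-repetition noise seeds.
#' @return A function of `(beta, alpha, lambda)`.
#' @export
make_model_runner <- function(arbor, protocol = stimulus_protocol(),
                              skin = skin_parameters(),
                              lif = lif_parameters(),
                              noise = noise_config(),
                              seed = 1) {
  sed_cache <- precompute_sed(protocol, skin)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, nrow(protocol$table))
  function(beta, alpha, lambda) {
    simulate_protocol(arbor, transduction_parameters(beta, alpha, lambda),
                      protocol, skin, lif, noise,
                      rep_seeds = rep_seeds, sed_cache = sed_cache)
  }
}

#' The four prototypical model arbors and their fitted parameters
#'
#' Reference arbor configurations spanning the observed range of zone
#' counts (3-5) and end-organ sizes (13-20 transduction units), each with
#' the transduction parameters fitted for it, plus the averaged parameter
#' set used for cross-architecture comparisons.
#'
#' @return A list with elements `arbors` (list of
#'   [arbor_configuration()]), `parameters` (matching list of
#'   [transduction_parameters()]) and `averaged` (a single
#'   [transduction_parameters()]).
#' @export
prototypical_arbors <- function() {
  arbors <- list(
    arbor_configuration(c(8, 5, 3, 1), "Arbor 1"),
    arbor_configuration(c(7, 6, 4, 2, 1), "Arbor 2"),
    arbor_configuration(c(5, 4, 3, 1), "Arbor 3"),
    arbor_configuration(c(6, 4, 3), "Arbor 4")
  )
  parameters <- list(
    transduction_parameters(5.643e-8, 2.539e-14, 5.833e-11),
    transduction_parameters(5.648e-8, 2.386e-14, 4.994e-11),
    transduction_parameters(5.672e-8, 2.641e-14, 6.491e-11),
    transduction_parameters(5.669e-8, 2.612e-14, 6.211e-11)
  )
  list(arbors = arbors, parameters = parameters,
       averaged = transduction_parameters(5.658e-8, 2.545e-14, 5.882e-11))
}

#' Grouping-perturbation design
#'
#' The paired cluster regroupings used to quantify how primary- and
#' secondary-cluster size shape firing: for each prototypical arbor, one
#' pair moves units into the primary cluster and one into the secondary
#' cluster, conserving the total unit count.
#'
#' @return A data frame with columns `arbor` (1-4), `type`
#'   (`"primary"`/`"secondary"`), `groupingA` (enlarged-cluster
#'   configuration), `groupingB` (baseline of the pair) and `units_moved`.
#' @export
grouping_design <- function() {
  rows <- list(
    list(1, "primary",   c(10, 5, 1, 1),    c(6, 5, 3, 3),    4),
    list(1, "secondary", c(8, 7, 1, 1),     c(8, 3, 3, 3),    4),
    list(2, "primary",   c(9, 6, 3, 1, 1),  c(6, 6, 4, 2, 2), 3),
    list(2, "secondary", c(7, 7, 4, 1, 1),  c(7, 4, 4, 3, 2), 3),
    list(3, "primary",   c(6, 4, 2, 1),     c(4, 4, 3, 2),    2),
    list(3, "secondary", c(5, 5, 2, 1),     c(5, 3, 3, 2),    2),
    list(4, "primary",   c(7, 4, 2),        c(5, 4, 4),       2),
    list(4, "secondary", c(6, 6, 1),        c(6, 4, 3),       2)
  )
  data.frame(
    arbor = vapply(rows, `[[`, numeric(1), 1),
    type = vapply(rows, `[[`, character(1), 2),
    groupingA = I(lapply(rows, `[[`, 3)),
    groupingB = I(lapply(rows, `[[`, 4)),
    units_moved = vapply(rows, `[[`, numeric(1), 5)
  )
}

# Static rates from a simulation table, optionally restricted to
# suprathreshold depths (depths whose mean static rate in `baseline` is
# positive).
.static_rates <- function(sim, baseline = NULL) {
  if (is.null(baseline)) return(sim$hfr)
  mean_by_depth <- tapply(baseline$hfr, baseline$depth, mean)
  supra <- as.numeric(names(mean_by_depth)[mean_by_depth > 0])
  sim$hfr[sim$depth %in% supra]
}

#' Percent firing-rate change between two arbor configurations
#'
#' Simulates both configurations over the protocol with common
#' per-repetition noise seeds and applies the summed-rate percent-change
#' statistic to the static rates.
#'
#' @param arborA,arborB [arbor_configuration()]s.
#' @param trans Shared [transduction_parameters()].
#' @param suprathreshold_only Restrict to depths whose mean static rate in
#'   the `arborB` (baseline) simulation is positive.
#' @param signed Report the signed statistic (positive when `arborA` fires
#'   more).
#' @inheritParams simulate_protocol
#' @return A list with `pct_change`, and the two simulation tables.
#' @export
compare_configurations <- function(arborA, arborB,
                                   trans = transduction_parameters(),
                                   protocol = stimulus_protocol(),
                                   skin = skin_parameters(),
                                   lif = lif_parameters(),
                                   noise = noise_config(),
                                   seed = 1,
                                   suprathreshold_only = FALSE,
                                   signed = FALSE,
                                   sed_cache = NULL) {
  if (is.null(sed_cache)) sed_cache <- precompute_sed(protocol, skin)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, nrow(protocol$table))
  simA <- simulate_protocol(arborA, trans, protocol, skin, lif, noise,
                            rep_seeds = rep_seeds, sed_cache = sed_cache)
  simB <- simulate_protocol(arborB, trans, protocol, skin, lif, noise,
                            rep_seeds = rep_seeds, sed_cache = sed_cache)
  base <- if (suprathreshold_only) simB else NULL
  rA <- .static_rates(simA, base)
  rB <- .static_rates(simB, base)
  list(pct_change = percent_fr_change(rA, rB, signed = signed),
       simA = simA, simB = simB)
}

#' Run the grouping-perturbation experiment
#'
#' For every pair in the design, simulates both groupings of the pair with
#' the arbor's transduction parameters and reports the percent firing-rate
#' change (enlarged-cluster configuration vs its baseline).
#'
#' @param design A [grouping_design()]-style data frame.
#' @param parameters A list of [transduction_parameters()], indexed by the
#'   design's `arbor` column.
#' @inheritParams compare_configurations
#' @return The design with columns `pct_change` and `pct_per_unit`
#'   appended.
#' @export
run_grouping_experiment <- function(design = grouping_design(),
                                    parameters = prototypical_arbors()$parameters,
                                    protocol = stimulus_protocol(),
                                    skin = skin_parameters(),
                                    lif = lif_parameters(),
                                    noise = noise_config(),
                                    seed = 1) {
  sed_cache <- precompute_sed(protocol, skin)
  pct <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    gA <- arbor_configuration(design$groupingA[[i]])
    gB <- arbor_configuration(design$groupingB[[i]])
    if (gA$total_units != gB$total_units)
      stop("grouping pair does not conserve total units", call. = FALSE)
    cmp <- compare_configurations(
      gA, gB, parameters[[design$arbor[i]]], protocol, skin, lif, noise,
      seed = seed + i, signed = TRUE, sed_cache = sed_cache)
    pct[i] <- cmp$pct_change
  }
  design$pct_change <- pct
  design$pct_per_unit <- pct / design$units_moved
  design
}

#' Run a cluster fill-up survey
#'
#' Grows an arbor towards a filled configuration under one or both fill
#' strategies and reports the percent firing-rate change of each
#' intermediate configuration relative to the starting arbor.
#'
#' @param arbor The starting [arbor_configuration()].
#' @param trans [transduction_parameters()] for this arbor.
#' @param strategies Fill strategies to survey.
#' @param max_added Maximum units to add per strategy.
#' @param final_only Simulate only the final configuration of each
#'   strategy (faster when intermediate points are not needed).
#' @inheritParams compare_configurations
#' @return A data frame with columns `strategy`, `units_added`,
#'   `total_units`, `configuration`, `pct_change`.
#' @export
run_fillup_survey <- function(arbor, trans = transduction_parameters(),
                              strategies = c("secondary", "smallest"),
                              max_added = Inf,
                              protocol = stimulus_protocol(),
                              skin = skin_parameters(),
                              lif = lif_parameters(),
                              noise = noise_config(),
                              seed = 1, final_only = FALSE) {
  sed_cache <- precompute_sed(protocol, skin)
  out <- list()
  for (strat in strategies) {
    seq_cfgs <- fill_up_sequence(arbor, strat, max_added)
    if (length(seq_cfgs) == 0L) next
    idx <- if (final_only) length(seq_cfgs) else seq_along(seq_cfgs)
    for (k in idx) {
      cmp <- compare_configurations(
        seq_cfgs[[k]], arbor, trans, protocol, skin, lif, noise,
        seed = seed + k, signed = TRUE, sed_cache = sed_cache)
      out[[length(out) + 1L]] <- data.frame(
        strategy = strat, units_added = k,
        total_units = seq_cfgs[[k]]$total_units,
        configuration = seq_cfgs[[k]]$name,
        pct_change = cmp$pct_change)
    }
  }
  do.call(rbind, out)
}

#' Simulated static-phase displacement-response relation
#'
#' Pools the static rates of every repetition at each depth (all
#' accelerations contribute) and fits the single-exponential
#' displacement-response model.
#'
#' @inheritParams simulate_protocol
#' @return A list with `fit` (from [fit_displacement_response()]), and
#'   `depths`/`rates` (one entry per indexed simulation).
#' @export
displacement_response <- function(arbor, trans = transduction_parameters(),
                                  protocol = stimulus_protocol(),
                                  skin = skin_parameters(),
                                  lif = lif_parameters(),
                                  noise = noise_config(),
                                  seed = 1, sed_cache = NULL) {
  sim <- simulate_protocol(arbor, trans, protocol, skin, lif, noise,
                           seed = seed, sed_cache = sed_cache)
  list(fit = fit_displacement_response(sim$depth, sim$hfr),
       depths = sim$depth, rates = sim$hfr)
}

#' Read a stimulus-protocol definition from YAML
#'
#' Expected keys: `depths_mm`, `accelerations_mm_s2`, `hold_s`,
#' `repetitions`.
#'
#' @param path YAML file path.
#' @return A [stimulus_protocol()].
#' @export
read_protocol_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  stimulus_protocol(
    depths = as.numeric(y$depths_mm),
    accelerations = as.numeric(y$accelerations_mm_s2),
    hold = if (!is.null(y$hold_s)) y$hold_s else 5,
    repetitions = if (!is.null(y$repetitions)) y$repetitions else 5)
}
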