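# Fitted baselines shared across the acceptance tests.  Fitting the four
# prototypical arbors to the synthetic target dominates the suite's
# runtime, so the results are computed once per session on first use.

.fit_store <- new.env(parent = emptyenv())

acceptance_fits <- function() {
  if (!is.null(.fit_store$fits)) return(.fit_store$fits)
  tgt <- make_prototypical_response()
  pa <- prototypical_arbors()
  fits <- vector("list", 4)
  for (k in 1:4) {
    runner <- make_model_runner(pa$arbors[[k]], seed = 100 + k)
    set.seed(200 + k)
    fits[[k]] <- rsm_fit(runner, tgt)
  }
  avg <- transduction_parameters(
    mean(vapply(fits, function(f) f$parameters$beta, numeric(1))),
    mean(vapply(fits, function(f) f$parameters$alpha, numeric(1))),
    mean(vapply(fits, function(f) f$parameters$lambda, numeric(1))))
  .fit_store$fits <- list(fits = fits, parameters = lapply(fits, `[[`,
                                                           "parameters"),
                          averaged = avg, target = tgt, arbors = pa$arbors)
  .fit_store$fits
}
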