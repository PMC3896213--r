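# Fitting the three free transduction parameters (beta, alpha, lambda) to a
# prototypical response by gradient-free Latin-hypercube response-surface
# search, maximizing the combined fractional sum of squares.

#' Combined fractional sum of squares
#'
#' The per-phase fractional sum of squares is
#' `1 - sum((target - sim)^2) / sum(target^2)`; the combined score adds the
#' static (hold) and dynamic (ramp) phases and equals 2 for a simulation
#' that matches the target exactly.
#'
#' @param sim_rfr,sim_hfr Simulated ramp and static rates, indexed 1..n.
#' @param target A data frame with aligned columns `rfr_target` and
#'   `hfr_target` (see [make_prototypical_response()]).
#' @return A list with `score`, `fss_ramp`, `fss_static`.
#' @export
combined_fss <- function(sim_rfr, sim_hfr, target) {
  hbar <- target$hfr_target
  rbar <- target$rfr_target
  if (length(sim_rfr) != length(rbar) || length(sim_hfr) != length(hbar))
    stop("simulated and target vectors must align", call. = FALSE)
  den_h <- sum(hbar^2)
  den_r <- sum(rbar^2)
  if (den_h == 0 || den_r == 0)
    stop("undefined score: a target phase is identically zero", call. = FALSE)
  fss_h <- 1 - sum((hbar - sim_hfr)^2) / den_h
  fss_r <- 1 - sum((rbar - sim_rfr)^2) / den_r
  list(score = fss_h + fss_r, fss_ramp = fss_r, fss_static = fss_h)
}

#' Latin-hypercube design over a box
#'
#' One point per equal-probability stratum per dimension, scaled to the
#' given bounds; reproducible under [set.seed()].
#'
#' @param n Number of points (>= 2).
#' @param lower,upper Bound vectors, one entry per dimension.
#' @return An n x d matrix of points.
#' @export
lhs_design <- function(n, lower, upper) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (length(lower) != length(upper) || any(!is.finite(c(lower, upper))))
    stop("bounds must be finite and of equal length", call. = FALSE)
  if (any(upper < lower)) stop("inverted bounds", call. = FALSE)
  u <- lhs::randomLHS(n, length(lower))
  sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
}

#' Response-surface fit of the transduction parameters
#'
#' Stage 1 is a 50-point Latin-hypercube domain search over the full bounds;
#' stage 2 iterates 20-point Latin-hypercube designs recentred on the
#' incumbent best with the search region shrunk by a factor of 0.5 per
#' iteration, stopping after `max_iter` iterations or when the score
#' improves by less than `tol`.  `alpha` and `lambda` are searched in
#' log10 space (they are positive and span decades), `beta` linearly.
#'
#' @param runner A function `(beta, alpha, lambda) -> data.frame` with
#'   columns `rfr` and `hfr` aligned with the target (see
#'   [make_model_runner()]).
#' @param target A [make_prototypical_response()] data frame.
#' @param bounds A list with elements `beta`, `alpha`, `lambda`, each a
#'   `c(lower, upper)` pair on the natural scale.
#' @param n_domain Points in the stage-1 domain search.
#' @param n_design Points per stage-2 design.
#' @param max_iter Maximum stage-2 iterations per start.
#' @param shrink Region shrink factor per iteration.
#' @param tol Stop a start when its score improves by less than this on two
#'   consecutive iterations.
#' @param n_starts Number of top-ranked stage-1 points used to seed
#'   independent stage-2 shrink sequences (guards against the domain search
#'   landing in a secondary basin).
#' @return An object of class `fit_result`: fitted
#'   [transduction_parameters()], `score`, `fss_ramp`, `fss_static`,
#'   `evaluations`, `trace` (best score per stage), and `on_boundary`.
#' @export
rsm_fit <- function(runner, target,
                    bounds = default_fit_bounds(),
                    n_domain = 50, n_design = 20,
                    max_iter = 12, shrink = 0.6, tol = 1e-4,
                    n_starts = 2) {
  lower <- c(bounds$beta[1], log10(bounds$alpha[1]), log10(bounds$lambda[1]))
  upper <- c(bounds$beta[2], log10(bounds$alpha[2]), log10(bounds$lambda[2]))
  from_theta <- function(th) list(beta = th[1], alpha = 10^th[2],
                                  lambda = 10^th[3])
  evals <- 0L
  score_of <- function(th) {
    p <- from_theta(th)
    sim <- runner(p$beta, p$alpha, p$lambda)
    evals <<- evals + 1L
    combined_fss(sim$rfr, sim$hfr, target)
  }
  eval_design <- function(X) {
    best <- NULL
    y <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
      sc <- score_of(X[i, ])
      y[i] <- sc$score
      if (is.null(best) || sc$score > best$sc$score)
        best <- list(th = X[i, ], sc = sc)
    }
    list(best = best, y = y)
  }
  # Box-Wilson step: fit a full quadratic to (X, y) in box-scaled
  # coordinates and return the predicted optimum inside the box, or NULL
  # if the fit is degenerate.
  quad_argmax <- function(X, y, lo, hi) {
    rng <- pmax(hi - lo, 1e-300)
    Z <- sweep(sweep(X, 2, lo, `-`), 2, rng, `/`)
    df <- data.frame(y = y, z1 = Z[, 1], z2 = Z[, 2], z3 = Z[, 3])
    fit <- tryCatch(stats::lm(
      y ~ z1 + z2 + z3 + I(z1^2) + I(z2^2) + I(z3^2) +
        z1:z2 + z1:z3 + z2:z3, data = df),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit))) return(NULL)
    co <- stats::coef(fit)
    b <- co[c("z1", "z2", "z3")]
    B <- matrix(0, 3, 3)
    diag(B) <- co[c("I(z1^2)", "I(z2^2)", "I(z3^2)")]
    B[1, 2] <- B[2, 1] <- co["z1:z2"] / 2
    B[1, 3] <- B[3, 1] <- co["z1:z3"] / 2
    B[2, 3] <- B[3, 2] <- co["z2:z3"] / 2
    z_star <- tryCatch(solve(-2 * B, b), error = function(e) NULL)
    inside <- !is.null(z_star) && all(is.finite(z_star)) &&
      all(z_star >= 0) && all(z_star <= 1) &&
      all(eigen(B, symmetric = TRUE, only.values = TRUE)$values < 0)
    if (!inside) {
      # surrogate argmax over a dense prediction sample in the box
      Zc <- lhs::randomLHS(256, 3)
      pred <- stats::predict(fit, data.frame(z1 = Zc[, 1], z2 = Zc[, 2],
                                             z3 = Zc[, 3]))
      z_star <- Zc[which.max(pred), ]
    }
    lo + as.numeric(z_star) * rng
  }
  # stage 1: domain search; rank the points to seed the stage-2 starts
  X <- lhs_design(n_domain, lower, upper)
  scores1 <- numeric(n_domain)
  cache1 <- vector("list", n_domain)
  for (i in seq_len(n_domain)) {
    cache1[[i]] <- score_of(X[i, ])
    scores1[i] <- cache1[[i]]$score
  }
  ord <- order(-scores1)[seq_len(min(n_starts, n_domain))]
  best <- list(th = X[ord[1], ], sc = cache1[[ord[1]]])
  trace <- best$sc$score
  score_at <- function(th) {
    sc <- score_of(th)
    list(th = th, sc = sc)
  }
  # stage 2: per start, iterated recentred designs shrinking by `shrink`
  # per iteration.  After each design a second-order response surface is
  # fitted to the design points and its predicted optimum evaluated as one
  # extra candidate (the classic Box-Wilson step); this follows curved
  # ridges that axis-aligned boxes track poorly.  A start stops on two
  # consecutive stalls.
  span <- upper - lower
  for (s in ord) {
    local_best <- list(th = X[s, ], sc = cache1[[s]])
    stalls <- 0L
    for (it in seq_len(max_iter)) {
      w <- span * shrink^it
      lo <- pmax(lower, local_best$th - w / 2)
      hi <- pmin(upper, local_best$th + w / 2)
      D <- lhs_design(n_design, lo, hi)
      sc_prev <- local_best$sc$score
      ev <- eval_design(D)
      if (ev$best$sc$score > local_best$sc$score) local_best <- ev$best
      # quadratic response-surface step on the just-evaluated design
      th_q <- quad_argmax(D, ev$y, lo, hi)
      if (!is.null(th_q)) {
        cq <- score_at(th_q)
        if (cq$sc$score > local_best$sc$score) local_best <- cq
      }
      improved <- local_best$sc$score - sc_prev
      if (local_best$sc$score > best$sc$score) best <- local_best
      trace <- c(trace, best$sc$score)
      stalls <- if (improved < tol) stalls + 1L else 0L
      if (stalls >= 2L) break
    }
  }
  edge <- 0.01 * (upper - lower)
  on_boundary <- any(best$th - lower < edge) || any(upper - best$th < edge)
  if (on_boundary)
    warning("best point lies on a search bound; consider widening bounds",
            call. = FALSE)
  p <- from_theta(best$th)
  structure(list(
    parameters = transduction_parameters(p$beta, p$alpha, p$lambda),
    score = best$sc$score,
    fss_ramp = best$sc$fss_ramp,
    fss_static = best$sc$fss_static,
    evaluations = evals,
    trace = trace,
    on_boundary = on_boundary
  ), class = "fit_result")
}

#' Default search bounds for the transduction parameters
#'
#' Bounds are set by dimensional analysis of the membrane drive `R * I`
#' rather than by fiat.  The offset `beta` must stay subthreshold but close
#' to threshold (85-99.9% of `threshold / R`), because sustained low-rate
#' static firing requires the mean drive to sit within the noise's reach of
#' threshold.  The static gain `alpha` is bounded so the primary cluster's
#' static drive `R * M1 * alpha * sed` spans roughly 0.1-30 mV at the
#' plateau SED scale, and the dynamic gain `lambda` so the ramp drive
#' `R * M1 * lambda * d(sed)/dt` spans roughly 1-300 mV at the peak SED
#' rate scale.
#'
#' @param lif A [lif_parameters()] object.
#' @param M1 Primary cluster size the drive window is referenced to.
#' @param sed_plateau Characteristic plateau SED at the largest depth, Pa.
#' @param sed_rate Characteristic peak SED rate during a fast ramp, Pa/ms.
#' @return A list of `c(lower, upper)` pairs.
#' @export
default_fit_bounds <- function(lif = lif_parameters(), M1 = 8,
                               sed_plateau = 1e4, sed_rate = 1.5e3) {
  R <- lif$resistance
  beta_max <- 0.999 * lif$threshold / R
  list(beta = c(0.85 * beta_max, beta_max),
       alpha = c(0.1, 30) / (R * M1 * sed_plateau),
       lambda = c(1, 300) / (R * M1 * sed_rate))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "fit: beta = %.4g mA, alpha = %.4g mA/Pa, lambda = %.4g mA.ms/Pa\n",
    x$parameters$beta, x$parameters$alpha, x$parameters$lambda))
  cat(sprintf("combined fss = %.4f (ramp %.4f, static %.4f), %d evaluations\n",
              x$score, x$fss_ramp, x$fss_static, x$evaluations))
  invisible(x)
}

#' Write / read a fitted parameter set as JSON
#'
#' @param params A [transduction_parameters()] object.
#' @param path File path.
#' @export
write_fit_json <- function(params, path) {
  jsonlite::write_json(list(beta_mA = params$beta,
                            alpha_mA_per_Pa = params$alpha,
                            lambda_mA_ms_per_Pa = params$lambda),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path)
  transduction_parameters(x$beta_mA, x$alpha_mA_per_Pa, x$lambda_mA_ms_per_Pa)
}
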