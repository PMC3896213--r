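# Arbor architecture: how transduction units are grouped at
# spike-initiation zones, and the structural surveys built on regrouping.

#' Arbor configuration
#'
#' An arbor is the ordered list of cluster sizes, one cluster of Merkel
#' cell-neurite complexes per spike-initiation zone, stored canonically in
#' descending order (primary, secondary, ...).  Brace notation such as
#' \{8,5,3,1\} is treated as unordered.
#'
#' @param clusters Positive integer cluster sizes.
#' @param name Optional label.
#' @return An object of class `arbor_configuration`.
#' @export
arbor_configuration <- function(clusters, name = NULL) {
  clusters <- as.integer(clusters)
  if (length(clusters) < 1L || any(clusters < 1L) || anyNA(clusters))
    stop("cluster sizes must be positive integers", call. = FALSE)
  clusters <- sort(clusters, decreasing = TRUE)
  if (is.null(name))
    name <- paste0("{", paste(clusters, collapse = ","), "}")
  structure(list(clusters = clusters, name = name,
                 total_units = sum(clusters),
                 n_zones = length(clusters)),
            class = "arbor_configuration")
}

#' @export
print.arbor_configuration <- function(x, ...) {
  cat(sprintf("arbor %s: %d zones, %d transduction units\n",
              x$name, x$n_zones, x$total_units))
  invisible(x)
}

#' Skew of an arbor's cluster-size distribution
#'
#' Orders clusters from largest to smallest and fits an ordinary
#' least-squares line of cluster size against rank (1, 2, ...).  The slope
#' captures how asymmetrically the transduction units are grouped; skew
#' magnitude is its absolute value.
#'
#' @param config An [arbor_configuration()].
#' @return A list with `slope` (units per rank), `skew` (= |slope|) and
#'   `r_squared`.
#' @export
skew_slope <- function(config) {
  s <- config$clusters
  if (length(s) < 2L)
    stop("skew is undefined for a single cluster", call. = FALSE)
  rank <- seq_along(s)
  fit <- stats::lm(s ~ rank)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((s - mean(s))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = slope, skew = abs(slope), r_squared = r2)
}

#' Move transduction units between clusters
#'
#' Moves `n` units out of the source ranks and into the destination rank,
#' conserving the total; no cluster may drop below one unit.  `from_rank`
#' may name several ranks, in which case units are taken one at a time,
#' round-robin, as long as the donor keeps at least two units.
#'
#' @param config An [arbor_configuration()].
#' @param from_rank Source rank(s) (1 = primary).
#' @param to_rank Destination rank.
#' @param n Number of units to move.
#' @return A new, re-sorted [arbor_configuration()].
#' @export
move_units <- function(config, from_rank, to_rank, n) {
  s <- config$clusters
  if (n == 0) return(arbor_configuration(s))
  moved <- 0L
  repeat {
    progressed <- FALSE
    for (fr in from_rank) {
      if (moved == n) break
      if (s[fr] > 1L) {
        s[fr] <- s[fr] - 1L
        s[to_rank] <- s[to_rank] + 1L
        moved <- moved + 1L
        progressed <- TRUE
      }
    }
    if (moved == n) break
    if (!progressed)
      stop("cannot move units: a source cluster would be emptied",
           call. = FALSE)
  }
  arbor_configuration(s)
}

#' Cluster fill-up sequences
#'
#' Grows an arbor one transduction unit at a time until all clusters equal
#' the primary cluster, following one of two strategies: `"secondary"` first
#' raises the secondary cluster to the primary size, then the tertiary, and
#' so on (skewing the distribution); `"smallest"` always increments the
#' currently smallest cluster (evening the distribution; ties go to the
#' last rank).  No cluster ever exceeds the primary size.
#'
#' @param config An [arbor_configuration()].
#' @param strategy `"secondary"` or `"smallest"`.
#' @param max_added Maximum number of units to add.
#' @return A list of [arbor_configuration()]s, one per added unit (possibly
#'   empty if the arbor is already filled).
#' @export
fill_up_sequence <- function(config, strategy = c("secondary", "smallest"),
                             max_added = Inf) {
  strategy <- match.arg(strategy)
  if (max_added < 1) stop("max_added must be >= 1", call. = FALSE)
  s <- config$clusters
  primary <- s[1]
  out <- list()
  while (length(out) < max_added && any(s[-1] < primary)) {
    if (strategy == "secondary") {
      idx <- which(s < primary)[1]        # highest unfilled rank
    } else {
      m <- min(s)
      if (m >= primary) break
      idx <- max(which(s == m))           # tie -> last rank
    }
    s[idx] <- s[idx] + 1L
    # canonical descending order, preserving fill order among equals
    s <- sort(s, decreasing = TRUE)
    out[[length(out) + 1L]] <- arbor_configuration(s)
  }
  out
}
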