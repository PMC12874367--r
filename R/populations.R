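#' Residence-time populations of the conformational states
#'
#' The fraction of trajectory frames spent in each state after discarding a
#' burn-in, i.e. the residence-time population obtained by integrating the
#' state densities. Multiple replicas are pooled by frame count (the pooled
#' fraction is the frame-weighted average of per-replica fractions).
#'
#' @param states a factor/character vector of state labels, or a list of such
#'   vectors (one per replica).
#' @param burn_in number of initial frames to discard per replica (default 0;
#'   equilibration is reported, never silently applied).
#' @return A `population_summary`: `fractions` (named, sums to 1),
#'   `per_replica` (matrix replica x state), `frame_counts`, `burn_in`.
#' @export
residence_fractions <- function(states, burn_in = 0) {
  reps <- if (is.list(states) && !is.data.frame(states)) states else list(states)
  burn_in <- as.integer(burn_in)
  if (burn_in < 0L) config_error("burn_in must be >= 0")
  kept <- lapply(reps, function(s) {
    s <- as_state_factor(s)
    if (burn_in >= length(s))
      data_error(sprintf("burn_in (%d) leaves no frames (series length %d)",
                         burn_in, length(s)))
    s[(burn_in + 1L):length(s)]
  })
  per_rep <- t(vapply(kept, function(s) table(s) / length(s),
                      numeric(length(STATE_LEVELS))))
  colnames(per_rep) <- STATE_LEVELS
  counts <- vapply(kept, length, integer(1))
  pooled <- colSums(per_rep * counts) / sum(counts)
  structure(list(fractions = pooled, per_replica = per_rep,
                 frame_counts = counts, burn_in = burn_in),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("<population_summary>", sum(x$frame_counts), "frames,",
      length(x$frame_counts), "replica(s), burn-in", x$burn_in, "\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Angle density over [0, 90] degrees
#'
#' Normalized histogram (default) or Gaussian kernel estimate of the
#' theta_min distribution; either integrates to 1 over `[0, 90]`.
#'
#' @param theta numeric values in `[0, 90]` (degrees).
#' @param breaks histogram break points spanning `[0, 90]`; default 1-degree
#'   bins, which align with the default state thresholds (55, 80).
#' @param estimator `"histogram"` or `"kernel"`.
#' @param bandwidth kernel bandwidth in degrees (`"kernel"` only); default
#'   `stats::bw.nrd0`.
#' @return A data.frame with `bin_center` (or evaluation point) and
#'   `density`, plus attribute `"breaks"` for histograms.
#' @export
angle_density <- function(theta, breaks = seq(0, 90, by = 1),
                          estimator = c("histogram", "kernel"),
                          bandwidth = NULL) {
  estimator <- match.arg(estimator)
  theta <- as.numeric(theta)
  if (!length(theta)) data_error("empty angle series")
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 90))
    data_error("angles must lie in [0, 90] degrees")
  if (estimator == "histogram") {
    if (breaks[1] > 0 || breaks[length(breaks)] < 90)
      config_error("histogram breaks must span [0, 90]")
    h <- graphics::hist(theta, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    out <- data.frame(bin_center = h$mids, density = h$density)
    attr(out, "breaks") <- h$breaks
    attr(out, "counts") <- h$counts
  } else {
    bw <- bandwidth %||% stats::bw.nrd0(theta)
    d <- stats::density(theta, bw = bw, from = 0, to = 90, n = 512)
    y <- d$y
    # renormalize over the observable [0, 90] window
    z <- sum((y[-1] + y[-length(y)]) / 2 * diff(d$x))
    out <- data.frame(bin_center = d$x, density = y / z)
    attr(out, "bandwidth") <- bw
  }
  attr(out, "estimator") <- estimator
  class(out) <- c("angle_density", class(out))
  out
}

#' Integrate a state density into per-state fractions
#'
#' Integrates an [angle_density()] over the three threshold intervals. For a
#' histogram whose breaks include the thresholds, the result is identical to
#' counting labels directly (the bins tile the intervals exactly).
#'
#' @param density an `angle_density` data.frame.
#' @param thresholds see [state_thresholds()].
#' @return Named numeric fractions (open, semiopen, closed), summing to 1.
#' @export
integrate_density <- function(density, thresholds = state_thresholds()) {
  thresholds <- do.call(state_thresholds, thresholds[c("open_max", "semiopen_max")])
  lo <- c(0, thresholds$open_max, thresholds$semiopen_max)
  hi <- c(thresholds$open_max, thresholds$semiopen_max, 90)
  est <- attr(density, "estimator") %||% "histogram"
  if (est == "histogram") {
    breaks <- attr(density, "breaks")
    if (is.null(breaks)) data_error("histogram density lacks breaks attribute")
    widths <- diff(breaks)
    mass <- density$density * widths
    # assign each bin to the state interval containing it; bins straddling a
    # threshold are split pro rata by overlap length
    frac <- vapply(seq_len(3L), function(s) {
      ov <- pmax(0, pmin(breaks[-1], hi[s]) - pmax(breaks[-length(breaks)], lo[s]))
      sum(mass * ifelse(widths > 0, ov / widths, 0))
    }, numeric(1))
  } else {
    x <- density$bin_center; y <- density$density
    frac <- vapply(seq_len(3L), function(s) {
      xx <- pmin(pmax(x, lo[s]), hi[s])
      keep <- x >= lo[s] & x <= hi[s]
      if (sum(keep) < 2) return(0)
      xi <- x[keep]; yi <- y[keep]
      sum((yi[-1] + yi[-length(yi)]) / 2 * diff(xi))
    }, numeric(1))
    frac <- frac / sum(frac)
  }
  stats::setNames(frac, STATE_LEVELS)
}

#' Boltzmann populations of an energy-labelled conformer ensemble
#'
#' Each structure i gets weight `w_i = exp(-(E_i - E_min) / (kB T))`
#' (centring at the minimum is exact and avoids underflow); per-state
#' populations are the normalized weight sums over each state's members, as
#' used to convert DFT scan energies into reference conformer populations.
#'
#' @param energies numeric energies in kcal/mol.
#' @param states state label per structure (open/semiopen/closed).
#' @param temperature temperature in K (default 298.15).
#' @param kB Boltzmann constant, kcal/(mol K).
#' @return Named numeric populations per state, summing to 1.
#' @export
boltzmann_populations <- function(energies, states, temperature = 298.15,
                                  kB = KB_KCAL) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    config_error("temperature must be a positive scalar (K)")
  energies <- as.numeric(energies)
  if (!length(energies) || any(!is.finite(energies)))
    data_error("energies must be a nonempty finite vector (kcal/mol)")
  states <- as_state_factor(states)
  if (length(states) != length(energies))
    data_error("states and energies must have equal length")
  w <- exp(-(energies - min(energies)) / (kB * temperature))
  pop <- tapply(w, states, sum, default = 0) / sum(w)
  stats::setNames(as.numeric(pop), STATE_LEVELS)
}

#' Write population fractions as JSON or CSV
#'
#' @param fractions named numeric vector or `population_summary`.
#' @param path output path (`.json` or `.csv` decides the format).
#' @return `path`, invisibly.
#' @export
write_populations <- function(fractions, path) {
  if (inherits(fractions, "population_summary")) {
    obj <- list(fractions = as.list(fractions$fractions),
                frame_counts = fractions$frame_counts,
                burn_in = fractions$burn_in,
                per_replica = apply(fractions$per_replica, 1, as.list,
                                    simplify = FALSE))
  } else obj <- list(fractions = as.list(fractions))
  if (tolower(tools::file_ext(path)) == "csv") {
    df <- data.frame(state = names(obj$fractions),
                     fraction = unlist(obj$fractions))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
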