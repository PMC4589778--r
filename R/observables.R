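#' Cooperation frequency
#'
#' Fraction of cooperators in one layer; the whole-system value is the
#' arithmetic mean of the two layers (they have equal size).
#'
#' @param state an `"idg_state"`.
#' @param layer `"system"` (default), `"SD"` or `"PD"`.
#' @return A fraction in `[0, 1]`.
#' @export
cooperation_frequency <- function(state, layer = c("system", "SD", "PD")) {
  layer <- match.arg(layer)
  switch(layer,
         SD = mean(state$sd),
         PD = mean(state$pd),
         system = (mean(state$sd) + mean(state$pd)) / 2)
}

#' Interlayer strategy-pair frequencies
#'
#' Classifies each of the `L^2` interlayer partner pairs by the strategies
#' held on (SD layer, PD layer): `f_cc` both cooperate, `f_dd` both defect,
#' `f_cd` cooperator in SD facing a defector in PD, `f_dc` the reverse. The
#' four fractions partition the pairs and sum to one.
#'
#' @param state an `"idg_state"`.
#' @return A list of class `"idg_pairs"` with elements `f_cc`, `f_dd`,
#'   `f_cd`, `f_dc`.
#' @export
pair_frequencies <- function(state) {
  N <- state$L^2
  cc <- sum(state$sd == 1L & state$pd == 1L) / N
  dd <- sum(state$sd == 0L & state$pd == 0L) / N
  cd <- sum(state$sd == 1L & state$pd == 0L) / N
  dc <- sum(state$sd == 0L & state$pd == 1L) / N
  structure(list(f_cc = cc, f_dd = dd, f_cd = cd, f_dc = dc),
            class = "idg_pairs")
}

#' @export
print.idg_pairs <- function(x, ...) {
  cat(sprintf("pair frequencies: C-C %.4f  D-D %.4f  C-D %.4f  D-C %.4f\n",
              x$f_cc, x$f_dd, x$f_cd, x$f_dc))
  invisible(x)
}

#' Interlayer synchronization index
#'
#' Fraction of partner pairs holding identical strategies,
#' `f_cc + f_dd`. Equals 1 for identical grids, 0 for complementary grids,
#' and 0.5 in expectation for independent uniform layers.
#'
#' @param state an `"idg_state"`.
#' @return A fraction in `[0, 1]`.
#' @export
synchronization_index <- function(state) {
  mean(state$sd == state$pd)
}

#' Steady-state averages of recorded observables
#'
#' Time-averages every recorded observable of a run over the final `window`
#' MC steps. For a single run the standard error is the time-series standard
#' deviation divided by `sqrt(window)` (a naive estimate that ignores
#' autocorrelation); for a list of replicate runs, the replicate means are
#' averaged and the standard error is the standard deviation across
#' replicates over `sqrt(n)`.
#'
#' @param x an `"idg_run"` or a list of them.
#' @param window number of final recorded MC steps to average over; defaults
#'   to the run's averaging phase (`avg`), or the full record if `avg = 0`.
#' @return A data frame with one row per observable: `observable`, `mean`,
#'   `se`, `n_runs`, `window`.
#' @export
steady_state_average <- function(x, window = NULL) {
  runs <- if (inherits(x, "idg_run")) list(x) else x
  if (!length(runs) || !all(vapply(runs, inherits, TRUE, "idg_run")))
    stop("x must be an idg_run or a list of idg_run objects")
  obs <- c("fc_sd", "fc_pd", "fc_sys", "f_cc", "f_cd", "f_dc", "f_dd", "sync")
  per_run <- vapply(runs, function(r) {
    win <- if (is.null(window)) max(r$avg, 1) else window
    nrec <- nrow(r$ts)
    if (win < 1 || win > nrec)
      stop("window must lie in [1, ", nrec, "]")
    tail_ts <- r$ts[(nrec - win + 1):nrec, obs, drop = FALSE]
    colMeans(tail_ts)
  }, numeric(length(obs)))
  per_run <- matrix(per_run, nrow = length(obs),
                    dimnames = list(obs, NULL))
  n <- length(runs)
  if (n == 1) {
    r <- runs[[1]]
    win <- if (is.null(window)) max(r$avg, 1) else window
    nrec <- nrow(r$ts)
    tail_ts <- r$ts[(nrec - win + 1):nrec, obs, drop = FALSE]
    se <- apply(tail_ts, 2, stats::sd) / sqrt(win)
    se[is.na(se)] <- 0
    data.frame(observable = obs, mean = per_run[, 1], se = se,
               n_runs = 1L, window = win, row.names = NULL)
  } else {
    data.frame(observable = obs,
               mean = rowMeans(per_run),
               se = apply(per_run, 1, stats::sd) / sqrt(n),
               n_runs = n,
               window = if (is.null(window)) NA_integer_ else window,
               row.names = NULL)
  }
}

#' Classify a steady-state cooperation level into a phase
#'
#' Maps a time-averaged cooperation frequency to the absorbing-phase labels
#' used in the b-s phase diagrams: `"D"` (defection, `f < epsilon`), `"C"`
#' (cooperation, `f > 1 - epsilon`), or `"C+D"` (coexistence).
#'
#' @param f_c_avg averaged cooperation frequencies in `[0, 1]` (vectorized).
#' @param epsilon classification tolerance, `0 < epsilon < 0.5`.
#' @return A character vector of `"C"`, `"D"`, `"C+D"`.
#' @export
classify_phase <- function(f_c_avg, epsilon = 0.01) {
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must be in (0, 0.5)")
  if (any(f_c_avg < 0 | f_c_avg > 1)) stop("f_c_avg must lie in [0, 1]")
  ifelse(f_c_avg < epsilon, "D",
         ifelse(f_c_avg > 1 - epsilon, "C", "C+D"))
}
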