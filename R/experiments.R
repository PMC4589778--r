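# Experiment drivers: replicated steady-state measurements over parameter
# grids, threshold (phase-transition) detection, phase diagrams, pair-
# frequency time courses and snapshot series.

# Replicated steady-state statistics at a single (b, s) point. Each replicate
# k uses seed seeds[k] for both its initial state and its engine stream.
.point_stats <- function(b, s, L, relax, avg, runs, seeds, epsilon = 0.01,
                         params = NULL) {
  if (is.null(params)) params <- game_params(b = b, s = s)
  else { params$b <- b; params$s <- s }
  obs <- c("fc_sd", "fc_pd", "fc_sys", "sync")
  per <- vapply(seq_len(runs), function(k) {
    r <- run_simulation(params, L = L, relax = relax, avg = avg,
                        seed = seeds[k])
    unlist(steady_state_average(r)$mean[match(obs,
      c("fc_sd", "fc_pd", "fc_sys", "f_cc", "f_cd", "f_dc", "f_dd", "sync"))])
  }, numeric(4))
  per <- matrix(per, nrow = 4, dimnames = list(obs, NULL))
  lab <- apply(per[1:3, , drop = FALSE], 1,
               function(v) classify_phase(v, epsilon))
  lab <- matrix(lab, ncol = 3, dimnames = list(NULL, obs[1:3]))
  list(mean = rowMeans(per),
       se = apply(per, 1, stats::sd) / sqrt(runs),
       labels = lab,
       majority = apply(lab, 2, .majority_label))
}

# majority over replicate phase labels; ties resolve toward the earlier of
# (D, C+D, C) for a conservative (defection-leaning) call
.majority_label <- function(labs) {
  tab <- table(factor(labs, levels = c("D", "C+D", "C")))
  names(tab)[which.max(tab)]
}

.make_sweep <- function(axis, grid, fixed, L, relax, avg, runs, base_seed,
                        epsilon) {
  if (is.unsorted(grid, strictly = TRUE))
    stop(axis, " grid must be strictly increasing")
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    seeds <- base_seed + (i - 1L) * runs + seq_len(runs) - 1L
    b <- if (axis == "b") grid[i] else fixed
    s <- if (axis == "s") grid[i] else fixed
    st <- .point_stats(b, s, L, relax, avg, runs, seeds, epsilon)
    rows[[i]] <- data.frame(
      x = grid[i],
      fc_sd = st$mean["fc_sd"], se_sd = st$se["fc_sd"],
      fc_pd = st$mean["fc_pd"], se_pd = st$se["fc_pd"],
      fc_sys = st$mean["fc_sys"], se_sys = st$se["fc_sys"],
      sync = st$mean["sync"],
      phase_sd = st$majority["fc_sd"], phase_pd = st$majority["fc_pd"],
      phase_sys = st$majority["fc_sys"],
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- axis
  structure(out,
            class = c("idg_sweep", "data.frame"),
            axis = axis, fixed = fixed,
            config = list(L = L, relax = relax, avg = avg, runs = runs,
                          base_seed = base_seed, epsilon = epsilon))
}

#' Sweep the temptation b at fixed social influence strength
#'
#' Replicated steady-state cooperation frequencies for each value of `b`.
#'
#' @param s social influence strength held fixed.
#' @param b_grid strictly increasing temptation values in `(1, 2]`.
#' @param L,relax,avg,runs,base_seed,epsilon steady-state protocol: lattice
#'   size, relaxation and averaging MC steps, replicate count, base seed
#'   (replicate seeds are consecutive integers from it) and phase tolerance.
#' @return An `"idg_sweep"` data frame with one row per grid point: per-layer
#'   and system mean cooperation frequency, standard errors, synchronization
#'   index, and majority phase labels.
#' @export
sweep_b <- function(s = 0.05, b_grid = seq(1.05, 1.5, by = 0.05), L = 100,
                    relax = 20000, avg = 2000, runs = 10, base_seed = 1,
                    epsilon = 0.01) {
  if (any(b_grid <= 1 | b_grid > 2)) stop("b values must lie in (1, 2]")
  .make_sweep("b", b_grid, s, L, relax, avg, runs, base_seed, epsilon)
}

#' Sweep the social influence strength s at fixed temptation
#'
#' @param b temptation held fixed.
#' @param s_grid strictly increasing influence strengths in `[0, 1]`.
#' @inheritParams sweep_b
#' @return An `"idg_sweep"` data frame, see [sweep_b()].
#' @export
sweep_s <- function(b = 1.1, s_grid = seq(0, 0.6, by = 0.05), L = 100,
                    relax = 20000, avg = 2000, runs = 10, base_seed = 1,
                    epsilon = 0.01) {
  if (any(s_grid < 0 | s_grid > 1)) stop("s values must lie in [0, 1]")
  .make_sweep("s", s_grid, b, L, relax, avg, runs, base_seed, epsilon)
}

#' Locate a phase-transition threshold on a sweep
#'
#' Scans the majority phase labels of a sweep for the characteristic change
#' and returns the bracketing grid interval and its midpoint. The three
#' threshold kinds are: `"s_o"`, the abrupt outbreak of cooperation
#' (last D -> C change along increasing s); `"s_v"`, the vanishing of
#' cooperation (last non-D -> D change along s); and `"b_c"`, the critical
#' temptation (last non-D -> D change along b). If a `probe` function is
#' supplied the bracket is refined by bisection on the phase label down to
#' `resolution`.
#'
#' @param sweep an `"idg_sweep"`.
#' @param kind `"s_o"`, `"s_v"` or `"b_c"`.
#' @param layer which phase-label column to scan: `"system"`, `"SD"`, `"PD"`.
#' @param probe optional function(x) returning the majority phase label
#'   (`"C"`, `"D"`, `"C+D"`) of a fresh replicated run at parameter `x`.
#' @param resolution target bracket width for bisection refinement.
#' @return A list of class `"idg_threshold"`: `kind`, `bracketed`, and when
#'   bracketed, `value` (bracket midpoint) and `bracket`.
#' @export
detect_threshold <- function(sweep, kind = c("s_o", "s_v", "b_c"),
                             layer = c("system", "SD", "PD"), probe = NULL,
                             resolution = 0.005) {
  kind <- match.arg(kind)
  layer <- match.arg(layer)
  axis <- attr(sweep, "axis")
  if (kind == "b_c" && axis != "b")
    stop("b_c detection needs a sweep over b")
  if (kind != "b_c" && axis != "s")
    stop(kind, " detection needs a sweep over s")
  x <- sweep[[axis]]
  lab <- sweep[[switch(layer, system = "phase_sys", SD = "phase_sd",
                       PD = "phase_pd")]]
  n <- length(x)
  hit <- NA
  for (i in seq_len(n - 1)) {
    change <- if (kind == "s_o") lab[i] == "D" && lab[i + 1] == "C"
              else lab[i] != "D" && lab[i + 1] == "D"
    if (change) hit <- i
  }
  if (is.na(hit))
    return(structure(list(kind = kind, bracketed = FALSE),
                     class = "idg_threshold"))
  lo <- x[hit]; hi <- x[hit + 1]
  lo_lab <- lab[hit]
  if (!is.null(probe)) {
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      if (identical(probe(mid), lo_lab)) lo <- mid else hi <- mid
    }
  }
  structure(list(kind = kind, bracketed = TRUE, value = (lo + hi) / 2,
                 bracket = c(lo, hi)),
            class = "idg_threshold")
}

#' @export
print.idg_threshold <- function(x, ...) {
  if (!x$bracketed) {
    cat(sprintf("threshold %s: not bracketed by the scanned grid\n", x$kind))
  } else {
    cat(sprintf("threshold %s = %.4f  (bracket [%.4f, %.4f])\n",
                x$kind, x$value, x$bracket[1], x$bracket[2]))
  }
  invisible(x)
}

#' Locate the cooperation-outbreak threshold s_o
#'
#' Full protocol for the abrupt defection-to-cooperation transition at fixed
#' temptation: sweep `s` over a grid, find the last D -> C change of the
#' majority phase label, then refine the bracket by bisection with fresh
#' replicated probe runs. If the scanned grid does not bracket the change,
#' the grid is extended (downward while everything is cooperative, upward
#' while everything is defective) before giving up.
#'
#' @param b temptation.
#' @param s_from,s_to,step scan grid for `s`.
#' @param resolution target bisection bracket width.
#' @param extend logical; extend the grid when the transition falls outside.
#' @inheritParams sweep_b
#' @return A list of class `"idg_outbreak"` with the combined `sweep` and the
#'   refined `threshold`.
#' @export
find_outbreak_threshold <- function(b = 1.1, s_from = 0.40, s_to = 0.55,
                                    step = 0.01, L = 100, relax = 20000,
                                    avg = 2000, runs = 10, base_seed = 1,
                                    epsilon = 0.01, resolution = 0.005,
                                    extend = TRUE) {
  grid <- seq(s_from, s_to, by = step)
  sw <- sweep_s(b = b, s_grid = grid, L = L, relax = relax, avg = avg,
                runs = runs, base_seed = base_seed, epsilon = epsilon)
  ext_seed <- base_seed + 100000L
  n_ext <- 0L
  repeat {
    th <- detect_threshold(sw, "s_o")
    if (th$bracketed || !extend || n_ext >= 40L) break
    lab <- sw$phase_sys
    if (all(lab == "C") && min(sw$s) - step >= 0) {
      new_s <- min(sw$s) - step
    } else if (all(lab == "D") && max(sw$s) + step <= 1) {
      new_s <- max(sw$s) + step
    } else break
    n_ext <- n_ext + 1L
    seeds <- ext_seed + (n_ext - 1L) * runs + seq_len(runs) - 1L
    st <- .point_stats(b, new_s, L, relax, avg, runs, seeds, epsilon)
    row <- data.frame(s = new_s,
                      fc_sd = st$mean["fc_sd"], se_sd = st$se["fc_sd"],
                      fc_pd = st$mean["fc_pd"], se_pd = st$se["fc_pd"],
                      fc_sys = st$mean["fc_sys"], se_sys = st$se["fc_sys"],
                      sync = st$mean["sync"],
                      phase_sd = st$majority["fc_sd"],
                      phase_pd = st$majority["fc_pd"],
                      phase_sys = st$majority["fc_sys"], row.names = NULL)
    at <- attributes(sw)
    sw <- rbind(row, as.data.frame(sw))
    sw <- sw[order(sw$s), ]
    attr(sw, "axis") <- at$axis; attr(sw, "fixed") <- at$fixed
    attr(sw, "config") <- at$config
    class(sw) <- c("idg_sweep", "data.frame")
  }
  probe_counter <- 0L
  probe <- function(x) {
    probe_counter <<- probe_counter + 1L
    seeds <- base_seed + 200000L + (probe_counter - 1L) * runs +
      seq_len(runs) - 1L
    st <- .point_stats(b, x, L, relax, avg, runs, seeds, epsilon)
    st$majority["fc_sys"]
  }
  th <- detect_threshold(sw, "s_o", probe = if (th$bracketed) probe,
                         resolution = resolution)
  structure(list(sweep = sw, threshold = th, b = b), class = "idg_outbreak")
}

#' @export
print.idg_outbreak <- function(x, ...) {
  cat(sprintf("Outbreak threshold search at b = %g\n", x$b))
  print(x$threshold)
  invisible(x)
}

#' Phase diagram in the b-s plane
#'
#' Replicated steady-state simulations on a grid of (temptation, social
#' influence) cells, recording per-layer phase labels and the system-average
#' cooperation frequency.
#'
#' @param b_grid,s_grid strictly increasing parameter grids.
#' @inheritParams sweep_b
#' @return An object of class `"idg_phase"`: matrices (`b` by `s`) of
#'   system-average cooperation `fc_sys`, per-layer frequencies and phase
#'   labels.
#' @export
phase_diagram <- function(b_grid, s_grid, L = 100, relax = 20000, avg = 2000,
                          runs = 5, base_seed = 1, epsilon = 0.01) {
  if (is.unsorted(b_grid, strictly = TRUE) ||
      is.unsorted(s_grid, strictly = TRUE))
    stop("b_grid and s_grid must be strictly increasing")
  nb <- length(b_grid); ns <- length(s_grid)
  dims <- list(b = as.character(b_grid), s = as.character(s_grid))
  fc_sys <- fc_sd <- fc_pd <- matrix(NA_real_, nb, ns, dimnames = dims)
  ph_sd <- ph_pd <- matrix(NA_character_, nb, ns, dimnames = dims)
  cell <- 0L
  for (i in seq_len(nb)) for (j in seq_len(ns)) {
    cell <- cell + 1L
    seeds <- base_seed + (cell - 1L) * runs + seq_len(runs) - 1L
    st <- .point_stats(b_grid[i], s_grid[j], L, relax, avg, runs, seeds,
                       epsilon)
    fc_sys[i, j] <- st$mean["fc_sys"]
    fc_sd[i, j] <- st$mean["fc_sd"]
    fc_pd[i, j] <- st$mean["fc_pd"]
    ph_sd[i, j] <- st$majority["fc_sd"]
    ph_pd[i, j] <- st$majority["fc_pd"]
  }
  structure(list(b = b_grid, s = s_grid, fc_sys = fc_sys, fc_sd = fc_sd,
                 fc_pd = fc_pd, phase_sd = ph_sd, phase_pd = ph_pd,
                 config = list(L = L, relax = relax, avg = avg, runs = runs,
                               base_seed = base_seed, epsilon = epsilon)),
            class = "idg_phase")
}

#' Time course of interlayer strategy-pair frequencies
#'
#' Runs a single simulation from a random 50/50 initial state and returns the
#' recorded pair frequencies, either at every MC step or at log-spaced
#' checkpoints (1, 2, 5, 10, ...) that resolve both the early splitting and
#' the late coarsening.
#'
#' @param b,s game parameters.
#' @param L lattice linear size.
#' @param steps time horizon in MC steps.
#' @param seed run seed.
#' @param record `"log"` (default) or `"all"`.
#' @return A data frame of class `"idg_timecourse"`: `step`, `f_cc`, `f_dd`,
#'   `f_cd`, `f_dc`, `fc_sd`, `fc_pd`, `fc_sys`, `sync`.
#' @export
time_course_pairs <- function(b = 1.1, s = 0.05, L = 100, steps = 10000,
                              seed = 1, record = c("log", "all")) {
  record <- match.arg(record)
  run <- run_simulation(game_params(b = b, s = s), L = L, relax = 0,
                        avg = steps, seed = seed)
  ts <- run$ts
  if (record == "log") {
    pts <- unique(c(0, as.vector(outer(c(1, 2, 5),
                                       10^(0:ceiling(log10(steps)))))))
    pts <- pts[pts <= steps]
    ts <- ts[ts$step %in% pts, , drop = FALSE]
  }
  structure(ts[, c("step", "f_cc", "f_dd", "f_cd", "f_dc",
                   "fc_sd", "fc_pd", "fc_sys", "sync")],
            class = c("idg_timecourse", "data.frame"),
            b = b, s = s, L = L, seed = seed)
}

#' Snapshot series from a prepared initial state
#'
#' Evolves a prepared centered cooperator block and keeps both layers' grids
#' at the requested MC steps, for visualizing how cooperative domains
#' survive, split, vanish or expand.
#'
#' @param b,s game parameters.
#' @param L lattice linear size.
#' @param times sorted ascending MC step indices (0 = initial state).
#' @param block_side side of the prepared cooperator block.
#' @param seed run seed.
#' @param horizon run length; defaults to `max(times)`. Requesting a time
#'   beyond the horizon is an error.
#' @return A list of class `"idg_snapshots"`: `times` and `states` (one
#'   `"idg_state"` per requested time), plus the run metadata.
#' @export
snapshot_series <- function(b = 1.1, s = 0.05, L = 200, times = c(0, 10, 100),
                            block_side = floor(L / 2), seed = 1,
                            horizon = max(times)) {
  if (is.unsorted(times)) stop("times must be sorted ascending")
  if (any(times > horizon)) stop("requested time beyond horizon")
  run <- run_simulation(game_params(b = b, s = s), L = L, init = "block",
                        block_side = block_side, relax = 0, avg = horizon,
                        seed = seed, snapshots = times)
  structure(list(times = times, states = run$snapshots, b = b, s = s, L = L,
                 block_side = block_side, seed = seed),
            class = "idg_snapshots")
}
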