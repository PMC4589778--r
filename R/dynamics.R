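# Asynchronous Monte Carlo dynamics. Two implementations coexist on purpose:
# a plain-R reference path (one elementary update at a time, driven by R's
# RNG) used for exposition and testing, and the compiled engine behind
# mc_step()/run_simulation() used for production runs. Their agreement is
# established distributionally against the exact enumeration oracle.

.grid_of <- function(state, layer) if (layer == "SD") state$sd else state$pd

.other_layer <- function(layer) if (layer == "SD") "PD" else "SD"

#' Fermi strategy-adoption probability
#'
#' Probability `W = 1 / (1 + exp((p_x - p_y) / K))` that a player with payoff
#' `p_x` adopts the strategy of a neighbor with payoff `p_y`. Strictly inside
#' `(0, 1)` up to floating-point resolution; the exponent is clamped to
#' +/- 500 so extreme payoff differences cannot overflow.
#'
#' @param p_x,p_y accumulated payoffs of the focal player and the model.
#' @param K uncertainty of the adoption process, `> 0`.
#' @return Adoption probabilities, vectorized over the payoff arguments.
#' @examples
#' fermi_probability(1, 1, 0.1)        # 0.5 by symmetry
#' fermi_probability(0.9, 1.0, 0.1)    # 1 / (1 + exp(-1))
#' @export
fermi_probability <- function(p_x, p_y, K = 0.1) {
  if (!is.numeric(K) || length(K) != 1 || K <= 0) stop("K must be > 0")
  z <- pmin(pmax((p_x - p_y) / K, -500), 500)
  1 / (1 + exp(z))
}

#' Majority strategy of a partner group
#'
#' The strategy held by at least 3 of the 5 group members (interlayer partner
#' plus the partner's four neighbors). With five members and two strategies a
#' tie is impossible.
#'
#' @param group vector of exactly five strategies, `"C"`/`"D"` or 1/0.
#' @return `"C"` or `"D"`.
#' @export
majority_strategy <- function(group) {
  if (length(group) != 5) stop("group must have exactly 5 members")
  g <- .as_strategies(group)
  if (sum(g == "C") >= 3) "C" else "D"
}

.as_strategies <- function(x) {
  if (is.numeric(x)) x <- c("D", "C")[x + 1]
  if (!all(x %in% c("C", "D"))) stop("strategies must be C/D or 1/0")
  x
}

#' Accumulated payoff of one player
#'
#' Sum of [payoff_single()] over the player's four von Neumann neighbors,
#' computed strictly within the player's own layer.
#'
#' @param state an `"idg_state"`.
#' @param layer `"SD"` or `"PD"`.
#' @param site 0-based `c(row, col)`.
#' @param params an [game_params()] object.
#' @return The accumulated payoff.
#' @export
accumulate_payoff <- function(state, layer, site, params = game_params()) {
  layer <- match.arg(layer, c("SD", "PD"))
  g <- .grid_of(state, layer)
  my <- c("D", "C")[g[site[1] + 1, site[2] + 1] + 1]
  nb <- neighbors(site, state$L)
  sum(vapply(seq_len(4), function(k) {
    opp <- c("D", "C")[g[nb[k, 1] + 1, nb[k, 2] + 1] + 1]
    payoff_single(my, opp, layer, params)
  }, numeric(1)))
}

# strategies of the partner group (partner site plus its four neighbors),
# all read from the other layer; 0/1 vector of length 5
.partner_group <- function(state, layer, site) {
  og <- .grid_of(state, .other_layer(layer))
  nb <- neighbors(site, state$L)
  c(og[site[1] + 1, site[2] + 1],
    og[nb[, 1] + 1 + nb[, 2] * state$L])
}

#' Social-influence (conformity) update
#'
#' Reference implementation of the conformity branch: with probability
#' `noise_prob` the result is a conformity-noise draw (see the `noise_mode`
#' argument of [game_params()]), otherwise it is the majority strategy of the
#' partner group on the other layer. Consumes R's RNG stream.
#'
#' @inheritParams accumulate_payoff
#' @return The new strategy, `"C"` or `"D"`.
#' @export
social_influence_update <- function(state, layer, site,
                                    params = game_params()) {
  layer <- match.arg(layer, c("SD", "PD"))
  group <- .partner_group(state, layer, site)
  if (runif(1) < params$noise_prob) {
    cur <- .grid_of(state, layer)[site[1] + 1, site[2] + 1]
    nC <- sum(group)
    switch(params$noise_mode,
           uniform = sample(c("C", "D"), 1),
           abstain = c("D", "C")[cur + 1],
           member  = c("D", "C")[sample(group, 1) + 1],
           set     = if (nC == 5) "C" else if (nC == 0) "D"
                     else sample(c("C", "D"), 1))
  } else {
    majority_strategy(group)
  }
}

#' Fermi imitation update
#'
#' Reference implementation of the imitation branch: picks one of the four
#' same-layer neighbors uniformly, computes both accumulated payoffs afresh,
#' and adopts the neighbor's strategy with probability
#' [fermi_probability()]. Consumes R's RNG stream.
#'
#' @inheritParams accumulate_payoff
#' @return The new strategy, `"C"` or `"D"`.
#' @export
imitation_update <- function(state, layer, site, params = game_params()) {
  layer <- match.arg(layer, c("SD", "PD"))
  g <- .grid_of(state, layer)
  sx <- c("D", "C")[g[site[1] + 1, site[2] + 1] + 1]
  nb <- neighbors(site, state$L)
  y <- nb[sample.int(4, 1), ]
  sy <- c("D", "C")[g[y[1] + 1, y[2] + 1] + 1]
  if (sy == sx) return(sx)  # adopting an identical strategy is a no-op
  p_x <- accumulate_payoff(state, layer, site, params)
  p_y <- accumulate_payoff(state, layer, y, params)
  if (runif(1) < fermi_probability(p_x, p_y, params$K)) sy else sx
}

#' One elementary update (reference path)
#'
#' Chooses a layer uniformly, a site uniformly among the `L^2` positions,
#' then executes the social-influence branch with probability `s` and the
#' imitation branch otherwise. At most one site changes.
#'
#' @param state an `"idg_state"`.
#' @param params an [game_params()] object.
#' @return A list with the updated `state` and an `event` record
#'   (`layer`, `site`, `branch`, `noise_fired`, `new_strategy`).
#' @export
elementary_update <- function(state, params = game_params()) {
  layer <- sample(c("SD", "PD"), 1)
  site <- c(sample.int(state$L, 1) - 1L, sample.int(state$L, 1) - 1L)
  si <- runif(1) < params$s
  noise_fired <- NA
  if (si) {
    # peek at the noise draw so the event record can report it
    u <- runif(1)
    noise_fired <- u < params$noise_prob
    group <- .partner_group(state, layer, site)
    new <- if (noise_fired) {
      cur <- .grid_of(state, layer)[site[1] + 1, site[2] + 1]
      nC <- sum(group)
      switch(params$noise_mode,
             uniform = sample(c("C", "D"), 1),
             abstain = c("D", "C")[cur + 1],
             member  = c("D", "C")[sample(group, 1) + 1],
             set     = if (nC == 5) "C" else if (nC == 0) "D"
                       else sample(c("C", "D"), 1))
    } else {
      majority_strategy(group)
    }
  } else {
    new <- imitation_update(state, layer, site, params)
  }
  g <- .grid_of(state, layer)
  g[site[1] + 1, site[2] + 1] <- as.integer(new == "C")
  if (layer == "SD") state$sd <- g else state$pd <- g
  list(state = state,
       event = list(layer = layer, site = site,
                    branch = if (si) "social_influence" else "imitation",
                    noise_fired = noise_fired, new_strategy = new))
}

# low-level bridge to the compiled engine
.engine_run <- function(state, params, steps, seed, snapshots = integer(0)) {
  run_engine(state$sd, state$pd, params$b, params$R, params$S, params$P_pd,
             params$P_sd, params$K, params$s, params$noise_prob,
             .noise_mode_int(params$noise_mode), as.integer(steps),
             as.integer(seed), as.integer(snapshots))
}

#' Advance a state by full Monte Carlo steps
#'
#' One full MC step performs `2 L^2` elementary updates (random sequential),
#' so that each player on both layers is selected once on average. Runs on
#' the compiled engine; identical `seed` and inputs give bit-identical
#' results.
#'
#' @param state an `"idg_state"`.
#' @param params an [game_params()] object.
#' @param steps number of full MC steps (default 1).
#' @param seed integer seed of the engine's RNG stream.
#' @return The updated `"idg_state"`.
#' @export
mc_step <- function(state, params = game_params(), steps = 1, seed = 1) {
  if (steps < 0) stop("steps must be >= 0")
  if (steps == 0) return(state)
  res <- .engine_run(state, params, steps, seed)
  lattice_state(res$sd, res$pd)
}

#' Run a full simulation
#'
#' Initializes a paired lattice, relaxes it for `relax` MC steps, then runs
#' `avg` further steps forming the averaging window. Cooperation frequencies
#' and interlayer pair frequencies are recorded after every MC step (step 0
#' is the initial state). All randomness derives from `seed`: the initial
#' state is drawn with R's RNG seeded at `seed`, and the engine stream is
#' seeded with the same integer.
#'
#' @param params an [game_params()] object.
#' @param L lattice linear size (used when `state` is not supplied).
#' @param init `"random"` for independent 50/50 layers or `"block"` for a
#'   prepared centered cooperator block.
#' @param block_side block side for `init = "block"` (default `L / 2`).
#' @param relax relaxation (transient) MC steps.
#' @param avg averaging-window MC steps.
#' @param seed integer seed; identical seed and configuration reproduce the
#'   trajectory bit-exactly.
#' @param state optional `"idg_state"` to start from, overriding `init`.
#' @param snapshots sorted MC step indices at which to keep full grid
#'   snapshots (0 = initial state).
#' @return An object of class `"idg_run"`: a list with the recorded
#'   time series `ts` (data frame: `step`, `fc_sd`, `fc_pd`, `fc_sys`,
#'   `f_cc`, `f_cd`, `f_dc`, `f_dd`, `sync`), the `final` state, any
#'   `snapshots`, and the run metadata.
#' @export
run_simulation <- function(params = game_params(), L = 100,
                           init = c("random", "block"), block_side = NULL,
                           relax = 20000, avg = 2000, seed = 1, state = NULL,
                           snapshots = integer(0)) {
  init <- match.arg(init)
  if (L < 3) stop("L must be >= 3")
  if (relax < 0 || avg < 0) stop("relax and avg must be >= 0")
  steps <- relax + avg
  snapshots <- as.integer(sort(snapshots))
  if (length(snapshots) && (any(snapshots < 0) || any(snapshots > steps)))
    stop("snapshot times must lie within [0, relax + avg]")
  if (is.null(state)) {
    if (!is.null(seed)) set.seed(seed)
    state <- if (init == "random") random_initial(L)
             else block_initial(L, if (is.null(block_side)) floor(L / 2)
                                   else block_side)
  } else {
    L <- state$L
  }
  res <- .engine_run(state, params, steps, seed, snapshots)
  N <- L^2
  cnt <- res$counts
  ts <- data.frame(step = 0:steps,
                   fc_sd = cnt[, 1] / N,
                   fc_pd = cnt[, 2] / N,
                   f_cc = cnt[, 3] / N)
  ts$fc_sys <- (ts$fc_sd + ts$fc_pd) / 2
  ts$f_cd <- ts$fc_sd - ts$f_cc
  ts$f_dc <- ts$fc_pd - ts$f_cc
  ts$f_dd <- 1 - ts$f_cc - ts$f_cd - ts$f_dc
  ts$sync <- ts$f_cc + ts$f_dd
  ts <- ts[, c("step", "fc_sd", "fc_pd", "fc_sys",
               "f_cc", "f_cd", "f_dc", "f_dd", "sync")]
  snaps <- lapply(res$snapshots, function(sn) lattice_state(sn$sd, sn$pd))
  structure(list(params = params, L = L, relax = relax, avg = avg,
                 seed = seed, init = init, ts = ts,
                 final = lattice_state(res$sd, res$pd), snapshots = snaps),
            class = "idg_run")
}

#' Replicate simulations from a parameter set
#'
#' @param object an [game_params()] object.
#' @param nsim number of replicate runs.
#' @param seed base seed; replicate `k` uses `seed + k - 1`.
#' @param ... passed on to [run_simulation()].
#' @return A list of `"idg_run"` objects.
#' @export
simulate.idg_params <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim) - 1L,
         function(k) run_simulation(params = object, seed = seed + k, ...))
}

#' Single-lattice reference simulation
#'
#' An independent single-layer implementation of the same game and Fermi
#' imitation rule (no interlayer coupling, no social influence), provided as
#' a comparator for the decoupled `s = 0` limit of the two-layer model. It is
#' written separately from the coupled engine.
#'
#' @param L lattice linear size, or `grid` a 0/1 matrix to start from.
#' @param layer `"SD"` or `"PD"`: selects the punishment payoff.
#' @param params an [game_params()] object (its `s`, `noise_prob` are ignored).
#' @param steps MC steps; each performs `L^2` elementary updates.
#' @param seed engine seed; the initial state (if `grid` not given) is drawn
#'   from R's RNG seeded with the same value.
#' @param grid optional initial 0/1 matrix.
#' @return A list with `fc` (cooperation frequency per recorded step,
#'   step 0 first) and the `final` grid.
#' @export
run_single_lattice <- function(L = 100, layer = c("SD", "PD"),
                               params = game_params(), steps = 1000,
                               seed = 1, grid = NULL) {
  layer <- match.arg(layer)
  if (is.null(grid)) {
    set.seed(seed)
    grid <- matrix(rbinom(L * L, 1L, 0.5), L)
  }
  storage.mode(grid) <- "integer"
  P <- if (layer == "SD") params$P_sd else params$P_pd
  res <- run_lattice_engine(grid, params$b, params$R, params$S, P, params$K,
                            as.integer(steps), as.integer(seed))
  list(fc = res$counts / length(grid), final = res$grid)
}
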