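# shared fixtures: small random states and the engine-vs-oracle chi-square

rand_state <- function(L, seed) {
  set.seed(seed)
  lattice_state(matrix(rbinom(L * L, 1L, 0.5), L),
                matrix(rbinom(L * L, 1L, 0.5), L))
}

# p-value of the chi-square comparison between the empirical single-update
# distribution of the compiled engine and the exact enumeration oracle;
# cells with expected count < 5 are pooled
chisq_engine_vs_oracle <- function(state, params, ndraws = 1e5, seed = 1) {
  pr <- enumerate_single_update(state, params)
  tl <- idnetgame:::tally_updates(
    state$sd, state$pd, params$b, params$R, params$S, params$P_pd,
    params$P_sd, params$K, params$s, params$noise_prob,
    idnetgame:::.noise_mode_int(params$noise_mode),
    as.integer(ndraws), as.integer(seed))
  e <- pr * ndraws
  big <- e >= 5
  o <- c(tl[big], sum(tl[!big]))
  ee <- c(e[big], sum(e[!big]))
  if (ee[length(ee)] == 0) {
    stopifnot(o[length(o)] == 0)
    o <- o[-length(o)]
    ee <- ee[-length(ee)]
  }
  stat <- sum((o - ee)^2 / ee)
  stats::pchisq(stat, df = length(ee) - 1, lower.tail = FALSE)
}

# a minimal idg_sweep-shaped object for threshold-detection tests
fake_sweep <- function(x, labels, axis = "s") {
  df <- data.frame(x = x, phase_sys = labels, phase_sd = labels,
                   phase_pd = labels, stringsAsFactors = FALSE)
  names(df)[1] <- axis
  structure(df, class = c("idg_sweep", "data.frame"), axis = axis)
}
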