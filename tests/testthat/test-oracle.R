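test_that("enumeration returns a normalized distribution", {
  for (seed in 1:6) {
    st <- rand_state(3, seed)
    p <- game_params(b = 1 + runif(1, 0.05, 1), s = runif(1),
                     noise_mode = sample(c("set", "uniform", "member",
                                           "abstain"), 1))
    pr <- enumerate_single_update(st, p)
    expect_equal(sum(pr), 1)
    expect_true(all(pr >= 0))
  }
  expect_error(enumerate_single_update(rand_state(5, 1)), "L <= 4")
})

test_that("all-defector state yields the exact known update distributions", {
  allD <- lattice_state(matrix(0L, 3, 3), matrix(0L, 3, 3))
  # pure imitation: point mass on the unchanged state
  pr0 <- enumerate_single_update(allD, game_params(s = 0))
  expect_equal(pr0[1], 1)
  # pure conformity with unconditional uniform noise: a cooperator appears
  # only via the noise draw, P(unchanged) = 1 - noise/2 = 0.95
  pr1 <- enumerate_single_update(allD, game_params(s = 1,
                                                   noise_mode = "uniform"))
  expect_equal(pr1[1], 0.95)
  expect_equal(unique(pr1[-1]), 0.05 / 18)  # mass spread over 18 sites
  # group-restricted noise cannot invent an absent strategy: absorbing
  pr2 <- enumerate_single_update(allD, game_params(s = 1, noise_mode = "set"))
  expect_equal(pr2[1], 1)
})

test_that("conformity branch lands on a C-majority group with rate 0.95", {
  # partner group mixed 3 C : 2 D, so every noise convention that can reach
  # both strategies gives P(C) = 0.9 * 1 + 0.1 * 0.5 = 0.95
  # group of SD site (0,0) = PD partner (0,0) plus its four neighbors
  g_pd <- matrix(0L, 3, 3)
  g_pd[1, 1] <- 1L   # partner
  g_pd[3, 1] <- 1L   # up neighbor (wraps)
  g_pd[2, 1] <- 1L   # down neighbor
  st <- lattice_state(matrix(0L, 3, 3), g_pd)
  for (mode in c("set", "uniform")) {
    p <- game_params(s = 1, noise_mode = mode)
    set.seed(42)
    draws <- replicate(4000, social_influence_update(st, "SD", c(0, 0), p))
    expect_equal(mean(draws == "C"), 0.95, tolerance = 0.03)
  }
})

test_that("engine single-update distribution matches the oracle", {
  # a quick spot check; the full 20-instance comparison lives in the
  # acceptance suite
  st <- rand_state(3, 99)
  p <- game_params(b = 1.3, s = 0.4)
  expect_gt(chisq_engine_vs_oracle(st, p, ndraws = 5e4, seed = 7), 0.01)
})
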