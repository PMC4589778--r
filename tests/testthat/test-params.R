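test_that("payoff matrix matches both games exactly for all 8 cases", {
  p <- game_params(b = 1.1)
  # PD: T > R > P > S with T = b, R = 1, P = 0.2, S = 0
  expect_identical(payoff_single("C", "C", "PD", p), 1)
  expect_identical(payoff_single("C", "D", "PD", p), 0)
  expect_identical(payoff_single("D", "C", "PD", p), 1.1)
  expect_identical(payoff_single("D", "D", "PD", p), 0.2)
  # SD: T > R > S > P with P = -0.2
  expect_identical(payoff_single("C", "C", "SD", p), 1)
  expect_identical(payoff_single("C", "D", "SD", p), 0)
  expect_identical(payoff_single("D", "C", "SD", p), 1.1)
  expect_identical(payoff_single("D", "D", "SD", p), -0.2)
})

test_that("payoff rankings hold for every admissible b", {
  for (b in c(1.01, 1.5, 2)) {
    p <- game_params(b = b)
    expect_true(p$b > p$R && p$R > p$P_pd && p$P_pd > p$S)  # PD
    expect_true(p$b > p$R && p$R > p$S && p$S > p$P_sd)     # SD
  }
})

test_that("invalid parameters are rejected with informative errors", {
  expect_error(game_params(b = 0.9), "b must")
  expect_error(game_params(b = 1), "b must")
  expect_error(game_params(b = 2.5), "b must")
  expect_error(game_params(s = -0.1), "s must")
  expect_error(game_params(s = 1.2), "s must")
  expect_error(game_params(K = 0), "K must")
  expect_error(game_params(noise_prob = 1.5), "noise_prob")
  expect_error(game_params(b = 1.1, P_pd = 1.2), "PD payoff ranking")
  expect_error(game_params(b = 1.1, P_sd = 0.5), "SD payoff ranking")
})
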