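test_that("Fermi probability matches its closed form and stays in (0,1)", {
  expect_equal(fermi_probability(1, 1, 0.1), 0.5)          # symmetry
  expect_equal(fermi_probability(0.9, 1.0, 0.1),
               1 / (1 + exp(-1)))                          # 0.7310586
  expect_equal(fermi_probability(-100, 100, 0.1), 1)       # limits, no overflow
  expect_equal(fermi_probability(100, -100, 0.1), 0)
  expect_error(fermi_probability(1, 1, 0), "K must")
})

test_that("Fermi probabilities of the two update directions sum to one", {
  set.seed(21)
  a <- runif(200, -5, 5); b <- runif(200, -5, 5)
  expect_equal(fermi_probability(a, b) + fermi_probability(b, a),
               rep(1, 200))
})

test_that("majority_strategy returns the 3-of-5 majority", {
  expect_identical(majority_strategy(c("C", "C", "C", "D", "D")), "C")
  expect_identical(majority_strategy(c("D", "D", "D", "D", "D")), "D")
  expect_identical(majority_strategy(c("C", "D", "D", "C", "D")), "D")
  expect_identical(majority_strategy(c(1, 1, 1, 0, 0)), "C")
  expect_error(majority_strategy(c("C", "D")), "exactly 5")
})

test_that("accumulated payoff sums the four neighbor games within one layer", {
  allC <- lattice_state(matrix(1L, 3, 3), matrix(1L, 3, 3))
  expect_equal(accumulate_payoff(allC, "PD", c(1, 1)), 4)    # 4 R
  allD <- lattice_state(matrix(0L, 3, 3), matrix(0L, 3, 3))
  expect_equal(accumulate_payoff(allD, "SD", c(1, 1)), -0.8) # 4 P_sd
  # C with exactly 2 C and 2 D neighbors in PD: 2 R + 2 S = 2
  g <- matrix(0L, 3, 3)
  g[2, 2] <- 1L; g[1, 2] <- 1L; g[3, 2] <- 1L  # up and down cooperate
  st <- lattice_state(g, g)
  expect_equal(accumulate_payoff(st, "PD", c(1, 1)), 2)
})

test_that("an elementary update changes at most one site", {
  set.seed(31)
  p <- game_params(b = 1.1, s = 0.4)
  for (rep in 1:25) {
    st <- rand_state(4, 100 + rep)
    out <- elementary_update(st, p)
    changed <- sum(out$state$sd != st$sd) + sum(out$state$pd != st$pd)
    expect_lte(changed, 1)
    expect_true(out$event$branch %in% c("social_influence", "imitation"))
  }
})

test_that("branch probabilities follow s at the extremes", {
  set.seed(32)
  st <- rand_state(4, 5)
  b1 <- replicate(50, elementary_update(st, game_params(s = 1))$event$branch)
  expect_true(all(b1 == "social_influence"))
  b0 <- replicate(50, elementary_update(st, game_params(s = 0))$event$branch)
  expect_true(all(b0 == "imitation"))
})

test_that("all-defector state is absorbing under pure imitation", {
  allD <- lattice_state(matrix(0L, 5, 5), matrix(0L, 5, 5))
  out <- mc_step(allD, game_params(s = 0), steps = 50, seed = 9)
  expect_identical(out$sd, allD$sd)
  expect_identical(out$pd, allD$pd)
})

test_that("trajectories are bit-identical for identical seeds", {
  p <- game_params(b = 1.2, s = 0.3)
  r1 <- run_simulation(p, L = 20, relax = 50, avg = 50, seed = 123)
  r2 <- run_simulation(p, L = 20, relax = 50, avg = 50, seed = 123)
  expect_identical(r1$ts, r2$ts)
  expect_identical(r1$final, r2$final)
  # distinct seeds give distinct trajectories (coexistence regime, so the
  # runs cannot both collapse onto the same absorbing state)
  p2 <- game_params(b = 1.1, s = 0.05)
  r3 <- run_simulation(p2, L = 20, relax = 50, avg = 50, seed = 123)
  r4 <- run_simulation(p2, L = 20, relax = 50, avg = 50, seed = 124)
  expect_false(identical(r3$ts, r4$ts))
})

test_that("run_simulation validates inputs and honors degenerate windows", {
  p <- game_params()
  expect_error(run_simulation(p, L = 2), "L must")
  expect_error(run_simulation(p, L = 10, relax = -1), "relax")
  r <- run_simulation(p, L = 10, relax = 30, avg = 0, seed = 1)
  expect_equal(nrow(r$ts), 31)  # steps 0..relax
  # snapshot at t = 0 reproduces the initial state exactly
  r2 <- run_simulation(p, L = 12, init = "block", relax = 0, avg = 5,
                       seed = 3, snapshots = 0)
  expect_identical(r2$snapshots[[1]]$sd, block_initial(12)$sd)
  expect_error(run_simulation(p, L = 10, relax = 5, avg = 0, snapshots = 9),
               "snapshot")
})

test_that("simulate() yields independent replicate runs", {
  p <- game_params(s = 0.2)
  runs <- simulate(p, nsim = 3, seed = 7, L = 15, relax = 20, avg = 20)
  expect_length(runs, 3)
  expect_false(identical(runs[[1]]$final, runs[[2]]$final))
  # replicate 1 is the same run as a direct call with the same seed
  direct <- run_simulation(p, L = 15, relax = 20, avg = 20, seed = 7)
  expect_identical(runs[[1]]$ts, direct$ts)
})
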