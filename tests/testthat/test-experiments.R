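test_that("threshold detection brackets constructed step curves", {
  sw <- fake_sweep(seq(0.40, 0.55, 0.01),
                   ifelse(seq(0.40, 0.55, 0.01) < 0.47, "D", "C"))
  th <- detect_threshold(sw, "s_o")
  expect_true(th$bracketed)
  expect_equal(th$bracket, c(0.46, 0.47))
  expect_equal(th$value, 0.465)
  # property: random step positions are always bracketed correctly
  set.seed(17)
  grid <- seq(0, 1, by = 0.02)
  for (rep in 1:20) {
    cross <- runif(1, 0.1, 0.9)
    sw <- fake_sweep(grid, ifelse(grid < cross, "D", "C"))
    th <- detect_threshold(sw, "s_o")
    expect_true(th$bracketed)
    expect_true(th$bracket[1] < cross && cross <= th$bracket[2] + 1e-12)
  }
})

test_that("vanishing-type thresholds use the non-D to D change", {
  grid <- seq(0, 0.4, by = 0.05)
  sw <- fake_sweep(grid, ifelse(grid < 0.15, "C+D", "D"))
  th <- detect_threshold(sw, "s_v")
  expect_true(th$bracketed)
  expect_equal(th$bracket, c(0.10, 0.15))
  bw <- fake_sweep(seq(1.05, 1.5, 0.05),
                   ifelse(seq(1.05, 1.5, 0.05) < 1.3, "C+D", "D"), axis = "b")
  tb <- detect_threshold(bw, "b_c")
  expect_true(tb$bracketed)
  expect_true(tb$bracket[1] < 1.3 && 1.3 <= tb$bracket[2])
})

test_that("a sweep without a phase change reports not-bracketed", {
  sw <- fake_sweep(seq(0.4, 0.5, 0.01), rep("D", 11))
  expect_false(detect_threshold(sw, "s_o")$bracketed)
  expect_output(print(detect_threshold(sw, "s_o")), "not bracketed")
})

test_that("bisection refines a bracket to the requested resolution", {
  cross <- 0.4632
  grid <- seq(0.40, 0.50, by = 0.02)
  sw <- fake_sweep(grid, ifelse(grid < cross, "D", "C"))
  th <- detect_threshold(sw, "s_o",
                         probe = function(x) if (x < cross) "D" else "C",
                         resolution = 0.0025)
  expect_lte(th$bracket[2] - th$bracket[1], 0.0025)
  expect_true(th$bracket[1] < cross && cross <= th$bracket[2])
  expect_equal(th$value, cross, tolerance = 0.0025)
})

test_that("sweeps are reproducible and carry the full summary", {
  sw1 <- sweep_s(b = 1.1, s_grid = c(0.0, 0.3), L = 16, relax = 150,
                 avg = 100, runs = 2, base_seed = 5)
  sw2 <- sweep_s(b = 1.1, s_grid = c(0.0, 0.3), L = 16, relax = 150,
                 avg = 100, runs = 2, base_seed = 5)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  expect_named(as.data.frame(sw1),
               c("s", "fc_sd", "se_sd", "fc_pd", "se_pd", "fc_sys",
                 "se_sys", "sync", "phase_sd", "phase_pd", "phase_sys"))
  expect_true(all(sw1$phase_sys %in% c("C", "D", "C+D")))
  expect_error(sweep_s(s_grid = c(0.5, 0.2)), "strictly increasing")
  expect_error(sweep_b(b_grid = c(0.9, 1.1)), "b values")
})

test_that("a 1x1 phase diagram cell agrees with the sweep at that point", {
  pd <- phase_diagram(b_grid = 1.15, s_grid = 0.25, L = 16, relax = 150,
                      avg = 100, runs = 2, base_seed = 9)
  sw <- sweep_s(b = 1.15, s_grid = 0.25, L = 16, relax = 150, avg = 100,
                runs = 2, base_seed = 9)
  expect_equal(unname(pd$fc_sys[1, 1]), sw$fc_sys[1])
  expect_equal(unname(pd$phase_sd[1, 1]), sw$phase_sd[1])
})

test_that("pair-frequency time courses start near the independent value", {
  tc <- time_course_pairs(b = 1.1, s = 0.3, L = 100, steps = 10, seed = 3,
                          record = "all")
  first <- tc[tc$step == 0, ]
  # independent 50/50 layers: each pair category has expectation 1/4
  for (col in c("f_cc", "f_dd", "f_cd", "f_dc"))
    expect_equal(first[[col]], 0.25, tolerance = 0.02)
  # log-spaced recording keeps the 1-2-5 ladder
  tcl <- time_course_pairs(b = 1.1, s = 0.3, L = 20, steps = 100, seed = 3)
  expect_true(all(tcl$step %in% c(0, 1, 2, 5, 10, 20, 50, 100)))
})

test_that("snapshot series obeys its horizon contract", {
  sn <- snapshot_series(b = 1.1, s = 0.05, L = 20, times = c(0, 5),
                        block_side = 10, seed = 2)
  expect_identical(sn$states[[1]]$sd, block_initial(20, 10)$sd)
  expect_identical(sn$states[[1]]$pd, block_initial(20, 10)$pd)
  expect_length(sn$states, 2)
  expect_error(snapshot_series(times = c(5, 0)), "sorted")
  expect_error(snapshot_series(times = c(0, 50), horizon = 10), "horizon")
})
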