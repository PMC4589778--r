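test_that("neighbors wraps periodically in the fixed up/down/left/right order", {
  expect_identical(neighbors(c(0, 0), 4),
                   matrix(c(3L, 0L, 1L, 0L, 0L, 3L, 0L, 1L),
                          ncol = 2, byrow = TRUE))
  expect_identical(neighbors(c(2, 2), 5),
                   matrix(c(1L, 2L, 3L, 2L, 2L, 1L, 2L, 3L),
                          ncol = 2, byrow = TRUE))
  expect_error(neighbors(c(4, 0), 4), "site")
})

test_that("neighbor relation is symmetric and 4-regular on the torus", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(3:8, 1)
    x <- c(sample(0:(L - 1), 1), sample(0:(L - 1), 1))
    nb <- neighbors(x, L)
    expect_equal(nrow(unique(nb)), 4)  # degree 4, all distinct for L >= 3
    for (k in 1:4) {
      back <- neighbors(nb[k, ], L)
      expect_true(any(back[, 1] == x[1] & back[, 2] == x[2]))
    }
  }
})

test_that("random initial states are reproducible, balanced and independent", {
  s1 <- random_initial(100, seed = 7)
  s2 <- random_initial(100, seed = 7)
  expect_identical(s1, s2)
  # binomial bound: n = 10^4 per layer, P(|fc - 0.5| > 0.05) < 1e-3
  expect_gt(mean(s1$sd), 0.45); expect_lt(mean(s1$sd), 0.55)
  expect_gt(mean(s1$pd), 0.45); expect_lt(mean(s1$pd), 0.55)
  # independent layers: agreement fraction near 1/2
  expect_gt(synchronization_index(s1), 0.45)
  expect_lt(synchronization_index(s1), 0.55)
})

test_that("block initial state has the prescribed geometry", {
  st <- block_initial(200, 100)
  expect_equal(mean(st$sd), 0.25)  # area fraction
  expect_equal(mean(st$pd), 0.25)
  expect_identical(st$sd, st$pd)
  expect_equal(synchronization_index(st), 1)
  expect_equal(mean(block_initial(8, 8)$sd), 1)  # block_side = L is all-C
  expect_error(block_initial(10, 11), "block_side")
})

test_that("lattice_state validates its grids", {
  g <- matrix(0L, 4, 4)
  expect_error(lattice_state(g, matrix(0L, 5, 5)), "identical dimensions")
  expect_error(lattice_state(matrix(2L, 4, 4), g), "only 0 and 1")
  expect_error(lattice_state(matrix(0L, 2, 2), matrix(0L, 2, 2)), "L must")
})
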