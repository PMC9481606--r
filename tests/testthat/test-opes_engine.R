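# The on-the-fly kernel bias: epsilon, deposits, bias evaluation, the full
# biased run, and FES reweighting.

test_that("epsilon_from_barrier has the closed form and limits", {
  expect_equal(epsilon_from_barrier(5, gamma = Inf, beta = 1), exp(-5))
  expect_equal(epsilon_from_barrier(3, gamma = 10, beta = 2),
               exp(-2 * 3 / (1 - 1 / 10)))
  expect_lt(epsilon_from_barrier(50, 10), epsilon_from_barrier(5, 10))
  expect_equal(epsilon_from_barrier(1e4, 10), 0)  # DeltaE -> Inf limit
  expect_error(epsilon_from_barrier(5, gamma = 1), "gamma")
})

test_that("deposit obeys the weight definition and the exclusion contract", {
  st <- bias_state(gamma = 10, sigma = 0.2, barrier = 5)
  expect_equal(evaluate_bias(st, 0.3), 0)      # V0 = 0 convention
  st <- deposit(st, 0.0)
  expect_equal(st$weights, 1)                  # w1 = e^0
  # excluded region: no kernel added, state unchanged
  stx <- bias_state(gamma = 10, sigma = 0.2, barrier = 5,
                    excluded_region = cv_region(min = 1))
  stx <- deposit(stx, 0.5)
  n0 <- nrow(stx$centers)
  stx2 <- deposit(stx, 1.5)
  expect_identical(nrow(stx2$centers), n0)
  expect_identical(stx2$weights, stx$weights)
  expect_error(deposit(st, NaN), "non-finite")
})

test_that("repeated deposits at one point with tiny epsilon keep weights 1", {
  # gamma = Inf, large barrier => epsilon ~ 0 => V at the deposited point
  # stays ~ log(1 + eps) ~ 0, so all weights stay 1 and P_n(s) is exactly
  # one normalised Gaussian evaluated at its centre
  st <- bias_state(gamma = Inf, sigma = 0.3, barrier = 18)
  for (i in 1:5) st <- deposit(st, 1.2)
  expect_equal(st$weights, rep(1, 5), tolerance = 1e-6)
  P <- sum(aquaopes:::.kernel_matrix(st, matrix(1.2)) %*% st$weights) /
    st$sum_w
  expect_equal(P, 1 / (0.3 * sqrt(2 * pi)), tolerance = 1e-12)
})

test_that("evaluate_bias matches Eq.-style direct kernel sums and limits", {
  set.seed(6)
  st <- bias_state(gamma = 8, sigma = 0.15, beta = 2, barrier = 4)
  for (s in rnorm(40, 0, 0.4)) st <- deposit(st, s)
  grid <- seq(-1.5, 1.5, length.out = 101)
  v <- evaluate_bias(st, grid, gradient = TRUE)

  # oracle: independent dense summation of normalised Gaussians
  P_or <- sapply(grid, function(s) {
    sum(st$weights * exp(-(s - st$centers[, 1])^2 / (2 * 0.15^2))) /
      (0.15 * sqrt(2 * pi)) / st$sum_w
  })
  v_or <- (1 - 1 / 8) / 2 * log(P_or / st$Z + st$epsilon)
  expect_equal(as.numeric(v), v_or, tolerance = 1e-12)

  # where P/Z >> eps the bias is the pure log-density term
  peak <- which.max(P_or)
  expect_equal(v[peak], (1 - 1 / 8) / 2 * log(P_or[peak] / st$Z),
               tolerance = 1e-3)
  # far away: the floor
  expect_equal(evaluate_bias(st, 50), bias_floor(st))
  # gradient vs central differences
  g <- attr(v, "gradient")[, 1]
  num <- (evaluate_bias(st, grid + 1e-6) -
            evaluate_bias(st, grid - 1e-6)) / 2e-6
  expect_equal(g, num, tolerance = 1e-6)
})

test_that("gamma = 1 means no bias at all", {
  st <- bias_state(gamma = 1, sigma = 0.2, epsilon = 0.5)
  for (s in c(-0.3, 0, 0.4)) st <- deposit(st, s)
  expect_equal(evaluate_bias(st, seq(-1, 1, 0.1)),
               rep(0, 21))
  # and a gamma = 1 run is the unbiased trajectory, bit for bit
  spec <- langevin_spec(dw1(3), n_steps = 5e4, seed = 77)
  r1 <- run_opes(spec, opes_config(barrier = 5, gamma = 1))
  r0 <- run_langevin(spec)
  expect_equal(r1$series$s, r0$s)
  expect_true(all(r1$series[["opes.bias"]] == 0))
})

test_that("bias magnitude scales exactly by (1 - 1/gamma)", {
  set.seed(8)
  st2 <- bias_state(gamma = 2, sigma = 0.2, epsilon = 1e-4)
  for (s in rnorm(10)) st2 <- deposit(st2, s)
  st20 <- st2; st20$gamma <- 20
  grid <- seq(-2, 2, 0.25)
  # same kernels, same Z: ratio of prefactors only
  expect_equal(evaluate_bias(st20, grid) / evaluate_bias(st2, grid),
               rep((1 - 1 / 20) / (1 - 1 / 2), length(grid)))
})

test_that("a biased run caps the bias, flattens the well and reweights back", {
  res <- opes_run_h5()
  st <- res$state
  # cap: dense grid scan after the full deposition history
  v <- evaluate_bias(st, seq(-2.5, 2.5, length.out = 1001))
  expect_lte(max(v), 6)
  expect_gte(min(v), bias_floor(st) - 1e-9)
  # many transitions vs unbiased
  expect_gte(count_transitions(res$series$s), 10)
  un <- run_langevin(langevin_spec(dw1(5), n_steps = 4e6, seed = 71,
                                   friction = 100))
  expect_lt(count_transitions(un$s), 3)
  # reweighted FES recovers the analytic potential
  fes <- reweighted_fes(res$series, discard = 0.2)
  sel <- is.finite(fes$free_energy) & fes$free_energy < 6
  U <- dw1(5)$energy(matrix(fes$s[sel], ncol = 1))
  U <- U - min(U)
  expect_lt(sqrt(mean((fes$free_energy[sel] - U)^2)), 0.75)
  # symmetric double well: interwell free-energy difference ~ 0
  left <- fes$free_energy[which.min(abs(fes$s + 1))]
  right <- fes$free_energy[which.min(abs(fes$s - 1))]
  err <- fes$error[which.min(abs(fes$s + 1))] +
    fes$error[which.min(abs(fes$s - 1))]
  expect_lt(abs(left - right), max(3 * err, 0.5))
})

test_that("deposit pacing contracts hold", {
  spec <- langevin_spec(dw1(3), n_steps = 1e4, seed = 5)
  res <- run_opes(spec, opes_config(barrier = 5, gamma = 10,
                                    deposit_period = 2e4))
  expect_true(all(res$series[["opes.bias"]] == 0))
  expect_equal(nrow(res$state$centers), 0L)
})

test_that("reweighted_fes handles the degenerate and unweighted cases", {
  ser <- run_langevin(langevin_spec(dw1(2), n_steps = 2e5, seed = 6),
                      stride = 10L)
  fes <- reweighted_fes(ser, n_blocks = 2)
  # zero bias: free energy equals the -log of the unweighted histogram
  h <- hist(ser$s, breaks = attr(fes, "edges"), plot = FALSE)
  Fh <- -log(h$counts / sum(h$counts))
  Fh <- Fh - min(Fh[is.finite(Fh)])
  expect_equal(fes$free_energy[is.finite(Fh)], Fh[is.finite(Fh)],
               tolerance = 1e-10)
  # two blocks made of identical halves -> zero block error
  dup <- ser
  dup_half <- ser[1:(nrow(ser) %/% 2), ]
  dup2 <- rbind(dup_half, dup_half)
  dup2$time <- seq_len(nrow(dup2))
  class(dup2) <- class(ser)
  attr(dup2, "kT") <- 1
  fes2 <- reweighted_fes(dup2, cv_col = "s", n_blocks = 2)
  expect_lt(max(fes2$error, na.rm = TRUE), 1e-10)
  expect_error(reweighted_fes(ser, bias_col = "nope"), "bias column")
  expect_error(reweighted_fes(ser, n_blocks = 1), "n_blocks")
})

test_that("no kernel centre ever falls in the excluded region", {
  spec <- langevin_spec(dw1(4), n_steps = 5e5, seed = 13)
  res <- run_opes(spec, opes_config(barrier = 3, gamma = 10,
                                    excluded_region = cv_region(min = 0)))
  expect_true(all(res$state$centers[, 1] < 0))
})

test_that("bias states serialize and restore", {
  res <- opes_run_h5()
  path <- withr::local_tempfile()
  write_bias_state(res$state, path)
  st2 <- read_bias_state(path)
  g <- seq(-2, 2, 0.05)
  expect_equal(evaluate_bias(st2, g), evaluate_bias(res$state, g),
               tolerance = 1e-8)
  expect_equal(st2$gamma, res$state$gamma)
  expect_equal(st2$epsilon, res$state$epsilon)
})
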