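test_that("without feedback the unique equilibrium matches the closed form", {
  p <- pfl_params()
  fp <- find_fixed_points(p, pfl_drive(S = 0.1, F = 0))
  expect_equal(nrow(fp), 1)
  expect_equal(fp$stability, "stable")
  expect_equal(c(fp$C_I, fp$C_P, fp$C_a),
               unname(closed_form_fixed_point(p, 0.1)), tolerance = 1e-8)
})

test_that("full feedback at zero stiffness gives the bistable diagonal trio", {
  p <- pfl_params()
  fp <- find_fixed_points(p, pfl_drive(S = 0, F = 1))
  expect_equal(nrow(fp), 3)
  expect_equal(fp$stability, c("stable", "saddle", "stable"))
  ## all equilibria on the diagonal for symmetric rates
  expect_lt(max(abs(fp$C_I - fp$C_P)), 1e-6)
  roots <- oracle_diagonal_roots(0, 1)
  expect_equal(fp$C_I, roots, tolerance = 5e-3)
  ## published-independent anchor values from the 1-D reduction
  expect_equal(roots, c(0, 0.114395, 0.794696), tolerance = 1e-4)
})

test_that("sufficient stiffness drive removes the quiescent branch", {
  p <- pfl_params()
  fp <- find_fixed_points(p, pfl_drive(S = 0.01, F = 1))
  expect_equal(sum(fp$stability == "stable"), 1)
  expect_gt(fp$C_a[fp$stability == "stable"], 0.9)
})

test_that("every fixed point satisfies the slaved C_a closed form", {
  p <- pfl_params()
  set.seed(3)
  for (i in 1:8) {
    drv <- pfl_drive(S = runif(1, 0, 5e-3), F = runif(1))
    fp <- find_fixed_points(p, drv, starts = 11)
    ca_expected <- p$k3f * (fp$C_I + fp$C_P) /
      (p$k3f * (fp$C_I + fp$C_P) + p$k3r)
    expect_lt(max(abs(fp$C_a - ca_expected)), 1e-9)
    expect_lt(max(fp$residual), 1e-9)
  }
})

test_that("multistart root-finder agrees with the nullcline-scan oracle", {
  p <- pfl_params()
  set.seed(101)
  for (i in 1:20) {
    S <- runif(1, 0, 8e-3); F <- runif(1)
    fp <- find_fixed_points(p, pfl_drive(S = S, F = F), starts = 21)
    orc <- oracle_fixed_points(S, F)
    expect_equal(nrow(fp), nrow(orc),
                 info = sprintf("count mismatch at S=%g F=%g", S, F))
    ord <- order(orc[, "C_a"])
    expect_lt(max(abs(fp$C_I - orc[ord, "C_I"])), 1e-3)
    expect_lt(max(abs(fp$C_P - orc[ord, "C_P"])), 1e-3)
  }
})

test_that("regime classification matches the diagonal-oracle root count", {
  p <- pfl_params()
  expect_equal(classify_regime(p, pfl_drive(S = 1.2e-3, F = 0)),
               "monostable_low")
  expect_equal(classify_regime(p, pfl_drive(S = 1.2e-3, F = 1)), "bistable")
  expect_equal(classify_regime(p, pfl_drive(S = 4.5e-3, F = 1)),
               "monostable_high")
})

test_that("stiffness sweep locates the saddle-node fold found by the oracle", {
  p <- pfl_params()
  bd <- bifurcation_sweep(p, pfl_drive(F = 1), axis = "S",
                          range = c(0, 6e-3), n = 25, starts = 11)
  expect_equal(length(bd$folds), 1)
  fold_oracle <- oracle_fold_S(F = 1)
  expect_lt(abs(bd$folds - fold_oracle) / fold_oracle, 0.01)
  ## regime label changes exactly at the fold
  eps <- 1e-5
  expect_equal(classify_regime(p, pfl_drive(S = bd$folds - eps, F = 1)),
               "bistable")
  expect_equal(classify_regime(p, pfl_drive(S = bd$folds + eps, F = 1)),
               "monostable_high")
})

test_that("feedback sweep shows a fold at soft stiffness but none at n = 1", {
  p <- pfl_params()
  bd <- bifurcation_sweep(p, pfl_drive(S = 1.2e-3), axis = "F",
                          range = c(0, 1), n = 21, starts = 11)
  expect_equal(length(bd$folds), 1)
  expect_gt(bd$folds, 0); expect_lt(bd$folds, 1)
  ## a first-order Hill term cannot produce bistability: one stable state
  ## everywhere, no saddle-node (the origin only exchanges stability)
  bd1 <- bifurcation_sweep(pfl_params(n = 1), pfl_drive(S = 0), axis = "F",
                           range = c(0, 1), n = 11, starts = 11)
  expect_equal(length(bd1$folds), 0)
  stable_per_val <- tapply(bd1$points$stability == "stable",
                           bd1$points$param, sum)
  expect_true(all(stable_per_val == 1))
  expect_error(bifurcation_sweep(p, pfl_drive(), axis = "F",
                                 range = c(0, 1), n = 2), "3 grid points")
})

test_that("stiffness hysteresis loop opens with feedback and closes without", {
  p <- pfl_params()
  up <- seq(0, 6e-3, by = 1e-3)
  path <- c(up, rev(up)[-1])
  hy <- hysteresis_sweep(p, path, F = 1)
  expect_true(hy$loop_open)
  ## the up sweep switches high past the fold; the down sweep stays high
  expect_lt(hy$states[1, "C_a"], 0.1)
  expect_gt(hy$states[length(path), "C_a"], 0.9)
  expect_false(hysteresis_sweep(p, path, F = 0)$loop_open)
  sub <- seq(0, 2e-3, by = 5e-4)
  expect_false(hysteresis_sweep(p, c(sub, rev(sub)[-1]), F = 1)$loop_open)
  expect_error(hysteresis_sweep(p, c(0, 1e-3)), "same value")
})
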