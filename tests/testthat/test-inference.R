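test_that("noiseless single-parameter recovery is essentially exact", {
  p <- pfl_params()
  sch <- make_dose_schedule("St14So14")
  truth_sch <- sch; truth_sch$feedback$F_max <- 0.8
  obs <- noisy_timecourse(p, truth_sch, times = seq(0, 28, length.out = 60),
                          noise = noise_model(sigma = 0, replicates = 1))
  fit <- pfl_fit(obs[, c("t", "value")], sch, free = list(F_max = c(0, 1)),
                 n_starts = 4, seed = 3)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), 0.8, tolerance = 1e-4)
})

test_that("the loss is minimized at the truth for noiseless data", {
  p <- pfl_params()
  sch <- make_dose_schedule("St14So14")
  truth_sch <- sch; truth_sch$feedback$F_max <- 0.8
  tt <- seq(0, 28, length.out = 40)
  obs <- noisy_timecourse(p, truth_sch, times = tt,
                          noise = noise_model(sigma = 0, replicates = 1))
  loss_at <- function(F_max) {
    s <- sch; s$feedback$F_max <- F_max
    tr <- pfl_simulate(p, s, times = tt)
    sum((tr$C_a - obs$value)^2)
  }
  l0 <- loss_at(0.8)
  expect_lt(l0, 1e-16)
  for (dF in c(-0.2, -0.05, 0.05, 0.2))
    expect_gt(loss_at(0.8 + dF), l0)
})

test_that("fits are invariant to observation row order and seeded", {
  p <- pfl_params()
  sch <- make_dose_schedule("St14So14")
  truth_sch <- sch; truth_sch$feedback$F_max <- 0.7
  obs <- noisy_timecourse(p, truth_sch, times = seq(0, 28, length.out = 50),
                          noise = noise_model(sigma = 0.02, replicates = 1,
                                              seed = 8))
  d <- obs[, c("t", "value")]
  f1 <- pfl_fit(d, sch, free = list(F_max = c(0, 1)), n_starts = 4, seed = 2)
  f2 <- pfl_fit(d[sample(nrow(d)), ], sch, free = list(F_max = c(0, 1)),
                n_starts = 4, seed = 2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  f3 <- pfl_fit(d, sch, free = list(F_max = c(0, 1)), n_starts = 4, seed = 2)
  expect_identical(coef(f1), coef(f3))
})

test_that("regime is preserved when fitting sub-threshold feedback", {
  p <- pfl_params()
  sch <- make_dose_schedule("St14So14")
  truth_sch <- sch; truth_sch$feedback$F_max <- 0.3
  obs <- noisy_timecourse(p, truth_sch, times = seq(0, 28, length.out = 60),
                          noise = noise_model(sigma = 0.01, replicates = 1,
                                              seed = 31))
  fit <- pfl_fit(obs[, c("t", "value")], sch, free = list(F_max = c(0, 1)),
                 n_starts = 4, seed = 31)
  soft_S <- stiffness_to_drive(4, sch$mapping)
  expect_equal(classify_regime(p, pfl_drive(S = soft_S, F = coef(fit))),
               classify_regime(p, pfl_drive(S = soft_S, F = 0.3)))
})

test_that("fit input validation and methods behave", {
  p <- pfl_params()
  sch <- make_dose_schedule("St7So7")
  obs <- noisy_timecourse(p, sch, times = seq(0, 14, length.out = 20),
                          noise = noise_model(sigma = 0, replicates = 1))
  d <- obs[, c("t", "value")]
  expect_error(pfl_fit(d[1:5, ], sch), "at least 10")
  expect_error(pfl_fit(d, sch, free = list()), "at least one")
  expect_error(pfl_fit(d, sch, free = list(bogus = c(0, 1))), "free parameters")
  expect_error(pfl_fit(d, sch, free = list(F_max = c(1, 0))), "increasing")
  fit <- pfl_fit(d, sch, free = list(F_max = c(0, 1)), n_starts = 2, seed = 1)
  expect_length(fitted(fit), nrow(d))
  expect_equal(unname(residuals(fit)), d$value - fitted(fit))
  expect_equal(length(predict(fit, times = c(0, 7, 14))), 3)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.pfl_fit")
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(nrow(d), 3))
})

test_that("recovery reports summarize bias and error correctly", {
  truth <- c(F_max = 0.8, n = 2)
  ident <- matrix(rep(truth, 3), 3, 2, byrow = TRUE,
                  dimnames = list(NULL, names(truth)))
  rep0 <- recovery_report(truth, ident)
  expect_equal(rep0$bias, c(0, 0))
  expect_equal(rep0$rmse, c(0, 0))
  ## symmetric perturbations: zero bias, positive rmse
  pert <- rbind(truth + c(0.1, 0.5), truth - c(0.1, 0.5))
  rep1 <- recovery_report(truth, pert)
  expect_equal(rep1$bias, c(0, 0), tolerance = 1e-12)
  expect_equal(rep1$rmse, c(0.1, 0.5), tolerance = 1e-12)
  expect_equal(rep1$median_rel_err, c(0.1 / 0.8, 0.25), tolerance = 1e-12)
  expect_error(recovery_report(truth, ident[1, , drop = FALSE]), "at least 2")
  colnames(pert) <- c("a", "b")
  expect_error(recovery_report(truth, pert), "match")
})
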