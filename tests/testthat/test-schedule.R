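test_that("dose protocol labels parse and format round-trip", {
  pr <- dose_protocol("St14So7")
  expect_equal(pr$priming_days, 14)
  expect_equal(pr$recovery_days, 7)
  expect_equal(format(pr), "St14So7")
  expect_equal(format(dose_protocol("St21")), "St21")
  expect_equal(dose_protocol("St21")$recovery_days, 0)
  for (lab in c("St0So7", "St7So1", "St14So7", "St21"))
    expect_equal(format(dose_protocol(lab)), lab)
  expect_error(dose_protocol("So7"), "parse")
  expect_error(dose_protocol("St14So"), "parse")
})

test_that("dose schedules have the documented segment structure", {
  sch <- make_dose_schedule("St14So7")
  expect_equal(sch$segments$t_start, c(0, 14))
  expect_equal(sch$segments$t_end, c(14, 21))
  expect_equal(sch$segments$stiffness_kpa, c(15, 4))
  s21 <- make_dose_schedule("St21")
  expect_equal(nrow(s21$segments), 1)
  expect_equal(s21$segments$stiffness_kpa, 15)
  s07 <- make_dose_schedule("St0So7")
  expect_equal(nrow(s07$segments), 1)
  expect_equal(s07$segments$stiffness_kpa, 4)
})

test_that("segment validation rejects malformed schedules", {
  expect_error(pfl_schedule(data.frame(t_start = 0, t_end = 0,
                                       stiffness_kpa = 4)), "t_start < t_end")
  expect_error(pfl_schedule(data.frame(t_start = c(0, 5), t_end = c(4, 9),
                                       stiffness_kpa = c(4, 15))),
               "contiguous")
  expect_error(pfl_schedule(data.frame(t_start = 0, t_end = 5,
                                       stiffness_kpa = -1)), "stiffness")
  expect_error(pfl_schedule(data.frame(t_start = 0, t_end = 5,
                                       stiffness_kpa = 4, u_I = 2)),
               "occupanc")
})

test_that("feedback ramps while stiff, freezes when soft, saturates at F_max", {
  sch <- make_dose_schedule("St14So7")
  dr <- drive_at(sch, c(0, 7, 14, 17, 21))
  expect_equal(dr$F, c(0, 0.5, 1, 1, 1), tolerance = 1e-12)
  ## 7-day priming freezes F at 0.5 on the soft substrate
  sch7 <- make_dose_schedule("St7So7")
  dr7 <- drive_at(sch7, c(3.5, 7, 10, 14))
  expect_equal(dr7$F, c(0.25, 0.5, 0.5, 0.5), tolerance = 1e-12)
  ## never-primed protocol never ramps
  dr0 <- drive_at(make_dose_schedule("St0So7"), c(0, 3, 7))
  expect_equal(dr0$F, c(0, 0, 0))
  ## long priming saturates
  dr21 <- drive_at(make_dose_schedule("St21"), c(14, 17.5, 21))
  expect_equal(dr21$F, c(1, 1, 1))
})

test_that("drive evaluation reflects mapping, segments and inhibitors", {
  m <- stiffness_mapping(sigma = 5e-5, exponent = 2)
  segs <- data.frame(t_start = c(0, 10), t_end = c(10, 20),
                     stiffness_kpa = c(15, 4), u_I = c(0, 0.6),
                     u_P = c(0, 0.3))
  sch <- pfl_schedule(segs, mapping = m)
  dr <- drive_at(sch, c(5, 15))
  expect_equal(dr$S, 5e-5 * c(15, 4)^2)
  expect_equal(dr$u_I, c(0, 0.6))
  expect_equal(dr$u_P, c(0, 0.3))
  expect_error(drive_at(sch, 25), "span")
  ## any in-span time yields a valid drive
  set.seed(7)
  tt <- runif(50, 0, 20)
  d <- drive_at(sch, tt)
  expect_true(all(d$S >= 0 & d$F >= 0 & d$F <= 1 &
                  d$u_I >= 0 & d$u_I <= 1 & d$u_P >= 0 & d$u_P <= 1))
})

test_that("explicit feedback breakpoints are interpolated piecewise-linearly", {
  segs <- data.frame(t_start = 0, t_end = 20, stiffness_kpa = 10)
  sch <- pfl_schedule(segs, feedback = feedback_explicit(c(5, 15), c(0, 1)))
  dr <- drive_at(sch, c(0, 5, 10, 15, 20))
  expect_equal(dr$F, c(0, 0, 0.5, 1, 1), tolerance = 1e-12)
  expect_error(feedback_explicit(c(5, 5), c(0, 1)), "increasing")
  expect_error(feedback_explicit(c(0, 1), c(0, 2)), "\\[0, 1\\]")
})

test_that("constant_schedule reproduces a raw drive exactly", {
  sch <- constant_schedule(S = 3.2e-3, duration = 10, F = 0.4)
  dr <- drive_at(sch, 5)
  expect_equal(dr$S, 3.2e-3, tolerance = 1e-12)
  expect_equal(dr$F, 0.4)
})
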