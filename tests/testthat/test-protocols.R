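test_that("memory protocols reproduce the dose-dependent reversibility split", {
  p <- pfl_params()
  out7 <- reversibility_assay(p, make_dose_schedule("St7So7"))
  expect_equal(out7$label, "reversible")
  expect_lt(out7$final_Ca, 0.5)
  out14 <- reversibility_assay(p, make_dose_schedule("St14So7"))
  expect_equal(out14$label, "irreversible")
  expect_gt(out14$final_Ca, 0.5)
  expect_gte(out14$min_Ca, 0.5)
  out0 <- reversibility_assay(p, make_dose_schedule("St0So7"))
  expect_equal(out0$label, "reversible")
  expect_lt(out0$final_Ca, 0.05)
})

test_that("irreversibility is monotone in priming duration", {
  p <- pfl_params()
  finals <- vapply(c(0, 7, 14, 21), function(d1) {
    sch <- make_dose_schedule(dose_protocol(priming_days = d1,
                                            recovery_days = 7))
    reversibility_assay(p, sch)$final_Ca
  }, 0)
  expect_true(all(diff(finals) > 0))
})

test_that("treatment scenarios reproduce the combined-intervention ordering", {
  p <- pfl_params()
  sc <- run_treatment_scenarios(p, "St14")
  fin <- vapply(sc, function(o) o$final_Ca, 0)
  ## combined softening + inhibition matches the no-memory reference
  expect_lt(abs(fin[["line3_soften_plus_inhibitors"]] -
                fin[["line1_no_memory"]]), 0.05)
  ## single interventions are strictly worse than the combination ...
  expect_lt(max(fin[["line1_no_memory"]],
                fin[["line3_soften_plus_inhibitors"]]),
            min(fin[["line2_soften_only"]], fin[["line4_inhibitors_only"]]))
  ## ... and strictly better than no intervention
  expect_lt(max(fin[["line2_soften_only"]], fin[["line4_inhibitors_only"]]),
            fin[["untreated"]])
  expect_equal(sc$line1_no_memory$label, "reversible")
  expect_equal(sc$untreated$label, "irreversible")
})

test_that("the no-memory reference relaxes to the no-feedback fixed point", {
  p <- pfl_params()
  sc <- run_treatment_scenarios(p, "St14", scenarios = "line1",
                                horizon = 14 + 120)
  soft_S <- stiffness_to_drive(4, stiffness_mapping())
  expect_equal(sc$line1_no_memory$final_Ca,
               unname(closed_form_fixed_point(p, soft_S)["C_a"]),
               tolerance = 1e-3)
})

test_that("unknown scenarios and bad plans are rejected", {
  expect_error(treatment_plan("line9"), "unknown scenario")
  expect_error(treatment_plan("line3", u_I = 1.4), "occupanc")
  expect_error(treatment_plan("line3", T2 = -1), "T2")
})

test_that("inhibitor phase diagram has the three-region structure", {
  p <- pfl_params()
  pd <- inhibitor_phase_diagram(p, u_I = seq(0, 1, 0.1), u_P = seq(0, 1, 0.1))
  ## region I (irreversible) at the origin, region III (reversible) at (1,1)
  expect_equal(pd$labels[1, 1], "irreversible")
  expect_equal(pd$labels[11, 11], "reversible")
  ## region II: partial reversal where one inhibitor dominates
  ii <- which(pd$labels == "partially_reversible", arr.ind = TRUE)
  expect_gt(nrow(ii), 0)
  expect_true(any(pmin(pd$x_values[ii[, 1]], pd$y_values[ii[, 2]]) <= 0.1))
  ## outcome severity is non-increasing in each occupancy (final C_a cellwise)
  expect_true(all(apply(pd$final_Ca, 2, diff) < 1e-6))
  expect_true(all(apply(pd$final_Ca, 1, diff) < 1e-6))
  expect_error(inhibitor_phase_diagram(p, u_I = c(0, 1), u_P = c(0, 1)),
               "at least 5")
})

test_that("phase-diagram cells equal independent reversibility assays", {
  p <- pfl_params()
  us <- seq(0, 1, 0.25)
  pd <- inhibitor_phase_diagram(p, u_I = us, u_P = us)
  for (cell in list(c(1, 1), c(3, 2), c(5, 5))) {
    plan <- treatment_plan("line3_soften_plus_inhibitors",
                           u_I = us[cell[1]], u_P = us[cell[2]],
                           T1 = 56, T2 = 28)
    sch <- build_treatment_schedule(plan, dose_protocol("St14"), 112)
    out <- reversibility_assay(p, sch, assess_from = 56)
    expect_equal(pd$labels[cell[1], cell[2]], out$label)
    expect_equal(pd$final_Ca[cell[1], cell[2]], out$final_Ca)
  }
})

test_that("timing diagram shows reactivation after early brief treatment", {
  p <- pfl_params()
  td <- timing_phase_diagram(p, T1 = seq(0, 20, 2), T2 = seq(0, 40, 4))
  ## untreated column is locked in
  expect_true(all(td$labels[, 1] == "irreversible"))
  ## early, brief treatment suppresses then loses the state
  react <- which(td$labels == "reactivated", arr.ind = TRUE)
  expect_gt(nrow(react), 0)
  expect_true(all(td$y_values[react[, 2]] <= 8))
  ## early, sustained treatment reverses
  expect_equal(td$labels[1, 11], "reversible")
  ## outcome severity non-increasing in treatment duration
  expect_true(all(apply(td$final_Ca[, -1], 1, diff) < 1e-6))
  expect_error(timing_phase_diagram(p, u = 0), "u")
})
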