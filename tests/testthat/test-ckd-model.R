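# CKD stage-ladder model: parameters, cumulative bias, the
# monitored/unmonitored treatment split, structure and base-run behaviour.

test_that("base-run defaults carry the published values", {
  p <- ckd_parameters()
  expect_equal(p$population_init, 6910840)
  expect_equal(p$diabetes_rate, 0.80)
  expect_equal(p$hypertension_rate, 0.80)
  expect_equal(p$provider_bias_stage1, 0.8)
  expect_equal(p$provider_bias_stage2, 0.08)
  expect_equal(p$provider_bias_stage3, 0.16)
  expect_equal(p$provider_bias_stage4, 0.073)
  expect_equal(p$provider_bias_stage5, 0.152)
  expect_equal(p$provider_bias_esrd, 0.33)
  expect_identical(unclass(default_parameters()), unclass(p))
  expect_error(ckd_parameters(not_a_field = 1), "unknown parameter")
  expect_error(ckd_parameters(diabetes_rate = -1), ">= 0")
  expect_error(ckd_parameters(screening_coverage = 1.5), "\\[0, 1\\]")
})

test_that("total bias is the additive sum of the four components", {
  p <- ckd_parameters(patient_bias_stage2 = 0.2, provider_bias_stage2 = 0.2,
                      nephrologist_bias_stage2 = 0.2, system_bias_stage2 = 0.2)
  expect_equal(total_bias("stage2", p), 0.8)
  expect_equal(total_bias(2, p), 0.8)

  zero <- ckd_parameters(patient_bias_stage4 = 0, provider_bias_stage4 = 0,
                         nephrologist_bias_stage4 = 0, system_bias_stage4 = 0)
  expect_equal(total_bias("stage4", zero), 0)

  base <- ckd_parameters()
  raised <- ckd_parameters(provider_bias_stage1 =
                             base$provider_bias_stage1 + 0.5)
  expect_equal(total_bias("stage1", raised), total_bias("stage1", base) + 0.5)
  expect_error(total_bias("stage9", base), "unknown stage")
})

test_that("unmonitored fraction is a clamped, monotone function of bias", {
  p <- ckd_parameters(bias_gain = 0.5, screening_coverage = 0)
  expect_equal(unmonitored_fraction(0, p), 0)
  expect_equal(unmonitored_fraction(3, p), 1)     # clamped at 1
  expect_equal(unmonitored_fraction(0.8, p), 0.4)
  grid <- unmonitored_fraction(seq(0, 5, by = 0.1), ckd_parameters())
  expect_true(all(diff(grid) >= 0))
  # screening coverage shrinks the unmonitored share
  expect_lt(unmonitored_fraction(1, ckd_parameters(screening_coverage = 0.9)),
            unmonitored_fraction(1, ckd_parameters(screening_coverage = 0)))
})

test_that("the built model has the stage-ladder structure", {
  m <- build_ckd_model(ckd_parameters())
  expect_equal(nrow(validate_sd_model(m)), 0L)
  sn <- vapply(m$stocks, `[[`, "", "name")
  expect_setequal(sn, c(ckdflow:::ckd_state_stocks(),
                        ckdflow:::ckd_counter_stocks()))
  expect_length(sn, 16L)
  fn <- vapply(m$flows, `[[`, "", "name")
  expect_true("incidence" %in% fn)
  expect_length(grep("^progression_", fn), 5L)
  expect_setequal(fn[vapply(m$flows, `[[`, "", "source") == "ESRD"],
                  c("to_dialysis", "to_transplant", "esrd_deaths"))
  # percentage-rate parameters are rounded to 2 decimals at build; bias is not
  m2 <- build_ckd_model(ckd_parameters(diabetes_rate = 0.806,
                                       provider_bias_stage4 = 0.073))
  expect_equal(m2$parameters[["diabetes_rate"]], 0.81)
  expect_equal(m2$parameters[["provider_bias_stage4"]], 0.073)
})

test_that("monitored_slowdown = 1 makes progression independent of bias", {
  cfg <- fast_config()
  lo <- simulate(build_ckd_model(ckd_parameters(monitored_slowdown = 1)),
                 config = cfg)
  hi <- simulate(build_ckd_model(ckd_parameters(monitored_slowdown = 1,
                                                provider_bias_stage1 = 2)),
                 config = cfg)
  expect_equal(lo$stocks[, "ProgressionTo2"], hi$stocks[, "ProgressionTo2"])
})

test_that("zero bias with no monitored progression freezes the ladder at stage 1", {
  p <- as.list(ckd_parameters())
  for (f in grep("_bias_", names(p), value = TRUE)) p[[f]] <- 0
  p$monitored_slowdown <- 0
  traj <- simulate(build_ckd_model(ckd_parameters(p)), config = fast_config())
  prog <- traj$flows[, grep("^progression_", colnames(traj$flows))]
  expect_true(all(prog == 0))
  expect_gt(endpoint(traj, "Stage1", 2022), 0)
  expect_equal(endpoint(traj, "Stage2", 2022), 0)
})

test_that("the base run conserves population and keeps counters ordered", {
  traj <- simulate(build_ckd_model(ckd_parameters()),
                   config = sim_config(2010, 2022, 0.0625))
  state <- traj$stocks[, ckdflow:::ckd_state_stocks()]
  expect_lt(max(abs(rowSums(state) - 6910840)) / 6910840, 1e-9)

  for (ctr in ckdflow:::ckd_counter_stocks()) {
    expect_true(all(diff(traj$stocks[, ctr]) >= 0), info = ctr)
    expect_equal(unname(traj$stocks[1, ctr]), 0, info = ctr)
  }
  # downstream cumulative progression never exceeds upstream
  ord <- c("ProgressionTo2", "ProgressionTo3", "ProgressionTo4",
           "ProgressionTo5", "ProgressionToESRD")
  for (k in seq_len(length(ord) - 1L)) {
    expect_true(all(traj$stocks[, ord[k + 1L]] <= traj$stocks[, ord[k]] + 1e-9),
                info = ord[k + 1L])
  }
  expect_gt(endpoint(traj, "DeathIncidence", 2022), 0)
})

test_that("endpoint reads grid values and rejects off-grid queries", {
  traj <- simulate(decay_model(1000, 10), config = sim_config(0, 12, 1))
  expect_equal(endpoint(traj, "S", 0), 1000)
  expect_equal(endpoint(traj, "S", 1), 900)
  expect_error(endpoint(traj, "S", 3.5), "not on the simulation grid")
  expect_error(endpoint(traj, "nope", 3), "unknown series")

  flat <- simulate(decay_model(500, 0), config = sim_config(0, 5, 1))
  for (yr in 0:5) expect_equal(endpoint(flat, "S", yr), 500)
})

test_that("raising one bias component weakly raises downstream progression", {
  cfg <- fast_config()
  base <- simulate(build_ckd_model(ckd_parameters()), config = cfg)
  cases <- list(c("patient_bias_stage1", "ProgressionTo2"),
                c("system_bias_stage3", "ProgressionTo4"),
                c("nephrologist_bias_esrd", "DeathIncidence"))
  for (cs in cases) {
    p <- as.list(ckd_parameters())
    p[[cs[1]]] <- p[[cs[1]]] + 1
    up <- simulate(build_ckd_model(ckd_parameters(p)), config = cfg)
    expect_true(all(up$stocks[, cs[2]] >= base$stocks[, cs[2]] - 1e-9),
                info = cs[1])
    expect_gt(endpoint(up, cs[2], 2022), endpoint(base, cs[2], 2022))
  }
})

test_that("the worked-example ESRD counts sum to the reported burden", {
  cts <- tennessee_esrd_counts()
  expect_identical(cts[["dialysis"]] + cts[["transplant"]], cts[["total"]])
})
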