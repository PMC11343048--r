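test_that("engine_config validates its fields", {
  expect_s3_class(engine_config(), "awc_engine_config")
  expect_error(engine_config(step1_result_gate = 130),
               "below cpr_phase_max")
  expect_error(engine_config(step1_first_start = 110),
               "no Step1 window fits")
  expect_error(engine_config(step1_duration = -1), "step1_duration")
})

test_that("scenario 2: non-shockable phase runs 4 Step1 analyses then Standard", {
  truth <- data.frame(start = 0, end = 1000, label = "ONR",
                      stringsAsFactors = FALSE)
  ph <- run_cpr_phase(0, oracle_classifier(), list(truth = truth),
                      engine_config(), phase_id = 1L)
  s1 <- ph$analyses[ph$analyses$stage == "STEP1", ]
  expect_identical(nrow(s1), 4L)
  expect_equal(s1$t_start, c(48, 66.5, 85, 103.5))
  expect_equal(s1$t_end, c(64, 82.5, 101, 119.5))
  expect_true(all(s1$decision == "NO_SHOCK"))
  expect_true(all(s1$gated))
  std <- ph$analyses[ph$analyses$stage == "STANDARD", ]
  expect_equal(std$t_start, 121)
  expect_equal(std$t_end, 126)
  expect_identical(ph$outcome, "RESUME_AFTER_STANDARD")
  expect_equal(ph$phase_end, 131)  # compressions resume 5 s after decision
  # event log: exactly 4 ANALYSIS_END events with stage STEP1
  expect_identical(
    sum(ph$events$type == "ANALYSIS_END" & ph$events$stage == "STEP1"), 4L)
})

test_that("scenario 1: refibrillation at 30 s leads to an early shock at 75 s", {
  truth <- data.frame(start = c(0, 30), end = c(30, 1000),
                      label = c("ONR", "VF"), stringsAsFactors = FALSE)
  ph <- run_cpr_phase(0, oracle_classifier(), list(truth = truth),
                      engine_config(), phase_id = 1L)
  expect_identical(ph$outcome, "EARLY_SHOCK")
  s1 <- ph$analyses[ph$analyses$stage == "STEP1", ]
  expect_identical(nrow(s1), 1L)
  expect_equal(c(s1$t_start, s1$t_end), c(48, 64))
  expect_identical(s1$decision, "SHOCK")
  s2 <- ph$analyses[ph$analyses$stage == "STEP2", ]
  expect_equal(c(s2$t_start, s2$t_end), c(69, 74))
  expect_identical(s2$decision, "SHOCK")
  expect_equal(ph$shock_time, 75)
  expect_equal(ph$phase_end, 75)
  # hands-off accounting: CC stop at 64 until the shock at 75
  expect_identical(ph$handsoff$cause, "COA_SHOCK")
  expect_equal(ph$handsoff$end - ph$handsoff$start, 11)
})

test_that("no Step1 result is acted on before the 1-minute gate", {
  truth <- data.frame(start = 0, end = 1000, label = "VF",
                      stringsAsFactors = FALSE)
  # force windows that end before the gate by starting Step1 early
  cfg <- engine_config(step1_first_start = 10)
  ph <- run_cpr_phase(0, oracle_classifier(), list(truth = truth), cfg)
  s1 <- ph$analyses[ph$analyses$stage == "STEP1", ]
  pre_gate <- s1[s1$t_end < 60, ]
  expect_gt(nrow(pre_gate), 0L)
  expect_true(all(!pre_gate$gated))
  expect_true(all(!pre_gate$acted))          # SHOCK results discarded
  first_acted <- s1[s1$acted, ][1, ]
  expect_gte(first_acted$t_end, 60)
})

test_that("ill-advised confirmation pauses cost the deterministic 10 s", {
  # Step1 wrongly advises shock on ASYS, Step2 rejects
  er <- data.frame(stage = "STEP1", label = "ASYS", error = 1,
                   stringsAsFactors = FALSE)
  truth <- data.frame(start = 0, end = 1000, label = "ASYS",
                      stringsAsFactors = FALSE)
  ph <- awcsim:::with_seed(1,
    run_cpr_phase(0, noisy_oracle_classifier(er), list(truth = truth),
                  engine_config()))
  rej <- ph$handsoff[ph$handsoff$cause == "COA_REJECT", ]
  expect_gt(nrow(rej), 0L)
  expect_true(all(rej$end - rej$start == 10))
  s2 <- ph$analyses[ph$analyses$stage == "STEP2", ]
  expect_true(all(s2$decision == "NO_SHOCK"))
})

test_that("run_intervention alternates phases and honours ROSC and the limit", {
  truth <- data.frame(start = c(0, 76), end = c(76, 1000),
                      label = c("VF", "ONR"), stringsAsFactors = FALSE)
  res <- run_intervention(truth, oracle_classifier(),
                          observation_limit = 400)
  # enrollment Standard at [0,5] shocks the initial VF
  enr <- res$analyses[1, ]
  expect_identical(enr$stage, "STANDARD")
  expect_equal(c(enr$t_start, enr$t_end), c(0, 5))
  expect_identical(enr$decision, "SHOCK")
  expect_equal(res$shocks[1], 6)
  expect_true(all(diff(res$events$t_s) >= 0))
  expect_true(max(res$events$t_s) <= 400 + 1e-9)

  res2 <- run_intervention(truth, oracle_classifier(),
                           observation_limit = 400, rosc_time = 150)
  expect_true("ROSC" %in% res2$events$type)
  expect_true(all(res2$analyses$t_end <= 150))
})

test_that("handsoff_summary reports per-cause medians and IQRs", {
  ho <- data.frame(start = c(0, 10, 50), end = c(10, 22, 61),
                   cause = c("COA_REJECT", "COA_REJECT", "STANDARD_RESUME"),
                   stringsAsFactors = FALSE)
  s <- handsoff_summary(ho)
  expect_identical(s$n[s$cause == "COA_REJECT"], 2L)
  expect_equal(s$median_s[s$cause == "COA_REJECT"], 11)
  expect_equal(s$median_s[s$cause == "STANDARD_RESUME"], 11)
  empty <- handsoff_summary(NULL)
  expect_identical(nrow(empty), 0L)
})
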