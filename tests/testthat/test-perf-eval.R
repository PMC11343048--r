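test_that("clustered proportion reproduces the hand-computed oracle", {
  est <- clustered_proportion(c(3, 1), c(4, 2))
  expect_equal(est$p_hat, 2 / 3, tolerance = 1e-12)
  # K=2: Var = 2 * ((3 - 8/3)^2 + (1 - 4/3)^2) / 36; LCL90 = p - 1.281552*se
  v <- 2 * ((3 - 8 / 3)^2 + (1 - 4 / 3)^2) / 36
  expect_equal(est$se_hat, sqrt(v), tolerance = 1e-12)
  expect_equal(est$lcl90, 2 / 3 - stats::qnorm(0.9) * sqrt(v),
               tolerance = 1e-9)
  expect_equal(round(est$lcl90, 6), 0.524272)
  expect_identical(est$n_clusters, 2L)
  expect_false(est$single_cluster)
})

test_that("clustered proportion properties: LCL90 <= p_hat, clamping, single cluster", {
  set.seed(42)
  for (i in 1:20) {
    K <- sample(2:20, 1)
    m <- sample(1:8, K, replace = TRUE)
    x <- vapply(m, function(mi) rbinom(1, mi, 0.8), integer(1))
    est <- clustered_proportion(x, m)
    expect_lte(est$lcl90, est$p_hat)
    expect_gte(est$lcl90, 0)
    expect_lte(est$lcl90, 1)
  }
  one <- clustered_proportion(3, 4)
  expect_true(one$single_cluster)
  expect_true(is.na(one$lcl90))
  expect_equal(one$p_hat, 0.75)
  expect_error(clustered_proportion(c(2, 5), c(4, 4)))  # x > m
  expect_error(clustered_proportion(numeric(0), numeric(0)), "no clusters")
})

test_that("with unit clusters the estimator converges to the binomial limit", {
  # all m_i = 1: Var -> p(1-p)/n * n/(n-1); compare against the binomial SE
  set.seed(7)
  n <- 5000
  x <- rbinom(n, 1, 0.9)
  est <- clustered_proportion(x, rep(1, n))
  p <- mean(x)
  se_binom <- sqrt(p * (1 - p) / n)
  expect_equal(est$se_hat, se_binom * sqrt(n / (n - 1)), tolerance = 1e-12)
  expect_equal(est$lcl90, p - stats::qnorm(0.9) * est$se_hat,
               tolerance = 1e-9)
})

test_that("sequential combination implements the confirmation contract", {
  s1 <- data.frame(analyses = 409, shock_advised = 380, no_shock_advised = 29)
  s2 <- data.frame(analyses = 380, shock_advised = 374, no_shock_advised = 6)
  seq_ <- sequential_combination(s1, s2)
  expect_identical(seq_$analyses, 409)
  expect_identical(seq_$shock_advised, 374)
  expect_identical(seq_$no_shock_advised, 35)
  expect_error(sequential_combination(s1, data.frame(
    analyses = 379, shock_advised = 374, no_shock_advised = 5)),
    "must equal Step1 shock-advised")
})

test_that("pool_counts sums rows element-wise", {
  rows <- data.frame(analyses = c(283, 409), shock_advised = c(283, 374),
                     no_shock_advised = c(0, 35))
  p <- pool_counts(rows)
  expect_identical(p$analyses, 692)
  expect_identical(p$shock_advised, 657)
  expect_identical(p$no_shock_advised, 35)
})

test_that("stage_counts separates primary and intermediate rhythms and honours gating", {
  rec <- data.frame(
    patient_id = c("A", "A", "B", "B", "B"),
    stage = c("STEP1", "STEP1", "STEP1", "STEP2", "STEP1"),
    decision = c("SHOCK", "NO_SHOCK", "SHOCK", "SHOCK", "SHOCK"),
    truth_label = c("VF", "VF", "FINE_VF", "VF", "VF"),
    gated = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  sc <- stage_counts(rec)
  vf <- sc$primary[sc$primary$stage == "STEP1" & sc$primary$rhythm == "VF", ]
  expect_identical(vf$analyses, 2L)  # ungated Step1 row dropped
  expect_identical(vf$patients, 1L)
  expect_identical(sc$intermediate$rhythm, "FINE_VF")
  sc_all <- stage_counts(rec, gated_only = FALSE)
  vf_all <- sc_all$primary[sc_all$primary$stage == "STEP1" &
                             sc_all$primary$rhythm == "VF", ]
  expect_identical(vf_all$analyses, 3L)
})

test_that("confirmation metrics count ill-advised pauses per patient", {
  rec <- data.frame(
    patient_id = c("A", "A", "A", "B"),
    stage = c("STEP1", "STEP1", "STANDARD", "STEP1"),
    decision = c("SHOCK", "SHOCK", "SHOCK", "NO_SHOCK"),
    truth_label = c("VF", "ASYS", "VF", "ONR"),
    gated = TRUE, stringsAsFactors = FALSE)
  cm <- confirmation_metrics(rec)
  expect_identical(cm$n_step1, 3L)
  expect_identical(cm$n_coa, 2L)
  expect_equal(cm$coa_rate, 2 / 3)
  expect_identical(cm$ill_advised_count, 1L)
  expect_equal(cm$ill_advised_rate, 1 / 3)
  expect_identical(as.integer(cm$per_patient_histogram[c("0", "1")]),
                   c(1L, 1L))
  expect_identical(names(cm$rhythm_mix), "ASYS")
})

test_that("goal checks are strict and aha_goals carries the published values", {
  g <- aha_goals()
  expect_equal(unname(g[c("VF", "NSR", "ONR", "ASYS")]),
               c(0.90, 0.99, 0.95, 0.95))
  expect_false(goal_check(0.90, 0.90))  # strictly greater required
  expect_true(goal_check(0.901, 0.90))
  est <- clustered_proportion(c(9, 9), c(10, 10), goal = 0.9)
  expect_false(est$goal_met)
})

test_that("fixture arithmetic reproduces every printed study table", {
  rep_ <- study_report()
  expect_true(rep_$consistent_with_printed)

  gp <- rep_$global_pool
  expect_identical(gp$shock_advised[gp$rhythm == "VF"], 657)
  expect_identical(gp$analyses[gp$rhythm == "VF"], 692)
  expect_equal(gp$performance_pct[gp$rhythm == "VF"], 100 * 657 / 692)
  expect_equal(round(gp$performance_pct, 1),
               c(94.9, 100, 99.3, 99.7)[match(gp$rhythm,
                                              c("VF", "NSR", "ONR", "ASYS"))])
  cp <- rep_$clean_pool
  expect_equal(round(cp$performance_pct[cp$rhythm == "VF"], 1), 99.1)
  expect_equal(round(cp$performance_pct[cp$rhythm == "ONR"], 1), 96.0)
  expect_equal(round(cp$performance_pct[cp$rhythm == "ASYS"], 1), 98.7)

  rates <- rep_$rates
  val <- function(m) rates$value[rates$metric == m]
  expect_equal(round(val("confirmation_rate_pct"), 1), 27.7)
  expect_equal(val("confirmation_rate_pct"), 100 * 557 / 2011)
  expect_equal(round(val("ill_advised_rate_pct"), 1), 5.9)
  expect_equal(round(val("sequence_accuracy_pct"), 1), 98.0)
  expect_equal(val("sequence_accuracy_pct"), 100 * 1836 / 1874)
  expect_identical(val("ill_advised_total_from_histogram"), 118)
  expect_identical(val("patients_any_ill_advised"), 76)
  expect_true(all(rep_$goal_checks$goal_met))

  # the comparison table's printed ratios agree with the count fixtures
  t2 <- study_table2()
  seq_acc <- t2[t2$metric == "sequence_accuracy_pct", ]
  expect_equal(seq_acc$awc_num / seq_acc$awc_den, 1836 / 1874)
})

test_that("table1b error rates match the published confusion counts", {
  er <- table1b_error_rates()
  g <- function(stage, label) er$error[er$stage == stage & er$label == label]
  expect_equal(g("STEP1", "VF"), 29 / 409)
  expect_equal(g("STEP1", "ONR"), 45 / 930)
  expect_equal(g("STEP1", "ASYS"), 72 / 535)
  expect_equal(g("STEP2", "VF"), 6 / 380)
  expect_equal(g("STANDARD", "VF"), 0)
  expect_false(any(er$label == "NSR" & er$stage != "STANDARD"))
})

test_that("cohort_performance builds per-patient clusters correctly", {
  rec <- data.frame(
    patient_id = c("A", "A", "B", "B", "C"),
    phase_id = 1L,
    stage = "STEP1",
    decision = c("SHOCK", "NO_SHOCK", "SHOCK", "SHOCK", "SHOCK"),
    truth_label = "VF", gated = TRUE, stringsAsFactors = FALSE)
  cp <- cohort_performance(rec)
  expect_equal(cp$numerator, 4)
  expect_equal(cp$denominator, 5)
  expect_identical(cp$n_clusters, 3L)
  manual <- clustered_proportion(c(1, 2, 1), c(2, 2, 1), goal = 0.9)
  expect_equal(cp$p_hat, manual$p_hat)
  expect_equal(cp$lcl90, manual$lcl90)
})
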