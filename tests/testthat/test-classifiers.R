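test_that("classify_clean decides the textbook cases and checks window length", {
  vf <- gen_ecg_segment("VF", 5, amplitude = 400, seed = 1)
  expect_identical(classify_clean(vf$samples, vf$fs), "SHOCK")
  asys <- gen_ecg_segment("ASYS", 5, amplitude = 50, seed = 2)
  expect_identical(classify_clean(asys$samples, asys$fs), "NO_SHOCK")
  nsr <- gen_ecg_segment("NSR", 5, rate = 75, seed = 3)
  expect_identical(classify_clean(nsr$samples, nsr$fs), "NO_SHOCK")
  vt <- gen_ecg_segment("RAPID_VT", 5, rate = 180, seed = 4)
  expect_identical(classify_clean(vt$samples, vt$fs), "SHOCK")
  expect_error(classify_clean(vf$samples[1:1000], vf$fs), "expected")
  expect_error(classify_clean(numeric(0), 500), "empty")
})

test_that("suppress_cc flags missing periodicity and passes clean input through", {
  seg <- gen_ecg_segment("VF", 16, seed = 5)
  flat_imp <- rep(80, length(seg$samples))
  out <- suppress_cc(seg$samples, flat_imp, seg$fs)
  expect_false(out$periodic)
  expect_identical(out$cleaned, seg$samples)
  expect_error(suppress_cc(seg$samples, flat_imp[-1]), "lengths differ")
})

test_that("suppress_cc meets the residual and band-energy recovery targets", {
  band_energy <- function(x, fs) {
    bf <- signal::butter(2, c(3, 8) / (fs / 2), type = "pass")
    sum(as.numeric(signal::filtfilt(bf, x))^2)
  }
  resid <- numeric(30); recov <- numeric(30)
  for (s in 1:30) {
    cc <- gen_cc_channelpair(16, seed = 1000 + s)
    asys <- gen_ecg_segment("ASYS", 16, amplitude = 50, seed = 2000 + s)
    sup <- suppress_cc(mix_cc(asys, cc$artifact), cc$impedance, asys$fs)
    expect_true(sup$periodic)
    q <- stats::quantile(sup$cleaned, c(0.002, 0.998), names = FALSE)
    resid[s] <- q[2] - q[1]
    vf <- gen_ecg_segment("VF", 16, amplitude = 500, seed = 3000 + s)
    supv <- suppress_cc(mix_cc(vf, cc$artifact), cc$impedance, vf$fs)
    recov[s] <- band_energy(supv$cleaned, vf$fs) /
      band_energy(vf$samples, vf$fs)
  }
  expect_gte(mean(resid < 100), 0.8)   # ASYS residual p2p < 100 uV
  expect_true(all(recov >= 0.7))       # VF 3-8 Hz band energy recovered
})

test_that("classifiers are pure: identical windows give identical decisions", {
  cc <- gen_cc_channelpair(16, seed = 6)
  vf <- gen_ecg_segment("VF", 16, seed = 7)
  mixed <- mix_cc(vf, cc$artifact)
  d1 <- classify_cc(mixed, cc$impedance, vf$fs)
  d2 <- classify_cc(mixed, cc$impedance, vf$fs)
  expect_identical(d1, d2)
  expect_identical(d1, "SHOCK")
})

test_that("increasing artifact amplitude never improves ASYS specificity", {
  amps <- c(500, 1000, 2000, 4000)
  spec <- vapply(amps, function(a) {
    model <- cc_artifact_model(amplitude = a)
    ok <- vapply(1:25, function(s) {
      cc <- gen_cc_channelpair(16, model, seed = 400 + s)
      asys <- gen_ecg_segment("ASYS", 16, seed = 500 + s)
      classify_cc(mix_cc(asys, cc$artifact), cc$impedance,
                  asys$fs) == "NO_SHOCK"
    }, logical(1))
    mean(ok)
  }, numeric(1))
  # common random numbers across the grid; allow one-step sampling noise
  expect_true(all(diff(spec) <= 0.04 + 1e-9))
})

test_that("oracle classifier reproduces the truth exactly", {
  truth <- data.frame(start = c(0, 100), end = c(100, 200),
                      label = c("VF", "ONR"), stringsAsFactors = FALSE)
  ctx <- list(truth = truth)
  clf <- oracle_classifier()
  dec <- awcsim:::classifier_decide(clf, 10, 26, "STEP1", TRUE, ctx)
  expect_identical(dec, "SHOCK")
  dec <- awcsim:::classifier_decide(clf, 120, 136, "STEP1", TRUE, ctx)
  expect_identical(dec, "NO_SHOCK")
  # transition window decided from the rhythm at the window end
  dec <- awcsim:::classifier_decide(clf, 95, 111, "STEP1", TRUE, ctx)
  expect_identical(dec, "NO_SHOCK")
  expect_identical(awcsim:::truth_label_at(truth, 95, 111), "TRANSITION")
})

test_that("noisy oracle matches the requested error rates within binomial error", {
  er <- data.frame(stage = c("STEP1", "STEP1"), label = c("VF", "ASYS"),
                   error = c(0.10, 0.25), stringsAsFactors = FALSE)
  clf <- noisy_oracle_classifier(er)
  n <- 10000
  flips <- awcsim:::with_seed(123, {
    vf_ctx <- list(truth = data.frame(start = 0, end = 1000, label = "VF"))
    as_ctx <- list(truth = data.frame(start = 0, end = 1000, label = "ASYS"))
    c(mean(vapply(seq_len(n), function(i)
        awcsim:::classifier_decide(clf, 0, 16, "STEP1", TRUE,
                                   vf_ctx) == "NO_SHOCK", logical(1))),
      mean(vapply(seq_len(n), function(i)
        awcsim:::classifier_decide(clf, 0, 16, "STEP1", TRUE,
                                   as_ctx) == "SHOCK", logical(1))))
  })
  # 4 sigma binomial tolerance
  expect_lt(abs(flips[1] - 0.10), 4 * sqrt(0.1 * 0.9 / n))
  expect_lt(abs(flips[2] - 0.25), 4 * sqrt(0.25 * 0.75 / n))
  # stages without a configured rate are error-free
  d <- awcsim:::classifier_decide(clf, 0, 5, "STANDARD", FALSE,
                                  list(truth = data.frame(
                                    start = 0, end = 10, label = "VF")))
  expect_identical(d, "SHOCK")
  expect_error(noisy_oracle_classifier(
    data.frame(stage = "STEP1", label = "VF", error = 1.5)),
    "probabilities")
})
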