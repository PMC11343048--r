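test_that("generators are deterministic in (params, seed) and leave the RNG alone", {
  a <- gen_ecg_segment("VF", 8, amplitude = 400, seed = 42)
  b <- gen_ecg_segment("VF", 8, amplitude = 400, seed = 42)
  expect_identical(a$samples, b$samples)
  d <- gen_ecg_segment("VF", 8, amplitude = 400, seed = 43)
  expect_false(identical(a$samples, d$samples))

  set.seed(99); before <- runif(3)
  set.seed(99); invisible(gen_ecg_segment("ONR", 5, seed = 1))
  invisible(gen_cc_channelpair(10, seed = 1))
  after <- runif(3)
  expect_identical(before, after)  # with_seed restores the RNG state

  c1 <- gen_cc_channelpair(20, seed = 7)
  c2 <- gen_cc_channelpair(20, seed = 7)
  expect_identical(c1$artifact, c2$artifact)
  expect_identical(c1$impedance, c2$impedance)
})

test_that("segments hit the requested peak-to-peak amplitude exactly", {
  for (spec in list(c("VF", 450), c("FINE_VF", 130), c("ONR", 900),
                    c("ASYS", 55))) {
    seg <- gen_ecg_segment(spec[1], 6, amplitude = as.numeric(spec[2]),
                           seed = 8)
    expect_equal(max(seg$samples) - min(seg$samples), as.numeric(spec[2]),
                 tolerance = 1e-9)
    expect_length(seg$samples, 6 * seg$fs)
    expect_identical(seg$fs, 500)
  }
})

test_that("incompatible label/parameter combinations error", {
  expect_error(gen_ecg_segment("ASYS", 5, amplitude = 300), "incompatible")
  expect_error(gen_ecg_segment("VF", 5, amplitude = 150), "incompatible")
  expect_error(gen_ecg_segment("RAPID_VT", 5, rate = 100), "incompatible")
  expect_error(gen_ecg_segment("SLOW_VT", 5, rate = 170), "incompatible")
  expect_error(gen_ecg_segment("TRANSITION", 5), "no generator")
})

test_that("compression schedule has 30:2 pauses and matches an independent computation", {
  model <- cc_artifact_model()
  cc <- gen_cc_channelpair(60, model, seed = 7)
  # independent schedule: blocks of 30 at dt=60/110 separated by dt+4 s
  dt <- 60 / 110
  sched <- numeric(0); t <- 0
  while (t < 60) {
    blk <- t + dt * 0:29
    sched <- c(sched, blk[blk < 60])
    t <- blk[30] + dt + 4
  }
  expect_identical(cc$compression_times, sched)
  gaps <- diff(cc$compression_times)
  expect_true(any(gaps > 3))           # ventilation pauses present
  # mean rate over compression blocks within +/-2 of the metronome
  block_rate <- 60 / median(gaps)
  expect_lt(abs(block_rate - 110), 2)
  # sub-cycle duration: at most one compression, no pause
  cc05 <- gen_cc_channelpair(0.5, model, seed = 1)
  expect_lte(length(cc05$compression_times), 1L)
})

test_that("impedance excursions align with compression times", {
  cc <- gen_cc_channelpair(30, seed = 3)
  base <- cc_artifact_model()$impedance_baseline
  thr <- base + 0.3
  above <- cc$impedance > thr
  runs <- rle(above)
  n_exc <- sum(runs$values)
  expect_identical(n_exc, length(cc$compression_times))
  # each excursion onset within one pulse width of a compression time
  onsets <- (which(diff(c(FALSE, above)) == 1) - 1) / cc$fs
  expect_true(all(abs(onsets - cc$compression_times) < 0.31))
})

test_that("artifact dominant frequency matches the compression rate within 0.1 Hz", {
  model <- cc_artifact_model()
  cc <- gen_cc_channelpair(60, model, seed = 21)
  # analyse one uninterrupted compression block
  fs <- cc$fs
  blk <- cc$artifact[seq(1L, round(16 * fs))]
  blk <- blk - mean(blk)
  n <- length(blk)
  sp <- Mod(stats::fft(blk))^2
  freq <- (seq_len(n) - 1) * fs / n
  sel <- freq > 0.8 & freq < 5
  dom <- freq[sel][which.max(sp[sel])]
  expect_lt(abs(dom - model$rate / 60), 0.1)
})

test_that("mix_cc is additive, invertible and length-checked", {
  seg <- gen_ecg_segment("VF", 10, seed = 2)
  cc <- gen_cc_channelpair(10, seed = 3)
  z <- numeric(length(seg$samples))
  expect_identical(mix_cc(seg$samples, z), seg$samples)
  expect_identical(mix_cc(z, cc$artifact), cc$artifact)
  mixed <- mix_cc(seg, cc$artifact)
  # invertible given the artifact (up to floating-point rounding of the sum)
  expect_equal(mixed - cc$artifact, seg$samples, tolerance = 1e-12)
  expect_error(mix_cc(seg$samples[-1], cc$artifact), "lengths differ")
})

test_that("corpus builder emits a manifest consistent with its segments", {
  co <- gen_corpus(c("VF", "ASYS"), n_per_class = 4, duration = 6, seed = 5)
  expect_length(co$segments, 8L)
  expect_identical(nrow(co$manifest), 8L)
  expect_identical(co$manifest$label,
                   vapply(co$segments, `[[`, "", "true_label"))
  i <- 3L
  re <- gen_ecg_segment(co$manifest$label[i], co$manifest$duration[i],
                        rate = if (is.na(co$manifest$rate[i])) NULL else
                          co$manifest$rate[i],
                        amplitude = co$manifest$amplitude[i],
                        seed = co$manifest$seed[i])
  expect_identical(re$samples, co$segments[[i]]$samples)
})
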