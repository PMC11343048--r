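# Synthetic ECG, compression artifact and impedance generators ---------------
#
# Seeded generators producing the two-channel signal an AED records: ECG in
# µV at 500 Hz and transthoracic impedance in Ohm.  Waveform realism is
# deliberately limited to what threshold-based annotation and the reference
# classifiers require: VF is band-limited (3-8 Hz) filtered noise, organized
# rhythms are template-beat trains (narrow sinus-like vs wide-complex
# templates) with rate jitter, asystole is low-amplitude baseline noise, and
# compression artifact is a train of half-sinusoid deflections with
# per-compression amplitude jitter and slow baseline wander.

DEFAULT_FS <- 500
NOISE_RMS_UV <- 10  # noise floor added to every synthetic ECG

class_defaults <- function(label) {
  switch(label,
    VF       = list(rate = NA_real_, amplitude = 500,  sinus = FALSE),
    FINE_VF  = list(rate = NA_real_, amplitude = 150,  sinus = FALSE),
    RAPID_VT = list(rate = 180,      amplitude = 800,  sinus = FALSE),
    SLOW_VT  = list(rate = 120,      amplitude = 800,  sinus = FALSE),
    NSR      = list(rate = 75,       amplitude = 1000, sinus = TRUE),
    ONR      = list(rate = 80,       amplitude = 1000, sinus = FALSE),
    ASYS     = list(rate = NA_real_, amplitude = 50,   sinus = FALSE),
    stop("no generator for label ", label, call. = FALSE)
  )
}

# narrow (sinus-like) beat: gaussian R wave (sd 12 ms) plus a low, broad
# T wave; wide complex: one biphasic sine period spanning 280 ms.
beat_template <- function(fs, wide = FALSE) {
  if (wide) {
    width <- 0.28
    n <- round(width * fs)
    t <- seq_len(n) / fs
    sin(2 * pi * t / width)
  } else {
    n <- round(0.44 * fs)
    t <- (seq_len(n) - n / 4) / fs
    r <- exp(-0.5 * (t / 0.012)^2)
    tw <- 0.30 * exp(-0.5 * ((t - 0.22) / 0.045)^2)
    r + tw
  }
}

gen_beat_train <- function(duration, rate, fs, wide) {
  n <- round(duration * fs)
  x <- numeric(n)
  tpl <- beat_template(fs, wide = wide)
  t <- 0
  interval <- 60 / rate
  while (t < duration) {
    i0 <- round(t * fs) + 1L
    idx <- i0:min(n, i0 + length(tpl) - 1L)
    if (length(idx) > 0 && idx[1] <= n) {
      x[idx] <- x[idx] + tpl[seq_along(idx)]
    }
    t <- t + interval * (1 + stats::runif(1, -0.02, 0.02))  # rate jitter
  }
  x
}

gen_fib_wave <- function(duration, fs) {
  n <- round(duration * fs)
  pad <- round(2 * fs)
  w <- stats::rnorm(n + 2 * pad)
  bf <- signal::butter(2, c(3, 8) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, w)
  y[(pad + 1):(pad + n)]
}

gen_baseline_noise <- function(duration, fs) {
  n <- round(duration * fs)
  pad <- round(fs)
  w <- stats::rnorm(n + 2 * pad)
  bf <- signal::butter(2, 15 / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, w)
  y[(pad + 1):(pad + n)]
}

#' Generate a synthetic ECG segment of a requested rhythm class
#'
#' Returns a seeded, deterministic ECG segment whose default-criteria
#' annotation (\code{\link{annotate_window}}) recovers \code{label}.  The
#' segment is rescaled so its peak-to-peak amplitude equals \code{amplitude}
#' exactly, after adding a 10 µV RMS noise floor.
#'
#' @param label rhythm class to synthesise: one of VF, FINE_VF, RAPID_VT,
#'   SLOW_VT, NSR, ONR, ASYS.
#' @param duration segment length in seconds.
#' @param rate heart rate in min^-1 for organized rhythms (ignored for
#'   VF/FINE_VF/ASYS); class default when NULL.
#' @param amplitude peak-to-peak amplitude in µV; class default when NULL.
#' @param fs sampling rate in Hz (default 500).
#' @param seed integer seed; identical arguments give identical samples.
#' @return Object of class \code{awc_ecg}: list with \code{samples} (µV),
#'   \code{fs}, \code{true_label}, \code{sinus_flag} and \code{params}.
#' @export
#' @examples
#' seg <- gen_ecg_segment("VF", duration = 16, amplitude = 400, seed = 1)
#' annotate_window(seg$samples, seg$fs)
gen_ecg_segment <- function(label, duration, rate = NULL, amplitude = NULL,
                            fs = DEFAULT_FS, seed = 1L) {
  assert_label(label)
  check_scalar(duration, "duration")
  check_scalar(fs, "fs")
  d <- class_defaults(label)
  if (is.null(rate)) rate <- d$rate
  if (is.null(amplitude)) amplitude <- d$amplitude
  crit <- annotation_criteria()

  # reject parameter combinations inconsistent with the requested class
  bad <- switch(label,
    ASYS     = amplitude >= crit$asys_max_amp,
    VF       = amplitude <= crit$vf_min_amp,
    FINE_VF  = amplitude < crit$fine_vf_low || amplitude > crit$vf_min_amp,
    RAPID_VT = rate < crit$rapid_vt_min_rate,
    SLOW_VT  = rate >= crit$rapid_vt_min_rate || rate <= crit$onr_min_rate,
    rate <= crit$onr_min_rate
  )
  if (isTRUE(bad)) {
    stop(sprintf("amplitude/rate (%s, %s) incompatible with class %s",
                 format(amplitude), format(rate), label), call. = FALSE)
  }

  samples <- with_seed(seed, {
    base <- switch(label,
      VF = , FINE_VF = gen_fib_wave(duration, fs),
      ASYS = gen_baseline_noise(duration, fs),
      RAPID_VT = , SLOW_VT = gen_beat_train(duration, rate, fs, wide = TRUE),
      NSR = , ONR = gen_beat_train(duration, rate, fs, wide = FALSE)
    )
    bp <- max(base) - min(base)
    if (bp > 0) base <- base * (amplitude / bp)
    x <- base + stats::rnorm(length(base), sd = NOISE_RMS_UV)
    # exact requested peak-to-peak after the noise floor
    x <- (x - min(x)) * (amplitude / (max(x) - min(x))) - amplitude / 2
    x
  })

  structure(
    list(samples = samples, fs = fs, true_label = label,
         sinus_flag = identical(label, "NSR"),
         params = list(rate = rate, amplitude = amplitude, seed = seed,
                       duration = duration)),
    class = "awc_ecg"
  )
}

#' @export
print.awc_ecg <- function(x, ...) {
  cat(sprintf("<awc_ecg> %s, %.1f s @ %g Hz, p2p %.0f uV\n",
              x$true_label, length(x$samples) / x$fs, x$fs,
              max(x$samples) - min(x$samples)))
  invisible(x)
}

#' Chest-compression artifact model
#'
#' Parameters of the compression artifact/impedance generator: metronome
#' rate, artifact amplitude, the 30:2 compression-to-ventilation duty
#' pattern (compressions per cycle and ventilation-pause length), and the
#' impedance excursion per compression.
#'
#' @param rate compression rate in min^-1 (default 110, metronome guided).
#' @param amplitude artifact peak amplitude on the ECG channel in µV
#'   (default 2000).
#' @param comps_per_cycle compressions per 30:2 cycle (default 30).
#' @param vent_pause_s ventilation pause after each cycle in seconds
#'   (default 4, two insufflations).
#' @param impedance_excursion impedance deflection per compression in Ohm
#'   (default 1).
#' @param impedance_baseline resting transthoracic impedance in Ohm
#'   (default 80).
#' @return Object of class \code{awc_cc_model}.
#' @export
cc_artifact_model <- function(rate = 110, amplitude = 2000,
                              comps_per_cycle = 30, vent_pause_s = 4,
                              impedance_excursion = 1,
                              impedance_baseline = 80) {
  check_scalar(rate, "rate")
  check_scalar(amplitude, "amplitude", positive = FALSE)
  check_scalar(comps_per_cycle, "comps_per_cycle", integer = TRUE)
  check_scalar(vent_pause_s, "vent_pause_s", positive = FALSE)
  structure(list(rate = rate, amplitude = amplitude,
                 comps_per_cycle = comps_per_cycle,
                 vent_pause_s = vent_pause_s,
                 impedance_excursion = impedance_excursion,
                 impedance_baseline = impedance_baseline),
            class = "awc_cc_model")
}

# deterministic 30:2 compression schedule over [0, duration)
cc_schedule <- function(duration, model) {
  dt <- 60 / model$rate
  times <- numeric(0)
  t <- 0
  repeat {
    block <- t + dt * (seq_len(model$comps_per_cycle) - 1L)
    block <- block[block < duration]
    times <- c(times, block)
    if (length(block) < model$comps_per_cycle) break
    t <- block[length(block)] + dt + model$vent_pause_s
    if (t >= duration) break
  }
  times
}

#' Generate compression artifact and impedance channels
#'
#' Produces the ECG-channel compression artifact (µV), the transthoracic
#' impedance channel (Ohm) and the compression time stamps for a 30:2 CPR
#' pattern at the model's metronome rate.  Each compression contributes a
#' half-sinusoid deflection with ±20% amplitude jitter on both channels;
#' slow baseline wander is added to the ECG artifact.
#'
#' @param duration seconds.
#' @param model a \code{\link{cc_artifact_model}}.
#' @param seed integer seed.
#' @param fs sampling rate in Hz.
#' @return List with \code{artifact} (µV), \code{impedance} (Ohm),
#'   \code{compression_times} (s) and \code{fs}.
#' @export
#' @examples
#' cc <- gen_cc_channelpair(20, seed = 1)
#' length(cc$compression_times)
gen_cc_channelpair <- function(duration, model = cc_artifact_model(),
                               seed = 1L, fs = DEFAULT_FS) {
  check_scalar(duration, "duration")
  stopifnot(inherits(model, "awc_cc_model"))
  n <- round(duration * fs)
  times <- cc_schedule(duration, model)

  with_seed(seed, {
    artifact <- numeric(n)
    impedance <- rep(model$impedance_baseline, n)
    pulse_dur <- 0.30  # s, compression deflection width
    m <- round(pulse_dur * fs)
    pulse <- sin(pi * seq_len(m) / m)
    for (tc in times) {
      a <- 1 + stats::runif(1, -0.2, 0.2)  # per-compression jitter
      i0 <- round(tc * fs) + 1L
      idx <- i0:min(n, i0 + m - 1L)
      artifact[idx] <- artifact[idx] + model$amplitude * a * pulse[seq_along(idx)]
      impedance[idx] <- impedance[idx] +
        model$impedance_excursion * a * pulse[seq_along(idx)]
    }
    # slow baseline wander on the ECG channel
    ph <- stats::runif(1, 0, 2 * pi)
    tt <- seq_len(n) / fs
    artifact <- artifact + 0.1 * model$amplitude * sin(2 * pi * 0.25 * tt + ph)
    list(artifact = artifact, impedance = impedance,
         compression_times = times, fs = fs)
  })
}

#' Add compression artifact to a clean ECG segment
#'
#' Sample-wise additive mixing; the corruption is exactly invertible given
#' the artifact.
#'
#' @param ecg an \code{awc_ecg} object or numeric vector (µV).
#' @param artifact numeric vector of equal length (µV).
#' @return Numeric vector of corrupted samples.
#' @export
mix_cc <- function(ecg, artifact) {
  x <- if (inherits(ecg, "awc_ecg")) ecg$samples else ecg
  if (length(x) != length(artifact)) {
    stop("ECG and artifact lengths differ", call. = FALSE)
  }
  x + artifact
}

#' Build a seeded corpus of annotated synthetic segments
#'
#' Generates \code{n_per_class} segments per rhythm class with per-segment
#' randomised rate/amplitude inside the class limits, and a manifest data
#' frame recording each segment's true label and parameters.
#'
#' @param classes rhythm classes to include.
#' @param n_per_class segments per class.
#' @param duration segment length in seconds.
#' @param seed integer master seed; segment seeds derive from it.
#' @param fs sampling rate.
#' @return List with \code{segments} (list of \code{awc_ecg}) and
#'   \code{manifest} (data frame: id, label, rate, amplitude, duration, seed).
#' @export
gen_corpus <- function(classes = c("VF", "ONR", "ASYS"), n_per_class = 50,
                       duration = 16, seed = 1L, fs = DEFAULT_FS) {
  params <- with_seed(seed, {
    do.call(rbind, lapply(classes, function(cl) {
      rate <- switch(cl,
        VF = , FINE_VF = , ASYS = rep(NA_real_, n_per_class),
        RAPID_VT = stats::runif(n_per_class, 155, 220),
        SLOW_VT  = stats::runif(n_per_class, 60, 140),
        NSR      = stats::runif(n_per_class, 55, 95),
        ONR      = stats::runif(n_per_class, 40, 130))
      amp <- switch(cl,
        VF       = stats::runif(n_per_class, 250, 900),
        FINE_VF  = stats::runif(n_per_class, 110, 195),
        ASYS     = stats::runif(n_per_class, 25, 85),
        stats::runif(n_per_class, 500, 1800))
      data.frame(label = cl, rate = rate, amplitude = amp,
                 seed = sample.int(2^30, n_per_class))
    }))
  })
  params$id <- seq_len(nrow(params))
  params$duration <- duration
  segments <- lapply(seq_len(nrow(params)), function(i) {
    gen_ecg_segment(params$label[i], duration,
                    rate = if (is.na(params$rate[i])) NULL else params$rate[i],
                    amplitude = params$amplitude[i],
                    fs = fs, seed = params$seed[i])
  })
  list(segments = segments,
       manifest = params[, c("id", "label", "rate", "amplitude",
                             "duration", "seed")])
}
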