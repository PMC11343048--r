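# Shock advisory classifiers --------------------------------------------------
#
# Decision functions for the three analysis contexts: a clean 5 s window
# (Standard analysis and confirmation analysis) and a 16 s window during
# chest compressions.  The during-CC path is an original reference stand-in:
# compression epochs are located on the impedance channel and a per-epoch
# scaled artifact template is subtracted from the ECG before the same
# feature-based decision rules are applied.  Oracle classifiers (exact and
# noisy) let the protocol engine and the evaluation suite be exercised
# independently of any signal processing.

#' Remove chest-compression artifact from a corrupted ECG window
#'
#' Locates individual compressions on the impedance channel, learns the mean
#' artifact waveform around each compression, fits a per-compression scale by
#' least squares, and subtracts the scaled template from the (high-pass
#' filtered) ECG.  When no compression periodicity is detectable the input is
#' returned unchanged with \code{periodic = FALSE}.
#'
#' @param ecg numeric vector, corrupted ECG in µV.
#' @param impedance numeric vector of equal length, Ohm.
#' @param fs sampling rate in Hz.
#' @return List with \code{cleaned} (µV, same length), \code{periodic}
#'   (logical flag) and \code{compression_idx} (detected sample indices).
#' @export
#' @examples
#' seg <- gen_ecg_segment("VF", 16, amplitude = 400, seed = 1)
#' cc <- gen_cc_channelpair(16, seed = 2)
#' out <- suppress_cc(mix_cc(seg, cc$artifact), cc$impedance, seg$fs)
#' out$periodic
suppress_cc <- function(ecg, impedance, fs = DEFAULT_FS) {
  if (length(ecg) != length(impedance)) {
    stop("ECG and impedance lengths differ", call. = FALSE)
  }
  n <- length(ecg)
  z <- impedance - stats::median(impedance)
  exc <- max(z) - min(z)
  # detect compression peaks on the impedance channel
  min_dist <- round(0.25 * fs)
  cand <- which(diff(sign(diff(z))) == -2) + 1L
  cand <- cand[z[cand] > 0.3 * max(z)]
  if (length(cand) > 1L) {
    keep <- cand[1L]
    for (i in cand[-1L]) {
      if (i - keep[length(keep)] >= min_dist) keep <- c(keep, i)
      else if (z[i] > z[keep[length(keep)]]) keep[length(keep)] <- i
    }
    cand <- keep
  }
  if (exc < 0.1 || length(cand) < 5L) {
    return(list(cleaned = ecg, periodic = FALSE,
                compression_idx = integer(0)))
  }

  x <- ecg
  # epochs tile each compression block: one inter-compression interval
  # centred on every detected impedance peak
  med_int <- stats::median(diff(cand))
  half <- round(med_int / 2)
  m <- 2L * half + 1L
  tt <- seq_len(m) - (half + 1L)

  # template: mean compression waveform after removing a per-epoch linear
  # trend (slow wander and inter-block baseline differences)
  full <- cand[cand - half >= 1L & cand + half <= n]
  if (length(full) < 5L) {
    return(list(cleaned = ecg, periodic = FALSE, compression_idx = cand))
  }
  detr <- vapply(full, function(i) {
    seg <- x[(i - half):(i + half)]
    stats::lm.fit(cbind(1, tt), seg)$residuals
  }, numeric(m))
  tpl <- rowMeans(detr)

  # subtract the per-compression fit (scaled template + affine trend);
  # epochs are clipped so no sample is corrected twice
  prev_hi <- 0L
  for (i in cand) {
    lo <- max(1L, i - half, prev_hi + 1L)
    hi <- min(n, i + half)
    if (hi < lo) next
    off <- (lo - (i - half) + 1L):(hi - (i - half) + 1L)
    idx <- lo:hi
    X <- cbind(tpl[off], 1, tt[off])
    x[idx] <- stats::lm.fit(X, x[idx])$residuals
    prev_hi <- hi
  }

  # residual slow wander (ventilation pauses are not covered by epochs)
  bf <- signal::butter(2, 0.8 / (fs / 2), type = "high")
  x <- as.numeric(signal::filtfilt(bf, x))
  list(cleaned = x, periodic = TRUE, compression_idx = cand)
}

# robust amplitude: trimmed peak-to-peak, tolerant of isolated residual spikes
robust_p2p <- function(x) {
  q <- stats::quantile(x, c(0.002, 0.998), names = FALSE, type = 7)
  q[2] - q[1]
}

# shared decision rule: shock for disorganized rhythm above the VF amplitude
# threshold, or organized wide-complex rhythm at/above the rapid-VT rate
decide_from_features <- function(f, criteria) {
  if (f$p2p <= criteria$asys_max_amp) return("NO_SHOCK")
  if (f$organized) {
    if (!is.na(f$width) && f$width > 0.065 &&
        f$rate >= criteria$rapid_vt_min_rate) {
      return("SHOCK")
    }
    return("NO_SHOCK")
  }
  if (f$p2p > criteria$vf_min_amp) "SHOCK" else "NO_SHOCK"
}

#' Reference shock decision on a clean ECG window
#'
#' Deterministic rule: shock for a disorganized rhythm with peak-to-peak
#' amplitude above the coarse-VF threshold, or an organized wide-complex
#' rhythm at or above the rapid-VT rate; no shock otherwise.
#'
#' @param ecg numeric vector, µV, approximately \code{expected_duration} long.
#' @param fs sampling rate in Hz.
#' @param criteria an \code{\link{annotation_criteria}} object.
#' @param expected_duration window length in seconds the caller scheduled
#'   (default 5); mismatch beyond one sample is an error.
#' @return \code{"SHOCK"} or \code{"NO_SHOCK"}.
#' @export
classify_clean <- function(ecg, fs = DEFAULT_FS,
                           criteria = annotation_criteria(),
                           expected_duration = 5) {
  if (length(ecg) == 0L) stop("empty ECG window", call. = FALSE)
  if (!is.null(expected_duration) &&
      abs(length(ecg) / fs - expected_duration) > 1 / fs + 1e-9) {
    stop(sprintf("window is %.3f s, expected %.3f s",
                 length(ecg) / fs, expected_duration), call. = FALSE)
  }
  f <- ecg_features(ecg, fs)
  decide_from_features(f, criteria)
}

#' Reference shock decision on a 16 s window during chest compressions
#'
#' Applies \code{\link{suppress_cc}} and then the clean-window decision rule
#' with a robust (trimmed) amplitude measure to tolerate residual artifact
#' spikes.
#'
#' @param ecg numeric vector, corrupted ECG in µV.
#' @param impedance aligned impedance channel, Ohm.
#' @param fs sampling rate in Hz.
#' @param criteria an \code{\link{annotation_criteria}} object.
#' @param expected_duration scheduled window length in seconds (default 16).
#' @return \code{"SHOCK"} or \code{"NO_SHOCK"}.
#' @export
classify_cc <- function(ecg, impedance, fs = DEFAULT_FS,
                        criteria = annotation_criteria(),
                        expected_duration = 16) {
  if (!is.null(expected_duration) &&
      abs(length(ecg) / fs - expected_duration) > 1 / fs + 1e-9) {
    stop(sprintf("window is %.3f s, expected %.3f s",
                 length(ecg) / fs, expected_duration), call. = FALSE)
  }
  sup <- suppress_cc(ecg, impedance, fs)
  f <- ecg_features(sup$cleaned, fs)
  f$p2p <- robust_p2p(sup$cleaned)
  decide_from_features(f, criteria)
}

# --- classifier interface consumed by the protocol engine --------------------

#' Shock advisory classifier objects
#'
#' Classifiers plug into the protocol engine through a uniform contract:
#' given an analysis window (start/end in seconds), the stage and the
#' engine context (ground-truth timeline and, for the reference classifier,
#' a signal provider), they return \code{"SHOCK"} or \code{"NO_SHOCK"}.
#'
#' \describe{
#' \item{\code{oracle_classifier()}}{reads the ground-truth timeline and
#'   shocks exactly the shockable labels; intermediate labels are not
#'   shocked, and a transition window is decided from the rhythm at the
#'   window end.}
#' \item{\code{noisy_oracle_classifier(error_rates)}}{the oracle decision
#'   flipped with a per-stage, per-label error probability; used to inject
#'   known confusion rates into a simulated cohort and verify the
#'   evaluation arithmetic independently of signal processing.}
#' \item{\code{reference_classifier()}}{applies \code{\link{classify_clean}}
#'   / \code{\link{classify_cc}} to synthesized window signals.}
#' }
#'
#' @param error_rates data frame with columns \code{stage} (STANDARD, STEP1,
#'   STEP2), \code{label} and \code{error} (probability that the oracle
#'   decision for that label at that stage is flipped).  See
#'   \code{\link{table1b_error_rates}}.
#' @param criteria an \code{\link{annotation_criteria}} object for the
#'   reference classifier.
#' @param cc_model a \code{\link{cc_artifact_model}} for synthesizing
#'   during-CC windows.
#' @return An object of class \code{awc_classifier}.
#' @export
oracle_classifier <- function() {
  structure(list(kind = "oracle"), class = "awc_classifier")
}

#' @rdname oracle_classifier
#' @export
noisy_oracle_classifier <- function(error_rates) {
  stopifnot(is.data.frame(error_rates),
            all(c("stage", "label", "error") %in% names(error_rates)))
  if (any(error_rates$error < 0 | error_rates$error > 1)) {
    stop("error rates must be probabilities", call. = FALSE)
  }
  structure(list(kind = "noisy_oracle", error_rates = error_rates),
            class = "awc_classifier")
}

#' @rdname oracle_classifier
#' @export
reference_classifier <- function(criteria = annotation_criteria(),
                                 cc_model = cc_artifact_model()) {
  structure(list(kind = "reference", criteria = criteria,
                 cc_model = cc_model),
            class = "awc_classifier")
}

#' @export
print.awc_classifier <- function(x, ...) {
  cat(sprintf("<awc_classifier> %s\n", x$kind))
  invisible(x)
}

# ground-truth label over a window.  A window overlapping both shockable and
# non-shockable rhythm is a TRANSITION; otherwise the label covering most of
# the window wins.
truth_label_at <- function(truth, start, end) {
  ov <- truth[truth$start < end & truth$end > start, , drop = FALSE]
  if (nrow(ov) == 0L) return("UNDEFINED")
  ov$cover <- pmin(ov$end, end) - pmax(ov$start, start)
  ov <- ov[ov$cover > 1e-9, , drop = FALSE]
  if (nrow(ov) == 0L) return("UNDEFINED")
  cats <- is_shockable(ov$label)
  if (any(cats == "shockable") && any(cats == "non_shockable")) {
    return("TRANSITION")
  }
  ov$label[which.max(ov$cover)]
}

# label of the rhythm present at one instant
truth_label_point <- function(truth, t) {
  ov <- truth[truth$start <= t & truth$end > t, , drop = FALSE]
  if (nrow(ov) == 0L) return("UNDEFINED")
  ov$label[nrow(ov)]
}

oracle_decide <- function(truth, start, end) {
  lab <- truth_label_at(truth, start, end)
  if (identical(lab, "TRANSITION")) {
    lab <- truth_label_point(truth, end - 1e-6)
  }
  if (is_shockable(lab) == "shockable") "SHOCK" else "NO_SHOCK"
}

# dispatch a classifier on one analysis window.  `ctx` carries the truth
# timeline and (for the reference classifier) a get_signal(start, end,
# during_cc) closure returning list(ecg, impedance, fs).
classifier_decide <- function(clf, start, end, stage, during_cc, ctx) {
  stopifnot(inherits(clf, "awc_classifier"))
  if (clf$kind == "oracle") {
    return(oracle_decide(ctx$truth, start, end))
  }
  if (clf$kind == "noisy_oracle") {
    base <- oracle_decide(ctx$truth, start, end)
    lab <- truth_label_at(ctx$truth, start, end)
    er <- clf$error_rates
    hit <- er$stage == stage & er$label == lab
    eps <- if (any(hit)) er$error[which(hit)[1]] else 0
    if (eps > 0 && stats::runif(1) < eps) {
      base <- if (base == "SHOCK") "NO_SHOCK" else "SHOCK"
    }
    return(base)
  }
  if (clf$kind == "reference") {
    sig <- ctx$get_signal(start, end, during_cc)
    if (during_cc) {
      return(classify_cc(sig$ecg, sig$impedance, sig$fs, clf$criteria,
                         expected_duration = end - start))
    }
    return(classify_clean(sig$ecg, sig$fs, clf$criteria,
                          expected_duration = end - start))
  }
  stop("unknown classifier kind: ", clf$kind, call. = FALSE)
}
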