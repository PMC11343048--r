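# Rhythm classes and annotation rules ----------------------------------------
#
# The AHA analysis scheme used by AED shock advisory systems distinguishes
# five primary rhythm classes (VF, rapid VT, NSR, ONR, ASYS) with performance
# goals, plus intermediate classes (fine VF, slow VT, in-window transitions)
# that are reported descriptively and excluded from sensitivity/specificity
# denominators.

#' Rhythm class labels
#'
#' The label vocabulary used throughout the package.  \code{VF} and
#' \code{RAPID_VT} are shockable; \code{NSR}, \code{ONR} and \code{ASYS} are
#' non-shockable; \code{FINE_VF}, \code{SLOW_VT} and \code{TRANSITION} are
#' intermediate classes excluded from sensitivity/specificity denominators;
#' \code{UNDEFINED} marks windows with no usable consensus label.
#'
#' @return Character vector of the nine recognised labels.
#' @export
#' @examples
#' rhythm_labels()
rhythm_labels <- function() {
  c("VF", "RAPID_VT", "NSR", "ONR", "ASYS",
    "FINE_VF", "SLOW_VT", "TRANSITION", "UNDEFINED")
}

#' @rdname rhythm_labels
#' @export
shockable_labels <- function() c("VF", "RAPID_VT")

#' @rdname rhythm_labels
#' @export
nonshockable_labels <- function() c("NSR", "ONR", "ASYS")

assert_label <- function(label) {
  if (!is.character(label) || any(!label %in% rhythm_labels())) {
    stop("invalid rhythm label; see rhythm_labels()", call. = FALSE)
  }
  invisible(label)
}

#' Annotation criteria for rhythm classification
#'
#' Amplitude and rate thresholds of the AHA rhythm classification scheme:
#' VF requires peak-to-peak amplitude above \code{vf_min_amp}; fine VF spans
#' \code{fine_vf_low} to \code{vf_min_amp} (both ends inclusive, the upper
#' boundary resolving to the intermediate class); rapid VT requires rate of
#' at least \code{rapid_vt_min_rate}; organized non-shockable rhythms need a
#' rate above \code{onr_min_rate}; asystole requires peak-to-peak amplitude
#' below \code{asys_max_amp} sustained for more than \code{asys_min_duration}.
#'
#' @param vf_min_amp µV, minimum peak-to-peak amplitude of coarse VF (default 200).
#' @param fine_vf_low µV, lower bound of the fine-VF amplitude band (default 100).
#' @param rapid_vt_min_rate min^-1, minimum rate of shockable VT (default 150).
#' @param onr_min_rate min^-1, minimum rate of an organized non-shockable
#'   rhythm (default 30).
#' @param asys_max_amp µV, maximum peak-to-peak amplitude of asystole
#'   (default 100).
#' @param asys_min_duration s, minimum sub-threshold duration required to
#'   assert asystole (default 4).
#' @return An object of class \code{awc_criteria}.
#' @export
#' @examples
#' annotation_criteria()
annotation_criteria <- function(vf_min_amp = 200,
                                fine_vf_low = 100,
                                rapid_vt_min_rate = 150,
                                onr_min_rate = 30,
                                asys_max_amp = 100,
                                asys_min_duration = 4) {
  check_scalar(vf_min_amp, "vf_min_amp")
  check_scalar(fine_vf_low, "fine_vf_low")
  check_scalar(rapid_vt_min_rate, "rapid_vt_min_rate")
  check_scalar(onr_min_rate, "onr_min_rate")
  check_scalar(asys_max_amp, "asys_max_amp")
  check_scalar(asys_min_duration, "asys_min_duration")
  if (fine_vf_low >= vf_min_amp) {
    stop("fine_vf_low must be below vf_min_amp", call. = FALSE)
  }
  if (asys_max_amp > fine_vf_low) {
    stop("asys_max_amp must not exceed the fine-VF lower bound", call. = FALSE)
  }
  structure(
    list(vf_min_amp = vf_min_amp, fine_vf_low = fine_vf_low,
         rapid_vt_min_rate = rapid_vt_min_rate, onr_min_rate = onr_min_rate,
         asys_max_amp = asys_max_amp, asys_min_duration = asys_min_duration),
    class = "awc_criteria"
  )
}

#' @export
print.awc_criteria <- function(x, ...) {
  cat("Rhythm annotation criteria:\n")
  cat(sprintf("  VF amplitude            > %g uV\n", x$vf_min_amp))
  cat(sprintf("  fine-VF amplitude band  [%g, %g] uV\n", x$fine_vf_low, x$vf_min_amp))
  cat(sprintf("  rapid VT rate           >= %g /min\n", x$rapid_vt_min_rate))
  cat(sprintf("  ONR rate                > %g /min\n", x$onr_min_rate))
  cat(sprintf("  asystole amplitude      < %g uV for > %g s\n",
              x$asys_max_amp, x$asys_min_duration))
  invisible(x)
}

# --- waveform features -------------------------------------------------------

# Peak-based features of a clean (artifact-free) ECG window.  Peaks are local
# maxima of the signal exceeding a prominence fraction of the peak-to-peak
# range, separated by at least 200 ms (i.e. rates up to 300/min resolve).
# Organization is judged from the regularity of peak intervals; complex width
# (narrow vs wide QRS) from the width of the deflection around each peak at
# half its height above the local baseline.
ecg_features <- function(ecg, fs) {
  n <- length(ecg)
  p2p <- max(ecg) - min(ecg)
  dur <- n / fs
  feats <- list(p2p = p2p, duration = dur, rate = NA_real_,
                rr_cv = NA_real_, width = NA_real_,
                organized = FALSE, n_peaks = 0L)
  if (p2p <= 0) return(feats)

  # light smoothing to stabilise peak picking against the noise floor
  k <- max(1L, round(0.02 * fs))
  sm <- stats::filter(ecg, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- ecg[is.na(sm)]
  sm <- as.numeric(sm)

  min_dist <- round(0.2 * fs)
  thresh <- min(sm) + 0.55 * (max(sm) - min(sm))
  cand <- which(diff(sign(diff(sm))) == -2) + 1L
  cand <- cand[sm[cand] >= thresh]
  if (length(cand) > 1L) {
    keep <- cand[1L]
    for (i in cand[-1L]) {
      if (i - keep[length(keep)] >= min_dist) {
        keep <- c(keep, i)
      } else if (sm[i] > sm[keep[length(keep)]]) {
        keep[length(keep)] <- i
      }
    }
    cand <- keep
  }
  feats$n_peaks <- length(cand)
  if (length(cand) >= 3L) {
    rr <- diff(cand) / fs
    # rate from sample counts so an exact beat interval gives an exact rate
    feats$rate <- 60 * fs / stats::median(diff(cand))
    feats$rr_cv <- stats::sd(rr) / mean(rr)
    # width at half height above the window median (baseline proxy)
    base <- stats::median(sm)
    widths <- vapply(cand, function(i) {
      half <- base + (sm[i] - base) / 2
      l <- i
      while (l > 1L && sm[l] > half) l <- l - 1L
      r <- i
      while (r < n && sm[r] > half) r <- r + 1L
      (r - l) / fs
    }, numeric(1))
    feats$width <- stats::median(widths)
    feats$organized <- feats$rr_cv < 0.18
  }
  feats
}

#' Annotate an artifact-free ECG window with a rhythm label
#'
#' Applies the AHA-style amplitude/rate criteria to a clean ECG window and
#' returns exactly one rhythm label.  Asystole is asserted only when the
#' peak-to-peak amplitude stays below the asystole threshold for longer than
#' the minimum duration; shorter sub-threshold windows return
#' \code{UNDEFINED}.  Organized rhythms are split by complex width and rate
#' into rapid VT, slow VT, and organized non-shockable rhythms; the
#' sinus-morphology flag (carried by the synthetic generator) selects NSR
#' over ONR.  Disorganized rhythms are split by amplitude into VF and fine
#' VF; the band boundaries 100 and 200 µV both resolve to fine VF.  Windows
#' known to contain a rhythm-category change are labelled \code{TRANSITION}.
#'
#' @param ecg numeric vector, ECG samples in µV.
#' @param fs sampling rate in Hz.
#' @param criteria an \code{\link{annotation_criteria}} object.
#' @param sinus logical; TRUE when the source generator flagged sinus
#'   morphology (selects NSR over ONR for organized narrow-complex rhythms).
#' @param transition logical; TRUE when the window contains a marked
#'   rhythm-category change.
#' @return A single rhythm label (see \code{\link{rhythm_labels}}).
#' @export
#' @examples
#' seg <- gen_ecg_segment("ASYS", duration = 5, amplitude = 60, seed = 1)
#' annotate_window(seg$samples, seg$fs)
annotate_window <- function(ecg, fs, criteria = annotation_criteria(),
                            sinus = FALSE, transition = FALSE) {
  if (length(ecg) == 0L) stop("empty ECG window", call. = FALSE)
  check_scalar(fs, "fs")
  stopifnot(inherits(criteria, "awc_criteria"))
  if (isTRUE(transition)) return("TRANSITION")

  f <- ecg_features(ecg, fs)
  if (f$p2p < criteria$asys_max_amp) {
    if (f$duration > criteria$asys_min_duration) return("ASYS")
    return("UNDEFINED")  # too short to assert asystole
  }
  if (f$organized) {
    if (!is.na(f$width) && f$width > 0.065) {
      if (f$rate >= criteria$rapid_vt_min_rate) return("RAPID_VT")
      return("SLOW_VT")
    }
    if (f$rate > criteria$onr_min_rate) {
      return(if (isTRUE(sinus)) "NSR" else "ONR")
    }
    return("UNDEFINED")  # organized but below the minimum organized rate
  }
  if (f$p2p > criteria$vf_min_amp) return("VF")
  "FINE_VF"  # disorganized, amplitude in [fine_vf_low, vf_min_amp]
}

#' Shockable / non-shockable / excluded partition of rhythm labels
#'
#' @param label character vector of rhythm labels.
#' @return Character vector: \code{"shockable"} for VF and rapid VT,
#'   \code{"non_shockable"} for NSR, ONR and ASYS, and
#'   \code{"intermediate_or_excluded"} for fine VF, slow VT, transitions and
#'   undefined windows.
#' @export
#' @examples
#' is_shockable(c("VF", "ASYS", "FINE_VF"))
is_shockable <- function(label) {
  assert_label(label)
  out <- rep("intermediate_or_excluded", length(label))
  out[label %in% shockable_labels()] <- "shockable"
  out[label %in% nonshockable_labels()] <- "non_shockable"
  out
}

#' Write / read window annotations as CSV
#'
#' Annotations serialize with columns \code{intervention_id},
#' \code{window_start_s}, \code{window_end_s}, \code{during_cc}, \code{label}.
#'
#' @param annotations data frame with the columns above.
#' @param path output file.
#' @return \code{write_annotations} returns \code{path} invisibly;
#'   \code{read_annotations} returns the data frame.
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("intervention_id", "window_start_s", "window_end_s",
            "during_cc", "label")
  if (!all(cols %in% names(annotations))) {
    stop("annotations must have columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(annotations[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_label(out$label)
  out
}
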