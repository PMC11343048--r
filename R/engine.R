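# AWC protocol state machine ---------------------------------------------------
#
# The engine schedules the analysis stages of a CPR phase: 16 s rhythm
# analyses during compressions (Step1), whose results count only from one
# minute into the phase; a 5 s confirmation analysis (CoA / Step2) on paused
# compressions whenever a counted Step1 result is shockable; and the 5 s
# Standard analysis after the full 2-minute phase when Step1 repeatedly found
# a non-shockable rhythm.  Two treatment scenarios follow: an early shock
# before the 2-minute mark for confirmed refibrillation, or an uninterrupted
# 2-minute phase for non-shockable rhythms.

#' Protocol timing configuration
#'
#' All protocol timing constants, in seconds.  Defaults reproduce the
#' recorded timings of the clinical protocol: the first during-CC analysis
#' window spans 48-64 s of the phase (so the first counted result arrives
#' just after the 1-minute gate), subsequent windows tile with a short
#' re-arm gap, the confirmation analysis starts 5 s after compressions stop,
#' and the Standard analysis runs just after the 2-minute mark.
#'
#' @param step1_duration s, during-CC analysis window (default 16).
#' @param step2_duration s, confirmation analysis window (default 5).
#' @param standard_duration s, Standard analysis window (default 5).
#' @param step1_result_gate s after CPR-phase start before a Step1 result is
#'   acted on (default 60).
#' @param cpr_phase_max s, maximum CPR-phase length (default 120).
#' @param step1_rearm_gap s between consecutive Step1 windows (default 2.5).
#' @param step1_first_start s after phase start when the first Step1 window
#'   opens (default 48, placing its result just past the 1-minute gate).
#' @param cc_stop_to_step2_delay s from compression stop to confirmation
#'   analysis start (default 5).
#' @param post_decision_latency s from a no-shock Standard decision to
#'   compression resumption (default 5).
#' @param shock_latency s from a shock decision to shock delivery (default 1).
#' @param standard_start_delay s from compression stop at the 2-minute mark
#'   to Standard analysis start (default 1).
#' @param reset_phase_on_coa_reject logical; if TRUE the phase clock restarts
#'   when a confirmation analysis rejects the shock (default FALSE: the phase
#'   still ends at \code{cpr_phase_max} from its original start).
#' @return Object of class \code{awc_engine_config}.
#' @export
engine_config <- function(step1_duration = 16,
                          step2_duration = 5,
                          standard_duration = 5,
                          step1_result_gate = 60,
                          cpr_phase_max = 120,
                          step1_rearm_gap = 2.5,
                          step1_first_start = 48,
                          cc_stop_to_step2_delay = 5,
                          post_decision_latency = 5,
                          shock_latency = 1,
                          standard_start_delay = 1,
                          reset_phase_on_coa_reject = FALSE) {
  for (nm in c("step1_duration", "step2_duration", "standard_duration",
               "step1_result_gate", "cpr_phase_max", "step1_rearm_gap",
               "cc_stop_to_step2_delay", "post_decision_latency",
               "shock_latency", "standard_start_delay")) {
    check_scalar(get(nm), nm, positive = nm %in% c(
      "step1_duration", "step2_duration", "standard_duration",
      "step1_result_gate", "cpr_phase_max"))
  }
  if (step1_result_gate >= cpr_phase_max) {
    stop("step1_result_gate must be below cpr_phase_max", call. = FALSE)
  }
  if (step1_first_start + step1_duration > cpr_phase_max) {
    stop("no Step1 window fits before cpr_phase_max", call. = FALSE)
  }
  structure(list(
    step1_duration = step1_duration, step2_duration = step2_duration,
    standard_duration = standard_duration,
    step1_result_gate = step1_result_gate, cpr_phase_max = cpr_phase_max,
    step1_rearm_gap = step1_rearm_gap, step1_first_start = step1_first_start,
    cc_stop_to_step2_delay = cc_stop_to_step2_delay,
    post_decision_latency = post_decision_latency,
    shock_latency = shock_latency,
    standard_start_delay = standard_start_delay,
    reset_phase_on_coa_reject = reset_phase_on_coa_reject
  ), class = "awc_engine_config")
}

new_event <- function(t, type, stage = NA_character_,
                      decision = NA_character_, phase_id = NA_integer_) {
  data.frame(t_s = round_ms(t), type = type, stage = stage,
             decision = decision, phase_id = phase_id,
             stringsAsFactors = FALSE)
}

new_analysis <- function(phase_id, stage, start, end, during_cc, decision,
                         truth_label, gated, acted) {
  data.frame(phase_id = phase_id, stage = stage,
             t_start = round_ms(start), t_end = round_ms(end),
             during_cc = during_cc, decision = decision,
             truth_label = truth_label, gated = gated, acted = acted,
             stringsAsFactors = FALSE)
}

#' Run one CPR phase of the AWC protocol
#'
#' Schedules Step1 analyses during compressions, acts on results whose window
#' ends at or after the 1-minute gate, triggers the confirmation analysis and
#' possibly an early shock, and otherwise runs the Standard analysis at the
#' 2-minute mark.  Pure protocol logic: all rhythm decisions come from the
#' supplied classifier.
#'
#' @param phase_start s, phase start time (immediately after the previous
#'   shock or no-shock decision).
#' @param classifier an \code{awc_classifier} (see
#'   \code{\link{oracle_classifier}}).
#' @param ctx engine context: list with \code{truth} (ground-truth timeline
#'   data frame with columns start, end, label) and, for the reference
#'   classifier, \code{get_signal(start, end, during_cc)}.
#' @param config an \code{\link{engine_config}}.
#' @param phase_id integer phase index.
#' @param limit s, hard end of observation; the phase is truncated there.
#' @return Object of class \code{awc_phase}: list with \code{phase_start},
#'   \code{phase_end}, \code{outcome} (\code{EARLY_SHOCK},
#'   \code{STANDARD_SHOCK}, \code{RESUME_AFTER_STANDARD} or, when truncated
#'   after a rejected confirmation, \code{RESUME_AFTER_COA}), \code{analyses}
#'   (data frame), \code{events} (data frame), \code{shock_time} (or NA),
#'   \code{handsoff} (data frame: start, end, cause, truth_label) and
#'   \code{truncated}.
#' @export
run_cpr_phase <- function(phase_start, classifier, ctx, config,
                          phase_id = 1L, limit = Inf) {
  stopifnot(inherits(config, "awc_engine_config"))
  events <- new_event(phase_start, "CC_START", phase_id = phase_id)
  analyses <- list()
  handsoff <- list()
  shock_time <- NA_real_
  outcome <- NULL
  truncated <- FALSE
  had_coa <- FALSE

  phase_cc_end <- phase_start + config$cpr_phase_max
  w_start <- phase_start + config$step1_first_start

  analyse <- function(start, end, stage, during_cc) {
    dec <- classifier_decide(classifier, start, end, stage, during_cc, ctx)
    lab <- truth_label_at(ctx$truth, start, end)
    events <<- rbind(events,
      new_event(start, "ANALYSIS_START", stage, phase_id = phase_id),
      new_event(end, "ANALYSIS_END", stage, phase_id = phase_id),
      new_event(end, "DECISION", stage, dec, phase_id))
    list(decision = dec, label = lab)
  }

  repeat {
    w_end <- w_start + config$step1_duration
    if (w_end > phase_cc_end + 1e-9) break
    if (w_end > limit) { truncated <- TRUE; break }
    res <- analyse(w_start, w_end, "STEP1", during_cc = TRUE)
    gated <- (w_end - phase_start) >= config$step1_result_gate - 1e-9
    acted <- gated && res$decision == "SHOCK"
    analyses[[length(analyses) + 1L]] <-
      new_analysis(phase_id, "STEP1", w_start, w_end, TRUE,
                   res$decision, res$label, gated, acted)

    if (acted) {
      cc_stop <- w_end
      events <- rbind(events, new_event(cc_stop, "CC_STOP",
                                        phase_id = phase_id))
      coa_start <- cc_stop + config$cc_stop_to_step2_delay
      coa_end <- coa_start + config$step2_duration
      if (coa_end > limit) { truncated <- TRUE; break }
      coa <- analyse(coa_start, coa_end, "STEP2", during_cc = FALSE)
      analyses[[length(analyses) + 1L]] <-
        new_analysis(phase_id, "STEP2", coa_start, coa_end, FALSE,
                     coa$decision, coa$label, TRUE, TRUE)
      had_coa <- TRUE
      if (coa$decision == "SHOCK") {
        shock_time <- coa_end + config$shock_latency
        events <- rbind(events, new_event(shock_time, "SHOCK",
                                          phase_id = phase_id))
        handsoff[[length(handsoff) + 1L]] <- data.frame(
          start = cc_stop, end = shock_time, cause = "COA_SHOCK",
          truth_label = coa$label, stringsAsFactors = FALSE)
        outcome <- "EARLY_SHOCK"
        break
      }
      # shock rejected: resume compressions (ill-advised pause when the
      # underlying rhythm was non-shockable)
      handsoff[[length(handsoff) + 1L]] <- data.frame(
        start = cc_stop, end = coa_end, cause = "COA_REJECT",
        truth_label = coa$label, stringsAsFactors = FALSE)
      if (coa_end >= phase_cc_end) {
        # no compression time left before the 2-minute mark
        break
      }
      events <- rbind(events, new_event(coa_end, "CC_START",
                                        phase_id = phase_id))
      if (config$reset_phase_on_coa_reject) {
        phase_cc_end <- coa_end + config$cpr_phase_max
      }
      w_start <- max(w_end + config$step1_rearm_gap,
                     coa_end + config$step1_rearm_gap)
      next
    }
    w_start <- w_end + config$step1_rearm_gap
  }

  analyses <- if (length(analyses)) do.call(rbind, analyses) else
    new_analysis(integer(0), character(0), numeric(0), numeric(0),
                 logical(0), character(0), character(0), logical(0),
                 logical(0))

  if (is.null(outcome) && !truncated) {
    # phase ran to the 2-minute mark: Standard analysis on paused CC
    last_t <- max(phase_start, analyses$t_end[analyses$stage == "STEP2"],
                  phase_cc_end)
    cc_stop <- max(phase_cc_end, if (had_coa) last_t else phase_cc_end)
    if (cc_stop > phase_cc_end) {
      # CoA rejection ran past the 2-minute mark; compressions never resumed
      std_start <- cc_stop + config$standard_start_delay
    } else {
      events <- rbind(events, new_event(phase_cc_end, "CC_STOP",
                                        phase_id = phase_id))
      cc_stop <- phase_cc_end
      std_start <- phase_cc_end + config$standard_start_delay
    }
    std_end <- std_start + config$standard_duration
    if (std_end > limit) {
      truncated <- TRUE
    } else {
      res <- analyse(std_start, std_end, "STANDARD", during_cc = FALSE)
      analyses <- rbind(analyses,
        new_analysis(phase_id, "STANDARD", std_start, std_end, FALSE,
                     res$decision, res$label, TRUE, TRUE))
      if (res$decision == "SHOCK") {
        shock_time <- std_end + config$shock_latency
        events <- rbind(events, new_event(shock_time, "SHOCK",
                                          phase_id = phase_id))
        handsoff[[length(handsoff) + 1L]] <- data.frame(
          start = cc_stop, end = shock_time, cause = "STANDARD_SHOCK",
          truth_label = res$label, stringsAsFactors = FALSE)
        outcome <- "STANDARD_SHOCK"
      } else {
        resume <- std_end + config$post_decision_latency
        handsoff[[length(handsoff) + 1L]] <- data.frame(
          start = cc_stop, end = resume, cause = "STANDARD_RESUME",
          truth_label = res$label, stringsAsFactors = FALSE)
        outcome <- "RESUME_AFTER_STANDARD"
      }
    }
  }
  if (is.null(outcome)) {
    outcome <- if (had_coa) "RESUME_AFTER_COA" else "TRUNCATED"
  }

  phase_end <- switch(outcome,
    EARLY_SHOCK = , STANDARD_SHOCK = shock_time,
    RESUME_AFTER_STANDARD =
      max(analyses$t_end) + config$post_decision_latency,
    min(limit, max(phase_start, events$t_s)))

  handsoff <- if (length(handsoff)) do.call(rbind, handsoff) else
    data.frame(start = numeric(0), end = numeric(0),
               cause = character(0), truth_label = character(0),
               stringsAsFactors = FALSE)

  structure(list(phase_start = phase_start, phase_end = phase_end,
                 phase_id = phase_id, outcome = outcome,
                 analyses = analyses, events = events,
                 shock_time = shock_time, handsoff = handsoff,
                 truncated = truncated),
            class = "awc_phase")
}

#' Run a full intervention on a fixed ground-truth timeline
#'
#' Emits the initial Standard analysis (the enrollment analysis, performed in
#' absence of compressions), then alternates CPR phases until the observation
#' limit or an optional ROSC time.  The truth timeline is static here; the
#' intervention simulator (\code{\link{simulate_intervention}}) drives this
#' engine with a dynamically evolving timeline instead.
#'
#' @param truth data frame with columns \code{start}, \code{end},
#'   \code{label} covering the observation window.
#' @param classifier an \code{awc_classifier}.
#' @param config an \code{\link{engine_config}}.
#' @param observation_limit s (default 600).
#' @param rosc_time s, optional; the run ends with a ROSC event there.
#' @param ctx optional pre-built context (for the reference classifier);
#'   defaults to \code{list(truth = truth)}.
#' @return List with \code{events}, \code{analyses}, \code{phases},
#'   \code{shocks} and \code{handsoff}.
#' @export
run_intervention <- function(truth, classifier, config = engine_config(),
                             observation_limit = 600, rosc_time = Inf,
                             ctx = NULL) {
  if (is.null(ctx)) ctx <- list(truth = truth)
  limit <- min(observation_limit, rosc_time)
  events <- list()
  analyses <- list()
  phases <- list()
  shocks <- numeric(0)
  handsoff <- list()

  # enrollment analysis in absence of CC
  std_end <- config$standard_duration
  dec <- classifier_decide(classifier, 0, std_end, "STANDARD", FALSE, ctx)
  lab <- truth_label_at(ctx$truth, 0, std_end)
  events[[1]] <- rbind(
    new_event(0, "ANALYSIS_START", "STANDARD", phase_id = 0L),
    new_event(std_end, "ANALYSIS_END", "STANDARD", phase_id = 0L),
    new_event(std_end, "DECISION", "STANDARD", dec, 0L))
  analyses[[1]] <- new_analysis(0L, "STANDARD", 0, std_end, FALSE, dec,
                                lab, TRUE, TRUE)
  t <- std_end
  if (dec == "SHOCK") {
    t <- std_end + config$shock_latency
    shocks <- c(shocks, t)
    events[[length(events) + 1L]] <- new_event(t, "SHOCK", phase_id = 0L)
  }

  pid <- 0L
  while (t < limit) {
    pid <- pid + 1L
    ph <- run_cpr_phase(t, classifier, ctx, config, phase_id = pid,
                        limit = limit)
    phases[[pid]] <- ph
    events[[length(events) + 1L]] <- ph$events
    analyses[[length(analyses) + 1L]] <- ph$analyses
    handsoff[[length(handsoff) + 1L]] <- ph$handsoff
    if (!is.na(ph$shock_time)) shocks <- c(shocks, ph$shock_time)
    if (ph$truncated || ph$phase_end <= t) break
    t <- ph$phase_end
  }
  if (is.finite(rosc_time) && rosc_time <= observation_limit) {
    events[[length(events) + 1L]] <- new_event(rosc_time, "ROSC")
  }

  events <- do.call(rbind, events)
  events <- events[order(events$t_s, seq_len(nrow(events))), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events,
       analyses = do.call(rbind, analyses),
       phases = phases,
       shocks = shocks,
       handsoff = do.call(rbind, handsoff))
}

#' Summarise hands-off intervals by cause
#'
#' Groups protocol-induced compression pauses by their cause (confirmation
#' analysis rejected, confirmation followed by shock, Standard analysis with
#' resume or shock) and reports count, median and interquartile range of the
#' pause durations, as median [IQR].
#'
#' @param handsoff data frame with columns \code{start}, \code{end},
#'   \code{cause} (from \code{\link{run_cpr_phase}} /
#'   \code{\link{run_intervention}}, possibly row-bound across a cohort).
#' @return Data frame: cause, n, median_s, q1_s, q3_s.
#' @export
handsoff_summary <- function(handsoff) {
  if (is.null(handsoff) || nrow(handsoff) == 0L) {
    return(data.frame(cause = character(0), n = integer(0),
                      median_s = numeric(0), q1_s = numeric(0),
                      q3_s = numeric(0), stringsAsFactors = FALSE))
  }
  dur <- handsoff$end - handsoff$start
  out <- do.call(rbind, lapply(split(dur, handsoff$cause), function(d) {
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(d), median_s = q[2], q1_s = q[1], q3_s = q[3])
  }))
  out$cause <- rownames(out)
  rownames(out) <- NULL
  out[, c("cause", "n", "median_s", "q1_s", "q3_s")]
}
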