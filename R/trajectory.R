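# Intervention trajectory simulator -------------------------------------------
#
# Simulates a patient's rhythm course over one out-of-hospital cardiac
# arrest intervention: an enrollment rhythm that is shockable at the first
# analysis, post-shock conversion to a non-shockable rhythm, refibrillation
# with an exponential hazard calibrated so that a configurable fraction of
# refibrillations falls inside the first post-shock minute, and possible
# return of spontaneous circulation (ROSC) ending the observation window.

#' Trajectory configuration
#'
#' @param refib_within_60s_prob probability that a refibrillation occurs
#'   within 60 s of the shock (default 0.82); the exponential hazard is
#'   derived as \code{-log(1 - p) / 60}.
#' @param post_shock_mix named probabilities of the first post-shock rhythm
#'   (default ASYS 0.4, ONR 0.5, NSR 0.1).
#' @param shock_success_prob probability that a shock on a shockable rhythm
#'   terminates it (default 0.9).
#' @param rosc_prob_per_phase probability of ROSC at the end of a CPR phase
#'   in which the rhythm is non-shockable (default 0.05).
#' @param initial_shockable_mix named probabilities of the enrollment rhythm
#'   (default VF 0.99, RAPID_VT 0.01).
#' @param observation_limit s, end of the observation window (default 600).
#' @return Object of class \code{awc_traj_config} (the derived hazard is in
#'   field \code{refib_hazard}, s^-1).
#' @export
trajectory_config <- function(refib_within_60s_prob = 0.82,
                              post_shock_mix = c(ASYS = 0.4, ONR = 0.5,
                                                 NSR = 0.1),
                              shock_success_prob = 0.9,
                              rosc_prob_per_phase = 0.05,
                              initial_shockable_mix = c(VF = 0.99,
                                                        RAPID_VT = 0.01),
                              observation_limit = 600) {
  check_prob(refib_within_60s_prob, "refib_within_60s_prob")
  check_prob(shock_success_prob, "shock_success_prob")
  check_prob(rosc_prob_per_phase, "rosc_prob_per_phase")
  check_scalar(observation_limit, "observation_limit")
  stopifnot(all(names(post_shock_mix) %in% nonshockable_labels()),
            abs(sum(post_shock_mix) - 1) < 1e-9,
            all(names(initial_shockable_mix) %in% shockable_labels()),
            abs(sum(initial_shockable_mix) - 1) < 1e-9)
  hazard <- if (refib_within_60s_prob <= 0) 0 else
    -log(1 - refib_within_60s_prob) / 60
  structure(list(refib_within_60s_prob = refib_within_60s_prob,
                 refib_hazard = hazard,
                 post_shock_mix = post_shock_mix,
                 shock_success_prob = shock_success_prob,
                 rosc_prob_per_phase = rosc_prob_per_phase,
                 initial_shockable_mix = initial_shockable_mix,
                 observation_limit = observation_limit),
            class = "awc_traj_config")
}

#' Sample a refibrillation time
#'
#' Draws the delay from a shock to refibrillation from the exponential
#' hazard implied by \code{refib_within_60s_prob}; memoryless within a
#' post-shock period, the hazard resets at each shock.  Returns \code{Inf}
#' (no refibrillation) when the configured probability is zero.  Uses the
#' current RNG stream; seed via \code{set.seed} or a seeded caller.
#'
#' @param config an \code{\link{trajectory_config}}.
#' @return Time in seconds (possibly \code{Inf}).
#' @export
#' @examples
#' set.seed(1)
#' sample_refib_time(trajectory_config())
sample_refib_time <- function(config = trajectory_config()) {
  stopifnot(inherits(config, "awc_traj_config"))
  if (config$refib_hazard <= 0) return(Inf)
  stats::rexp(1, rate = config$refib_hazard)
}

# close the open (end = Inf) truth segment at time t and append a new one
truth_append <- function(truth, t, label, sinus = FALSE) {
  open <- which(!is.finite(truth$end))
  if (length(open)) {
    if (truth$start[open] >= t) {
      truth <- truth[-open, , drop = FALSE]
    } else {
      truth$end[open] <- t
    }
  }
  rbind(truth, data.frame(start = t, end = Inf, label = label,
                          sinus = sinus, stringsAsFactors = FALSE))
}

# age sampler matching a right-skewed OHCA cohort:
# median 60, IQR 51-72 (interpolated inverse CDF)
sample_age <- function(n) {
  q <- c(0.01, 0.25, 0.5, 0.75, 0.99)
  v <- c(25, 51, 60, 72, 95)
  round(stats::approx(q, v, xout = stats::runif(n), rule = 2)$y)
}

# window-signal provider for the reference classifier: synthesizes the clean
# ECG for the truth labels covering the window (concatenating across rhythm
# changes) and adds compression artifact when the window is during CC.
make_signal_provider <- function(ctx, cc_model, base_seed, fs = DEFAULT_FS) {
  force(ctx); force(cc_model); force(base_seed); force(fs)
  function(start, end, during_cc) {
    truth <- ctx$truth
    ov <- truth[truth$start < end & truth$end > start, , drop = FALSE]
    ov$start <- pmax(ov$start, start)
    ov$end <- pmin(ov$end, end)
    ov <- ov[ov$end - ov$start > 1e-9, , drop = FALSE]
    wseed <- (base_seed + round(start * 97)) %% 2147483629L + 1L
    n_target <- round((end - start) * fs)
    ecg <- numeric(0)
    for (k in seq_len(nrow(ov))) {
      lab <- ov$label[k]
      n_left <- n_target - length(ecg)
      dur <- if (k == nrow(ov)) n_left / fs else ov$end[k] - ov$start[k]
      if (dur <= 0) next
      seg <- gen_ecg_segment(lab, dur, fs = fs, seed = wseed + k)
      ecg <- c(ecg, seg$samples)
    }
    length(ecg) <- n_target
    ecg[is.na(ecg)] <- 0
    if (during_cc) {
      cc <- gen_cc_channelpair(end - start, cc_model, seed = wseed + 31L,
                               fs = fs)
      list(ecg = mix_cc(ecg, cc$artifact), impedance = cc$impedance, fs = fs)
    } else {
      list(ecg = ecg, impedance = rep(cc_model$impedance_baseline, n_target),
           fs = fs)
    }
  }
}

#' Simulate one intervention
#'
#' Draws an enrollment shockable rhythm, runs the protocol engine phase by
#' phase, and evolves the ground-truth rhythm in response to shocks: a
#' successful shock converts the rhythm to a draw from the post-shock mix
#' and schedules an exponential refibrillation time; ROSC may end the run at
#' a phase boundary.  The full event log, analysis records with matched
#' ground-truth annotations, hands-off intervals and the truth timeline are
#' returned.
#'
#' @param traj a \code{\link{trajectory_config}}.
#' @param engine an \code{\link{engine_config}}.
#' @param classifier an \code{awc_classifier}; the reference classifier gets
#'   per-window synthesized signals.
#' @param seed integer seed (all randomness: trajectory, classifier noise,
#'   signal synthesis).
#' @param patient_id identifier copied into all records.
#' @param cc_model compression-artifact model for per-window signal
#'   synthesis (reference classifier only).
#' @return Object of class \code{awc_intervention}: list with
#'   \code{patient_id}, \code{events}, \code{analyses}, \code{phases},
#'   \code{shocks}, \code{handsoff}, \code{truth}, \code{rosc_time},
#'   \code{meta} (age, sex) and \code{seed}.
#' @export
#' @examples
#' iv <- simulate_intervention(seed = 7)
#' head(iv$analyses)
simulate_intervention <- function(traj = trajectory_config(),
                                  engine = engine_config(),
                                  classifier = oracle_classifier(),
                                  seed = 1L,
                                  patient_id = sprintf("P%05d", seed),
                                  cc_model = cc_artifact_model()) {
  stopifnot(inherits(traj, "awc_traj_config"),
            inherits(engine, "awc_engine_config"))
  with_seed(seed, {
    ctx <- new.env(parent = emptyenv())
    init <- sample(names(traj$initial_shockable_mix), 1,
                   prob = traj$initial_shockable_mix)
    ctx$truth <- data.frame(start = 0, end = Inf, label = init,
                            sinus = FALSE, stringsAsFactors = FALSE)
    ctx$get_signal <- make_signal_provider(ctx, cc_model, base_seed = seed)

    limit <- traj$observation_limit
    events <- list(); analyses <- list(); phases <- list()
    shocks <- numeric(0); handsoff <- list()
    rosc_time <- NA_real_

    apply_shock <- function(t_shock) {
      cur <- truth_label_point(ctx$truth, t_shock)
      if (is_shockable(cur) != "shockable") return(invisible())
      if (stats::runif(1) >= traj$shock_success_prob) return(invisible())
      post <- sample(names(traj$post_shock_mix), 1,
                     prob = traj$post_shock_mix)
      ctx$truth <- truth_append(ctx$truth, t_shock, post,
                                sinus = identical(post, "NSR"))
      refib <- sample_refib_time(traj)
      if (is.finite(refib)) {
        ctx$truth <- truth_append(ctx$truth, t_shock + refib, "VF")
      }
      invisible()
    }

    # enrollment analysis in absence of CC
    std_end <- engine$standard_duration
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
      t <- std_end + engine$shock_latency
      shocks <- c(shocks, t)
      events[[length(events) + 1L]] <- new_event(t, "SHOCK", phase_id = 0L)
      apply_shock(t)
    }

    pid <- 0L
    while (t < limit) {
      pid <- pid + 1L
      ph <- run_cpr_phase(t, classifier, ctx, engine, phase_id = pid,
                          limit = limit)
      phases[[pid]] <- ph
      events[[length(events) + 1L]] <- ph$events
      analyses[[length(analyses) + 1L]] <- ph$analyses
      handsoff[[length(handsoff) + 1L]] <- ph$handsoff
      if (!is.na(ph$shock_time)) {
        shocks <- c(shocks, ph$shock_time)
        apply_shock(ph$shock_time)
      } else if (!ph$truncated) {
        cur <- truth_label_point(ctx$truth, ph$phase_end)
        if (is_shockable(cur) == "non_shockable" &&
            stats::runif(1) < traj$rosc_prob_per_phase) {
          rosc_time <- ph$phase_end
          events[[length(events) + 1L]] <- new_event(rosc_time, "ROSC")
          break
        }
      }
      if (ph$truncated || ph$phase_end <= t) break
      t <- ph$phase_end
    }

    events <- do.call(rbind, events)
    events <- events[order(events$t_s, seq_len(nrow(events))), ,
                     drop = FALSE]
    rownames(events) <- NULL
    analyses <- do.call(rbind, analyses)
    analyses <- cbind(patient_id = patient_id, analyses,
                      stringsAsFactors = FALSE)
    handsoff <- do.call(rbind, handsoff)
    if (!is.null(handsoff) && nrow(handsoff)) {
      handsoff <- cbind(patient_id = patient_id, handsoff,
                        stringsAsFactors = FALSE)
    }
    truth <- ctx$truth
    truth$end[!is.finite(truth$end)] <-
      if (is.na(rosc_time)) limit else rosc_time
    meta <- list(age = sample_age(1),
                 sex = sample(c("M", "F"), 1, prob = c(0.81, 0.19)))

    structure(list(patient_id = patient_id, events = events,
                   analyses = analyses, phases = phases, shocks = shocks,
                   handsoff = handsoff, truth = truth,
                   rosc_time = rosc_time, meta = meta, seed = seed),
              class = "awc_intervention")
  })
}

#' @export
print.awc_intervention <- function(x, ...) {
  cat(sprintf("<awc_intervention> %s: %d phases, %d analyses, %d shocks%s\n",
              x$patient_id, length(x$phases), nrow(x$analyses),
              length(x$shocks),
              if (!is.na(x$rosc_time)) sprintf(", ROSC at %.0f s",
                                               x$rosc_time) else ""))
  invisible(x)
}

#' Simulate a cohort of interventions
#'
#' @param n number of patients.
#' @param traj,engine,classifier,cc_model as in
#'   \code{\link{simulate_intervention}}.
#' @param seed master seed; patient seeds derive from it.
#' @return List with \code{interventions} (list of \code{awc_intervention}),
#'   \code{analyses} (row-bound), \code{handsoff} (row-bound) and
#'   \code{manifest} (patient_id, seed, age, sex, counts).
#' @export
simulate_cohort <- function(n, traj = trajectory_config(),
                            engine = engine_config(),
                            classifier = oracle_classifier(),
                            seed = 1L, cc_model = cc_artifact_model()) {
  check_scalar(n, "n", integer = TRUE)
  seeds <- with_seed(seed, sample.int(2^30, n))
  ivs <- lapply(seq_len(n), function(i) {
    simulate_intervention(traj, engine, classifier, seed = seeds[i],
                          patient_id = sprintf("P%05d", i),
                          cc_model = cc_model)
  })
  analyses <- do.call(rbind, lapply(ivs, `[[`, "analyses"))
  ho <- do.call(rbind, Filter(Negate(is.null),
                              lapply(ivs, `[[`, "handsoff")))
  manifest <- do.call(rbind, lapply(ivs, function(iv) {
    data.frame(patient_id = iv$patient_id, seed = iv$seed,
               age = iv$meta$age, sex = iv$meta$sex,
               n_phases = length(iv$phases),
               n_analyses = nrow(iv$analyses),
               n_shocks = length(iv$shocks),
               rosc = !is.na(iv$rosc_time),
               stringsAsFactors = FALSE)
  }))
  list(interventions = ivs, analyses = analyses, handsoff = ho,
       manifest = manifest)
}
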