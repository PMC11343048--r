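# Packaged study count tables --------------------------------------------------
#
# CSV transcriptions of the decision-count tables published by a clinical
# evaluation of the AWC shock advisory protocol (285 first-analysis
# shockable OHCA patients; 576 Standard analyses, 2011 during-CC analyses,
# 557 confirmation analyses).  The counts let the pooled-performance
# arithmetic be recomputed exactly; the printed percentage columns are
# retained for cross-checking only.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "awcsim")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install use
  if (!file.exists(p)) stop("fixture not found: ", file, call. = FALSE)
  p
}

#' Packaged study count tables
#'
#' \code{study_table1a}: global shock-advisory performance per rhythm
#' (Standard + Step1/Step2 sequence).  \code{study_table1b}: per-stage counts
#' (Standard, Step1 during CC, Step2 confirmation, and the Step1+Step2
#' sequence).  \code{study_table2}: side-by-side comparison of the AWC
#' protocol with another clinically evaluated two-stage algorithm
#' (cprINSIGHT), as printed.  \code{study_fig4_histogram}: patients binned by
#' their number of ill-advised confirmation analyses.  \code{study_summary}:
#' scalar study quantities (total analyses per stage, ill-advised counts,
#' hands-off medians).
#'
#' @return A data frame.
#' @export
study_table1a <- function() {
  utils::read.csv(fixture_path("study_table1a.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname study_table1a
#' @export
study_table1b <- function() {
  utils::read.csv(fixture_path("study_table1b.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname study_table1a
#' @export
study_table2 <- function() {
  utils::read.csv(fixture_path("study_table2.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname study_table1a
#' @export
study_fig4_histogram <- function() {
  utils::read.csv(fixture_path("study_fig4_histogram.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname study_table1a
#' @export
study_summary <- function() {
  utils::read.csv(fixture_path("study_summary.csv"),
                  stringsAsFactors = FALSE)
}

study_summary_value <- function(quantity) {
  s <- study_summary()
  v <- s$value[s$quantity == quantity]
  if (length(v) != 1L) stop("unknown summary quantity: ", quantity,
                            call. = FALSE)
  v
}

#' Per-stage, per-rhythm error rates implied by the study count table
#'
#' The misclassification probability of each stage on each primary rhythm:
#' missed shocks over analyses for shockable classes, false shock advice
#' over analyses for non-shockable classes.  Used to drive the noisy oracle
#' classifier so a simulated cohort reproduces the study's confusion
#' structure.
#'
#' @return Data frame with columns \code{stage}, \code{label}, \code{error}.
#' @export
#' @examples
#' table1b_error_rates()
table1b_error_rates <- function() {
  tb <- study_table1b()
  tb <- tb[tb$stage != "SEQUENCE" & tb$analyses > 0, , drop = FALSE]
  err <- ifelse(is_shockable(tb$rhythm) == "shockable",
                tb$no_shock_advised / tb$analyses,
                tb$shock_advised / tb$analyses)
  data.frame(stage = tb$stage, label = tb$rhythm, error = err,
             stringsAsFactors = FALSE)
}

#' Recompute the study's derived performance tables from raw counts
#'
#' Rebuilds, from the packaged per-stage counts alone: the Step1+Step2
#' sequence rows, the global pool (Standard + sequence), the clean-ECG pool
#' (Standard + Step2), the sequence accuracy, the confirmation-rate and
#' ill-advised metrics, and AHA goal checks — and cross-checks each derived
#' percentage against the printed value.
#'
#' @return List of data frames: \code{per_stage}, \code{sequence},
#'   \code{global_pool}, \code{clean_pool}, \code{rates} (scalar metrics),
#'   \code{goal_checks}.
#' @export
#' @examples
#' rep <- study_report()
#' rep$global_pool
study_report <- function() {
  tb <- study_table1b()
  t1a <- study_table1a()
  rhythms <- c("VF", "NSR", "ONR", "ASYS")

  row_of <- function(stage, rhythm) {
    tb[tb$stage == stage & tb$rhythm == rhythm, , drop = FALSE]
  }
  perf_of <- function(row) {
    if (row$analyses == 0) return(NA_real_)
    100 * (if (is_shockable(row$rhythm[1]) == "shockable")
      row$shock_advised else row$no_shock_advised) / row$analyses
  }

  seq_rows <- do.call(rbind, lapply(rhythms, function(rh) {
    s1 <- row_of("STEP1", rh); s2 <- row_of("STEP2", rh)
    if (s1$analyses == 0) {
      out <- data.frame(analyses = 0, shock_advised = 0,
                        no_shock_advised = 0)
    } else {
      out <- sequential_combination(
        s1[, c("analyses", "shock_advised", "no_shock_advised")],
        s2[, c("analyses", "shock_advised", "no_shock_advised")])
    }
    cbind(rhythm = rh, out, stringsAsFactors = FALSE)
  }))
  seq_rows$performance_pct <- vapply(seq_len(nrow(seq_rows)), function(i)
    perf_of(seq_rows[i, ]), numeric(1))

  pool_with <- function(stage2) {
    do.call(rbind, lapply(rhythms, function(rh) {
      s0 <- row_of("STANDARD", rh)
      other <- if (identical(stage2, "SEQUENCE_DERIVED")) {
        seq_rows[seq_rows$rhythm == rh,
                 c("analyses", "shock_advised", "no_shock_advised")]
      } else {
        row_of(stage2, rh)[, c("analyses", "shock_advised",
                               "no_shock_advised")]
      }
      out <- pool_counts(rbind(
        s0[, c("analyses", "shock_advised", "no_shock_advised")], other))
      cbind(rhythm = rh, out, stringsAsFactors = FALSE)
    }))
  }
  global_pool <- pool_with("SEQUENCE_DERIVED")
  clean_pool <- pool_with("STEP2")
  global_pool$performance_pct <- vapply(seq_len(nrow(global_pool)),
    function(i) perf_of(global_pool[i, ]), numeric(1))
  clean_pool$performance_pct <- vapply(seq_len(nrow(clean_pool)),
    function(i) perf_of(clean_pool[i, ]), numeric(1))

  # sequence accuracy: correct decisions over all sequence analyses
  correct <- sum(ifelse(is_shockable(seq_rows$rhythm) == "shockable",
                        seq_rows$shock_advised, seq_rows$no_shock_advised))
  total <- sum(seq_rows$analyses)

  n_step1 <- study_summary_value("step1_analyses")
  n_coa <- study_summary_value("step2_analyses")
  n_ill <- study_summary_value("ill_advised_coa")
  hist_ <- study_fig4_histogram()
  rates <- data.frame(
    metric = c("confirmation_rate_pct", "ill_advised_rate_pct",
               "sequence_accuracy_pct", "ill_advised_total_from_histogram",
               "patients_any_ill_advised"),
    value = c(100 * n_coa / n_step1,
              100 * n_ill / n_step1,
              100 * correct / total,
              sum(hist_$ill_advised_coa * hist_$patients),
              sum(hist_$patients[hist_$ill_advised_coa > 0])),
    stringsAsFactors = FALSE)

  goals <- aha_goals()
  goal_checks <- data.frame(
    rhythm = global_pool$rhythm,
    performance_pct = global_pool$performance_pct,
    goal_pct = 100 * unname(goals[global_pool$rhythm]),
    goal_met = global_pool$performance_pct >
      100 * unname(goals[global_pool$rhythm]),
    stringsAsFactors = FALSE)

  # cross-check every derived percentage against the printed tables
  chk <- function(derived, printed) {
    all(abs(derived - printed) < 0.06 | (is.na(derived) & is.na(printed)),
        na.rm = TRUE)
  }
  printed_seq <- tb[tb$stage == "SEQUENCE", ]
  consistent <- chk(seq_rows$performance_pct[seq_rows$analyses > 0],
                    printed_seq$performance_pct[printed_seq$analyses > 0]) &&
    chk(global_pool$performance_pct,
        t1a$performance_pct[match(global_pool$rhythm, t1a$rhythm)])

  list(per_stage = tb, sequence = seq_rows, global_pool = global_pool,
       clean_pool = clean_pool, rates = rates, goal_checks = goal_checks,
       consistent_with_printed = consistent)
}

#' Write the recomputed study tables to a directory
#'
#' Emits the full table set of \code{\link{study_report}} as CSV files plus
#' a formatted text summary.
#'
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_report <- function(dir) {
  rep <- study_report()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("per_stage", "sequence", "global_pool", "clean_pool",
               "rates", "goal_checks")) {
    utils::write.csv(rep[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  txt <- c(
    "Shock advisory performance recomputed from packaged count tables",
    "",
    sprintf("Global %s: %.1f%% (%d/%d)%s", rep$global_pool$rhythm,
            rep$global_pool$performance_pct,
            ifelse(is_shockable(rep$global_pool$rhythm) == "shockable",
                   rep$global_pool$shock_advised,
                   rep$global_pool$no_shock_advised),
            rep$global_pool$analyses,
            ifelse(rep$goal_checks$goal_met, " [goal met]", " [goal NOT met]")),
    "",
    sprintf("%s = %.1f", rep$rates$metric, rep$rates$value),
    "",
    sprintf("Derived values consistent with printed tables: %s",
            rep$consistent_with_printed))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
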