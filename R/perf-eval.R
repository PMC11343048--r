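# Performance evaluation --------------------------------------------------------
#
# Reproduces the evaluation pipeline of a clinical shock advisory study:
# per-stage decision-count tables, clustered sensitivity/specificity with a
# one-sided 90% lower confidence limit (ratio estimator over per-patient
# clusters), sequential Step1+Step2 combination, pooling across stages,
# confirmation-rate and ill-advised-confirmation metrics, and AHA
# performance-goal checks.

Z_LCL90 <- stats::qnorm(0.90)  # 1.281552

#' Per-stage decision counts by rhythm class
#'
#' Tabulates analysis records into count rows (patients, analyses, shock
#' advised, no shock advised) per stage and rhythm.  Intermediate and
#' undefined rhythms are routed to a separate descriptive table: they never
#' enter sensitivity/specificity denominators.
#'
#' @param records data frame of analysis records with columns
#'   \code{patient_id}, \code{stage}, \code{decision}, \code{truth_label}
#'   (as produced by \code{\link{simulate_cohort}}).
#' @param gated_only if TRUE (default) only Step1 records whose window ended
#'   at or after the result gate are counted.
#' @return List with \code{primary} (data frame: stage, rhythm, patients,
#'   analyses, shock_advised, no_shock_advised) and \code{intermediate}
#'   (same columns, for the excluded classes).
#' @export
stage_counts <- function(records, gated_only = TRUE) {
  stopifnot(all(c("patient_id", "stage", "decision", "truth_label")
                %in% names(records)))
  if (gated_only && "gated" %in% names(records)) {
    records <- records[records$gated | records$stage != "STEP1", ,
                       drop = FALSE]
  }
  tab <- function(df) {
    if (nrow(df) == 0L) {
      return(data.frame(stage = character(0), rhythm = character(0),
                        patients = integer(0), analyses = integer(0),
                        shock_advised = integer(0),
                        no_shock_advised = integer(0),
                        stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, lapply(
      split(df, list(df$stage, df$truth_label), drop = TRUE),
      function(g) data.frame(
        stage = g$stage[1], rhythm = g$truth_label[1],
        patients = length(unique(g$patient_id)),
        analyses = nrow(g),
        shock_advised = sum(g$decision == "SHOCK"),
        no_shock_advised = sum(g$decision == "NO_SHOCK"),
        stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out[order(out$stage, out$rhythm), , drop = FALSE]
  }
  cat_ <- is_shockable(records$truth_label)
  list(primary = tab(records[cat_ != "intermediate_or_excluded", ,
                             drop = FALSE]),
       intermediate = tab(records[cat_ == "intermediate_or_excluded", ,
                                  drop = FALSE]))
}

#' Clustered proportion with one-sided 90% lower confidence limit
#'
#' Ratio estimator for a proportion observed in clusters (multiple analyses
#' per patient): \eqn{\hat p = \sum x_i / \sum m_i} with variance
#' \eqn{\frac{K}{K-1} \sum_i (x_i - \hat p m_i)^2 / (\sum m_i)^2} over the
#' \eqn{K} clusters, and \eqn{LCL_{90} = \hat p - z_{0.90}\sqrt{Var}}
#' clamped to [0, 1].  With a single cluster the variance is undefined and
#' the LCL is returned as \code{NA} with a flag.
#'
#' @param x per-cluster success counts.
#' @param m per-cluster trial counts (same length, all > 0 clusters kept).
#' @param goal optional performance goal (proportion) to check strictly
#'   (\code{p_hat > goal}).
#' @return Object of class \code{awc_perf}: list with \code{p_hat},
#'   \code{se_hat}, \code{lcl90}, \code{numerator}, \code{denominator},
#'   \code{n_clusters}, \code{goal}, \code{goal_met},
#'   \code{single_cluster}.
#' @export
#' @examples
#' clustered_proportion(c(3, 1), c(4, 2))
clustered_proportion <- function(x, m, goal = NA_real_) {
  stopifnot(length(x) == length(m), all(m >= 0), all(x >= 0), all(x <= m))
  keep <- m > 0
  x <- x[keep]; m <- m[keep]
  K <- length(x)
  if (K == 0L) stop("no clusters with trials", call. = FALSE)
  p_hat <- sum(x) / sum(m)
  if (K == 1L) {
    est <- list(p_hat = p_hat, se_hat = NA_real_, lcl90 = NA_real_,
                numerator = sum(x), denominator = sum(m), n_clusters = 1L,
                goal = goal, goal_met = if (is.na(goal)) NA else p_hat > goal,
                single_cluster = TRUE)
    return(structure(est, class = "awc_perf"))
  }
  v <- (K / (K - 1)) * sum((x - p_hat * m)^2) / (sum(m)^2)
  se <- sqrt(v)
  lcl <- min(1, max(0, p_hat - Z_LCL90 * se))
  structure(list(p_hat = p_hat, se_hat = se, lcl90 = lcl,
                 numerator = sum(x), denominator = sum(m), n_clusters = K,
                 goal = goal,
                 goal_met = if (is.na(goal)) NA else p_hat > goal,
                 single_cluster = FALSE),
            class = "awc_perf")
}

#' @export
print.awc_perf <- function(x, ...) {
  cat(sprintf("%.1f%% (%d/%d), LCL90 %s, %d clusters%s\n",
              100 * x$p_hat, x$numerator, x$denominator,
              if (is.na(x$lcl90)) "NA" else sprintf("%.1f%%", 100 * x$lcl90),
              x$n_clusters,
              if (isTRUE(x$goal_met)) ", goal met"
              else if (isFALSE(x$goal_met)) ", goal NOT met" else ""))
  invisible(x)
}

#' Combine Step1 and Step2 counts into the analysis-sequence row
#'
#' A confirmation analysis follows every Step1 shock advice, so the sequence
#' over both stages advises a shock only when Step2 confirms it:
#' sequence shock = Step2 shock; sequence no-shock = Step1 no-shock +
#' Step2 no-shock; sequence analyses = Step1 analyses.
#'
#' @param step1,step2 single count rows (lists or one-row data frames with
#'   \code{analyses}, \code{shock_advised}, \code{no_shock_advised}).
#' @return One-row data frame of the combined sequence counts.
#' @export
#' @examples
#' sequential_combination(
#'   data.frame(analyses = 409, shock_advised = 380, no_shock_advised = 29),
#'   data.frame(analyses = 380, shock_advised = 374, no_shock_advised = 6))
sequential_combination <- function(step1, step2) {
  step1 <- as.list(step1); step2 <- as.list(step2)
  if (step2$analyses != step1$shock_advised) {
    stop("Step2 analyses must equal Step1 shock-advised count ",
         "(confirmation follows every Step1 shock advice)", call. = FALSE)
  }
  data.frame(
    analyses = step1$analyses,
    shock_advised = step2$shock_advised,
    no_shock_advised = step1$no_shock_advised + step2$no_shock_advised,
    stringsAsFactors = FALSE)
}

#' Pool count rows element-wise
#'
#' @param rows data frame of count rows of one rhythm class (columns
#'   \code{analyses}, \code{shock_advised}, \code{no_shock_advised};
#'   \code{patients} optional and summed if present).
#' @return One-row data frame of sums (a zero row for empty input).
#' @export
pool_counts <- function(rows) {
  cols <- intersect(c("patients", "analyses", "shock_advised",
                      "no_shock_advised"), names(rows))
  if (length(cols) == 0L) cols <- c("analyses", "shock_advised",
                                    "no_shock_advised")
  out <- as.data.frame(as.list(colSums(rows[, cols, drop = FALSE])))
  if (nrow(rows) == 0L) out[1, ] <- 0
  out
}

#' Confirmation-analysis metrics from Step1 records
#'
#' The confirmation rate is the share of during-CC analyses that advised a
#' shock (hence triggered a confirmation pause); an ill-advised confirmation
#' is a Step1 shock advice issued while the underlying rhythm was
#' non-shockable.
#'
#' @param records analysis records (all stages accepted; Step1 rows are
#'   selected, gated results only when a \code{gated} column is present).
#' @return List with \code{n_step1}, \code{n_coa}, \code{coa_rate},
#'   \code{ill_advised_count}, \code{ill_advised_rate},
#'   \code{per_patient_histogram} (table of patients by ill-advised count)
#'   and \code{rhythm_mix} (table of ill-advised underlying rhythms).
#' @export
confirmation_metrics <- function(records) {
  s1 <- records[records$stage == "STEP1", , drop = FALSE]
  if ("gated" %in% names(s1)) s1 <- s1[s1$gated, , drop = FALSE]
  n <- nrow(s1)
  coa <- s1$decision == "SHOCK"
  ill <- coa & is_shockable(s1$truth_label) == "non_shockable"
  per_pat <- tapply(ill, s1$patient_id, sum)
  list(n_step1 = n,
       n_coa = sum(coa),
       coa_rate = if (n > 0) sum(coa) / n else NA_real_,
       ill_advised_count = sum(ill),
       ill_advised_rate = if (n > 0) sum(ill) / n else NA_real_,
       per_patient_histogram = table(per_pat),
       rhythm_mix = table(s1$truth_label[ill]))
}

#' AHA performance goals per rhythm class
#'
#' Published AED arrhythmia-analysis goals for artifact-free signals:
#' sensitivity above 90% for coarse VF and rapid VT; specificity above 99%
#' for NSR and above 95% for ONR and asystole.
#'
#' @return Named numeric vector of goal proportions.
#' @export
aha_goals <- function() {
  c(VF = 0.90, RAPID_VT = 0.90, NSR = 0.99, ONR = 0.95, ASYS = 0.95)
}

#' Check an estimate against its performance goal
#'
#' Goal attainment is strict: the point estimate must exceed the goal.
#'
#' @param estimate an \code{awc_perf} object or a proportion.
#' @param goal goal proportion.
#' @return Logical.
#' @export
goal_check <- function(estimate, goal) {
  p <- if (inherits(estimate, "awc_perf")) estimate$p_hat else estimate
  check_prob(goal, "goal")
  p > goal
}

#' Clustered estimates for every stage and rhythm of a simulated cohort
#'
#' Convenience wrapper: builds per-patient clusters from analysis records
#' and returns one \code{\link{clustered_proportion}} per stage and primary
#' rhythm class, measuring sensitivity (shock advised) for shockable and
#' specificity (no shock advised) for non-shockable classes.
#'
#' @param records analysis records (see \code{\link{stage_counts}}).
#' @param cluster \code{"patient"} (default) or \code{"phase"}: the cluster
#'   unit for the variance estimator.
#' @return Data frame: stage, rhythm, measure, p_hat, lcl90, numerator,
#'   denominator, n_clusters, goal, goal_met.
#' @export
cohort_performance <- function(records, cluster = c("patient", "phase")) {
  cluster <- match.arg(cluster)
  if ("gated" %in% names(records)) {
    records <- records[records$gated | records$stage != "STEP1", ,
                       drop = FALSE]
  }
  cat_ <- is_shockable(records$truth_label)
  records <- records[cat_ != "intermediate_or_excluded", , drop = FALSE]
  records$success <- ifelse(
    is_shockable(records$truth_label) == "shockable",
    records$decision == "SHOCK", records$decision == "NO_SHOCK")
  key <- if (cluster == "patient") records$patient_id else
    paste(records$patient_id, records$phase_id, sep = "/")
  goals <- aha_goals()
  out <- lapply(split(records, list(records$stage, records$truth_label),
                      drop = TRUE), function(g) {
    k <- if (cluster == "patient") g$patient_id else
      paste(g$patient_id, g$phase_id, sep = "/")
    x <- tapply(g$success, k, sum)
    m <- tapply(rep(1L, nrow(g)), k, sum)
    est <- clustered_proportion(as.numeric(x), as.numeric(m),
                                goal = unname(goals[g$truth_label[1]]))
    data.frame(stage = g$stage[1], rhythm = g$truth_label[1],
               measure = if (is_shockable(g$truth_label[1]) == "shockable")
                 "sensitivity" else "specificity",
               p_hat = est$p_hat, lcl90 = est$lcl90,
               numerator = est$numerator, denominator = est$denominator,
               n_clusters = est$n_clusters, goal = est$goal,
               goal_met = est$goal_met, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$stage, out$rhythm), , drop = FALSE]
}
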