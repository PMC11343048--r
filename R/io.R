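# File formats: JSON-lines event logs, signal CSV, WFDB export, YAML config.

EVENT_LOG_SCHEMA <- "awcsim-events-1"
EVENT_TYPES <- c("CC_START", "CC_STOP", "ANALYSIS_START", "ANALYSIS_END",
                 "DECISION", "SHOCK", "ROSC", "END")

#' Write / read a JSON-lines event log
#'
#' One JSON object per line.  The first line is a header object carrying the
#' schema version and optional metadata; subsequent lines are events with
#' fields \code{t_s} (seconds, 3 decimals), \code{type}, and optional
#' \code{stage}, \code{decision}, \code{phase_id}.  Events must be
#' time-sorted.  \code{read_event_log} validates the schema and ordering and
#' reports the offending line number on malformed input, so that
#' read(write(x)) returns \code{x} exactly.
#'
#' @param events data frame with columns \code{t_s}, \code{type},
#'   \code{stage}, \code{decision}, \code{phase_id} (as produced by the
#'   engine/simulator).
#' @param path file path.
#' @param meta optional named list stored in the header line.
#' @return \code{write_event_log}: the path, invisibly.
#'   \code{read_event_log}: the event data frame, with the header metadata
#'   attached as attribute \code{"meta"}.
#' @export
write_event_log <- function(events, path, meta = list()) {
  stopifnot(is.data.frame(events),
            all(c("t_s", "type") %in% names(events)))
  if (is.unsorted(events$t_s)) {
    stop("events must be time-sorted before writing", call. = FALSE)
  }
  bad <- setdiff(unique(events$type), EVENT_TYPES)
  if (length(bad)) stop("unknown event type(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  hdr <- jsonlite::toJSON(c(list(schema = EVENT_LOG_SCHEMA), meta),
                          auto_unbox = TRUE, digits = NA, null = "null")
  lines <- vapply(seq_len(nrow(events)), function(i) {
    ev <- list(t_s = round_ms(events$t_s[i]), type = events$type[i])
    for (f in c("stage", "decision", "phase_id")) {
      v <- events[[f]][i]
      if (!is.null(v) && !is.na(v)) ev[[f]] <- v
    }
    as.character(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(c(as.character(hdr), lines), path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty event log: ", path, call. = FALSE)
  parse_line <- function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) NULL)
    if (is.null(obj)) stop("malformed JSON at line ", i, " of ", path,
                           call. = FALSE)
    obj
  }
  hdr <- parse_line(1L)
  if (!identical(hdr$schema, EVENT_LOG_SCHEMA)) {
    stop("line 1: unknown or missing schema (expected ",
         EVENT_LOG_SCHEMA, ")", call. = FALSE)
  }
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    ev <- parse_line(i)
    if (is.null(ev$t_s) || is.null(ev$type)) {
      stop("line ", i, ": event missing t_s/type", call. = FALSE)
    }
    if (!ev$type %in% EVENT_TYPES) {
      stop("line ", i, ": unknown event type '", ev$type, "'",
           call. = FALSE)
    }
    data.frame(t_s = as.numeric(ev$t_s), type = ev$type,
               stage = ev$stage %||% NA_character_,
               decision = ev$decision %||% NA_character_,
               phase_id = as.integer(ev$phase_id %||% NA_integer_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(t_s = numeric(0), type = character(0),
                      stage = character(0), decision = character(0),
                      phase_id = integer(0), stringsAsFactors = FALSE)
  }
  if (is.unsorted(out$t_s)) {
    stop("event log not time-sorted: ", path, call. = FALSE)
  }
  meta <- hdr[setdiff(names(hdr), "schema")]
  attr(out, "meta") <- meta
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a two-channel signal CSV
#'
#' Plain CSV with a one-line comment header carrying the sampling rate and
#' per-column units, e.g. \code{# fs=500 Hz; ecg_uv in uV; impedance_ohm in
#' Ohm}, followed by standard CSV columns.
#'
#' @param ecg numeric ECG samples in microvolts.
#' @param impedance numeric impedance samples in Ohm (same length), or NULL
#'   for a single-channel file.
#' @param fs sampling rate in Hz.
#' @param path file path.
#' @return \code{write_signal_csv}: the path, invisibly.
#'   \code{read_signal_csv}: list with \code{ecg}, \code{impedance} (or
#'   NULL), \code{fs}.
#' @export
write_signal_csv <- function(ecg, impedance = NULL, fs, path) {
  stopifnot(is.numeric(ecg), length(ecg) > 0, fs > 0)
  if (!is.null(impedance) && length(impedance) != length(ecg)) {
    stop("ecg and impedance lengths differ", call. = FALSE)
  }
  cols <- "ecg_uv in uV"
  df <- data.frame(ecg_uv = ecg)
  if (!is.null(impedance)) {
    cols <- c(cols, "impedance_ohm in Ohm")
    df$impedance_ohm <- impedance
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# fs=%s Hz; %s", format(fs),
                     paste(cols, collapse = "; ")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("^# fs=([0-9.]+) Hz", hdr))[[1]]
  if (length(m) != 2L) stop("missing fs header line in ", path,
                            call. = FALSE)
  fs <- as.numeric(m[2])
  df <- utils::read.csv(path, skip = 1L)
  list(ecg = df$ecg_uv,
       impedance = if ("impedance_ohm" %in% names(df)) df$impedance_ohm,
       fs = fs)
}

#' Minimal WFDB record export / import (format 16)
#'
#' Writes a two-signal WFDB-compatible record: a \code{.hea} text header and
#' a \code{.dat} file of interleaved little-endian 16-bit integers.  Channel
#' 1 is ECG (gain in ADC units per mV), channel 2 impedance (ADC units per
#' Ohm).  Intended for interoperability with standard WFDB readers, not as a
#' full implementation of the format.
#'
#' @param record record path without extension (directory must exist).
#' @param ecg,impedance,fs as in \code{\link{write_signal_csv}}; impedance
#'   is required here.
#' @param ecg_gain ADC units per millivolt for the ECG channel.
#' @param imp_gain ADC units per Ohm for the impedance channel.
#' @return \code{write_wfdb}: the record name, invisibly.
#'   \code{read_wfdb}: list with \code{ecg} (uV), \code{impedance} (Ohm),
#'   \code{fs}.
#' @export
write_wfdb <- function(record, ecg, impedance, fs,
                       ecg_gain = 200, imp_gain = 100) {
  stopifnot(length(ecg) == length(impedance), fs > 0)
  n <- length(ecg)
  base <- basename(record)
  # quantize: ECG stored in ADC units of (1/ecg_gain) mV, i.e. 1000/ecg_gain uV
  a1 <- as.integer(round(ecg * ecg_gain / 1000))
  a2 <- as.integer(round(impedance * imp_gain))
  lim <- 32767L
  if (any(abs(a1) > lim) || any(abs(a2) > lim)) {
    stop("signal exceeds 16-bit range at the chosen gain", call. = FALSE)
  }
  dat <- integer(2L * n)
  dat[seq(1L, 2L * n, by = 2L)] <- a1
  dat[seq(2L, 2L * n, by = 2L)] <- a2
  con <- file(paste0(record, ".dat"), "wb")
  writeBin(dat, con, size = 2L, endian = "little")
  close(con)
  hea <- c(sprintf("%s 2 %s %d", base, format(fs), n),
           sprintf("%s.dat 16 %s/mV 16 0 %d 0 0 ECG", base,
                   format(ecg_gain), a1[1]),
           sprintf("%s.dat 16 %s/Ohm 16 0 %d 0 0 IMP", base,
                   format(imp_gain), a2[1]))
  writeLines(hea, paste0(record, ".hea"))
  invisible(record)
}

#' @rdname write_wfdb
#' @export
read_wfdb <- function(record) {
  hea <- readLines(paste0(record, ".hea"))
  top <- strsplit(hea[1], "[ \t]+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  if (nsig != 2L) stop("expected 2 signals, found ", nsig, call. = FALSE)
  gain_of <- function(line) {
    f <- strsplit(line, "[ \t]+")[[1]]
    as.numeric(sub("/.*$", "", f[3]))
  }
  g1 <- gain_of(hea[2]); g2 <- gain_of(hea[3])
  con <- file(paste0(record, ".dat"), "rb")
  raw <- readBin(con, "integer", n = 2L * n, size = 2L, signed = TRUE,
                 endian = "little")
  close(con)
  list(ecg = raw[seq(1L, 2L * n, by = 2L)] * 1000 / g1,
       impedance = raw[seq(2L, 2L * n, by = 2L)] / g2,
       fs = fs)
}

#' Run configuration: YAML round trip
#'
#' A run configuration bundles the engine timing constants, trajectory
#' parameters, classifier selection, cohort size and seed into one
#' serializable object.  \code{write_run_config}/\code{read_run_config}
#' round-trip it through a YAML file bit-exactly.
#'
#' @param engine \code{\link{engine_config}}.
#' @param trajectory \code{\link{trajectory_config}}.
#' @param classifier one of \code{"oracle"}, \code{"noisy_oracle"},
#'   \code{"reference"}.
#' @param cohort_size number of simulated interventions.
#' @param seed integer master seed.
#' @param out output directory for runs driven by this config.
#' @return \code{run_config}: a list of class \code{awc_run_config}.
#' @export
run_config <- function(engine = engine_config(),
                       trajectory = trajectory_config(),
                       classifier = c("oracle", "noisy_oracle", "reference"),
                       cohort_size = 10L, seed = 1L, out = "awcsim-out") {
  classifier <- match.arg(classifier)
  check_scalar(cohort_size, "cohort_size"); check_scalar(seed, "seed")
  structure(list(engine = engine, trajectory = trajectory,
                 classifier = classifier,
                 cohort_size = as.integer(cohort_size),
                 seed = as.integer(seed), out = out),
            class = "awc_run_config")
}

#' @rdname run_config
#' @param config an \code{awc_run_config}.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "awc_run_config"))
  x <- list(
    engine = unclass(config$engine),
    trajectory = {
      tr <- unclass(config$trajectory)
      tr$refib_hazard <- NULL  # derived, recomputed on read
      tr$post_shock_mix <- as.list(tr$post_shock_mix)
      tr$initial_shockable_mix <- as.list(tr$initial_shockable_mix)
      tr
    },
    classifier = config$classifier,
    cohort_size = config$cohort_size,
    seed = config$seed,
    out = config$out)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (req in c("engine", "trajectory", "classifier", "cohort_size",
                "seed")) {
    if (is.null(x[[req]])) stop("config missing field: ", req,
                                call. = FALSE)
  }
  tr <- x$trajectory
  trajectory <- trajectory_config(
    refib_within_60s_prob = tr$refib_within_60s_prob,
    post_shock_mix = unlist(tr$post_shock_mix),
    shock_success_prob = tr$shock_success_prob,
    rosc_prob_per_phase = tr$rosc_prob_per_phase,
    initial_shockable_mix = unlist(tr$initial_shockable_mix),
    observation_limit = tr$observation_limit)
  engine <- do.call(engine_config, x$engine)
  run_config(engine = engine, trajectory = trajectory,
             classifier = x$classifier, cohort_size = x$cohort_size,
             seed = x$seed, out = x$out %||% "awcsim-out")
}

#' @export
print.awc_run_config <- function(x, ...) {
  cat("<awc_run_config>\n")
  cat("  classifier:", x$classifier, " cohort:", x$cohort_size,
      " seed:", x$seed, "\n")
  cat("  out:", x$out, "\n")
  invisible(x)
}
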