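#' Construct an accelerometer session
#'
#' @param participant_id Identifier.
#' @param rate_hz Sampling rate in Hz.
#' @param samples N x 3 numeric matrix of acceleration in g (columns
#'   `ax_g`, `ay_g`, `az_g`).
#' @param labels Length-N 0/1 vector of per-sample SIB labels.
#' @param prompts Length-N 0/1 vector of per-sample prompt indicators.
#' @return An object of class `accel_session`.
#' @export
accel_session <- function(participant_id, rate_hz, samples,
                          labels = integer(nrow(samples)),
                          prompts = integer(nrow(samples))) {
  assert_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L || nrow(samples) < 1L || !is.numeric(samples)) {
    stop("`samples` must be a numeric N x 3 matrix", call. = FALSE)
  }
  colnames(samples) <- c("ax_g", "ay_g", "az_g")
  n <- nrow(samples)
  if (length(labels) != n || length(prompts) != n) {
    stop("`labels` and `prompts` must match the number of samples", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || !all(prompts %in% c(0, 1))) {
    stop("`labels` and `prompts` must be 0/1", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id), rate_hz = rate_hz,
         samples = samples, labels = as.integer(labels),
         prompts = as.integer(prompts)),
    class = "accel_session"
  )
}

#' @export
print.accel_session <- function(x, ...) {
  cat(sprintf("<accel_session> %s: %d samples @ %g Hz (%.1f s), %d SIB samples (%.1f%%)\n",
              x$participant_id, nrow(x$samples), x$rate_hz,
              nrow(x$samples) / x$rate_hz, sum(x$labels),
              100 * mean(x$labels)))
  invisible(x)
}

SESSION_COLUMNS <- c("time_s", "ax_g", "ay_g", "az_g", "label", "prompt")

#' Write / read a session as delimited text
#'
#' Sessions are stored as comma-separated text with the header
#' `time_s, ax_g, ay_g, az_g, label, prompt`, one row per sample.
#'
#' @param session An `accel_session`.
#' @param path File path.
#' @param participant_id Identifier to attach on read.
#' @return `read_session` returns an `accel_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "accel_session"))
  n <- nrow(session$samples)
  df <- data.frame(
    time_s = (seq_len(n) - 1) / session$rate_hz,
    ax_g = session$samples[, 1], ay_g = session$samples[, 2],
    az_g = session$samples[, 3],
    label = session$labels, prompt = session$prompts
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path, participant_id) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(SESSION_COLUMNS, names(df))
  if (length(missing)) {
    stop(sprintf("session file %s is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("time_s", "ax_g", "ay_g", "az_g")) {
    if (!is.numeric(df[[col]])) {
      stop(sprintf("column %s must be numeric", col), call. = FALSE)
    }
  }
  for (col in c("label", "prompt")) {
    if (!all(df[[col]] %in% c(0, 1))) {
      stop(sprintf("column %s must contain only 0/1", col), call. = FALSE)
    }
  }
  if (nrow(df) < 2) stop("session file must contain at least 2 samples", call. = FALSE)
  rate <- 1 / stats::median(diff(df$time_s))
  accel_session(participant_id, rate,
                as.matrix(df[, c("ax_g", "ay_g", "az_g")]),
                df$label, df$prompt)
}

#' Write a cohort to a directory
#'
#' One CSV per participant plus a YAML manifest listing the files, sampling
#' rate, and participant ids.
#'
#' @param cohort Named list of `accel_session` objects.
#' @param dir Output directory (created if needed).
#' @return `read_cohort` returns a named list of sessions.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(names(cohort), function(id) {
    f <- file.path(dir, paste0("session_", id, ".csv"))
    write_session(cohort[[id]], f)
    basename(f)
  }, character(1))
  manifest <- list(
    participants = lapply(names(cohort), function(id) {
      list(participant_id = id, file = unname(files[[id]]),
           rate_hz = cohort[[id]]$rate_hz)
    })
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  sessions <- lapply(manifest$participants, function(p) {
    read_session(file.path(dir, p$file), p$participant_id)
  })
  names(sessions) <- vapply(manifest$participants, `[[`, character(1),
                            "participant_id")
  sessions
}

#' Low-pass Butterworth filter of a session
#'
#' Causal (single-pass, recursive) 4th-order Butterworth low-pass filtering
#' of each acceleration channel, with unit DC gain. Causal filtering is used
#' rather than zero-phase filtering to match a real-time monitoring setting;
#' the filtered signal feeds the time- and frequency-domain features while
#' nonlinear features are computed on raw data.
#'
#' @param session An `accel_session`.
#' @param cutoff_hz Cutoff frequency in Hz (default 20); must be below the
#'   Nyquist frequency.
#' @param order Filter order (default 4).
#' @return An `accel_session` with filtered samples.
#' @export
butterworth_lowpass <- function(session, cutoff_hz = 20, order = 4) {
  stopifnot(inherits(session, "accel_session"))
  assert_scalar_number(cutoff_hz, "cutoff_hz", positive = TRUE)
  if (cutoff_hz >= session$rate_hz / 2) {
    stop(sprintf("cutoff_hz (%g) must be below Nyquist (%g Hz)",
                 cutoff_hz, session$rate_hz / 2), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (session$rate_hz / 2), type = "low")
  filtered <- apply(session$samples, 2, function(x) {
    as.numeric(signal::filter(bf, x))
  })
  out <- session
  out$samples <- filtered
  colnames(out$samples) <- colnames(session$samples)
  out
}

#' Window-level presence labeling
#'
#' A window is labeled positive when any sample in its span is positive
#' (presence rule); the prompt indicator is aggregated the same way.
#'
#' @param span_labels 0/1 vector of per-sample labels over the window span.
#' @return 0 or 1.
#' @export
label_window <- function(span_labels) {
  as.integer(any(span_labels == 1))
}

#' Segment a session into overlapping analysis windows
#'
#' Cuts the session into `window_s`-second windows advancing by `step_s`
#' seconds (default 2-s windows with 1-s overlap), aligned to the start of
#' the session; a trailing partial segment is dropped. Each window retains
#' both the raw samples (input to the nonlinear motor-variability features)
#' and the low-pass-filtered samples (input to the time/frequency features),
#' together with its presence-rule outcome and prompt flag.
#'
#' @param session An `accel_session`.
#' @param window_s Window length in seconds (default 2).
#' @param step_s Step between window starts in seconds (default 1).
#' @param cutoff_hz,filter_order Passed to [butterworth_lowpass()].
#' @return A `window_set`: list with `windows` (list of `sib_window`),
#'   `rate_hz`, `window_s`, `step_s`.
#' @export
segment_windows <- function(session, window_s = 2, step_s = 1,
                            cutoff_hz = 20, filter_order = 4) {
  stopifnot(inherits(session, "accel_session"))
  assert_scalar_number(window_s, "window_s", positive = TRUE)
  assert_scalar_number(step_s, "step_s", positive = TRUE)
  n <- nrow(session$samples)
  w <- round(window_s * session$rate_hz)
  if (n < w) {
    stop(sprintf("session %s is shorter (%.2f s) than one %g-s window",
                 session$participant_id, n / session$rate_hz, window_s),
         call. = FALSE)
  }
  filt <- butterworth_lowpass(session, cutoff_hz, filter_order)
  n_windows <- floor((n / session$rate_hz - window_s) / step_s) + 1
  windows <- lapply(seq_len(n_windows) - 1, function(k) {
    i0 <- round(k * step_s * session$rate_hz) + 1
    idx <- i0:(i0 + w - 1)
    structure(
      list(participant_id = session$participant_id,
           start_s = k * step_s,
           rate_hz = session$rate_hz,
           raw = session$samples[idx, , drop = FALSE],
           filtered = filt$samples[idx, , drop = FALSE],
           outcome = label_window(session$labels[idx]),
           prompt = label_window(session$prompts[idx])),
      class = "sib_window"
    )
  })
  structure(
    list(windows = windows, rate_hz = session$rate_hz,
         window_s = window_s, step_s = step_s),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  outcomes <- vapply(x$windows, `[[`, integer(1), "outcome")
  cat(sprintf("<window_set> %d windows of %g s (step %g s) @ %g Hz; %d positive (%.1f%%)\n",
              length(x$windows), x$window_s, x$step_s, x$rate_hz,
              sum(outcomes), 100 * mean(outcomes)))
  invisible(x)
}
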