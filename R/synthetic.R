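#' Describe one synthetic participant
#'
#' A participant profile parameterizes the synthetic session generator:
#' the dominant burst frequency and amplitude of self-injurious movement
#' episodes, the background activity level, and the episode process. Profiles
#' also carry an optional per-feature slope shift used by the feature-level
#' multilevel simulator.
#'
#' @param participant_id Identifier (coerced to character).
#' @param sib_frequency_hz Dominant episode burst frequency in Hz; must lie
#'   below the Nyquist frequency of the session it is used in (30 Hz at the
#'   60 Hz default sampling rate). Rhythmic SIB such as head banging or
#'   hitting typically drives the wrist at a few Hz, so 2--5 is realistic.
#' @param sib_amplitude_g Episode burst amplitude in g.
#' @param baseline_activity_scale Standard-deviation scale of the background
#'   (non-episode) motion, in g.
#' @param episode_rate_per_min Expected number of episodes per minute
#'   (Poisson); 0 yields an episode-free session.
#' @param episode_duration_range_s Length-2 vector, low <= high, episode
#'   duration bounds in seconds (uniform draw).
#' @param random_slope_shift Optional numeric vector of per-feature slope
#'   deviations, consumed by the feature-level simulator.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(participant_id,
                                sib_frequency_hz = 3,
                                sib_amplitude_g = 0.8,
                                baseline_activity_scale = 0.15,
                                episode_rate_per_min = 2,
                                episode_duration_range_s = c(2, 8),
                                random_slope_shift = numeric(0)) {
  assert_scalar_number(sib_frequency_hz, "sib_frequency_hz", positive = TRUE)
  assert_scalar_number(sib_amplitude_g, "sib_amplitude_g", positive = TRUE)
  assert_scalar_number(baseline_activity_scale, "baseline_activity_scale", positive = TRUE)
  assert_scalar_number(episode_rate_per_min, "episode_rate_per_min", nonneg = TRUE)
  if (length(episode_duration_range_s) != 2L ||
      any(episode_duration_range_s <= 0) ||
      episode_duration_range_s[1] > episode_duration_range_s[2]) {
    stop("`episode_duration_range_s` must be c(low, high) with 0 < low <= high",
         call. = FALSE)
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      sib_frequency_hz = sib_frequency_hz,
      sib_amplitude_g = sib_amplitude_g,
      baseline_activity_scale = baseline_activity_scale,
      episode_rate_per_min = episode_rate_per_min,
      episode_duration_range_s = as.numeric(episode_duration_range_s),
      random_slope_shift = as.numeric(random_slope_shift)
    ),
    class = "participant_profile"
  )
}

#' Describe a synthetic cohort
#'
#' @param profiles List of [participant_profile()] objects, one per participant.
#' @param session_duration_s Session length in seconds (same for all).
#' @param sampling_rate_hz Sampling rate in Hz (default 60).
#' @param seed Master seed; per-participant child seeds are derived from it
#'   deterministically.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(profiles, session_duration_s, sampling_rate_hz = 60,
                        seed = 1L) {
  if (!is.list(profiles) || length(profiles) == 0L ||
      !all(vapply(profiles, inherits, logical(1), "participant_profile"))) {
    stop("`profiles` must be a non-empty list of participant_profile objects",
         call. = FALSE)
  }
  assert_scalar_number(session_duration_s, "session_duration_s", positive = TRUE)
  assert_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  for (p in profiles) {
    if (p$sib_frequency_hz >= sampling_rate_hz / 2) {
      stop(sprintf("profile %s: sib_frequency_hz must be below Nyquist (%g Hz)",
                   p$participant_id, sampling_rate_hz / 2), call. = FALSE)
    }
  }
  ids <- vapply(profiles, `[[`, character(1), "participant_id")
  if (anyDuplicated(ids)) stop("duplicate participant ids", call. = FALSE)
  structure(
    list(
      n_participants = length(profiles),
      session_duration_s = session_duration_s,
      sampling_rate_hz = sampling_rate_hz,
      seed = as.integer(seed),
      profiles = profiles
    ),
    class = "cohort_spec"
  )
}

## 1/f ("pink") noise via spectral shaping of white noise, unit variance.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  k <- 0:(n - 1)
  k <- pmin(k, n - k)       # two-sided frequency index
  k[1] <- 1                 # keep DC finite
  spec <- spec / sqrt(k)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate one synthetic accelerometer session
#'
#' Produces a tri-axial 60 Hz (by default) acceleration stream with sparse
#' rhythmic SIB episodes superimposed on background motion, plus per-sample
#' binary SIB labels and a per-sample prompt indicator. Background motion is
#' pink (1/f) noise plus a slow 0.1 Hz postural drift; episodes are
#' sinusoidal bursts with per-episode jitter in frequency, amplitude, phase,
#' and channel gain. Episode onsets are uniform over the session without
#' overlap; episodes are truncated at the session end. About half of the
#' episodes are preceded by a 2-s prompt interval, emulating in-session
#' behavioral prompts.
#'
#' @param profile A [participant_profile()].
#' @param duration_s Session duration in seconds (>= 2).
#' @param rate_hz Sampling rate in Hz.
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @param episode_onsets_s,episode_durations_s Optional explicit episode
#'   placement (both vectors of equal length, seconds); overrides the random
#'   episode process. Useful for controlled experiments.
#' @param prompt_prob Probability that an episode is preceded by a prompt.
#' @return An `accel_session`: list with `participant_id`, `rate_hz`,
#'   `samples` (N x 3 matrix, g), `labels` and `prompts` (length-N 0/1).
#' @export
generate_session <- function(profile, duration_s, rate_hz = 60, seed = 1L,
                             episode_onsets_s = NULL,
                             episode_durations_s = NULL,
                             prompt_prob = 0.5) {
  stopifnot(inherits(profile, "participant_profile"))
  assert_scalar_number(duration_s, "duration_s", positive = TRUE)
  assert_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  if (duration_s < 2) {
    stop("`duration_s` must be at least one 2-s analysis window", call. = FALSE)
  }
  n <- round(duration_s * rate_hz)
  tt <- (seq_len(n) - 1) / rate_hz

  with_seed(seed, {
    ## background: pink noise per channel + slow drift
    samples <- vapply(1:3, function(ch) {
      drift_phase <- stats::runif(1, 0, 2 * pi)
      profile$baseline_activity_scale * pink_noise(n) +
        0.02 * sin(2 * pi * 0.1 * tt + drift_phase)
    }, numeric(n))
    colnames(samples) <- c("ax_g", "ay_g", "az_g")

    ## episode placement
    if (is.null(episode_onsets_s)) {
      n_ep <- stats::rpois(1, profile$episode_rate_per_min * duration_s / 60)
      onsets <- numeric(0)
      durs <- numeric(0)
      if (n_ep > 0) {
        for (e in seq_len(n_ep)) {
          d <- stats::runif(1, profile$episode_duration_range_s[1],
                            profile$episode_duration_range_s[2])
          placed <- FALSE
          for (try in 1:100) {           # rejection sampling: no overlap
            o <- stats::runif(1, 0, duration_s)
            if (!length(onsets) ||
                all(o + d <= onsets | o >= onsets + durs)) {
              onsets <- c(onsets, o); durs <- c(durs, d)
              placed <- TRUE
              break
            }
          }
          if (!placed) next              # session saturated; drop episode
        }
      }
    } else {
      if (length(episode_onsets_s) != length(episode_durations_s)) {
        stop("episode onset/duration vectors must have equal length", call. = FALSE)
      }
      onsets <- as.numeric(episode_onsets_s)
      durs <- as.numeric(episode_durations_s)
    }

    labels <- integer(n)
    prompts <- integer(n)
    if (length(onsets)) {
      ord <- order(onsets)
      onsets <- onsets[ord]; durs <- durs[ord]
      for (e in seq_along(onsets)) {
        i0 <- floor(onsets[e] * rate_hz) + 1
        i1 <- min(n, i0 + round(durs[e] * rate_hz) - 1)
        if (i0 > n) next
        idx <- i0:i1
        labels[idx] <- 1L
        f <- profile$sib_frequency_hz * stats::runif(1, 0.9, 1.1)
        a <- profile$sib_amplitude_g * stats::runif(1, 0.8, 1.2)
        gains <- stats::runif(3, 0.5, 1)
        phase <- stats::runif(1, 0, 2 * pi)
        ## smooth on/off ramp over ~0.1 s avoids clicks at episode edges
        env <- pmin(1, pmin(seq_along(idx), rev(seq_along(idx))) / (0.1 * rate_hz))
        burst <- a * sin(2 * pi * f * tt[idx] + phase) * env
        for (ch in 1:3) samples[idx, ch] <- samples[idx, ch] + gains[ch] * burst
        if (stats::runif(1) < prompt_prob) {
          p1 <- i0 - 1
          p0 <- max(1, i0 - round(2 * rate_hz))
          if (p1 >= p0) prompts[p0:p1] <- 1L
        }
      }
    }

    accel_session(profile$participant_id, rate_hz, samples, labels, prompts)
  })
}

#' Generate a synthetic cohort
#'
#' One session per profile in the spec; each participant's session is
#' generated under a child seed derived deterministically from the cohort
#' seed, so participants are mutually independent yet the whole cohort is
#' reproducible from one integer.
#'
#' @param spec A [cohort_spec()].
#' @return Named list of `accel_session` objects (names = participant ids).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sessions <- lapply(seq_along(spec$profiles), function(i) {
    generate_session(spec$profiles[[i]], spec$session_duration_s,
                     spec$sampling_rate_hz, seed = derive_seed(spec$seed, i))
  })
  names(sessions) <- vapply(spec$profiles, `[[`, character(1), "participant_id")
  sessions
}

#' Serialize / restore a cohort spec as a YAML config file
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `read_cohort_spec` returns the restored `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- list(
    session_duration_s = spec$session_duration_s,
    sampling_rate_hz = spec$sampling_rate_hz,
    seed = spec$seed,
    profiles = lapply(spec$profiles, function(p) {
      p <- unclass(p)
      p$random_slope_shift <- as.list(p$random_slope_shift)
      p
    })
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  profiles <- lapply(x$profiles, function(p) {
    participant_profile(
      participant_id = p$participant_id,
      sib_frequency_hz = p$sib_frequency_hz,
      sib_amplitude_g = p$sib_amplitude_g,
      baseline_activity_scale = p$baseline_activity_scale,
      episode_rate_per_min = p$episode_rate_per_min,
      episode_duration_range_s = unlist(p$episode_duration_range_s),
      random_slope_shift = as.numeric(unlist(p$random_slope_shift))
    )
  })
  cohort_spec(profiles, x$session_duration_s, x$sampling_rate_hz, x$seed)
}

#' Specify a feature-level multilevel simulation
#'
#' Defines the two-level logistic data-generating process used for model
#' recovery experiments: window-level features X are standard normal; each
#' participant j draws an intercept `alpha_j ~ N(gamma_0, intercept_sd^2)`
#' and slopes `beta_jk ~ N(gamma_k, slope_sds[k]^2)` (mutually independent);
#' the window outcome is Bernoulli with probability
#' `plogis(alpha_j + sum_k beta_jk X_k)`.
#'
#' @param n_participants Number of participants J (>= 1).
#' @param windows_per_participant Windows per participant (>= 1).
#' @param n_features Number of features K (>= 1).
#' @param gamma Fixed coefficients, length K + 1 (intercept first).
#' @param intercept_sd Between-participant intercept SD (>= 0).
#' @param slope_sds Between-participant slope SDs, length K (all >= 0).
#' @param seed Integer seed.
#' @return An object of class `multilevel_sim_spec`.
#' @export
multilevel_sim_spec <- function(n_participants, windows_per_participant,
                                n_features, gamma, intercept_sd, slope_sds,
                                seed = 1L) {
  assert_scalar_number(n_participants, "n_participants", positive = TRUE)
  assert_scalar_number(windows_per_participant, "windows_per_participant",
                       positive = TRUE)
  if (!is.numeric(n_features) || n_features < 1) {
    stop("`n_features` must be >= 1 (an intercept-only simulation is not supported)",
         call. = FALSE)
  }
  if (length(gamma) != n_features + 1) {
    stop("`gamma` must have length n_features + 1 (intercept first)", call. = FALSE)
  }
  assert_scalar_number(intercept_sd, "intercept_sd", nonneg = TRUE)
  if (length(slope_sds) != n_features || any(slope_sds < 0)) {
    stop("`slope_sds` must be length n_features, all >= 0", call. = FALSE)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      windows_per_participant = as.integer(windows_per_participant),
      n_features = as.integer(n_features),
      gamma = as.numeric(gamma),
      intercept_sd = intercept_sd,
      slope_sds = as.numeric(slope_sds),
      seed = as.integer(seed)
    ),
    class = "multilevel_sim_spec"
  )
}

#' Simulate a feature-level multilevel dataset
#'
#' @param spec A [multilevel_sim_spec()].
#' @return A list of class `mlr_sim` with `data` (data.frame:
#'   `participant_id`, `outcome`, `X1`..`XK`) and `params` (the realized
#'   per-participant `alpha`, `beta` matrix, and the generating `gamma` and
#'   SDs) for parameter-recovery checks.
#' @export
generate_multilevel_features <- function(spec) {
  stopifnot(inherits(spec, "multilevel_sim_spec"))
  J <- spec$n_participants
  W <- spec$windows_per_participant
  K <- spec$n_features
  with_seed(spec$seed, {
    alpha <- stats::rnorm(J, spec$gamma[1], spec$intercept_sd)
    beta <- vapply(seq_len(K), function(k) {
      stats::rnorm(J, spec$gamma[k + 1], spec$slope_sds[k])
    }, numeric(J))
    beta <- matrix(beta, nrow = J, ncol = K)
    pid <- rep(sprintf("P%02d", seq_len(J)), each = W)
    X <- matrix(stats::rnorm(J * W * K), nrow = J * W, ncol = K)
    colnames(X) <- paste0("X", seq_len(K))
    eta <- alpha[rep(seq_len(J), each = W)] +
      rowSums(X * beta[rep(seq_len(J), each = W), , drop = FALSE])
    y <- stats::rbinom(J * W, 1, stats::plogis(eta))
    data <- data.frame(participant_id = pid, outcome = y, X,
                       stringsAsFactors = FALSE)
    structure(
      list(data = data,
           params = list(alpha = alpha, beta = beta, gamma = spec$gamma,
                         intercept_sd = spec$intercept_sd,
                         slope_sds = spec$slope_sds)),
      class = "mlr_sim"
    )
  })
}
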