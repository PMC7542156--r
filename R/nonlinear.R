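## Nonlinear motor-variability battery: delay embedding (with data-driven
## selection of the delay and embedding dimension), sample entropy,
## cross-sample entropy, recurrence quantification analysis, and detrended
## fluctuation analysis. 9 features x 3 channels = 27 per window, computed on
## raw (unfiltered) samples.

#' Embedding parameters
#'
#' @param tau Time delay in samples (default 5, the value selected for this
#'   kind of wrist-accelerometry data by the mutual-information /
#'   autocorrelation procedure in [select_time_delay()]).
#' @param M Embedding dimension (default 4, from false-nearest-neighbor
#'   analysis, [select_embedding_dimension()]).
#' @return An object of class `embedding_params`.
#' @export
embedding_params <- function(tau = 5, M = 4) {
  if (tau < 1 || tau != round(tau)) stop("`tau` must be a positive integer", call. = FALSE)
  if (M < 1 || M != round(M)) stop("`M` must be a positive integer", call. = FALSE)
  structure(list(tau = as.integer(tau), M = as.integer(M)),
            class = "embedding_params")
}

## Average mutual information between x(t) and x(t+lag), histogram estimator
## on `bins` equal-width bins.
average_mutual_information <- function(x, lag, bins = 16) {
  n <- length(x)
  a <- x[1:(n - lag)]
  b <- x[(1 + lag):n]
  brks <- seq(min(x), max(x), length.out = bins + 1)
  ia <- findInterval(a, brks, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(b, brks, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(factor(ia, levels = 1:bins), factor(ib, levels = 1:bins))
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Select the embedding time delay
#'
#' Two standard criteria are computed: (1) the lag of the first local minimum
#' of the average mutual information (AMI) function, and (2) the first lag at
#' which the autocorrelation drops below 1/e. When the two agree to within
#' one sample the AMI value is returned; otherwise the AMI value is returned
#' with a `"methods_diverge"` flag. If the AMI function has no local minimum
#' within `max_lag`, the autocorrelation value is returned with a
#' `"no_ami_minimum"` flag.
#'
#' @param x Numeric series (length >= 20).
#' @param max_lag Largest lag examined (default length/3).
#' @param bins Number of histogram bins for the AMI estimator (default 16).
#' @return Integer delay with attributes `tau_ami`, `tau_acf`, and possibly
#'   `flags`.
#' @export
select_time_delay <- function(x, max_lag = floor(length(x) / 3), bins = 16) {
  n <- length(x)
  if (n < 20) stop("series too short for delay selection (need >= 20)", call. = FALSE)
  max_lag <- max(2L, min(max_lag, n - 2L))

  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  tau_acf <- which(ac < exp(-1))[1]
  if (is.na(tau_acf)) tau_acf <- max_lag

  ami <- vapply(1:max_lag, function(l) average_mutual_information(x, l, bins),
                numeric(1))
  tau_ami <- NA_integer_
  for (l in 2:(max_lag - 1)) {
    if (ami[l] < ami[l - 1] && ami[l] <= ami[l + 1]) { tau_ami <- l; break }
  }

  if (is.na(tau_ami)) {
    out <- as.integer(tau_acf)
    out <- set_flag(out, "no_ami_minimum")
  } else if (abs(tau_ami - tau_acf) <= 1) {
    out <- as.integer(tau_ami)
  } else {
    out <- as.integer(tau_ami)
    out <- set_flag(out, "methods_diverge")
  }
  attr(out, "tau_ami") <- tau_ami
  attr(out, "tau_acf") <- as.integer(tau_acf)
  out
}

#' Select the embedding dimension by global false nearest neighbors
#'
#' For each candidate dimension M, every embedded point's nearest neighbor is
#' found (brute force, Euclidean); the neighbor is declared false when either
#' standard criterion fires: the extra-coordinate separation at dimension M+1
#' exceeds `rtol` times the distance at dimension M, or the M+1-dimensional
#' separation exceeds `atol` times the attractor size (the series SD) -- the
#' second criterion keeps stochastic signals from spuriously "unfolding" as
#' near-neighbor distances grow with dimension. The smallest M with a
#' false-neighbor fraction below `threshold` is returned; if none qualifies,
#' `M_max` is returned with an `"fnn_not_converged"` flag.
#'
#' @param x Numeric series.
#' @param tau Time delay in samples.
#' @param M_max Largest dimension examined (default 10).
#' @param rtol False-neighbor distance ratio tolerance (default 15).
#' @param atol False-neighbor attractor-size tolerance (default 2).
#' @param threshold Acceptable false-neighbor fraction (default 0.01).
#' @return Integer dimension with attribute `fnn_fraction` (per-M fractions).
#' @export
select_embedding_dimension <- function(x, tau, M_max = 10, rtol = 15,
                                       atol = 2, threshold = 0.01) {
  n <- length(x)
  if (n <= (M_max - 1) * tau + 1) {
    stop(sprintf("series too short (N = %d) for M_max = %d at tau = %d",
                 n, M_max, tau), call. = FALSE)
  }
  fractions <- rep(NA_real_, M_max)
  result <- NA_integer_
  for (M in 1:M_max) {
    k <- n - M * tau            # points embeddable at both M and M+1
    if (k < 2) break
    E <- reconstruct_phase_space(x, tau, M)$vectors[1:k, , drop = FALSE]
    extra <- x[(1:k) + M * tau] # the coordinate added at dimension M+1
    D <- as.matrix(stats::dist(E))
    diag(D) <- Inf
    nn <- apply(D, 1, which.min)
    dM <- D[cbind(1:k, nn)]
    ## scale-relative floor: exact recurrences of a periodic orbit otherwise
    ## divide a few-ulp separation by ~0 and masquerade as false neighbors
    dM <- pmax(dM, .Machine$double.eps^0.5 * stats::sd(x))
    sep <- abs(extra - extra[nn])
    false <- (sep / dM > rtol) |
      (sqrt(dM^2 + sep^2) / stats::sd(x) > atol)
    fractions[M] <- mean(false)
    if (is.na(result) && fractions[M] < threshold) result <- M
  }
  if (is.na(result)) {
    out <- as.integer(M_max)
    out <- set_flag(out, "fnn_not_converged")
  } else {
    out <- as.integer(result)
  }
  attr(out, "fnn_fraction") <- fractions
  out
}

#' Delay-embed a scalar series into phase space
#'
#' Builds the K x M matrix of delay vectors
#' `X(t) = [x(t), x(t + tau), ..., x(t + (M-1) tau)]`, t = 1..K with
#' K = N - (M - 1) tau.
#'
#' @param x Numeric series of length N > (M-1) tau.
#' @param tau Time delay in samples.
#' @param M Embedding dimension.
#' @return A `phase_space`: list with `vectors` (K x M), `n`, `tau`, `M`.
#' @export
reconstruct_phase_space <- function(x, tau = 5, M = 4) {
  n <- length(x)
  if (tau < 1 || M < 1) stop("tau and M must be positive integers", call. = FALSE)
  k <- n - (M - 1) * tau
  if (k < 1) {
    stop(sprintf("series of length %d cannot be embedded with M = %d, tau = %d",
                 n, M, tau), call. = FALSE)
  }
  vectors <- vapply(0:(M - 1), function(m) x[(1:k) + m * tau], numeric(k))
  vectors <- matrix(vectors, nrow = k, ncol = M)
  structure(list(vectors = vectors, n = n, tau = as.integer(tau),
                 M = as.integer(M)),
            class = "phase_space")
}

## Chebyshev (infinity-norm) distance matrix between delay vectors of
## dimension m built from x (template delay 1).
chebyshev_template_dist <- function(x, m) {
  k <- length(x) - m + 1
  D <- matrix(0, k, k)
  for (d in 1:m) {
    v <- x[(1:k) + d - 1]
    D <- pmax(D, abs(outer(v, v, "-")))
  }
  D
}

## Average template match count at dimension m: for each of the K = N - m + 1
## templates, the number of other templates within r (Chebyshev, self
## excluded), averaged over templates.
saen_phi <- function(x, m, r) {
  D <- chebyshev_template_dist(x, m)
  mean(rowSums(D <= r) - 1)
}

#' Sample entropy
#'
#' SaEn = -ln(phi^(M+1)(r) / phi^M(r)), where phi^m(r) is the average over
#' all N - m + 1 length-m templates (delay 1) of the number of other
#' templates within Chebyshev distance r = `r_coeff` * SD(x), self-matches
#' excluded. Low values indicate a regular, predictable signal. A constant
#' series returns 0 (flagged); if no template pair matches at dimension M+1
#' the value is +Inf with a `"no_matches"` flag.
#'
#' @param x Numeric series (length >= M + 2).
#' @param M Template length (embedding dimension).
#' @param r_coeff Tolerance as a fraction of the series SD (default 0.2).
#' @return Nonnegative scalar (possibly `Inf`, flagged).
#' @export
sample_entropy <- function(x, M, r_coeff = 0.2) {
  n <- length(x)
  if (n < M + 2) stop("series too short for sample entropy", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(set_flag(0, "constant_input"))
  r <- r_coeff * s
  phi_m <- saen_phi(x, M, r)
  phi_m1 <- saen_phi(x, M + 1, r)
  if (phi_m <= 0 || phi_m1 <= 0) return(set_flag(Inf, "no_matches"))
  -log(phi_m1 / phi_m)
}

#' Cross-sample entropy between two series
#'
#' Parallels [sample_entropy()] but matches templates of one stream against
#' templates of the other: both series are standardized (zero mean, unit SD),
#' phi^m is the average number of y-templates within Chebyshev distance
#' r = `r_coeff` (on the standardized scale) of each x-template, and the
#' value is -ln(phi^(M+1)/phi^M). Low values indicate similar, synchronized
#' streams. Symmetric in (x, y). A constant series yields 0 with a
#' `"constant_input"` flag.
#'
#' @param x,y Numeric series of equal length (>= M + 2).
#' @param M Template length.
#' @param r_coeff Tolerance on the standardized scale (default 0.2).
#' @return Nonnegative scalar (possibly `Inf`, flagged).
#' @export
cross_sample_entropy <- function(x, y, M, r_coeff = 0.2) {
  n <- length(x)
  if (length(y) != n) stop("series must have equal length", call. = FALSE)
  if (n < M + 2) stop("series too short for cross-sample entropy", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(set_flag(0, "constant_input"))
  }
  xs <- as.numeric(scale(x))
  ys <- as.numeric(scale(y))
  phi <- function(m) {
    k <- n - m + 1
    D <- matrix(0, k, k)
    for (d in 1:m) {
      D <- pmax(D, abs(outer(xs[(1:k) + d - 1], ys[(1:k) + d - 1], "-")))
    }
    mean(rowSums(D <= r_coeff))
  }
  phi_m <- phi(M)
  phi_m1 <- phi(M + 1)
  if (phi_m <= 0 || phi_m1 <= 0) return(set_flag(Inf, "no_matches"))
  -log(phi_m1 / phi_m)
}

#' Threshold a phase space into a recurrence plot
#'
#' Computes the Euclidean distance matrix between embedded vectors and picks
#' the recurrence radius as the off-Theiler distance quantile whose strict
#' `<` thresholding yields a recurrence percentage as close as possible to
#' `target_pct`, constrained to lie inside `band` (default 0.1--2% of the
#' off-Theiler cells). The recurrence percentage is recomputed from the final
#' binary matrix and verified against the band.
#'
#' @param ps A `phase_space` with at least 10 vectors.
#' @param band Admissible recurrence-percentage band (default `c(0.1, 2)`).
#' @param target_pct Targeted recurrence percentage (default 1, the band
#'   midpoint on the log scale is not used; 1% is the conventional aim).
#' @param theiler Theiler window: pairs with |i - j| <= `theiler` are
#'   excluded from the percentage and from the radius selection (default 1,
#'   i.e. the main diagonal is excluded).
#' @return A `recurrence_plot`: list with `matrix` (K x K logical),
#'   `radius`, `recurrence_pct`, `theiler`.
#' @export
rqa_threshold <- function(ps, band = c(0.1, 2), target_pct = 1, theiler = 1) {
  stopifnot(inherits(ps, "phase_space"))
  k <- nrow(ps$vectors)
  if (k < 10) stop("need at least 10 embedded vectors", call. = FALSE)
  D <- as.matrix(stats::dist(ps$vectors))
  off <- abs(row(D) - col(D)) > theiler
  d <- sort(D[off])
  m <- length(d)
  ## Achievable recurrence percentages under strict '<' thresholding are
  ## 100 * (cumulative count of distances <= u) / m for radii just above each
  ## distinct distance value u.
  u <- unique(d)
  cum <- findInterval(u, d)      # counts of d <= u (d sorted)
  pct <- 100 * cum / m
  ok <- pct >= band[1] & pct <= band[2]
  if (!any(ok)) {
    stop(sprintf(
      "no radius achieves a recurrence percentage inside the %g-%g%% band (closest achievable: %.3g%%)",
      band[1], band[2], pct[which.min(abs(pct - target_pct))]), call. = FALSE)
  }
  pick <- which(ok)[which.min(abs(pct[ok] - target_pct))]
  ## radius strictly between the picked distance and the next larger one
  eps <- if (pick < length(u)) (u[pick] + u[pick + 1]) / 2 else u[pick] * (1 + 1e-9)
  R <- D < eps
  pct_final <- 100 * sum(R[off]) / m
  if (pct_final < band[1] || pct_final > band[2]) {
    stop(sprintf("selected radius yields %.3g%%, outside the %g-%g%% band",
                 pct_final, band[1], band[2]), call. = FALSE)
  }
  structure(list(matrix = R, radius = eps, recurrence_pct = pct_final,
                 theiler = as.integer(theiler)),
            class = "recurrence_plot")
}

## Run lengths of TRUE values in a logical vector.
true_run_lengths <- function(v) {
  if (!length(v)) return(integer(0))
  r <- rle(v)
  r$lengths[r$values]
}

#' Recurrence quantification metrics
#'
#' Summarizes a recurrence plot with six measures, all computed over the
#' off-Theiler cells: recurrence (% of cells recurrent), determinism (% of
#' recurrent points lying on diagonal lines of length >= `lmin`), laminarity
#' (% on vertical lines of length >= `vmin`), maximum diagonal line length,
#' divergence (its inverse), and trapping time (mean vertical line length
#' among lines >= `vmin`). With no recurrent points, determinism and
#' laminarity are 0 and divergence is 0 with a `"no_diagonal"` flag.
#'
#' @param rp A `recurrence_plot`.
#' @param lmin Minimum diagonal line length (default 2).
#' @param vmin Minimum vertical line length (default 2).
#' @return An `rqa_metrics`: named list with `recurrence`, `determinism`,
#'   `laminarity`, `divergence`, `max_diag_len`, `trapping_time`.
#' @export
rqa_metrics <- function(rp, lmin = 2, vmin = 2) {
  stopifnot(inherits(rp, "recurrence_plot"))
  R <- rp$matrix
  k <- nrow(R)
  off <- abs(row(R) - col(R)) > rp$theiler
  n_off <- sum(off)
  Rm <- R & off
  n_rec <- sum(Rm)
  recurrence <- 100 * n_rec / n_off

  flags <- character(0)
  ## diagonal lines (offsets beyond the Theiler band)
  diag_lengths <- integer(0)
  for (o in setdiff(-(k - 1):(k - 1), -rp$theiler:rp$theiler)) {
    i <- if (o >= 0) 1:(k - o) else (1 - o):k
    j <- i + o
    diag_lengths <- c(diag_lengths, true_run_lengths(R[cbind(i, j)]))
  }
  ## vertical lines within off-Theiler cells
  vert_lengths <- unlist(lapply(seq_len(k), function(j) {
    true_run_lengths(Rm[, j])
  }))

  if (n_rec == 0) {
    determinism <- 0
    laminarity <- 0
    max_diag <- 0L
    divergence <- 0
    trapping <- 0
    flags <- c(flags, "no_recurrent_points", "no_diagonal")
  } else {
    determinism <- 100 * sum(diag_lengths[diag_lengths >= lmin]) / n_rec
    laminarity <- 100 * sum(vert_lengths[vert_lengths >= vmin]) / n_rec
    max_diag <- if (length(diag_lengths)) max(diag_lengths) else 0L
    if (max_diag >= 1) {
      divergence <- 1 / max_diag
    } else {
      divergence <- 0
      flags <- c(flags, "no_diagonal")
    }
    vl <- vert_lengths[vert_lengths >= vmin]
    trapping <- if (length(vl)) mean(vl) else 0
  }
  out <- structure(
    list(recurrence = recurrence, determinism = determinism,
         laminarity = laminarity, divergence = divergence,
         max_diag_len = as.integer(max_diag), trapping_time = trapping),
    class = "rqa_metrics"
  )
  if (length(flags)) out <- set_flag(out, flags)
  out
}

#' Detrended fluctuation analysis exponent
#'
#' Integrates the mean-centered series into a profile, splits it into
#' non-overlapping boxes of log-spaced sizes, removes a linear trend per box,
#' and regresses log RMS fluctuation on log box size. The slope alpha
#' quantifies long-range correlation: alpha > 0.5 indicates persistence,
#' alpha < 0.5 anti-persistence (white noise gives 0.5, integrated white
#' noise 1.5). Zero fluctuation at any box size (e.g. a pure linear ramp)
#' yields a flagged result with `alpha = 0`.
#'
#' @param x Numeric series (length >= 16).
#' @param box_range Smallest and largest box size in samples
#'   (default `c(4, N/4)`).
#' @param n_boxes Number of log-spaced box sizes (default 12).
#' @return A `dfa_result`: list with `alpha`, `box_sizes`, `fluctuations`,
#'   `fit_r2`.
#' @export
dfa_exponent <- function(x, box_range = c(4, floor(length(x) / 4)),
                         n_boxes = 12) {
  n <- length(x)
  if (n < 16) stop("series too short for DFA (need >= 16)", call. = FALSE)
  lo <- max(4, box_range[1])
  hi <- min(floor(n / 2), max(lo + 1, box_range[2]))
  sizes <- unique(round(exp(seq(log(lo), log(hi), length.out = n_boxes))))
  profile <- cumsum(x - mean(x))
  fl <- vapply(sizes, function(s) {
    nb <- floor(n / s)
    idx <- seq_len(nb * s)
    segs <- matrix(profile[idx], nrow = s)
    t <- seq_len(s)
    ## residual sum of squares of a per-box linear fit, vectorized over boxes
    X <- cbind(1, t)
    H <- X %*% solve(crossprod(X), t(X))
    res <- segs - H %*% segs
    sqrt(mean(res^2))
  }, numeric(1))
  flags <- character(0)
  if (any(fl <= .Machine$double.eps^0.5)) {
    out <- structure(list(alpha = 0, box_sizes = sizes, fluctuations = fl,
                          fit_r2 = 0), class = "dfa_result")
    return(set_flag(out, "zero_fluctuation"))
  }
  fit <- stats::lm(log(fl) ~ log(sizes))
  out <- structure(
    list(alpha = unname(stats::coef(fit)[2]), box_sizes = sizes,
         fluctuations = fl, fit_r2 = summary(fit)$r.squared),
    class = "dfa_result"
  )
  out
}

## Finite cap applied when a sample-entropy estimate is the +Inf sentinel
## (no template matches at dimension M+1): the conventional upper bound
## -ln(2 / ((N - M)(N - M - 1))) for a series of length N.
saen_cap <- function(n, M) -log(2 / ((n - M) * (n - M - 1)))

#' Nonlinear motor-variability features of one window (27 values)
#'
#' Per raw (unfiltered) channel: the DFA exponent, sample entropy,
#' cross-sample entropy against the cyclically paired channel (X vs Y, Y vs
#' Z, Z vs X), and the six recurrence-quantification measures of the
#' delay-embedded channel thresholded into the 0.1--2% recurrence band.
#' Degenerate inputs never produce NaN: entropy sentinels are capped at the
#' maximum finite estimate for the window length, a failed recurrence
#' thresholding (e.g. a constant channel) yields zeroed RQA values, and all
#' such fallbacks are recorded as flags on the returned vector.
#'
#' @param window A `sib_window`.
#' @param params An [embedding_params()] (default tau = 5, M = 4).
#' @param r_coeff Entropy tolerance coefficient (default 0.2).
#' @param band,theiler Passed to [rqa_threshold()].
#' @return Named numeric vector of length 27 (`<feature>_<channel>`).
#' @export
nonlinear_features <- function(window, params = embedding_params(),
                               r_coeff = 0.2, band = c(0.1, 2), theiler = 1) {
  stopifnot(inherits(window, "sib_window"))
  x <- window$raw
  n <- nrow(x)
  flags <- character(0)
  out <- numeric(0)
  for (ci in seq_along(CHANNELS)) {
    ch <- CHANNELS[ci]
    v <- x[, ci]
    v2 <- x[, match(CHANNEL_PAIR[[ch]], CHANNELS)]

    dfa <- dfa_exponent(v)
    if (has_flag(dfa, "zero_fluctuation")) {
      flags <- c(flags, paste0("dfa_degenerate_", ch))
    }

    se <- sample_entropy(v, params$M, r_coeff)
    if (is.infinite(se)) {
      se <- saen_cap(n, params$M)
      flags <- c(flags, paste0("saen_capped_", ch))
    } else if (has_flag(se, "constant_input")) {
      flags <- c(flags, paste0("saen_constant_", ch))
    }

    xse <- cross_sample_entropy(v, v2, params$M, r_coeff)
    if (is.infinite(xse)) {
      xse <- saen_cap(n, params$M)
      flags <- c(flags, paste0("xsaen_capped_", ch))
    } else if (has_flag(xse, "constant_input")) {
      flags <- c(flags, paste0("xsaen_constant_", ch))
    }

    rqa <- tryCatch({
      ps <- reconstruct_phase_space(v, params$tau, params$M)
      rqa_metrics(rqa_threshold(ps, band = band, theiler = theiler))
    }, error = function(e) {
      flags <<- c(flags, paste0("rqa_failed_", ch))
      list(recurrence = 0, determinism = 0, laminarity = 0,
           divergence = 0, max_diag_len = 0L, trapping_time = 0)
    })

    vals <- c(dfa$alpha, as.numeric(se), as.numeric(xse),
              rqa$recurrence, rqa$determinism, rqa$laminarity,
              rqa$divergence, rqa$max_diag_len, rqa$trapping_time)
    names(vals) <- paste0(
      c("dfa_alpha", "saen", "xsaen", "rqa_recurrence", "rqa_determinism",
        "rqa_laminarity", "rqa_divergence", "rqa_max_diag", "rqa_trapping"),
      "_", ch)
    out <- c(out, vals)
  }
  if (length(flags)) out <- set_flag(out, flags)
  out
}

#' Full per-window feature table (96 features)
#'
#' Applies the linear (69) and nonlinear (27) feature batteries to every
#' window and returns a flat table with one row per window: identifiers
#' (`participant_id`, `start_s`), the window outcome and prompt flag, and 96
#' named feature columns.
#'
#' @param ws A `window_set` (or a list of them, one per participant).
#' @param params An [embedding_params()].
#' @return A data.frame; `attr(, "feature_names")` holds the 96 feature
#'   column names.
#' @export
featurize_windows <- function(ws, params = embedding_params()) {
  sets <- if (inherits(ws, "window_set")) list(ws) else ws
  rows <- lapply(sets, function(s) {
    lapply(s$windows, function(w) {
      lf <- linear_features(w)
      nf <- nonlinear_features(w, params)
      c(list(participant_id = w$participant_id, start_s = w$start_s,
             outcome = w$outcome, prompt = w$prompt),
        as.list(c(unclass(lf), unclass(nf))))
    })
  })
  rows <- unlist(rows, recursive = FALSE)
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  attr(df, "feature_names") <- setdiff(
    names(df), c("participant_id", "start_s", "outcome", "prompt"))
  df
}
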