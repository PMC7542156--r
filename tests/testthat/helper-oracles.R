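# Independent oracles and small fixtures used across the suite. These are
# deliberately naive (explicit double loops, manual run counting) so they
# share no code path with the implementation they check.

# Build a window directly (bypassing segmentation/filtering) from a raw
# matrix; filtered defaults to raw.
make_window <- function(raw, rate_hz = 60, filtered = raw) {
  raw <- as.matrix(raw)
  structure(
    list(participant_id = "T01", start_s = 0, rate_hz = rate_hz,
         raw = raw, filtered = as.matrix(filtered),
         outcome = 0L, prompt = 0L),
    class = "sib_window")
}

# Brute-force sample-entropy oracle: explicit template double loop, counting
# Chebyshev matches (self excluded) and averaging over all N - m + 1
# templates at each dimension.
brute_phi <- function(x, m, r) {
  n <- length(x)
  k <- n - m + 1
  total <- 0
  for (t in 1:k) {
    cnt <- 0
    for (i in 1:k) {
      if (i == t) next
      d <- max(abs(x[t:(t + m - 1)] - x[i:(i + m - 1)]))
      if (d <= r) cnt <- cnt + 1
    }
    total <- total + cnt
  }
  total / k
}

brute_saen <- function(x, M, r_coeff = 0.2) {
  r <- r_coeff * stats::sd(x)
  pm <- brute_phi(x, M, r)
  pm1 <- brute_phi(x, M + 1, r)
  if (pm <= 0 || pm1 <= 0) return(Inf)
  -log(pm1 / pm)
}

# Brute-force cross-sample-entropy oracle: all (i, j) template pairs across
# the two standardized streams.
brute_xphi <- function(x, y, m, r) {
  k <- length(x) - m + 1
  total <- 0
  for (t in 1:k) {
    for (i in 1:k) {
      d <- max(abs(x[t:(t + m - 1)] - y[i:(i + m - 1)]))
      if (d <= r) total <- total + 1
    }
  }
  total / k
}

brute_xsaen <- function(x, y, M, r_coeff = 0.2) {
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
  pm <- brute_xphi(xs, ys, M, r_coeff)
  pm1 <- brute_xphi(xs, ys, M + 1, r_coeff)
  if (pm <= 0 || pm1 <= 0) return(Inf)
  -log(pm1 / pm)
}

# Exhaustive RQA line-statistic oracle on a binary matrix: walks every
# diagonal and every column cell by cell, counting runs by hand.
brute_rqa <- function(R, theiler = 1, lmin = 2, vmin = 2) {
  k <- nrow(R)
  off <- abs(row(R) - col(R)) > theiler
  n_rec <- sum(R & off)
  recurrence <- 100 * n_rec / sum(off)

  diag_lengths <- integer(0)
  for (o in -(k - 1):(k - 1)) {
    if (abs(o) <= theiler) next
    run <- 0
    for (i in 1:k) {
      j <- i + o
      v <- if (j >= 1 && j <= k) R[i, j] else FALSE
      if (v) run <- run + 1
      if (!v || i == k) {
        if (run > 0) diag_lengths <- c(diag_lengths, run)
        run <- 0
      }
    }
  }
  vert_lengths <- integer(0)
  for (j in 1:k) {
    run <- 0
    for (i in 1:k) {
      v <- R[i, j] && abs(i - j) > theiler
      if (v) run <- run + 1
      if (!v || i == k) {
        if (run > 0) vert_lengths <- c(vert_lengths, run)
        run <- 0
      }
    }
  }
  max_diag <- if (length(diag_lengths)) max(diag_lengths) else 0
  list(
    recurrence = recurrence,
    determinism = if (n_rec > 0) 100 * sum(diag_lengths[diag_lengths >= lmin]) / n_rec else 0,
    laminarity = if (n_rec > 0) 100 * sum(vert_lengths[vert_lengths >= vmin]) / n_rec else 0,
    divergence = if (max_diag >= 1) 1 / max_diag else 0,
    max_diag_len = max_diag,
    trapping_time = if (any(vert_lengths >= vmin)) mean(vert_lengths[vert_lengths >= vmin]) else 0
  )
}

# Wrap a binary matrix as a recurrence_plot object.
as_recurrence_plot <- function(R, theiler = 1, radius = 1) {
  structure(list(matrix = R, radius = radius,
                 recurrence_pct = NA_real_, theiler = as.integer(theiler)),
            class = "recurrence_plot")
}

# Fractional Gaussian noise by circulant embedding (Davies-Harte); used as a
# surrogate with known Hurst exponent for the DFA monotonicity property.
fgn <- function(n, H) {
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  acov <- g(0:(n - 1))
  circ <- c(acov, 0, rev(acov[-1]))
  lam <- Re(stats::fft(circ))
  lam[lam < 0] <- 0
  m <- length(circ)
  z <- stats::rnorm(m) + 1i * stats::rnorm(m)
  x <- Re(stats::fft(sqrt(lam / (2 * m)) * z))[1:n] * sqrt(2)
  x
}
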