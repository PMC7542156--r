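test_that("time-delay selection matches ACF and AMI behavior", {
  set.seed(10)
  wn <- rnorm(600)
  tau <- select_time_delay(wn)
  expect_equal(attr(tau, "tau_acf"), 1L)   # white noise decorrelates at lag 1

  # sine of period 24 samples: AMI first minimum near a quarter period
  x <- sin(2 * pi * (1:480) / 24) + rnorm(480, sd = 0.05)
  tau_s <- select_time_delay(x)
  expect_true(attr(tau_s, "tau_ami") >= 5 && attr(tau_s, "tau_ami") <= 7)

  expect_error(select_time_delay(rnorm(10)), "too short")
})

test_that("false-nearest-neighbor analysis separates structure from noise", {
  x <- sin(2 * pi * (1:400) / 25)
  m_sine <- select_embedding_dimension(x, tau = 6)
  expect_lte(as.integer(m_sine), 3)

  set.seed(11)
  wn <- rnorm(300)
  m_noise <- select_embedding_dimension(wn, tau = 1, M_max = 6)
  expect_true("fnn_not_converged" %in% attr(m_noise, "flags"))
  expect_equal(as.integer(m_noise), 6L)

  expect_error(select_embedding_dimension(rnorm(20), tau = 5, M_max = 10),
               "too short")
})

test_that("phase-space reconstruction maps indices exactly", {
  ps <- reconstruct_phase_space(1:10, tau = 2, M = 3)
  expect_equal(dim(ps$vectors), c(6, 3))
  expect_equal(ps$vectors[1, ], c(1, 3, 5))
  expect_equal(ps$vectors[6, ], c(6, 8, 10))

  ps1 <- reconstruct_phase_space(c(4, 2, 7), tau = 3, M = 1)
  expect_equal(as.numeric(ps1$vectors), c(4, 2, 7))

  expect_error(reconstruct_phase_space(1:8, tau = 4, M = 3), "embedded")

  # row-count invariant across a sweep
  set.seed(12)
  for (i in 1:20) {
    n <- sample(10:100, 1); tau <- sample(1:5, 1); M <- sample(1:5, 1)
    if (n - (M - 1) * tau < 1) next
    expect_equal(nrow(reconstruct_phase_space(rnorm(n), tau, M)$vectors),
                 n - (M - 1) * tau)
  }
})

test_that("sample entropy equals the brute-force template-counting oracle", {
  set.seed(13)
  x <- rnorm(50)
  expect_equal(sample_entropy(x, M = 2), brute_saen(x, 2), tolerance = 1e-12)

  # randomized property sweep on short series
  for (i in 1:15) {
    n <- sample(20:60, 1)
    M <- sample(1:3, 1)
    x <- rnorm(n)
    got <- sample_entropy(x, M)
    want <- brute_saen(x, M)
    if (is.infinite(want)) {
      expect_true(is.infinite(got))
      expect_true("no_matches" %in% attr(got, "flags"))
    } else {
      expect_equal(as.numeric(got), want, tolerance = 1e-12)
    }
  }
})

test_that("sample entropy ranks regular below irregular signals", {
  expect_equal(as.numeric(sample_entropy(rep(3, 30), M = 2)), 0)

  set.seed(14)
  periodic <- sin(2 * pi * (1:200) / 20)
  noise <- rnorm(200, sd = stats::sd(periodic))
  expect_lt(sample_entropy(periodic, M = 2), sample_entropy(noise, M = 2))
})

test_that("cross-sample entropy is symmetric and tracks similarity", {
  set.seed(15)
  x <- rnorm(60); y <- rnorm(60)
  expect_equal(as.numeric(cross_sample_entropy(x, y, M = 2)),
               as.numeric(cross_sample_entropy(y, x, M = 2)), tolerance = 1e-12)
  expect_equal(as.numeric(cross_sample_entropy(x, y, M = 2)),
               brute_xsaen(x, y, 2), tolerance = 1e-12)
  # self-comparison equals the oracle too, and scores far below an
  # independent pair (identical streams are maximally synchronized)
  expect_equal(as.numeric(cross_sample_entropy(x, x, M = 2)),
               brute_xsaen(x, x, 2), tolerance = 1e-12)
  base <- sin(2 * pi * (1:120) / 15)
  twin <- base + rnorm(120, sd = 0.01)
  indep <- rnorm(120)
  expect_lt(cross_sample_entropy(base, twin, M = 2),
            cross_sample_entropy(base, indep, M = 2))

  expect_true(has_flags <- "constant_input" %in%
                attr(cross_sample_entropy(rep(1, 30), rnorm(30), M = 2), "flags"))
})

test_that("recurrence thresholding lands inside the 0.1-2% band", {
  set.seed(16)
  for (i in 1:5) {
    ps <- reconstruct_phase_space(rnorm(120), tau = 5, M = 4)
    rp <- rqa_threshold(ps)
    expect_gte(rp$recurrence_pct, 0.1)
    expect_lte(rp$recurrence_pct, 2)
    # recomputed from the final matrix
    off <- abs(row(rp$matrix) - col(rp$matrix)) > rp$theiler
    expect_equal(100 * sum(rp$matrix[off]) / sum(off), rp$recurrence_pct)
  }

  # recurrence is monotone in the radius
  ps <- reconstruct_phase_space(rnorm(80), tau = 3, M = 3)
  D <- as.matrix(dist(ps$vectors))
  radii <- quantile(D, c(0.05, 0.2, 0.5, 0.9))
  pct <- vapply(radii, function(e) mean(D < e), numeric(1))
  expect_true(all(diff(pct) >= 0))

  # degenerate: identical points cannot satisfy the band
  ps0 <- reconstruct_phase_space(rep(1, 30), tau = 2, M = 2)
  expect_error(rqa_threshold(ps0), "band")
})

test_that("RQA metrics match exhaustive line enumeration", {
  # hand-built 6x6 plot: one length-3 diagonal (plus its transpose)
  R <- matrix(FALSE, 6, 6)
  for (i in 1:3) { R[i, i + 3] <- TRUE; R[i + 3, i] <- TRUE }
  m <- rqa_metrics(as_recurrence_plot(R))
  expect_equal(m$determinism, 100)
  expect_equal(m$max_diag_len, 3L)
  expect_equal(m$divergence, 1 / 3)
  expect_equal(m$laminarity, 0)
  expect_equal(m$trapping_time, 0)

  # empty plot
  m0 <- rqa_metrics(as_recurrence_plot(matrix(FALSE, 5, 5)))
  expect_equal(m0$recurrence, 0)
  expect_equal(m0$determinism, 0)
  expect_true("no_recurrent_points" %in% attr(m0, "flags"))

  # random binary matrices up to 20x20 against the brute-force oracle
  set.seed(17)
  for (i in 1:10) {
    k <- sample(8:20, 1)
    R <- matrix(runif(k * k) < 0.2, k, k)
    got <- rqa_metrics(as_recurrence_plot(R))
    want <- brute_rqa(R)
    for (f in names(want)) {
      expect_equal(as.numeric(got[[f]]), as.numeric(want[[f]]), tolerance = 1e-12)
    }
    if (got$max_diag_len >= 1) {
      expect_equal(got$divergence * got$max_diag_len, 1)
    }
  }
})

test_that("a periodic orbit is highly deterministic", {
  # period 50 over 200 samples: the recurrences of the orbit (diagonal
  # stripes at multiples of the period) fit inside the 0.1-2% band
  x <- sin(2 * pi * (1:200) / 50)
  rp <- rqa_threshold(reconstruct_phase_space(x, tau = 12, M = 3))
  m <- rqa_metrics(rp)
  expect_gte(m$determinism, 95)
  expect_equal(as.numeric(m$determinism),
               brute_rqa(rp$matrix)$determinism, tolerance = 1e-12)
})

test_that("DFA recovers the known exponents of canonical processes", {
  set.seed(18)
  wn <- rnorm(4096)
  expect_lt(abs(dfa_exponent(wn)$alpha - 0.5), 0.05)
  expect_lt(abs(dfa_exponent(cumsum(wn))$alpha - 1.5), 0.1)

  # a constant series has an identically-zero profile: zero fluctuation at
  # every box size
  flat <- dfa_exponent(rep(2, 64))
  expect_true("zero_fluctuation" %in% attr(flat, "flags"))
  expect_equal(flat$alpha, 0)

  expect_error(dfa_exponent(rnorm(10)), "too short")
})

test_that("DFA alpha increases with the generating Hurst exponent", {
  set.seed(19)
  H <- seq(0.2, 0.8, by = 0.1)
  alpha <- vapply(H, function(h) dfa_exponent(fgn(2048, h))$alpha, numeric(1))
  expect_gt(cor(H, alpha, method = "spearman"), 0.9)
})

test_that("the nonlinear battery emits 27 flagged-not-NaN features", {
  set.seed(20)
  s <- generate_session(participant_profile("P"), 10, seed = 20)
  w <- segment_windows(s)$windows[[3]]
  nf <- nonlinear_features(w)
  expect_length(nf, 27)
  expect_true(all(is.finite(nf)))

  # constant window exercises every degenerate path without NaN
  wc <- make_window(matrix(1, 120, 3))
  nfc <- nonlinear_features(wc)
  expect_true(all(is.finite(nfc)))
  expect_equal(unname(nfc["saen_X"]), 0)
  flags <- attr(nfc, "flags")
  expect_true(any(grepl("dfa_degenerate", flags)))
  expect_true(any(grepl("rqa_failed", flags)))

  # distinguishable dynamics yield different determinism
  tt <- (0:119) / 60
  w_per <- make_window(cbind(sin(2 * pi * 3 * tt), sin(2 * pi * 3 * tt + 1),
                             sin(2 * pi * 3 * tt + 2)))
  set.seed(21)
  w_noise <- make_window(matrix(rnorm(360), 120, 3))
  expect_gt(nonlinear_features(w_per)["rqa_determinism_X"],
            nonlinear_features(w_noise)["rqa_determinism_X"])
})
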