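test_that("Morlet decomposition localises a pure tone at its frequency", {
  fs <- 2000
  tt <- (0:5999) / fs
  x <- sin(2 * pi * 30 * tt)
  co <- morlet_tfr(x, fs, 4:100)
  pw <- rowMeans(Mod(co)^2, na.rm = TRUE)
  expect_equal((4:100)[which.max(pw)], 30)
  # symmetric fall-off around the peak
  expect_gt(pw[30 - 3], pw[30 - 3 - 5])
  expect_gt(pw[30 - 3], pw[30 - 3 + 10])
  # zero signal -> zero power; doubling the amplitude quadruples power
  expect_equal(max(Mod(morlet_tfr(numeric(4000), fs, c(10, 40)))^2,
                   na.rm = TRUE), 0)
  r <- Mod(morlet_tfr(2 * x, fs, 25:35))^2 / Mod(morlet_tfr(x, fs, 25:35))^2
  expect_equal(mean(r, na.rm = TRUE), 4, tolerance = 1e-9)
  # edge samples with incomplete wavelet support are NA, not zero
  expect_true(all(is.na(co[1, 1:100])))
  # too short an epoch for the lowest frequency is an error
  expect_error(morlet_tfr(numeric(500), fs, 4:10), "epoch too short")
})

test_that("induced power is total minus evoked, zero for phase-locked trials", {
  fs <- 2000; n <- 4000; ntr <- 6
  tt <- (0:(n - 1)) / fs
  base <- sin(2 * pi * 25 * tt)
  serp <- array(rep(base, ntr), c(1, n, ntr))
  rec <- fake_recordings(serp, baseline_steps = 2000)
  tfr <- induced_power(rec, freqs = c(20, 25, 30), baseline = NULL)
  # identical trials: evoked = total, induced ~ 0
  expect_lt(max(abs(tfr$induced), na.rm = TRUE),
            1e-10 * max(tfr$total, na.rm = TRUE))
  # additivity holds exactly before baseline correction, by construction
  expect_equal(tfr$total, tfr$evoked + tfr$induced)
  expect_error(induced_power(rec, trials = 1), "at least 2 trials")
})

test_that("random-phase oscillations are induced, not evoked", {
  fs <- 2000; n <- 4000; ntr <- 40
  tt <- (0:(n - 1)) / fs
  set.seed(50)
  serp <- array(0, c(1, n, ntr))
  for (k in 1:ntr) serp[1, , k] <- sin(2 * pi * 25 * tt + runif(1, 0, 2 * pi))
  rec <- fake_recordings(serp, baseline_steps = 2000)
  tfr <- induced_power(rec, freqs = 25, baseline = NULL)
  expect_lt(mean(tfr$evoked, na.rm = TRUE),
            0.1 * mean(tfr$total, na.rm = TRUE))
  expect_equal(mean(tfr$induced, na.rm = TRUE),
               mean(tfr$total, na.rm = TRUE), tolerance = 0.15)
})

test_that("baseline correction zeroes the baseline window on average", {
  fs <- 2000; n <- 6000; ntr <- 8
  set.seed(51)
  serp <- array(rnorm(n * ntr), c(1, n, ntr))   # stationary noise
  rec <- fake_recordings(serp, baseline_steps = 3000)
  tfr <- induced_power(rec, freqs = c(10, 20, 40), baseline = c(-0.5, -0.1))
  bsel <- tfr$times >= -0.5 & tfr$times <= -0.1
  for (k in c("total", "evoked", "induced")) {
    expect_lt(abs(mean(tfr[[k]][, , bsel])), 1e-10)
  }
})

test_that("total band power tracks signal variance on stationary noise", {
  fs <- 2000; n <- 4000; ntr <- 6
  set.seed(52)
  mk <- function(sd) {
    serp <- array(rnorm(n * ntr, sd = sd), c(1, n, ntr))
    tfr <- induced_power(fake_recordings(serp, baseline_steps = 2000),
                         freqs = seq(10, 90, 10), baseline = NULL)
    mean(tfr$total, na.rm = TRUE)
  }
  p1 <- mk(1); p2 <- mk(2); p4 <- mk(4)
  expect_gt(p2, p1); expect_gt(p4, p2)
  expect_equal(p2 / p1, 4, tolerance = 0.3)
})

test_that("coherence is 1 for identical channels and ~1/N for noise", {
  fs <- 2000; n <- 3000; ntr <- 5
  set.seed(53)
  serp <- array(rnorm(2 * n * ntr), c(2, n, ntr))
  serp[2, , ] <- serp[1, , ]
  rec <- fake_recordings(serp, baseline_steps = 1500)
  ch <- wavelet_coherence(rec, "area1", "area2", freqs = c(15, 40, 80))
  expect_equal(min(ch$coherence, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(max(ch$coherence, na.rm = TRUE), 1, tolerance = 1e-9)
  # independent white noise: mean coherence ~ 1/N_trials
  reps <- 30
  m <- numeric(reps)
  for (r in seq_len(reps)) {
    s2 <- array(rnorm(2 * n * ntr), c(2, n, ntr))
    ch2 <- wavelet_coherence(fake_recordings(s2, baseline_steps = 1500),
                             "area1", "area2", freqs = c(20, 60))
    m[r] <- mean(ch2$coherence, na.rm = TRUE)
  }
  expect_equal(mean(m), 1 / ntr, tolerance = 0.25)
  expect_error(wavelet_coherence(rec, "area1", "nope"), "unknown")
})

test_that("a shared oscillation produces a coherence peak at its frequency", {
  fs <- 2000; n <- 3000; ntr <- 12
  tt <- (0:(n - 1)) / fs
  set.seed(54)
  serp <- array(0, c(2, n, ntr))
  for (k in 1:ntr) {
    common <- sin(2 * pi * 28 * tt + runif(1, 0, 2 * pi))
    serp[1, , k] <- common + rnorm(n, sd = 1)
    serp[2, , k] <- common + rnorm(n, sd = 1)
  }
  rec <- fake_recordings(serp, baseline_steps = 1500)
  ch <- wavelet_coherence(rec, "area1", "area2", freqs = seq(8, 88, 4))
  prof <- rowMeans(ch$coherence, na.rm = TRUE)
  expect_equal(ch$freqs[which.max(prof)], 28)
  # invariance under a global amplitude rescaling of both channels
  ch2 <- wavelet_coherence(fake_recordings(serp * 3.7, baseline_steps = 1500),
                           "area1", "area2", freqs = seq(8, 88, 4))
  expect_equal(ch2$coherence, ch$coherence, tolerance = 1e-9)
})

test_that("cluster permutation test: null, saturated and exact cases", {
  set.seed(60)
  a <- array(rnorm(12 * 2 * 10), c(12, 2, 10))
  # identical conditions: no clusters, smallest p reported as 1
  r0 <- cluster_permutation_test(a, a, n_perm = 200)
  expect_null(r0$clusters)
  expect_equal(r0$min_p, 1)
  # large offset over all bins: positive clusters spanning every bin at
  # the smallest attainable Monte-Carlo p
  b <- array(rnorm(12 * 2 * 10), c(12, 2, 10)) - 5
  r1 <- cluster_permutation_test(a, b, n_perm = 999)
  expect_equal(nrow(r1$clusters), 2L)          # one per site strip
  expect_true(all(r1$clusters$from == 1 & r1$clusters$to == 10))
  expect_true(all(r1$clusters$sign == 1))
  expect_lte(r1$min_p, 2 / (999 + 1))
  expect_error(cluster_permutation_test(a[1, , , drop = FALSE],
                                        b[1, , , drop = FALSE]), "2 pairs")
})

test_that("exhaustive cluster permutation matches brute-force enumeration", {
  set.seed(61)
  n <- 4; bins <- 6
  a <- matrix(rnorm(n * bins), n, bins)
  b <- a + matrix(rnorm(n * bins, sd = 0.5), n, bins)
  b[, 3:4] <- b[, 3:4] - 5                     # an embedded effect
  r <- cluster_permutation_test(a, b, n_perm = NULL)
  expect_false(is.null(r$clusters))
  # independent oracle: enumerate all 2^4 sign flips from scratch
  d <- a - b
  tcrit <- qt(0.975, n - 1)
  tvec <- function(dd) apply(dd, 2, function(col) mean(col) / (sd(col) / sqrt(n)))
  cl_masses <- function(tv) {
    out <- c()
    for (sgn in c(1, -1)) {
      runs <- rle(sgn * tv > tcrit)
      e <- cumsum(runs$lengths); s <- e - runs$lengths + 1
      for (k in which(runs$values)) out <- c(out, sum(tv[s[k]:e[k]]))
    }
    out
  }
  grid <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null <- apply(grid, 1, function(sg) {
    m <- cl_masses(tvec(d * sg))
    if (length(m)) max(abs(m)) else 0
  })
  obs <- cl_masses(tvec(d))
  for (i in seq_len(nrow(r$clusters))) {
    m <- abs(r$clusters$mass[i])
    expect_equal(r$clusters$p[i], sum(null >= m) / length(null))
  }
})

test_that("cluster permutation p values are valid under exchangeability", {
  # empirical type-I error at alpha = 0.05 over null simulations
  set.seed(62)
  reps <- 60; n <- 6
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    a <- matrix(rnorm(n * 12), n, 12)
    b <- matrix(rnorm(n * 12), n, 12)
    rr <- cluster_permutation_test(a, b, n_perm = 200)
    rej[r] <- rr$min_p <= 0.05
  }
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(rej), 0.05 + 3 * mc_se)
})

test_that("peak amplitude extraction and paired test behave as specified", {
  # toy 5-instance table vs the closed-form paired t statistic
  w <- c(3.1, 2.8, 3.5, 2.9, 3.3)
  pw <- c(2.7, 2.9, 3.0, 2.5, 3.1)
  r <- peak_amplitude_test(w, pw)
  d <- w - pw
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(r$t), 4))
  # identical conditions: t = 0
  expect_equal(peak_amplitude_test(w, w)$t, 0)
  # constant positive offset: degenerate, reported with a warning
  wi <- c(3, 2, 4, 5, 3)                       # exact arithmetic in floats
  expect_warning(rd <- peak_amplitude_test(wi + 1, wi), "degenerate")
  expect_true(rd$degenerate)
  expect_equal(rd$t, Inf)
  expect_error(peak_amplitude_test(w, pw[1:3]), "instance counts")
  # extraction: peak within an area in the window, averaged across areas
  serp <- array(0, c(2, 100, 2))
  serp[1, 60, 1] <- 7; serp[2, 70, 1] <- 3    # trial 1 peaks
  serp[1, 65, 2] <- 1; serp[2, 65, 2] <- 1
  rec <- fake_recordings(serp, dt = 10, baseline_steps = 50)  # 10 ms steps
  pk <- peak_serp_amplitude(rec, window = c(0.05, 0.45))
  expect_equal(pk$peak, c(5, 1))
})
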