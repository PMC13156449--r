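test_that("navigator resampling reproduces smooth signals", {
  t0 <- seq(0, 10, by = 0.015)
  nav <- new_navigator_series(cbind(sin(2 * pi * 0.2 * t0) + 2), t0)
  r <- resample_navigator(nav)
  expect_equal(r$values[, 1], Mod(nav$values[, 1]), tolerance = 1e-12)
  # alternating-TR sampling of a 0.2 Hz sine
  tt <- cumsum(rep(c(0.01308, 0.02076), 300))
  x <- 2 + sin(2 * pi * 0.2 * tt)
  nav2 <- new_navigator_series(cbind(x), tt)
  r2 <- resample_navigator(nav2)
  truth <- 2 + sin(2 * pi * 0.2 * r2$timestamps)
  expect_lt(max(abs(r2$values[, 1] - truth)), 0.01)
  # constant input stays constant; single sample errors
  navc <- new_navigator_series(cbind(rep(3, 100)), seq_len(100) * 0.017)
  expect_true(all(resample_navigator(navc)$values == 3))
  expect_error(resample_navigator(new_navigator_series(cbind(1), 0)),
               "at least 2")
})

test_that("moving average follows the sinc transfer function", {
  dt <- 0.015
  t <- seq(0, 30, by = dt)
  for (f in c(1, 1 / 3.6)) {
    nav <- new_navigator_series(cbind(10 + sin(2 * pi * f * t)), t,
                                dt = dt)
    out <- respiratory_signal(nav)
    # drop edges where the window shrinks
    core <- 150:(length(t) - 150)
    amp <- (max(out$values[core, 1]) - min(out$values[core, 1])) / 2
    W <- round(1.5 / dt) * dt
    expected <- abs(sin(pi * f * W) / (pi * f * W))
    expect_equal(amp, expected, tolerance = 0.02)
  }
  navc <- new_navigator_series(cbind(rep(5, 3000)), seq_len(3000) * dt,
                               dt = dt)
  expect_true(all(abs(respiratory_signal(navc)$values - 5) < 1e-12))
})

test_that("respiratory binning is balanced and amplitude-ordered", {
  t <- seq_len(800) * 0.06
  sig_t <- seq(0, 49, by = 0.015)
  ramp <- seq_along(sig_t)
  b <- bin_respiratory(ramp, sig_t, t, 8)
  expect_true(all(tabulate(b, 8) == 100))
  # a monotone signal makes bins contiguous time blocks
  expect_true(all(diff(b) >= 0))
  # raised-cosine waveform: extreme octiles capture >= 90% of the range
  d <- 18.4 * (1 - cos(2 * pi * sig_t / 3.6)) / 2
  bb <- bin_respiratory(d, sig_t, t, 8)
  dproj <- naheart:::signal_at(d, sig_t, t)
  m <- tapply(dproj, bb, mean)
  expect_gt(m[8] - m[1], 0.9 * 18.4)
  expect_error(bin_respiratory(rep(1, length(sig_t)), sig_t, t, 8),
               "constant")
})

test_that("cardiac spectrum analysis finds the dominant peak and channel", {
  dt <- 0.015
  t <- seq(0, 60, by = dt)
  set.seed(21)
  tone <- sin(2 * pi * 1.2 * t)
  nav <- new_navigator_series(
    cbind(10 + 0.1 * tone + rnorm(length(t), 0, 0.3),
          10 + tone + rnorm(length(t), 0, 0.3)), t, dt = dt)
  cs <- cardiac_channel_spectrum(nav)
  expect_identical(cs$channel, 2L)
  row <- cs$spectrum_stats[cs$spectrum_stats$channel == 2, ]
  expect_lt(abs(row$f_card - 1.2), 0.05)
  # pure white noise: no reliable peak
  navn <- new_navigator_series(cbind(rnorm(length(t))), t, dt = dt)
  res <- try(cardiac_channel_spectrum(navn), silent = TRUE)
  if (!inherits(res, "try-error")) {
    # a spurious noise peak may exist but must score far below a tone
    expect_lt(res$spectrum_stats$score[1],
              cs$spectrum_stats$score[cs$spectrum_stats$channel == 2])
  }
})

test_that("trigger detection recovers rate and tracks chirps", {
  dt <- 0.015
  t <- seq(0, 60, by = dt)
  x <- sin(2 * pi * 1.0 * t) + rnorm(length(t), 0, 0.1)
  trig <- cardiac_triggers(x, t, f_card = 1.0, w_card = 0.05)
  expect_lt(abs(length(trig) - 60), 2)
  expect_lt(abs(median(diff(trig)) - 1.0), 0.03)
  # chirp 0.9 -> 1.1 Hz: RR intervals track the instantaneous period
  f0 <- 0.9
  k <- (1.1 - 0.9) / 60
  phase <- 2 * pi * (f0 * t + k * t^2 / 2)
  xc <- sin(phase)
  trig2 <- cardiac_triggers(xc, t, f_card = 1.0, w_card = 0.1)
  # exact peak times: phase = pi/2 + 2 pi m; edge triggers are affected
  # by the filter transient and excluded
  m <- 0:70
  tm <- (-f0 + sqrt(f0^2 + 2 * k * (0.25 + m))) / k
  tm <- tm[tm <= max(t)]
  core <- trig2[3:(length(trig2) - 2)]
  err <- vapply(core, function(tr) min(abs(tm - tr)), numeric(1))
  expect_lt(max(err) / 1.0, 0.05)
  expect_error(cardiac_triggers(rep(1, length(t)), t, 1, 0.05), "constant")
  expect_error(cardiac_triggers(x, t, f_card = 0.1, w_card = 0.2),
               "cutoff")
})

test_that("cardiac phase assignment partitions the RR interval", {
  trig <- c(10, 11, 12, 13)
  expect_identical(bin_cardiac(10, trig, 10), 1L)
  expect_identical(bin_cardiac(10.55, trig, 10), 6L)
  # uniform stream, constant RR: balanced phases
  t <- seq(5.005, 14.995, by = 0.01)
  ph <- bin_cardiac(t, trig, 10)
  expect_lte(diff(range(tabulate(ph, 10))), 1)
  # times before the first trigger are handled by extrapolation
  expect_true(all(bin_cardiac(c(5.01, 9.99), trig, 10) %in% 1:10))
})

test_that("trigger recovery stays within 30 ms over 40-120 bpm", {
  # full chain: spectral peak estimation then bandpass trigger detection;
  # the series is long enough for the spectral peak width to be resolved
  dt <- 0.015
  t <- seq(0, 180, by = dt)
  set.seed(22)
  for (bpm in c(42, 70, 118)) {
    f <- bpm / 60
    x <- 10 + sin(2 * pi * f * t) + rnorm(length(t), 0, 1 / 5)
    nav <- new_navigator_series(cbind(x), t, dt = dt)
    cs <- cardiac_channel_spectrum(nav)
    row <- cs$spectrum_stats[1, ]
    expect_lt(abs(row$f_card - f), 0.05)
    xd <- x - naheart:::moving_average(x, 100)
    trig <- cardiac_triggers(xd, t, row$f_card, row$w_card)
    truth <- (seq(0.25 / f, max(t), by = 1 / f))
    err <- vapply(trig, function(tr) min(abs(truth - tr)), numeric(1))
    expect_gte(mean(err <= 0.030 + 1e-9), 0.95)
  }
})

test_that("phase clustering separates contracted from relaxed states", {
  set.seed(23)
  base <- naheart:::gauss_filter3(array(rnorm(16^3), rep(16, 3)), 2)
  contracted <- naheart:::gauss_filter3(array(rnorm(16^3), rep(16, 3)), 2)
  mask <- array(TRUE, rep(16, 3))
  mix <- function(w) base * (1 - w) + contracted * w
  imgs <- lapply(c(0.9, 1, 0.95, 0.2, 0, 0.05, 0, 0, 0.1, 0.3), mix)
  cl <- cluster_phases(imgs, mask, seed = 1)
  expect_setequal(cl$systolic, c(1, 2, 3))
  expect_gte(length(cl$diastolic), 5)
  # permutation of the input permutes the labels consistently
  perm <- c(4:10, 1:3)
  cl2 <- cluster_phases(imgs[perm], mask, seed = 1)
  expect_setequal(perm[cl2$systolic], cl$systolic)
  # identical images: degenerate
  expect_error(cluster_phases(rep(list(base), 10), mask), "degenerate")
})
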