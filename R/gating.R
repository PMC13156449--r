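#' Navigator series container
#'
#' Per-1H-projection k-space centre (k0) values per receive channel.
#'
#' @param values complex (or numeric) matrix, time x channel.
#' @param timestamps acquisition times (s), sorted.
#' @param dt uniform sampling interval (s) if resampled, else `NA`.
#' @export
new_navigator_series <- function(values, timestamps, dt = NA_real_) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(timestamps), !is.unsorted(timestamps))
  structure(list(values = values, timestamps = timestamps, dt = dt),
            class = "navigator_series")
}

#' @export
print.navigator_series <- function(x, ...) {
  cat(sprintf("<navigator_series: %d samples x %d channels%s>\n",
              nrow(x$values), ncol(x$values),
              if (is.na(x$dt)) "" else sprintf(", dt = %g ms", x$dt * 1e3)))
  invisible(x)
}

#' Resample a navigator series to a uniform time grid
#'
#' The channel magnitude is taken first, then linearly interpolated onto a
#' uniform grid (default 15 ms) spanning the original time range; this
#' removes the alternating-TR sampling pattern of the interleaved
#' sequence.
#'
#' @param nav a [new_navigator_series()].
#' @param dt target sampling interval (s).
#' @export
resample_navigator <- function(nav, dt = 0.015) {
  if (nrow(nav$values) < 2) stop("need at least 2 navigator samples")
  tt <- nav$timestamps
  tu <- seq(tt[1], tt[length(tt)], by = dt)
  out <- vapply(seq_len(ncol(nav$values)), function(ch)
    approx(tt, Mod(nav$values[, ch]), xout = tu)$y, numeric(length(tu)))
  new_navigator_series(matrix(out, ncol = ncol(nav$values)), tu, dt = dt)
}

#' Gating parameters
#'
#' @param resp_window_s moving-average window suppressing cardiac
#'   fluctuations (s).
#' @param n_resp_bins equal-count respiratory bins.
#' @param cardiac_band_hz search band for the cardiac frequency (Hz).
#' @param n_cardiac_phases cardiac phases per cycle.
#' @param butter_order Butterworth bandpass order.
#' @param sg_window,sg_order Savitzky-Golay spectral smoothing window
#'   (samples, odd) and polynomial order.
#' @export
gating_params <- function(resp_window_s = 1.5, n_resp_bins = 8,
                          cardiac_band_hz = c(0.5, 2.0),
                          n_cardiac_phases = 10, butter_order = 4,
                          sg_window = 21, sg_order = 3) {
  stopifnot(cardiac_band_hz[1] < cardiac_band_hz[2], n_resp_bins >= 2,
            sg_window %% 2 == 1)
  structure(list(resp_window_s = resp_window_s, n_resp_bins = n_resp_bins,
                 cardiac_band_hz = cardiac_band_hz,
                 n_cardiac_phases = n_cardiac_phases,
                 butter_order = butter_order, sg_window = sg_window,
                 sg_order = sg_order),
            class = "gating_params")
}

# centered moving average with shrinking windows at the edges
moving_average <- function(x, window) {
  n <- length(x)
  h <- floor(window / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Respiratory signal from navigator magnitudes
#'
#' Centred moving average (default 1.5 s window) of each channel of a
#' uniformly resampled navigator series; heart rates above 40 bpm fall
#' well inside the averaging window and are suppressed while the slower
#' respiratory modulation is retained.
#'
#' @param nav resampled [new_navigator_series()] (uniform `dt`).
#' @param params a [gating_params()].
#' @return navigator_series of filtered real signals.
#' @export
respiratory_signal <- function(nav, params = gating_params()) {
  if (is.na(nav$dt)) stop("navigator must be resampled to a uniform grid")
  w <- round(params$resp_window_s / nav$dt)
  if (nrow(nav$values) <= w) stop("series shorter than the averaging window")
  out <- apply(Mod(nav$values), 2, moving_average, window = w)
  new_navigator_series(out, nav$timestamps, nav$dt)
}

# nearest-sample navigator value at arbitrary timestamps
signal_at <- function(signal, sig_t, t) {
  idx <- findInterval(t, sig_t, all.inside = TRUE)
  use_next <- (t - sig_t[idx]) > (sig_t[pmin(idx + 1, length(sig_t))] - t)
  signal[idx + use_next]
}

#' Bin projections into equal-count respiratory states
#'
#' The respiratory signal is looked up at each projection's timestamp
#' (nearest navigator sample) and ranked; amplitude quantiles define
#' `n_bins` bins with counts equal within one.  By convention bin 1 is one
#' amplitude extreme and bin `n_bins` the other; use
#' [orient_respiratory_bins()] to fix which extreme is the exhaled state.
#'
#' @param signal respiratory signal values (one channel).
#' @param sig_t signal timestamps (s).
#' @param t projection timestamps of one nucleus (s).
#' @param n_bins number of bins.
#' @return integer bin label per projection.
#' @export
bin_respiratory <- function(signal, sig_t, t, n_bins = 8) {
  v <- signal_at(signal, sig_t, t)
  if (max(v) - min(v) < .Machine$double.eps * max(abs(v), 1))
    stop("constant respiratory signal: no respiratory information")
  r <- rank(v, ties.method = "first")
  as.integer(ceiling(n_bins * r / length(r)))
}

#' Flip respiratory bin labels so that the last bin is the exhaled state
#'
#' The navigator sign is arbitrary per channel, so which amplitude extreme
#' corresponds to exhalation is resolved from the reconstructed extreme-bin
#' images: the two bins are rigidly registered over the heart mask and the
#' sign of the superior-inferior translation decides the orientation
#' (exhaled = most inferior heart position).
#'
#' @param bins_list list of integer bin vectors (one per nucleus).
#' @param si_translation SI component (mm) of the transform mapping the
#'   bin-1 image onto the bin-`n` image.
#' @param n_bins number of bins.
#' @return `bins_list` possibly flipped (bin b -> n + 1 - b).
#' @export
orient_respiratory_bins <- function(bins_list, si_translation, n_bins = 8) {
  # registering bin 1 onto bin n yields t = d(bin1) - d(binN); with the
  # convention that inhalation displaces the heart toward +SI, a negative
  # SI component means bin 1 is the exhaled-like extreme and the labels
  # must be flipped so that bin n is exhaled
  if (si_translation < 0) {
    bins_list <- lapply(bins_list, function(b) n_bins + 1L - b)
  }
  bins_list
}

#' Select the navigator channel most sensitive to respiration
#'
#' For each channel the projections are binned by that channel's filtered
#' signal, the two extreme bins are reconstructed and rigidly registered
#' within the heart region, and the channel with the largest
#' superior-inferior displacement between the extremes is selected.
#'
#' @param nav_filt filtered navigator series ([respiratory_signal()]).
#' @param kspace_h 1H `kspace_set`.
#' @param grid,voxel_mm reconstruction grid for the bin images.
#' @param heart_mask logical mask on that grid.
#' @param n_bins respiratory bin count.
#' @return list: `channel`, per-channel `si_mm` displacement, and the
#'   selected channel's extreme-bin transform (`transform`).
#' @export
select_respiratory_channel <- function(nav_filt, kspace_h, grid, voxel_mm,
                                       heart_mask, n_bins = 8) {
  nch <- ncol(nav_filt$values)
  # widen the mask so both extreme heart positions fall inside it: only
  # the magnitude and sign of the SI displacement matter here
  wide_mask <- morph_mask(heart_mask, 20 / voxel_mm, "dilate")
  si <- rep(NA_real_, nch)
  tfs <- vector("list", nch)
  for (ch in seq_len(nch)) {
    res <- try({
      b <- bin_respiratory(nav_filt$values[, ch], nav_filt$timestamps,
                           kspace_h$timestamps, n_bins)
      i1 <- h1_bias_correction(
        reconstruct(kspace_h, grid, voxel_mm, proj_idx = which(b == 1),
                    frame = "bin1"))
      i8 <- h1_bias_correction(
        reconstruct(kspace_h, grid, voxel_mm,
                    proj_idx = which(b == n_bins), frame = "binN"),
        body_mask = attr(i1, "body_mask"))
      register_rigid(i1, i8, wide_mask, rot_penalty = 1e-3)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("registration failed on channel ", ch, "; channel skipped")
      next
    }
    tfs[[ch]] <- res
    si[ch] <- abs(res$translation[1])
  }
  if (all(is.na(si))) stop("respiratory channel selection failed on all channels")
  ch <- which.max(si)
  list(channel = ch, si_mm = si, transform = tfs[[ch]])
}

# topographic prominence of a peak in a 1D series
peak_prominence <- function(y, i) {
  n <- length(y)
  lv <- if (i > 1) {
    left <- y[1:(i - 1)]
    higher <- which(left >= y[i])
    if (length(higher)) min(y[(max(higher) + 1):(i - 1)], y[i]) else min(left)
  } else y[i]
  rv <- if (i < n) {
    right <- y[(i + 1):n]
    higher <- which(right >= y[i])
    if (length(higher)) min(y[(i + 1):(i + min(higher) - 1)], y[i]) else min(right)
  } else y[i]
  y[i] - max(lv, rv)
}

#' Cardiac peak analysis of the navigator spectrum
#'
#' Per channel: the respiratory trend (moving average) is subtracted, the
#' power spectrum computed and denoised with a Savitzky-Golay filter, and
#' the dominant peak within the cardiac band (default 0.5-2 Hz) located.
#' Its topographic prominence `p_card`, centre frequency `f_card`, and
#' width at half prominence `w_card` are extracted; `S_noise` is the
#' remaining in-band power outside `f_card +/- 2 w_card`.  The channel
#' with the highest `p_card / S_noise` score is selected.
#'
#' @param nav resampled navigator series.
#' @param params a [gating_params()].
#' @return list: `channel`, and per-channel data.frame `spectrum_stats`
#'   (`f_card, w_card, p_card, S_noise, score`).
#' @export
cardiac_channel_spectrum <- function(nav, params = gating_params()) {
  if (is.na(nav$dt)) stop("navigator must be resampled to a uniform grid")
  n <- nrow(nav$values)
  if (n * nav$dt < 10) stop("series too short for 0.1 Hz spectral resolution")
  fs <- 1 / nav$dt
  freqs <- (0:(n - 1)) * fs / n
  band <- params$cardiac_band_hz
  inband <- which(freqs >= band[1] & freqs <= band[2])
  stats <- lapply(seq_len(ncol(nav$values)), function(ch) {
    x <- Mod(nav$values[, ch])
    x <- x - moving_average(x, round(params$resp_window_s / nav$dt))
    p <- Mod(fft(x))^2 / n
    ps <- signal::sgolayfilt(p, p = params$sg_order, n = params$sg_window)
    pb <- ps[inband]
    loc <- which(diff(sign(diff(c(-Inf, pb, -Inf)))) < 0)
    if (!length(loc)) return(NULL)
    prom <- vapply(loc, function(i) peak_prominence(pb, i), numeric(1))
    best <- loc[which.max(prom)]
    pc <- max(prom)
    if (pc <= 0) return(NULL)
    fc <- freqs[inband[best]]
    # width at half prominence by linear interpolation
    half <- pb[best] - pc / 2
    l <- best
    while (l > 1 && pb[l] > half) l <- l - 1
    r <- best
    while (r < length(pb) && pb[r] > half) r <- r + 1
    df <- fs / n
    wl <- if (pb[l] <= half && l < best)
      (l + (half - pb[l]) / (pb[l + 1] - pb[l])) else l
    wr <- if (pb[r] <= half && r > best)
      (r - (half - pb[r]) / (pb[r - 1] - pb[r])) else r
    wc <- max((wr - wl) * df, df)
    excl <- abs(freqs[inband] - fc) <= 2 * wc
    sn <- sum(pb[!excl])
    if (sn <= 0) sn <- .Machine$double.eps
    data.frame(f_card = fc, w_card = wc, p_card = pc, S_noise = sn,
               score = pc / sn)
  })
  ok <- !vapply(stats, is.null, logical(1))
  if (!any(ok)) stop("no cardiac peak found in band on any channel")
  tab <- do.call(rbind, lapply(seq_along(stats), function(i) {
    if (ok[i]) cbind(channel = i, stats[[i]])
  }))
  list(channel = tab$channel[which.max(tab$score)], spectrum_stats = tab)
}

#' Cardiac trigger detection from the navigator signal
#'
#' The selected channel's detrended signal is bandpass-filtered with a
#' zero-phase Butterworth filter (cutoffs `f_card +/- 2 w_card`) and local
#' maxima with a minimum spacing of half a cardiac period serve as
#' triggers.
#'
#' @param x navigator signal values (one channel, uniform sampling).
#' @param t timestamps (s).
#' @param f_card,w_card cardiac peak centre and width (Hz).
#' @param params a [gating_params()].
#' @return trigger times (s).
#' @export
cardiac_triggers <- function(x, t, f_card, w_card, params = gating_params()) {
  if (f_card - 2 * w_card <= 0) stop("bandpass lower cutoff not positive")
  if (max(x) - min(x) < .Machine$double.eps * max(abs(x), 1))
    stop("constant signal: no cardiac information")
  dt <- t[2] - t[1]
  fs <- 1 / dt
  lo <- f_card - 2 * w_card
  hi <- min(f_card + 2 * w_card, 0.99 * fs / 2)
  bf <- signal::butter(params$butter_order, c(lo, hi) / (fs / 2),
                       type = "pass")
  y <- signal::filtfilt(bf, x - mean(x))
  mind <- round(0.5 / f_card / dt)
  loc <- which(diff(sign(diff(c(-Inf, y, -Inf)))) < 0)
  loc <- loc[y[loc] > 0]
  # enforce minimum spacing, higher peaks take precedence
  acc <- integer(0)
  for (i in loc[order(y[loc], decreasing = TRUE)]) {
    if (!length(acc) || min(abs(acc - i)) >= mind) acc <- c(acc, i)
  }
  acc <- sort(acc)
  # sub-sample refinement by parabolic interpolation around each maximum
  shift <- vapply(acc, function(i) {
    if (i <= 1 || i >= length(y)) return(0)
    den <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (y[i - 1] - y[i + 1]) / den))
  }, numeric(1))
  trig <- t[acc] + shift * dt
  if (length(trig) < 3) stop("fewer than 3 cardiac triggers detected")
  trig
}

#' Assign projections to cardiac phases
#'
#' Phase labels from the time since the last trigger, normalized by the
#' local RR interval: `phase = floor(n (t - t_trig)/RR) + 1` clipped to
#' `n`.  Projections before the first trigger use the first RR interval
#' extrapolated backwards.
#'
#' @param t projection timestamps (s).
#' @param triggers trigger times (s).
#' @param n_phases number of phases.
#' @return integer phase per projection.
#' @export
bin_cardiac <- function(t, triggers, n_phases = 10) {
  stopifnot(length(triggers) >= 2)
  rr1 <- triggers[2] - triggers[1]
  nback <- ceiling(max(0, triggers[1] - min(t)) / rr1)
  ext <- c(triggers[1] - rev(seq_len(max(nback, 0))) * rr1, triggers)
  idx <- findInterval(t, ext, all.inside = TRUE)
  rr <- c(diff(ext), ext[length(ext)] - ext[length(ext) - 1])
  # beyond the last trigger the first RR is continued periodically
  u <- ((t - ext[idx]) / rr[idx]) %% 1
  ph <- floor(n_phases * u) + 1
  as.integer(pmin(pmax(ph, 1), n_phases))
}

#' Cluster cardiac phases into systole and diastole
#'
#' Each phase image is described by its vector of structural similarities
#' (SSIM within the heart mask) to all phases; k-means with k = 2
#' separates contracted from relaxed phases, and the larger cluster is
#' labelled diastole (diastole occupies about 60% of the cycle).
#'
#' @param phase_images list of reconstructed 1H phase images.
#' @param heart_mask logical mask.
#' @param seed k-means seed (10 restarts).
#' @return list with integer vectors `systolic` and `diastolic`.
#' @export
cluster_phases <- function(phase_images, heart_mask, seed = 1) {
  np <- length(phase_images)
  stopifnot(np >= 2)
  # restrict the SSIM computation to the heart bounding box (plus margin)
  bb <- lapply(1:3, function(a) {
    r <- range(which(apply(heart_mask, a, any)))
    max(1, r[1] - 4):min(dim(heart_mask)[a], r[2] + 4)
  })
  crop <- function(x) array(abs_or_re(x)[bb[[1]], bb[[2]], bb[[3]]],
                            dim = lengths(bb))
  imgs <- lapply(phase_images, crop)
  mk <- crop(heart_mask) > 0
  S <- matrix(1, np, np)
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      S[i, j] <- S[j, i] <- ssim(imgs[[i]], imgs[[j]], mk)
    }
  }
  if (max(1 - S) < 1e-8)
    stop("degenerate clustering: all phase images identical")
  km <- with_seed(seed, kmeans(S, centers = 2, nstart = 10))
  if (any(tabulate(km$cluster, 2) == 0))
    stop("degenerate clustering: empty cluster")
  dia <- which.max(tabulate(km$cluster, 2))
  list(systolic = which(km$cluster != dia),
       diastolic = which(km$cluster == dia))
}
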