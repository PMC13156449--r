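#' Steady-state spoiled-GRE signal weight per compartment
#'
#' Per-sample signal weight
#' \deqn{w_c(t) = c_c E_{ss,c} [r_c e^{-t/T2s,c} + (1-r_c) e^{-t/T2l,c}]}
#' with the spoiled steady state
#' \eqn{E_{ss} = \sin FA (1-E_1)/(1-\cos FA\, E_1)}, \eqn{E_1 =
#' e^{-TR/T_1}}, and `t` the time since excitation (TE plus readout
#' offset, ms).
#'
#' @param tissue one row (or several) of [tissue_params()].
#' @param t_ms vector of sample times since excitation (ms).
#' @param FA_deg flip angle (degrees).
#' @param TR_ms repetition time (ms).
#' @return matrix `length(t_ms) x nrow(tissue)` of weights.
#' @export
signal_weight <- function(tissue, t_ms, FA_deg, TR_ms) {
  fa <- FA_deg * pi / 180
  w <- vapply(seq_len(nrow(tissue)), function(i) {
    p <- tissue[i, ]
    e1 <- exp(-TR_ms / p$T1)
    ess <- sin(fa) * (1 - e1) / (1 - cos(fa) * e1)
    p$c * ess * (p$r * exp(-t_ms / p$T2s) + (1 - p$r) * exp(-t_ms / p$T2l))
  }, numeric(length(t_ms)))
  matrix(w, nrow = length(t_ms))
}

# oversampled centred spectrum of one (possibly coil-weighted) compartment
comp_spectrum <- function(plan, labels, label_id, coil_ch = NULL) {
  ind <- array(as.numeric(labels == label_id), dim = plan$grid)
  if (!is.null(coil_ch)) ind <- ind * coil_ch
  cfft3(pad_center(deap_apply(ind + 0i, plan), plan$nos))
}

#' Radial k-space forward simulation of a labelled volume
#'
#' Evaluates \deqn{S(k_j) = \sum_c w_c(t_j) F\{1_c \cdot s_{ch}\}(k_j)}
#' with `F` the Fourier transform of the compartment indicator (type-2
#' NUFFT), optionally weighted by complex coil sensitivities, and
#' relaxation/saturation weights from [signal_weight()].
#'
#' @param labels a `label_volume` ([build_labels()]).
#' @param tissue [tissue_params()] covering every nonzero label.
#' @param traj a [radial_trajectory()].
#' @param FA_deg,TR_ms excitation parameters for the weights.
#' @param coil optional [coil_sensitivities()] (per-channel output).
#' @param proj_idx projections to simulate (default all).
#' @param plan optional pre-built [nufft_plan()] for the label grid.
#' @param spectra optional cached result of a previous call (attribute
#'   `spectra`) to skip the per-compartment FFTs.
#' @return complex array `n_samples x n_proj x n_channels`; the cached
#'   per-compartment spectra are attached as attribute `spectra`.
#' @export
forward_signal <- function(labels, tissue, traj, FA_deg, TR_ms, coil = NULL,
                           proj_idx = NULL, plan = NULL, spectra = NULL,
                           cache_labels = tissue$label) {
  labs_present <- sort(unique(as.vector(labels)))
  labs_present <- labs_present[labs_present != 0]
  if (!all(labs_present %in% tissue$label))
    stop("unknown label in volume: no tissue parameters for ",
         paste(setdiff(labs_present, tissue$label), collapse = ", "))
  voxel_mm <- attr(labels, "voxel_mm")
  if (is.null(plan)) plan <- nufft_plan(dim(labels))
  if (is.null(proj_idx)) proj_idx <- seq_len(nrow(traj$dirs))
  nch <- if (is.null(coil)) 1L else dim(coil)[4]
  pts <- sweep(traj_freq(traj, voxel_mm, proj_idx), 2, plan$nos, "*")
  W <- signal_weight(tissue, traj$t_ms, FA_deg, TR_ms)
  ns <- length(traj$radii)
  out <- array(0 + 0i, dim = c(ns, length(proj_idx), nch))
  keep <- tissue$label %in% labs_present
  new_spectra <- if (is.null(spectra)) list() else spectra
  for (i in which(keep)) {
    lab <- tissue$label[i]
    wfull <- rep(W[, i], length(proj_idx))
    for (ch in seq_len(nch)) {
      key <- paste0("l", lab, "c", ch)
      sp <- new_spectra[[key]]
      if (is.null(sp)) {
        cc <- if (is.null(coil)) NULL else array(coil[, , , ch],
                                                 dim = plan$grid)
        sp <- comp_spectrum(plan, labels, lab, cc)
        if (lab %in% cache_labels) new_spectra[[key]] <- sp
      }
      v <- cpp_kb_interp(sp, plan$nos, pts, plan$width, plan$beta)
      out[, , ch] <- out[, , ch] + array(v * wfull,
                                         dim = c(ns, length(proj_idx)))
    }
  }
  attr(out, "spectra") <- new_spectra
  out
}

new_kspace_set <- function(data, traj, timestamps, nucleus, labels = NULL) {
  structure(list(data = data, traj = traj, timestamps = timestamps,
                 nucleus = nucleus, labels = labels),
            class = "kspace_set")
}

#' @export
print.kspace_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace_set %s: %d projections x %d samples x %d channel(s)>\n",
              x$nucleus, d[2], d[1], d[3]))
  invisible(x)
}

# motion state id for timestamps under a given motion mode (used to group
# projections so each distinct phantom state is simulated once)
motion_state_id <- function(t, motion, mode) {
  if (mode == "static") return(rep(0L, length(t)))
  rid <- floor((t %% motion$resp_cycle_s) / motion$dt_state_s)
  nk <- n_motion_states(motion, "cardiac")
  dtk <- if (!is.null(motion$n_cardiac_states))
    motion$card_cycle_s / motion$n_cardiac_states else motion$dt_state_s
  kid <- pmin(floor((t %% motion$card_cycle_s) / dtk), nk - 1)
  switch(mode, resp = as.integer(rid), cardiac = as.integer(kid),
         combined = as.integer(rid * nk + kid))
}

#' Assemble a composite k-space over the motion cycle
#'
#' Simulates every projection from the phantom state at its acquisition
#' timestamp (snapped to the motion-state grid) and combines them into a
#' single composite radial k-space per nucleus, as acquired by the
#' interleaved sequence.  States are simulated once and reused.
#'
#' @param geometry,motion phantom description ([phantom_geometry()],
#'   [motion_params()]).
#' @param seq a [sequence_params()].
#' @param TA_s acquisition duration (s).
#' @param mode motion mode: `"static"`, `"resp"`, `"cardiac"`, `"combined"`.
#' @param coil [coil_sensitivities()] for the 1H channel(s).
#' @param tissue_na,tissue_h tissue parameter tables.
#' @param progress print per-state progress.
#' @return list with `na` and `h` [new_kspace_set()]s, the navigator
#'   series (`nav`), and the `timeline`.
#' @export
assemble_composite_kspace <- function(geometry, motion, seq, TA_s,
                                      mode = "resp", coil = NULL,
                                      tissue_na = tissue_params("23Na"),
                                      tissue_h = tissue_params("1H"),
                                      progress = FALSE) {
  tl <- sequence_timeline(seq, TA_s)
  t_na <- tl$t[tl$nucleus == "23Na"]
  t_h <- tl$t[tl$nucleus == "1H"]
  traj_na <- radial_trajectory(length(t_na), seq$na_samples, seq$na_dwell_us,
                               seq$TE_23Na, seq$na_nominal_mm)
  traj_h <- radial_trajectory(length(t_h), seq$h_samples, seq$h_dwell_us,
                              seq$TE_1H, seq$h_nominal_mm)
  nch <- if (is.null(coil)) 1L else dim(coil)[4]
  plan <- nufft_plan(geometry$grid_shape)
  data_na <- array(0 + 0i, dim = c(seq$na_samples, length(t_na), 1))
  data_h <- array(0 + 0i, dim = c(seq$h_samples, length(t_h), nch))
  nav <- matrix(0 + 0i, length(t_h), nch)
  sid_na <- motion_state_id(t_na, motion, mode)
  sid_h <- motion_state_id(t_h, motion, mode)
  states <- sort(unique(c(sid_na, sid_h)))
  # compartments whose masks are unchanged across the states of this motion
  # mode are simulated once and their k-space spectra cached; the body is
  # carved by the moving organs under respiration, while cardiac
  # contraction only exchanges voxels between the heart and the
  # surrounding pericardial lung shell
  static_labs <- switch(mode, static = 1:4, resp = integer(0),
                        cardiac = 1L, combined = integer(0))
  keys_na <- paste0("l", static_labs, "c", 1)
  keys_h <- as.vector(outer(paste0("l", static_labs, "c"), seq_len(nch),
                            paste0))
  cache_na <- list()
  cache_h <- list()
  wnav <- signal_weight(tissue_h, seq$TE_1H, seq$FA_1H, mean(seq$TR_1H))
  for (s in states) {
    if (progress) message("simulating motion state ", s)
    ina <- which(sid_na == s)
    ih <- which(sid_h == s)
    t_rep <- if (length(ina)) t_na[ina[1]] else t_h[ih[1]]
    labs <- phantom_state(geometry, motion, t_rep, mode)
    if (length(ina)) {
      v <- forward_signal(labs, tissue_na, traj_na, seq$FA_23Na, seq$TR_23Na,
                          proj_idx = ina, plan = plan, spectra = cache_na,
                          cache_labels = static_labs)
      data_na[, ina, 1] <- data_na[, ina, 1] + v[, , 1]
      cache_na <- attr(v, "spectra")
    }
    if (length(ih)) {
      v <- forward_signal(labs, tissue_h, traj_h, seq$FA_1H, mean(seq$TR_1H),
                          coil = coil, proj_idx = ih, plan = plan,
                          spectra = cache_h, cache_labels = static_labs)
      data_h[, ih, ] <- data_h[, ih, , drop = FALSE] + v
      cache_h <- attr(v, "spectra")
      # navigator: coil-weighted volume integral of the current state
      k0 <- vapply(seq_len(nch), function(ch) {
        cc <- if (is.null(coil)) array(1, dim = dim(labs)) else
          array(coil[, , , ch], dim = dim(labs))
        sum(vapply(seq_len(nrow(tissue_h)), function(i)
          wnav[1, i] * sum(cc[labs == tissue_h$label[i]]), complex(1)))
      }, complex(1))
      nav[ih, ] <- matrix(k0, length(ih), nch, byrow = TRUE)
    }
  }
  list(na = new_kspace_set(data_na, traj_na, t_na, "23Na"),
       h = new_kspace_set(data_h, traj_h, t_h, "1H"),
       nav = new_navigator_series(nav, t_h),
       timeline = tl)
}

#' Add complex Gaussian noise to k-space or navigator data
#'
#' i.i.d. Gaussian noise of standard deviation `sigma` per real and
#' imaginary component, deterministic for a fixed seed; the input is left
#' untouched.  For navigator series the effective sigma is divided by
#' `sqrt(nav_samples)` to reflect the averaging of the k0 samples.
#'
#' @param x a `kspace_set` or `navigator_series`.
#' @param sigma noise standard deviation per component.
#' @param seed RNG seed.
#' @param nav_samples navigator averaging factor (navigator method).
#' @export
add_noise <- function(x, sigma, seed, ...) UseMethod("add_noise")

#' @rdname add_noise
#' @export
add_noise.kspace_set <- function(x, sigma, seed, ...) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  n <- length(x$data)
  x$data <- x$data + with_seed(seed, array(complex(real = rnorm(n, 0, sigma),
                                                   imaginary = rnorm(n, 0, sigma)),
                                           dim = dim(x$data)))
  x
}

#' @rdname add_noise
#' @export
add_noise.navigator_series <- function(x, sigma, seed, nav_samples = 10, ...) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  s <- sigma / sqrt(nav_samples)
  n <- length(x$values)
  x$values <- x$values + with_seed(seed + 1L,
    matrix(complex(real = rnorm(n, 0, s), imaginary = rnorm(n, 0, s)),
           nrow(x$values), ncol(x$values)))
  x
}
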