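#' Parametric dynamic digital torso phantom
#'
#' A simple ellipsoid-based torso phantom standing in for anatomical
#' simulation phantoms: a torso body, two lungs, and a heart consisting of a
#' myocardial shell enclosing a ventricular blood pool; the heart sits
#' retrosternally (anterior) as in real anatomy.  Respiratory motion
#' rigidly translates heart and lungs; cardiac motion contracts the
#' ventricle.  All arrays are ordered (SI, AP, LR); world coordinates are in
#' mm at voxel centres with the origin at the voxel with 0-based index
#' `n/2` on each axis.
#'
#' @param grid_shape voxels per axis (SI, AP, LR).
#' @param voxel_mm isotropic voxel size in mm.
#' @param torso,lung_left,lung_right,heart lists with `center` and `semi`
#'   (semiaxes), both length-3 in mm.  Lung centres are mirrored defaults.
#' @param wall_mm myocardial wall thickness in mm.
#' @param pericardium_mm thickness of the low-signal (lung-labelled)
#'   shell embedding the heart, emulating the cardiac notch of the lungs.
#' @return a `phantom_geometry` object.
#' @export
phantom_geometry <- function(grid_shape = c(64, 64, 64), voxel_mm = 4,
                             torso = list(center = c(0, 0, 0),
                                          semi = c(125, 85, 105)),
                             lung_left = list(center = c(15, -8, 68),
                                              semi = c(72, 45, 25)),
                             lung_right = list(center = c(15, -8, -68),
                                               semi = c(72, 45, 25)),
                             heart = list(center = c(0, -20, 10),
                                          semi = c(42, 36, 30)),
                             wall_mm = 10, pericardium_mm = 25) {
  g <- list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
            torso = torso, lung_left = lung_left, lung_right = lung_right,
            heart = heart, wall_mm = wall_mm,
            pericardium_mm = pericardium_mm)
  class(g) <- "phantom_geometry"
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  semis <- c(g$torso$semi, g$lung_left$semi, g$lung_right$semi, g$heart$semi)
  if (any(semis <= 0)) stop("all ellipsoid semiaxes must be positive")
  if (g$wall_mm <= 0) stop("myocardial wall thickness must be positive")
  if (any(g$wall_mm >= g$heart$semi))
    stop("wall thickness must be smaller than every ventricular semiaxis")
  # heart strictly inside the torso (sufficient check on the bounding box)
  hi <- abs(g$heart$center) + g$heart$semi
  if (any(hi >= g$torso$semi))
    stop("invalid geometry: heart ellipsoid not strictly inside the torso")
  invisible(g)
}

#' Physiological motion parameters
#'
#' Defaults encode a 3.6 s respiratory cycle with (18.4, 2.4, 0) mm
#' (SI, AP, LR) peak heart excursion and a 1 s cardiac cycle with 400 ms
#' systole and 600 ms diastole, both sampled on a 60 ms motion-state grid.
#'
#' @param resp_cycle_s respiratory period (s).
#' @param resp_excursion_mm peak (SI, AP, LR) excursion of heart + lungs.
#' @param card_cycle_s,systole_s,diastole_s cardiac timing (s).
#' @param contraction_fraction peak systolic reduction of the ventricular
#'   inner radius (unitless, in (0, 1)).
#' @param dt_state_s motion-state sampling interval (s).
#' @param n_cardiac_states optional explicit number of cardiac states; by
#'   default states fall on the `dt_state_s` grid within one cycle.
#' @export
motion_params <- function(resp_cycle_s = 3.6,
                          resp_excursion_mm = c(18.4, 2.4, 0),
                          card_cycle_s = 1.0, systole_s = 0.4,
                          diastole_s = 0.6, contraction_fraction = 0.25,
                          dt_state_s = 0.060, n_cardiac_states = NULL) {
  stopifnot(abs(systole_s + diastole_s - card_cycle_s) < 1e-9,
            contraction_fraction > 0, contraction_fraction < 1,
            dt_state_s > 0)
  m <- list(resp_cycle_s = resp_cycle_s,
            resp_excursion_mm = resp_excursion_mm,
            card_cycle_s = card_cycle_s, systole_s = systole_s,
            diastole_s = diastole_s,
            contraction_fraction = contraction_fraction,
            dt_state_s = dt_state_s,
            n_cardiac_states = n_cardiac_states)
  class(m) <- "motion_params"
  m
}

#' Tissue parameters per compartment
#'
#' Sodium defaults: myocardium 43 mM (41 umol/g at a specific gravity of
#' 1.05 g/mL), blood 81 mM; biexponential T2* with a short fraction `r`;
#' T1 of 30 ms (myocardium) and 49.5 ms (blood).  The `h1` set holds the
#' proton parameters used for the 1H channel of the interleaved simulation
#' (mono-exponential T2*, short fraction zero).
#'
#' @param nucleus `"23Na"` or `"1H"`.
#' @return data.frame with one row per compartment (label ids match
#'   [build_labels()]): `label, name, c, T1, T2s, T2l, r` (times in ms,
#'   concentrations in mM or relative proton density).
#' @export
tissue_params <- function(nucleus = c("23Na", "1H")) {
  nucleus <- match.arg(nucleus)
  if (nucleus == "23Na") {
    data.frame(
      label = 1:4,
      name = c("body", "lung", "myocardium", "blood"),
      c = c(20, 4, 43, 81),
      T1 = c(25, 20, 30, 49.5),
      T2s = c(2.0, 1.5, 3.0, 2.5),
      T2l = c(15, 10, 20, 17),
      r = c(0.6, 0.6, 0.6, 0.6))
  } else {
    # effective densities emulate the appearance of an inflow-enhanced
    # spoiled GRE: bright ventricular blood, darker myocardium, dark lung
    data.frame(
      label = 1:4,
      name = c("body", "lung", "myocardium", "blood"),
      c = c(0.80, 0.12, 0.60, 1.30),
      T1 = c(1500, 1300, 1900, 2200),
      T2s = c(20, 1.5, 15, 20),
      T2l = c(20, 1.5, 15, 20),
      r = c(0, 0, 0, 0))
  }
}

# world coordinates (mm) of all voxel centres, M x 3, NUFFT-centred
grid_coords <- function(grid_shape, voxel_mm) {
  ax <- lapply(1:3, function(a)
    ((seq_len(grid_shape[a]) - 1) - grid_shape[a] / 2) * voxel_mm)
  list(x = ax[[1]], y = ax[[2]], z = ax[[3]])
}

# squared normalized ellipsoid distance field on the grid (<= 1 inside)
ellipsoid_q <- function(co, center, semi) {
  qx <- ((co$x - center[1]) / semi[1])^2
  qy <- ((co$y - center[2]) / semi[2])^2
  qz <- ((co$z - center[3]) / semi[3])^2
  outer(outer(qx, qy, "+"), qz, "+")
}

#' Build compartment labels for a phantom state
#'
#' Labels: 0 background, 1 body, 2 lung, 3 myocardium, 4 blood pool.
#' The myocardium is the shell between the outer heart ellipsoid and the
#' inner (blood pool) ellipsoid obtained by shrinking each semiaxis by the
#' wall thickness; drawing order body < lung < myocardium < blood resolves
#' anatomical overlap of heart and lungs.
#'
#' @param geometry a [phantom_geometry()].
#' @param heart_shift,lung_shift rigid translations (mm) applied to the
#'   heart and lung centres (respiratory state).
#' @param inner_scale,outer_scale scale factors for the inner and outer
#'   ventricular semiaxes (cardiac state).
#' @param time_s timestamp tag stored with the volume.
#' @return a `label_volume`: integer array with attributes `voxel_mm` and
#'   `time_s`.
#' @export
build_labels <- function(geometry, heart_shift = c(0, 0, 0),
                         lung_shift = heart_shift, inner_scale = 1,
                         outer_scale = 1, time_s = 0) {
  g <- validate_geometry(geometry)
  co <- grid_coords(g$grid_shape, g$voxel_mm)
  lab <- array(0L, dim = g$grid_shape)
  lab[ellipsoid_q(co, g$torso$center, g$torso$semi) <= 1] <- 1L
  lab[ellipsoid_q(co, g$lung_left$center + lung_shift,
                  g$lung_left$semi) <= 1] <- 2L
  lab[ellipsoid_q(co, g$lung_right$center + lung_shift,
                  g$lung_right$semi) <= 1] <- 2L
  hc <- g$heart$center + heart_shift
  # pericardial lung shell: the heart sits in the cardiac notch of the
  # lungs, so contraction exposes low-signal lung rather than body
  lab[ellipsoid_q(co, hc, g$heart$semi + g$pericardium_mm) <= 1] <- 2L
  outer_semi <- g$heart$semi * outer_scale
  inner_semi <- (g$heart$semi - g$wall_mm) * inner_scale
  lab[ellipsoid_q(co, hc, outer_semi) <= 1] <- 3L
  lab[ellipsoid_q(co, hc, inner_semi) <= 1] <- 4L
  structure(lab, voxel_mm = g$voxel_mm, time_s = time_s,
            class = c("label_volume", "array"))
}

# raised-cosine respiratory displacement (0 = fully exhaled at t = 0)
resp_displacement <- function(motion, t) {
  phase <- (1 - cos(2 * pi * t / motion$resp_cycle_s)) / 2
  motion$resp_excursion_mm * phase
}

# cardiac contraction profile on [0, cycle): smooth systolic ramp to 1,
# recovery over the first third of diastole, then relaxed plateau
contraction_profile <- function(motion, t) {
  tc <- t %% motion$card_cycle_s
  sys <- motion$systole_s
  rec <- motion$diastole_s / 3
  p <- numeric(length(tc))
  i1 <- tc < sys
  p[i1] <- sin(pi * tc[i1] / (2 * sys))^2
  i2 <- tc >= sys & tc < sys + rec
  p[i2] <- cos(pi * (tc[i2] - sys) / (2 * rec))^2
  p
}

# snap a time to the motion-state grid and return the state's nominal time
snap_state_time <- function(t, cycle_s, dt, n_states = NULL) {
  if (!is.null(n_states)) dt <- cycle_s / n_states
  idx <- floor((t %% cycle_s) / dt)
  idx <- pmin(idx, ceiling(cycle_s / dt) - 1)
  idx * dt
}

#' Phantom compartment masks at a given time
#'
#' @param geometry a [phantom_geometry()].
#' @param motion a [motion_params()].
#' @param t time since scan start (s), snapped to the motion-state grid.
#' @param mode `"resp"` (heart end-diastolic, breathing only), `"cardiac"`
#'   (fully exhaled, heartbeat only), `"combined"`, or `"static"`.
#' @return a `label_volume` (see [build_labels()]).
#' @export
phantom_state <- function(geometry, motion, t,
                          mode = c("resp", "cardiac", "combined", "static")) {
  mode <- match.arg(mode)
  stopifnot(t >= 0)
  d <- c(0, 0, 0)
  iscale <- 1
  oscale <- 1
  if (mode %in% c("resp", "combined")) {
    tr <- snap_state_time(t, motion$resp_cycle_s, motion$dt_state_s)
    d <- resp_displacement(motion, tr)
  }
  if (mode %in% c("cardiac", "combined")) {
    tk <- snap_state_time(t, motion$card_cycle_s, motion$dt_state_s,
                          motion$n_cardiac_states)
    p <- contraction_profile(motion, tk)
    iscale <- 1 - motion$contraction_fraction * p
    # outer semiaxes shrink so that myocardial (shell) volume is conserved
    vin <- prod(geometry$heart$semi - geometry$wall_mm) /
      prod(geometry$heart$semi)
    oscale <- (1 - vin * (1 - iscale^3))^(1 / 3)
  }
  build_labels(geometry, heart_shift = d, lung_shift = d,
               inner_scale = iscale, outer_scale = oscale, time_s = t)
}

# number of distinct motion states per cycle
n_motion_states <- function(motion, which = c("resp", "cardiac")) {
  which <- match.arg(which)
  if (which == "resp") {
    as.integer(round(motion$resp_cycle_s / motion$dt_state_s))
  } else if (!is.null(motion$n_cardiac_states)) {
    as.integer(motion$n_cardiac_states)
  } else {
    as.integer(ceiling(motion$card_cycle_s / motion$dt_state_s))
  }
}

#' Smooth complex coil sensitivity maps
#'
#' Gaussian-magnitude lobes centred on points around the torso surface with
#' a smooth per-channel linear phase; a single channel is centred on the
#' torso for a near-uniform profile.  Deterministic for a fixed seed.
#'
#' @param geometry a [phantom_geometry()].
#' @param n_channels number of receive channels.
#' @param seed RNG seed for channel jitter and phase.
#' @param sigma_mm lobe width (mm).
#' @return `coil_model`: complex array (grid x channel) plus channel
#'   positions in the `positions` attribute.
#' @export
coil_sensitivities <- function(geometry, n_channels = 16, seed = 1,
                               sigma_mm = 70) {
  stopifnot(n_channels >= 1)
  g <- geometry
  co <- grid_coords(g$grid_shape, g$voxel_mm)
  sens <- array(0 + 0i, dim = c(g$grid_shape, n_channels))
  pos <- matrix(0, n_channels, 3)
  with_seed(seed, {
    for (ch in seq_len(n_channels)) {
      if (n_channels == 1) {
        p <- g$torso$center
      } else {
        th <- 2 * pi * (ch - 1) / n_channels + runif(1, -0.1, 0.1)
        si <- g$torso$semi[1] * 0.3 * (2 * (ch %% 2) - 1) + runif(1, -10, 10)
        p <- c(si, 1.05 * g$torso$semi[2] * cos(th),
               1.05 * g$torso$semi[3] * sin(th))
      }
      pos[ch, ] <- p
      r2 <- ellipsoid_q(co, p, rep(sigma_mm, 3))
      gphase <- runif(3, -pi, pi) / (g$grid_shape * g$voxel_mm)
      ph <- outer(outer(co$x * gphase[1], co$y * gphase[2], "+"),
                  co$z * gphase[3], "+") + runif(1, -pi, pi)
      sens[, , , ch] <- exp(-r2 / 2) * exp(1i * ph)
    }
  })
  structure(sens, positions = pos, voxel_mm = g$voxel_mm,
            class = c("coil_model", "array"))
}

#' Synthetic multiplicative B1 bias field
#'
#' Product of an exponential receive-type falloff from the anterior
#' surface, a low-order polynomial ramp, and Gaussian-filtered white
#' noise with correlation scale `smoothness_mm`, normalized to mean 1
#' over the heart region.  The defaults emulate the strong transmit/
#' receive profile of a 7T torso coil, which varies by tens of percent
#' across the heart and perturbs uncorrected quantification accordingly.
#' Infinite smoothness yields the constant field 1.
#'
#' @param geometry a [phantom_geometry()].
#' @param seed RNG seed.
#' @param smoothness_mm Gaussian smoothing scale of the stochastic part.
#' @param noise_amp relative amplitude of the stochastic part.
#' @param poly_amp relative amplitude of the linear ramp part.
#' @param falloff_mm decay length of the anterior-posterior receive
#'   falloff (`Inf` disables it).
#' @return `bias_field`: positive array with attribute
#'   `provenance = "synthetic"`.
#' @export
synthetic_bias_field <- function(geometry, seed = 1, smoothness_mm = 60,
                                 noise_amp = 0.15, poly_amp = 0.35,
                                 falloff_mm = 120) {
  g <- geometry
  stopifnot(is.infinite(smoothness_mm) || smoothness_mm > g$voxel_mm)
  co <- grid_coords(g$grid_shape, g$voxel_mm)
  fov <- g$grid_shape * g$voxel_mm
  field <- array(1, dim = g$grid_shape)
  if (!is.infinite(smoothness_mm)) {
    with_seed(seed, {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      ramp <- outer(outer(co$x * dir[1] / fov[1], co$y * dir[2] / fov[2], "+"),
                    co$z * dir[3] / fov[3], "+")
      noise <- array(rnorm(prod(g$grid_shape)), dim = g$grid_shape)
      sm <- gauss_filter3(noise, smoothness_mm / g$voxel_mm)
      sm <- (sm - mean(sm)) / sd(sm)
      field <- 1 + poly_amp * ramp + noise_amp * sm
      if (is.finite(falloff_mm)) {
        depth <- outer(outer(rep(0, g$grid_shape[1]),
                             co$y - min(co$y), "+"),
                       rep(0, g$grid_shape[3]), "+")
        field <- field * exp(-depth / falloff_mm)
      }
    })
  }
  heart <- ellipsoid_q(co, g$heart$center, g$heart$semi) <= 1
  field <- field / mean(field[heart])
  field <- pmax(field, 0.05)
  structure(array(field, dim = g$grid_shape), provenance = "synthetic",
            voxel_mm = g$voxel_mm, class = c("bias_field", "array"))
}

#' Shift a field by a world-space offset
#'
#' Samples the input at `x - shift_mm` with trilinear interpolation
#' (clamped at the boundary), emulating a changed position of the anatomy
#' relative to the coil's bias field.
#'
#' @param field 3D array with a `voxel_mm` attribute (or `voxel_mm` given).
#' @param shift_mm length-3 shift in mm (SI, AP, LR).
#' @param voxel_mm voxel size override.
#' @export
shift_field <- function(field, shift_mm, voxel_mm = attr(field, "voxel_mm")) {
  d <- dim(field)
  idx <- as.matrix(expand.grid(seq_len(d[1]) - 1, seq_len(d[2]) - 1,
                               seq_len(d[3]) - 1))
  pts <- sweep(idx, 2, shift_mm / voxel_mm, "-")
  pts <- pmin(pmax(pts, 0), matrix(rep(d - 1, each = nrow(pts)), ncol = 3))
  out <- array(cpp_trilinear(as.vector(field), d, pts, 0), dim = d)
  attributes(out) <- attributes(field)
  out
}

# isotropic Gaussian filter via FFT (circular); sigma in voxels
gauss_filter3 <- function(x, sigma_vox) {
  d <- dim(x)
  kern1 <- function(n) {
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    exp(-2 * (pi * f * sigma_vox)^2)
  }
  K <- outer(outer(kern1(d[1]), kern1(d[2])), kern1(d[3]))
  Re(fft(fft(x) * K, inverse = TRUE)) / prod(d)
}
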