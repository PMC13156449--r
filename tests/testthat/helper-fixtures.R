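# shared small-scale fixtures; heavyweight simulations are cached per
# session so several test files can reuse them

small_geometry <- function(n = 32, voxel = 8) {
  phantom_geometry(grid_shape = rep(n, 3), voxel_mm = voxel)
}

test_sequence <- function(voxel = 8) {
  sequence_params(na_nominal_mm = voxel, h_nominal_mm = voxel)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# static composite acquisition of the default small phantom
static_sim <- function() {
  cached("static_sim", {
    geom <- small_geometry()
    assemble_composite_kspace(geom, motion_params(), test_sequence(), 48,
                              mode = "static")
  })
}

# structured image fixture with texture that breaks rotational symmetry
textured_image <- function(n = 48, voxel = 5, seed = 3) {
  geom <- phantom_geometry(grid_shape = rep(n, 3), voxel_mm = voxel)
  labs <- build_labels(geom)
  tex <- with_seed(seed, {
    noise <- array(rnorm(n^3), dim = rep(n, 3))
    naheart:::gauss_filter3(noise, 2)
  })
  img <- (as.numeric(labs > 0) + (labs == 3) + 2 * (labs == 4)) *
    (1 + 0.4 * tex)
  img <- array(img, dim = rep(n, 3))
  attr(img, "voxel_mm") <- voxel
  list(geometry = geom, labels = labs, image = img)
}

# brute-force discrete Fourier sum (independent of the NUFFT machinery)
dft_direct <- function(img, freq) {
  d <- dim(img)
  xc <- lapply(1:3, function(a) (seq_len(d[a]) - 1) - d[a] / 2)
  co <- as.matrix(expand.grid(xc[[1]], xc[[2]], xc[[3]]))
  v <- as.vector(img)
  vapply(seq_len(nrow(freq)), function(m)
    sum(v * exp(-2i * pi * (co %*% freq[m, ]))), complex(1))
}
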