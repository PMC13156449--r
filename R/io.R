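#' Read and write volumes as NIfTI-1
#'
#' Label volumes are stored as integers, images as floats; the affine
#' encodes the isotropic voxel size.  Attributes `voxel_mm` (and label
#' class) are restored on read.
#'
#' @param vol 3D array with a `voxel_mm` attribute.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_volume <- function(vol, path) {
  voxel_mm <- attr(vol, "voxel_mm")
  if (is.null(voxel_mm)) stop("volume needs a voxel_mm attribute")
  arr <- array(vol, dim = dim(vol))
  attr(arr, "pixdim") <- rep(voxel_mm, 3)
  img <- RNifti::asNifti(arr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param path input path.
#' @param labels read as an integer label volume.
#' @export
read_volume <- function(path, labels = FALSE) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1]
  arr <- if (labels) array(as.integer(round(img)), dim = dim(img)) else
    array(as.numeric(img), dim = dim(img))
  attr(arr, "voxel_mm") <- vox
  if (labels) class(arr) <- c("label_volume", "array")
  arr
}

#' Serialize a k-space set
#'
#' The composite radial k-space (complex samples, trajectory, timestamps,
#' gating labels) is stored as a single RDS container.
#'
#' @param ks a `kspace_set` (or a list of them).
#' @param path output path.
#' @export
write_kspace <- function(ks, path) {
  saveRDS(ks, path)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) readRDS(path)

#' Rigid transform JSON round trip
#'
#' Translations in mm, rotations in degrees, with the rotation centre and
#' Euler order recorded for interoperability.
#'
#' @param tf a [rigid_transform()] (or list of).
#' @param path output `.json` path.
#' @export
write_transform <- function(tf, path) {
  one <- function(x) list(translation_mm = x$translation,
                          rotation_deg = x$rotation,
                          reference = x$reference,
                          center = "image center", euler_order = "SI-AP-LR")
  obj <- if (inherits(tf, "rigid_transform")) one(tf) else lapply(tf, one)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(o) rigid_transform(unlist(o$translation_mm),
                                       unlist(o$rotation_deg),
                                       o$reference)
  if (!is.null(obj$translation_mm)) build(obj) else lapply(obj, build)
}

#' Run configuration round trip (YAML)
#'
#' @param config nested list of run parameters.
#' @param path `.yaml` path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

# short provenance hash of a configuration list
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}
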