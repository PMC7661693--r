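#' Read and write dual-echo volumes as paired NIfTI files
#'
#' A complex dual-echo volume is stored as four NIfTI images
#' (`<prefix>_echo<n>_<real|imag>.nii.gz`) plus a JSON sidecar
#' (`<prefix>.json`) recording the dialect and acquisition parameters.
#'
#' @param volume An `mra_dual_echo` volume.
#' @param prefix Path prefix (directory must exist).
#' @return `write_dual_echo()` returns the prefix invisibly;
#'   `read_dual_echo()` returns an `mra_dual_echo`.
#' @export
write_dual_echo <- function(volume, prefix) {
  stopifnot(inherits(volume, "mra_dual_echo"))
  p <- volume$params
  parts <- list(echo1_real = Re(volume$echo1), echo1_imag = Im(volume$echo1),
                echo2_real = Re(volume$echo2), echo2_imag = Im(volume$echo2))
  for (nm in names(parts)) {
    img <- RNifti::asNifti(parts[[nm]], pixdim = p$voxel_size_mm)
    RNifti::writeNifti(img, paste0(prefix, "_", nm, ".nii.gz"))
  }
  sidecar <- list(dialect = "real_imag",
                  files = paste0(basename(prefix), "_", names(parts), ".nii.gz"),
                  params = p[c("te1_ms", "te2_ms", "tr_ms", "field_strength_t",
                               "fat_offset_hz", "station_label", "voxel_size_mm")])
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_dual_echo
#' @export
read_dual_echo <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(sidecar$dialect, "real_imag")) {
    stop("unsupported dual-echo dialect: ", sidecar$dialect, call. = FALSE)
  }
  rd <- function(part) {
    arr <- RNifti::readNifti(paste0(prefix, "_", part, ".nii.gz"))
    array(as.numeric(arr), dim(arr))
  }
  sp <- sidecar$params
  params <- acquisition_params(sp$te1_ms, sp$te2_ms, sp$tr_ms,
                               sp$field_strength_t, sp$fat_offset_hz,
                               sp$station_label, sp$voxel_size_mm)
  dual_echo_volume(rd("echo1_real") + 1i * rd("echo1_imag"),
                   rd("echo2_real") + 1i * rd("echo2_imag"),
                   params)
}

#' Read and write magnitude volumes as NIfTI
#'
#' @param volume 3D numeric array.
#' @param path NIfTI file path.
#' @param voxel_size_mm Voxel size recorded in the header.
#' @return `read_volume()` returns a plain 3D array.
#' @export
write_volume <- function(volume, path, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  RNifti::writeNifti(RNifti::asNifti(volume, pixdim = voxel_size_mm), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim(arr))
}

#' Persist a phantom specification as YAML
#'
#' @param spec An `mra_phantom_spec`.
#' @param path YAML file path.
#' @return `read_phantom_spec()` returns the reconstructed spec.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "mra_phantom_spec"))
  x <- unclass(spec)
  x$vessel_tree <- lapply(seq_len(nrow(spec$vessel_tree)),
                          function(i) as.list(spec$vessel_tree[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$vessel_tree <- dplyr::bind_rows(lapply(x$vessel_tree, tibble::as_tibble))
  phantom_spec(grid_shape = unlist(x$grid_shape),
               voxel_size_mm = unlist(x$voxel_size_mm),
               vessel_tree = x$vessel_tree,
               fat_params = x$fat_params,
               enhancement_factor = x$enhancement_factor,
               pre_contrast_fraction = x$pre_contrast_fraction,
               field_map_params = x$field_map_params,
               noise_sd = x$noise_sd,
               seed = x$seed)
}
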