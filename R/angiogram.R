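#' Station image: one reconstructed magnitude volume at one table position
#'
#' @param volume Nonnegative (or signed, for unclipped subtractions) 3D
#'   magnitude array.
#' @param params [acquisition_params()].
#' @param method `"mdixon"` or `"subtraction"`.
#' @param table_offset_mm Foot-head offset of the station origin in the
#'   stitched frame.
#' @return An object of class `mra_station_image`.
#' @export
station_image <- function(volume, params, method = c("mdixon", "subtraction"),
                          table_offset_mm = 0) {
  method <- match.arg(method)
  stopifnot(is.array(volume), length(dim(volume)) == 3L,
            inherits(params, "mra_params"))
  if (!all(is.finite(volume))) stop("station volume must be finite", call. = FALSE)
  structure(list(volume = volume, params = params, method = method,
                 table_offset_mm = table_offset_mm),
            class = "mra_station_image")
}

#' Water image of a Dixon reconstruction as a station image
#'
#' @param wf An `mra_water_fat` result.
#' @param table_offset_mm Foot-head offset of the station.
#' @return An `mra_station_image` with method `"mdixon"`.
#' @export
water_station_image <- function(wf, table_offset_mm = 0) {
  stopifnot(inherits(wf, "mra_water_fat"))
  station_image(wf$water, wf$params, "mdixon", table_offset_mm)
}

#' Conventional subtraction reconstruction
#'
#' Voxelwise magnitude subtraction of the pre-contrast from the
#' post-contrast first-echo image; only TE1 is used. Negative residuals are
#' clipped to zero by default (for maximum-intensity projection; clipped
#' signed noise would otherwise surface in the projection). Noise
#' statistics, however, are distorted by clipping, so quantitative analyses
#' of the subtraction image use `clip = FALSE`.
#'
#' @param pre,post `mra_dual_echo` volumes of the same station and shape.
#' @param clip Clip negative values to zero?
#' @param table_offset_mm Foot-head offset of the station.
#' @return An `mra_station_image` with method `"subtraction"`.
#' @export
subtract <- function(pre, post, clip = TRUE, table_offset_mm = 0) {
  stopifnot(inherits(pre, "mra_dual_echo"), inherits(post, "mra_dual_echo"))
  if (!identical(dim(pre$echo1), dim(post$echo1))) {
    stop("shape mismatch between pre (", paste(dim(pre$echo1), collapse = "x"),
         ") and post (", paste(dim(post$echo1), collapse = "x"), ")",
         call. = FALSE)
  }
  if (!identical(pre$params$station_label, post$params$station_label)) {
    stop("pre and post volumes belong to different stations", call. = FALSE)
  }
  v <- Mod(post$echo1) - Mod(pre$echo1)
  if (clip) v <- pmax(v, 0)
  station_image(v, post$params, "subtraction", table_offset_mm)
}

#' Coronal maximum-intensity projection
#'
#' Projects a station volume along the anterior-posterior axis (y), the
#' standard angiographic rendering: each (x, z) pixel takes the maximum
#' over its A-P column.
#'
#' @param image An `mra_station_image`.
#' @return An object of class `mra_mip`: the 2D projection plus pixel
#'   sizes, table offset and method.
#' @export
mip_coronal <- function(image) {
  stopifnot(inherits(image, "mra_station_image"))
  proj <- apply(image$volume, c(1, 3), max)
  structure(list(pixels = proj,
                 pixel_size_mm = image$params$voxel_size_mm[c(1, 3)],
                 table_offset_mm = image$table_offset_mm,
                 method = image$method,
                 station_label = image$params$station_label),
            class = "mra_mip")
}

#' Stitch station MIPs into a whole-leg panorama
#'
#' Places each coronal MIP at its foot-head table offset on a common canvas
#' spanning the union of the station extents; overlapping rows are combined
#' by per-pixel maximum (consistent with MIP semantics). A gap between
#' stations raises a warning and stays zero.
#'
#' @param mips List of `mra_mip` objects with identical foot-head pixel
#'   size and width.
#' @return An object of class `mra_panorama` with the stitched pixel matrix
#'   and `extent_fh_mm`, the total foot-head coverage.
#' @export
stitch <- function(mips) {
  stopifnot(length(mips) >= 1L, all(vapply(mips, inherits, TRUE, "mra_mip")))
  vz <- vapply(mips, function(m) m$pixel_size_mm[2], 1)
  if (max(vz) - min(vz) > 1e-9) {
    stop("foot-head pixel sizes differ between stations", call. = FALSE)
  }
  vz <- vz[1]
  nx <- vapply(mips, function(m) nrow(m$pixels), 1L)
  if (length(unique(nx)) != 1L) stop("station widths differ", call. = FALSE)
  offs <- vapply(mips, function(m) m$table_offset_mm, 1)
  mips <- mips[order(offs)]
  offs <- sort(offs)

  z0 <- min(offs)
  row0 <- (offs - z0) / vz
  if (any(abs(row0 - round(row0)) > 1e-6)) {
    stop("table offsets are not integer multiples of the foot-head pixel size",
         call. = FALSE)
  }
  row0 <- as.integer(round(row0))
  nz <- vapply(mips, function(m) ncol(m$pixels), 1L)
  n_total <- max(row0 + nz)
  canvas <- matrix(0, nrow = nx[1], ncol = n_total)
  covered <- logical(n_total)
  for (i in seq_along(mips)) {
    cols <- (row0[i] + 1L):(row0[i] + nz[i])
    canvas[, cols] <- pmax(canvas[, cols], mips[[i]]$pixels)
    covered[cols] <- TRUE
  }
  if (!all(covered)) {
    warning("gap between stations: ", sum(!covered),
            " uncovered foot-head rows left zero", call. = FALSE)
  }
  structure(list(pixels = canvas,
                 pixel_size_mm = c(mips[[1]]$pixel_size_mm[1], vz),
                 extent_fh_mm = n_total * vz,
                 method = mips[[1]]$method),
            class = "mra_panorama")
}

#' @export
print.mra_mip <- function(x, ...) {
  cat(sprintf("<mra_mip> %s, %dx%d px (%s station)\n", x$method,
              nrow(x$pixels), ncol(x$pixels), x$station_label))
  invisible(x)
}

#' @export
print.mra_panorama <- function(x, ...) {
  cat(sprintf("<mra_panorama> %s, %dx%d px, %.0f mm foot-head extent\n",
              x$method, nrow(x$pixels), ncol(x$pixels), x$extent_fh_mm))
  invisible(x)
}
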