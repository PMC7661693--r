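#' Phantom specification for a synthetic dual-echo angiography station
#'
#' Describes everything needed to generate one station of a synthetic
#' contrast-enhanced peripheral MRA exam: the voxel grid, a branching vessel
#' tree (tube segments with optional stenoses/occlusions), a smooth water/fat
#' tissue partition (elliptical body with a subcutaneous fat shell), the
#' lumen enhancement factor, a smooth off-resonance field, and the complex
#' noise level.
#'
#' @param grid_shape Integer length-3: voxels per axis (x = L-R, y = A-P,
#'   z = F-H).
#' @param voxel_size_mm Numeric length-3 voxel size in mm.
#' @param vessel_tree Tibble with columns `segment`, `x1,y1,z1,x2,y2,z2`
#'   (endpoints in mm), `radius_mm`, `stenosis` (fraction 0-1 by which the
#'   radius is reduced over the middle third of the segment) and `occluded`
#'   (logical; an occluded segment contributes no lumen voxels).
#' @param fat_params List of tissue-partition parameters:
#'   `body_semiaxes_frac` (in-plane semi-axes of the body ellipse as a
#'   fraction of the field of view), `shell_thickness_mm` (subcutaneous fat
#'   layer), `shell_fat_fraction`, `interior_fat_fraction`, `tissue_density`
#'   (arbitrary units) and `lumen_water_density`.
#' @param enhancement_factor Multiplicative gain of the lumen water signal
#'   after contrast arrival (>= 1).
#' @param pre_contrast_fraction Pre-contrast lumen signal as a fraction of
#'   the post-contrast lumen signal (default 0.05; first-pass saturation
#'   keeps it below 0.10).
#' @param field_map_params List with `amplitude_hz` and `scale_mm` of the
#'   smooth off-resonance field.
#' @param noise_sd SD of the additive complex Gaussian noise, per real
#'   channel, in the same arbitrary units as the tissue densities.
#' @param seed Integer RNG seed for the noise substreams.
#'
#' @return An object of class `mra_phantom_spec`.
#' @seealso [default_phantom_spec()] for the station presets,
#'   [build_phantom()], [simulate_dual_echo()].
#' @export
phantom_spec <- function(grid_shape = c(144, 64, 86),
                         voxel_size_mm = c(3, 3, 5),
                         vessel_tree,
                         fat_params = list(body_semiaxes_frac = c(0.45, 0.42),
                                           shell_thickness_mm = 12,
                                           shell_fat_fraction = 0.9,
                                           interior_fat_fraction = 0.2,
                                           tissue_density = 1,
                                           lumen_water_density = 1),
                         enhancement_factor = 4,
                         pre_contrast_fraction = 0.05,
                         field_map_params = list(amplitude_hz = 30, scale_mm = 150),
                         noise_sd = 0.15,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, length(voxel_size_mm) == 3L)
  if (any(grid_shape < 1)) stop("grid_shape must be positive", call. = FALSE)
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be positive", call. = FALSE)
  vessel_tree <- as_vessel_tree(vessel_tree)
  if (enhancement_factor < 1) stop("enhancement_factor must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (pre_contrast_fraction < 0 || pre_contrast_fraction > 0.10) {
    stop("pre_contrast_fraction must lie in [0, 0.10]", call. = FALSE)
  }
  structure(
    list(grid_shape = as.integer(grid_shape),
         voxel_size_mm = as.numeric(voxel_size_mm),
         vessel_tree = vessel_tree,
         fat_params = fat_params,
         enhancement_factor = enhancement_factor,
         pre_contrast_fraction = pre_contrast_fraction,
         field_map_params = field_map_params,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "mra_phantom_spec"
  )
}

as_vessel_tree <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("segment", "x1", "y1", "z1", "x2", "y2", "z2", "radius_mm")
  missing <- setdiff(needed, names(x))
  if (length(missing)) stop("vessel_tree lacks columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (!"stenosis" %in% names(x)) x$stenosis <- 0
  if (!"occluded" %in% names(x)) x$occluded <- FALSE
  if (any(x$radius_mm <= 0)) stop("all vessel radii must be > 0", call. = FALSE)
  if (any(x$stenosis < 0 | x$stenosis > 1)) {
    stop("stenosis fractions must lie in [0, 1]", call. = FALSE)
  }
  len2 <- (x$x2 - x$x1)^2 + (x$y2 - x$y1)^2 + (x$z2 - x$z1)^2
  if (any(len2 == 0)) {
    stop("degenerate (zero-length) tube segment: ",
         paste(x$segment[len2 == 0], collapse = ", "), call. = FALSE)
  }
  x
}

# voxel-centre world coordinates along one axis (1-based index i -> (i-0.5)*v)
axis_coords <- function(n, v) (seq_len(n) - 0.5) * v

#' Rasterize a phantom specification into ground-truth tissue maps
#'
#' Produces the water density, fat density, true vessel mask and
#' off-resonance field on the voxel grid. A voxel belongs to the lumen when
#' its centre lies inside a tube segment whose local radius is reduced by the
#' stenosis fraction over the middle third of the segment; occluded segments
#' contribute nothing. Vessel voxels carry pure (unenhanced) water at the
#' lumen density; non-vessel body voxels split the tissue density between
#' water and fat according to the subcutaneous-shell/interior fat fractions.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `mra_tissue_maps`: list with 3D arrays
#'   `water`, `fat`, `vessel_mask`, `field_map_hz` and the `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "mra_phantom_spec"))
  d <- spec$grid_shape
  v <- spec$voxel_size_mm
  xs <- axis_coords(d[1], v[1]); ys <- axis_coords(d[2], v[2]); zs <- axis_coords(d[3], v[3])

  vessel <- array(FALSE, d)
  for (i in seq_len(nrow(spec$vessel_tree))) {
    seg <- spec$vessel_tree[i, ]
    if (isTRUE(seg$occluded)) next
    vessel <- vessel | rasterize_tube(seg, xs, ys, zs, d)
  }

  fov <- d * v
  fp <- spec$fat_params
  ax <- fp$body_semiaxes_frac[1] * fov[1]
  ay <- fp$body_semiaxes_frac[2] * fov[2]
  cx <- fov[1] / 2; cy <- fov[2] / 2
  exy <- outer((xs - cx)^2 / ax^2, (ys - cy)^2 / ay^2, "+")
  body2d <- exy <= 1
  axi <- max(ax - fp$shell_thickness_mm, 1e-6)
  ayi <- max(ay - fp$shell_thickness_mm, 1e-6)
  interior2d <- outer((xs - cx)^2 / axi^2, (ys - cy)^2 / ayi^2, "+") <= 1
  ff2d <- ifelse(interior2d, fp$interior_fat_fraction,
                 ifelse(body2d, fp$shell_fat_fraction, 0))
  body <- array(rep(body2d, times = d[3]), d)
  ff <- array(rep(ff2d, times = d[3]), d)

  water <- array(0, d); fat <- array(0, d)
  water[body] <- fp$tissue_density * (1 - ff[body])
  fat[body] <- fp$tissue_density * ff[body]
  water[vessel] <- fp$lumen_water_density
  fat[vessel] <- 0

  fm <- spec$field_map_params
  cz <- fov[3] / 2
  s <- fm$scale_mm
  field <- fm$amplitude_hz *
    outer(outer(cos(pi * (xs - cx) / (2 * s)), cos(pi * (ys - cy) / (2 * s))),
          cos(pi * (zs - cz) / (2 * s)))

  structure(list(water = water, fat = fat, vessel_mask = vessel,
                 field_map_hz = field, spec = spec),
            class = "mra_tissue_maps")
}

# voxel centres inside one (possibly stenosed) tube segment
rasterize_tube <- function(seg, xs, ys, zs, d) {
  p1 <- c(seg$x1, seg$y1, seg$z1); p2 <- c(seg$x2, seg$y2, seg$z2)
  dv <- p2 - p1
  len2 <- sum(dv^2)
  r <- seg$radius_mm
  lo <- pmin(p1, p2) - r; hi <- pmax(p1, p2) + r
  ix <- which(xs >= lo[1] & xs <= hi[1])
  iy <- which(ys >= lo[2] & ys <= hi[2])
  iz <- which(zs >= lo[3] & zs <= hi[3])
  out <- array(FALSE, d)
  if (!length(ix) || !length(iy) || !length(iz)) return(out)
  gx <- xs[ix]; gy <- ys[iy]; gz <- zs[iz]
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  X <- rep(gx, times = ny * nz)
  Y <- rep(rep(gy, each = nx), times = nz)
  Z <- rep(gz, each = nx * ny)
  t <- ((X - p1[1]) * dv[1] + (Y - p1[2]) * dv[2] + (Z - p1[3]) * dv[3]) / len2
  tc <- pmin(pmax(t, 0), 1)
  dx <- X - (p1[1] + tc * dv[1])
  dy <- Y - (p1[2] + tc * dv[2])
  dz <- Z - (p1[3] + tc * dv[3])
  rad2 <- dx^2 + dy^2 + dz^2
  r_loc <- r * (1 - seg$stenosis * as.numeric(tc > 1 / 3 & tc < 2 / 3))
  inside <- rad2 <= r_loc^2
  sub <- array(inside, c(nx, ny, nz))
  out[ix, iy, iz] <- sub
  out
}

#' Simulate a dual-gradient-echo acquisition of a phantom
#'
#' Per voxel the complex signal at echo n is
#' `(W' + F * c(TE_n)) * exp(i 2 pi psi TE_n) + eps_n`, where `W'` is the
#' water density with the lumen scaled by the enhancement factor
#' (post-contrast) or by `pre_contrast_fraction` times that (pre-contrast),
#' `c(TE)` the fat spectral phasor, `psi` the off-resonance field in Hz and
#' `eps_n` i.i.d. complex Gaussian noise with per-channel SD `noise_sd`.
#'
#' @param maps [build_phantom()] output.
#' @param params [acquisition_params()] for the station.
#' @param fat_model Fat spectral model; default single peak at the
#'   acquisition's fat offset.
#' @param contrast `"post"` or `"pre"`.
#' @param spec Phantom spec; defaults to the one stored in `maps`.
#' @return An object of class `mra_dual_echo` (see [dual_echo_volume()]).
#' @export
simulate_dual_echo <- function(maps, params,
                               fat_model = fat_model_single_peak(params$fat_offset_hz),
                               contrast = c("post", "pre"),
                               spec = maps$spec) {
  stopifnot(inherits(maps, "mra_tissue_maps"), inherits(params, "mra_params"))
  contrast <- match.arg(contrast)
  d <- dim(maps$water)
  lumen_gain <- spec$enhancement_factor *
    if (contrast == "pre") spec$pre_contrast_fraction else 1
  wprime <- maps$water
  wprime[maps$vessel_mask] <- wprime[maps$vessel_mask] * lumen_gain

  echoes <- lapply(c(params$te1_ms, params$te2_ms), function(te) {
    c_te <- fat_phasor(fat_model, te)
    (wprime + maps$fat * c_te) *
      exp(2i * pi * maps$field_map_hz * te / 1000)
  })

  if (spec$noise_sd > 0) {
    seed <- substream_seed(spec$seed, paste0("noise_", contrast, "_", params$station_label))
    old <- .Random.seed_store()
    set.seed(seed)
    n <- prod(d)
    for (k in 1:2) {
      echoes[[k]] <- echoes[[k]] +
        complex(real = stats::rnorm(n, 0, spec$noise_sd),
                imaginary = stats::rnorm(n, 0, spec$noise_sd))
    }
    .Random.seed_restore(old)
  }
  dual_echo_volume(array(echoes[[1]], d), array(echoes[[2]], d), params)
}

#' Simulate a noise-only acquisition (RF excitation disabled)
#'
#' @param grid_shape Integer length-3 grid.
#' @param noise_sd Per-channel SD of the complex Gaussian noise.
#' @param seed Integer seed.
#' @param params Acquisition parameters attached to the result.
#' @return An `mra_dual_echo` volume of pure zero-mean complex noise.
#' @export
simulate_noise_only <- function(grid_shape, noise_sd, seed,
                                params = acquisition_params(1.48, 2.84)) {
  stopifnot(length(grid_shape) == 3L, noise_sd >= 0)
  d <- as.integer(grid_shape)
  n <- prod(d)
  old <- .Random.seed_store()
  set.seed(as.integer(seed))
  mk <- function() {
    if (noise_sd == 0) return(array(0 + 0i, d))
    array(complex(real = stats::rnorm(n, 0, noise_sd),
                  imaginary = stats::rnorm(n, 0, noise_sd)), d)
  }
  e1 <- mk(); e2 <- mk()
  .Random.seed_restore(old)
  dual_echo_volume(e1, e2, params)
}

#' Paired dual-echo complex volume
#'
#' @param echo1,echo2 Complex 3D arrays of identical shape (TE1 and TE2).
#' @param params [acquisition_params()].
#' @return An object of class `mra_dual_echo`.
#' @export
dual_echo_volume <- function(echo1, echo2, params) {
  stopifnot(is.array(echo1), is.array(echo2), inherits(params, "mra_params"))
  if (!identical(dim(echo1), dim(echo2))) {
    stop("echo volumes must share a shape", call. = FALSE)
  }
  if (!is.complex(echo1)) echo1 <- array(as.complex(echo1), dim(echo1))
  if (!is.complex(echo2)) echo2 <- array(as.complex(echo2), dim(echo2))
  structure(list(echo1 = echo1, echo2 = echo2, params = params),
            class = "mra_dual_echo")
}

#' @export
print.mra_dual_echo <- function(x, ...) {
  cat(sprintf("<mra_dual_echo> %s grid, %s station, TE1/TE2 = %.2f/%.2f ms\n",
              paste(dim(x$echo1), collapse = "x"), x$params$station_label,
              x$params$te1_ms, x$params$te2_ms))
  invisible(x)
}

# save/restore the global RNG state so simulators are pure given their seed
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
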