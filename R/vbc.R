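#' Cylindrical region of interest centred on a vessel
#'
#' @param label Vessel-segment name.
#' @param center_mm Length-3 isocenter in world mm.
#' @param radius_mm Cylinder radius, > 0.
#' @param half_length_mm Half-length along the axis, > 0.
#' @param axis Cylinder axis (defaults to the slice normal of the axial
#'   reformat, i.e. z); normalised internally.
#' @return An object of class `mra_roi`.
#' @export
cylindrical_roi <- function(label, center_mm, radius_mm, half_length_mm,
                            axis = c(0, 0, 1)) {
  stopifnot(length(center_mm) == 3L, length(axis) == 3L)
  if (radius_mm <= 0 || half_length_mm <= 0) {
    stop("radius_mm and half_length_mm must be > 0", call. = FALSE)
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be nonzero", call. = FALSE)
  structure(list(label = as.character(label),
                 center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm,
                 half_length_mm = half_length_mm,
                 axis = as.numeric(axis) / nrm),
            class = "mra_roi")
}

#' Convert between ROI lists and tibbles
#'
#' `roi_table()` flattens a list of [cylindrical_roi()] to a tibble (axis
#' fixed to z); `as_roi_list()` accepts either form and returns a list.
#' `read_rois()` / `write_rois()` persist the tabular form as CSV.
#'
#' @param rois List of `mra_roi` or a tibble with columns `label`,
#'   `x_mm,y_mm,z_mm`, `radius_mm`, `half_length_mm`.
#' @return A tibble / list of `mra_roi` respectively.
#' @export
roi_table <- function(rois) {
  purrr::map_dfr(as_roi_list(rois), function(r) {
    tibble::tibble(label = r$label, x_mm = r$center_mm[1],
                   y_mm = r$center_mm[2], z_mm = r$center_mm[3],
                   radius_mm = r$radius_mm, half_length_mm = r$half_length_mm)
  })
}

#' @rdname roi_table
#' @export
as_roi_list <- function(rois) {
  if (is.data.frame(rois)) {
    return(purrr::pmap(rois, function(label, x_mm, y_mm, z_mm, radius_mm,
                                      half_length_mm, ...) {
      cylindrical_roi(label, c(x_mm, y_mm, z_mm), radius_mm, half_length_mm)
    }))
  }
  if (inherits(rois, "mra_roi")) return(list(rois))
  stopifnot(is.list(rois), all(vapply(rois, inherits, TRUE, "mra_roi")))
  rois
}

#' @rdname roi_table
#' @param path CSV file path.
#' @export
read_rois <- function(path) {
  as_roi_list(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname roi_table
#' @export
write_rois <- function(rois, path) {
  readr::write_csv(roi_table(rois), path)
  invisible(path)
}

#' Voxels inside a cylindrical ROI
#'
#' A voxel belongs to the ROI when its centre, at world coordinate
#' `(i - 0.5) * voxel_size`, lies inside the cylinder.
#'
#' @param roi An `mra_roi`.
#' @param dim Integer length-3 grid shape.
#' @param voxel_size_mm Voxel size.
#' @return Sorted vector of linear voxel indices (1-based).
#' @export
roi_voxel_indices <- function(roi, dim, voxel_size_mm) {
  d <- as.integer(dim); v <- as.numeric(voxel_size_mm)
  ext <- roi$radius_mm + roi$half_length_mm
  lo <- roi$center_mm - ext; hi <- roi$center_mm + ext
  rng <- lapply(1:3, function(a) {
    which(axis_coords(d[a], v[a]) >= lo[a] & axis_coords(d[a], v[a]) <= hi[a])
  })
  if (any(lengths(rng) == 0L)) return(integer(0))
  gx <- axis_coords(d[1], v[1])[rng[[1]]]
  gy <- axis_coords(d[2], v[2])[rng[[2]]]
  gz <- axis_coords(d[3], v[3])[rng[[3]]]
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  X <- rep(gx, times = ny * nz) - roi$center_mm[1]
  Y <- rep(rep(gy, each = nx), times = nz) - roi$center_mm[2]
  Z <- rep(gz, each = nx * ny) - roi$center_mm[3]
  t_ax <- X * roi$axis[1] + Y * roi$axis[2] + Z * roi$axis[3]
  r2 <- (X - t_ax * roi$axis[1])^2 + (Y - t_ax * roi$axis[2])^2 +
    (Z - t_ax * roi$axis[3])^2
  inside <- abs(t_ax) <= roi$half_length_mm & r2 <= roi$radius_mm^2
  if (!any(inside)) return(integer(0))
  ix <- rep(rng[[1]], times = ny * nz)
  iy <- rep(rep(rng[[2]], each = nx), times = nz)
  iz <- rep(rng[[3]], each = nx * ny)
  idx <- ix + d[1] * (iy - 1L) + d[1] * d[2] * (iz - 1L)
  sort(idx[inside])
}

# 26-connected neighbours of linear indices; returns a (length(idx) x 26)
# matrix with NA outside the grid
neighbours26 <- function(idx, d) {
  ix <- (idx - 1L) %% d[1] + 1L
  iy <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  iz <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  out <- matrix(NA_integer_, nrow = length(idx), ncol = 26L)
  for (j in seq_len(26L)) {
    nx_ <- ix + offs$dx[j]; ny_ <- iy + offs$dy[j]; nz_ <- iz + offs$dz[j]
    ok <- nx_ >= 1L & nx_ <= d[1] & ny_ >= 1L & ny_ <= d[2] &
      nz_ >= 1L & nz_ <= d[3]
    val <- nx_ + d[1] * (ny_ - 1L) + d[1] * d[2] * (nz_ - 1L)
    val[!ok] <- NA_integer_
    out[, j] <- val
  }
  out
}

voxel_centers_mm <- function(idx, d, v) {
  cbind(((idx - 1L) %% d[1] + 0.5) * v[1],
        (((idx - 1L) %/% d[1]) %% d[2] + 0.5) * v[2],
        ((idx - 1L) %/% (d[1] * d[2]) + 0.5) * v[3])
}

#' Most intense local maxima within an ROI
#'
#' Finds up to `k` strict-or-plateau local maxima (26-neighbourhood,
#' ROI-restricted: only neighbours inside the ROI are compared) of the
#' volume restricted to the ROI, ordered by descending intensity. Plateau
#' maxima (connected sets of equal value, all of whose outer neighbours are
#' lower) are collapsed to the member voxel nearest the plateau centroid.
#' An ROI of constant intensity has no informative maxima: an empty result
#' flagged `degenerate` is returned.
#'
#' @param volume 3D array.
#' @param roi An `mra_roi`.
#' @param voxel_size_mm Voxel size.
#' @param k Maximum number of maxima returned.
#' @return Tibble with columns `linear_index`, `intensity`,
#'   `x_mm,y_mm,z_mm`, `dist_center_mm`, ordered by descending intensity
#'   (ties by linear index); attribute `degenerate` when flagged.
#' @export
find_local_maxima <- function(volume, roi, voxel_size_mm, k = 10) {
  d <- dim(volume)
  idx <- roi_voxel_indices(roi, d, voxel_size_mm)
  if (length(idx) == 0L) {
    stop("ROI '", roi$label, "' does not intersect the volume", call. = FALSE)
  }
  vals <- volume[idx]
  empty <- tibble::tibble(linear_index = integer(0), intensity = numeric(0),
                          x_mm = numeric(0), y_mm = numeric(0),
                          z_mm = numeric(0), dist_center_mm = numeric(0))
  if (max(vals) == min(vals)) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  # comparisons are ROI-restricted: a cylinder cuts through its vessel, so
  # comparing against out-of-ROI lumen voxels would lose the cap maxima
  in_roi <- array(FALSE, d); in_roi[idx] <- TRUE
  nb <- neighbours26(idx, d)
  nbv <- matrix(-Inf, nrow = nrow(nb), ncol = ncol(nb))
  ok <- !is.na(nb)
  ok[ok] <- in_roi[nb[ok]]
  nbv[ok] <- volume[nb[ok]]
  is_max <- vals >= apply(nbv, 1, max)
  if (!any(is_max)) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }

  flag_idx <- idx[is_max]
  flag_val <- vals[is_max]
  comp <- plateau_components(flag_idx, flag_val, d)
  reps <- vapply(split(seq_along(flag_idx), comp), function(members) {
    mi <- flag_idx[members]
    ctr <- voxel_centers_mm(mi, d, voxel_size_mm)
    cen <- colMeans(ctr)
    dist2 <- rowSums(sweep(ctr, 2, cen)^2)
    mi[order(dist2, mi)[1]]
  }, integer(1))
  reps <- unname(reps)
  rep_val <- volume[reps]
  ord <- order(-rep_val, reps)
  reps <- reps[ord][seq_len(min(k, length(reps)))]
  ctr <- voxel_centers_mm(reps, d, voxel_size_mm)
  tibble::tibble(
    linear_index = reps,
    intensity = volume[reps],
    x_mm = ctr[, 1], y_mm = ctr[, 2], z_mm = ctr[, 3],
    dist_center_mm = sqrt(rowSums(sweep(ctr, 2, roi$center_mm)^2))
  )
}

# label 26-connected components among flagged voxels of equal intensity
plateau_components <- function(flag_idx, flag_val, d) {
  n <- length(flag_idx)
  comp <- integer(n)
  nb <- neighbours26(flag_idx, d)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      cand <- match(as.vector(nb[frontier, , drop = FALSE]), flag_idx)
      cand <- cand[!is.na(cand)]
      cand <- unique(cand[comp[cand] == 0L & flag_val[cand] == flag_val[i]])
      comp[cand] <- cur
      frontier <- cand
    }
  }
  comp
}

#' Select the seed voxel among local maxima
#'
#' The maxima are sorted by Euclidean distance to the ROI isocenter and the
#' innermost one becomes the vessel seed; distance ties go to the higher
#' intensity, then the lower linear index. Only maxima whose intensity
#' reaches `min_rel_intensity` times the brightest maximum qualify as seed
#' candidates: background noise also produces local maxima, and an ROI on a
#' tight stenosis can place one of those nearer the isocenter than the
#' surviving lumen maxima. A maximum too faint to belong to a lumen grown
#' from the brightest one is not a plausible vessel seed.
#'
#' @param maxima Tibble from [find_local_maxima()].
#' @param roi The `mra_roi` (unused beyond its isocenter, already encoded
#'   in `dist_center_mm`).
#' @param min_rel_intensity Fraction of the brightest maximum an eligible
#'   seed must reach (default the flood-fill threshold 0.5).
#' @return One-row tibble (the seed).
#' @export
select_seed <- function(maxima, roi = NULL, min_rel_intensity = 0.5) {
  if (nrow(maxima) == 0L) {
    stop("no local maxima to select a seed from", call. = FALSE)
  }
  eligible <- maxima[maxima$intensity >=
                       min_rel_intensity * max(maxima$intensity), ]
  eligible[order(eligible$dist_center_mm, -eligible$intensity,
                 eligible$linear_index)[1], ]
}

#' Flood-fill segmentation of the vessel lumen
#'
#' Grows a 26-connected region from the seed over ROI voxels whose
#' intensity is at least `theta` times the seed intensity.
#'
#' @param volume 3D array.
#' @param seed Seed voxel: a linear index or a one-row tibble from
#'   [select_seed()].
#' @param roi An `mra_roi`.
#' @param voxel_size_mm Voxel size.
#' @param theta Relative inclusion threshold in (0, 1]; 0 makes the fill
#'   cover the seed's whole connected ROI component.
#' @return Sorted vector of linear voxel indices of the lumen.
#' @export
flood_fill_vessel <- function(volume, seed, roi, voxel_size_mm, theta = 0.5) {
  if (is.data.frame(seed)) seed <- seed$linear_index[1]
  d <- dim(volume)
  roi_idx <- roi_voxel_indices(roi, d, voxel_size_mm)
  if (!(seed %in% roi_idx)) stop("seed lies outside the ROI", call. = FALSE)
  if (volume[seed] <= 0) {
    stop("seed intensity is not positive; cannot segment ROI '",
         roi$label, "'", call. = FALSE)
  }
  thr <- theta * volume[seed]
  candidate <- roi_idx[volume[roi_idx] >= thr]
  flood_fill_from(seed, candidate, d)
}

# 26-connected component of `candidate` containing `seed`
flood_fill_from <- function(seed, candidate, d) {
  candidate <- sort(candidate)
  in_mask <- logical(length(candidate))
  pos <- match(seed, candidate)
  if (is.na(pos)) stop("seed not in candidate set", call. = FALSE)
  in_mask[pos] <- TRUE
  frontier <- pos
  while (length(frontier)) {
    nb <- neighbours26(candidate[frontier], d)
    cand <- match(as.vector(nb), candidate)
    cand <- unique(cand[!is.na(cand)])
    cand <- cand[!in_mask[cand]]
    in_mask[cand] <- TRUE
    frontier <- cand
  }
  candidate[in_mask]
}

#' Construct the background mask of an ROI
#'
#' Starting from the ROI voxels outside the vessel mask, every non-seed
#' local maximum that is itself hyperintense (at or above the lumen
#' inclusion threshold `theta * I(seed)`) seeds its own flood fill (same
#' relative-threshold rule, applied to that maximum) and the filled
#' region — a vessel branch or other hyperintense structure — is moved to
#' the discarded mask; any remaining voxel at or above `theta * I(seed)` is
#' discarded as well. Maxima below the lumen threshold are ordinary
#' background texture and stay in the background — treating them as
#' structures would flood the whole background away. What remains
#' approximates the true background.
#'
#' @param volume 3D array.
#' @param roi An `mra_roi`.
#' @param vessel_mask Linear indices of the lumen (from
#'   [flood_fill_vessel()]).
#' @param maxima Tibble of local maxima; the first row matching the seed is
#'   skipped.
#' @param seed Seed voxel (linear index or tibble row).
#' @param voxel_size_mm Voxel size.
#' @param theta Relative threshold shared with the lumen rule.
#' @return List with sorted index vectors `background` and `discarded`.
#' @export
build_background <- function(volume, roi, vessel_mask, maxima, seed,
                             voxel_size_mm, theta = 0.5) {
  if (is.data.frame(seed)) seed <- seed$linear_index[1]
  d <- dim(volume)
  roi_idx <- roi_voxel_indices(roi, d, voxel_size_mm)
  base <- setdiff(roi_idx, vessel_mask)
  discarded <- integer(0)
  for (m in setdiff(maxima$linear_index, seed)) {
    if (m %in% vessel_mask || !(m %in% base)) next
    if (volume[m] < theta * volume[seed]) next
    cand <- base[volume[base] >= theta * volume[m]]
    discarded <- union(discarded, flood_fill_from(m, cand, d))
  }
  hyper <- base[volume[base] >= theta * volume[seed]]
  discarded <- sort(union(discarded, hyper))
  background <- setdiff(base, discarded)
  if (length(background) == 0L) {
    stop("background empty after discarding hyperintense voxels in ROI '",
         roi$label, "'", call. = FALSE)
  }
  list(background = background, discarded = discarded)
}

#' Segment one ROI into vessel, background and discarded voxels
#'
#' Runs the full semi-automated pipeline on one cylindrical ROI: the 10
#' most intense local maxima, innermost-maximum seed selection, flood-fill
#' lumen segmentation, and background construction with branch/hyperintense
#' removal.
#'
#' @param volume 3D array (the water image; the segmentation is transferred
#'   unchanged to other reconstructions with [transfer_segmentation()]).
#' @param roi An `mra_roi`.
#' @param voxel_size_mm Voxel size.
#' @param theta Relative flood-fill threshold.
#' @param k Number of local maxima searched.
#' @return An object of class `mra_roi_seg`: label, sorted index vectors
#'   `vessel`, `background`, `discarded`, plus `roi_idx`, `seed`, `dim`.
#' @export
segment_roi <- function(volume, roi, voxel_size_mm, theta = 0.5, k = 10) {
  d <- dim(volume)
  maxima <- find_local_maxima(volume, roi, voxel_size_mm, k = k)
  if (nrow(maxima) == 0L) {
    stop("ROI '", roi$label, "' is degenerate (no local maxima)", call. = FALSE)
  }
  seed <- select_seed(maxima)
  vessel <- flood_fill_vessel(volume, seed, roi, voxel_size_mm, theta = theta)
  bg <- build_background(volume, roi, vessel, maxima, seed, voxel_size_mm,
                         theta = theta)
  structure(list(label = roi$label,
                 vessel = vessel,
                 background = bg$background,
                 discarded = bg$discarded,
                 roi_idx = roi_voxel_indices(roi, d, voxel_size_mm),
                 seed = seed$linear_index[1],
                 dim = d),
            class = "mra_roi_seg")
}

#' Vessel-to-background contrast of a segmented ROI
#'
#' VBC = (mean vessel - mean background) / SD(background), with arithmetic
#' means and the sample (n-1) standard deviation. The statistic is
#' invariant under positive affine intensity transforms.
#'
#' @param volume 3D array on the segmentation's grid.
#' @param seg An `mra_roi_seg`.
#' @param method Reconstruction label recorded in the output.
#' @return One-row tibble: `label`, `method`, `n_vessel`, `n_background`,
#'   `mean_vessel`, `mean_background`, `sd_background`, `vbc`.
#' @export
compute_vbc <- function(volume, seg, method = "mdixon") {
  stopifnot(inherits(seg, "mra_roi_seg"))
  if (!identical(dim(volume), seg$dim)) {
    stop("volume grid does not match the segmentation grid", call. = FALSE)
  }
  if (length(seg$background) < 2L) {
    stop("background of ROI '", seg$label, "' has fewer than 2 voxels",
         call. = FALSE)
  }
  mv <- mean(volume[seg$vessel])
  mb <- mean(volume[seg$background])
  sb <- stats::sd(volume[seg$background])
  if (sb == 0) {
    stop("background SD of ROI '", seg$label, "' is zero", call. = FALSE)
  }
  tibble::tibble(label = seg$label, method = method,
                 n_vessel = length(seg$vessel),
                 n_background = length(seg$background),
                 mean_vessel = mv, mean_background = mb,
                 sd_background = sb, vbc = (mv - mb) / sb)
}

#' Apply a segmentation unchanged to another reconstruction
#'
#' The masks derived on the water image are applied voxel-for-voxel to the
#' other reconstruction (e.g. the subtraction image), as required for a
#' paired comparison of the two methods.
#'
#' @param seg An `mra_roi_seg`.
#' @param other_volume 3D array on the same grid.
#' @param method Reconstruction label recorded in the output.
#' @return One-row VBC tibble (see [compute_vbc()]).
#' @export
transfer_segmentation <- function(seg, other_volume, method = "subtraction") {
  compute_vbc(other_volume, seg, method = method)
}

#' @export
print.mra_roi_seg <- function(x, ...) {
  cat(sprintf("<mra_roi_seg> '%s': %d vessel, %d background, %d discarded voxels\n",
              x$label, length(x$vessel), length(x$background),
              length(x$discarded)))
  invisible(x)
}
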