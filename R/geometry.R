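#' Built-in vessel-tree geometry for the three table stations
#'
#' Returns the synthetic arterial tree of one station of a peripheral
#' run-off exam, in station-local world coordinates (mm). The 23 segments of
#' the full exam split 7/8/8 over the stations: infrarenal aorta plus
#' common/external/internal iliacs (abdominal), common/deep/superficial
#' femoral and popliteal arteries (upper leg), and tibiofibular trunk,
#' anterior/posterior tibial and peroneal arteries (lower leg). The right
#' superficial femoral artery carries a 50% stenosis over its middle third.
#'
#' @param station_label Station name.
#' @return A vessel-tree tibble suitable for [phantom_spec()].
#' @export
station_vessel_tree <- function(station_label = c("abdominal", "upper_leg", "lower_leg")) {
  station_label <- match.arg(station_label)
  seg <- function(segment, p1, p2, r, stenosis = 0, occluded = FALSE) {
    tibble::tibble(segment = segment,
                   x1 = p1[1], y1 = p1[2], z1 = p1[3],
                   x2 = p2[1], y2 = p2[2], z2 = p2[3],
                   radius_mm = r, stenosis = stenosis, occluded = occluded)
  }
  mirror <- function(tbl) {
    # reflect a right-sided segment about the mid-sagittal plane x = 216
    m <- tbl
    m$segment <- sub("_r$", "_l", m$segment)
    m$x1 <- 432 - m$x1; m$x2 <- 432 - m$x2
    m
  }
  tree <- switch(
    station_label,
    abdominal = {
      right <- dplyr::bind_rows(
        seg("common_iliac_r",   c(216, 96, 240), c(251, 96, 120), 8),
        seg("external_iliac_r", c(251, 96, 120), c(286, 96, 0), 7),
        seg("internal_iliac_r", c(251, 96, 120), c(276, 56, 30), 5)
      )
      dplyr::bind_rows(
        seg("aorta", c(216, 96, 430), c(216, 96, 240), 12),
        right, mirror(right)
      )
    },
    upper_leg = {
      right <- dplyr::bind_rows(
        seg("common_femoral_r",      c(286, 96, 430), c(286, 96, 340), 7),
        seg("deep_femoral_r",        c(286, 96, 340), c(306, 76, 180), 5),
        seg("superficial_femoral_r", c(286, 96, 340), c(281, 96, 120), 6, stenosis = 0.5),
        seg("popliteal_r",           c(281, 96, 120), c(281, 96, 0), 6)
      )
      dplyr::bind_rows(right, mirror(right))
    },
    lower_leg = {
      right <- dplyr::bind_rows(
        seg("tibiofibular_trunk_r", c(286, 96, 430), c(286, 96, 360), 5),
        seg("anterior_tibial_r",    c(286, 96, 360), c(306, 76, 0), 4),
        seg("posterior_tibial_r",   c(286, 96, 360), c(281, 106, 0), 4),
        seg("peroneal_r",           c(286, 96, 360), c(266, 96, 0), 3.5)
      )
      dplyr::bind_rows(right, mirror(right))
    }
  )
  tree
}

#' Default phantom specification for a station
#'
#' Station preset used by [run_study()]: a 144 x 64 x 86 grid at
#' 3 x 3 x 5 mm (432 x 192 x 430 mm field of view, 430 mm foot-head as in a
#' stepping-table station), the built-in vessel tree, 4-fold lumen
#' enhancement, a 30 Hz smooth off-resonance field and complex noise of SD
#' 0.1 relative to a unit tissue density (post-contrast lumen SNR ~ 40,
#' typical of first-pass contrast-enhanced MRA).
#'
#' @param station_label Station name.
#' @param seed RNG seed stored in the spec.
#' @param noise_sd Per-channel complex noise SD.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return An `mra_phantom_spec`.
#' @export
default_phantom_spec <- function(station_label = c("abdominal", "upper_leg", "lower_leg"),
                                 seed = 1L, noise_sd = 0.1, ...) {
  station_label <- match.arg(station_label)
  phantom_spec(vessel_tree = station_vessel_tree(station_label),
               seed = seed, noise_sd = noise_sd, ...)
}

#' Cylindrical ROIs along every vessel segment of a station
#'
#' Places `n_per_segment` cylindrical ROIs on each segment of the station's
#' vessel tree, centred on the vessel axis at evenly spaced fractional
#' positions, with an ROI radius of the vessel radius plus a background
#' margin. With the default three ROIs per segment the full three-station
#' exam yields 23 x 3 = 69 ROIs per subject.
#'
#' @param vessel_tree A vessel-tree tibble, e.g. [station_vessel_tree()].
#' @param n_per_segment ROIs per segment.
#' @param margin_mm Background margin added to the vessel radius.
#' @param half_length_mm Half-length of each cylinder along its axis (z).
#' @return A list of [cylindrical_roi()] objects.
#' @export
station_rois <- function(vessel_tree, n_per_segment = 3,
                         margin_mm = 9, half_length_mm = 12) {
  fracs <- seq(1, n_per_segment) / (n_per_segment + 1)
  out <- list()
  for (i in seq_len(nrow(vessel_tree))) {
    sgm <- vessel_tree[i, ]
    p1 <- c(sgm$x1, sgm$y1, sgm$z1); p2 <- c(sgm$x2, sgm$y2, sgm$z2)
    for (j in seq_along(fracs)) {
      ctr <- p1 + fracs[j] * (p2 - p1)
      out[[length(out) + 1L]] <- cylindrical_roi(
        label = paste0(sgm$segment, "_roi", j),
        center_mm = ctr,
        radius_mm = sgm$radius_mm + margin_mm,
        half_length_mm = half_length_mm
      )
    }
  }
  out
}
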