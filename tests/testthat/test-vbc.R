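vx <- c(2, 2, 2)

# an ROI covering most of a small grid
big_roi <- function(d, label = "roi") {
  cylindrical_roi(label, d * vx / 2, min(d[1:2]) * vx[1] / 2 - 1, d[3] * vx[3] / 2)
}

test_that("cylindrical ROI voxelisation matches the point-in-cylinder rule", {
  d <- c(12, 12, 10)
  roi <- cylindrical_roi("r", c(12, 12, 10), 5, 6)
  idx <- roi_voxel_indices(roi, d, vx)
  # oracle: exhaustive sweep
  oracle <- integer(0)
  for (x in 1:12) for (y in 1:12) for (z in 1:10) {
    pt <- (c(x, y, z) - 0.5) * vx
    if (abs(pt[3] - 10) <= 6 && sum((pt[1:2] - c(12, 12))^2) <= 25) {
      oracle <- c(oracle, x + 12 * (y - 1) + 144 * (z - 1))
    }
  }
  expect_equal(idx, sort(oracle))
  expect_error(cylindrical_roi("r", c(0, 0, 0), -1, 5), "> 0")
})

test_that("ROI tables round-trip through tibbles and CSV", {
  rois <- list(cylindrical_roi("a", c(1, 2, 3), 4, 5),
               cylindrical_roi("b", c(9, 8, 7), 6, 5))
  tbl <- roi_table(rois)
  expect_equal(nrow(tbl), 2)
  back <- as_roi_list(tbl)
  expect_equal(back[[1]]$center_mm, c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rois(rois, path)
  again <- read_rois(path)
  expect_equal(roi_table(again), tbl)
})

test_that("local maxima are found, ordered and matched by an exhaustive oracle", {
  d <- c(15, 15, 9)
  vol <- array(0, d)
  blob <- function(c0, amp, w = 2) {
    for (x in 1:15) for (y in 1:15) for (z in 1:9) {
      vol[x, y, z] <<- vol[x, y, z] +
        amp * exp(-sum(((c(x, y, z) - c0) / w)^2))
    }
  }
  blob(c(5, 8, 5), 10)
  blob(c(11, 8, 5), 8)
  roi <- big_roi(d)
  mx <- find_local_maxima(vol, roi, vx)
  expect_equal(mx$intensity[1:2], c(10, 8), tolerance = 1e-2)
  expect_equal(mx$linear_index[1], 5 + 15 * 7 + 225 * 4)
  # every reported maximum passes the exhaustive neighbour comparison
  idx <- roi_voxel_indices(roi, d, vx)
  expect_true(all(mx$linear_index %in% oracle_local_max(vol, idx)))

  # constant ROI: degenerate, no informative maxima
  flat <- find_local_maxima(array(3, d), roi, vx)
  expect_equal(nrow(flat), 0)
  expect_true(isTRUE(attr(flat, "degenerate")))
  expect_error(find_local_maxima(vol, cylindrical_roi("far", c(900, 900, 900), 2, 2), vx),
               "intersect")
})

test_that("seed selection is innermost-first with intensity then index tie-breaks", {
  mx <- tibble::tibble(linear_index = c(10L, 20L, 30L),
                       intensity = c(9, 5, 7),
                       x_mm = 0, y_mm = 0, z_mm = 0,
                       dist_center_mm = c(3.0, 1.0, 1.0))
  s <- select_seed(mx)
  expect_equal(s$linear_index, 30L)  # distance tie, higher intensity wins
  mx$intensity <- c(9, 7, 7)
  expect_equal(select_seed(mx)$linear_index, 20L)  # full tie: lower index
  mx$dist_center_mm <- c(1, 2, 3)
  expect_equal(select_seed(mx)$linear_index, 10L)
  expect_error(select_seed(mx[0, ]), "no local maxima")
})

test_that("flood fill equals the thresholded connected-component oracle", {
  # uniform tube in faint background
  d <- c(16, 16, 12)
  vol <- array(1, d)
  tube <- integer(0)
  for (x in 7:10) for (y in 7:10) for (z in 1:12) {
    tube <- c(tube, x + 16 * (y - 1) + 256 * (z - 1))
  }
  vol[tube] <- 100
  roi <- big_roi(d)
  idx <- roi_voxel_indices(roi, d, vx)
  seed <- tube[100]
  mask <- flood_fill_vessel(vol, seed, roi, vx, theta = 0.5)
  expect_equal(mask, sort(intersect(tube, idx)))
  expect_equal(mask, oracle_component(seed, idx[vol[idx] >= 50], d))

  # a single isolated bright voxel fills to itself
  iso <- array(1, d); iso[5, 5, 3] <- 50
  s <- 5 + 16 * 4 + 256 * 2
  expect_equal(flood_fill_vessel(iso, s, roi, vx, theta = 0.5), s)

  # theta = 0 grabs the seed's whole connected ROI component
  expect_equal(flood_fill_vessel(iso, s, roi, vx, theta = 0), idx)
  expect_error(flood_fill_vessel(array(0, d), s, roi, vx), "not positive")

  # randomized exhaustive check on small grids
  set.seed(77)
  for (rep in 1:12) {
    dv <- sample(5:14, 3, replace = TRUE)
    volr <- array(stats::runif(prod(dv)), dv)
    roir <- cylindrical_roi("r", dv * vx / 2, max(dv[1:2]) * vx[1], dv[3] * vx[3])
    idxr <- roi_voxel_indices(roir, dv, vx)
    seedr <- idxr[which.max(volr[idxr])]
    th <- stats::runif(1, 0.2, 0.9)
    got <- flood_fill_vessel(volr, seedr, roir, vx, theta = th)
    want <- oracle_component(seedr, idxr[volr[idxr] >= th * volr[seedr]], dv)
    expect_equal(got, want)
  }
})

test_that("background construction discards branches and hyperintense specks", {
  d <- c(20, 20, 12)
  vol <- array(1, d)
  main <- integer(0); branch <- integer(0)
  for (z in 1:12) {
    for (x in 9:12) for (y in 9:12) main <- c(main, x + 20 * (y - 1) + 400 * (z - 1))
    for (x in 16:17) for (y in 9:10) branch <- c(branch, x + 20 * (y - 1) + 400 * (z - 1))
  }
  vol[main] <- 100; vol[branch] <- 90
  roi <- big_roi(d)
  seg <- segment_roi(vol, roi, vx, theta = 0.5, k = 10)
  idx <- roi_voxel_indices(roi, d, vx)
  expect_setequal(seg$vessel, intersect(main, idx))
  expect_true(all(intersect(branch, idx) %in% seg$discarded))
  expect_false(any(seg$background %in% c(main, branch)))

  # uniform background with no secondary structures: background = ROI - vessel
  vol2 <- array(1, d); vol2[main] <- 100
  seg2 <- segment_roi(vol2, roi, vx)
  expect_setequal(seg2$background, setdiff(idx, seg2$vessel))
  expect_length(seg2$discarded, 0)

  # hyperintense speck above theta * I(seed) without a local-max flag among
  # the k retained maxima is still discarded by the intensity sweep
  d3 <- c(5, 5, 5)
  vol3 <- array(1, d3)
  vol3[3, 3, ] <- 100          # vessel column
  vol3[2, 1, 3] <- 60          # speck above 0.5 * 100
  roi3 <- cylindrical_roi("s", c(5, 5, 5), 4.9, 5)
  seg3 <- segment_roi(vol3, roi3, vx, theta = 0.5, k = 1)
  speck <- 2 + 5 * 0 + 25 * 2
  expect_true(speck %in% seg3$discarded)
  expect_false(speck %in% seg3$background)
})

test_that("VBC matches the hand-computed definition and its invariances", {
  d <- c(6, 6, 6)
  vol <- array(0, d)
  seg <- structure(list(label = "hand", vessel = c(1L, 2L),
                        background = c(10L, 11L, 12L, 13L),
                        discarded = integer(0),
                        roi_idx = 1:20, seed = 1L, dim = as.integer(d)),
                   class = "mra_roi_seg")
  vol[c(1, 2)] <- 10
  vol[10:13] <- c(2, 2, 4, 4)
  res <- compute_vbc(vol, seg)
  expect_equal(res$vbc, 6.062177826491071, tolerance = 1e-9)
  expect_equal(res$sd_background, stats::sd(c(2, 2, 4, 4)))

  # zero contrast
  vol0 <- vol; vol0[c(1, 2)] <- 3
  expect_equal(compute_vbc(vol0, seg)$vbc, 0)

  # positive affine invariance
  expect_equal(compute_vbc(3 * vol + 5, seg)$vbc, res$vbc, tolerance = 1e-12)

  # transfer: identical volume gives identical statistic, scaling changes nothing
  expect_equal(transfer_segmentation(seg, vol)$vbc, res$vbc)
  expect_equal(transfer_segmentation(seg, 2 * vol)$vbc, res$vbc, tolerance = 1e-12)
  expect_error(transfer_segmentation(seg, array(0, c(2, 2, 2))), "grid")

  seg$background <- 10L
  expect_error(compute_vbc(vol, seg), "fewer than 2")
})

test_that("segmentations keep masks disjoint and ROI-contained on fuzzed phantoms", {
  set.seed(20260921)
  for (rep in 1:25) {
    spec <- tiny_tube_spec(noise_sd = stats::runif(1, 0.02, 0.1),
                           seed = sample.int(1e6, 1),
                           grid = c(20, 20, 12))
    maps <- build_phantom(spec)
    vol <- simulate_dual_echo(maps, acquisition_params(1.48, 2.84,
                                                       voxel_size_mm = spec$voxel_size_mm),
                              contrast = "post", spec = spec)
    water <- separate_water_fat(vol)$water
    roi <- cylindrical_roi("fuzz", c(24, 24, stats::runif(1, 8, 24)),
                           stats::runif(1, 9.5, 14), stats::runif(1, 4, 8))
    seg <- segment_roi(water, roi, spec$voxel_size_mm)
    idx <- roi_voxel_indices(roi, spec$grid_shape, spec$voxel_size_mm)
    expect_length(intersect(seg$vessel, seg$background), 0)
    expect_length(intersect(seg$vessel, seg$discarded), 0)
    expect_length(intersect(seg$background, seg$discarded), 0)
    expect_true(all(c(seg$vessel, seg$background, seg$discarded) %in% idx))
    expect_true(seg$seed %in% seg$vessel)
  }
})
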