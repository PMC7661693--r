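mk_noise_pair <- function(d = c(32, 32, 16), sd0 = 1, seeds = c(1, 2)) {
  p <- acquisition_params(1.48, 2.84, voxel_size_mm = c(2, 2, 2))
  list(pre = simulate_noise_only(d, sd0, seeds[1], p),
       post = simulate_noise_only(d, sd0, seeds[2], p))
}

test_that("magnitude subtraction behaves on identity, zero and mismatched inputs", {
  np <- mk_noise_pair()
  s_self <- subtract(np$post, np$post)
  expect_true(all(s_self$volume == 0))

  p <- np$post$params
  zero <- dual_echo_volume(array(0 + 0i, dim(np$post$echo1)),
                           array(0 + 0i, dim(np$post$echo1)), p)
  s_zero <- subtract(zero, np$post)
  expect_equal(s_zero$volume, Mod(np$post$echo1))

  small <- dual_echo_volume(array(0 + 0i, c(2, 2, 2)), array(0 + 0i, c(2, 2, 2)), p)
  expect_error(subtract(small, np$post), "2x2x2.*32x32x16")
})

test_that("subtraction noise SD scales with sqrt(2) where signal dominates", {
  # the sqrt(2) law applies to Gaussian noise riding on signal; add a
  # constant background well above sigma so the magnitudes are Gaussianized
  d <- c(48, 48, 44)
  p <- acquisition_params(1.48, 2.84)
  set.seed(8)
  n <- prod(d)
  mk <- function() {
    dual_echo_volume(
      array(20 + complex(real = rnorm(n), imaginary = rnorm(n)), d),
      array(20 + complex(real = rnorm(n), imaginary = rnorm(n)), d), p)
  }
  s <- subtract(mk(), mk(), clip = FALSE)
  expect_equal(stats::sd(s$volume), sqrt(2), tolerance = 0.02)
})

test_that("clipping is monotone and only removes negative residuals", {
  np <- mk_noise_pair()
  s_signed <- subtract(np$pre, np$post, clip = FALSE)
  s_clip <- subtract(np$pre, np$post, clip = TRUE)
  expect_equal(s_clip$volume, pmax(s_signed$volume, 0))
  # increasing a post-contrast voxel never decreases the clipped subtraction
  post2 <- np$post
  post2$echo1[5, 5, 5] <- post2$echo1[5, 5, 5] * 10
  s2 <- subtract(np$pre, post2, clip = TRUE)
  expect_true(all(s2$volume >= s_clip$volume - 1e-12))
})

test_that("the coronal MIP equals an explicit per-column maximum", {
  set.seed(12)
  d <- c(10, 7, 9)
  vol <- array(runif(prod(d)), d)
  img <- station_image(vol, acquisition_params(1.48, 2.84), "mdixon")
  m <- mip_coronal(img)
  oracle <- matrix(0, d[1], d[3])
  for (x in seq_len(d[1])) for (z in seq_len(d[3])) {
    oracle[x, z] <- max(vol[x, , z])
  }
  expect_equal(m$pixels, oracle)
  expect_true(all(m$pixels >= vol[, 4, ]))

  # single nonzero voxel projects to a single nonzero pixel
  one <- array(0, d); one[3, 2, 6] <- 5
  m1 <- mip_coronal(station_image(one, acquisition_params(1.48, 2.84), "mdixon"))
  expect_equal(which(m1$pixels != 0), 3 + 10 * 5)

  # a single-slice volume is its own MIP
  flat <- array(runif(10 * 1 * 9), c(10, 1, 9))
  mf <- mip_coronal(station_image(flat, acquisition_params(1.48, 2.84), "mdixon"))
  expect_equal(mf$pixels, flat[, 1, ])
})

test_that("stitching spans the union of station extents and maxes overlaps", {
  p <- default_stations()
  mk_mip <- function(nm, fill) {
    img <- station_image(array(fill, c(20, 4, 86)), p[[nm]], "mdixon",
                         table_offset_mm = attr(p[[nm]], "table_offset_mm"))
    mip_coronal(img)
  }
  mips <- list(mk_mip("abdominal", 1), mk_mip("upper_leg", 2), mk_mip("lower_leg", 3))
  pano <- stitch(mips)
  expect_equal(pano$extent_fh_mm, 1210)
  expect_equal(dim(pano$pixels), c(20, 242))

  # a single station stitches to itself
  single <- stitch(mips[2])
  expect_equal(single$pixels, mips[[2]]$pixels)
  expect_equal(single$extent_fh_mm, 430)

  # two identical overlapping stations agree with either input on the overlap
  m_a <- mk_mip("abdominal", 7)
  m_b <- mk_mip("abdominal", 7)
  m_b$table_offset_mm <- m_b$table_offset_mm - 100
  pano2 <- stitch(list(m_a, m_b))
  expect_true(all(pano2$pixels[, 21:86] == 7))

  # a gap between stations warns and stays zero
  m_c <- mk_mip("abdominal", 1)
  m_c$table_offset_mm <- m_c$table_offset_mm + 1000
  expect_warning(pano3 <- stitch(list(m_a, m_c)), "gap")
  expect_true(any(colSums(pano3$pixels) == 0))
})

test_that("MIP and stitching commute with positive scaling", {
  set.seed(5)
  p <- acquisition_params(1.48, 2.84)
  v <- array(runif(20 * 6 * 43), c(20, 6, 43))
  i1 <- station_image(v, p, "mdixon", table_offset_mm = 0)
  i2 <- station_image(v[, , 43:1], p, "mdixon", table_offset_mm = 150)
  pano <- stitch(list(mip_coronal(i1), mip_coronal(i2)))
  i1s <- station_image(3 * v, p, "mdixon", table_offset_mm = 0)
  i2s <- station_image(3 * v[, , 43:1], p, "mdixon", table_offset_mm = 150)
  panos <- stitch(list(mip_coronal(i1s), mip_coronal(i2s)))
  expect_equal(panos$pixels, 3 * pano$pixels)
})
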