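params_abd <- function(voxel = c(2, 2, 2)) {
  acquisition_params(1.48, 2.84, voxel_size_mm = voxel)
}

test_that("the fat phasor sums peak contributions correctly", {
  # full phase cycle of a single peak: back to +1
  fm <- fat_model_single_peak(-500)
  expect_equal(fat_phasor(fm, 2), 1 + 0i, tolerance = 1e-12)
  # half cycle: -1
  fm2 <- fat_model_single_peak(-421.5)
  expect_equal(fat_phasor(fm2, 1000 / (2 * 421.5)), -1 + 0i, tolerance = 1e-12)
  # symmetric pair of peaks: real cosine
  fm3 <- dixonmra:::new_fat_model(tibble::tibble(offset_hz = c(-300, 300),
                                                 amplitude = c(0.5, 0.5)))
  expect_equal(fat_phasor(fm3, 0.7), complex(real = cos(2 * pi * 300 * 0.7e-3)),
               tolerance = 1e-12)
  # vectorised over echo times
  expect_length(fat_phasor(fm2, c(1, 2, 3)), 3)
  expect_error(dixonmra:::new_fat_model(tibble::tibble(offset_hz = 1,
                                                       amplitude = 0.5)),
               "sum to 1")
})

test_that("per-voxel candidates invert the forward model at a noiseless voxel", {
  p <- params_abd()
  fm <- fat_model_single_peak(-421.5)
  c1 <- fat_phasor(fm, p$te1_ms); c2 <- fat_phasor(fm, p$te2_ms)
  mk_vol <- function(w, f, phi1 = 0, phi2 = 0) {
    s1 <- array((w + c1 * f) * exp(1i * phi1), c(1, 1, 1))
    s2 <- array((w + c2 * f) * exp(1i * phi2), c(1, 1, 1))
    dual_echo_volume(s1, s2, p)
  }
  cand <- solve_two_point(mk_vol(2, 1, 0.3, 0.5), fm)
  wf_pairs <- rbind(c(cand$cand1$W[1], cand$cand1$F[1]),
                    c(cand$cand2$W[1], cand$cand2$F[1]))
  hit <- which(abs(wf_pairs[, 1] - 2) < 1e-9 & abs(wf_pairs[, 2] - 1) < 1e-9)
  expect_length(hit, 1)
  expect_lt(cand[[hit]]$residual[1], 1e-9)
  # the recovered between-echo phasor carries the synthesized phase
  expect_equal(Arg(cand[[hit]]$p[1]), 0.5 - 0.3, tolerance = 1e-9)

  # pure water: the F = 0 candidate has zero residual
  cw <- solve_two_point(mk_vol(3, 0), fm)
  f_vals <- c(cw$cand1$F[1], cw$cand2$F[1])
  res <- c(cw$cand1$residual[1], cw$cand2$residual[1])
  expect_lt(res[which.min(abs(f_vals))], 1e-9)

  # zero signal: both candidates collapse to (0, 0), phasor undefined
  cz <- solve_two_point(mk_vol(0, 0), fm)
  expect_equal(c(cz$cand1$W[1], cz$cand1$F[1], cz$cand2$W[1], cz$cand2$F[1]),
               rep(0, 4))
  expect_false(cz$cand1$ok[1] || cz$cand2$ok[1])
})

test_that("an ill-conditioned echo pair is rejected with the echo times named", {
  # a full fat cycle between echoes: c(TE1) == c(TE2)
  p <- acquisition_params(1, 3, fat_offset_hz = -500)
  vol <- dual_echo_volume(array(1 + 0i, c(2, 2, 2)), array(1 + 0i, c(2, 2, 2)), p)
  expect_error(solve_two_point(vol, fat_model_single_peak(-500)),
               "ill-conditioned.*TE1 = 1\\.000.*TE2 = 3\\.000")
})

test_that("water and fat are recovered exactly on a noiseless phantom with a smooth field", {
  spec <- tiny_tube_spec(noise_sd = 0, grid = c(32, 32, 20))
  maps <- build_phantom(spec)
  vol <- simulate_dual_echo(maps, params_abd(), contrast = "post", spec = spec)
  wf <- separate_water_fat(vol, field_smooth = 0)
  wtrue <- true_enhanced_water(maps, spec)
  sel <- wf$resolved & (wtrue + maps$fat) > 0
  tot <- wtrue[sel] + maps$fat[sel]
  expect_gt(sum(sel), 1000)
  expect_lt(max(abs(wf$water[sel] - wtrue[sel]) / tot), 1e-6)
  expect_lt(max(abs(wf$fat[sel] - maps$fat[sel]) / tot), 1e-6)
  # the selected phasor field has unit modulus wherever defined
  expect_equal(Mod(wf$phasor[wf$resolved]), rep(1, sum(wf$resolved)),
               tolerance = 1e-9)
})

test_that("region growing equals per-voxel lower-residual selection on a zero field map", {
  # water-dominant phantom, zero field: both rules reduce to the same choice
  spec <- tiny_tube_spec(noise_sd = 0, grid = c(20, 20, 12))
  spec$field_map_params$amplitude_hz <- 0
  spec$fat_params$interior_fat_fraction <- 0.2
  spec$fat_params$shell_fat_fraction <- 0.3
  maps <- build_phantom(spec)
  vol <- simulate_dual_echo(maps, params_abd(), contrast = "post", spec = spec)
  cands <- solve_two_point(vol)
  wf <- resolve_ambiguity(cands, vol, field_smooth = 0)

  tol <- 1e-6 * (Mod(vol$echo1) + Mod(vol$echo2)) / 2
  r1 <- cands$cand1$residual; r2 <- cands$cand2$residual
  pick <- ifelse(r1 < r2 - tol, 1L,
                 ifelse(r2 < r1 - tol, 2L,
                        ifelse(cands$cand1$W >= cands$cand2$W, 1L, 2L)))
  w_oracle <- ifelse(pick == 1L, cands$cand1$W, cands$cand2$W)
  sel <- wf$resolved
  expect_equal(wf$water[sel], array(w_oracle, dim(wf$water))[sel],
               tolerance = 1e-9)
})

test_that("an all-water phantom is never swapped", {
  spec <- tiny_tube_spec(noise_sd = 0)
  spec$fat_params$interior_fat_fraction <- 0
  spec$fat_params$shell_fat_fraction <- 0
  maps <- build_phantom(spec)
  vol <- simulate_dual_echo(maps, params_abd(), contrast = "post", spec = spec)
  wf <- separate_water_fat(vol, field_smooth = 0)
  wtrue <- true_enhanced_water(maps, spec)
  sel <- wf$resolved
  expect_lt(max(abs(wf$water[sel] - wtrue[sel])), 1e-9)
  expect_lt(max(wf$fat[sel]), 1e-9)
})

test_that("the separation is equivariant under positive intensity scaling", {
  spec <- tiny_tube_spec(noise_sd = 0.05, seed = 3, grid = c(20, 20, 12))
  maps <- build_phantom(spec)
  vol <- simulate_dual_echo(maps, params_abd(), contrast = "post", spec = spec)
  k <- 3.7
  vol_k <- dual_echo_volume(vol$echo1 * k, vol$echo2 * k, vol$params)
  wf <- separate_water_fat(vol)
  wf_k <- separate_water_fat(vol_k)
  expect_equal(wf_k$water, k * wf$water, tolerance = 1e-9)
  expect_equal(wf_k$fat, k * wf$fat, tolerance = 1e-9)
})

test_that("noise in the water image follows the closed-form propagation factor", {
  # uniform mixed tissue + noise: SD of the water image in the interior
  # approaches sigma / sqrt(1 - cos(2 pi dTE dfF))
  p <- acquisition_params(1.48, 2.84)
  d <- c(48, 48, 44)
  sd0 <- 0.05
  fm <- fat_model_single_peak(-421.5)
  c1 <- fat_phasor(fm, p$te1_ms); c2 <- fat_phasor(fm, p$te2_ms)
  set.seed(41)
  n <- prod(d)
  s1 <- (0.8 + c1 * 0.2) + complex(real = rnorm(n, 0, sd0),
                                   imaginary = rnorm(n, 0, sd0))
  s2 <- (0.8 + c2 * 0.2) + complex(real = rnorm(n, 0, sd0),
                                   imaginary = rnorm(n, 0, sd0))
  vol <- dual_echo_volume(array(s1, d), array(s2, d), p)
  wf <- separate_water_fat(vol, sigma = sd0)
  expect_equal(stats::sd(wf$water),
               sd0 / separation_gain(p$te1_ms, p$te2_ms, p$fat_offset_hz),
               tolerance = 0.05)
})

test_that("the noise SD estimator recovers sigma on background-dominated volumes", {
  vol <- simulate_noise_only(c(48, 48, 24), 0.7, seed = 5)
  expect_equal(estimate_noise_sd(vol), 0.7, tolerance = 0.05)
})
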