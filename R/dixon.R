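#' Estimate the per-channel noise SD of a dual-echo volume
#'
#' Assumes the lower quartile of the first-echo magnitude image is
#' background (air) noise, whose magnitude is Rayleigh distributed: the
#' 25th percentile of a Rayleigh field equals sigma * sqrt(2 ln(4/3)), so
#' dividing by that constant recovers the per-channel Gaussian SD. On
#' volumes with little air this overestimates sigma, which only makes the
#' downstream signal floor more conservative.
#'
#' @param volume An `mra_dual_echo` volume.
#' @return Estimated per-channel noise SD (scalar).
#' @export
estimate_noise_sd <- function(volume) {
  stopifnot(inherits(volume, "mra_dual_echo"))
  q25 <- stats::quantile(Mod(volume$echo1), 0.25, names = FALSE)
  q25 / sqrt(2 * log(4 / 3))
}

#' Per-voxel two-point water-fat candidate solutions
#'
#' Solves, independently per voxel, the two-point Dixon model
#' `S1 = (W + c1 F) q1`, `S2 = (W + c2 F) q1 p` for nonnegative water and
#' fat magnitudes `W`, `F` and unit phasors, where `c_n = c(TE_n)` is the
#' fat spectral phasor. Eliminating the phases leaves a homogeneous
#' quadratic in the fat/water ratio with (generically) two admissible
#' roots — the water/fat swap ambiguity. Both candidates are returned with
#' their magnitude-space residuals and between-echo phasors; candidates
#' whose direction leaves the nonnegative quadrant are projected onto the
#' nearer of the pure-water / pure-fat axes (picking up a nonzero residual).
#'
#' @param volume An `mra_dual_echo` volume.
#' @param fat_model Fat spectral model.
#' @param condition_tol Minimum `|c(TE1) - c(TE2)|`; below it the echo pair
#'   cannot separate water from fat and an error is raised.
#' @return An object of class `mra_dixon_candidates`: per-candidate arrays
#'   `W`, `F`, `residual`, `p` (between-echo phasor), `q1` (TE1 phasor) and
#'   `ok` (phasor defined), plus `c1`, `c2` and the acquisition parameters.
#' @export
solve_two_point <- function(volume, fat_model = fat_model_single_peak(volume$params$fat_offset_hz),
                            condition_tol = 1e-3) {
  stopifnot(inherits(volume, "mra_dual_echo"))
  p <- volume$params
  c1 <- fat_phasor(fat_model, p$te1_ms)
  c2 <- fat_phasor(fat_model, p$te2_ms)
  if (Mod(c1 - c2) < condition_tol) {
    stop(sprintf("ill-conditioned echo pair TE1 = %.3f ms, TE2 = %.3f ms: |c1 - c2| = %.2e < %g",
                 p$te1_ms, p$te2_ms, Mod(c1 - c2), condition_tol), call. = FALSE)
  }
  d <- dim(volume$echo1)
  S1 <- as.vector(volume$echo1); S2 <- as.vector(volume$echo2)
  m1 <- Mod(S1); m2 <- Mod(S2)
  a1 <- Re(c1); a2 <- Re(c2)
  ac1 <- Mod(c1)^2; ac2 <- Mod(c2)^2

  # homogeneous quadratic alpha W^2 + beta W F + gamma F^2 = 0 in the
  # candidate direction (W : F), from |S1|^2 / |S2|^2
  alpha <- m2^2 - m1^2
  beta <- 2 * (m2^2 * a1 - m1^2 * a2)
  gamma <- m2^2 * ac1 - m1^2 * ac2
  disc <- pmax(beta^2 - 4 * alpha * gamma, 0)
  sq <- sqrt(disc)

  # each root has two algebraically equivalent homogeneous representations;
  # keep the better-conditioned one
  dir_of <- function(wa, fa, wb, fb) {
    use_b <- (wb^2 + fb^2) > (wa^2 + fa^2)
    w0 <- ifelse(use_b, wb, wa); f0 <- ifelse(use_b, fb, fa)
    nrm <- sqrt(w0^2 + f0^2)
    degen <- nrm == 0
    w0 <- ifelse(degen, 1, w0 / pmax(nrm, 1e-300))
    f0 <- ifelse(degen, 0, f0 / pmax(nrm, 1e-300))
    flip <- (w0 < 0 & f0 <= 0) | (f0 < 0 & w0 <= 0)
    list(w = ifelse(flip, -w0, w0), f = ifelse(flip, -f0, f0))
  }
  d1 <- dir_of(-beta + sq, 2 * alpha, 2 * gamma, -beta - sq)
  d2 <- dir_of(-beta - sq, 2 * alpha, 2 * gamma, -beta + sq)

  zero_sig <- (m1 + m2) < 1e-300
  mk_candidate <- function(dir) {
    w0 <- dir$w; f0 <- dir$f
    # directions escaping the nonnegative quadrant are projected onto the
    # closer axis (pure water vs pure fat, by residual)
    mixed <- w0 * f0 < 0
    if (any(mixed)) {
      lw <- (m1 + m2) / 2
      rw <- sqrt((lw - m1)^2 + (lw - m2)^2)
      bf1 <- sqrt(ac1); bf2 <- sqrt(ac2)
      lf <- (m1 * bf1 + m2 * bf2) / (ac1 + ac2)
      rf <- sqrt((lf * bf1 - m1)^2 + (lf * bf2 - m2)^2)
      take_f <- rf < rw
      w0 <- ifelse(mixed, ifelse(take_f, 0, 1), w0)
      f0 <- ifelse(mixed, ifelse(take_f, 1, 0), f0)
    }
    den1 <- w0 + c1 * f0
    den2 <- w0 + c2 * f0
    b1 <- Mod(den1); b2 <- Mod(den2)
    lam <- ifelse(b1^2 + b2^2 > 0, (m1 * b1 + m2 * b2) / (b1^2 + b2^2), 0)
    W <- lam * w0; F <- lam * f0
    residual <- sqrt((lam * b1 - m1)^2 + (lam * b2 - m2)^2)
    q1n <- S1 * Conj(den1)
    q2n <- S2 * Conj(den2)
    ok <- Mod(q1n) > 0 & Mod(q2n) > 0 & !zero_sig
    q1 <- ifelse(ok, q1n / Mod(q1n), NA_complex_)
    q2 <- ifelse(ok, q2n / Mod(q2n), NA_complex_)
    W[zero_sig] <- 0; F[zero_sig] <- 0
    residual[zero_sig] <- 0
    list(W = array(W, d), F = array(F, d),
         residual = array(residual, d),
         p = array(q2 * Conj(q1), d), q1 = array(q1, d),
         ok = array(ok, d))
  }
  structure(list(cand1 = mk_candidate(d1), cand2 = mk_candidate(d2),
                 c1 = c1, c2 = c2, dim = d, params = p),
            class = "mra_dixon_candidates")
}

#' Resolve the water/fat swap ambiguity by seeded region growing
#'
#' The highest-magnitude voxel above the signal floor seeds the first
#' region with its lower-residual candidate (ties to the water-dominant
#' one). The region grows through its 6-connected frontier in descending
#' magnitude order (ties by linear index); each grown voxel takes the
#' candidate whose between-echo phasor is closest to the mean phasor of its
#' already-resolved 6-neighbours, so the selected phasor field follows the
#' smooth off-resonance map. Disconnected regions seed independently. The resolved
#' (optionally smoothed) phasor field then demodulates both echoes and a
#' per-voxel 2x2 complex linear solve yields the final water and fat
#' magnitudes. Voxels below the floor keep an identity phasor (undefined
#' field) but still receive the linear-solve magnitudes, so background noise
#' texture is preserved rather than zeroed.
#'
#' @param candidates Output of [solve_two_point()].
#' @param volume The `mra_dual_echo` volume the candidates came from.
#' @param sigma Per-channel noise SD; estimated with [estimate_noise_sd()]
#'   when `NULL`.
#' @param signal_floor Mean-echo-magnitude threshold below which the phasor
#'   is considered undefined; defaults to `3 * sigma`.
#' @param field_smooth Radius (voxels) of the box kernel used to smooth the
#'   resolved field phasor before the final solve; `0` keeps the exact
#'   per-voxel phasor (use for noiseless data).
#' @return An object of class `mra_water_fat`: arrays `water`, `fat`,
#'   `phasor` (unit-modulus between-echo phasor, `NA` where unresolved),
#'   `resolved`, `choice`, plus `sigma`, `signal_floor` and the acquisition
#'   parameters.
#' @export
resolve_ambiguity <- function(candidates, volume, sigma = NULL,
                              signal_floor = NULL, field_smooth = 1) {
  stopifnot(inherits(candidates, "mra_dixon_candidates"),
            inherits(volume, "mra_dual_echo"))
  d <- candidates$dim
  mag <- (Mod(volume$echo1) + Mod(volume$echo2)) / 2
  if (is.null(sigma)) sigma <- estimate_noise_sd(volume)
  if (is.null(signal_floor)) signal_floor <- 3 * sigma

  active <- which(as.vector(mag) >= signal_floor & as.vector(mag) > 0)
  ord <- active[order(-as.vector(mag)[active], active, method = "radix")]

  ca <- candidates$cand1; cb <- candidates$cand2
  p1 <- as.vector(ca$p); p2 <- as.vector(cb$p)
  ok1 <- as.vector(ca$ok) & !is.na(p1)
  ok2 <- as.vector(cb$ok) & !is.na(p2)
  p1[!ok1] <- 0 + 0i; p2[!ok2] <- 0 + 0i
  # where the two candidate phasors (nearly) coincide the choice is
  # immaterial but the shared phasor is unreliable (noise-degenerate double
  # roots sit halfway between the hypotheses): keep such voxels out of the
  # neighbour phasor means
  informative <- (ok1 != ok2) | (ok1 & ok2 & Mod(p1 - p2) > 0.05)
  choice <- resolve_region_grow_cpp(
    as.integer(d), as.integer(ord - 1L),
    Re(p1), Im(p1), Re(p2), Im(p2), ok1, ok2, informative,
    as.vector(ca$residual), as.vector(cb$residual),
    as.vector(ca$W), as.vector(cb$W),
    as.vector(mag)
  )
  resolved <- choice > 0L

  P <- ifelse(choice == 1L, p1, ifelse(choice == 2L, p2, NA_complex_))
  Q1 <- ifelse(choice == 1L, as.vector(ca$q1),
               ifelse(choice == 2L, as.vector(cb$q1), NA_complex_))
  P <- array(P, d); Q1 <- array(Q1, d)
  resolved <- array(resolved, d)

  if (field_smooth > 0) {
    w <- mag * resolved
    Pz <- P; Pz[!resolved] <- 0 + 0i
    Qz <- Q1; Qz[!resolved] <- 0 + 0i
    num_p <- box_sum3d(Pz * w, field_smooth)
    num_q <- box_sum3d(Qz * w, field_smooth)
    den <- box_sum3d(w, field_smooth)
    have <- den > 0 & Mod(num_p) > 0 & Mod(num_q) > 0
    Pd <- array(1 + 0i, d); Qd <- array(1 + 0i, d)
    Pd[have] <- num_p[have] / Mod(num_p[have])
    Qd[have] <- num_q[have] / Mod(num_q[have])
  } else {
    Pd <- P; Qd <- Q1
    Pd[!resolved | is.na(Pd)] <- 1 + 0i
    Qd[!resolved | is.na(Qd)] <- 1 + 0i
  }

  # demodulate and solve the linear two-point system per voxel
  c1 <- candidates$c1; c2 <- candidates$c2
  det <- c2 - c1
  S1h <- volume$echo1 * Conj(Qd)
  S2h <- volume$echo2 * Conj(Qd * Pd)
  Wc <- (c2 * S1h - c1 * S2h) / det
  Fc <- (S2h - S1h) / det

  structure(list(water = Mod(Wc), fat = Mod(Fc),
                 phasor = P, resolved = resolved,
                 choice = array(choice, d),
                 sigma = sigma, signal_floor = signal_floor,
                 field_smooth = field_smooth,
                 params = volume$params),
            class = "mra_water_fat")
}

#' Two-point Dixon water-fat separation
#'
#' Composition of [solve_two_point()] and [resolve_ambiguity()]: the water
#' volume is the inherently fat-suppressed, subtractionless angiogram.
#'
#' @inheritParams solve_two_point
#' @inheritParams resolve_ambiguity
#' @return An `mra_water_fat` object.
#' @examples
#' spec <- default_phantom_spec("abdominal", noise_sd = 0)
#' maps <- build_phantom(spec)
#' vol <- simulate_dual_echo(maps, acquisition_params(1.48, 2.84))
#' wf <- separate_water_fat(vol, field_smooth = 0)
#' @export
separate_water_fat <- function(volume, fat_model = fat_model_single_peak(volume$params$fat_offset_hz),
                               sigma = NULL, signal_floor = NULL,
                               field_smooth = 1, condition_tol = 1e-3) {
  cands <- solve_two_point(volume, fat_model, condition_tol = condition_tol)
  resolve_ambiguity(cands, volume, sigma = sigma,
                    signal_floor = signal_floor, field_smooth = field_smooth)
}

#' @export
print.mra_water_fat <- function(x, ...) {
  cat(sprintf("<mra_water_fat> %s grid, %.1f%% voxels above floor (sigma = %.4g)\n",
              paste(dim(x$water), collapse = "x"),
              100 * mean(x$resolved), x$sigma))
  invisible(x)
}

# sliding box sum with zero padding; works for numeric and complex arrays
box_sum3d <- function(arr, r) {
  d <- dim(arr)
  out <- array(if (is.complex(arr)) 0 + 0i else 0, d)
  for (dx in -r:r) {
    sx <- max(1, 1 - dx):min(d[1], d[1] - dx)
    tx <- sx + dx
    for (dy in -r:r) {
      sy <- max(1, 1 - dy):min(d[2], d[2] - dy)
      ty <- sy + dy
      for (dz in -r:r) {
        sz <- max(1, 1 - dz):min(d[3], d[3] - dz)
        tz <- sz + dz
        out[tx, ty, tz] <- out[tx, ty, tz] + arr[sx, sy, sz]
      }
    }
  }
  out
}
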