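# independent brute-force helpers used as oracles in several test files

# connected component of `candidate` (linear indices) containing `seed`,
# by breadth-first search with an explicit 26-neighbour loop
oracle_component <- function(seed, candidate, d) {
  candset <- rep(FALSE, prod(d))
  candset[candidate] <- TRUE
  seen <- rep(FALSE, prod(d))
  seen[seed] <- TRUE
  queue <- seed
  out <- seed
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    x <- (cur - 1) %% d[1] + 1
    y <- ((cur - 1) %/% d[1]) %% d[2] + 1
    z <- (cur - 1) %/% (d[1] * d[2]) + 1
    for (ax in -1:1) for (ay in -1:1) for (az in -1:1) {
      if (ax == 0 && ay == 0 && az == 0) next
      xx <- x + ax; yy <- y + ay; zz <- z + az
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
      nb <- xx + d[1] * (yy - 1) + d[1] * d[2] * (zz - 1)
      if (candset[nb] && !seen[nb]) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
        out <- c(out, nb)
      }
    }
  }
  sort(out)
}

# strict-or-plateau local maxima by exhaustive per-voxel neighbour
# comparison, restricted to the voxel set `idx`
oracle_local_max <- function(volume, idx) {
  d <- dim(volume)
  inset <- rep(FALSE, prod(d)); inset[idx] <- TRUE
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    x <- (i - 1) %% d[1] + 1
    y <- ((i - 1) %/% d[1]) %% d[2] + 1
    z <- (i - 1) %/% (d[1] * d[2]) + 1
    ok <- TRUE
    for (ax in -1:1) for (ay in -1:1) for (az in -1:1) {
      if (ax == 0 && ay == 0 && az == 0) next
      xx <- x + ax; yy <- y + ay; zz <- z + az
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
      nb <- xx + d[1] * (yy - 1) + d[1] * d[2] * (zz - 1)
      if (inset[nb] && volume[nb] > volume[i]) ok <- FALSE
    }
    keep[k] <- ok
  }
  idx[keep]
}

# voxel count of a straight cylinder by per-voxel point-in-cylinder test
oracle_cylinder_count <- function(p1, p2, r, d, v) {
  dv <- p2 - p1
  len2 <- sum(dv^2)
  cnt <- 0L
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    pt <- c((x - 0.5) * v[1], (y - 0.5) * v[2], (z - 0.5) * v[3])
    t <- sum((pt - p1) * dv) / len2
    t <- min(max(t, 0), 1)
    if (sum((pt - p1 - t * dv)^2) <= r^2) cnt <- cnt + 1L
  }
  cnt
}

# small straight-tube phantom spec on a compact grid
tiny_tube_spec <- function(noise_sd = 0, seed = 1L, stenosis = 0, occluded = FALSE,
                           grid = c(24, 24, 16), voxel = c(2, 2, 2)) {
  tree <- tibble::tibble(segment = "tube",
                         x1 = grid[1] * voxel[1] / 2, y1 = grid[2] * voxel[2] / 2, z1 = 0,
                         x2 = grid[1] * voxel[1] / 2, y2 = grid[2] * voxel[2] / 2,
                         z2 = grid[3] * voxel[3],
                         radius_mm = 3 * voxel[1], stenosis = stenosis,
                         occluded = occluded)
  phantom_spec(grid_shape = grid, voxel_size_mm = voxel, vessel_tree = tree,
               noise_sd = noise_sd, seed = seed)
}

# enhanced ground-truth water map of a phantom
true_enhanced_water <- function(maps, spec = maps$spec) {
  w <- maps$water
  w[maps$vessel_mask] <- w[maps$vessel_mask] * spec$enhancement_factor
  w
}
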