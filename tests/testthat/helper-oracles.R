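# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths where feasible (fine sampling instead of the
# production step size; explicit enumeration instead of closed forms).

# brute-force streamline density: for EVERY voxel of the grid, a slab
# (axis-interval intersection) test of every segment against the voxel cube.
# This is the exact limit of arbitrarily fine point sampling, and shares no
# code path with the package's boundary-crossing traversal.
oracle_density <- function(streamlines, affine, shape) {
  inv <- solve(affine)
  grid <- as.matrix(expand.grid(0:(shape[1] - 1), 0:(shape[2] - 1),
                                0:(shape[3] - 1)))
  counts <- array(0L, shape)
  nvox <- nrow(grid)
  for (s in streamlines) {
    pv <- t(inv %*% rbind(t(s), 1))[, 1:3, drop = FALSE]
    hit <- rep(FALSE, nvox)
    for (k in seq_len(nrow(pv) - 1)) {
      p0 <- pv[k, ]; d <- pv[k + 1, ] - p0
      tlo <- rep(0, nvox); thi <- rep(1, nvox); ok <- rep(TRUE, nvox)
      for (a in 1:3) {
        lo <- grid[, a] - 0.5 - p0[a]
        hi <- grid[, a] + 0.5 - p0[a]
        if (abs(d[a]) < 1e-14) {
          ok <- ok & (lo <= 0 & 0 <= hi)
        } else {
          t1 <- lo / d[a]; t2 <- hi / d[a]
          tlo <- pmax(tlo, pmin(t1, t2))
          thi <- pmin(thi, pmax(t1, t2))
        }
      }
      hit <- hit | (ok & tlo <= thi)
    }
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# exact two-sided signed-rank p-value by full 2^n sign enumeration
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  p <- 2 * min(mean(vs <= v), mean(vs >= v))
  min(1, p)
}

# random binary mask on a small grid
random_mask <- function(shape, p = 0.3, affine = diag(4)) {
  bundle_mask(array(stats::runif(prod(shape)) < p, shape), affine)
}

# random gentle 3-D polyline inside a grid (world mm, identity affine)
random_streamline <- function(shape, n_pts = 8) {
  start <- stats::runif(3, 1, shape - 2)
  steps <- matrix(stats::rnorm(3 * (n_pts - 1), 0, 1.5), n_pts - 1, 3)
  pts <- rbind(start, start + apply(steps, 2, cumsum))
  pmin(pmax(pts, 0), matrix(shape - 1e-6, n_pts, 3, byrow = TRUE))
}

# analytic digital cylinder mask: axis +x, length L, radius r, 1 mm grid
cylinder_mask <- function(L = 100, r = 5) {
  shape <- c(as.integer(L + 4), as.integer(2 * r + 6), as.integer(2 * r + 6))
  aff <- diag(4)
  aff[1:3, 4] <- c(-1.5, -(r + 2.5), -(r + 2.5))
  g <- expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                   z = 0:(shape[3] - 1))
  w <- cbind(g$x + aff[1, 4], g$y + aff[2, 4], g$z + aff[3, 4])
  inside <- w[, 1] >= 0 & w[, 1] <= L & (w[, 2]^2 + w[, 3]^2) <= r^2
  bundle_mask(array(inside, shape), aff)
}

# straight parallel bundle: n x n streamlines at integer (y, z) offsets,
# length L along +x; world coordinates sit at voxel centres of an identity
# grid shifted by `origin`
grid_bundle <- function(n = 10, L = 50, origin = c(2, 2, 2)) {
  sl <- list()
  for (y in 0:(n - 1)) for (z in 0:(n - 1)) {
    sl[[length(sl) + 1L]] <-
      cbind(seq(0, L, by = 1) + origin[1], y + origin[2], z + origin[3])
  }
  tractogram(sl, diag(4), as.integer(c(L + 2 * origin[1], n + 2 * origin[2],
                                       n + 2 * origin[3])))
}

# voxelize a tractogram on its own grid and binarize at density 1
mask_of <- function(t, ...) density_to_mask(streamlines_to_density(t, ...))

# 1 mm grid covering a tractogram's bounding box plus a margin
bundle_grid <- function(t, margin = 5) {
  pts <- do.call(rbind, t$streamlines)
  lo <- floor(apply(pts, 2, min) - margin)
  hi <- ceiling(apply(pts, 2, max) + margin)
  aff <- diag(4); aff[1:3, 4] <- lo + 0.5
  list(affine = aff, shape = as.integer(hi - lo))
}

# voxelize on a covering grid and return both tractogram-with-grid and mask
bundle_and_mask <- function(t, margin = 5) {
  g <- bundle_grid(t, margin)
  t2 <- tractogram(t$streamlines, g$affine, g$shape)
  for (at in c("centerline", "core")) attr(t2, at) <- attr(t, at)
  list(t = t2, mask = density_to_mask(streamlines_to_density(t2)))
}

# deterministic filled-cylinder bundle: straight streamlines along +x tiling
# a disc of radius r at sub-voxel spacing, so the density-1 mask is a solid
# digital cylinder at scale 1 and 2 alike
cylinder_bundle <- function(L = 50, r = 5, spacing = 0.5) {
  offs <- as.matrix(expand.grid(y = seq(-r, r, by = spacing),
                                z = seq(-r, r, by = spacing)))
  offs <- offs[rowSums(offs^2) <= r^2, , drop = FALSE]
  sl <- lapply(seq_len(nrow(offs)), function(i)
    cbind(seq(0, L, by = 1), offs[i, 1], offs[i, 2]))
  tractogram(sl)
}
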