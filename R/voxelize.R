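#' Streamline density map
#'
#' Counts, for every voxel of a target grid, the number of distinct
#' streamlines that intersect it (a streamline increments a voxel at most
#' once). By default the streamline-voxel intersection is exact: every
#' half-voxel boundary crossing of every segment is enumerated and the
#' voxel of each inter-crossing interval recorded, which agrees with
#' arbitrarily fine sub-voxel sampling. Passing a `step` instead walks each
#' segment at that spacing (the simple sub-sampling formulation, useful for
#' cross-checks).
#'
#' @param t a [tractogram()].
#' @param grid_affine 4x4 voxel-to-world map of the target grid; defaults to
#'   the tractogram's reference affine.
#' @param grid_shape integer 3-vector; defaults to the tractogram's reference
#'   shape.
#' @param step `NULL` for exact traversal (default), or a sub-voxel walk step
#'   in mm.
#' @return An object of class `density_map`: `counts` (3-D integer array),
#'   `affine`, `voxel_sizes`, `n_streamlines`, `n_outside` (streamlines that
#'   fell entirely outside the grid; each raises a warning).
#' @export
streamlines_to_density <- function(t, grid_affine = t$affine,
                                   grid_shape = t$shape, step = NULL) {
  stopifnot(inherits(t, "tractogram"), is.null(step) || step > 0)
  grid_affine <- as_affine(grid_affine)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape <= 0)) stop("grid_shape must be positive")
  counts <- array(0L, grid_shape)
  inv <- solve(grid_affine)
  n_outside <- 0L
  n_sl <- t$n_streamlines
  if (n_sl > 0L) {
    if (is.null(step)) {
      to_vox <- function(s) t(inv %*% rbind(t(s), 1))[, 1:3, drop = FALSE]
      per <- lapply(t$streamlines, function(s) polyline_voxels_exact(to_vox(s)))
    } else {
      per <- lapply(t$streamlines, function(s) {
        pts <- densify_polyline(s, step)
        round_half_down(t(inv %*% rbind(t(pts), 1))[, 1:3, drop = FALSE])
      })
    }
    ids <- rep(seq_len(n_sl), vapply(per, nrow, integer(1)))
    idx <- do.call(rbind, per)
    keep <- in_grid(idx, grid_shape)
    ids <- ids[keep]
    lin <- 1 + idx[keep, 1] +
      grid_shape[1] * (idx[keep, 2] + grid_shape[2] * idx[keep, 3])
    # one increment per distinct (streamline, voxel); double keys stay exact
    key <- (ids - 1) * prod(grid_shape) + lin
    first <- !duplicated(key)
    tab <- tabulate(lin[first], nbins = prod(grid_shape))
    counts[] <- counts + tab
    n_outside <- n_sl - length(unique(ids))
    if (n_outside > 0L)
      warning(n_outside, " streamline(s) fell entirely outside the grid")
  }
  structure(list(counts = counts, affine = grid_affine,
                 voxel_sizes = voxel_sizes(grid_affine),
                 n_streamlines = t$n_streamlines, n_outside = n_outside),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s grid, %d streamlines, max count %d\n",
              paste(dim(x$counts), collapse = " x "), x$n_streamlines,
              max(x$counts)))
  invisible(x)
}

#' Binarize a density map into a bundle mask
#'
#' A voxel enters the mask when at least `threshold` streamlines visit it;
#' the default threshold of 1 reproduces density-1 binarization. Supply
#' `target` to standardize the result onto a 1 mm grid in the same call.
#'
#' @param d a `density_map`.
#' @param threshold minimum streamline count (>= 1).
#' @param target optional list with `affine` and `shape` of a 1 mm target
#'   grid, forwarded to [standardize_mask()].
#' @return A [bundle_mask()]; `empty_flagged` is set if no voxel survives.
#' @export
density_to_mask <- function(d, threshold = 1, target = NULL) {
  stopifnot(inherits(d, "density_map"), threshold >= 1)
  m <- bundle_mask(d$counts >= threshold, d$affine,
                   empty_flagged = !any(d$counts >= threshold))
  if (!is.null(target)) m <- standardize_mask(m, target)
  m
}

#' Threshold a probability / visitation map into a bundle mask
#'
#' For probabilistic workflows that emit normalized visitation maps rather
#' than streamlines. The threshold is inclusive (values equal to it are kept).
#'
#' @param p a [volume()] with nonnegative values.
#' @param threshold inclusive probability threshold; the default 2.5e-4
#'   suits normalized visitation-count distributions.
#' @param target optional 1 mm target grid, as in [density_to_mask()].
#' @return A [bundle_mask()].
#' @export
probability_to_mask <- function(p, threshold = 2.5e-4, target = NULL) {
  stopifnot(inherits(p, "volume"))
  if (any(p$data < 0)) stop("probability map contains negative values")
  m <- bundle_mask(p$data >= threshold, p$affine,
                   empty_flagged = !any(p$data >= threshold))
  if (!is.null(target)) m <- standardize_mask(m, target)
  m
}

#' Resample a binary mask onto a 1 mm isotropic grid
#'
#' Nearest-neighbour resampling: each target voxel centre is mapped into the
#' source grid and takes the source voxel's value (ties toward the lower
#' index), so the output stays strictly binary. If the target grid fails to
#' cover nonzero source voxels, a warning reports how many were clipped.
#'
#' @param m a [bundle_mask()].
#' @param target list with `affine` (4x4) and `shape` (3 ints) describing the
#'   1 mm grid; `NULL` builds a corner-aligned 1 mm grid covering the source
#'   field of view (see details in the package vignette).
#' @return A [bundle_mask()] on the target grid with 1 mm isotropic voxels.
#' @export
standardize_mask <- function(m, target = NULL) {
  stopifnot(inherits(m, "bundle_mask"))
  if (is.null(target)) target <- grid_1mm(m$affine, dim(m$mask))
  tgt_aff <- as_affine(target$affine)
  tgt_shape <- as.integer(target$shape)
  if (affines_equal(tgt_aff, m$affine) &&
      identical(tgt_shape, as.integer(dim(m$mask))))
    return(bundle_mask(m$mask, m$affine, empty_flagged = m$empty_flagged))

  src_shape <- dim(m$mask)
  # all target voxel centres -> world -> source voxel indices
  g <- as.matrix(expand.grid(0:(tgt_shape[1] - 1L),
                             0:(tgt_shape[2] - 1L),
                             0:(tgt_shape[3] - 1L)))
  w <- voxel_to_world(g, tgt_aff)
  sv <- round_half_down(world_to_voxel(w, m$affine))
  ok <- in_grid(sv, src_shape)
  out <- array(FALSE, tgt_shape)
  lin_src <- 1L + sv[ok, 1] + src_shape[1] * (sv[ok, 2] + src_shape[2] * sv[ok, 3])
  out[which(ok)] <- m$mask[lin_src]

  # clipped-source check: nonzero source voxel centres outside the target FOV
  #
  # (shared with resample_volume_nn below, which performs the same pull-style
  # nearest-neighbour mapping for scalar volumes)
  nz <- which(m$mask)
  if (length(nz)) {
    nz0 <- arrayInd(nz, src_shape) - 1L
    wv <- voxel_to_world(nz0, m$affine)
    tv <- round_half_down(world_to_voxel(wv, tgt_aff))
    clipped <- sum(!in_grid(tv, tgt_shape))
    if (clipped > 0L)
      warning("target grid clips ", clipped, " nonzero source voxel(s)")
  }
  bundle_mask(out, tgt_aff, empty_flagged = m$empty_flagged && !any(out))
}

#' Nearest-neighbour resampling of a scalar volume onto a target grid
#'
#' Pull-style resampling: each target voxel centre is mapped into the source
#' grid and takes the nearest source voxel's value (`fill` outside the source
#' field of view). Used to bring native-resolution metric maps (FA, MD) onto
#' the standardized 1 mm mask grid before in-bundle extraction.
#'
#' @param v a [volume()].
#' @param target list with `affine` and `shape` of the target grid.
#' @param fill value for target voxels outside the source FOV.
#' @return A [volume()] on the target grid.
#' @export
resample_volume_nn <- function(v, target, fill = NA_real_) {
  stopifnot(inherits(v, "volume"))
  tgt_aff <- as_affine(target$affine)
  tgt_shape <- as.integer(target$shape)
  src_shape <- dim(v$data)
  g <- as.matrix(expand.grid(0:(tgt_shape[1] - 1L),
                             0:(tgt_shape[2] - 1L),
                             0:(tgt_shape[3] - 1L)))
  w <- voxel_to_world(g, tgt_aff)
  sv <- round_half_down(world_to_voxel(w, v$affine))
  ok <- in_grid(sv, src_shape)
  out <- array(fill, tgt_shape)
  lin <- 1L + sv[ok, 1] + src_shape[1] * (sv[ok, 2] + src_shape[2] * sv[ok, 3])
  out[which(ok)] <- v$data[lin]
  volume(out, tgt_aff, allow_na = TRUE)
}

# exact voxel traversal of a polyline given in continuous 0-based voxel
# coordinates: enumerate every half-integer boundary crossing per segment and
# take the midpoint of each inter-crossing interval — each interval lies
# wholly inside one voxel, so the result equals arbitrarily fine sampling.
# Voxel ownership matches round_half_down (cells are (k-0.5, k+0.5]).
polyline_voxels_exact <- function(pv) {
  n <- nrow(pv)
  if (n < 2L) return(round_half_down(pv))
  p0 <- pv[-n, , drop = FALSE]
  d <- pv[-1, , drop = FALSE] - p0
  nseg <- n - 1L
  seg_ids <- integer(0); tvals <- numeric(0)
  for (a in 1:3) {
    lo <- ceiling(pmin(pv[-n, a], pv[-1, a]) - 0.5)
    hi <- ceiling(pmax(pv[-n, a], pv[-1, a]) - 0.5)
    k <- hi - lo
    pos <- which(k > 0)
    if (!length(pos)) next
    reps <- k[pos]
    sid <- rep(pos, reps)
    bval <- sequence(reps) - 0.5 + rep(lo[pos], reps)
    seg_ids <- c(seg_ids, sid)
    tvals <- c(tvals, (bval - p0[sid, a]) / d[sid, a])
  }
  seg_ids <- c(seg_ids, seq_len(nseg), seq_len(nseg))
  tvals <- c(pmin(pmax(tvals, 0), 1), rep(0, nseg), rep(1, nseg))
  o <- order(seg_ids, tvals)
  seg_ids <- seg_ids[o]; tvals <- tvals[o]
  m <- length(tvals)
  same <- seg_ids[-m] == seg_ids[-1]
  tm <- ((tvals[-m] + tvals[-1]) / 2)[same]
  sid <- seg_ids[-m][same]
  round_half_down(p0[sid, , drop = FALSE] + tm * d[sid, , drop = FALSE])
}
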