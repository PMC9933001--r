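#' Streamline tractogram container
#'
#' A tractogram is an ordered collection of streamlines, each an ordered
#' polyline of 3-D points expressed in world RAS millimetres, together with
#' the affine and shape of the reference voxel grid the bundle was traced in.
#' All package functions operate in world RAS mm; on-disk conventions (the
#' TRK voxel-mm dialect in particular) are converted at read/write time.
#'
#' @param streamlines list of numeric matrices, each n_i x 3 (n_i >= 2), in
#'   world RAS mm.
#' @param affine 4x4 voxel-to-world matrix of the reference grid.
#' @param shape integer vector of length 3, reference grid dimensions.
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, affine = diag(4), shape = c(0L, 0L, 0L)) {
  stopifnot(is.list(streamlines))
  affine <- as_affine(affine)
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L)
      stop("each streamline must be an n x 3 matrix of world RAS mm points")
    if (nrow(s) < 2L)
      stop("each streamline must have at least 2 points")
    if (!all(is.finite(s)))
      stop("streamline coordinates must be finite")
    dimnames(s) <- NULL
    s
  })
  structure(
    list(streamlines = streamlines,
         n_streamlines = length(streamlines),
         affine = affine,
         shape = as.integer(shape)),
    class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("<tractogram> %d streamlines, reference grid %s\n",
              x$n_streamlines, paste(x$shape, collapse = " x ")))
  invisible(x)
}

#' Number of streamlines
#' @param x a `tractogram`
#' @param ... unused
#' @export
length.tractogram <- function(x) x$n_streamlines

#' Scalar 3-D image volume
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param allow_na permit `NA` voxels (e.g. metric maps that were only fit
#'   inside a mask); plain volumes must be finite everywhere.
#' @return An object of class `volume` with fields `data`, `affine`,
#'   `voxel_sizes` (mm per axis, the column norms of the affine).
#' @export
volume <- function(data, affine = diag(4), allow_na = FALSE) {
  affine <- as_affine(affine)
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3-D array")
  if (!allow_na && !all(is.finite(data)))
    stop("volume data must be finite")
  if (allow_na && any(is.infinite(data)))
    stop("volume data must not contain infinities")
  vs <- voxel_sizes(affine)
  if (any(vs <= 0)) stop("voxel sizes must be strictly positive")
  structure(list(data = data, affine = affine, voxel_sizes = vs),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s, voxels %.3g x %.3g x %.3g mm\n",
              paste(dim(x$data), collapse = " x "),
              x$voxel_sizes[1], x$voxel_sizes[2], x$voxel_sizes[3]))
  invisible(x)
}

#' Binary bundle mask
#'
#' The common currency of all overlap comparisons: a binary voxel set on an
#' explicit grid. Standardized masks live on a 1 mm isotropic grid (see
#' [standardize_mask()]).
#'
#' @param mask 3-D array coercible to logical.
#' @param affine 4x4 voxel-to-world matrix.
#' @param empty_flagged logical; set when a thresholding operation produced
#'   an empty mask (routed to QC rather than silently dropped).
#' @return An object of class `bundle_mask`.
#' @export
bundle_mask <- function(mask, affine = diag(4), empty_flagged = FALSE) {
  affine <- as_affine(affine)
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask values must be 0/1, no NA")
  structure(list(mask = mask, affine = affine,
                 voxel_sizes = voxel_sizes(affine),
                 empty = !any(mask) , empty_flagged = empty_flagged),
            class = "bundle_mask")
}

#' @export
print.bundle_mask <- function(x, ...) {
  cat(sprintf("<bundle_mask> %s grid, %d voxels set (%.0f mm^3)%s\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask),
              mask_volume(x), if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Volume of a bundle mask in mm^3
#' @param m a `bundle_mask`
#' @return numeric scalar, voxel count times voxel volume.
#' @export
mask_volume <- function(m) {
  stopifnot(inherits(m, "bundle_mask"))
  sum(m$mask) * prod(m$voxel_sizes)
}

# ---- affine helpers ---------------------------------------------------------

as_affine <- function(a) {
  a <- as.matrix(a)
  storage.mode(a) <- "double"
  if (!all(dim(a) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(a[1:3, 1:3])) < .Machine$double.eps * 64)
    stop("affine must be invertible")
  dimnames(a) <- NULL
  a
}

voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# world (n x 3, mm) -> continuous voxel coordinates (0-based)
world_to_voxel <- function(pts, affine) {
  pts <- rbind(t(pts), 1)
  v <- solve(affine) %*% pts
  t(v[1:3, , drop = FALSE])
}

# continuous voxel coordinates (0-based) -> world mm
voxel_to_world <- function(vox, affine) {
  v <- rbind(t(vox), 1)
  t((affine %*% v)[1:3, , drop = FALSE])
}

# Voxel ownership: round with ties broken toward the LOWER index, so
# v = k + 0.5 belongs to voxel k. ceiling(v - 0.5) implements exactly that.
round_half_down <- function(v) ceiling(v - 0.5)

# logical vector: which 0-based integer voxel triples are inside `shape`
in_grid <- function(idx, shape) {
  idx[, 1] >= 0 & idx[, 1] < shape[1] &
  idx[, 2] >= 0 & idx[, 2] < shape[2] &
  idx[, 3] >= 0 & idx[, 3] < shape[3]
}

affines_equal <- function(a, b, tol = 1e-4) {
  max(abs(a - b)) <= tol
}

# grid spec for a 1 mm isotropic grid covering the field of view of `affine`
# + `shape`; corner-aligned with the source grid.
grid_1mm <- function(affine, shape) {
  corners <- as.matrix(expand.grid(c(-0.5, shape[1] - 0.5),
                                   c(-0.5, shape[2] - 0.5),
                                   c(-0.5, shape[3] - 0.5)))
  w <- voxel_to_world(corners, affine)
  lo <- apply(w, 2, min)
  hi <- apply(w, 2, max)
  new_shape <- as.integer(ceiling(hi - lo))
  new_affine <- diag(4)
  new_affine[1:3, 4] <- lo + 0.5   # voxel (0,0,0) centre half a voxel in
  list(affine = new_affine, shape = new_shape)
}

# arc length of one streamline polyline
polyline_length <- function(s) {
  if (nrow(s) < 2L) return(0)
  sum(sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
}

# resample a polyline at (approximately) equal arc-length spacing `step`,
# keeping the original vertices so no corner is skipped
densify_polyline <- function(s, step) {
  d <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  cum <- c(0, cumsum(d))
  total <- cum[length(cum)]
  if (total == 0) return(s[1, , drop = FALSE])
  t_new <- sort(unique(c(seq(0, total, by = step), cum)))
  cbind(stats::approx(cum, s[, 1], xout = t_new, ties = "ordered")$y,
        stats::approx(cum, s[, 2], xout = t_new, ties = "ordered")$y,
        stats::approx(cum, s[, 3], xout = t_new, ties = "ordered")$y)
}

# resample a polyline to exactly n points at equal arc-length spacing
resample_polyline_n <- function(s, n) {
  d <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  cum <- c(0, cumsum(d))
  t_new <- seq(0, cum[length(cum)], length.out = n)
  cbind(stats::approx(cum, s[, 1], xout = t_new, ties = "ordered")$y,
        stats::approx(cum, s[, 2], xout = t_new, ties = "ordered")$y,
        stats::approx(cum, s[, 3], xout = t_new, ties = "ordered")$y)
}

# run code under a temporary RNG state derived from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
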