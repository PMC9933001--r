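#' Orient all streamlines of a bundle the same way
#'
#' Streamlines come off tractography with arbitrary point order; end-region
#' and trunk analysis needs them all running nominally from one end of the
#' bundle to the other. Endpoints are split into two side groups by the sign
#' of their projection onto the principal axis of all endpoints (deterministic,
#' no iterative clustering), and each streamline is flipped so its first point
#' is the endpoint closer to the side-A centroid.
#'
#' @param t a [tractogram()] with at least one streamline.
#' @return The oriented tractogram, with attribute `degenerate = TRUE` if all
#'   endpoints coincide (no axis to orient along).
#' @export
orient_streamlines <- function(t) {
  stopifnot(inherits(t, "tractogram"), t$n_streamlines >= 1L)
  starts <- t(vapply(t$streamlines, function(s) s[1, ], numeric(3)))
  ends <- t(vapply(t$streamlines, function(s) s[nrow(s), ], numeric(3)))
  ep <- rbind(starts, ends)
  ctr <- colMeans(ep)
  centered <- sweep(ep, 2, ctr)
  if (max(abs(centered)) < 1e-9) {
    attr(t, "degenerate") <- TRUE
    return(t)
  }
  axis <- svd(centered, nu = 0, nv = 1)$v[, 1]
  proj <- centered %*% axis
  side_a <- proj < 0
  if (!any(side_a) || all(side_a)) {
    # all endpoints on one side of the centroid cannot happen for proj
    # centred data unless everything projects to ~0; fall back to median split
    side_a <- proj <= stats::median(proj)
  }
  centroid_a <- colMeans(ep[side_a, , drop = FALSE])
  flipped <- lapply(seq_len(t$n_streamlines), function(i) {
    s <- t$streamlines[[i]]
    d_start <- sum((s[1, ] - centroid_a)^2)
    d_end <- sum((s[nrow(s), ] - centroid_a)^2)
    if (d_end < d_start) s[nrow(s):1, , drop = FALSE] else s
  })
  out <- tractogram(flipped, t$affine, t$shape)
  attr(out, "oriented") <- TRUE
  out
}

#' Bundle length features: mean length, span, curl
#'
#' Mean length is the average streamline arc length; span is the Euclidean
#' distance between the centroid of start points and the centroid of end
#' points (robust to single outlier streamlines); curl is their ratio — 1 for
#' a perfectly straight bundle, pi/2 for a semicircle.
#'
#' @param t an oriented [tractogram()] (see [orient_streamlines()]).
#' @return one-row tibble: `mean_length`, `span`, `curl` (all mm except
#'   unitless curl; curl is `NA` when span is zero).
#' @export
length_features <- function(t) {
  stopifnot(inherits(t, "tractogram"), t$n_streamlines >= 1L)
  lens <- vapply(t$streamlines, polyline_length, numeric(1))
  starts <- t(vapply(t$streamlines, function(s) s[1, ], numeric(3)))
  ends <- t(vapply(t$streamlines, function(s) s[nrow(s), ], numeric(3)))
  span <- sqrt(sum((colMeans(starts) - colMeans(ends))^2))
  tibble::tibble(mean_length = mean(lens), span = span,
                 curl = if (span > 0) mean(lens) / span else NA_real_)
}

#' Bundle volume, surface area and derived shape ratios
#'
#' Volume is the voxel count of the standardized mask times the voxel volume.
#' Surface area counts exposed voxel faces under 6-connectivity (exact on
#' voxel sets). The remaining features model the bundle as an equivalent
#' cylinder of the same volume and length: diameter
#' `2*sqrt(volume/(pi*mean_length))`, elongation `mean_length/diameter`, and
#' irregularity `surface_area/(pi*diameter*mean_length)` (1 for a perfect
#' cylinder, larger for rougher or branching bundles).
#'
#' @param m a standardized 1 mm [bundle_mask()].
#' @param mean_length bundle mean streamline length in mm, from
#'   [length_features()].
#' @return one-row tibble: `volume` (mm^3), `surface_area` (mm^2),
#'   `diameter` (mm), `elongation`, `irregularity`. All `NA` for an empty
#'   mask.
#' @export
volume_area_features <- function(m, mean_length) {
  stopifnot(inherits(m, "bundle_mask"))
  if (!any(m$mask))
    return(tibble::tibble(volume = NA_real_, surface_area = NA_real_,
                          diameter = NA_real_, elongation = NA_real_,
                          irregularity = NA_real_))
  vs <- m$voxel_sizes
  vol <- sum(m$mask) * prod(vs)
  sa <- surface_area_6conn(m$mask, vs)
  diam <- 2 * sqrt(vol / (pi * mean_length))
  tibble::tibble(volume = vol, surface_area = sa, diameter = diam,
                 elongation = mean_length / diam,
                 irregularity = sa / (pi * diam * mean_length))
}

# exposed-face counting under 6-connectivity; exact on voxel sets
surface_area_6conn <- function(mask, vs = c(1, 1, 1)) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  face_areas <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])
  total <- 0
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (sh in shifts) {
    nb <- pad[2:(d[1] + 1L) + sh[1], 2:(d[2] + 1L) + sh[2],
              2:(d[3] + 1L) + sh[3]]
    axis <- which(sh != 0)
    total <- total + sum(mask & !nb) * face_areas[axis]
  }
  total
}

#' End-region area and radius
#'
#' The end region of each side is the set of standardized-mask-grid voxels
#' containing at least one streamline endpoint of that side. `end_area` is
#' the total area of both regions (voxel count times voxel face area);
#' `end_radius` is the average over the two sides of the disc-equivalent
#' radius `sqrt(area/pi)`.
#'
#' @param t an oriented [tractogram()].
#' @param m the bundle's standardized [bundle_mask()] (supplies the grid).
#' @return one-row tibble: `end_area` (mm^2), `end_radius` (mm). A side with
#'   no endpoint inside the grid yields `NA`s.
#' @export
end_region_features <- function(t, m) {
  stopifnot(inherits(t, "tractogram"), inherits(m, "bundle_mask"))
  shp <- dim(m$mask)
  vs <- m$voxel_sizes
  face <- vs[1] * vs[2]  # isotropic standardized grid: 1 mm^2
  count_side <- function(pts) {
    idx <- round_half_down(world_to_voxel(pts, m$affine))
    idx <- idx[in_grid(idx, shp), , drop = FALSE]
    if (nrow(idx) == 0L) return(NA_integer_)
    nrow(unique(idx))
  }
  starts <- t(vapply(t$streamlines, function(s) s[1, ], numeric(3)))
  ends <- t(vapply(t$streamlines, function(s) s[nrow(s), ], numeric(3)))
  na <- count_side(starts); nb <- count_side(ends)
  if (is.na(na) || is.na(nb))
    return(tibble::tibble(end_area = NA_real_, end_radius = NA_real_))
  area_a <- na * face; area_b <- nb * face
  tibble::tibble(end_area = area_a + area_b,
                 end_radius = mean(c(sqrt(area_a / pi), sqrt(area_b / pi))))
}

#' Trunk and branch volume
#'
#' The trunk is the part of the bundle traced by "core" streamlines: those
#' whose both endpoints fall in the main endpoint cluster of their side
#' (largest single-linkage cluster at `linkage_mm` merge distance).
#' `trunk_volume` is the volume of the density-1 mask of the core streamlines
#' (restricted to the bundle mask); `branch_volume` is the remainder, so the
#' two always sum to `volume` exactly.
#'
#' @param t an oriented [tractogram()].
#' @param m the bundle's standardized [bundle_mask()].
#' @param linkage_mm single-linkage merge distance defining the main endpoint
#'   clusters (mm).
#' @return one-row tibble: `trunk_volume`, `branch_volume` (mm^3),
#'   `n_core` (core streamline count). `trunk_volume` 0 with `n_core` 0 if no
#'   streamline qualifies.
#' @export
trunk_branch <- function(t, m, linkage_mm = 10) {
  stopifnot(inherits(t, "tractogram"), inherits(m, "bundle_mask"))
  vol <- mask_volume(m)
  starts <- t(vapply(t$streamlines, function(s) s[1, ], numeric(3)))
  ends <- t(vapply(t$streamlines, function(s) s[nrow(s), ], numeric(3)))
  main_cluster <- function(pts) {
    cl <- single_linkage_components(pts, linkage_mm)
    cl == which.max(tabulate(cl))
  }
  core <- main_cluster(starts) & main_cluster(ends)
  if (!any(core)) {
    return(tibble::tibble(trunk_volume = 0, branch_volume = vol, n_core = 0L))
  }
  core_t <- tractogram(t$streamlines[core], t$affine, t$shape)
  dens <- streamlines_to_density(core_t, m$affine, dim(m$mask))
  trunk_mask <- (dens$counts >= 1) & m$mask
  trunk <- sum(trunk_mask) * prod(m$voxel_sizes)
  tibble::tibble(trunk_volume = trunk, branch_volume = vol - trunk,
                 n_core = sum(core))
}

#' All twelve bundle shape descriptors
#'
#' Convenience wrapper computing the full descriptor set from a tractogram
#' and its standardized 1 mm mask: mean length, span, diameter, end radius
#' (length features, mm); surface area, end area (mm^2); volume, trunk
#' volume, branch volume (mm^3); curl, elongation, irregularity (unitless).
#'
#' @param t a [tractogram()] (oriented internally).
#' @param m the bundle's standardized [bundle_mask()].
#' @param linkage_mm trunk endpoint clustering distance, see [trunk_branch()].
#' @return one-row tibble with the 12 feature columns in the order above.
#' @export
shape_features <- function(t, m, linkage_mm = 10) {
  t <- orient_streamlines(t)
  lf <- length_features(t)
  va <- volume_area_features(m, lf$mean_length)
  er <- end_region_features(t, m)
  tb <- trunk_branch(t, m, linkage_mm)
  tibble::tibble(
    mean_length = lf$mean_length, span = lf$span, diameter = va$diameter,
    end_radius = er$end_radius, surface_area = va$surface_area,
    end_area = er$end_area, volume = va$volume,
    trunk_volume = tb$trunk_volume, branch_volume = tb$branch_volume,
    curl = lf$curl, elongation = va$elongation,
    irregularity = va$irregularity)
}

#' Names of the twelve shape descriptors
#' @export
SHAPE_FEATURES <- c("mean_length", "span", "diameter", "end_radius",
                    "surface_area", "end_area", "volume", "trunk_volume",
                    "branch_volume", "curl", "elongation", "irregularity")

# single-linkage clusters cut at distance h, computed as the connected
# components of the h-neighbourhood graph (identical grouping, but without
# materializing the full O(n^2) distance matrix that hclust needs)
single_linkage_components <- function(pts, h) {
  n <- nrow(pts)
  comp <- integer(n)
  h2 <- h^2
  cur <- 0L
  sq <- rowSums(pts^2)
  while (any(comp == 0L)) {
    cur <- cur + 1L
    frontier <- which(comp == 0L)[1]
    comp[frontier] <- cur
    while (length(frontier)) {
      cand <- which(comp == 0L)
      if (!length(cand)) break
      hit <- logical(length(cand))
      for (chunk in split(frontier, ceiling(seq_along(frontier) / 512))) {
        d2 <- outer(sq[cand], sq[chunk], "+") -
          2 * pts[cand, , drop = FALSE] %*% t(pts[chunk, , drop = FALSE])
        hit <- hit | (matrixStats_rowMins(d2) <= h2 + 1e-12)
      }
      frontier <- cand[hit]
      comp[frontier] <- cur
    }
  }
  comp
}

matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))
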