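#' Dice overlap between two bundle masks
#'
#' Set-theoretic Dice coefficient 2|A n B| / (|A| + |B|) on binary voxel
#' sets, together with the volumes involved. Both masks must live on the
#' same grid (shape and affine within 1e-4). When both masks are empty the
#' coefficient is undefined and returned as `NA` with `both_empty = TRUE`
#' (such pairs belong in QC, not in the Dice distribution).
#'
#' @param a,b [bundle_mask()] objects on a common 1 mm grid.
#' @return A one-row tibble: `dice`, `vol_a`, `vol_b`, `intersection`
#'   (all volumes in mm^3), `both_empty`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "bundle_mask"), inherits(b, "bundle_mask"))
  if (!identical(dim(a$mask), dim(b$mask)))
    stop("mask grids differ in shape: ", paste(dim(a$mask), collapse = "x"),
         " vs ", paste(dim(b$mask), collapse = "x"))
  if (!affines_equal(a$affine, b$affine))
    stop("mask grids differ in affine (beyond 1e-4); masks are not aligned")
  vv <- prod(a$voxel_sizes)
  na <- sum(a$mask); nb <- sum(b$mask)
  ni <- sum(a$mask & b$mask)
  d <- if (na + nb == 0L) NA_real_ else 2 * ni / (na + nb)
  tibble::tibble(dice = d, vol_a = na * vv, vol_b = nb * vv,
                 intersection = ni * vv, both_empty = na + nb == 0L)
}

#' Voxelwise agreement and disagreement maps
#'
#' For a set of mask pairs (one pair per subject, all on a shared grid),
#' computes for every voxel the fraction of pairs in which both masks
#' contain it (agreement: the pathway is consistently located there) and the
#' fraction in which exactly one does (disagreement: variability). The
#' denominator is the number of pairs, so
#' `agree_frac + disagree_frac + neither_frac = 1` voxelwise.
#'
#' @param pairs list of two-element lists/pairs of [bundle_mask()] objects.
#' @return An object of class `agreement_map`: `agree_frac` and
#'   `disagree_frac` (3-D arrays in `[0,1]`), `n_pairs`, `affine`.
#' @export
agreement_map <- function(pairs) {
  if (length(pairs) == 0L) stop("empty pair list")
  ref <- pairs[[1]][[1]]
  shp <- dim(ref$mask)
  agree <- array(0, shp); disagree <- array(0, shp)
  for (p in pairs) {
    a <- p[[1]]; b <- p[[2]]
    stopifnot(inherits(a, "bundle_mask"), inherits(b, "bundle_mask"))
    if (!identical(dim(a$mask), shp) || !identical(dim(b$mask), shp) ||
        !affines_equal(a$affine, ref$affine) ||
        !affines_equal(b$affine, ref$affine))
      stop("all masks must share one common grid")
    agree <- agree + (a$mask & b$mask)
    disagree <- disagree + xor(a$mask, b$mask)
  }
  structure(list(agree_frac = agree / length(pairs),
                 disagree_frac = disagree / length(pairs),
                 n_pairs = length(pairs), affine = ref$affine),
            class = "agreement_map")
}

#' @export
print.agreement_map <- function(x, ...) {
  cat(sprintf("<agreement_map> %s grid, %d pairs, max agreement %.2f\n",
              paste(dim(x$agree_frac), collapse = " x "), x$n_pairs,
              max(x$agree_frac)))
  invisible(x)
}

#' Tidy an agreement map into a long voxel table
#'
#' @param x an `agreement_map`.
#' @param drop_empty drop voxels where no pair ever placed the pathway.
#' @param ... unused.
#' @return tibble with voxel indices (`i`, `j`, `k`, 1-based), `agree_frac`,
#'   `disagree_frac`.
#' @export
#' @method tidy agreement_map
tidy.agreement_map <- function(x, drop_empty = TRUE, ...) {
  keep <- if (drop_empty) which(x$agree_frac > 0 | x$disagree_frac > 0)
          else seq_along(x$agree_frac)
  idx <- arrayInd(keep, dim(x$agree_frac))
  tibble::tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                 agree_frac = x$agree_frac[keep],
                 disagree_frac = x$disagree_frac[keep])
}

#' Plot an axial slice of an agreement map
#'
#' Agreement (both masks contain the voxel) is shown in a warm palette,
#' disagreement (exactly one does) in a cool one, mirroring the standard
#' hot/cold localization display.
#'
#' @param object an `agreement_map`.
#' @param slice axial (k) slice index; defaults to the slice with the most
#'   agreement mass.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @method autoplot agreement_map
autoplot.agreement_map <- function(object, slice = NULL, ...) {
  if (is.null(slice)) {
    mass <- apply(object$agree_frac, 3, sum)
    slice <- which.max(mass)
  }
  df <- tidy.agreement_map(object, drop_empty = TRUE)
  df <- df[df$k == slice, , drop = FALSE]
  long <- tidyr::pivot_longer(df, c("agree_frac", "disagree_frac"),
                              names_to = "kind", values_to = "fraction")
  long$kind <- factor(long$kind, c("agree_frac", "disagree_frac"),
                      c("agreement", "disagreement"))
  ggplot2::ggplot(long, ggplot2::aes(.data$i, .data$j, fill = .data$fraction)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~kind) +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "i (voxel)", y = "j (voxel)",
                  title = sprintf("Axial slice k = %d (%d pairs)",
                                  slice, object$n_pairs))
}
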