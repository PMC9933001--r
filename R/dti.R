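#' Fit the diffusion tensor by iteratively reweighted linear least squares
#'
#' Per voxel, solves the log-linearized single-tensor model
#' `log S_i = log S0 - b_i g_i' D g_i` with design rows
#' `(1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz)`.
#' The first pass is ordinary (unweighted) log-linear least squares; each of
#' the `n_iter` reweighting passes then refits with weights equal to the
#' squared model-predicted signals, which undoes the heteroscedasticity the
#' log transform introduces. With `n_iter = 0` the fit reduces exactly to
#' ordinary log-linear LS. Non-positive signals are excluded per voxel; a
#' voxel with fewer than 7 usable volumes is flagged and left `NA`.
#'
#' @param dwi 4-D numeric array (x, y, z, volume) of diffusion-weighted
#'   signals, or a list with `data` and `affine` as from [read_volume4d()].
#' @param scheme a [dwi_scheme()] matching the 4th dimension.
#' @param mask optional [bundle_mask()] or logical array selecting voxels to
#'   fit (default: voxels whose mean b0 signal is positive).
#' @param n_iter number of reweighting passes (default 2).
#' @return An object of class `tensor_fit`: arrays `fa`, `md` (mm^2/s), `s0`,
#'   6-component `tensor` (x,y,z,6: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `affine`,
#'   and `n_failed` voxels with too few usable volumes.
#' @export
fit_tensor_irwlls <- function(dwi, scheme, mask = NULL, n_iter = 2) {
  affine <- diag(4)
  if (is.list(dwi) && !is.null(dwi$data)) {
    affine <- dwi$affine
    dwi <- dwi$data
  }
  stopifnot(length(dim(dwi)) == 4L, inherits(scheme, "dwi_scheme"))
  if (dim(dwi)[4] != scheme$n_volumes)
    stop("DWI volume count (", dim(dwi)[4], ") does not match scheme (",
         scheme$n_volumes, ")")
  shp <- dim(dwi)[1:3]
  X <- design_matrix(scheme)
  if (is.null(mask)) {
    b0 <- scheme$bvals <= scheme$b0_threshold
    mean_b0 <- apply(dwi[, , , b0, drop = FALSE], 1:3, mean)
    mask_arr <- mean_b0 > 0
  } else {
    mask_arr <- if (inherits(mask, "bundle_mask")) mask$mask else as.array(mask)
  }
  vox <- which(mask_arr)
  n_total <- prod(shp)
  nv <- scheme$n_volumes
  sig_mat <- matrix(dwi, nrow = n_total, ncol = nv)[vox, , drop = FALSE]

  theta <- matrix(NA_real_, length(vox), 7)
  n_failed <- 0L
  clean <- rowSums(!is.finite(sig_mat) | sig_mat <= 0) == 0L
  if (any(clean))  # batch path: shared design, vectorized across voxels
    theta[clean, ] <- t(irwlls_batch(X, t(log(sig_mat[clean, , drop = FALSE])),
                                     n_iter))
  for (r in which(!clean)) {        # voxels with excluded signals: fit alone
    s <- sig_mat[r, ]
    use <- is.finite(s) & s > 0
    if (sum(use) < 7L) { n_failed <- n_failed + 1L; next }
    Xu <- X[use, , drop = FALSE]
    y <- log(s[use])
    th <- tryCatch(qr.solve(Xu, y), error = function(e) NULL)
    if (is.null(th)) { n_failed <- n_failed + 1L; next }
    if (n_iter > 0) for (it in seq_len(n_iter)) {
      w <- exp(Xu %*% th)^2          # squared predicted signals
      XtW <- t(Xu * as.numeric(w))
      th2 <- tryCatch(solve(XtW %*% Xu, XtW %*% y), error = function(e) NULL)
      if (is.null(th2)) break
      th <- as.numeric(th2)
    }
    theta[r, ] <- th
  }
  n_failed <- n_failed + sum(!is.finite(theta[, 1]) & clean)
  ok <- !is.na(theta[, 1])
  fa <- array(NA_real_, shp); md <- array(NA_real_, shp)
  s0 <- array(NA_real_, shp)
  tensor <- array(NA_real_, c(shp, 6L))
  s0[vox[ok]] <- exp(theta[ok, 1])
  tensor_flat <- matrix(tensor, n_total, 6)
  tensor_flat[vox[ok], ] <- theta[ok, 2:7, drop = FALSE]
  tensor <- array(tensor_flat, c(shp, 6L))
  famd <- fa_md_from_tensor(theta[ok, 2:7, drop = FALSE])
  fa[vox[ok]] <- famd$fa
  md[vox[ok]] <- famd$md
  structure(list(fa = fa, md = md, s0 = s0, tensor = tensor, affine = affine,
                 n_failed = n_failed, n_iter = n_iter),
            class = "tensor_fit")
}

# vectorized IRWLLS over voxels sharing one design matrix.
# Y: n_volumes x N matrix of log signals. Returns 7 x N coefficients.
irwlls_batch <- function(X, Y, n_iter) {
  XtX <- crossprod(X)
  theta <- solve(XtX, crossprod(X, Y))          # ordinary log-linear LS
  if (n_iter > 0) {
    # rows of P are vec(x_i x_i'), so t(P) %*% W gives per-voxel normal
    # matrices in one multiply
    P <- t(apply(X, 1, tcrossprod))
    for (it in seq_len(n_iter)) {
      W <- exp(X %*% theta)^2
      M <- crossprod(P, W)                      # 49 x N
      R <- crossprod(X, W * Y)                  # 7 x N
      for (j in seq_len(ncol(Y))) {
        th <- tryCatch(solve(matrix(M[, j], 7, 7), R[, j]),
                       error = function(e) rep(NA_real_, 7))
        theta[, j] <- th
      }
    }
  }
  theta
}

# design matrix rows (1, -b gx^2, -b gy^2, -b gz^2, -2b gxgy, -2b gxgz, -2b gygz)
design_matrix <- function(scheme) {
  b <- scheme$bvals
  g <- scheme$bvecs
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

# FA/MD from rows of 6-component tensors (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz);
# negative eigenvalues are clamped to 0 first, which bounds FA in [0,1]
fa_md_from_tensor <- function(d6) {
  n <- nrow(d6)
  fa <- numeric(n); md <- numeric(n)
  for (i in seq_len(n)) {
    D <- matrix(c(d6[i, 1], d6[i, 4], d6[i, 5],
                  d6[i, 4], d6[i, 2], d6[i, 6],
                  d6[i, 5], d6[i, 6], d6[i, 3]), 3, 3)
    ev <- pmax(eigen(D, symmetric = TRUE, only.values = TRUE)$values, 0)
    mv <- mean(ev)
    md[i] <- mv
    ss <- sum(ev^2)
    fa[i] <- if (ss > 0) sqrt(1.5 * sum((ev - mv)^2) / ss) else 0
  }
  list(fa = fa, md = md)
}

#' @export
print.tensor_fit <- function(x, ...) {
  ok <- is.finite(x$fa)
  cat(sprintf(
    "<tensor_fit> %s grid, %d voxels fit (IRWLLS, %d reweighting passes)\n",
    paste(dim(x$fa), collapse = " x "), sum(ok), x$n_iter))
  if (any(ok))
    cat(sprintf("  FA %.3f +/- %.3f, MD %.3g +/- %.2g mm^2/s\n",
                mean(x$fa[ok]), stats::sd(x$fa[ok]),
                mean(x$md[ok]), stats::sd(x$md[ok])))
  invisible(x)
}

#' Summarise a tensor fit
#' @param x a `tensor_fit`.
#' @param ... unused.
#' @return one-row tibble: voxel counts and FA/MD means/SDs.
#' @export
#' @method glance tensor_fit
glance.tensor_fit <- function(x, ...) {
  ok <- is.finite(x$fa)
  tibble::tibble(n_voxels = sum(ok), n_failed = x$n_failed,
                 mean_fa = mean(x$fa[ok]), sd_fa = stats::sd(x$fa[ok]),
                 mean_md = mean(x$md[ok]), sd_md = stats::sd(x$md[ok]))
}

#' Mean of a scalar map inside a bundle mask
#'
#' The simple in-bundle average used for per-bundle FA/MD summaries
#' (unweighted; density or certainty weighting is deliberately not applied).
#'
#' @param metric a [volume()] or 3-D array (FA or MD map).
#' @param roi a [bundle_mask()] on the same grid.
#' @return one-row tibble: `mean`, `n_voxels`. `mean` is `NA` (flagged via
#'   `empty_roi`) for an empty ROI.
#' @export
extract_in_bundle <- function(metric, roi) {
  data <- if (inherits(metric, "volume")) metric$data else as.array(metric)
  stopifnot(inherits(roi, "bundle_mask"))
  if (!identical(dim(data), dim(roi$mask)))
    stop("metric and ROI grids differ")
  vals <- data[roi$mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L)
    return(tibble::tibble(mean = NA_real_, n_voxels = 0L, empty_roi = TRUE))
  tibble::tibble(mean = mean(vals), n_voxels = length(vals),
                 empty_roi = FALSE)
}

#' Isolate tractography-added variance in microstructure measures
#'
#' For each confound contrast, in-bundle means are extracted twice: with the
#' subject's single reference-dataset ROI applied to both metric maps
#' (fixed ROI — variation from the acquisition confound only) and with each
#' dataset's own tractography-derived ROI (native ROI — confound variation
#' plus tractography variation). The gap `mape_native - mape_fixed` is the
#' variance tractography adds.
#'
#' @param extractions tibble with one row per (subject, pathway, confound,
#'   metric) and columns `fixed_a`, `fixed_b`, `native_a`, `native_b` holding
#'   the four in-bundle means.
#' @return the input tibble with `mape_fixed_roi`, `mape_native_roi`, and
#'   `added_variance` (= native - fixed) columns appended.
#' @export
variance_decomposition <- function(extractions) {
  required <- c("fixed_a", "fixed_b", "native_a", "native_b")
  missing <- setdiff(required, names(extractions))
  if (length(missing))
    stop("extractions lacks columns: ", paste(missing, collapse = ", "))
  dplyr::mutate(extractions,
    mape_fixed_roi = mape(.data$fixed_a, .data$fixed_b),
    mape_native_roi = mape(.data$native_a, .data$native_b),
    added_variance = .data$mape_native_roi - .data$mape_fixed_roi)
}
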