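fa_closed_form <- function(ev) {
  mv <- mean(ev)
  sqrt(1.5 * sum((ev - mv)^2) / sum(ev^2))
}

test_that("noise-free isotropic signals give FA 0 and exact MD", {
  sc <- make_scheme(30, 1000, 1)
  tf <- array(rep(c(1e-3, 1e-3, 1e-3, 0, 0, 0), each = 8), c(2, 2, 2, 6))
  dwi <- simulate_dwi(tf, sc, s0 = 100, snr = Inf)
  fit <- fit_tensor_irwlls(dwi, sc)
  expect_equal(max(abs(fit$fa)), 0, tolerance = 1e-9)
  expect_equal(fit$md[1, 1, 1], 1e-3, tolerance = 1e-9)
})

test_that("noise-free anisotropic tensors are recovered to 1e-9 relative", {
  sc <- make_scheme(30, 1000, 1)
  D <- c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  tf <- array(rep(D, each = 1), c(1, 1, 1, 6))
  dwi <- simulate_dwi(tf, sc, s0 = 100, snr = Inf)
  fit <- fit_tensor_irwlls(dwi, sc)
  expect_equal(as.numeric(fit$tensor[1, 1, 1, ]), D, tolerance = 1e-9)
  expect_equal(fit$md[1, 1, 1], mean(c(1.7, 0.3, 0.3)) * 1e-3,
               tolerance = 1e-9)
  expect_equal(fit$fa[1, 1, 1], fa_closed_form(c(1.7, 0.3, 0.3) * 1e-3),
               tolerance = 1e-6)
  expect_equal(fit$s0[1, 1, 1], 100, tolerance = 1e-6)

  # off-diagonal tensor (rotated frame) also recovered
  R <- qr.Q(qr(matrix(c(1, 2, 0, 0, 1, 1, 1, 0, 1), 3, 3)))
  Dm <- R %*% diag(c(1.7, 0.3, 0.3) * 1e-3) %*% t(R)
  D2 <- c(Dm[1, 1], Dm[2, 2], Dm[3, 3], Dm[1, 2], Dm[1, 3], Dm[2, 3])
  tf2 <- array(rep(D2, each = 1), c(1, 1, 1, 6))
  fit2 <- fit_tensor_irwlls(simulate_dwi(tf2, sc, 100, Inf), sc)
  expect_equal(as.numeric(fit2$tensor[1, 1, 1, ]), D2, tolerance = 1e-9)
})

test_that("zero reweighting passes reduce to ordinary log-linear least squares", {
  withr::local_seed(12)
  sc <- make_scheme(20, 1000, 2)
  D <- c(1.2e-3, 0.5e-3, 0.4e-3, 1e-4, -5e-5, 2e-5)
  tf <- array(rep(D, each = 10), c(10, 1, 1, 6))
  dwi <- simulate_dwi(tf, sc, s0 = 100, snr = 25, seed = 3)
  fit0 <- fit_tensor_irwlls(dwi, sc, n_iter = 0)
  # independent ordinary LS via qr on the log signals
  b <- sc$bvals; g <- sc$bvecs
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  for (i in 1:10) {
    th <- qr.solve(X, log(dwi[i, 1, 1, ]))
    expect_equal(as.numeric(fit0$tensor[i, 1, 1, ]), as.numeric(th[2:7]),
                 tolerance = 1e-9)
  }
  # reweighting changes the noisy fit (sanity that n_iter is not a no-op)
  fit2 <- fit_tensor_irwlls(dwi, sc, n_iter = 2)
  expect_false(isTRUE(all.equal(fit0$tensor, fit2$tensor, tolerance = 1e-12)))
})

test_that("FA is recovered within tolerance under Rician noise at SNR 30", {
  sc <- make_scheme(30, 1000, 1)
  # high and moderate anisotropy; bias magnitude < 0.05 at SNR 30
  for (ev in list(c(1.7, 0.3, 0.3) * 1e-3, c(1.05, 0.63, 0.62) * 1e-3)) {
    tf <- array(rep(c(ev, 0, 0, 0), each = 200), c(200, 1, 1, 6))
    dwi <- simulate_dwi(tf, sc, s0 = 100, snr = 30, seed = 1)
    fit <- fit_tensor_irwlls(dwi, sc)
    expect_lt(abs(mean(fit$fa) - fa_closed_form(ev)), 0.03)
    expect_lt(abs(mean(fit$fa) - fa_closed_form(ev)), 0.05)
  }
})

test_that("FA is invariant to rotating both tensor and gradient set", {
  sc <- make_scheme(30, 1000, 1)
  ev <- c(1.7, 0.3, 0.3) * 1e-3
  tf <- array(rep(c(ev, 0, 0, 0), each = 1), c(1, 1, 1, 6))
  fit <- fit_tensor_irwlls(simulate_dwi(tf, sc, 100, Inf), sc)
  R <- qr.Q(qr(matrix(c(2, 1, 1, 0, 1, 3, 1, 0, 1), 3, 3)))
  sc_rot <- dwi_scheme(sc$bvals, sc$bvecs %*% t(R))
  Dm <- R %*% diag(ev) %*% t(R)
  tf_rot <- array(rep(c(diag(Dm), Dm[1, 2], Dm[1, 3], Dm[2, 3]), each = 1),
                  c(1, 1, 1, 6))
  fit_rot <- fit_tensor_irwlls(simulate_dwi(tf_rot, sc_rot, 100, Inf), sc_rot)
  expect_equal(fit_rot$fa[1, 1, 1], fit$fa[1, 1, 1], tolerance = 1e-6)
})

test_that("voxels with too few usable volumes are flagged, not fit", {
  sc <- make_scheme(10, 1000, 1)
  tf <- array(rep(c(1e-3, 1e-3, 1e-3, 0, 0, 0), each = 2), c(2, 1, 1, 6))
  dwi <- simulate_dwi(tf, sc, s0 = 100, snr = Inf)
  dwi[2, 1, 1, 2:7] <- -1            # 5 usable volumes left in voxel 2
  fit <- fit_tensor_irwlls(dwi, sc)
  expect_true(is.finite(fit$fa[1, 1, 1]))
  expect_true(is.na(fit$fa[2, 1, 1]))
  expect_equal(fit$n_failed, 1L)
})

test_that("in-bundle extraction averages exactly over ROI voxels", {
  roi <- random_mask(c(6, 6, 6), 0.4)
  const <- array(0.5, c(6, 6, 6))
  expect_equal(extract_in_bundle(const, roi)$mean, 0.5)

  half <- array(0, c(6, 6, 6))
  idx <- which(roi$mask)
  half[idx[seq_len(floor(length(idx) / 2))]] <- 1
  if (length(idx) %% 2 == 0)
    expect_equal(extract_in_bundle(half, roi)$mean, 0.5)

  withr::local_seed(8)
  vals <- array(rnorm(216), c(6, 6, 6))
  r <- extract_in_bundle(vals, roi)
  expect_equal(r$mean, sum(vals[roi$mask]) / sum(roi$mask))
  expect_equal(r$n_voxels, sum(roi$mask))

  e <- bundle_mask(array(FALSE, c(6, 6, 6)), diag(4))
  expect_true(extract_in_bundle(vals, e)$empty_roi)
})

test_that("variance decomposition separates confound and tractography variance", {
  tb <- tibble::tibble(
    subject = "s1", pathway = "p", confound = c("A", "B"), metric = "fa",
    fixed_a = c(0.5, 0.5), fixed_b = c(0.5, 0.55),
    native_a = c(0.52, 0.5), native_b = c(0.48, 0.55))
  v <- variance_decomposition(tb)
  expect_equal(v$mape_fixed_roi[1], 0)            # identical maps, fixed ROI
  expect_gte(v$mape_native_roi[1], 0)
  expect_equal(v$mape_fixed_roi[2], v$mape_native_roi[2])  # identical ROIs
  expect_equal(v$added_variance, v$mape_native_roi - v$mape_fixed_roi)
  expect_error(variance_decomposition(tb[, 1:5]), "lacks")
})
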