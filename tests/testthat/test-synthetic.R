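test_that("bundle generation is deterministic and honours zero dispersion", {
  spec <- bundle_spec("straight", length = 40, tube_sd = 0, n_streamlines = 10)
  b1 <- generate_bundle(spec, seed = 5)
  b2 <- generate_bundle(spec, seed = 5)
  expect_identical(b1$streamlines, b2$streamlines)
  # zero dispersion: all streamlines identical, curl exactly 1
  for (s in b1$streamlines) expect_identical(s, b1$streamlines[[1]])
  lf <- length_features(orient_streamlines(b1))
  expect_equal(lf$curl, 1, tolerance = 1e-9)

  b3 <- generate_bundle(spec, seed = 6)
  expect_false(identical(b1$streamlines, b3$streamlines) &&
                 spec$tube_sd > 0)   # different seed matters when dispersed
  spec_d <- bundle_spec("straight", length = 40, tube_sd = 2,
                        n_streamlines = 10)
  expect_false(identical(generate_bundle(spec_d, seed = 1)$streamlines,
                         generate_bundle(spec_d, seed = 2)$streamlines))
})

test_that("arc bundles have the closed-form arc length", {
  spec <- bundle_spec("arc", radius = 30, angle = 180, tube_sd = 0,
                      n_streamlines = 5, step = 0.5)
  b <- generate_bundle(spec, seed = 1)
  for (s in b$streamlines) {
    len <- sum(sqrt(rowSums(diff(s)^2)))
    expect_equal(len, pi * 30, tolerance = 0.01)
  }
})

test_that("identity perturbations leave the bundle untouched", {
  spec <- bundle_spec("arc", radius = 30, angle = 160, tube_sd = 2,
                      n_streamlines = 50)
  b <- generate_bundle(spec, seed = 2)
  d0 <- perturb_bundle(b, "dropout", 0, seed = 1)
  expect_identical(d0$streamlines, b$streamlines)
  a0 <- perturb_bundle(b, "affine", diag(4))
  expect_equal(a0$streamlines, b$streamlines, tolerance = 1e-12)
  g <- bundle_grid(b)
  m <- mask_of(tractogram(b$streamlines, g$affine, g$shape))
  m0 <- mask_of(tractogram(d0$streamlines, g$affine, g$shape))
  expect_equal(dice(m, m0)$dice, 1)
})

test_that("dropout removes the expected fraction and never empties silently", {
  spec <- bundle_spec("straight", length = 40, tube_sd = 1,
                      n_streamlines = 500)
  b <- generate_bundle(spec, seed = 3)
  d <- perturb_bundle(b, "dropout", 0.3, seed = 7)
  expect_lt(abs(d$n_streamlines / 500 - 0.7), 0.07)
  expect_no_error(perturb_bundle(b, "dropout", 0.9, seed = 1))
  expect_error(perturb_bundle(b, "dropout", 1, seed = 1))
})

test_that("radius scaling dilates the mask about the centerline", {
  spec <- bundle_spec("straight", length = 50, tube_sd = 2,
                      n_streamlines = 300)
  b <- generate_bundle(spec, seed = 8)
  big <- perturb_bundle(b, "radius_scale", 1.5)
  g <- bundle_grid(big)
  vol1 <- mask_volume(mask_of(tractogram(b$streamlines, g$affine, g$shape)))
  vol2 <- mask_volume(mask_of(tractogram(big$streamlines, g$affine, g$shape)))
  expect_gt(vol2, vol1)
})

test_that("Dice against the original decreases monotonically with jitter", {
  spec <- bundle_spec("arc", radius = 30, angle = 180, tube_sd = 2,
                      n_streamlines = 100)
  means <- sapply(c(0, 1, 2, 4), function(j) {
    mean(sapply(1:5, function(s) {
      b <- generate_bundle(spec, seed = s)
      g <- bundle_grid(b, margin = 10)
      m0 <- mask_of(tractogram(b$streamlines, g$affine, g$shape))
      bp <- perturb_bundle(b, "jitter", j, seed = 100 + s)
      m1 <- mask_of(tractogram(bp$streamlines, g$affine, g$shape))
      dice(m0, m1)$dice
    }))
  })
  expect_equal(means[1], 1)
  expect_true(all(diff(means) < 0))
})

test_that("simulated DWI signals follow the exponential model exactly without noise", {
  sc <- make_scheme(30, 1000, 2)
  D <- c(1e-3, 1e-3, 1e-3, 0, 0, 0)
  tf <- array(rep(D, each = 4), c(4, 1, 1, 6))
  dwi <- simulate_dwi(tf, sc, s0 = 100, snr = Inf)
  b0 <- sc$bvals <= 50
  expect_equal(as.numeric(dwi[, , , which(b0)]), rep(100, 8),
               tolerance = 1e-12)
  expect_equal(as.numeric(dwi[, , , which(!b0)]),
               rep(100 * exp(-1), 4 * 30), tolerance = 1e-12)
  # anisotropic: check one direction analytically
  D2 <- c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  tf2 <- array(rep(D2, each = 1), c(1, 1, 1, 6))
  dwi2 <- simulate_dwi(tf2, sc, s0 = 100, snr = Inf)
  g <- sc$bvecs[3, ]; b <- sc$bvals[3]
  expected <- 100 * exp(-b * (g[1]^2 * 1.7e-3 + g[2]^2 * 0.3e-3 +
                                g[3]^2 * 0.3e-3))
  expect_equal(dwi2[1, 1, 1, 3], expected, tolerance = 1e-12)

  # noise is reproducible under a fixed seed
  n1 <- simulate_dwi(tf2, sc, 100, snr = 30, seed = 4)
  n2 <- simulate_dwi(tf2, sc, 100, snr = 30, seed = 4)
  expect_identical(n1, n2)
})

test_that("simulated studies write the full dataset tree deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  pw <- default_pathways(60)   # small bundles: QC is not under test here
  mpath <- simulate_study(file.path(dir1, "s"), pathways = pw,
                          n_subjects = 2, seed = 42)
  simulate_study(file.path(dir2, "s"), pathways = pw,
                 n_subjects = 2, seed = 42)
  m <- read_manifest(mpath)
  expect_length(m$datasets, 4L)          # ref + 3 confounds
  trks <- list.files(file.path(dir1, "s"), pattern = "\\.trk$",
                     recursive = TRUE)
  expect_length(trks, 2 * 4 * 2)         # subjects x datasets x pathways
  for (f in trks) {
    expect_identical(readBin(file.path(dir1, "s", f), "raw",
                             file.size(file.path(dir1, "s", f))),
                     readBin(file.path(dir2, "s", f), "raw",
                             file.size(file.path(dir2, "s", f))))
  }
  truth <- readr::read_csv(file.path(dir1, "s", "ground_truth.csv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), 16L)
})
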