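#' Specify a synthetic bundle
#'
#' Defines a parametric tube of streamlines around a centerline: a straight
#' segment, a circular arc, or a helix. Streamlines are displaced from the
#' centerline by a radial offset that is constant along the streamline plus a
#' low-frequency cosine wobble, giving coherent tubes rather than white-noise
#' scribbles.
#'
#' @param kind `"straight"`, `"arc"`, or `"helix"`.
#' @param length straight centerline length (mm).
#' @param radius arc/helix radius (mm).
#' @param angle arc angle (degrees).
#' @param pitch helix rise per turn (mm).
#' @param turns helix number of turns.
#' @param n_streamlines streamlines per bundle.
#' @param tube_sd Gaussian radial dispersion (mm).
#' @param step point spacing along each streamline (mm).
#' @param origin world position of the centerline start.
#' @param branch_fraction fraction of streamlines diverted into a side lobe
#'   (0 for a branchless bundle); the diverted streamlines' far endpoints are
#'   displaced by `branch_offset`.
#' @param branch_offset 3-vector displacement of branch endpoints (mm).
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(kind = c("straight", "arc", "helix"),
                        length = 60, radius = 30, angle = 180,
                        pitch = 20, turns = 1.5,
                        n_streamlines = 200, tube_sd = 2, step = 1,
                        origin = c(0, 0, 0),
                        branch_fraction = 0, branch_offset = c(0, 0, 30)) {
  kind <- match.arg(kind)
  stopifnot(n_streamlines >= 1, tube_sd >= 0, step > 0,
            branch_fraction >= 0, branch_fraction < 1)
  structure(list(kind = kind, length = length, radius = radius, angle = angle,
                 pitch = pitch, turns = turns,
                 n_streamlines = as.integer(n_streamlines),
                 tube_sd = tube_sd, step = step, origin = origin,
                 branch_fraction = branch_fraction,
                 branch_offset = branch_offset),
            class = "bundle_spec")
}

spec_centerline <- function(spec) {
  o <- spec$origin
  if (spec$kind == "straight") {
    s <- seq(0, spec$length, by = spec$step)
    cbind(o[1] + s, o[2], o[3])
  } else if (spec$kind == "arc") {
    total <- spec$radius * spec$angle * pi / 180
    s <- seq(0, total, by = spec$step)
    phi <- s / spec$radius
    # arc in the xy-plane, starting at origin, initial tangent +x
    cbind(o[1] + spec$radius * sin(phi),
          o[2] + spec$radius * (1 - cos(phi)),
          o[3])
  } else {
    circ <- sqrt((2 * pi * spec$radius)^2 + spec$pitch^2)
    total <- spec$turns * circ
    s <- seq(0, total, by = spec$step)
    phi <- 2 * pi * s / circ
    cbind(o[1] + spec$radius * sin(phi),
          o[2] + spec$radius * (1 - cos(phi)),
          o[3] + spec$pitch * phi / (2 * pi))
  }
}

# parallel-transported orthonormal frames (normal, binormal) along a polyline
transport_frames <- function(cl) {
  n <- nrow(cl)
  nxt <- pmin(seq_len(n) + 1L, n)
  prv <- pmax(seq_len(n) - 1L, 1L)
  tang <- cl[nxt, , drop = FALSE] - cl[prv, , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  nor <- matrix(0, n, 3); bin <- matrix(0, n, 3)
  ref <- if (abs(tang[1, 3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v <- ref - sum(ref * tang[1, ]) * tang[1, ]
  nor[1, ] <- v / sqrt(sum(v^2))
  bin[1, ] <- crossprod3(tang[1, ], nor[1, ])
  for (i in 2:n) {
    v <- nor[i - 1, ] - sum(nor[i - 1, ] * tang[i, ]) * tang[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) v <- bin[i - 1, ] - sum(bin[i - 1, ] * tang[i, ]) * tang[i, ]
    nor[i, ] <- v / sqrt(sum(v^2))
    bin[i, ] <- crossprod3(tang[i, ], nor[i, ])
  }
  list(normal = nor, binormal = bin)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a synthetic streamline bundle
#'
#' Deterministic given the seed. The true centerline and the core/branch
#' labels are attached as attributes `centerline` and `core` for use as
#' ground truth in validation.
#'
#' @param spec a [bundle_spec()].
#' @param seed integer seed.
#' @param affine,shape reference grid for the resulting [tractogram()]
#'   (defaults to a unit grid; [simulate_study()] supplies real ones).
#' @return A [tractogram()].
#' @export
generate_bundle <- function(spec, seed = 1, affine = diag(4),
                            shape = c(0L, 0L, 0L)) {
  stopifnot(inherits(spec, "bundle_spec"))
  cl <- spec_centerline(spec)
  fr <- transport_frames(cl)
  npts <- nrow(cl)
  arc <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  total <- arc[npts]
  n <- spec$n_streamlines
  with_seed(seed, {
    a0 <- stats::rnorm(n, 0, spec$tube_sd)
    b0 <- stats::rnorm(n, 0, spec$tube_sd)
    wob_a <- stats::rnorm(n, 0, spec$tube_sd / 2)
    wob_b <- stats::rnorm(n, 0, spec$tube_sd / 2)
    ph_a <- stats::runif(n, 0, 2 * pi)
    ph_b <- stats::runif(n, 0, 2 * pi)
    n_branch <- round(spec$branch_fraction * n)
    branch <- seq_len(n) <= n_branch   # deterministic label block
    streamlines <- vector("list", n)
    for (i in seq_len(n)) {
      off_a <- a0[i] + wob_a[i] * cos(2 * pi * arc / max(total, 1) + ph_a[i])
      off_b <- b0[i] + wob_b[i] * cos(2 * pi * arc / max(total, 1) + ph_b[i])
      pts <- cl + off_a * fr$normal + off_b * fr$binormal
      if (branch[i]) {
        # divert the far half smoothly toward the branch offset
        ramp <- pmax(0, (arc / total - 0.5) * 2)
        pts <- pts + outer(ramp, spec$branch_offset)
      }
      streamlines[[i]] <- pts
    }
    out <- tractogram(streamlines, affine, shape)
    attr(out, "centerline") <- cl
    attr(out, "core") <- !branch
    out
  })
}

#' Perturb a bundle to emulate an acquisition confound
#'
#' Models: `jitter` applies an i.i.d. Gaussian rigid shift per streamline
#' (scan/rescan and scanner noise); `dropout` removes a random fraction of
#' streamlines (direction-count effects); `affine` applies a 4x4 matrix to
#' all points (vendor/registration bias); `radius_scale` scales radial
#' offsets about the centerline (systematic dilation bias); `resample` leaves
#' streamlines untouched — resolution effects enter at the voxel-grid level
#' when the bundle is voxelized on a coarser grid (see [simulate_study()]).
#'
#' @param t a [tractogram()].
#' @param model one of `"jitter"`, `"dropout"`, `"affine"`, `"radius_scale"`,
#'   `"resample"`.
#' @param magnitude jitter SD (mm), dropout fraction in `[0,1)`, a 4x4
#'   matrix, a positive scale factor, or (for `resample`) the new voxel size
#'   in mm (recorded as attribute `target_voxel_mm`).
#' @param seed integer seed (used by the stochastic models).
#' @return the perturbed [tractogram()]; deterministic given seed.
#' @export
perturb_bundle <- function(t, model = c("jitter", "dropout", "affine",
                                        "radius_scale", "resample"),
                           magnitude, seed = 1) {
  stopifnot(inherits(t, "tractogram"))
  model <- match.arg(model)
  out <- switch(model,
    jitter = with_seed(seed, {
      sl <- lapply(t$streamlines, function(s) {
        s + matrix(stats::rnorm(3, 0, magnitude), nrow(s), 3, byrow = TRUE)
      })
      tractogram(sl, t$affine, t$shape)
    }),
    dropout = {
      stopifnot(magnitude >= 0, magnitude < 1)
      with_seed(seed, {
        keep <- stats::runif(t$n_streamlines) >= magnitude
        if (!any(keep)) stop("dropout removed every streamline")
        tractogram(t$streamlines[keep], t$affine, t$shape)
      })
    },
    affine = {
      A <- as_affine(magnitude)
      sl <- lapply(t$streamlines, function(s) {
        t((A %*% rbind(t(s), 1))[1:3, , drop = FALSE])
      })
      tractogram(sl, t$affine, t$shape)
    },
    radius_scale = {
      stopifnot(is.numeric(magnitude), magnitude > 0)
      cl <- attr(t, "centerline")
      if (is.null(cl)) cl <- mean_streamline(t)
      cl_dense <- densify_polyline(cl, 0.5)
      sl <- lapply(t$streamlines, function(s) {
        near <- nearest_rows(s, cl_dense)
        near + magnitude * (s - near)
      })
      tractogram(sl, t$affine, t$shape)
    },
    resample = {
      out <- tractogram(t$streamlines, t$affine, t$shape)
      attr(out, "target_voxel_mm") <- magnitude
      out
    })
  for (at in c("centerline", "core"))
    if (!is.null(attr(t, at)) && model != "dropout")
      attr(out, at) <- attr(t, at)
  if (model == "dropout" && !is.null(attr(t, "centerline")))
    attr(out, "centerline") <- attr(t, "centerline")
  out
}

# centroid polyline: all streamlines resampled to 100 equal-arc points, averaged
mean_streamline <- function(t, n = 100) {
  acc <- matrix(0, n, 3)
  for (s in t$streamlines) acc <- acc + resample_polyline_n(s, n)
  acc / t$n_streamlines
}

# for each row of `pts`, the nearest row of `refs`
nearest_rows <- function(pts, refs) {
  # small sizes: exact search via cross-distances in blocks
  d2 <- outer(rowSums(pts^2), rowSums(refs^2), "+") - 2 * pts %*% t(refs)
  refs[max.col(-d2, ties.method = "first"), , drop = FALSE]
}

#' Build an evenly spread single-shell gradient scheme
#'
#' Deterministic Fibonacci-sphere directions plus leading b0 volumes.
#'
#' @param n_dir number of diffusion-weighted directions.
#' @param bval shell b-value (s/mm^2).
#' @param n_b0 number of b = 0 volumes.
#' @return A [dwi_scheme()].
#' @export
make_scheme <- function(n_dir = 30, bval = 1000, n_b0 = 1) {
  i <- seq_len(n_dir) - 0.5
  golden <- (1 + sqrt(5)) / 2
  theta <- acos(1 - 2 * i / n_dir)
  phi <- 2 * pi * i / golden
  g <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  dwi_scheme(c(rep(0, n_b0), rep(bval, n_dir)),
             rbind(matrix(0, n_b0, 3), g))
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' Single-tensor forward model `S_i = S0 exp(-b_i g_i' D g_i)` with Rician
#' noise of level `S0/snr` (magnitude MR noise; `snr = Inf` disables noise).
#'
#' @param tensor_field array (x, y, z, 6) of tensor components
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) in mm^2/s.
#' @param scheme a [dwi_scheme()].
#' @param s0 non-diffusion-weighted signal (scalar or 3-D array).
#' @param snr signal-to-noise ratio at b0.
#' @param seed integer seed for the noise.
#' @return 4-D array (x, y, z, volume).
#' @export
simulate_dwi <- function(tensor_field, scheme, s0 = 100, snr = Inf, seed = 1) {
  stopifnot(length(dim(tensor_field)) == 4L, dim(tensor_field)[4] == 6L,
            inherits(scheme, "dwi_scheme"), snr > 0)
  shp <- dim(tensor_field)[1:3]
  nvox <- prod(shp)
  d6 <- matrix(tensor_field, nvox, 6)
  s0v <- if (length(s0) == 1L) rep(s0, nvox) else as.numeric(s0)
  X <- design_matrix(scheme)
  theta <- cbind(log(s0v), d6)
  signal <- exp(theta %*% t(X))          # nvox x n_volumes
  if (is.finite(snr)) {
    sigma <- s0v / snr
    signal <- with_seed(seed, {
      e1 <- matrix(stats::rnorm(length(signal), 0, sigma), nvox)
      e2 <- matrix(stats::rnorm(length(signal), 0, sigma), nvox)
      sqrt((signal + e1)^2 + e2^2)
    })
  }
  array(signal, c(shp, scheme$n_volumes))
}

#' Simulate a multi-dataset bundle reproducibility study on disk
#'
#' Writes, per subject, a reference dataset and one perturbed dataset per
#' confound contrast (TRK bundles plus a grid-defining NIfTI per dataset, and
#' optionally DWI + bval/bvec), together with a study manifest and a
#' ground-truth table. The whole study shares one world field of view, so all
#' standardized masks land on a common grid. Fully deterministic given the
#' seed.
#'
#' @param dir output directory (created).
#' @param pathways named list of [bundle_spec()]s, one per pathway.
#' @param confounds tibble with columns `confound`, `model`, `magnitude`
#'   (see [perturb_bundle()]); one dataset is generated per row.
#' @param n_subjects number of subjects.
#' @param seed master integer seed.
#' @param dwi also simulate diffusion-weighted volumes per dataset.
#' @param snr DWI signal-to-noise ratio at b0.
#' @param scheme gradient scheme for the DWI (default [make_scheme()]).
#' @param voxel_mm reference grid voxel size (mm).
#' @param dwi_voxel_mm DWI acquisition grid voxel size (mm); diffusion
#'   volumes are simulated at their native coarse resolution and metric maps
#'   are brought to the 1 mm mask grid downstream, as in a real pipeline.
#' @return the manifest path, invisibly.
#' @export
simulate_study <- function(dir,
                           pathways = default_pathways(),
                           confounds = default_confounds(),
                           n_subjects = 3, seed = 1,
                           dwi = FALSE, snr = 30,
                           scheme = make_scheme(), voxel_mm = 1,
                           dwi_voxel_mm = 2.5) {
  stopifnot(all(c("confound", "model", "magnitude") %in% names(confounds)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- sprintf("sub%02d", seq_len(n_subjects))
  datasets <- c("ref", tolower(confounds$confound))

  # one study-wide FOV from the centerlines + dispersion + jitter margin
  all_cl <- do.call(rbind, lapply(pathways, spec_centerline))
  margin <- 15
  lo <- floor(apply(all_cl, 2, min) - margin)
  hi <- ceiling(apply(all_cl, 2, max) + margin)
  ref_shape <- as.integer(ceiling((hi - lo) / voxel_mm))
  ref_affine <- diag(c(rep(voxel_mm, 3), 1))
  ref_affine[1:3, 4] <- lo + voxel_mm / 2

  grid_for <- function(vox) {
    shp <- as.integer(ceiling((hi - lo) / vox))
    aff <- diag(c(rep(vox, 3), 1))
    aff[1:3, 4] <- lo + vox / 2
    list(affine = aff, shape = shp)
  }

  truth <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[si]
    for (pi in seq_along(pathways)) {
      pw <- names(pathways)[pi]
      spec <- pathways[[pi]]
      base_seed <- derive_seed(seed, 7919, si * 1009 + pi * 101)
      base <- generate_bundle(spec, seed = base_seed,
                              affine = ref_affine, shape = ref_shape)
      for (di in seq_along(datasets)) {
        ds <- datasets[di]
        vox <- voxel_mm
        if (ds == "ref") {
          bundle <- base
          model <- "none"; mag <- 0
        } else {
          model <- confounds$model[di - 1L]
          mag <- confounds$magnitude[di - 1L]
          pseed <- derive_seed(base_seed, 1, di * 7907)
          bundle <- perturb_bundle(base, model, mag, seed = pseed)
          if (model == "resample") vox <- mag
        }
        g <- grid_for(vox)
        ds_dir <- file.path(dir, sub, ds)
        dir.create(ds_dir, recursive = TRUE, showWarnings = FALSE)
        b_out <- tractogram(bundle$streamlines, g$affine, g$shape)
        write_tractogram(b_out, file.path(ds_dir, paste0(pw, ".trk")))
        if (pi == 1L)
          write_volume(volume(array(0, g$shape), g$affine),
                       file.path(ds_dir, "grid.nii.gz"))
        truth[[length(truth) + 1L]] <- tibble::tibble(
          subject = sub, dataset = ds, pathway = pw, model = model,
          magnitude = if (is.numeric(mag) && length(mag) == 1) mag else NA_real_,
          n_streamlines = b_out$n_streamlines,
          n_core = sum(attr(bundle, "core") %||% rep(TRUE, b_out$n_streamlines)))
      }
    }
    if (dwi) {
      # one tensor field per subject (fixed anatomy) on the acquisition grid,
      # fresh noise per dataset
      dg <- grid_for(dwi_voxel_mm)
      field <- subject_tensor_field(pathways, dg$affine, dg$shape, seed, si)
      for (di in seq_along(datasets)) {
        ds <- datasets[di]
        ds_dir <- file.path(dir, subjects[si], ds)
        nseed <- derive_seed(seed, 104729, si * 331 + di * 17)
        vols <- simulate_dwi(field, scheme, s0 = 100, snr = snr, seed = nseed)
        write_volume(list(data = vols, affine = dg$affine),
                     file.path(ds_dir, "dwi.nii.gz"))
        write_scheme(scheme, file.path(ds_dir, "dwi.bval"),
                     file.path(ds_dir, "dwi.bvec"))
      }
    }
  }
  truth <- dplyr::bind_rows(truth)
  readr::write_csv(truth, file.path(dir, "ground_truth.csv"))

  manifest <- list(
    subjects = as.list(subjects),
    pathways = as.list(names(pathways)),
    datasets = as.list(datasets),
    reference_dataset = "ref",
    dwi = dwi,
    templates = list(
      bundle = "{subject}/{dataset}/{pathway}.trk",
      grid = "{subject}/{dataset}/grid.nii.gz",
      dwi = "{subject}/{dataset}/dwi.nii.gz",
      bval = "{subject}/{dataset}/dwi.bval",
      bvec = "{subject}/{dataset}/dwi.bvec"),
    contrasts = lapply(seq_len(nrow(confounds)), function(i) {
      list(confound = confounds$confound[i], a = "ref",
           b = tolower(confounds$confound[i]))
    }))
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

# anisotropic tensors (principal axis x, FA ~ 0.80) inside the union of the
# subject's bundles, isotropic tensors of the same MD outside
subject_tensor_field <- function(pathways, affine, shape, seed, si) {
  inside <- array(FALSE, shape)
  for (pi in seq_along(pathways)) {
    base_seed <- derive_seed(seed, 7919, si * 1009 + pi * 101)
    b <- generate_bundle(pathways[[pi]], seed = base_seed,
                         affine = affine, shape = shape)
    d <- streamlines_to_density(b, affine, shape)
    inside <- inside | (d$counts >= 1)
  }
  nvox <- prod(shape)
  d6 <- matrix(rep(c(0.7667e-3, 0.7667e-3, 0.7667e-3, 0, 0, 0), each = nvox),
               nvox, 6)
  idx <- which(inside)
  d6[idx, 1] <- 1.7e-3; d6[idx, 2] <- 0.3e-3; d6[idx, 3] <- 0.3e-3
  array(d6, c(shape, 6L))
}

#' Default two-pathway bundle set for synthetic studies
#'
#' An arcuate-like semicircular bundle and a corticospinal-like straight
#' bundle, separated in space so their masks never touch.
#' @param n_streamlines streamlines per bundle.
#' @return named list of [bundle_spec()]s.
#' @export
default_pathways <- function(n_streamlines = 200) {
  list(
    ARC = bundle_spec("arc", radius = 30, angle = 180, tube_sd = 2,
                      n_streamlines = n_streamlines, origin = c(0, 0, 0)),
    STR = bundle_spec("straight", length = 60, tube_sd = 2,
                      n_streamlines = n_streamlines, origin = c(0, 0, 40)))
}

#' Default confound perturbation plan
#'
#' Scan-rescan as small per-streamline jitter, cross-scanner as larger
#' jitter, and resolution as acquisition at a coarser voxel grid — the
#' magnitude ordering mirrors the relative sizes of those effects in
#' multi-scanner diffusion studies.
#' @return tibble with `confound`, `model`, `magnitude`.
#' @export
default_confounds <- function() {
  tibble::tibble(
    confound = c("RESCAN", "SCAN1", "RES1"),
    model = c("jitter", "jitter", "resample"),
    magnitude = c(0.5, 1.0, 2.4))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed derivation in double precision (exact below 2^53),
# folded into the 32-bit range R's RNG accepts
derive_seed <- function(seed, mult, add) {
  as.integer((as.numeric(seed) * mult + add) %% 2147483647)
}
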