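#' Run the full bundle reproducibility analysis from a manifest
#'
#' Orchestrates every stage in dependency order: voxelization of each
#' (subject, dataset, pathway) bundle to a binary mask standardized on the
#' subject's reference 1 mm grid; streamline-count QC; pairwise Dice per
#' confound contrast; voxelwise agreement/disagreement maps per pathway and
#' confound; the 12 shape descriptors and their paired MAPE/MPV per contrast;
#' Wilcoxon signed-rank comparisons between confounds; and, when the study
#' carries DWI, IRWLLS tensor fits with fixed-reference vs native ROI
#' extraction of FA/MD. Per-bundle failures (missing files, empty masks) are
#' recorded and the run continues; a missing reference dataset aborts.
#'
#' @param manifest a `study_manifest` or path to a manifest YAML.
#' @param out_dir output directory for CSV tables, NIfTI maps and the QC
#'   report (created). `NULL` keeps results in memory only.
#' @param density_threshold streamline-density binarization threshold.
#' @param probability_threshold inclusive threshold for probability maps.
#' @param qc_min,qc_sd,qc_subject_frac QC thresholds, see [qc_filter()].
#' @param alpha uncorrected significance level for the Wilcoxon grid.
#' @param linkage_mm trunk endpoint clustering distance, see [trunk_branch()].
#' @return An object of class `bundle_study`: list with tibbles `dice`,
#'   `shape`, `paired` (per-contrast feature MAPE/MPV), `wilcoxon_dice`,
#'   `microstructure` (or NULL), `qc` (a `qc_report`), `agreement` (named
#'   list of `agreement_map`s), `missing`, and `config`.
#' @export
run_study <- function(manifest, out_dir = NULL,
                      density_threshold = 1, probability_threshold = 2.5e-4,
                      qc_min = 200, qc_sd = 3, qc_subject_frac = 0.20,
                      alpha = 0.05, linkage_mm = 10) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "study_manifest"))
  m <- manifest
  config <- list(density_threshold = density_threshold,
                 probability_threshold = probability_threshold,
                 qc_min = qc_min, qc_sd = qc_sd,
                 qc_subject_frac = qc_subject_frac, alpha = alpha,
                 linkage_mm = linkage_mm)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- reference grids, standardized to 1 mm per subject -------------------
  std_grid <- list()
  for (sub in m$subjects) {
    gp <- manifest_path(m, "grid", subject = sub, dataset = m$reference_dataset)
    if (!file.exists(gp))
      stop("missing reference dataset grid for subject ", sub, ": ", gp)
    g <- read_volume(gp)
    std_grid[[sub]] <-
      if (all(abs(g$voxel_sizes - 1) < 1e-6))
        list(affine = g$affine, shape = as.integer(dim(g$data)))
      else grid_1mm(g$affine, dim(g$data))
  }

  # --- load, voxelize, standardize ------------------------------------------
  masks <- list(); tracts <- list()
  counts <- list(); missing <- list()
  for (sub in m$subjects) for (ds in m$datasets) {
    gp <- manifest_path(m, "grid", subject = sub, dataset = ds)
    native <- if (file.exists(gp)) {
      g <- read_volume(gp)
      list(affine = g$affine, shape = as.integer(dim(g$data)))
    } else std_grid[[sub]]
    for (pw in m$pathways) {
      bp <- manifest_path(m, "bundle", subject = sub, dataset = ds,
                          pathway = pw)
      if (!file.exists(bp)) {
        missing[[length(missing) + 1L]] <- tibble::tibble(
          subject = sub, dataset = ds, pathway = pw, file = bp)
        next
      }
      t <- read_tractogram(bp)
      dens <- streamlines_to_density(t, native$affine, native$shape)
      msk <- density_to_mask(dens, density_threshold,
                             target = std_grid[[sub]])
      key <- paste(sub, ds, pw, sep = "/")
      masks[[key]] <- msk
      tracts[[key]] <- t
      counts[[length(counts) + 1L]] <- tibble::tibble(
        subject = sub, dataset = ds, pathway = pw,
        n_streamlines = t$n_streamlines)
      if (!is.null(out_dir)) {
        mdir <- file.path(out_dir, "masks")
        dir.create(mdir, showWarnings = FALSE)
        write_volume(msk, file.path(mdir, paste0(
          paste(sub, ds, pw, sep = "_"), ".nii.gz")))
      }
    }
  }
  counts <- dplyr::bind_rows(counts)
  missing <- if (length(missing)) dplyr::bind_rows(missing) else
    tibble::tibble(subject = character(), dataset = character(),
                   pathway = character(), file = character())

  # --- QC -------------------------------------------------------------------
  qc <- qc_filter(counts, min_streamlines = qc_min, sd_factor = qc_sd,
                  subject_frac = qc_subject_frac)
  kept <- qc$bundles[qc$bundles$keep, c("subject", "dataset", "pathway")]
  keep_key <- paste(kept$subject, kept$dataset, kept$pathway, sep = "/")

  # --- Dice per contrast ----------------------------------------------------
  dice_rows <- list()
  for (i in seq_len(nrow(m$contrasts))) {
    ct <- m$contrasts[i, ]
    for (sub in m$subjects) for (pw in m$pathways) {
      ka <- paste(sub, ct$a, pw, sep = "/")
      kb <- paste(sub, ct$b, pw, sep = "/")
      if (!(ka %in% keep_key) || !(kb %in% keep_key)) next
      if (is.null(masks[[ka]]) || is.null(masks[[kb]])) next
      d <- dice(masks[[ka]], masks[[kb]])
      dice_rows[[length(dice_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(subject = sub, pathway = pw, confound = ct$confound),
        d)
    }
  }
  dice_tbl <- dplyr::bind_rows(dice_rows)

  # --- agreement maps per (pathway, confound), across subjects --------------
  agreement <- list()
  grids_common <- length(unique(vapply(std_grid, function(g)
    paste(c(g$shape, round(g$affine, 6)), collapse = ","), ""))) == 1L
  if (grids_common) {
    for (i in seq_len(nrow(m$contrasts))) {
      ct <- m$contrasts[i, ]
      for (pw in m$pathways) {
        pairs <- list()
        for (sub in m$subjects) {
          ka <- paste(sub, ct$a, pw, sep = "/")
          kb <- paste(sub, ct$b, pw, sep = "/")
          if (ka %in% keep_key && kb %in% keep_key &&
              !is.null(masks[[ka]]) && !is.null(masks[[kb]]))
            pairs[[length(pairs) + 1L]] <- list(masks[[ka]], masks[[kb]])
        }
        if (length(pairs)) {
          am <- agreement_map(pairs)
          agreement[[paste(pw, ct$confound, sep = "/")]] <- am
          if (!is.null(out_dir)) {
            adir <- file.path(out_dir, "agreement")
            dir.create(adir, showWarnings = FALSE)
            base <- paste(pw, ct$confound, sep = "_")
            write_volume(list(data = am$agree_frac, affine = am$affine),
                         file.path(adir, paste0(base, "_agree.nii.gz")))
            write_volume(list(data = am$disagree_frac, affine = am$affine),
                         file.path(adir, paste0(base, "_disagree.nii.gz")))
          }
        }
      }
    }
  }

  # --- shape features and paired MAPE/MPV -----------------------------------
  shape_rows <- list()
  for (key in keep_key) {
    if (is.null(tracts[[key]])) next
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    sf <- shape_features(tracts[[key]], masks[[key]], linkage_mm = linkage_mm)
    shape_rows[[length(shape_rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(subject = parts[1], dataset = parts[2],
                     pathway = parts[3]), sf)
  }
  shape_tbl <- dplyr::bind_rows(shape_rows)

  paired_rows <- list()
  if (nrow(shape_tbl)) {
    long <- tidyr::pivot_longer(shape_tbl, dplyr::all_of(SHAPE_FEATURES),
                                names_to = "feature", values_to = "value")
    for (i in seq_len(nrow(m$contrasts))) {
      ct <- m$contrasts[i, ]
      a <- long[long$dataset == ct$a, c("subject", "pathway", "feature", "value")]
      b <- long[long$dataset == ct$b, c("subject", "pathway", "feature", "value")]
      j <- dplyr::inner_join(a, b, by = c("subject", "pathway", "feature"),
                             suffix = c("_a", "_b"))
      if (!nrow(j)) next
      j$confound <- ct$confound
      j$mape <- suppressWarnings(mape(j$value_a, j$value_b))
      j$mpv <- suppressWarnings(mpv(j$value_a, j$value_b))
      paired_rows[[length(paired_rows) + 1L]] <- j
    }
  }
  paired_tbl <- dplyr::bind_rows(paired_rows)

  # --- Wilcoxon between confounds on Dice -----------------------------------
  wilcoxon_dice <- NULL
  if (nrow(dice_tbl) && length(unique(dice_tbl$confound)) >= 2L) {
    vals <- tibble::tibble(
      confound = dice_tbl$confound,
      unit = paste(dice_tbl$subject, dice_tbl$pathway, sep = "/"),
      value = dice_tbl$dice)
    wilcoxon_dice <- tryCatch(paired_wilcoxon(vals, alpha = alpha),
                              error = function(e) NULL)
  }

  # --- microstructure: fixed vs native ROI FA/MD ----------------------------
  micro_tbl <- NULL
  if (isTRUE(m$dwi)) micro_tbl <-
    microstructure_stage(m, masks, keep_key, std_grid)

  # --- write tables ----------------------------------------------------------
  res <- structure(list(
    dice = dice_tbl, shape = shape_tbl, paired = paired_tbl,
    wilcoxon_dice = wilcoxon_dice, microstructure = micro_tbl,
    qc = qc, agreement = agreement, missing = missing, config = config),
    class = "bundle_study")
  if (!is.null(out_dir)) {
    readr::write_csv(dice_tbl, file.path(out_dir, "dice.csv"))
    readr::write_csv(shape_tbl, file.path(out_dir, "shape.csv"))
    readr::write_csv(paired_tbl, file.path(out_dir, "paired_features.csv"))
    readr::write_csv(qc$bundles, file.path(out_dir, "qc_bundles.csv"))
    if (!is.null(wilcoxon_dice))
      readr::write_csv(tidy.wilcoxon_grid(wilcoxon_dice),
                       file.path(out_dir, "wilcoxon_dice.csv"))
    if (!is.null(micro_tbl))
      readr::write_csv(micro_tbl, file.path(out_dir, "microstructure.csv"))
    jsonlite_free_provenance(config, file.path(out_dir, "provenance.json"))
  }
  res
}

# provenance without adding a jsonlite dependency: yaml is already imported
jsonlite_free_provenance <- function(config, path) {
  prov <- c(config,
            list(package = "bundlerepro",
                 version = as.character(utils::packageVersion("bundlerepro"))))
  yaml::write_yaml(prov, path)
}

microstructure_stage <- function(m, masks, keep_key, std_grid) {
  rows <- list()
  for (sub in m$subjects) {
    grid <- std_grid[[sub]]
    # union ROI per subject limits the voxels to fit
    union_mask <- NULL
    for (ds in m$datasets) for (pw in m$pathways) {
      key <- paste(sub, ds, pw, sep = "/")
      if (key %in% keep_key && !is.null(masks[[key]])) {
        union_mask <- if (is.null(union_mask)) masks[[key]]$mask
                      else union_mask | masks[[key]]$mask
      }
    }
    if (is.null(union_mask)) next
    union_std <- bundle_mask(union_mask, grid$affine)
    maps <- list()
    for (ds in m$datasets) {
      dp <- manifest_path(m, "dwi", subject = sub, dataset = ds)
      if (!file.exists(dp)) next
      dwi <- read_volume4d(dp)
      dwi_grid <- list(affine = dwi$affine,
                       shape = as.integer(dim(dwi$data)[1:3]))
      # fit on the acquisition grid, restricted to (a dilation-free NN
      # projection of) the union ROI; metric maps then go to the 1 mm grid
      fit_roi <- standardize_mask(union_std, target = dwi_grid)
      scheme <- read_scheme(
        manifest_path(m, "bval", subject = sub, dataset = ds),
        manifest_path(m, "bvec", subject = sub, dataset = ds))
      fit <- fit_tensor_irwlls(dwi$data, scheme, mask = fit_roi)
      maps[[ds]] <- list(
        fa = resample_volume_nn(volume(fit$fa, dwi$affine, allow_na = TRUE),
                                grid)$data,
        md = resample_volume_nn(volume(fit$md, dwi$affine, allow_na = TRUE),
                                grid)$data)
    }
    for (i in seq_len(nrow(m$contrasts))) {
      ct <- m$contrasts[i, ]
      if (is.null(maps[[ct$a]]) || is.null(maps[[ct$b]])) next
      for (pw in m$pathways) {
        kr <- paste(sub, m$reference_dataset, pw, sep = "/")
        ka <- paste(sub, ct$a, pw, sep = "/")
        kb <- paste(sub, ct$b, pw, sep = "/")
        if (!all(c(kr, ka, kb) %in% keep_key)) next
        for (metric in c("fa", "md")) {
          map_a <- maps[[ct$a]][[metric]]
          map_b <- maps[[ct$b]][[metric]]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            subject = sub, pathway = pw, confound = ct$confound,
            metric = metric,
            fixed_a = extract_in_bundle(map_a, masks[[kr]])$mean,
            fixed_b = extract_in_bundle(map_b, masks[[kr]])$mean,
            native_a = extract_in_bundle(map_a, masks[[ka]])$mean,
            native_b = extract_in_bundle(map_b, masks[[kb]])$mean)
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  variance_decomposition(dplyr::bind_rows(rows))
}

#' @export
print.bundle_study <- function(x, ...) {
  cat("<bundle_study>\n")
  cat(sprintf("  dice: %d rows | shape: %d rows | paired: %d rows\n",
              nrow(x$dice), nrow(x$shape), nrow(x$paired)))
  cat(sprintf("  QC: %d bundle(s) removed | %d missing file(s)\n",
              nrow(x$qc$removed_bundles), nrow(x$missing)))
  if (!is.null(x$microstructure))
    cat(sprintf("  microstructure: %d rows\n", nrow(x$microstructure)))
  invisible(x)
}

#' Summarize a bundle study
#'
#' Per-confound Dice medians/IQRs and the per-feature MAPE ordering (features
#' sorted from lowest to highest mean MAPE, ties broken by name).
#'
#' @param r a `bundle_study` from [run_study()].
#' @return list of tibbles `dice_by_confound`, `mape_by_feature`,
#'   `mape_by_confound`.
#' @export
summarize_study <- function(r) {
  stopifnot(inherits(r, "bundle_study"))
  if (!nrow(r$dice) && !nrow(r$paired)) stop("empty results")
  dice_by_confound <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(r$dice, .data$confound),
    n = dplyr::n(),
    median_dice = stats::median(.data$dice, na.rm = TRUE),
    iqr_dice = stats::IQR(.data$dice, na.rm = TRUE),
    mean_dice = mean(.data$dice, na.rm = TRUE),
    .groups = "drop"), dplyr::desc(.data$median_dice), .data$confound)
  mape_by_feature <- NULL
  mape_by_confound <- NULL
  if (nrow(r$paired)) {
    mape_by_feature <- dplyr::arrange(dplyr::summarise(
      dplyr::group_by(r$paired, .data$feature),
      mean_mape = mean(.data$mape, na.rm = TRUE),
      median_mape = stats::median(.data$mape, na.rm = TRUE),
      .groups = "drop"), .data$mean_mape, .data$feature)
    mape_by_confound <- dplyr::arrange(dplyr::summarise(
      dplyr::group_by(r$paired, .data$confound),
      mean_mape = mean(.data$mape, na.rm = TRUE),
      median_mape = stats::median(.data$mape, na.rm = TRUE),
      .groups = "drop"), .data$mean_mape, .data$confound)
  }
  list(dice_by_confound = dice_by_confound,
       mape_by_feature = mape_by_feature,
       mape_by_confound = mape_by_confound)
}

#' Dice distributions per confound
#'
#' Box plots of per-(subject, pathway) Dice for every confound contrast,
#' the tabular analogue of the study-level overlap figures.
#'
#' @param object a `bundle_study`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @method autoplot bundle_study
autoplot.bundle_study <- function(object, ...) {
  ggplot2::ggplot(object$dice,
                  ggplot2::aes(.data$confound, .data$dice,
                               fill = .data$confound)) +
    ggplot2::geom_boxplot(outlier.size = 0.7, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.8,
                         show.legend = FALSE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "source of variation", y = "Dice overlap")
}

#' Feature MAPE by confound
#'
#' @param r a `bundle_study`.
#' @return a ggplot object: per-feature MAPE boxes faceted by confound.
#' @export
plot_feature_mape <- function(r) {
  stopifnot(inherits(r, "bundle_study"))
  ord <- summarize_study(r)$mape_by_feature$feature
  df <- r$paired
  df$feature <- factor(df$feature, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$mape)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~confound) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "MAPE (%)")
}
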