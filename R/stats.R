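#' Mean absolute percentage error between two paired measurements
#'
#' The paired variability measure for scalar features: the absolute
#' difference divided by the pair mean, times 100. Symmetric in its
#' arguments; 0 for identical values, 200 at the nonnegative extreme
#' (one value zero). Vectorized.
#'
#' @param x1,x2 numeric vectors of paired measurements.
#' @return numeric vector of percentages; `NA` where the pair mean is zero
#'   (undefined), with a warning.
#' @export
mape <- function(x1, x2) {
  m <- (x1 + x2) / 2
  out <- ifelse(m == 0, NA_real_, 100 * abs(x1 - x2) / m)
  if (anyNA(out) && any(m == 0, na.rm = TRUE))
    warning("MAPE undefined for ", sum(m == 0, na.rm = TRUE),
            " pair(s) with zero mean")
  out
}

#' Mean percent variation (signed MAPE)
#'
#' Signed counterpart of [mape()], used to detect systematic bias between
#' conditions: positive when the non-reference measurement is larger.
#' `abs(mpv(a, b)) == mape(a, b)` always.
#'
#' @param x_ref reference-condition values (e.g. repeat 1).
#' @param x_other comparison-condition values (e.g. repeat 2).
#' @return numeric vector of signed percentages (`NA` where the mean is zero).
#' @export
mpv <- function(x_ref, x_other) {
  m <- (x_ref + x_other) / 2
  out <- ifelse(m == 0, NA_real_, 100 * (x_other - x_ref) / m)
  if (anyNA(out) && any(m == 0, na.rm = TRUE))
    warning("MPV undefined for ", sum(m == 0, na.rm = TRUE),
            " pair(s) with zero mean")
  out
}

#' Pairwise paired Wilcoxon signed-rank tests between confounds
#'
#' For every pair of confound contrasts, compares their per-unit values
#' (units are subject or subject-pathway combinations, matched across the
#' two confounds) with a two-sided Wilcoxon signed-rank test: exact null
#' distribution for n <= 25 without ties, normal approximation with
#' continuity correction otherwise. Zero differences are dropped (Wilcoxon's
#' treatment) and the effective n reported; all-zero difference vectors give
#' p = 1. Significance is Bonferroni-corrected at
#' `alpha / (n_comparisons * n_methods)`.
#'
#' @param values tibble with columns `confound`, `unit` (pairing key), and
#'   `value`.
#' @param alpha family-wise error rate before correction.
#' @param n_methods number of parallel analysis families (e.g. segmentation
#'   workflows) sharing the correction, as in "p < .05 / pairs / methods".
#' @param min_pairs minimum matched units per comparison; pairs with fewer
#'   are skipped (reported with `NA` p).
#' @return An object of class `wilcoxon_grid` (also a tibble): one row per
#'   confound pair with `n` (nonzero differences), `statistic`, `p_value`,
#'   `significant`; attributes `alpha_corrected` and `n_tests`.
#' @export
paired_wilcoxon <- function(values, alpha = 0.05, n_methods = 1,
                            min_pairs = 3) {
  stopifnot(all(c("confound", "unit", "value") %in% names(values)))
  confs <- unique(values$confound)
  if (length(confs) < 2L) stop("need at least two confounds to compare")
  pairs <- utils::combn(confs, 2, simplify = FALSE)
  n_tests <- length(pairs) * n_methods
  alpha_c <- alpha / n_tests
  rows <- lapply(pairs, function(pr) {
    a <- values[values$confound == pr[1], c("unit", "value")]
    b <- values[values$confound == pr[2], c("unit", "value")]
    j <- merge(a, b, by = "unit")
    d <- j$value.x - j$value.y
    d <- d[is.finite(d)]
    if (length(d) < min_pairs)
      return(tibble::tibble(confound_a = pr[1], confound_b = pr[2],
                            n = length(d), statistic = NA_real_,
                            p_value = NA_real_, skipped = TRUE))
    nz <- d[d != 0]
    if (length(nz) == 0L) {
      stat <- 0; p <- 1
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(nz, alternative = "two.sided",
                           exact = length(nz) <= 25,
                           correct = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    tibble::tibble(confound_a = pr[1], confound_b = pr[2],
                   n = length(nz), statistic = stat, p_value = p,
                   skipped = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha_c
  attr(out, "alpha_corrected") <- alpha_c
  attr(out, "n_tests") <- n_tests
  class(out) <- c("wilcoxon_grid", class(out))
  out
}

#' @export
#' @method tidy wilcoxon_grid
tidy.wilcoxon_grid <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @export
#' @method glance wilcoxon_grid
glance.wilcoxon_grid <- function(x, ...) {
  tibble::tibble(n_tests = attr(x, "n_tests"),
                 alpha_corrected = attr(x, "alpha_corrected"),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 n_skipped = sum(x$skipped))
}

#' Streamline-count quality control
#'
#' Applies the two numeric bundle QC rules, in order: a bundle is removed if
#' its streamline count falls more than `sd_factor` standard deviations below
#' the per-pathway mean, or below the absolute floor `min_streamlines`
#' (tractography failure). A subject is then removed for a given method when
#' more than `subject_frac` of its pathways failed. A manual exclusion list
#' can be appended for bundles flagged by visual inspection.
#'
#' @param counts tibble with columns `subject`, `dataset`, `pathway`,
#'   `n_streamlines`, and optionally `method` (defaults to a single method).
#' @param min_streamlines absolute floor (default 200).
#' @param sd_factor low-outlier cut in per-pathway SDs (default 3).
#' @param subject_frac fraction of failed pathways above which the subject
#'   is dropped for that method (default 0.20, strict inequality).
#' @param manual_exclusions optional tibble with `subject`, `dataset`,
#'   `pathway` rows to remove with reason `"manual"`.
#' @return An object of class `qc_report`: list with `bundles` (input rows
#'   plus `keep` and `reason`), `removed_bundles`, `removed_subjects`
#'   (subject, method, fraction_failed).
#' @export
qc_filter <- function(counts, min_streamlines = 200, sd_factor = 3,
                      subject_frac = 0.20, manual_exclusions = NULL) {
  stopifnot(all(c("subject", "dataset", "pathway", "n_streamlines") %in%
                  names(counts)))
  if (!"method" %in% names(counts)) counts$method <- "default"
  counts <- dplyr::group_by(counts, .data$method, .data$pathway)
  counts <- dplyr::mutate(counts,
    path_mean = mean(.data$n_streamlines),
    path_sd = stats::sd(.data$n_streamlines))
  counts <- dplyr::ungroup(counts)
  low_sd <- !is.na(counts$path_sd) & counts$path_sd > 0 &
    counts$n_streamlines < counts$path_mean - sd_factor * counts$path_sd
  low_abs <- counts$n_streamlines < min_streamlines
  manual <- rep(FALSE, nrow(counts))
  if (!is.null(manual_exclusions) && nrow(manual_exclusions)) {
    key <- paste(counts$subject, counts$dataset, counts$pathway)
    mkey <- paste(manual_exclusions$subject, manual_exclusions$dataset,
                  manual_exclusions$pathway)
    manual <- key %in% mkey
  }
  # exactly one recorded reason per removal, applied in rule order
  reason <- dplyr::case_when(
    low_sd ~ "below_3sd",
    low_abs ~ "below_min_streamlines",
    manual ~ "manual",
    .default = NA_character_)
  counts$reason <- reason
  counts$keep <- is.na(reason)

  subj <- dplyr::summarise(
    dplyr::group_by(counts, .data$subject, .data$method),
    fraction_failed = mean(!.data$keep), .groups = "drop")
  removed_subjects <- dplyr::filter(subj, .data$fraction_failed > subject_frac)
  if (nrow(removed_subjects)) {
    drop_key <- paste(removed_subjects$subject, removed_subjects$method)
    hit <- paste(counts$subject, counts$method) %in% drop_key & counts$keep
    counts$keep[hit] <- FALSE
    counts$reason[hit] <- "subject_failed_qc"
  }
  bundles <- dplyr::select(counts, -"path_mean", -"path_sd")
  structure(list(
    bundles = bundles,
    removed_bundles = dplyr::filter(bundles, !.data$keep),
    removed_subjects = removed_subjects),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d bundles removed, %d subject-method pairs removed\n",
              nrow(x$removed_bundles), nrow(x$bundles),
              nrow(x$removed_subjects)))
  invisible(x)
}

#' @export
#' @method tidy qc_report
tidy.qc_report <- function(x, ...) x$bundles

#' @export
#' @method glance qc_report
glance.qc_report <- function(x, ...) {
  tibble::tibble(n_bundles = nrow(x$bundles),
                 n_removed = nrow(x$removed_bundles),
                 n_subjects_removed = nrow(x$removed_subjects))
}
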