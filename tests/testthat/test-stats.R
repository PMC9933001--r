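test_that("MAPE follows the difference-over-mean formula", {
  expect_equal(mape(100, 100), 0)
  expect_equal(mape(100, 110), 100 * 10 / 105, tolerance = 1e-12)
  expect_equal(mape(0, 10), 200)
  expect_warning(out <- mape(0, 0), "zero mean")
  expect_true(is.na(out))
})

test_that("MPV is the signed MAPE with the other-minus-reference convention", {
  expect_equal(mpv(100, 110), 100 * 10 / 105, tolerance = 1e-12)
  expect_equal(mpv(110, 100), -100 * 10 / 105, tolerance = 1e-12)
  withr::local_seed(14)
  a <- runif(1000, 1, 100); b <- runif(1000, 1, 100)
  expect_equal(abs(mpv(a, b)), mape(a, b), tolerance = 1e-12)
  expect_equal(mpv(a, b), -mpv(b, a), tolerance = 1e-12)
  expect_equal(mape(a, b), mape(b, a), tolerance = 1e-12)
})

test_that("identical paired values give p = 1 across the comparison grid", {
  vals <- tibble::tibble(
    confound = rep(c("A", "B"), each = 6),
    unit = rep(paste0("u", 1:6), 2),
    value = rep(c(3, 1, 4, 1, 5, 9), 2))
  w <- paired_wilcoxon(vals)
  expect_equal(w$p_value, 1)
  expect_equal(w$n, 0L)          # all differences zero
  expect_false(any(w$significant))
})

test_that("all-positive differences over 6 pairs give exact p = 2/64", {
  base <- c(10, 20, 30, 40, 50, 60)
  vals <- tibble::tibble(
    confound = rep(c("A", "B"), each = 6),
    unit = rep(paste0("u", 1:6), 2),
    value = c(base + 1:6, base))
  w <- paired_wilcoxon(vals)
  expect_equal(w$p_value, 2 / 64, tolerance = 1e-12)
})

test_that("exact Wilcoxon p-values match full 2^n sign enumeration", {
  withr::local_seed(21)
  for (n in c(5, 6, 8, 10)) {
    d <- rnorm(n, 0.3, 1)   # continuous: no tied ranks, no zeros
    n_eff <- length(d)
    vals <- tibble::tibble(
      confound = rep(c("A", "B"), each = n_eff),
      unit = rep(paste0("u", seq_len(n_eff)), 2),
      value = c(50 + d, rep(50, n_eff)))
    w <- paired_wilcoxon(vals)
    expect_equal(w$p_value, oracle_signed_rank_p(d), tolerance = 1e-12,
                 label = paste("n =", n))
  }
})

test_that("the corrected threshold counts comparisons and methods", {
  withr::local_seed(30)
  vals <- tibble::tibble(
    confound = rep(c("A", "B", "C", "D"), each = 5),
    unit = rep(paste0("u", 1:5), 4),
    value = rnorm(20))
  w <- paired_wilcoxon(vals, alpha = 0.05, n_methods = 4)
  expect_equal(nrow(w), choose(4, 2))
  expect_equal(attr(w, "n_tests"), 6 * 4)
  expect_equal(attr(w, "alpha_corrected"), 0.05 / 24)
  expect_s3_class(tidy(w), "tbl_df")
  expect_equal(glance(w)$n_tests, 24)
})

test_that("comparisons with too few common subjects are skipped, not guessed", {
  vals <- tibble::tibble(
    confound = c("A", "A", "B", "B"),
    unit = c("u1", "u2", "u1", "u2"),
    value = c(1, 2, 3, 4))
  w <- paired_wilcoxon(vals, min_pairs = 3)
  expect_true(w$skipped)
  expect_true(is.na(w$p_value))
})

test_that("null rejection rate at uncorrected alpha sits in its binomial CI", {
  withr::local_seed(99)
  n_sims <- 1000; n <- 10; alpha <- 0.05
  rej <- 0L
  for (i in seq_len(n_sims)) {
    d <- rnorm(n)                        # true null: symmetric differences
    vals <- tibble::tibble(
      confound = rep(c("A", "B"), each = n),
      unit = rep(paste0("u", 1:n), 2),
      value = c(100 + d, rep(100, n)))
    w <- paired_wilcoxon(vals)
    rej <- rej + (w$p_value < alpha)
  }
  rate <- rej / n_sims
  ci <- 2.576 * sqrt(alpha * (1 - alpha) / n_sims)
  expect_lt(abs(rate - alpha), ci + 0.01)  # discreteness of the exact null
})

test_that("QC removes bundles below the absolute streamline floor", {
  counts <- tibble::tibble(
    subject = paste0("s", 1:10), dataset = "d1", pathway = "AF",
    n_streamlines = c(rep(1000, 9), 150))
  qc <- qc_filter(counts)
  expect_equal(nrow(qc$removed_bundles), 1L)
  expect_equal(qc$removed_bundles$subject, "s10")
  expect_equal(qc$removed_bundles$reason, "below_min_streamlines")
})

test_that("QC removes per-pathway low outliers beyond 3 SD", {
  counts <- tibble::tibble(
    subject = paste0("s", 1:21), dataset = "d1", pathway = "CST",
    n_streamlines = c(rep(1000, 20), 500))
  # mean 976.2, sd 109.1: 500 < 976.2 - 3 * 109.1 but above the 200 floor
  qc <- qc_filter(counts)
  expect_equal(qc$removed_bundles$subject, "s21")
  expect_equal(qc$removed_bundles$reason, "below_3sd")
})

test_that("subjects are dropped only above the 20% failed-pathway fraction", {
  make_counts <- function(n_fail) {
    tibble::tibble(
      subject = c(rep("bad", 14), rep(paste0("s", 1:9), each = 14)),
      dataset = "d1",
      pathway = rep(paste0("p", 1:14), 10),
      n_streamlines = c(
        c(rep(100, n_fail), rep(1000, 14 - n_fail)),   # "bad" subject
        rep(1000, 126)))
  }
  qc2 <- qc_filter(make_counts(2))     # 2/14 = 14.3% <= 20%: retained
  expect_equal(nrow(qc2$removed_subjects), 0L)
  expect_equal(nrow(qc2$removed_bundles), 2L)

  qc3 <- qc_filter(make_counts(3))     # 3/14 = 21.4% > 20%: removed
  expect_equal(qc3$removed_subjects$subject, "bad")
  expect_gt(qc3$removed_subjects$fraction_failed, 0.20)
  # all 14 of the subject's bundles now excluded, each with one reason
  bad_rows <- qc3$bundles[qc3$bundles$subject == "bad", ]
  expect_true(all(!bad_rows$keep))
  expect_true(all(!is.na(bad_rows$reason)))
})

test_that("manual exclusions are honoured with their own reason", {
  counts <- tibble::tibble(
    subject = paste0("s", 1:10), dataset = "d1", pathway = "AF",
    n_streamlines = rep(1000, 10))
  qc <- qc_filter(counts, manual_exclusions = tibble::tibble(
    subject = "s3", dataset = "d1", pathway = "AF"))
  expect_equal(qc$removed_bundles$subject, "s3")
  expect_equal(qc$removed_bundles$reason, "manual")
  expect_s3_class(tidy(qc), "tbl_df")
  expect_equal(glance(qc)$n_removed, 1L)
})
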