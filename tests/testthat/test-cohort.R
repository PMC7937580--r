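# minimal hand-built cohort: one modality, one threshold
hand_cohort <- function(frac, pft, metric = "fev_fvc",
                        modality = "ventilation") {
  tb <- tibble::tibble(
    patient_id = sprintf("P%02d", seq_along(frac)),
    fvc_pct_pred = 90, fev_pct_pred = 75, fev_fvc = 65, dlco_pct_pred = 60,
    modality = modality, threshold = 0.30, fractional_volume = frac)
  tb[[metric]] <- pft
  tb
}

test_that("the Pearson cell matches the textbook formula on 5 points", {
  x <- c(0.12, 0.35, 0.41, 0.58, 0.77)
  y <- c(42, 55, 61, 70, 88)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tab <- build_correlogram(hand_cohort(x, y))
  cell <- dplyr::filter(tab, pft_metric == "fev_fvc")
  expect_equal(cell$r, r_hand, tolerance = 1e-12)
  expect_equal(cell$n, 5L)
  # Fisher-z interval, computed independently
  zr <- atanh(r_hand)
  expect_equal(cell$ci_low, tanh(zr - qnorm(0.975) / sqrt(2)),
               tolerance = 1e-9)
  expect_equal(cell$ci_high, tanh(zr + qnorm(0.975) / sqrt(2)),
               tolerance = 1e-9)
})

test_that("an exactly linear cohort correlates at 1 and constants are flagged", {
  pft <- seq(40, 90, length.out = 12)
  co <- hand_cohort(frac = 0.002 + 0.008 * pft, pft = pft)
  tab <- build_correlogram(co)
  fev <- dplyr::filter(tab, pft_metric == "fev_fvc")
  expect_equal(fev$r, 1, tolerance = 1e-12)
  # the other metrics were held constant: undefined, not zero
  const <- dplyr::filter(tab, pft_metric != "fev_fvc")
  expect_true(all(is.na(const$r)))
  expect_true(all(const$reason == "constant variable"))
})

test_that("cells with fewer than 3 usable patients are undefined with reason", {
  co <- hand_cohort(frac = c(0.2, 0.4), pft = c(50, 70))
  tab <- build_correlogram(co)
  expect_true(all(is.na(tab$r)))
  expect_true(all(tab$reason == "fewer than 3 usable patients"))

  # NA fractions (perfusion-only patients) reduce the usable n
  co3 <- hand_cohort(frac = c(0.2, 0.4, NA, NA), pft = c(50, 70, 60, 80))
  expect_equal(dplyr::filter(build_correlogram(co3),
                             pft_metric == "fev_fvc")$n, 2L)
})

test_that("the correlogram is invariant to patient ordering", {
  co <- generate_cohort(n = 30, seed = 77)
  shuffled <- withr::with_seed(1, dplyr::slice_sample(co, prop = 1))
  expect_equal(build_correlogram(co), build_correlogram(shuffled))
})

test_that("perfusion-only patients contribute to perfusion cells only", {
  co <- generate_cohort(n = 66, seed = 5)
  tab <- build_correlogram(co)
  expect_true(all(dplyr::filter(tab, modality == "perfusion")$n == 66L))
  expect_true(all(dplyr::filter(tab, modality == "ventilation")$n == 52L))
  expect_true(all(dplyr::filter(tab, modality == "matched")$n == 52L))
})

test_that("excluding sub-percent clipped fractions barely moves the correlogram", {
  co <- generate_cohort(n = 66, seed = 8)
  with_clip <- build_correlogram(co)
  without_clip <- build_correlogram(co, exclude_clipped = TRUE)
  joined <- dplyr::inner_join(
    with_clip, without_clip,
    by = c("pft_metric", "modality", "threshold"), suffix = c("", "_ex"))
  deltas <- abs(joined$r - joined$r_ex)
  expect_true(all(deltas < 0.05, na.rm = TRUE))
  expect_error(build_correlogram(dplyr::select(
    co, -normalized_volume_fraction), exclude_clipped = TRUE),
    "normalized_volume_fraction")
})

test_that("normalized-volume summaries reproduce direct order statistics", {
  co <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    modality = "ventilation", threshold = 0.30,
    fractional_volume = 0.5,
    normalized_volume_fraction = c(0.001, 0.0023, 0.05),
    reduction_applied = TRUE)
  s <- summarize_normalized_volumes(co)
  expect_equal(s$median_pct, 0.23)
  expect_equal(s$max_pct, 5.0)
  expect_equal(s$n_reduced, 3L)

  # no patient clipped: counts reported, statistics absent
  co0 <- dplyr::mutate(co, reduction_applied = FALSE,
                       normalized_volume_fraction = 0)
  s0 <- summarize_normalized_volumes(co0)
  expect_equal(s0$n_reduced, 0L)
  expect_true(is.na(s0$median_pct))

  # a patient without a ventilation study leaves the denominator
  co_na <- dplyr::bind_rows(co, tibble::tibble(
    patient_id = "D", modality = "ventilation", threshold = 0.30,
    fractional_volume = NA_real_,
    normalized_volume_fraction = NA_real_, reduction_applied = NA))
  expect_equal(summarize_normalized_volumes(co_na)$n_total, 3L)
})

test_that("cohort CSV round-trips through the wide schema", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(n = 12, seed = 31)
  p <- file.path(dir, "cohort.csv")
  write_cohort(co, p)
  back <- read_cohort(p)
  key <- c("patient_id", "modality", "threshold")
  a <- dplyr::arrange(co, !!!rlang::syms(key))
  b <- dplyr::arrange(back[names(a)], !!!rlang::syms(key))
  expect_equal(as.data.frame(b), as.data.frame(a), tolerance = 1e-12)
  # and the correlograms agree exactly
  expect_equal(build_correlogram(back)$r, build_correlogram(co)$r,
               tolerance = 1e-12)
})

test_that("correlogram heatmaps render deterministically to disk", {
  dir <- withr::local_tempdir()
  tab <- build_correlogram(generate_cohort(n = 20, seed = 2))
  out <- file.path(dir, "correlogram.png")
  plot_correlogram(tab, out)
  expect_true(file.exists(out) && file.size(out) > 0)
  # undefined-only tables are refused
  empty_tab <- dplyr::mutate(tab, r = NA_real_)
  expect_error(plot_correlogram(empty_tab, file.path(dir, "x.png")),
               "no defined cells")
  p <- ggplot2::autoplot(tab)
  expect_s3_class(p, "ggplot")
})
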