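pft_metrics <- c("fvc_pct_pred", "fev_pct_pred", "fev_fvc", "dlco_pct_pred")

# linear scales for the four PFT metrics (value = centre + scale * latent N(0,1));
# centres follow typical stage-III NSCLC cohort means, spreads chosen so that
# +/-3 SD stays within plausible physiological ranges
pft_scales <- list(
  fvc_pct_pred = c(centre = 91, scale = 14),
  fev_pct_pred = c(centre = 76, scale = 15),
  fev_fvc = c(centre = 65, scale = 10),
  dlco_pct_pred = c(centre = 64, scale = 13)
)

#' Simulate a V/Q imaging cohort with designed PFT correlations
#'
#' Draws a synthetic cohort of patients with the four pulmonary function
#' test (PFT) metrics and per-threshold fractional functional volumes for
#' ventilation, perfusion, and matched modalities, such that the Pearson
#' correlation between each PFT metric and the fractional volume at the
#' reference threshold equals the designed value exactly in expectation.
#'
#' The generative model is a single-factor Gaussian design: a latent
#' function factor `g` drives both modalities' fractional volumes (loading
#' `sqrt(0.95)` each, so ventilation and perfusion fractions correlate at
#' 0.95) and each PFT metric loads on `g` so that its marginal correlation
#' with either modality's fraction equals the designed rho. All maps from
#' latent to observed scales are linear (fractions clamped to \[0, 1\], a
#' < 0.1% event under the defaults), so Pearson correlations survive the
#' transformation. Fractional volumes at other thresholds scale down
#' linearly from the reference threshold, giving monotone per-patient
#' threshold profiles; matched fractions are 0.95 of the ventilation/
#' perfusion minimum, emulating imperfect spatial overlap.
#'
#' A fraction of patients (default 14/66, mirroring tracer availability in
#' typical cohorts) receives a perfusion study only: their ventilation and
#' matched rows carry `NA` fractional volumes.
#'
#' Each patient/modality also receives a `normalized_volume_fraction` (the
#' fraction of lung clipped by peak normalization) drawn from a right-skewed
#' lognormal at the sub-percent scale typical of clinical studies, with
#' ventilation requiring reduction more often than perfusion.
#'
#' @param n Number of patients, at least 3.
#' @param correlation_design Named numeric vector of designed Pearson
#'   correlations (each in (-1, 1)) between fractional volume and the PFT
#'   metrics `fvc_pct_pred`, `fev_pct_pred`, `fev_fvc`, `dlco_pct_pred`.
#' @param reference_threshold Threshold fraction at which the designed
#'   correlation holds. Default 0.30.
#' @param thresholds Threshold grid. Default [default_thresholds()].
#' @param perfusion_only_fraction Fraction of patients with no ventilation
#'   study. Default 14/66.
#' @param seed Integer seed.
#'
#' @return A long tibble with columns `patient_id`, the four PFT metrics,
#'   `modality`, `threshold`, `fractional_volume`,
#'   `normalized_volume_fraction`, `reduction_applied`.
#' @export
generate_cohort <- function(n = 66L,
                            correlation_design = c(fvc_pct_pred = 0.25,
                                                   fev_pct_pred = 0.35,
                                                   fev_fvc = 0.6,
                                                   dlco_pct_pred = 0.25),
                            reference_threshold = 0.30,
                            thresholds = default_thresholds(),
                            perfusion_only_fraction = 14 / 66,
                            seed = 1L) {
  if (n < 3L) stop("need at least 3 patients", call. = FALSE)
  stopifnot(all(names(correlation_design) %in% pft_metrics))
  rho <- correlation_design
  if (any(abs(rho) >= 1)) {
    stop("designed correlations must lie in (-1, 1)", call. = FALSE)
  }
  # modality loading on the shared function factor: 0.95^0.5 by default
  # (ventilation and perfusion fractions correlate at 0.95), raised just
  # enough when a designed rho approaches 1 to keep every PFT loading < 1
  lambda <- sqrt(min(0.9995, max(0.95, max(rho^2) + 0.002)))
  if (any(abs(rho) / lambda >= 1)) {
    stop("infeasible correlation design: |rho| must be < ", round(lambda, 4),
         " for the single-factor model to remain positive definite",
         call. = FALSE)
  }

  withr::with_seed(seed, {
    g <- stats::rnorm(n)
    z_vent <- lambda * g + sqrt(1 - lambda^2) * stats::rnorm(n)
    z_perf <- lambda * g + sqrt(1 - lambda^2) * stats::rnorm(n)

    pft <- lapply(pft_metrics, function(m) {
      r <- if (m %in% names(rho)) unname(rho[m]) else 0
      b <- r / lambda
      latent <- b * g + sqrt(1 - b^2) * stats::rnorm(n)
      sc <- pft_scales[[m]]
      sc["centre"] + sc["scale"] * latent
    })
    names(pft) <- pft_metrics

    base_vent <- pmin(1, pmax(0, 0.5 + 0.15 * z_vent))
    base_perf <- pmin(1, pmax(0, 0.5 + 0.15 * z_perf))

    n_perf_only <- round(perfusion_only_fraction * n)
    perf_only <- seq_len(n) %in% sample.int(n, n_perf_only)

    # clipped-volume fractions at the sub-percent scale; ventilation
    # reductions are more frequent and larger than perfusion ones
    draw_clip <- function(p_reduce, median_frac, sdlog) {
      applied <- stats::runif(n) < p_reduce
      frac <- ifelse(applied,
                     pmin(0.05, stats::rlnorm(n, log(median_frac), sdlog)),
                     0)
      list(applied = applied, frac = frac)
    }
    clip_v <- draw_clip(48 / 52, 0.0023, 1.1)
    clip_q <- draw_clip(21 / 66, 0.0006, 1.2)

    profile <- (1 - thresholds) / (1 - reference_threshold)
    nt <- length(thresholds)
    # per patient x threshold fraction matrices (patients in rows)
    fv <- pmin(outer(base_vent, profile), 1)
    fq <- pmin(outer(base_perf, profile), 1)
    fm <- 0.95 * pmin(fv, fq)
    fv[perf_only, ] <- NA_real_
    fm[perf_only, ] <- NA_real_
    clip_v$frac[perf_only] <- NA_real_
    clip_v$applied[perf_only] <- NA

    per_pat <- function(x) rep(x, each = nt) # expand to modality block
    tibble::tibble(
      patient_id = rep(per_pat(sprintf("P%03d", seq_len(n))), 3L),
      fvc_pct_pred = rep(per_pat(pft$fvc_pct_pred), 3L),
      fev_pct_pred = rep(per_pat(pft$fev_pct_pred), 3L),
      fev_fvc = rep(per_pat(pft$fev_fvc), 3L),
      dlco_pct_pred = rep(per_pat(pft$dlco_pct_pred), 3L),
      modality = rep(c("ventilation", "perfusion", "matched"), each = n * nt),
      threshold = rep(thresholds, 3L * n),
      fractional_volume = c(t(fv), t(fq), t(fm)),
      normalized_volume_fraction = c(per_pat(clip_v$frac),
                                     per_pat(clip_q$frac),
                                     rep(NA_real_, n * nt)),
      reduction_applied = c(per_pat(clip_v$applied),
                            per_pat(clip_q$applied),
                            rep(NA, n * nt))
    ) |>
      dplyr::arrange(.data$patient_id)
  })
}

#' Pearson correlogram of fractional volumes against PFT metrics
#'
#' Computes the Pearson correlation between fractional functional volume
#' and each pulmonary function test metric, per modality and threshold,
#' over pairwise-complete patients. Perfusion-only patients therefore
#' contribute to perfusion cells but not to ventilation or matched cells.
#' 95% confidence intervals come from the Fisher z-transform; they are
#' reported as honest uncertainty, not used for any gating. Cells with
#' fewer than 3 usable patients or a constant variable are returned with
#' `NA` correlation and a `reason`.
#'
#' @param cohort A long cohort tibble as produced by [generate_cohort()] or
#'   [read_cohort()]: columns `patient_id`, the four PFT metrics,
#'   `modality`, `threshold`, `fractional_volume`.
#' @param exclude_clipped If `TRUE` and the cohort carries
#'   `normalized_volume_fraction`, the clipped fraction is removed from each
#'   fractional volume before correlating (sensitivity analysis of the
#'   reintroduced hotspot volume).
#' @return A tibble of class `correlogram`: `pft_metric`, `modality`,
#'   `threshold`, `r`, `n`, `ci_low`, `ci_high`, `reason` (`NA` when
#'   defined).
#' @export
build_correlogram <- function(cohort, exclude_clipped = FALSE) {
  stopifnot(all(c("patient_id", "modality", "threshold",
                  "fractional_volume") %in% names(cohort)))
  metrics <- intersect(pft_metrics, names(cohort))
  if (length(metrics) == 0L) {
    stop("cohort has none of the PFT columns: ",
         paste(pft_metrics, collapse = ", "), call. = FALSE)
  }
  dat <- cohort
  if (exclude_clipped) {
    if (!"normalized_volume_fraction" %in% names(dat)) {
      stop("`exclude_clipped = TRUE` needs a `normalized_volume_fraction` ",
           "column", call. = FALSE)
    }
    dat <- dplyr::mutate(
      dat,
      fractional_volume = pmax(
        0, .data$fractional_volume -
          dplyr::coalesce(.data$normalized_volume_fraction, 0)))
  }

  long <- tidyr::pivot_longer(
    dat, cols = dplyr::all_of(metrics),
    names_to = "pft_metric", values_to = "pft_value")

  out <- long |>
    dplyr::group_by(.data$pft_metric, .data$modality, .data$threshold) |>
    dplyr::summarise(
      cell = list(pearson_cell(.data$fractional_volume, .data$pft_value)),
      .groups = "drop") |>
    tidyr::unnest_wider("cell") |>
    dplyr::arrange(.data$pft_metric, .data$modality, .data$threshold)
  class(out) <- c("correlogram", class(out))
  out
}

# Pearson r with Fisher-z 95% CI on pairwise-complete observations
pearson_cell <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) {
    return(list(r = NA_real_, n = n, ci_low = NA_real_, ci_high = NA_real_,
                reason = "fewer than 3 usable patients"))
  }
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n = n, ci_low = NA_real_, ci_high = NA_real_,
                reason = "constant variable"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), n = n,
       ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
       reason = NA_character_)
}

#' Summarise clipped (normalized) volume fractions across a cohort
#'
#' Per modality, reports the median, mean, and maximum of the
#' normalized-volume fraction over the patients for whom a peak reduction
#' was actually applied, as percentages of total lung volume, along with the
#' reduction counts (`n_reduced` of `n_total` scanned patients).
#'
#' @param cohort A cohort tibble with `modality`,
#'   `normalized_volume_fraction` and `reduction_applied` columns (one or
#'   more rows per patient; deduplicated by `patient_id`).
#' @return A tibble: `modality`, `n_reduced`, `n_total`, `median_pct`,
#'   `mean_pct`, `max_pct`. Modalities with no reduced patient report the
#'   counts with `NA` statistics.
#' @export
summarize_normalized_volumes <- function(cohort) {
  stopifnot(all(c("patient_id", "modality", "normalized_volume_fraction",
                  "reduction_applied") %in% names(cohort)))
  per_patient <- cohort |>
    dplyr::filter(.data$modality %in% c("ventilation", "perfusion")) |>
    dplyr::distinct(.data$patient_id, .data$modality,
                    .data$normalized_volume_fraction,
                    .data$reduction_applied) |>
    dplyr::filter(!is.na(.data$reduction_applied))
  per_patient |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(
      n_reduced = sum(.data$reduction_applied),
      n_total = dplyr::n(),
      median_pct = if (any(.data$reduction_applied)) {
        100 * stats::median(
          .data$normalized_volume_fraction[.data$reduction_applied])
      } else NA_real_,
      mean_pct = if (any(.data$reduction_applied)) {
        100 * mean(.data$normalized_volume_fraction[.data$reduction_applied])
      } else NA_real_,
      max_pct = if (any(.data$reduction_applied)) {
        100 * max(.data$normalized_volume_fraction[.data$reduction_applied])
      } else NA_real_,
      .groups = "drop")
}

#' Read / write a cohort table as CSV
#'
#' The on-disk schema is wide: `patient_id`, the four PFT columns, then one
#' column per modality/threshold fraction named
#' `<modality>_<percent>` (e.g. `ventilation_30`), plus optional
#' `<modality>_normalized_fraction` and `<modality>_reduction_applied`
#' columns. [read_cohort()] pivots this to the long tibble used by
#' [build_correlogram()].
#'
#' @param path CSV path.
#' @return For `read_cohort`, a long cohort tibble; for `write_cohort`,
#'   invisibly `path`.
#' @export
read_cohort <- function(path) {
  wide <- utils::read.csv(path, check.names = FALSE)
  frac_cols <- grep("^(ventilation|perfusion|matched)_[0-9]+$",
                    names(wide), value = TRUE)
  if (length(frac_cols) == 0L) {
    stop("no fractional-volume columns (e.g. 'ventilation_30') in ", path,
         call. = FALSE)
  }
  long <- wide |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(dplyr::all_of(frac_cols),
                        names_to = c("modality", "threshold"),
                        names_pattern = "^(.*)_([0-9]+)$",
                        values_to = "fractional_volume") |>
    dplyr::mutate(threshold = as.numeric(.data$threshold) / 100)
  long$normalized_volume_fraction <- NA_real_
  long$reduction_applied <- NA
  for (mod in c("ventilation", "perfusion")) {
    nf <- paste0(mod, "_normalized_fraction")
    ra <- paste0(mod, "_reduction_applied")
    sel <- long$modality == mod
    if (nf %in% names(long)) {
      long$normalized_volume_fraction[sel] <- long[[nf]][sel]
    }
    if (ra %in% names(long)) {
      long$reduction_applied[sel] <- as.logical(long[[ra]][sel])
    }
  }
  drop <- grep("_(normalized_fraction|reduction_applied)$", names(long),
               value = TRUE)
  dplyr::select(long, -dplyr::all_of(drop))
}

#' @rdname read_cohort
#' @param cohort A long cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  wide <- cohort |>
    dplyr::mutate(col = paste0(.data$modality, "_",
                               round(100 * .data$threshold))) |>
    dplyr::select(-dplyr::any_of(c("modality", "threshold",
                                   "normalized_volume_fraction",
                                   "reduction_applied"))) |>
    tidyr::pivot_wider(names_from = "col",
                       values_from = "fractional_volume")
  if (all(c("normalized_volume_fraction", "reduction_applied") %in%
          names(cohort))) {
    extra <- cohort |>
      dplyr::filter(.data$modality %in% c("ventilation", "perfusion")) |>
      dplyr::distinct(.data$patient_id, .data$modality,
                      .data$normalized_volume_fraction,
                      .data$reduction_applied) |>
      tidyr::pivot_wider(
        names_from = "modality",
        values_from = c("normalized_volume_fraction", "reduction_applied"))
    names(extra) <- sub("^normalized_volume_fraction_(.*)$",
                        "\\1_normalized_fraction", names(extra))
    names(extra) <- sub("^reduction_applied_(.*)$",
                        "\\1_reduction_applied", names(extra))
    wide <- dplyr::left_join(wide, extra, by = "patient_id")
  }
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
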