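#' Fit a thermal melt curve
#'
#' Extracts the melting temperature (Tm, the temperature of 50% unfold)
#' from a dye-based thermal-denaturation trace. The trace is truncated at
#' its global fluorescence maximum — beyond the peak the signal decays as
#' the unfolded protein aggregates and dye is released, which a two-state
#' model does not describe — and a Boltzmann sigmoid
#' `F(T) = B_l + (B_u - B_l) / (1 + exp((Tm - T)/s))`
#' is fitted by nonlinear least squares, initialising Tm at the maximum of
#' the smoothed first derivative (centred moving average, 5 points).
#'
#' @param curve Tibble with columns `temp_c` (strictly increasing) and
#'   `fluorescence`.
#' @param min_points Minimum usable points after truncation.
#' @return A `melt_fit` object: list with `tm` (full precision; round to
#'   0.1 degC for reporting), `slope`, `baseline_lower`, `baseline_upper`,
#'   `residual_norm`, `truncated_at` (temperature of the retained
#'   maximum), `n_points`. Errors with class `"immunopep_no_transition"`
#'   on flat/monotone-decreasing traces or when the fitted transition is
#'   too broad or outside the data to be a genuine unfold.
#' @examples
#' tt <- seq(35, 90)
#' fl <- 1 + 9 / (1 + exp((70 - tt) / 1.5))
#' fit_melt(tibble::tibble(temp_c = tt, fluorescence = fl))$tm # ~70
#' @export
fit_melt <- function(curve, min_points = 10) {
  stopifnot(all(c("temp_c", "fluorescence") %in% names(curve)))
  tt <- curve$temp_c
  ff <- curve$fluorescence
  if (length(tt) < 20 || (max(tt) - min(tt)) < 20) {
    abort("melt curve must have >= 20 points spanning >= 20 degC")
  }
  if (is.unsorted(tt, strictly = TRUE)) {
    abort("temperatures must be strictly increasing")
  }
  # truncate at the global maximum: exclude post-peak aggregation decay
  peak <- which.max(ff)
  if (peak < min_points) {
    abort("fluorescence maximum too early in the trace: no resolvable transition",
          class = "immunopep_no_transition")
  }
  tt <- tt[1:peak]; ff <- ff[1:peak]

  amp <- max(ff) - min(ff)
  if (amp <= 0 || !is.finite(amp)) {
    abort("flat trace: no transition", class = "immunopep_no_transition")
  }
  dsm <- moving_average(diff(ff) / diff(tt), 5)
  tm0 <- tt[which.max(dsm) + 1]
  start <- list(bl = as.numeric(quantile(ff, 0.05)),
                bu = as.numeric(quantile(ff, 0.95)),
                tm = tm0, s = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ff ~ bl + (bu - bl) / (1 + exp((tm - tt) / s)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(paste0("melt fit did not converge: ",
                                     conditionMessage(e)))
  )
  p <- as.list(coef(fit))
  span <- max(tt) - min(tt)
  # a genuine two-state transition is sharp relative to the scan and
  # centred inside it; a line fits only as an absurdly broad sigmoid
  if (abs(p$s) > span / 4 || p$tm < min(tt) || p$tm > max(tt) ||
      (p$bu - p$bl) * sign(p$s) <= 0) {
    abort("no sigmoidal transition detected in the trace",
          class = "immunopep_no_transition")
  }
  structure(
    list(tm = p$tm, slope = p$s, baseline_lower = p$bl, baseline_upper = p$bu,
         residual_norm = sqrt(sum(stats::residuals(fit)^2)),
         truncated_at = tt[length(tt)], n_points = length(tt)),
    class = "melt_fit"
  )
}

moving_average <- function(x, window) {
  stats::filter(x, rep(1 / window, window), sides = 2) |>
    as.numeric() |>
    (\(v) ifelse(is.na(v), x, v))()
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("<melt_fit> Tm =", sprintf("%.1f", x$tm), "degC | slope =",
      round(x$slope, 2), "| residual norm =", signif(x$residual_norm, 3), "\n")
  invisible(x)
}

#' @method glance melt_fit
#' @export
glance.melt_fit <- function(x, ...) {
  tibble(tm = x$tm, slope = x$slope, baseline_lower = x$baseline_lower,
         baseline_upper = x$baseline_upper, residual_norm = x$residual_norm,
         truncated_at = x$truncated_at, n_points = x$n_points)
}

#' Fit every (sample, replicate) melt curve in a long table
#'
#' @param curves Long tibble with columns `sample`, `replicate`, `temp_c`,
#'   `fluorescence`.
#' @return Tibble with one row per (sample, replicate): fitted `tm`,
#'   `slope`, `residual_norm`, and `error` (message for curves that could
#'   not be fitted, `NA` otherwise).
#' @export
fit_melt_curves <- function(curves) {
  stopifnot(all(c("sample", "replicate", "temp_c", "fluorescence") %in% names(curves)))
  curves %>%
    group_by(.data$sample, .data$replicate) %>%
    dplyr::group_modify(function(df, key) {
      res <- tryCatch(fit_melt(arrange(df, .data$temp_c)), error = identity)
      if (inherits(res, "error")) {
        tibble(tm = NA_real_, slope = NA_real_, residual_norm = NA_real_,
               error = conditionMessage(res))
      } else {
        tibble(tm = res$tm, slope = res$slope,
               residual_norm = res$residual_norm, error = NA_character_)
      }
    }) %>%
    ungroup()
}

#' Summarise replicate Tm estimates
#'
#' @param results Tibble with columns `sample` and `tm` (e.g. from
#'   [fit_melt_curves()]); rows with missing `tm` are excluded.
#' @return Tibble per sample: `mean_tm`, `sd_tm` (sample standard
#'   deviation, n-1 denominator; 0 for a single replicate), `n`.
#' @export
summarize_replicates <- function(results) {
  stopifnot(all(c("sample", "tm") %in% names(results)))
  results %>%
    filter(!is.na(.data$tm)) %>%
    group_by(.data$sample) %>%
    summarise(
      mean_tm = mean(.data$tm),
      sd_tm = if (n() > 1) sd(.data$tm) else 0,
      n = n(),
      .groups = "drop"
    )
}

#' Stability change between a variant and a reference complex
#'
#' `delta_tm = mean Tm(variant) - mean Tm(reference)`, classified with the
#' conventional 1 degC rule: changes of magnitude above 1 degC are called
#' stabilising (positive) or destabilising (negative); smaller changes
#' are negligible given typical replicate scatter.
#'
#' @param summaries A [summarize_replicates()] table (columns `sample`,
#'   `mean_tm`, `sd_tm`, `n`).
#' @param variant,reference Sample ids present in `summaries`.
#' @return One-row tibble: `variant`, `reference`, `delta_tm` (rounded to
#'   0.1 degC), `class`.
#' @export
delta_tm <- function(summaries, variant, reference) {
  get_row <- function(id) {
    row <- filter(summaries, .data$sample == id)
    if (nrow(row) != 1) abort(paste0("sample not found (or duplicated): ", id))
    row
  }
  d <- get_row(variant)$mean_tm - get_row(reference)$mean_tm
  d <- round(d, 1)
  tibble(
    variant = variant, reference = reference, delta_tm = d,
    class = dplyr::case_when(d > 1 ~ "stabilising",
                             d < -1 ~ "destabilising",
                             TRUE ~ "negligible")
  )
}

#' Tabulated stability report
#'
#' Builds a per-sample report of mean Tm (to 0.1 degC), replicate sd and
#' n, with one delta-Tm column per requested substitution contrast.
#'
#' @param summaries A [summarize_replicates()] table.
#' @param contrasts Tibble with columns `label`, `variant`, `reference`;
#'   each row adds `delta_tm` / `class` rows to the output.
#' @return Tibble with columns `label`, `variant`, `reference`,
#'   `variant_tm`, `reference_tm`, `delta_tm`, `class`.
#' @export
delta_tm_table <- function(summaries, contrasts) {
  purrr::pmap_dfr(contrasts, function(label, variant, reference) {
    d <- delta_tm(summaries, variant, reference)
    tibble(
      label = label, variant = variant, reference = reference,
      variant_tm = round(filter(summaries, .data$sample == variant)$mean_tm, 1),
      reference_tm = round(filter(summaries, .data$sample == reference)$mean_tm, 1),
      delta_tm = d$delta_tm, class = d$class
    )
  })
}

#' Plot a melt curve with its fitted sigmoid
#'
#' @param curve Tibble with `temp_c`, `fluorescence`.
#' @param fit Optional [fit_melt()] result; computed if omitted.
#' @return A ggplot of the trace, the fitted curve over the retained
#'   region, and a vertical line at Tm.
#' @export
plot_melt_curve <- function(curve, fit = NULL) {
  if (is.null(fit)) fit <- fit_melt(curve)
  tt <- seq(min(curve$temp_c), fit$truncated_at, length.out = 200)
  pred <- tibble(
    temp_c = tt,
    fluorescence = fit$baseline_lower +
      (fit$baseline_upper - fit$baseline_lower) /
      (1 + exp((fit$tm - tt) / fit$slope))
  )
  ggplot(curve, aes(x = .data$temp_c, y = .data$fluorescence)) +
    geom_point(size = 0.8, alpha = 0.6) +
    geom_line(data = pred, colour = "firebrick") +
    geom_vline(xintercept = fit$tm, linetype = "dashed") +
    labs(x = "temperature (degC)", y = "fluorescence (a.u.)",
         subtitle = sprintf("Tm = %.1f degC", fit$tm)) +
    theme_minimal()
}
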