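#' Normalised spectral dot product
#'
#' Similarity between an observed set of fragment areas and a library
#' spectrum: the normalised inner product of square-root-transformed
#' intensities over the union of fragment ids (fragments missing from
#' either side contribute zero), the convention of targeted-proteomics
#' library software. The value is 1 iff the two spectra are proportional
#' and 0 for disjoint fragment sets.
#'
#' @param observed Named numeric vector of fragment areas, or tibble with
#'   columns `fragment`, `area`.
#' @param library_spectrum Named numeric vector of relative intensities,
#'   or tibble with columns `fragment`, `intensity`.
#' @return Dot product in [0, 1]. Completely disjoint fragment sets give
#'   0; exactly one shared fragment is an error (a single matching
#'   transition is no evidence of spectral similarity), as is a spectrum
#'   with fewer than 2 fragments.
#' @examples
#' spectral_dot_product(c(b3 = 100, y5 = 25, y7 = 4),
#'                      c(b3 = 81, y5 = 36, y7 = 9)) # ~0.988
#' @export
spectral_dot_product <- function(observed, library_spectrum) {
  obs <- as_fragment_vector(observed, "area")
  lib <- as_fragment_vector(library_spectrum, "intensity")
  if (length(obs) < 2 || length(lib) < 2) {
    abort("spectra need at least 2 fragments for a dot product")
  }
  n_shared <- length(intersect(names(obs), names(lib)))
  if (n_shared == 0) return(0)
  if (n_shared == 1) {
    abort("only 1 shared fragment id: dot product undefined")
  }
  frags <- union(names(obs), names(lib))
  o <- sqrt(pmax(obs[frags], 0)); o[is.na(o)] <- 0
  l <- sqrt(pmax(lib[frags], 0)); l[is.na(l)] <- 0
  denom <- sqrt(sum(o^2)) * sqrt(sum(l^2))
  if (denom == 0) return(0)
  as.numeric(sum(o * l) / denom)
}

as_fragment_vector <- function(x, value_col) {
  if (is.data.frame(x)) {
    stopifnot(all(c("fragment", value_col) %in% names(x)))
    setNames(x[[value_col]], x$fragment)
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

#' Validate MRM peptide detections
#'
#' A (peptide, experiment) pair is a detection *candidate* when all of the
#' peptide's configured transitions were observed co-eluting (retention-
#' time spread within `co_elution_tol`). Candidates accompanied by an
#' MRM-triggered MS/MS event in that experiment are `ms2_confirmed`.
#' Remaining candidates are `rt_dotp_rescued` iff the peptide has at
#' least one confirmed detection, the candidate's retention time lies
#' within `rt_window` (inclusive) of the mean retention time of those
#' confirmed detections, and the spectral dot product against the library
#' exceeds `dotp_threshold` (strict); otherwise they are `rejected` with
#' the failed requirement recorded.
#'
#' @param transitions Tibble with columns `peptide`, `fragment`,
#'   `experiment`, `rt_min`, `area`, `ms2_triggered` (logical).
#' @param library_spectra Tibble with columns `peptide`, `fragment`,
#'   `intensity`.
#' @param co_elution_tol Maximum retention-time spread (min) across a
#'   peptide's transitions for them to count as co-eluting. Default 0.2.
#' @param rt_window Retention-time window (min) for rescue, inclusive.
#'   Default 1.5.
#' @param dotp_threshold Dot-product threshold for rescue, strict.
#'   Default 0.7.
#' @return Tibble of `DetectionResult`s: `peptide`, `experiment`,
#'   `validated`, `basis` (`ms2_confirmed` / `rt_dotp_rescued` /
#'   `rejected`), `dotp`, `rt` (mean transition RT), `rt_delta` (vs the
#'   confirmed mean; `NA` when no confirmed detection exists), `reason`.
#' @export
validate_detections <- function(transitions, library_spectra,
                                co_elution_tol = 0.2, rt_window = 1.5,
                                dotp_threshold = 0.7) {
  transitions <- as_tibble(transitions)
  req <- c("peptide", "fragment", "experiment", "rt_min", "area", "ms2_triggered")
  stopifnot(all(req %in% names(transitions)))

  n_frag <- transitions %>%
    distinct(.data$peptide, .data$fragment) %>%
    count(.data$peptide)
  bad <- n_frag$peptide[n_frag$n < 3]
  if (length(bad)) {
    abort(paste0("peptides with fewer than 3 configured transitions: ",
                 paste(bad, collapse = ", ")))
  }

  cand <- transitions %>%
    group_by(.data$peptide, .data$experiment) %>%
    summarise(
      n_obs = dplyr::n_distinct(.data$fragment),
      rt = mean(.data$rt_min),
      rt_spread = max(.data$rt_min) - min(.data$rt_min),
      ms2 = any(.data$ms2_triggered),
      .groups = "drop"
    ) %>%
    left_join(rename(n_frag, n_config = "n"), by = "peptide") %>%
    mutate(candidate = .data$n_obs == .data$n_config &
             .data$rt_spread <= co_elution_tol)

  dotp_for <- function(pep, exp) {
    obs <- transitions %>%
      filter(.data$peptide == pep, .data$experiment == exp) %>%
      group_by(.data$fragment) %>%
      summarise(area = sum(.data$area), .groups = "drop")
    lib <- library_spectra %>% filter(.data$peptide == pep)
    if (nrow(lib) < 2) return(NA_real_)
    spectral_dot_product(obs, lib)
  }
  cand$dotp <- purrr::map2_dbl(cand$peptide, cand$experiment, dotp_for)

  confirmed_rt <- cand %>%
    filter(.data$candidate, .data$ms2) %>%
    group_by(.data$peptide) %>%
    summarise(mean_rt = mean(.data$rt), .groups = "drop")

  cand %>%
    left_join(confirmed_rt, by = "peptide") %>%
    mutate(
      rt_delta = .data$rt - .data$mean_rt,
      basis = dplyr::case_when(
        !.data$candidate ~ "rejected",
        .data$ms2 ~ "ms2_confirmed",
        !is.na(.data$rt_delta) & abs(.data$rt_delta) <= rt_window &
          .data$dotp > dotp_threshold ~ "rt_dotp_rescued",
        TRUE ~ "rejected"
      ),
      validated = .data$basis != "rejected",
      reason = dplyr::case_when(
        .data$basis != "rejected" ~ NA_character_,
        !.data$candidate ~ "transitions missing or not co-eluting",
        is.na(.data$rt_delta) ~ "no ms2-confirmed detection to anchor RT",
        abs(.data$rt_delta) > rt_window ~ "outside RT window",
        TRUE ~ "dot product at or below threshold"
      )
    ) %>%
    select("peptide", "experiment", "validated", "basis", "dotp",
           "rt", "rt_delta", "reason")
}

#' Normalised relative abundance of validated detections
#'
#' For each validated (peptide, experiment), the combined peak area over
#' the peptide's transitions is divided by that experiment's
#' beta-2-microglobulin (beta2m) area — the amount of HLA purified — to
#' correct for loading; the normalised abundance is then expressed as a
#' proportion of the peptide's maximum across all experiments in the
#' call, so values are comparable across samples despite the absence of
#' absolute quantitation.
#'
#' @param detections Output of [validate_detections()] (or any tibble
#'   with `peptide`, `experiment`, `validated`).
#' @param transitions The transition table (for the areas).
#' @param norms Tibble with columns `experiment`, `beta2m_area`
#'   (strictly positive).
#' @return Tibble with `peptide`, `experiment`, `total_area`,
#'   `normalised`, `proportion_of_max`; the maximum per peptide is
#'   exactly 1.
#' @export
relative_abundance <- function(detections, transitions, norms) {
  stopifnot(all(c("experiment", "beta2m_area") %in% names(norms)))
  if (any(!is.finite(norms$beta2m_area) | norms$beta2m_area <= 0)) {
    abort("beta2m normalisation factors must be strictly positive")
  }
  valid <- filter(as_tibble(detections), .data$validated)
  missing_norm <- setdiff(unique(valid$experiment), norms$experiment)
  if (length(missing_norm)) {
    abort(paste0("no beta2m factor for experiment(s): ",
                 paste(missing_norm, collapse = ", ")))
  }
  valid %>%
    inner_join(
      transitions %>%
        group_by(.data$peptide, .data$experiment) %>%
        summarise(total_area = sum(.data$area), .groups = "drop"),
      by = c("peptide", "experiment")
    ) %>%
    left_join(norms, by = "experiment") %>%
    mutate(normalised = .data$total_area / .data$beta2m_area) %>%
    group_by(.data$peptide) %>%
    mutate(proportion_of_max = .data$normalised / max(.data$normalised)) %>%
    ungroup() %>%
    select("peptide", "experiment", "total_area", "normalised",
           "proportion_of_max")
}

#' Plot relative abundances across experiments
#'
#' @param abundance Output of [relative_abundance()].
#' @param group_map Optional tibble mapping `experiment` to a display
#'   group (e.g. allotype); joined when supplied.
#' @return A ggplot of proportion-of-max per peptide and experiment.
#' @export
plot_relative_abundance <- function(abundance, group_map = NULL) {
  df <- abundance
  if (!is.null(group_map)) df <- left_join(df, group_map, by = "experiment")
  colour_var <- if (!is.null(group_map)) names(group_map)[2] else "experiment"
  ggplot(df, aes(x = .data$peptide, y = .data$proportion_of_max,
                 colour = .data[[colour_var]])) +
    geom_point(position = position_dodge(width = 0.5), size = 2) +
    labs(x = NULL, y = "proportion of maximum normalised area") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
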