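#' Build a position-specific residue profile with anchor biases
#'
#' Non-anchor positions follow the background amino-acid frequencies;
#' anchor positions mix the stated residue preferences with the
#' background renormalised over the remaining probability mass. This is
#' the generative structure of an eluted-ligand motif: a handful of
#' strongly constrained pockets over an otherwise proteome-like
#' composition.
#'
#' @param L Peptide length.
#' @param anchors Named list: names are positions (as characters, or the
#'   special names `"omega"` and `"omega_minus_2"`), values are named
#'   numeric vectors of residue probabilities (summing to < 1; the rest
#'   is background).
#' @param background Named frequencies over the 20 amino acids.
#' @return An `L x 20` row-stochastic matrix (rows = positions).
#' @export
anchor_profile <- function(L, anchors = list(),
                           background = swissprot_human_frequencies()) {
  bg <- as.numeric(unclass(background)[AA20])
  prof <- matrix(rep(bg, each = L), nrow = L, dimnames = list(NULL, AA20))
  for (nm in names(anchors)) {
    pos <- switch(nm,
                  omega = p_omega(L),
                  omega_minus_2 = p_omega(L, 2),
                  as.integer(nm))
    stopifnot(pos >= 1, pos <= L)
    pref <- anchors[[nm]]
    stopifnot(all(names(pref) %in% AA20), sum(pref) < 1, all(pref >= 0))
    row <- bg
    row[match(names(pref), AA20)] <- 0
    row <- row / sum(row) * (1 - sum(pref))
    row[match(names(pref), AA20)] <- pref
    prof[pos, ] <- row
  }
  prof
}

#' Specify a synthetic peptide repertoire
#'
#' @param n Number of true-ligand records to draw.
#' @param length_weights Named numeric vector of length probabilities
#'   (names = lengths), e.g. `c("9" = 0.6, "10" = 0.25, "11" = 0.15)`.
#' @param profiles Named list (names = lengths) of `L x 20` position
#'   profile matrices, e.g. from [anchor_profile()].
#' @param couplings List of injected inter-position couplings, each a
#'   list with `length`, `i`, `j`, `joint` (20 x 20 joint distribution
#'   over residue pairs, dimnames = amino acids) and `weight` (mixing
#'   probability in [0, 1]: with this probability the residue pair at
#'   `(i, j)` is drawn jointly instead of independently).
#' @param confidence_true,confidence_low,confidence_contaminant
#'   `c(min, max)` ranges for uniform confidence draws of confident true
#'   ligands, the under-sampled low-confidence tail, and contaminants.
#' @param low_confidence_fraction Fraction of true ligands assigned a
#'   confidence from `confidence_low`.
#' @param contaminant_sequences Character vector spiked in as contaminant
#'   records.
#' @param contaminant_fraction Contaminant records as a fraction of `n`.
#' @param allotype,n_replicates Labels written into the table.
#' @param seed Mandatory seed: generation is a pure function of the spec.
#' @return A `repertoire_spec` list.
#' @export
repertoire_spec <- function(n, length_weights, profiles, couplings = list(),
                            confidence_true = c(96, 100),
                            confidence_low = c(30, 94.9),
                            low_confidence_fraction = 0.1,
                            confidence_contaminant = c(50, 99),
                            contaminant_sequences = character(),
                            contaminant_fraction = 0,
                            allotype = "synthetic", n_replicates = 3,
                            seed) {
  stopifnot(!missing(seed), n >= 1,
            abs(sum(length_weights) - 1) < 1e-9,
            all(names(length_weights) %in% names(profiles)),
            low_confidence_fraction >= 0, low_confidence_fraction <= 1,
            contaminant_fraction >= 0)
  for (cp in couplings) {
    stopifnot(all(c("length", "i", "j", "joint", "weight") %in% names(cp)),
              cp$weight >= 0, cp$weight <= 1,
              abs(sum(cp$joint) - 1) < 1e-9)
  }
  structure(
    list(n = n, length_weights = length_weights, profiles = profiles,
         couplings = couplings, confidence_true = confidence_true,
         confidence_low = confidence_low,
         low_confidence_fraction = low_confidence_fraction,
         confidence_contaminant = confidence_contaminant,
         contaminant_sequences = contaminant_sequences,
         contaminant_fraction = contaminant_fraction,
         allotype = allotype, n_replicates = n_replicates, seed = seed),
    class = "repertoire_spec"
  )
}

#' Simulate a peptide-identification table
#'
#' Draws peptides position-independently from the per-length profiles,
#' except at injected coupling pairs where, with probability equal to the
#' mixing weight, the residue pair is drawn from its joint distribution.
#' Confidences are drawn from the specified ranges, contaminant records
#' are appended, and rows are assigned to replicates. Output is in the
#' dialect read by [read_peptide_table()] / [filter_repertoire()]; the
#' same spec (including seed) always yields the identical table.
#'
#' @param spec A [repertoire_spec()].
#' @return Tibble with columns `sequence`, `modifications`, `confidence`,
#'   `allotype`, `replicate`, plus a logical `is_contaminant` column
#'   carrying the ground truth.
#' @export
simulate_repertoire <- function(spec) {
  stopifnot(inherits(spec, "repertoire_spec"))
  withr::with_seed(spec$seed, {
    len_values <- as.integer(names(spec$length_weights))
    lens <- len_values[sample.int(length(len_values), spec$n, replace = TRUE,
                                  prob = spec$length_weights)]
    seqs <- character(spec$n)
    for (Lc in unique(lens)) {
      idx <- which(lens == Lc)
      prof <- spec$profiles[[as.character(Lc)]]
      mat <- vapply(seq_len(Lc), function(j) {
        sample(AA20, length(idx), replace = TRUE, prob = prof[j, ])
      }, character(length(idx)))
      if (length(idx) == 1) mat <- matrix(mat, nrow = 1)
      for (cp in spec$couplings) {
        if (cp$length != Lc) next
        use_joint <- runif(length(idx)) < cp$weight
        if (any(use_joint)) {
          cells <- sample(400L, sum(use_joint), replace = TRUE,
                          prob = as.numeric(cp$joint))
          mat[use_joint, cp$i] <- rownames(cp$joint)[(cells - 1L) %% 20L + 1L]
          mat[use_joint, cp$j] <- colnames(cp$joint)[(cells - 1L) %/% 20L + 1L]
        }
      }
      seqs[idx] <- apply(mat, 1, paste0, collapse = "")
    }
    low <- runif(spec$n) < spec$low_confidence_fraction
    conf <- ifelse(low,
                   runif(spec$n, spec$confidence_low[1], spec$confidence_low[2]),
                   runif(spec$n, spec$confidence_true[1], spec$confidence_true[2]))
    out <- tibble(
      sequence = seqs, modifications = "", confidence = round(conf, 1),
      allotype = spec$allotype,
      replicate = paste0("rep", sample.int(spec$n_replicates, spec$n, replace = TRUE)),
      is_contaminant = FALSE
    )
    n_cont <- round(spec$contaminant_fraction * spec$n)
    if (n_cont > 0 && length(spec$contaminant_sequences)) {
      cont <- tibble(
        sequence = sample(spec$contaminant_sequences, n_cont, replace = TRUE),
        modifications = "",
        confidence = round(runif(n_cont, spec$confidence_contaminant[1],
                                 spec$confidence_contaminant[2]), 1),
        allotype = spec$allotype,
        replicate = paste0("rep", sample.int(spec$n_replicates, n_cont, replace = TRUE)),
        is_contaminant = TRUE
      )
      out <- bind_rows(out, cont)
    }
    out
  })
}

#' Bundled B57-family-like example specs
#'
#' Three synthetic "allotypes" mirroring the qualitative contrasts of the
#' HLA-B57 family: all share Ser/Thr/Ala/Val-biased P2 and aromatic
#' C termini; `"B5701-like"` and `"B5801-like"` are Trp-major at P-omega
#' while `"B5703-like"` is Phe-major; only `"B5701-like"` enriches Arg at
#' the secondary anchor P-omega-2 (the others deplete it, `"B5703-like"`
#' favouring Pro and `"B5801-like"` Glu instead). A P2-P-omega joint
#' coupling is injected into the 9mers of every allotype.
#'
#' @param allotype One of `"B5701-like"`, `"B5703-like"`, `"B5801-like"`.
#' @param n Number of true ligands.
#' @param seed Seed (each allotype should get a distinct one).
#' @param contaminant_sequences,contaminant_fraction Passed through to
#'   [repertoire_spec()].
#' @return A [repertoire_spec()].
#' @export
b57_example_spec <- function(allotype = c("B5701-like", "B5703-like", "B5801-like"),
                             n = 3000, seed,
                             contaminant_sequences = character(),
                             contaminant_fraction = 0) {
  allotype <- match.arg(allotype)
  p2 <- c(S = 0.35, T = 0.18, A = 0.15, V = 0.10)
  omega <- switch(allotype,
    "B5701-like" = c(W = 0.50, F = 0.20, Y = 0.15),
    "B5703-like" = c(F = 0.45, W = 0.22, Y = 0.10, L = 0.06, M = 0.03),
    "B5801-like" = c(W = 0.48, F = 0.22, Y = 0.14)
  )
  omega2 <- switch(allotype,
    "B5701-like" = c(R = 0.12, K = 0.07, E = 0.08),
    "B5703-like" = c(R = 0.002, K = 0.01, P = 0.11, E = 0.07),
    "B5801-like" = c(R = 0.002, K = 0.01, E = 0.13)
  )
  profiles <- lapply(setNames(9:11, 9:11), function(L) {
    anchor_profile(L, anchors = list(`2` = p2, omega = omega,
                                     omega_minus_2 = omega2))
  })
  # joint P2-Pomega preference: Ser pairs with the allotype's major
  # aromatic, Ala with its minor one
  major <- names(omega)[1]; minor <- names(omega)[2]
  joint <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  joint["S", major] <- 0.45
  joint["A", minor] <- 0.25
  joint["T", major] <- 0.20
  joint["V", minor] <- 0.10
  couplings <- list(list(length = 9L, i = 2L, j = 9L, joint = joint,
                         weight = 0.5))
  repertoire_spec(
    n = n,
    length_weights = c(`9` = 0.6, `10` = 0.25, `11` = 0.15),
    profiles = profiles, couplings = couplings,
    contaminant_sequences = contaminant_sequences,
    contaminant_fraction = contaminant_fraction,
    allotype = allotype, seed = seed
  )
}

#' Specify a synthetic MRM experiment
#'
#' @param truth Numeric matrix of ground-truth relative abundances,
#'   rows = peptides (rownames), columns = experiments (colnames);
#'   0 means the peptide is absent from that experiment.
#' @param n_fragments Transitions per peptide (3 or 4).
#' @param area_sdlog Lognormal multiplicative noise (sdlog) on transition
#'   areas.
#' @param rt_jitter_sd Gaussian jitter (min) on retention times.
#' @param loading Named per-experiment loading factors (how much HLA was
#'   purified); beta-2-microglobulin areas scale with these.
#' @param beta2m_base Beta2m area at loading 1.
#' @param ms2_trigger_prob Probability that a present peptide triggers
#'   MS/MS in an experiment.
#' @param never_triggered Peptide ids that never trigger MS/MS (their
#'   detections can only be rescued or rejected).
#' @param seed Mandatory seed.
#' @return An `mrm_sim_spec` list.
#' @export
mrm_sim_spec <- function(truth, n_fragments = 4, area_sdlog = 0.2,
                         rt_jitter_sd = 0.05, loading = NULL,
                         beta2m_base = 1e6, ms2_trigger_prob = 0.8,
                         never_triggered = character(), seed) {
  stopifnot(!missing(seed), is.matrix(truth), !is.null(rownames(truth)),
            !is.null(colnames(truth)), all(truth >= 0),
            n_fragments >= 3, n_fragments <= 4)
  if (is.null(loading)) loading <- setNames(rep(1, ncol(truth)), colnames(truth))
  stopifnot(all(colnames(truth) %in% names(loading)), all(loading > 0))
  structure(
    list(truth = truth, n_fragments = n_fragments, area_sdlog = area_sdlog,
         rt_jitter_sd = rt_jitter_sd, loading = loading[colnames(truth)],
         beta2m_base = beta2m_base, ms2_trigger_prob = ms2_trigger_prob,
         never_triggered = never_triggered, seed = seed),
    class = "mrm_sim_spec"
  )
}

#' Simulate MRM transition data with known ground truth
#'
#' Each peptide gets `n_fragments` library fragments with random relative
#' intensities and a retention time; observed transition areas are
#' `truth x fragment intensity x experiment loading x lognormal noise`,
#' and the beta2m normalisation factor of each experiment scales with its
#' loading, so normalisation recovers the truth up to noise.
#'
#' @param spec An [mrm_sim_spec()].
#' @return List with `transitions` (tibble in the
#'   [validate_detections()] dialect), `library` (peptide, fragment,
#'   intensity), `norms` (experiment, beta2m_area) and `truth` (long
#'   tibble of the generating abundances).
#' @export
simulate_mrm <- function(spec) {
  stopifnot(inherits(spec, "mrm_sim_spec"))
  withr::with_seed(spec$seed, {
    peptides <- rownames(spec$truth)
    experiments <- colnames(spec$truth)
    lib <- purrr::map_dfr(peptides, function(p) {
      tibble(peptide = p,
             fragment = paste0("y", seq_len(spec$n_fragments) + 2),
             intensity = sort(runif(spec$n_fragments, 0.2, 1), decreasing = TRUE))
    })
    rt_mean <- setNames(runif(length(peptides), 10, 60), peptides)
    rows <- list()
    for (p in peptides) {
      libp <- filter(lib, .data$peptide == p)
      for (e in experiments) {
        ab <- spec$truth[p, e]
        if (ab <= 0) next
        rt <- rt_mean[p] + rnorm(1, 0, spec$rt_jitter_sd)
        trig <- !(p %in% spec$never_triggered) &&
          runif(1) < spec$ms2_trigger_prob
        rows[[length(rows) + 1]] <- tibble(
          peptide = p, fragment = libp$fragment, experiment = e,
          rt_min = rt + rnorm(spec$n_fragments, 0, 0.01),
          area = ab * libp$intensity * spec$loading[e] *
            exp(rnorm(spec$n_fragments, 0, spec$area_sdlog)),
          ms2_triggered = trig
        )
      }
    }
    truth_long <- as_tibble(as.data.frame.table(spec$truth,
                                                responseName = "abundance",
                                                stringsAsFactors = FALSE)) %>%
      rename(peptide = "Var1", experiment = "Var2")
    list(
      transitions = bind_rows(rows),
      library = lib,
      norms = tibble(experiment = experiments,
                     beta2m_area = spec$beta2m_base *
                       as.numeric(spec$loading[experiments])),
      truth = truth_long
    )
  })
}

#' Specify synthetic thermal melt curves
#'
#' @param samples Tibble with columns `sample` and `tm` (true melting
#'   temperatures, degC, within 40-85).
#' @param slope Sigmoid slope parameter s (degC).
#' @param baseline_lower,baseline_upper Fluorescence baselines.
#' @param decay_rate Post-peak aggregation decay rate (per degC) applied
#'   beyond `tm + decay_onset`.
#' @param decay_onset Degrees above Tm at which the decay begins.
#' @param noise_sd Gaussian noise, as a fraction of the amplitude.
#' @param n_replicates Replicates per sample.
#' @param seed Mandatory seed.
#' @return A `melt_sim_spec` list.
#' @export
melt_sim_spec <- function(samples, slope = 1.5, baseline_lower = 1,
                          baseline_upper = 10, decay_rate = 0.05,
                          decay_onset = 5, noise_sd = 0.02,
                          n_replicates = 4, seed) {
  stopifnot(!missing(seed), all(c("sample", "tm") %in% names(samples)),
            all(samples$tm >= 40 & samples$tm <= 85),
            baseline_upper > baseline_lower, slope > 0)
  structure(
    list(samples = as_tibble(samples), slope = slope,
         baseline_lower = baseline_lower, baseline_upper = baseline_upper,
         decay_rate = decay_rate, decay_onset = decay_onset,
         noise_sd = noise_sd, n_replicates = n_replicates, seed = seed),
    class = "melt_sim_spec"
  )
}

#' Simulate dye-based melt curves
#'
#' Generates, per sample and replicate, a 35-90 degC trace at 1 degC
#' steps: a Boltzmann sigmoid with the sample's Tm, attenuated beyond
#' `tm + decay_onset` by an exponential aggregation decay, plus Gaussian
#' noise.
#'
#' @param spec A [melt_sim_spec()].
#' @return Long tibble with columns `sample`, `replicate`, `temp_c`,
#'   `fluorescence`, as read by [fit_melt_curves()].
#' @export
simulate_melt <- function(spec) {
  stopifnot(inherits(spec, "melt_sim_spec"))
  amp <- spec$baseline_upper - spec$baseline_lower
  tt <- seq(35, 90, by = 1)
  withr::with_seed(spec$seed, {
    purrr::map_dfr(seq_len(nrow(spec$samples)), function(i) {
      s <- spec$samples[i, ]
      purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
        clean <- spec$baseline_lower +
          amp / (1 + exp((s$tm - tt) / spec$slope)) *
          exp(-spec$decay_rate * pmax(0, tt - (s$tm + spec$decay_onset)))
        tibble(
          sample = s$sample, replicate = paste0("rep", r), temp_c = tt,
          fluorescence = clean + rnorm(length(tt), 0, spec$noise_sd * amp)
        )
      })
    })
  })
}
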