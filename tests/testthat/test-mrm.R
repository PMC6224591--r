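test_that("spectral dot product follows the square-root-intensity convention", {
  lib <- c(b3 = 81, y5 = 36, y7 = 9)
  expect_equal(spectral_dot_product(lib, lib), 1.0)
  expect_equal(spectral_dot_product(c(b3 = 100, y5 = 25, y7 = 4), lib),
               0.9883037, tolerance = 1e-6)
  # proportional spectra are identical up to scale
  expect_equal(spectral_dot_product(lib * 7.3, lib), 1.0)
  # symmetry
  obs <- c(b3 = 100, y5 = 25, y7 = 4)
  expect_equal(spectral_dot_product(obs, lib), spectral_dot_product(lib, obs))
  # disjoint fragment sets padded over the union
  expect_equal(spectral_dot_product(c(b2 = 10, y3 = 5), c(y6 = 4, y8 = 2)), 0)
  # one shared fragment, or tiny spectra, are errors
  expect_error(spectral_dot_product(c(b3 = 10, y9 = 5), lib), "1 shared")
  expect_error(spectral_dot_product(c(b3 = 10), lib), "at least 2 fragments")
  # tibble input
  expect_equal(spectral_dot_product(
    tibble::tibble(fragment = names(obs), area = unname(obs)),
    tibble::tibble(fragment = names(lib), intensity = unname(lib))),
    0.9883037, tolerance = 1e-6)
})

# a small hand-built MRM data set: peptide PEP1 with 4 transitions
make_mrm_fixture <- function() {
  lib <- tibble::tibble(
    peptide = "PEP1",
    fragment = c("y3", "y4", "y5", "y6"),
    intensity = c(1, 0.8, 0.5, 0.2)
  )
  tr_row <- function(exp, rt, scale, trig, intens = c(1, 0.8, 0.5, 0.2)) {
    tibble::tibble(peptide = "PEP1", fragment = c("y3", "y4", "y5", "y6"),
                   experiment = exp, rt_min = rt, area = scale * intens,
                   ms2_triggered = trig)
  }
  list(lib = lib, tr_row = tr_row)
}

test_that("detection validation implements the confirm/rescue/reject rule table", {
  fx <- make_mrm_fixture()
  transitions <- dplyr::bind_rows(
    fx$tr_row("e1", 20.0, 1000, TRUE),   # co-eluting + trigger -> confirmed
    fx$tr_row("e2", 20.4, 500, FALSE),   # RT 0.4 off, dotp 1 -> rescued
    fx$tr_row("e3", 22.0, 500, FALSE),   # RT 2.0 off -> rejected despite dotp 1
    fx$tr_row("e4", 21.5, 500, FALSE),   # RT delta exactly 1.5 -> rescued (inclusive)
    fx$tr_row("e5", 21.6, 500, FALSE)    # RT delta 1.6 -> rejected
  )
  det <- validate_detections(transitions, fx$lib)
  basis <- setNames(det$basis, det$experiment)
  expect_equal(unname(basis[c("e1", "e2", "e3", "e4", "e5")]),
               c("ms2_confirmed", "rt_dotp_rescued", "rejected",
                 "rt_dotp_rescued", "rejected"))
  expect_equal(det$reason[det$experiment == "e3"], "outside RT window")
  expect_true(all(det$dotp > 0.99))

  # dotp threshold is strict: a perfect dotp of 1 does not pass "> 1"
  det_strict <- validate_detections(transitions, fx$lib, dotp_threshold = 1)
  expect_equal(det_strict$basis[det_strict$experiment == "e2"], "rejected")
  expect_match(det_strict$reason[det_strict$experiment == "e2"], "dot product")
})

test_that("non-co-eluting or incomplete transition sets are not candidates", {
  fx <- make_mrm_fixture()
  spread <- fx$tr_row("e1", 20, 1000, TRUE)
  spread$rt_min <- c(20.0, 20.1, 20.5, 20.0) # spread 0.5 > 0.2 tolerance
  det <- validate_detections(spread, fx$lib)
  expect_equal(det$basis, "rejected")
  expect_match(det$reason, "co-eluting")

  missing <- fx$tr_row("e1", 20, 1000, TRUE)[-2, ]
  extra <- fx$tr_row("e2", 20, 1000, TRUE) # establishes 4 configured transitions
  det2 <- validate_detections(dplyr::bind_rows(missing, extra), fx$lib)
  expect_equal(det2$basis[det2$experiment == "e1"], "rejected")

  # fewer than 3 configured transitions is a hard error
  few <- fx$tr_row("e1", 20, 1000, TRUE)[1:2, ]
  expect_error(validate_detections(few, fx$lib), "fewer than 3")
})

test_that("a peptide never confirmed anywhere cannot be rescued", {
  fx <- make_mrm_fixture()
  transitions <- fx$tr_row("e1", 20, 500, FALSE)
  det <- validate_detections(transitions, fx$lib)
  expect_equal(det$basis, "rejected")
  expect_match(det$reason, "no ms2-confirmed")
})

test_that("beta2m normalisation cancels loading and proportions peak at 1", {
  det <- tibble::tibble(peptide = "PEP1", experiment = c("e1", "e2"),
                        validated = TRUE)
  transitions <- tibble::tibble(
    peptide = "PEP1", fragment = rep(c("y3", "y4", "y5"), 2),
    experiment = rep(c("e1", "e2"), each = 3),
    rt_min = 20, area = c(500, 300, 200, 250, 150, 100), ms2_triggered = TRUE
  )
  norms <- tibble::tibble(experiment = c("e1", "e2"), beta2m_area = c(2000, 1000))
  ab <- relative_abundance(det, transitions, norms)
  expect_equal(ab$normalised, c(0.5, 0.5))
  expect_equal(ab$proportion_of_max, c(1, 1))

  # single detection -> proportion 1
  ab1 <- relative_abundance(det[1, ], transitions, norms)
  expect_equal(ab1$proportion_of_max, 1)

  # scaling one experiment's areas and beta2m together changes nothing
  tr2 <- transitions
  tr2$area[tr2$experiment == "e1"] <- tr2$area[tr2$experiment == "e1"] * 37
  norms2 <- norms
  norms2$beta2m_area[1] <- norms2$beta2m_area[1] * 37
  ab2 <- relative_abundance(det, tr2, norms2)
  expect_equal(ab2$proportion_of_max, ab$proportion_of_max)

  expect_error(relative_abundance(det, transitions, norms[1, ]), "no beta2m")
  bad <- norms; bad$beta2m_area[1] <- 0
  expect_error(relative_abundance(det, transitions, bad), "strictly positive")
})

test_that("noise-free simulation recovers truth proportions exactly", {
  truth <- matrix(c(10, 5, 1,
                    2, 8, 4), nrow = 2, byrow = TRUE,
                  dimnames = list(c("PEPA", "PEPB"), c("e1", "e2", "e3")))
  sim <- simulate_mrm(mrm_sim_spec(truth, area_sdlog = 0, rt_jitter_sd = 0,
                                   loading = c(e1 = 1, e2 = 2, e3 = 0.5),
                                   ms2_trigger_prob = 1, seed = 4))
  det <- validate_detections(sim$transitions, sim$library)
  expect_true(all(det$validated))
  ab <- relative_abundance(det, sim$transitions, sim$norms)
  for (p in rownames(truth)) {
    got <- ab[ab$peptide == p, ]
    want <- truth[p, got$experiment] / max(truth[p, ])
    expect_equal(got$proportion_of_max, unname(want), tolerance = 1e-12)
  }
})

test_that("recovered proportions rank-correlate with truth under lognormal noise", {
  withr::with_seed(9, {
    truth <- matrix(rlnorm(20 * 9, 1, 1), nrow = 20,
                    dimnames = list(paste0("P", 1:20), paste0("e", 1:9)))
  })
  sim <- simulate_mrm(mrm_sim_spec(truth, area_sdlog = 0.2,
                                   ms2_trigger_prob = 1, seed = 10))
  det <- validate_detections(sim$transitions, sim$library)
  ab <- relative_abundance(det, sim$transitions, sim$norms)
  truth_prop <- sim$truth %>%
    dplyr::group_by(peptide) %>%
    dplyr::mutate(truth_prop = abundance / max(abundance)) %>%
    dplyr::ungroup()
  joined <- dplyr::inner_join(ab, truth_prop, by = c("peptide", "experiment"))
  expect_gt(cor(joined$proportion_of_max, joined$truth_prop,
                method = "spearman"), 0.9)
})

test_that("a never-triggered peptide with aberrant RT is rejected end to end", {
  truth <- matrix(c(5, 5, 5), nrow = 1, dimnames = list("PEPX", paste0("e", 1:3)))
  sim <- simulate_mrm(mrm_sim_spec(truth, never_triggered = "PEPX",
                                   ms2_trigger_prob = 1, seed = 12))
  det <- validate_detections(sim$transitions, sim$library)
  expect_true(all(det$basis == "rejected"))
})
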