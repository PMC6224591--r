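test_that("length distribution covers the range plus an 'other' bucket", {
  one <- tibble::tibble(sequence = "LSSPVTKSF")
  ld <- length_distribution(one)
  expect_equal(ld$proportion[ld$length == "9"], 1)
  expect_equal(sum(ld$proportion), 1)

  spec <- b57_example_spec("B5701-like", n = 20000, seed = 21)
  tab <- simulate_repertoire(spec)
  ld2 <- length_distribution(tab)
  got <- setNames(ld2$proportion, ld2$length)
  for (L in c("9", "10", "11")) {
    expect_lt(abs(got[[L]] - c(`9` = 0.6, `10` = 0.25, `11` = 0.15)[[L]]), 0.02)
  }
  expect_equal(ld2$length[which.max(ld2$count)], "9") # nonamer mode
})

test_that("position frequency matrices tabulate residues exactly", {
  pfm <- position_frequency_matrix(tibble::tibble(sequence = "LSSPVTKSF"), 9)
  expect_equal(unname(pfm$counts[1, "L"]), 1)
  expect_equal(sum(pfm$counts[1, ]), 1)

  pfm2 <- position_frequency_matrix(
    tibble::tibble(sequence = c("AAAAAAAAA", "CCCCCCCCC")), 9)
  expect_true(all(pfm2$freqs[, "A"] == 0.5))
  expect_true(all(pfm2$freqs[, "C"] == 0.5))
  expect_true(all(rowSums(pfm2$counts) == pfm2$n))
  expect_true(all(abs(rowSums(pfm2$freqs) - 1) < 1e-9))

  expect_error(position_frequency_matrix(tibble::tibble(sequence = "AAAA"), 9),
               "no peptides of length 9")
})

test_that("empirical position frequencies track the generating profile", {
  prof <- anchor_profile(9, anchors = list(`2` = c(S = 0.4, T = 0.2),
                                           omega = c(W = 0.5, F = 0.3)))
  seqs <- random_peptides(4000, 9, prof, seed = 7)
  pfm <- position_frequency_matrix(tibble::tibble(sequence = seqs), 9)
  tol <- 3 * sqrt(prof * (1 - prof) / pfm$n)
  expect_true(all(abs(pfm$freqs - prof) <= tol + 1e-12))
})

test_that("motif summary applies the prevalence threshold and ordering", {
  # exact composition at position 2: 45% S, 30% T, 15% A, 10% G
  seqs <- paste0("L", c(rep("S", 45), rep("T", 30), rep("A", 15), rep("G", 10)),
                 "SPVTKSF")
  pfm <- position_frequency_matrix(tibble::tibble(sequence = seqs), 9)
  ms <- motif_summary(pfm, min_prevalence = 0.10)
  p2 <- ms[ms$position == 2, ]
  expect_equal(p2$aa, c("S", "T", "A", "G"))
  p2_strict <- motif_summary(pfm, min_prevalence = 0.12)
  expect_equal(p2_strict$aa[p2_strict$position == 2], c("S", "T", "A"))

  # uniform position: nothing reaches 10%
  useqs <- random_peptides(2000, 9, seed = 9) # uniform 1/20 per residue
  pfmu <- position_frequency_matrix(tibble::tibble(sequence = useqs), 9)
  msu <- motif_summary(pfmu, min_prevalence = 0.10)
  expect_equal(nrow(msu[msu$position == 5, ]), 0)
})

test_that("background frequencies come from the embedded table or a FASTA", {
  emb <- swissprot_human_frequencies()
  expect_equal(sum(emb), 1, tolerance = 1e-12)
  expect_true(all(emb > 0))
  expect_lt(emb[["W"]], emb[["F"]]) # Trp rarer than Phe in the proteome

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">b", "ACD"), fa)
  bg <- background_frequencies(fa)
  for (aa in c("A", "C", "D")) {
    expect_equal(unname(unclass(bg)[aa]), 1 / 3, tolerance = 1e-4)
  }
  expect_equal(sum(bg), 1, tolerance = 1e-9)
  expect_true(all(bg > 0)) # floor keeps absent residues non-zero

  fa1 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AAAA"), fa1)
  bg1 <- background_frequencies(fa1)
  expect_equal(unname(unclass(bg1)["A"]), 1, tolerance = 1e-4)

  fa0 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(">a", fa0)
  expect_error(background_frequencies(fa0), "empty FASTA")
})

test_that("enrichment matches the binomial z formula and status rules", {
  # n = 100 peptides, 20 of them with K at position 1, reference 5%
  seqs <- c(rep("KAAAAAAAA", 20), rep("GAAAAAAAA", 80))
  pfm <- position_frequency_matrix(tibble::tibble(sequence = seqs), 9)
  ref <- swissprot_human_frequencies()
  ref_k <- unclass(ref)
  ref_k[] <- (1 - 0.05) * ref_k / sum(ref_k[setdiff(names(ref_k), "K")])
  ref_k["K"] <- 0.05
  ref_k <- ref_k / sum(ref_k)
  ref2 <- structure(ref_k, source = "test", class = "reference_frequencies")
  prof <- enrichment_profile(pfm, ref2)
  cell <- prof[prof$position == 1 & prof$aa == "K", ]
  expect_equal(cell$fc, 4.0, tolerance = 1e-12)
  expect_equal(cell$z, 6.882472, tolerance = 1e-6)
  expect_equal(cell$status, "enriched")
  expect_equal(cell$value, 4.0)

  # every cell has exactly one status; value conventions hold
  expect_true(all(prof$status %in%
                    c("enriched", "depleted", "absent", "not_significant")))
  expect_true(all(prof$value[prof$status == "enriched"] >= 1))
  expect_true(all(prof$value[prof$status == "depleted"] <= -1))
  expect_true(all(prof$value[prof$status == "absent"] == -100))
  expect_true(all(prof$count[prof$status == "absent"] == 0))
  dep <- prof[prof$status == "depleted", ]
  expect_equal(dep$value, -1 / (dep$freq / dep$ref_freq), tolerance = 1e-12)
})

test_that("observed frequency equal to the reference is never significant", {
  # composition engineered to match a uniform reference exactly
  seqs <- random_peptides(200, 9, seed = 5)
  pfm <- position_frequency_matrix(tibble::tibble(sequence = seqs), 9)
  uni <- structure(setNames(rep(0.05, 20), aa20), source = "uniform",
                   class = "reference_frequencies")
  pfm$counts[] <- 10L # force p_obs = 0.05 everywhere
  pfm$freqs[] <- 0.05
  pfm$n <- 200L
  prof <- enrichment_profile(pfm, uni)
  expect_true(all(prof$fc == 1))
  expect_true(all(prof$status == "not_significant"))
})

test_that("swapping observed and reference inverts FC and the sign of z", {
  n <- 500
  seqs <- c(rep("WAAAAAAAA", 100), rep("FAAAAAAAA", 400))
  pfm <- position_frequency_matrix(tibble::tibble(sequence = seqs), 9)
  uni <- structure(setNames(rep(0.05, 20), aa20), source = "uniform",
                   class = "reference_frequencies")
  fwd <- enrichment_profile(pfm, uni)
  # swapped direction: observed counts realise the uniform reference
  # exactly, and the reference becomes the original observed distribution
  pfm_ref <- pfm
  pfm_ref$counts[1, ] <- 25L
  obs_freqs <- setNames(pfm$counts[1, ] / n, aa20)
  obs_freqs <- pmax(obs_freqs, 1e-6); obs_freqs <- obs_freqs / sum(obs_freqs)
  swapped_ref <- structure(obs_freqs, source = "swapped",
                           class = "reference_frequencies")
  rev <- enrichment_profile(pfm_ref, swapped_ref)
  w_fwd <- fwd[fwd$position == 1 & fwd$aa == "W", ]
  w_rev <- rev[rev$position == 1 & rev$aa == "W", ]
  expect_equal(w_fwd$freq / w_fwd$ref_freq,
               1 / (w_rev$freq / w_rev$ref_freq), tolerance = 1e-4)
  expect_equal(sign(w_rev$z), -sign(w_fwd$z))
})

test_that("under the null the significant-cell rate is near alpha", {
  # small-scale calibration check (the full 200-repertoire version runs in
  # the acceptance suite)
  ref <- swissprot_human_frequencies()
  prof <- anchor_profile(9) # pure background: the null
  rates <- vapply(1:30, function(b) {
    seqs <- random_peptides(500, 9, prof, seed = 100 + b)
    ep <- enrichment_profile(position_frequency_matrix(
      tibble::tibble(sequence = seqs), 9), ref)
    mean(ep$status %in% c("enriched", "depleted"))
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.015)
})

test_that("C-terminal anchored indexing maps P-omega across lengths", {
  expect_equal(p_omega(9), 9)
  expect_equal(p_omega(10, 2), 8)
  expect_equal(p_omega(11, 2), 9)
  expect_error(p_omega(9, 9))
})
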