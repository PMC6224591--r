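test_that("feature encoding has the stated shape, order and standardisation", {
  rep <- tibble::tibble(sequence = c("LSSPVTKSF", "LTVQVARVY", "KAKAQTDRE",
                                     "AVFDRKSDA"))
  feats <- encode_peptides(rep, 9)
  labels <- attr(feats, "labels")
  expect_equal(nrow(labels), 24 * 9)
  expect_equal(labels$feature[1:4],
               c("mw", "hydropathy", "surface_area", "isoelectric_point"))
  expect_equal(nrow(feats), 4)
  # surviving columns are standardised
  expect_true(all(abs(colMeans(feats)) < 1e-10))
  expect_true(all(abs(apply(feats, 2, sd) - 1) < 1e-10))
  # un-standardising recovers identity indicators that sum to L per row
  ctr <- attr(feats, "center"); scl <- attr(feats, "scale")
  raw <- sweep(sweep(unclass(feats), 2, scl[colnames(feats)], "*"),
               2, ctr[colnames(feats)], "+")
  id_cols <- grepl("_is_", colnames(raw))
  id_sums <- rowSums(raw[, id_cols, drop = FALSE])
  # dropped identity columns are constant (all-0 or all-1), so the surviving
  # indicators sum to the same value <= L in every row
  expect_true(all(abs(id_sums - id_sums[1]) < 1e-9))
  expect_lte(id_sums[1], 9 + 1e-9)
})

test_that("degenerate and near-degenerate inputs are handled explicitly", {
  same <- tibble::tibble(sequence = rep("LSSPVTKSF", 5))
  expect_error(encode_peptides(same, 9), class = "immunopep_degenerate")

  two <- tibble::tibble(sequence = c("LSSPVTKSW", "LSSPVTKSF"))
  feats <- encode_peptides(two, 9)
  pos <- attr(feats, "labels")$position[match(colnames(feats),
                                              attr(feats, "labels")$column)]
  expect_true(all(pos == 9)) # only the P9 W/F contrast survives
})

test_that("PCA reconstructs the standardised matrix and fixes PC signs", {
  spec <- b57_example_spec("B5701-like", n = 150, seed = 8)
  rep <- simulate_repertoire(spec)
  feats <- encode_peptides(rep, 9)
  fit <- pca_cluster(feats, k_candidates = 2:3, seed = 1)
  recon <- fit$scores %*% t(fit$loadings)
  expect_equal(max(abs(recon - unclass(feats)[, colnames(recon)])), 0,
               tolerance = 1e-8)
  # sign convention: the largest-|loading| entry of each PC is positive
  for (comp in 1:5) {
    l <- fit$loadings[, comp]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_true(all(diff(fit$variance_fraction) <= 1e-12))
  expect_equal(sum(fit$cluster_percent), 100, tolerance = 1e-9)
})

test_that("two synthetic P-omega populations are recovered at k = 2", {
  skip_if_not_installed("mclust")
  prof_w <- anchor_profile(9, anchors = list(`2` = c(S = 0.4),
                                             omega = c(W = 0.97)))
  prof_f <- anchor_profile(9, anchors = list(`2` = c(S = 0.4),
                                             omega = c(F = 0.97)))
  n_half <- 500
  seqs <- c(random_peptides(n_half, 9, prof_w, seed = 61),
            random_peptides(n_half, 9, prof_f, seed = 62))
  truth <- rep(1:2, each = n_half)
  feats <- encode_peptides(tibble::tibble(sequence = seqs), 9)
  fit <- pca_cluster(feats, k_candidates = 2:6, seed = 1)
  expect_equal(fit$k, 2)
  expect_gt(mclust::adjustedRandIndex(fit$labels, truth), 0.9)
})

test_that("duplicating the data leaves scores and labels unchanged", {
  spec <- b57_example_spec("B5703-like", n = 120, seed = 13)
  rep <- simulate_repertoire(spec)
  seqs <- rep$sequence[nchar(rep$sequence) == 9]
  f1 <- encode_peptides(tibble::tibble(sequence = seqs), 9)
  f2 <- encode_peptides(tibble::tibble(sequence = rep(seqs, 2)), 9)
  fit1 <- pca_cluster(f1, k_candidates = 2, seed = 1)
  fit2 <- pca_cluster(f2, k_candidates = 2, seed = 1)
  n <- length(seqs)
  # duplication changes the n-1 sd denominator by a common factor, so
  # scores agree up to that uniform rescaling
  expect_equal(abs(fit2$scores[1:n, 1:2]), abs(fit1$scores[, 1:2]),
               tolerance = 1e-2)
  expect_equal(fit2$labels[1:n], fit2$labels[n + 1:n])
})

test_that("flipping the P-omega bias flips the majority cluster in a shared basis", {
  prof_wmaj <- anchor_profile(9, anchors = list(`2` = c(S = 0.4),
                                                omega = c(W = 0.7, F = 0.25)))
  prof_fmaj <- anchor_profile(9, anchors = list(`2` = c(S = 0.4),
                                                omega = c(F = 0.7, W = 0.25)))
  a <- tibble::tibble(sequence = random_peptides(600, 9, prof_wmaj, seed = 71))
  b <- tibble::tibble(sequence = random_peptides(600, 9, prof_fmaj, seed = 72))
  fa <- encode_peptides(a, 9)
  fit <- pca_cluster(fa, k_candidates = 2, seed = 1)
  maj_a <- as.integer(names(which.max(table(fit$labels))))
  # project the flipped repertoire through the same encoding and basis
  fb <- encode_peptides(b, 9, encoding = fa)
  pred <- predict(fit, fb)
  maj_b <- as.integer(names(which.max(table(pred$cluster))))
  expect_false(maj_a == maj_b)
})

test_that("P-omega surface area ranks among the top PC1 drivers", {
  spec <- b57_example_spec("B5701-like", n = 800, seed = 17)
  rep <- simulate_repertoire(spec)
  feats <- encode_peptides(rep, 9)
  fit <- pca_cluster(feats, k_candidates = 2, seed = 1)
  drivers <- tidy(fit)
  top_pc1 <- drivers[drivers$component == 1 & drivers$rank <= 10, ]
  expect_true("p9_surface_area" %in% top_pc1$column)
})

test_that("cluster motifs expose the per-cluster anchor composition", {
  prof_w <- anchor_profile(9, anchors = list(omega = c(W = 0.97)))
  prof_f <- anchor_profile(9, anchors = list(omega = c(F = 0.97)))
  seqs <- c(random_peptides(300, 9, prof_w, seed = 81),
            random_peptides(300, 9, prof_f, seed = 82))
  feats <- encode_peptides(tibble::tibble(sequence = seqs), 9)
  fit <- pca_cluster(feats, k_candidates = 2, seed = 1)
  cms <- cluster_motifs(fit)
  p9 <- cms[cms$position == 9, ]
  expect_setequal(p9$aa[p9$prevalence > 0.9], c("W", "F"))
})
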