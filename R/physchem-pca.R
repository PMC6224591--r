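#' Encode fixed-length peptides as physicochemical + identity features
#'
#' Each peptide of length `L` becomes a row of `24 * L` features: at every
#' position, four physicochemical descriptors (molecular weight,
#' hydropathy, surface area, isoelectric point; see [aa_property_table()])
#' followed by 20 amino-acid identity indicators. Columns are ordered
#' position-major, standardised to zero mean / unit standard deviation
#' (mixing daltons, angstroms-squared and indicators requires a common
#' scale), and zero-variance columns are dropped and recorded.
#'
#' @param rep Repertoire tibble with a `sequence` column.
#' @param L Peptide length.
#' @param table Property table with columns `aa`, `mw`, `hydropathy`,
#'   `surface_area`, `isoelectric_point`.
#' @param encoding Optional `pep_features` object whose standardisation
#'   (column means/sds and dropped columns) is reused, so that a second
#'   repertoire can be projected into the feature space of a first.
#' @return A `pep_features` object: the standardised numeric matrix with
#'   attributes `sequences`, `labels` (tibble: column, position, feature,
#'   type), `center`, `scale`, `dropped` (labels of zero-variance columns).
#'   Errors with class `"immunopep_degenerate"` if every column has zero
#'   variance (all peptides identical).
#' @export
encode_peptides <- function(rep, L, table = aa_property_table(), encoding = NULL) {
  seqs <- rep$sequence[nchar(rep$sequence) == L]
  if (!length(seqs)) abort(paste0("no peptides of length ", L))
  stopifnot(all(c("aa", "mw", "hydropathy", "surface_area",
                  "isoelectric_point") %in% names(table)))
  props <- as.matrix(table[match(AA20, table$aa),
                           c("mw", "hydropathy", "surface_area", "isoelectric_point")])
  rownames(props) <- AA20
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)

  blocks <- lapply(seq_len(L), function(j) {
    idx <- match(chars[, j], AA20)
    ident <- matrix(0, length(seqs), 20)
    ident[cbind(seq_along(idx), idx)] <- 1
    cbind(props[idx, , drop = FALSE], ident)
  })
  x <- do.call(cbind, blocks)
  feat_names <- c("mw", "hydropathy", "surface_area", "isoelectric_point",
                  paste0("is_", AA20))
  labels <- tibble(
    position = rep(seq_len(L), each = 24L),
    feature = rep(feat_names, L),
    type = rep(c(rep("property", 4), rep("identity", 20)), L)
  ) %>% mutate(column = paste0("p", .data$position, "_", .data$feature))
  colnames(x) <- labels$column

  if (is.null(encoding)) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    dropped <- labels$column[scl == 0]
    if (length(dropped) == ncol(x)) {
      abort("all feature columns have zero variance (identical peptides)",
            class = "immunopep_degenerate")
    }
  } else {
    ctr <- attr(encoding, "center")
    scl <- attr(encoding, "scale")
    dropped <- attr(encoding, "dropped")
  }
  keep <- setdiff(labels$column, dropped)
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep], "-"),
              2, scl[keep], "/")
  structure(xs, sequences = seqs, labels = labels,
            center = ctr, scale = scl, dropped = dropped,
            class = c("pep_features", "matrix", "array"))
}

#' PCA and k-means clustering of peptide feature space
#'
#' Runs principal component analysis (via singular-value decomposition of
#' the standardised feature matrix), orients every component so that its
#' largest-magnitude loading is positive (a fixed sign convention for
#' reproducibility), then clusters the first two component scores with
#' k-means (seeded, multiple restarts) for each candidate `k`. The number
#' of clusters is chosen at the peak of the mean silhouette coefficient.
#'
#' @param features A [encode_peptides()] result.
#' @param k_candidates Candidate cluster counts (default 2:6).
#' @param seed Seed controlling the k-means restarts.
#' @param nstart Restarts per k-means run.
#' @return A `pep_pca` object: list with `scores`, `loadings`,
#'   `variance_fraction`, `silhouette` (tibble k / mean width), chosen
#'   `k`, `labels`, `cluster_percent`, `centers` (k-means centres in PC1/2
#'   space), and the input `sequences`.
#' @export
pca_cluster <- function(features, k_candidates = 2:6, seed = 1, nstart = 10) {
  x <- unclass(features)
  attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <- NULL
  if (nrow(x) < 2) abort("need at least 2 peptides for PCA")
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  # sign convention: largest-|loading| entry of each PC is positive
  for (comp in seq_len(ncol(pc$rotation))) {
    top <- which.max(abs(pc$rotation[, comp]))
    if (pc$rotation[top, comp] < 0) {
      pc$rotation[, comp] <- -pc$rotation[, comp]
      pc$x[, comp] <- -pc$x[, comp]
    }
  }
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  s2 <- pc$x[, 1:2, drop = FALSE]

  k_candidates <- sort(unique(as.integer(k_candidates)))
  k_candidates <- k_candidates[k_candidates >= 2 & k_candidates < nrow(x)]
  if (!length(k_candidates)) abort("no feasible k candidate (need k < n rows)")
  d2 <- dist(s2)
  fits <- withr::with_seed(seed, {
    lapply(k_candidates, function(k) kmeans(s2, centers = k, nstart = nstart))
  })
  sil <- vapply(seq_along(k_candidates), function(ki) {
    mean(cluster::silhouette(fits[[ki]]$cluster, d2)[, "sil_width"])
  }, numeric(1))
  best <- which.max(sil)
  km <- fits[[best]]
  # stable label order: clusters numbered by increasing PC1 centre
  relabel <- rank(km$centers[, 1], ties.method = "first")
  labels <- as.integer(relabel[km$cluster])
  centers <- km$centers[order(km$centers[, 1]), , drop = FALSE]
  rownames(centers) <- seq_len(nrow(centers))

  pct <- as.numeric(100 * table(factor(labels, levels = seq_len(k_candidates[best]))) /
                      length(labels))
  structure(
    list(
      scores = pc$x, loadings = pc$rotation, variance_fraction = varfrac,
      silhouette = tibble(k = k_candidates, mean_silhouette = sil),
      k = k_candidates[best], labels = labels, cluster_percent = pct,
      centers = centers, sequences = attr(features, "sequences"),
      seed = seed
    ),
    class = "pep_pca"
  )
}

#' @export
print.pep_pca <- function(x, ...) {
  cat("<pep_pca>", nrow(x$scores), "peptides |",
      ncol(x$loadings), "components | k =", x$k, "\n")
  cat("  PC1/PC2 variance:", paste0(round(100 * x$variance_fraction[1:2], 1), "%",
                                    collapse = " / "), "\n")
  cat("  cluster %:", paste(round(x$cluster_percent, 1), collapse = " / "), "\n")
  invisible(x)
}

#' @describeIn pca_cluster Long tibble of loadings ranked by magnitude
#'   within each component, with position/feature/type parsed from the
#'   column labels.
#' @param x,object A `pep_pca` object.
#' @param components Components to include (default first two).
#' @param ... Unused.
#' @method tidy pep_pca
#' @export
tidy.pep_pca <- function(x, components = 1:2, ...) {
  purrr::map_dfr(components, function(comp) {
    l <- x$loadings[, comp]
    tibble(
      component = comp, column = names(l), loading = as.numeric(l)
    )
  }) %>%
    mutate(
      position = as.integer(sub("^p([0-9]+)_.*$", "\\1", .data$column)),
      feature = sub("^p[0-9]+_", "", .data$column),
      type = if_else(startsWith(.data$feature, "is_"), "identity", "property")
    ) %>%
    group_by(.data$component) %>%
    arrange(desc(abs(.data$loading)), .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    ungroup()
}

#' @describeIn pca_cluster One-row model summary (chosen k, silhouette at
#'   k, variance fractions of the first two components).
#' @method glance pep_pca
#' @export
glance.pep_pca <- function(x, ...) {
  tibble(
    n = nrow(x$scores), k = x$k,
    mean_silhouette = x$silhouette$mean_silhouette[x$silhouette$k == x$k],
    pc1_variance = x$variance_fraction[1],
    pc2_variance = x$variance_fraction[2]
  )
}

#' Project new peptides into a fitted PCA/cluster model
#'
#' Encodes nothing itself: supply features built with the *reference*
#' standardisation (`encode_peptides(..., encoding = ref_features)`) so
#' the new peptides live in the same feature space. Scores are obtained
#' with the fitted loadings and cluster labels by nearest k-means centre
#' in PC1/PC2.
#'
#' @param object A `pep_pca` fit.
#' @param features A `pep_features` matrix in the reference feature space.
#' @param ... Unused.
#' @return Tibble with `sequence`, `PC1`, `PC2`, `cluster`.
#' @export
predict.pep_pca <- function(object, features, ...) {
  x <- unclass(features)
  attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <- NULL
  scores <- x %*% object$loadings[, 1:2, drop = FALSE]
  d <- as.matrix(dist(rbind(object$centers, scores)))
  k <- nrow(object$centers)
  nearest <- apply(d[-(1:k), 1:k, drop = FALSE], 1, which.min)
  tibble(
    sequence = attr(features, "sequences"),
    PC1 = scores[, 1], PC2 = scores[, 2],
    cluster = as.integer(nearest)
  )
}

#' Per-cluster motif summaries
#'
#' @param object A `pep_pca` fit.
#' @param min_prevalence Threshold passed to [motif_summary()].
#' @return Tibble of per-cluster prevalence-thresholded motifs.
#' @export
cluster_motifs <- function(object, min_prevalence = 0.10) {
  purrr::map_dfr(sort(unique(object$labels)), function(cl) {
    seqs <- object$sequences[object$labels == cl]
    pfm <- position_frequency_matrix(tibble(sequence = seqs), nchar(seqs[1]))
    motif_summary(pfm, min_prevalence) %>% mutate(cluster = cl, .before = 1)
  })
}

#' PC1/PC2 density plot with cluster labels
#'
#' @param object A `pep_pca` fit.
#' @param ... Unused.
#' @return A ggplot: peptide scores in PC1/PC2 coloured by cluster with
#'   2-D kernel-density contours.
#' @method autoplot pep_pca
#' @export
autoplot.pep_pca <- function(object, ...) {
  df <- tibble(PC1 = object$scores[, 1], PC2 = object$scores[, 2],
               cluster = factor(object$labels))
  ggplot(df, aes(x = .data$PC1, y = .data$PC2)) +
    geom_point(aes(colour = .data$cluster), alpha = 0.4, size = 0.8) +
    geom_density_2d(colour = "grey30", linewidth = 0.3) +
    labs(
      x = paste0("PC1 (", round(100 * object$variance_fraction[1], 1), "%)"),
      y = paste0("PC2 (", round(100 * object$variance_fraction[2], 1), "%)")
    ) +
    theme_minimal()
}
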