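#' Inter-position statistical coupling matrix
#'
#' Measures, for peptides of a fixed length, the degree to which the
#' amino-acid frequency distribution at one position shifts when the set
#' is conditioned ("perturbed") on the residue present at another
#' position. For sites `i != j`, each residue `x` observed at site `i` in
#' at least `n_min` peptides defines a perturbation; its effect on site
#' `j` is a frequency-weighted root-mean-square log-ratio between the
#' conditional and the marginal distributions,
#' `delta_{ij|x} = sqrt( sum_a f~_{j|x}(a) ln( f~_{j|x}(a) / f~_j(a) )^2 )`,
#' and the coupling is the count-weighted sum
#' `coupling(i,j) = sum_x (n_x / n) * delta_{ij|x}`.
#' Weighting each residue's squared log-ratio by its conditional
#' frequency keeps the statistic from being dominated by residues merely
#' *unobserved* in a small conditioning subset, whose log-ratios are pure
#' sampling noise: an unweighted sum over all 20 residues acquires a
#' positive bias proportional to the number of unobserved residues and,
#' at realistic repertoire sizes, ranks independent position pairs above
#' genuinely coupled ones.
#' The diagonal reports positional conservation,
#' `D_j = sqrt( sum_a f~_j(a) ln( f~_j(a) / q(a) )^2 )`, against a
#' background `q`.
#'
#' Frequencies are smoothed by mixture with the uniform distribution,
#' `f~ = (1 - smooth) f + smooth/20`, which keeps every log-ratio finite
#' and — because the smoothing does not depend on subset size — makes the
#' coupling of any invariant site exactly zero and the whole matrix
#' invariant to duplicating the data set.
#'
#' @param rep Repertoire tibble with a `sequence` column.
#' @param L Peptide length to analyse.
#' @param n_min Minimum subset size for a residue to define a
#'   perturbation; default `max(10, 0.1 n)` — conditional frequencies
#'   from smaller subsets are dominated by sampling noise.
#' @param smooth Uniform-mixture smoothing weight in (0, 1), default 0.05.
#' @param background Background `q` for the conservation diagonal:
#'   `"pooled"` (default; the repertoire's own all-position residue
#'   frequencies) or a `reference_frequencies` object.
#' @return A `pep_coupling` object: list with `L`, `n`, `values` (L x L,
#'   diagonal = conservation), `symmetric` (off-diagonal mean of
#'   transposes, for display/ranking), and the parameters used.
#' @export
coupling_matrix <- function(rep, L, n_min = NULL, smooth = 0.05,
                            background = "pooled") {
  seqs <- rep$sequence[nchar(rep$sequence) == L]
  n <- length(seqs)
  if (is.null(n_min)) n_min <- max(10, ceiling(0.1 * n))
  if (n < n_min) {
    abort(paste0("need at least n_min = ", n_min, " peptides of length ", L,
                 "; found ", n))
  }
  stopifnot(smooth > 0, smooth < 1)
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)

  smo <- function(f) (1 - smooth) * f + smooth / 20
  col_freq <- function(col) {
    as.numeric(table(factor(col, levels = AA20))) / length(col)
  }
  marg <- lapply(seq_len(L), function(j) smo(col_freq(mat[, j])))

  values <- matrix(0, L, L, dimnames = list(seq_len(L), seq_len(L)))
  for (i in seq_len(L)) {
    tab_i <- table(mat[, i])
    xs <- names(tab_i)[tab_i >= n_min]
    for (x in xs) {
      sub <- mat[mat[, i] == x, , drop = FALSE]
      w <- nrow(sub) / n
      for (j in seq_len(L)) {
        if (j == i) next
        fcond <- smo(col_freq(sub[, j]))
        values[i, j] <- values[i, j] +
          w * sqrt(sum(fcond * log(fcond / marg[[j]])^2))
      }
    }
  }
  q <- if (identical(background, "pooled")) {
    smo(col_freq(as.vector(mat)))
  } else {
    as.numeric(unclass(background)[AA20])
  }
  for (j in seq_len(L)) {
    values[j, j] <- sqrt(sum(marg[[j]] * log(marg[[j]] / q)^2))
  }
  symm <- (values + t(values)) / 2
  diag(symm) <- diag(values)
  structure(
    list(L = as.integer(L), n = n, values = values, symmetric = symm,
         n_min = n_min, smooth = smooth,
         background = if (identical(background, "pooled")) "pooled" else "reference"),
    class = "pep_coupling"
  )
}

#' @export
print.pep_coupling <- function(x, ...) {
  cat("<pep_coupling> L =", x$L, "| n =", x$n,
      "| n_min =", x$n_min, "| smooth =", x$smooth, "\n")
  print(round(x$symmetric, 3))
  invisible(x)
}

#' @method tidy pep_coupling
#' @export
tidy.pep_coupling <- function(x, ...) {
  as_tibble(as.data.frame.table(x$values, responseName = "coupling",
                                stringsAsFactors = FALSE)) %>%
    rename(i = "Var1", j = "Var2") %>%
    mutate(i = as.integer(.data$i), j = as.integer(.data$j),
           kind = if_else(.data$i == .data$j, "conservation", "coupling")) %>%
    arrange(.data$i, .data$j)
}

#' Top coupled position pairs
#'
#' Ranks unordered position pairs by the symmetrised coupling value.
#'
#' @param m A [coupling_matrix()] result.
#' @param k Number of pairs to return; if larger than the number of pairs,
#'   all pairs are returned.
#' @return Tibble with columns `i`, `j` (`i < j`) and `value`, sorted
#'   descending by value with deterministic `(i, j)` tie-break.
#' @export
top_coupled_pairs <- function(m, k = 5) {
  stopifnot(k >= 1)
  L <- m$L
  pairs <- which(upper.tri(m$symmetric), arr.ind = TRUE)
  out <- tibble(
    i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
    value = m$symmetric[pairs]
  ) %>%
    arrange(desc(.data$value), .data$i, .data$j)
  head(out, min(k, nrow(out)))
}

#' Permutation null for a coupling matrix
#'
#' Destroys inter-position dependence by independently permuting each
#' position's column of residues, recomputing the coupling matrix each
#' time, and pooling the off-diagonal values. Observed couplings exceeding
#' the upper tail of this null indicate genuine covariation.
#'
#' @param rep Repertoire tibble.
#' @param L Peptide length.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutations.
#' @inheritParams coupling_matrix
#' @return Numeric vector of pooled null off-diagonal coupling values
#'   (length `n_perm * L * (L-1)`).
#' @export
coupling_permutation_null <- function(rep, L, n_perm = 50, seed = 1,
                                      n_min = NULL, smooth = 0.05) {
  seqs <- rep$sequence[nchar(rep$sequence) == L]
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  withr::with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(b) {
      perm <- apply(mat, 2, sample)
      shuffled <- tibble(sequence = apply(perm, 1, paste0, collapse = ""))
      cm <- coupling_matrix(shuffled, L, n_min = n_min, smooth = smooth)
      cm$values[row(cm$values) != col(cm$values)]
    }))
  })
}

#' Heat-map of a coupling matrix
#'
#' @param object A `pep_coupling` result.
#' @param ... Unused.
#' @return A ggplot tile plot of the symmetrised matrix (diagonal =
#'   conservation) using a perceptually uniform fill scale.
#' @method autoplot pep_coupling
#' @export
autoplot.pep_coupling <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(object$symmetric, responseName = "value",
                                      stringsAsFactors = FALSE)) %>%
    rename(i = "Var1", j = "Var2") %>%
    mutate(i = as.integer(.data$i), j = as.integer(.data$j))
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c() +
    scale_y_reverse(breaks = seq_len(object$L)) +
    scale_x_continuous(breaks = seq_len(object$L)) +
    labs(x = "position", y = "position", fill = "coupling") +
    coord_fixed() +
    theme_minimal()
}
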