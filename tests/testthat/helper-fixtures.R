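# in-code fixtures shared across test files

# write a small peptide table to a temp file and return the path
write_toy_table <- function(rows, delim = ",", ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(c(
    paste(c("sequence", "confidence", "modifications", "allotype", "replicate"),
          collapse = delim),
    vapply(rows, paste, character(1), collapse = delim)
  ), path)
  path
}

# n random peptides of length L drawn i.i.d. from a profile (L x 20 matrix,
# columns in immunopep's amino-acid order)
aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptides <- function(n, L, profile = NULL, seed = 1) {
  if (is.null(profile)) profile <- matrix(1 / 20, L, 20)
  withr::with_seed(seed, {
    mat <- vapply(seq_len(L), function(j) {
      sample(aa20, n, replace = TRUE, prob = profile[j, ])
    }, character(n))
    if (n == 1) mat <- matrix(mat, nrow = 1)
    apply(mat, 1, paste0, collapse = "")
  })
}

# independent mutual-information oracle for position pairs
pairwise_mi <- function(sequences, i, j) {
  ci <- substr(sequences, i, i)
  cj <- substr(sequences, j, j)
  tab <- table(ci, cj) / length(sequences)
  pi_ <- rowSums(tab); pj <- colSums(tab)
  mi <- 0
  for (a in rownames(tab)) for (b in colnames(tab)) {
    p <- tab[a, b]
    if (p > 0) mi <- mi + p * log(p / (pi_[a] * pj[b]))
  }
  as.numeric(mi)
}

# brute-force oracle for the overlap rescue rule on small instances
brute_force_overlap <- function(tables, primary, rescue) {
  best <- lapply(tables, function(t) tapply(t$confidence, t$sequence, max))
  eff <- lapply(seq_along(tables), function(d) {
    keys <- names(best[[d]])
    keep <- vapply(keys, function(k) {
      conf <- best[[d]][[k]]
      if (conf >= primary) return(TRUE)
      if (conf <= rescue) return(FALSE)
      any(vapply(seq_along(tables)[-d], function(o) {
        k %in% names(best[[o]]) && best[[o]][[k]] >= primary
      }, logical(1)))
    }, logical(1))
    keys[keep]
  })
  list(sizes = lengths(eff),
       common = length(Reduce(intersect, eff)))
}
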