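#' Peptide length distribution
#'
#' Tabulates peptide lengths over a reporting range (HLA class I ligands
#' are predominantly 8-18 residues, with a strong nonamer mode); lengths
#' outside the range are pooled into an `"other"` bucket so the
#' proportions always sum to 1.
#'
#' @param rep A repertoire tibble (any data frame with a `sequence` column).
#' @param range Integer vector of lengths to report individually.
#' @return Tibble with columns `length` (character; range values plus
#'   `"other"`), `count`, `proportion`.
#' @export
length_distribution <- function(rep, range = 8:18) {
  len <- nchar(rep$sequence)
  lab <- ifelse(len %in% range, as.character(len), "other")
  lab <- factor(lab, levels = c(as.character(range), "other"))
  counts <- table(lab)
  tibble(
    length = names(counts),
    count = as.integer(counts),
    proportion = if (sum(counts) > 0) as.numeric(counts) / sum(counts) else 0
  )
}

#' Position frequency matrix for peptides of one length
#'
#' Tabulates amino-acid occurrences at each position over all peptides of
#' exactly length `L`. Post-translational modifications are ignored: motif
#' analysis operates on the bare sequence.
#'
#' @param rep Repertoire tibble with a `sequence` column.
#' @param L Peptide length.
#' @return A `pep_pfm` object: list with `L`, `n`, `counts` (L x 20 integer
#'   matrix, rows = positions, columns = amino acids), `freqs` (row-wise
#'   proportions). Errors if no peptide of length `L` is present.
#' @export
position_frequency_matrix <- function(rep, L) {
  seqs <- rep$sequence[nchar(rep$sequence) == L]
  if (!length(seqs)) {
    abort(paste0("no peptides of length ", L, " in the repertoire"))
  }
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  counts <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = AA20))
    as.integer(tab)
  }, integer(20))
  counts <- t(counts)
  dimnames(counts) <- list(position = as.character(seq_len(L)), aa = AA20)
  structure(
    list(L = as.integer(L), n = length(seqs), counts = counts,
         freqs = counts / length(seqs)),
    class = "pep_pfm"
  )
}

#' @export
print.pep_pfm <- function(x, ...) {
  cat("<pep_pfm> L =", x$L, "| n =", x$n, "peptides\n")
  print(round(x$freqs, 3))
  invisible(x)
}

#' @method tidy pep_pfm
#' @export
tidy.pep_pfm <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, responseName = "count",
                                stringsAsFactors = FALSE)) %>%
    mutate(position = as.integer(.data$position),
           freq = .data$count / x$n) %>%
    arrange(.data$position, .data$aa)
}

#' Prevalence-thresholded motif summary
#'
#' For each position, lists the residues whose prevalence meets
#' `min_prevalence` (default 10%, the conventional depiction threshold for
#' eluted-ligand motifs), sorted by decreasing prevalence.
#'
#' @param pfm A [position_frequency_matrix()] result.
#' @param min_prevalence Minimum proportion for a residue to be listed.
#' @return Tibble with columns `position`, `aa`, `prevalence`; positions
#'   where no residue reaches the threshold contribute no rows.
#' @export
motif_summary <- function(pfm, min_prevalence = 0.10) {
  tidy(pfm) %>%
    filter(.data$freq >= min_prevalence) %>%
    arrange(.data$position, desc(.data$freq), .data$aa) %>%
    select(position = "position", aa = "aa", prevalence = "freq")
}

#' Background amino-acid frequencies
#'
#' Either the embedded human Swiss-Prot mean composition
#' ([swissprot_human_frequencies()]) or frequencies derived from a
#' proteome FASTA. In FASTA mode, frequencies are computed over all
#' residues of all entries; non-standard letters are skipped and counted
#' in the `"skipped"` attribute, and a floor of `1e-6` is applied before
#' renormalisation so that residues absent from a small FASTA cannot
#' produce infinite fold changes downstream.
#'
#' @param source `"embedded"` or a path to a FASTA file.
#' @return A `reference_frequencies` object (named proportions over the 20
#'   standard amino acids, summing to 1).
#' @export
background_frequencies <- function(source = "embedded") {
  if (identical(source, "embedded")) {
    return(swissprot_human_frequencies())
  }
  seqs <- read_fasta_sequences(source)
  if (!length(seqs) || all(nchar(seqs) == 0)) abort("empty FASTA")
  letters <- strsplit(toupper(paste(seqs, collapse = "")), "")[[1]]
  std <- letters %in% AA20
  counts <- table(factor(letters[std], levels = AA20))
  f <- pmax(as.numeric(counts) / sum(counts), 1e-6)
  f <- f / sum(f)
  out <- new_reference_frequencies(setNames(f, AA20), source = "fasta_derived")
  attr(out, "skipped") <- sum(!std)
  out
}

#' Positional enrichment against a background proteome
#'
#' For every (position, amino acid) cell of a position frequency matrix,
#' compares the observed prevalence `p_obs = count/n` with the background
#' prevalence `p_ref` via the binomial z-score
#' `z = (p_obs - p_ref) / sqrt(p_ref (1 - p_ref) / n)` and reports the
#' fold change in the convention used for eluted-ligand enrichment plots:
#' significantly enriched residues carry `FC = p_obs/p_ref >= 1`,
#' significantly depleted residues carry the converted fold change
#' `FC_con = -1/FC <= -1`, residues absent from the data carry the
#' sentinel `-100`, and non-significant cells carry no displayed value.
#'
#' @param pfm A [position_frequency_matrix()] result with `n > 0`.
#' @param ref A `reference_frequencies` object
#'   (default [swissprot_human_frequencies()]).
#' @param alpha Two-sided significance level for the z-test (default 0.05).
#' @return A `pep_enrichment` tibble: columns `position`, `aa`, `count`,
#'   `freq`, `ref_freq`, `fc` (signed fold change, `-1/FC` when `FC < 1`),
#'   `z`, `status` (`enriched`/`depleted`/`absent`/`not_significant`) and
#'   `value` (`fc` for significant cells, `-100` for absent, `NA`
#'   otherwise). Attributes record `alpha` and the critical z.
#' @examples
#' rep <- tibble::tibble(sequence = c("LSSPVTKSF", "LSSPVTRSF", "ASSPVTRSF"))
#' pfm <- position_frequency_matrix(rep, 9)
#' enrichment_profile(pfm)
#' @export
enrichment_profile <- function(pfm, ref = swissprot_human_frequencies(), alpha = 0.05) {
  stopifnot(pfm$n > 0)
  zcrit <- qnorm(1 - alpha / 2)
  out <- tidy(pfm) %>%
    mutate(
      ref_freq = as.numeric(unclass(ref)[.data$aa]),
      z = (.data$freq - .data$ref_freq) /
        sqrt(.data$ref_freq * (1 - .data$ref_freq) / pfm$n),
      fc_raw = .data$freq / .data$ref_freq,
      fc = if_else(.data$fc_raw >= 1, .data$fc_raw, -1 / .data$fc_raw),
      status = dplyr::case_when(
        .data$count == 0 ~ "absent",
        abs(.data$z) < zcrit ~ "not_significant",
        .data$fc_raw >= 1 ~ "enriched",
        TRUE ~ "depleted"
      ),
      value = dplyr::case_when(
        .data$status == "absent" ~ -100,
        .data$status == "not_significant" ~ NA_real_,
        TRUE ~ .data$fc
      )
    ) %>%
    select("position", "aa", "count", "freq", "ref_freq", "fc", "z",
           "status", "value")
  structure(out, alpha = alpha, z_critical = zcrit, n = pfm$n, L = pfm$L,
            class = c("pep_enrichment", class(tibble())))
}

#' @method glance pep_enrichment
#' @export
glance.pep_enrichment <- function(x, ...) {
  tibble(
    L = attr(x, "L"), n = attr(x, "n"), alpha = attr(x, "alpha"),
    n_enriched = sum(x$status == "enriched"),
    n_depleted = sum(x$status == "depleted"),
    n_absent = sum(x$status == "absent")
  )
}

#' Plot positional enrichment as signed fold-change bars
#'
#' @param object A `pep_enrichment` result.
#' @param positions Positions to display (default: all).
#' @param ... Unused.
#' @return A ggplot object; significant cells are drawn as bars of the
#'   signed fold change (absent residues are shown at the -100 sentinel
#'   capped to the panel).
#' @method autoplot pep_enrichment
#' @export
autoplot.pep_enrichment <- function(object, positions = NULL, ...) {
  df <- as_tibble(object) %>% filter(!is.na(.data$value))
  if (!is.null(positions)) df <- filter(df, .data$position %in% positions)
  df$display <- pmax(df$value, -25)
  ggplot(df, aes(x = .data$aa, y = .data$display, fill = .data$status)) +
    geom_col() +
    facet_wrap(~position, labeller = label_both) +
    labs(x = NULL, y = "fold change (FC; FC_con = -1/FC below 0)",
         fill = NULL) +
    theme_minimal()
}

#' Plot a length distribution
#'
#' @param rep Repertoire tibble.
#' @param range Lengths to report, see [length_distribution()].
#' @return A ggplot bar chart of length proportions.
#' @export
plot_length_distribution <- function(rep, range = 8:18) {
  ld <- length_distribution(rep, range)
  ld$length <- factor(ld$length, levels = ld$length)
  ggplot(ld, aes(x = .data$length, y = .data$proportion)) +
    geom_col() +
    labs(x = "peptide length", y = "proportion") +
    theme_minimal()
}
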