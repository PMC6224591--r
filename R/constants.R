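#' Mean amino-acid composition of the reviewed human proteome
#'
#' Background amino-acid frequencies used as the static reference for
#' positional enrichment statistics. Values are the mean composition of the
#' reviewed (Swiss-Prot) human proteome, expressed as proportions summing
#' to 1. Release-to-release drift in these means is on the order of 0.1
#' percentage points and is the dominant source of disagreement when
#' comparing fold changes computed against different proteome versions.
#'
#' @return A [reference_frequencies] object: a named numeric vector over the
#'   20 standard amino acids with attribute `source = "embedded_swissprot_means"`.
#' @examples
#' swissprot_human_frequencies()[["W"]] # Trp is rare, about 1.2%
#' @export
swissprot_human_frequencies <- function() {
  f <- c(
    A = 7.01, R = 5.64, N = 3.58, D = 4.74, C = 2.30,
    Q = 4.77, E = 7.10, G = 6.58, H = 2.63, I = 4.34,
    L = 9.97, K = 5.72, M = 2.13, F = 3.65, P = 6.31,
    S = 8.33, T = 5.36, W = 1.22, Y = 2.66, V = 5.96
  ) / 100
  new_reference_frequencies(f[AA20], source = "embedded_swissprot_means")
}

new_reference_frequencies <- function(freqs, source) {
  stopifnot(length(freqs) == 20L, all(AA20 %in% names(freqs)))
  freqs <- freqs[AA20]
  if (any(!is.finite(freqs)) || any(freqs <= 0)) {
    abort("reference frequencies must be finite and strictly positive")
  }
  if (abs(sum(freqs) - 1) > 1e-9) {
    abort("reference frequencies must sum to 1")
  }
  structure(freqs, source = source, class = "reference_frequencies")
}

#' @export
print.reference_frequencies <- function(x, ...) {
  cat("<reference_frequencies> source:", attr(x, "source"), "\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Physicochemical properties of the 20 standard amino acids
#'
#' The per-residue descriptor set used to encode peptides for PCA:
#' average residue molecular weight (Da), Kyte-Doolittle hydropathy index
#' (unitless), theoretical maximum accessible surface area (A^2, Tien et
#' al. 2013), and isoelectric point of the free amino acid (pH units).
#' Any complete replacement table with the same columns may be supplied to
#' [encode_peptides()].
#'
#' @return A tibble with columns `aa`, `mw`, `hydropathy`, `surface_area`,
#'   `isoelectric_point`, one row per amino acid.
#' @export
aa_property_table <- function() {
  tibble(
    aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    mw = c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12, 57.05,
           137.14, 113.16, 113.16, 128.17, 131.19, 147.18, 97.12, 87.08,
           101.10, 186.21, 163.18, 99.13),
    hydropathy = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                   3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
    surface_area = c(129, 274, 195, 193, 167, 225, 223, 104, 224, 197,
                     201, 236, 224, 240, 159, 155, 172, 285, 263, 174),
    isoelectric_point = c(6.00, 10.76, 5.41, 2.77, 5.07, 5.65, 3.22, 5.97,
                          7.59, 6.02, 5.98, 9.74, 5.74, 5.48, 6.30, 5.68,
                          5.60, 5.89, 5.66, 5.96)
  ) %>% arrange(.data$aa)
}

# C-terminal-anchored position index: p_omega(L) = L, p_omega(L, 2) = L - 2,
# so anchor positions can be compared across peptide lengths.

#' C-terminal-anchored peptide position
#'
#' HLA class I anchor positions are conserved relative to the peptide C
#' terminus: the final residue (P-omega) and the residue two upstream
#' (P-omega-2) occupy the F and E pockets regardless of peptide length.
#'
#' @param length Peptide length L.
#' @param offset Non-negative offset upstream of the C terminus (0 = the
#'   C-terminal residue itself).
#' @return 1-based position index within a peptide of that length.
#' @examples
#' p_omega(9)      # 9
#' p_omega(11, 2)  # 9: P-omega-2 of an 11mer
#' @export
p_omega <- function(length, offset = 0) {
  stopifnot(length >= 1, offset >= 0, offset < length)
  as.integer(length - offset)
}
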