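#' Read a peptide-identification table
#'
#' Reads a CSV/TSV table of eluted-ligand identifications (one row per
#' peptide-spectrum assignment) into a tidy record table. Column names are
#' resolved through `dialect`, so tables exported from different search
#' engines can be read without renaming. Rows whose sequence contains a
#' non-standard residue code (B, J, O, U, X, Z or anything outside the
#' 20-letter alphabet) or whose confidence is non-numeric or outside
#' [0, 100] are excluded from the result but collected in a row-level error
#' report attached as the `"errors"` attribute (see [peptide_read_errors()]):
#' motif statistics assume the standard alphabet, and silently recoding
#' ambiguous residues would bias them.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named list mapping the canonical column roles
#'   (`sequence`, `confidence`, `modifications`, `allotype`, `replicate`)
#'   to the column names used in the file. Only `sequence` and `confidence`
#'   are required; missing optional columns are defaulted
#'   (`modifications = ""`, `allotype`/`replicate = NA`).
#' @param delim Field delimiter; `NULL` (default) auto-detects `","` vs
#'   `"\t"` from the header line.
#' @return A tibble with columns `sequence`, `modifications` (canonical
#'   `"pos:name"` strings, `;`-separated, `""` if none), `confidence`,
#'   `allotype`, `replicate`, plus an `"errors"` attribute (tibble with
#'   `row`, `reason`).
#' @seealso [filter_repertoire()] to apply confidence/contaminant filters.
#' @export
read_peptide_table <- function(path, dialect = list(), delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("peptide table not found: ", path))
  }
  dialect <- modifyList(
    list(sequence = "sequence", confidence = "confidence",
         modifications = "modifications", allotype = "allotype",
         replicate = "replicate"),
    dialect
  )
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  for (role in c("sequence", "confidence")) {
    if (!dialect[[role]] %in% names(raw)) {
      abort(paste0("required column '", dialect[[role]], "' (role: ", role,
                   ") not found in ", path))
    }
  }
  get_col <- function(role, default) {
    nm <- dialect[[role]]
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  tab <- tibble(
    sequence = toupper(trimws(get_col("sequence", NA_character_))),
    modifications = get_col("modifications", ""),
    confidence_raw = get_col("confidence", NA_character_),
    allotype = get_col("allotype", NA_character_),
    replicate = get_col("replicate", NA_character_)
  )
  tab$modifications <- canonical_modifications(tab$modifications)
  conf <- suppressWarnings(as.numeric(tab$confidence_raw))

  bad_seq <- is.na(tab$sequence) | !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", tab$sequence)
  bad_conf <- is.na(conf) | conf < 0 | conf > 100
  bad_mod <- !is.na(tab$sequence) & mod_position_exceeds(tab$modifications, nchar(tab$sequence))

  errors <- bind_rows(
    tibble(row = which(bad_seq), reason = "invalid or missing sequence"),
    tibble(row = which(!bad_seq & bad_conf), reason = "malformed or out-of-range confidence"),
    tibble(row = which(!bad_seq & !bad_conf & bad_mod),
           reason = "modification position exceeds sequence length")
  ) %>% arrange(.data$row)

  keep <- !(bad_seq | bad_conf | bad_mod)
  out <- tab[keep, c("sequence", "modifications", "allotype", "replicate")]
  out$confidence <- conf[keep]
  out <- out[, c("sequence", "modifications", "confidence", "allotype", "replicate")]
  attr(out, "errors") <- errors
  out
}

#' Row-level error report from [read_peptide_table()]
#'
#' @param x A table returned by [read_peptide_table()].
#' @return Tibble with columns `row` (1-based data-row index in the source
#'   file) and `reason`.
#' @export
peptide_read_errors <- function(x) {
  attr(x, "errors") %||% tibble(row = integer(), reason = character())
}

# canonicalise a modification annotation to a sorted "pos:name;pos:name"
# string so identity keys are stable across input dialects
canonical_modifications <- function(mods) {
  mods[is.na(mods)] <- ""
  vapply(mods, function(m) {
    m <- trimws(m)
    if (m == "" || toupper(m) %in% c("NA", "NONE")) return("")
    parts <- trimws(strsplit(m, "[;,]")[[1]])
    parts <- parts[parts != ""]
    pos <- suppressWarnings(as.integer(sub("^([0-9]+)\\s*[:@]\\s*.*$", "\\1", parts)))
    name <- sub("^[0-9]+\\s*[:@]\\s*", "", parts)
    ord <- order(pos, name)
    paste(paste0(pos[ord], ":", name[ord]), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

mod_position_exceeds <- function(mods, len) {
  vapply(seq_along(mods), function(i) {
    if (mods[i] == "") return(FALSE)
    pos <- as.integer(sub(":.*$", "", strsplit(mods[i], ";")[[1]]))
    any(is.na(pos)) || any(pos < 1) || any(pos > len[i])
  }, logical(1))
}

#' Identity key of a peptide record
#'
#' Peptides are considered redundant when they share an identity key:
#' either the bare sequence (`"sequence_only"`) or the sequence plus the
#' canonical modification string (`"sequence_plus_modifications"`).
#'
#' @param sequence,modifications Character vectors.
#' @param identity_mode One of `"sequence_only"`,
#'   `"sequence_plus_modifications"`.
#' @return Character vector of keys.
#' @export
identity_key <- function(sequence, modifications = "",
                         identity_mode = c("sequence_only", "sequence_plus_modifications")) {
  identity_mode <- match.arg(identity_mode)
  if (identity_mode == "sequence_only") {
    sequence
  } else {
    ifelse(modifications == "" | is.na(modifications),
           sequence, paste0(sequence, "|", modifications))
  }
}

#' Assemble contaminant exclusion lists
#'
#' Three classes of identifications are removed from eluted-ligand data
#' sets before motif analysis: peptides known to bind the endogenous HLA
#' class I of the parental cell line (for C1R cells, HLA-C*04:01 and
#' HLA-B*35:03 ligands), generic contaminants recurrent across
#' immunoaffinity elution experiments, and peptides derived from the HLA
#' proteins themselves. The last are matched as substrings of the supplied
#' HLA protein sequences rather than as an explicit peptide list.
#'
#' @param endogenous_ligands,generic_contaminants Character vectors of
#'   peptide sequences (or paths to one-sequence-per-line text files).
#' @param hla_proteins Character vector of HLA protein sequences, or a path
#'   to a FASTA file (read with Biostrings when available, otherwise with a
#'   minimal reader).
#' @return A `contaminant_lists` object.
#' @export
contaminant_lists <- function(endogenous_ligands = character(),
                              generic_contaminants = character(),
                              hla_proteins = character()) {
  structure(
    list(
      endogenous_ligands = unique(toupper(read_sequences_arg(endogenous_ligands))),
      generic_contaminants = unique(toupper(read_sequences_arg(generic_contaminants))),
      hla_proteins = unique(toupper(read_sequences_arg(hla_proteins, fasta_ok = TRUE)))
    ),
    class = "contaminant_lists"
  )
}

read_sequences_arg <- function(x, fasta_ok = FALSE) {
  if (length(x) == 1 && !grepl("^[A-Za-z]+$", x) && file.exists(x)) {
    lines <- readLines(x)
    if (fasta_ok && any(startsWith(lines, ">"))) {
      return(read_fasta_sequences(x))
    }
    lines <- trimws(lines)
    return(lines[lines != "" & !startsWith(lines, "#")])
  }
  as.character(x)
}

read_fasta_sequences <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    return(as.character(Biostrings::readAAStringSet(path)))
  }
  lines <- readLines(path)
  idx <- cumsum(startsWith(lines, ">"))
  body <- lines[!startsWith(lines, ">")]
  grp <- idx[!startsWith(lines, ">")]
  vapply(split(body, grp), paste0, character(1), collapse = "")
}

#' Filter identifications into a non-redundant repertoire
#'
#' Applies, in order: the confidence cutoff (records with
#' `confidence >= cutoff` are retained; the default 95 corresponds to a 5%
#' local FDR in typical search-engine output, with per-replicate values in
#' the 95.2-97 range supplied via `cutoff` when known), removal of
#' contaminant sequences ([contaminant_lists()]), and deduplication by
#' identity key, keeping the highest-confidence instance (ties broken by
#' first occurrence). Replicates are pooled: the filter acts per record
#' before deduplication.
#'
#' @param records Tibble of peptide records ([read_peptide_table()] output
#'   or any data frame with `sequence` and `confidence`; `modifications`,
#'   `allotype`, `replicate` optional).
#' @param cutoff Confidence threshold in [0, 100].
#' @param lists A [contaminant_lists()] object.
#' @param identity_mode Identity key mode, see [identity_key()].
#' @param allotype Optional allotype label recorded on the result
#'   (defaults to the modal `allotype` value in `records`).
#' @return A `pep_repertoire`: a tibble of unique records (all with
#'   `confidence >= cutoff`) with attributes `allotype`, `cutoff`,
#'   `identity_mode` and `provenance` (a per-filter removal count table,
#'   see [provenance()]).
#' @examples
#' recs <- tibble::tibble(
#'   sequence = c("LSSPVTKSF", "LSSPVTKSF", "LTVQVARVY"),
#'   confidence = c(99, 96, 50)
#' )
#' rep <- filter_repertoire(recs, cutoff = 95)
#' nrow(rep)       # 1: duplicate collapsed, low-confidence record removed
#' provenance(rep)
#' @export
filter_repertoire <- function(records, cutoff = 95,
                              lists = contaminant_lists(),
                              identity_mode = c("sequence_only", "sequence_plus_modifications"),
                              allotype = NULL) {
  identity_mode <- match.arg(identity_mode)
  stopifnot(cutoff >= 0, cutoff <= 100)
  records <- as_tibble(records)
  if (!"modifications" %in% names(records)) records$modifications <- ""
  if (!"allotype" %in% names(records)) records$allotype <- NA_character_
  if (!"replicate" %in% names(records)) records$replicate <- NA_character_
  records$modifications[is.na(records$modifications)] <- ""

  n_input <- nrow(records)
  below <- records$confidence < cutoff
  records <- records[!below, , drop = FALSE]

  is_endo <- records$sequence %in% lists$endogenous_ligands
  records_after_endo <- records[!is_endo, , drop = FALSE]
  is_generic <- records_after_endo$sequence %in% lists$generic_contaminants
  records_after_gen <- records_after_endo[!is_generic, , drop = FALSE]
  is_hla <- is_hla_derived(records_after_gen$sequence, lists$hla_proteins)
  kept <- records_after_gen[!is_hla, , drop = FALSE]

  kept$.key <- identity_key(kept$sequence, kept$modifications, identity_mode)
  kept$.row <- seq_len(nrow(kept))
  # keep highest-confidence instance per key (first occurrence wins ties),
  # preserving the input row order of the survivors
  ord <- order(kept$.key, -kept$confidence, kept$.row)
  sorted <- kept[ord, , drop = FALSE]
  dup <- duplicated(sorted$.key)
  dedup_removed <- sum(dup)
  kept <- sorted[!dup, , drop = FALSE]
  kept <- kept[order(kept$.row), , drop = FALSE]
  kept$.key <- NULL
  kept$.row <- NULL

  if (is.null(allotype)) {
    av <- kept$allotype[!is.na(kept$allotype)]
    allotype <- if (length(av)) names(sort(table(av), decreasing = TRUE))[1] else NA_character_
  }
  provenance <- tibble(
    filter = c("below_cutoff", "endogenous_ligand", "generic_contaminant",
               "hla_protein_peptide", "duplicate_identity"),
    removed = c(sum(below), sum(is_endo), sum(is_generic), sum(is_hla), dedup_removed)
  )
  new_pep_repertoire(kept, allotype = allotype, cutoff = cutoff,
                     identity_mode = identity_mode, provenance = provenance,
                     n_input = n_input)
}

is_hla_derived <- function(sequences, hla_proteins) {
  if (!length(hla_proteins) || !length(sequences)) {
    return(rep(FALSE, length(sequences)))
  }
  vapply(sequences, function(s) {
    any(stringr::str_detect(hla_proteins, stringr::fixed(s)))
  }, logical(1), USE.NAMES = FALSE)
}

new_pep_repertoire <- function(tbl, allotype, cutoff, identity_mode, provenance, n_input) {
  structure(
    as_tibble(tbl),
    allotype = allotype, cutoff = cutoff, identity_mode = identity_mode,
    provenance = provenance, n_input = n_input,
    class = c("pep_repertoire", class(tibble()))
  )
}

#' Filtering provenance of a repertoire
#'
#' @param x A `pep_repertoire` from [filter_repertoire()].
#' @return Tibble of per-filter removal counts; the counts plus `nrow(x)`
#'   sum to the number of input records.
#' @export
provenance <- function(x) attr(x, "provenance")

#' @export
print.pep_repertoire <- function(x, ...) {
  cat("<pep_repertoire> allotype:", attr(x, "allotype") %||% NA,
      "| cutoff:", attr(x, "cutoff"),
      "| identity:", attr(x, "identity_mode"),
      "| peptides:", nrow(x), "\n")
  NextMethod()
}

#' Write / re-read a repertoire as TSV
#'
#' The record table is written as plain TSV (columns `sequence`,
#' `modifications`, `confidence`, `allotype`, `replicate`);
#' [read_repertoire()] restores the records losslessly.
#'
#' @param x A `pep_repertoire` or record tibble.
#' @param path Output path.
#' @return `write_repertoire()` returns `path` invisibly;
#'   `read_repertoire()` returns a record tibble.
#' @export
write_repertoire <- function(x, path) {
  readr::write_tsv(as_tibble(x)[, c("sequence", "modifications", "confidence",
                                    "allotype", "replicate")], path)
  invisible(path)
}

#' @rdname write_repertoire
#' @export
read_repertoire <- function(path) {
  read_peptide_table(path, delim = "\t")
}
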