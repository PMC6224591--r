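#' Repertoire overlap with a confidence-rescue rule
#'
#' Compares 2-3 unfiltered identification data sets. A peptide belongs to
#' the *effective* set of data set D if it was identified there with
#' confidence at or above `primary_cutoff`, or — the rescue rule — with
#' confidence strictly above `rescue_cutoff` provided it reaches
#' `primary_cutoff` in at least one of the *other* compared data sets.
#' The rescue rule recovers peptides that were confidently sequenced in
#' one eluate and present but under-sampled in another.
#'
#' Duplicate identifications of a peptide within one data set are
#' collapsed to the maximum confidence before the rule is applied.
#'
#' @param tables A named list of 2-3 record tibbles (columns `sequence`,
#'   `confidence`, optional `modifications`), or a single long tibble with
#'   a `dataset` column.
#' @param primary_cutoff Confidence for core membership (default 95,
#'   inclusive).
#' @param rescue_cutoff Confidence floor for rescue (default 20, strict).
#' @param identity_mode Identity key mode; `"sequence_plus_modifications"`
#'   (default) treats modified forms as distinct, `"sequence_only"`
#'   collapses them (use this to compare repertoires "by sequence alone").
#' @return A `pep_overlap` object: list with `membership` (tibble: key x
#'   dataset with per-dataset max confidence and status
#'   `core`/`rescued`/`absent`), `counts` (effective and core sizes,
#'   unique counts, all pairwise intersections, `common_all`), and the
#'   parameters.
#' @examples
#' tabs <- list(
#'   A = tibble::tibble(sequence = c("LSSPVTKSF", "LTVQVARVY"),
#'                      confidence = c(99, 50)),
#'   B = tibble::tibble(sequence = c("LTVQVARVY", "KAKAQTDRE"),
#'                      confidence = c(96, 99))
#' )
#' ov <- repertoire_overlap(tabs)
#' ov$counts$pairwise  # A-B intersection = 1 (LTVQVARVY rescued into A)
#' @export
repertoire_overlap <- function(tables, primary_cutoff = 95, rescue_cutoff = 20,
                               identity_mode = c("sequence_plus_modifications",
                                                 "sequence_only")) {
  identity_mode <- match.arg(identity_mode)
  if (is.data.frame(tables)) {
    stopifnot("dataset" %in% names(tables))
    tables <- split(as_tibble(tables), tables$dataset)
  }
  if (length(tables) < 2) abort("need at least 2 data sets to compare")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("dataset", seq_along(tables))
  }
  ds_names <- names(tables)

  long <- purrr::imap_dfr(tables, function(tab, nm) {
    tab <- as_tibble(tab)
    if (!"modifications" %in% names(tab)) tab$modifications <- ""
    tab$modifications[is.na(tab$modifications)] <- ""
    tibble(
      dataset = nm,
      key = identity_key(tab$sequence, tab$modifications, identity_mode),
      confidence = tab$confidence
    )
  }) %>%
    group_by(.data$dataset, .data$key) %>%
    summarise(confidence = max(.data$confidence), .groups = "drop")

  wide <- tidyr::pivot_wider(long, names_from = "dataset",
                             values_from = "confidence")
  conf <- as.matrix(wide[, ds_names, drop = FALSE])
  core <- !is.na(conf) & conf >= primary_cutoff
  any_other_core <- vapply(seq_along(ds_names), function(d) {
    rowSums(core[, -d, drop = FALSE]) > 0
  }, logical(nrow(conf)))
  rescued <- !core & !is.na(conf) & conf > rescue_cutoff & any_other_core
  effective <- core | rescued

  status <- matrix("absent", nrow(conf), ncol(conf), dimnames = dimnames(conf))
  status[rescued] <- "rescued"
  status[core] <- "core"

  membership <- wide %>%
    mutate(!!!setNames(
      lapply(seq_along(ds_names), function(d) status[, d]),
      paste0("status_", ds_names)
    ))

  pair_idx <- utils::combn(seq_along(ds_names), 2)
  pairwise <- tibble(
    a = ds_names[pair_idx[1, ]], b = ds_names[pair_idx[2, ]],
    intersection = vapply(seq_len(ncol(pair_idx)), function(p) {
      sum(effective[, pair_idx[1, p]] & effective[, pair_idx[2, p]])
    }, integer(1))
  )
  counts <- list(
    effective_size = setNames(colSums(effective), ds_names),
    core_size = setNames(colSums(core), ds_names),
    unique = setNames(vapply(seq_along(ds_names), function(d) {
      sum(effective[, d] & rowSums(effective[, -d, drop = FALSE]) == 0)
    }, integer(1)), ds_names),
    pairwise = pairwise,
    common_all = sum(rowSums(effective) == length(ds_names))
  )
  structure(
    list(membership = membership, counts = counts,
         identity_mode = identity_mode,
         primary_cutoff = primary_cutoff, rescue_cutoff = rescue_cutoff),
    class = "pep_overlap"
  )
}

#' @export
print.pep_overlap <- function(x, ...) {
  cat("<pep_overlap> identity:", x$identity_mode,
      "| primary >=", x$primary_cutoff, "| rescue >", x$rescue_cutoff, "\n")
  cat("  effective sizes:",
      paste(names(x$counts$effective_size), x$counts$effective_size,
            sep = "=", collapse = ", "), "\n")
  cat("  common to all:", x$counts$common_all, "\n")
  invisible(x)
}

#' @method tidy pep_overlap
#' @export
tidy.pep_overlap <- function(x, ...) {
  x$membership
}

#' @method glance pep_overlap
#' @export
glance.pep_overlap <- function(x, ...) {
  tibble(
    n_datasets = length(x$counts$effective_size),
    common_all = x$counts$common_all,
    min_pairwise = min(x$counts$pairwise$intersection),
    max_pairwise = max(x$counts$pairwise$intersection)
  )
}

#' Overlap proportions with both denominator choices
#'
#' Expresses the common-to-all and pairwise intersections as percentages
#' of each data set's size, using both the effective (core + rescued) and
#' the core-only size as denominator, since either convention is
#' defensible.
#'
#' @param x A `pep_overlap` result.
#' @return Tibble with columns `dataset`, `denominator`
#'   (`effective`/`core`), `size`, `pct_common_all`.
#' @export
overlap_proportions <- function(x) {
  purrr::map_dfr(c("effective", "core"), function(denom) {
    sizes <- if (denom == "effective") x$counts$effective_size else x$counts$core_size
    tibble(
      dataset = names(sizes), denominator = denom, size = as.integer(sizes),
      pct_common_all = 100 * x$counts$common_all / as.numeric(sizes)
    )
  })
}
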