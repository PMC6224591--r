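#' Run the comparative immunopeptidome pipeline
#'
#' Orchestrates the analysis stages over one or more data sets from a
#' single configuration (a nested list, or the path to a YAML file with
#' the same structure), writing per-stage tables under `out_dir` and a
#' machine-readable JSON summary stamped with the seed and a hash of the
#' configuration. Stages execute in dependency order; a failing stage
#' aborts with its name.
#'
#' Configuration keys (all stage sections optional; a stage only runs if
#' it is in `stages` and its inputs are available):
#' \describe{
#'   \item{seed}{integer, required; controls every stochastic stage.}
#'   \item{out_dir}{output directory, required.}
#'   \item{stages}{character vector from `simulate`, `filter`, `motif`,
#'     `enrich`, `covary`, `pca`, `overlap`, `mrm`, `melt`, `report`.}
#'   \item{datasets}{either `simulate = <character vector of
#'     [b57_example_spec()] allotypes>` (with optional `n`), or
#'     `tables = <named list of list(path, dialect)>`.}
#'   \item{filter}{`cutoff`, `identity_mode`, and optional contaminant
#'     list paths `endogenous`, `generic`, `hla_fasta`.}
#'   \item{motif}{`lengths` (default 9), `min_prevalence`.}
#'   \item{enrich}{`alpha`, `background` (`"embedded"` or FASTA path).}
#'   \item{covary}{`smooth`, optional `n_min`.}
#'   \item{pca}{`k_candidates`.}
#'   \item{overlap}{`primary_cutoff`, `rescue_cutoff`, `identity_mode`.}
#'   \item{mrm}{`transitions`, `library`, `norms` (CSV/TSV paths).}
#'   \item{melt}{`curves` (long CSV path), optional `contrasts` (tibble
#'     or path: label, variant, reference).}
#' }
#'
#' @param config Nested list or YAML path.
#' @return Invisibly, the summary list (also written as
#'   `summary.json` in `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) abort("config$seed is required")
  if (is.null(config$out_dir)) abort("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("filter", "motif", "enrich", "report")
  cfg_hash <- rlang::hash(config)
  summary <- list(config_hash = cfg_hash, seed = config$seed, stages = list())

  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    summary$stages[[name]] <<- res
    invisible(res)
  }

  tables <- list()
  raw <- list()

  run_stage("simulate", function() {
    sim <- config$datasets$simulate
    if (is.null(sim)) abort("no datasets$simulate entry in config")
    n <- config$datasets$n %||% 3000
    out <- list()
    for (k in seq_along(sim)) {
      spec <- b57_example_spec(sim[k], n = n, seed = config$seed + k)
      tab <- simulate_repertoire(spec)
      path <- file.path(config$out_dir, paste0(gsub("[^A-Za-z0-9]", "_", sim[k]),
                                               "_peptides.tsv"))
      readr::write_tsv(select(tab, -"is_contaminant"), path)
      tables[[sim[k]]] <<- list(path = path, dialect = list())
      # summaries carry the basename so reruns in different directories
      # produce identical reports
      out[[sim[k]]] <- list(n_rows = nrow(tab), file = basename(path))
    }
    out
  })

  if (!length(tables) && !is.null(config$datasets$tables)) {
    tables <- config$datasets$tables
  }

  load_raw <- function() {
    if (!length(raw)) {
      raw <<- purrr::imap(tables, function(t, nm) {
        read_peptide_table(t$path, dialect = t$dialect %||% list())
      })
    }
    raw
  }

  repertoires <- list()
  run_stage("filter", function() {
    fc <- config$filter %||% list()
    lists <- contaminant_lists(
      endogenous_ligands = fc$endogenous %||% character(),
      generic_contaminants = fc$generic %||% character(),
      hla_proteins = fc$hla_fasta %||% character()
    )
    out <- purrr::imap(load_raw(), function(tab, nm) {
      rep <- filter_repertoire(tab, cutoff = fc$cutoff %||% 95, lists = lists,
                               identity_mode = fc$identity_mode %||% "sequence_only",
                               allotype = nm)
      repertoires[[nm]] <<- rep
      write_repertoire(rep, file.path(config$out_dir,
                                      paste0(gsub("[^A-Za-z0-9]", "_", nm),
                                             "_repertoire.tsv")))
      c(list(n_peptides = nrow(rep)),
        setNames(as.list(provenance(rep)$removed),
                 paste0("removed_", provenance(rep)$filter)))
    })
    out
  })

  run_stage("motif", function() {
    mc <- config$motif %||% list()
    lengths <- mc$lengths %||% 9
    purrr::imap(repertoires, function(rep, nm) {
      ld <- length_distribution(rep)
      readr::write_tsv(ld, file.path(config$out_dir,
                                     paste0(gsub("[^A-Za-z0-9]", "_", nm),
                                            "_lengths.tsv")))
      per_len <- lapply(setNames(lengths, lengths), function(L) {
        pfm <- position_frequency_matrix(rep, L)
        ms <- motif_summary(pfm, mc$min_prevalence %||% 0.10)
        readr::write_tsv(ms, file.path(config$out_dir,
                                       paste0(gsub("[^A-Za-z0-9]", "_", nm),
                                              "_motif_", L, ".tsv")))
        list(n = pfm$n, n_motif_entries = nrow(ms))
      })
      list(modal_length = ld$length[which.max(ld$count)], per_length = per_len)
    })
  })

  run_stage("enrich", function() {
    ec <- config$enrich %||% list()
    ref <- background_frequencies(ec$background %||% "embedded")
    lengths <- (config$motif %||% list())$lengths %||% 9
    purrr::imap(repertoires, function(rep, nm) {
      lapply(setNames(lengths, lengths), function(L) {
        prof <- enrichment_profile(position_frequency_matrix(rep, L), ref,
                                   alpha = ec$alpha %||% 0.05)
        readr::write_tsv(as_tibble(prof),
                         file.path(config$out_dir,
                                   paste0(gsub("[^A-Za-z0-9]", "_", nm),
                                          "_enrichment_", L, ".tsv")))
        omega2 <- prof[prof$position == p_omega(L, 2), ]
        list(
          n_enriched = sum(prof$status == "enriched"),
          n_depleted = sum(prof$status == "depleted"),
          omega2_enriched = omega2$aa[omega2$status == "enriched"]
        )
      })
    })
  })

  run_stage("covary", function() {
    cc <- config$covary %||% list()
    lengths <- (config$motif %||% list())$lengths %||% 9
    purrr::imap(repertoires, function(rep, nm) {
      lapply(setNames(lengths, lengths), function(L) {
        cm <- coupling_matrix(rep, L, n_min = cc$n_min,
                              smooth = cc$smooth %||% 0.05)
        readr::write_tsv(tidy(cm),
                         file.path(config$out_dir,
                                   paste0(gsub("[^A-Za-z0-9]", "_", nm),
                                          "_coupling_", L, ".tsv")))
        top <- top_coupled_pairs(cm, 1)
        list(top_pair = paste0(top$i, "-", top$j),
             top_value = round(top$value, 4))
      })
    })
  })

  run_stage("pca", function() {
    pc <- config$pca %||% list()
    lengths <- (config$motif %||% list())$lengths %||% 9
    purrr::imap(repertoires, function(rep, nm) {
      lapply(setNames(lengths, lengths), function(L) {
        feats <- encode_peptides(rep, L)
        fit <- pca_cluster(feats, k_candidates = pc$k_candidates %||% 2:6,
                           seed = config$seed)
        readr::write_tsv(
          tibble(sequence = fit$sequences, PC1 = fit$scores[, 1],
                 PC2 = fit$scores[, 2], cluster = fit$labels),
          file.path(config$out_dir, paste0(gsub("[^A-Za-z0-9]", "_", nm),
                                           "_pca_", L, ".tsv")))
        g <- glance(fit)
        list(k = g$k, mean_silhouette = round(g$mean_silhouette, 4),
             cluster_percent = round(fit$cluster_percent, 2))
      })
    })
  })

  run_stage("overlap", function() {
    oc <- config$overlap %||% list()
    if (length(tables) < 2) abort("overlap needs >= 2 datasets")
    ov <- repertoire_overlap(
      load_raw(),
      primary_cutoff = oc$primary_cutoff %||% 95,
      rescue_cutoff = oc$rescue_cutoff %||% 20,
      identity_mode = oc$identity_mode %||% "sequence_plus_modifications"
    )
    readr::write_tsv(tidy(ov), file.path(config$out_dir, "overlap_membership.tsv"))
    list(common_all = ov$counts$common_all,
         effective_size = as.list(ov$counts$effective_size),
         unique = as.list(ov$counts$unique))
  })

  run_stage("mrm", function() {
    mc <- config$mrm
    if (is.null(mc)) abort("no mrm section in config")
    trans <- read_any_delim(mc$transitions)
    lib <- read_any_delim(mc$library)
    norms <- read_any_delim(mc$norms)
    det <- validate_detections(trans, lib)
    ab <- relative_abundance(det, trans, norms)
    readr::write_tsv(det, file.path(config$out_dir, "mrm_detections.tsv"))
    readr::write_tsv(ab, file.path(config$out_dir, "mrm_abundance.tsv"))
    list(n_validated = sum(det$validated),
         n_rescued = sum(det$basis == "rt_dotp_rescued"),
         n_rejected = sum(det$basis == "rejected"))
  })

  run_stage("melt", function() {
    mc <- config$melt
    if (is.null(mc)) abort("no melt section in config")
    curves <- read_any_delim(mc$curves)
    fits <- fit_melt_curves(curves)
    summ <- summarize_replicates(fits)
    readr::write_tsv(summ, file.path(config$out_dir, "melt_tm.tsv"))
    out <- list(n_fitted = sum(!is.na(fits$tm)),
                n_failed = sum(is.na(fits$tm)))
    if (!is.null(mc$contrasts)) {
      contrasts <- if (is.character(mc$contrasts)) read_any_delim(mc$contrasts)
                   else as_tibble(mc$contrasts)
      dt <- delta_tm_table(summ, contrasts)
      readr::write_tsv(dt, file.path(config$out_dir, "melt_delta_tm.tsv"))
      out$delta_tm <- setNames(as.list(dt$delta_tm), dt$label)
    }
    out
  })

  if ("report" %in% stages || TRUE) {
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 8)
  }
  invisible(summary)
}

read_any_delim <- function(path) {
  stopifnot(is.character(path), file.exists(path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

#' Bundled thermal-stability reference summaries
#'
#' Published replicate-mean melting temperatures (with standard deviation
#' and replicate count) for HLA-B57-family complexes with LSSPVTKSF,
#' LTVQVARVY, SAAADETLRLW and their P-omega-2 -> Gln / P-omega -> Trp
#' substitution variants. Used as fixed inputs to [delta_tm()] /
#' [delta_tm_table()]; sample ids are `<allotype>/<peptide>`.
#'
#' @return Tibble with columns `sample`, `mean_tm`, `sd_tm`, `n`.
#' @export
b57_tm_summaries <- function() {
  path <- system.file("extdata", "b57_tm_summaries.tsv", package = "immunopep")
  readr::read_tsv(path, show_col_types = FALSE) %>%
    mutate(sample = paste0(.data$allotype, "/", .data$peptide)) %>%
    select("sample", "allotype", "peptide", "mean_tm", "sd_tm", "n")
}
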