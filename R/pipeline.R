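PIPELINE_SCHEMA <- list(
  out_dir = NULL, seed = NULL, n_samples = NULL,
  sim = c("n_coding_transcripts", "n_lncrna_transcripts",
          "utr5_length_range", "cds_length_range", "utr3_length_range",
          "planted_orf_mix", "expression_log10_mean", "expression_log10_sd",
          "initiation_enrichment", "background_scale", "nb_dispersion",
          "offset_map", "read_length_weights", "total_reads",
          "start_codons", "seed"),
  antigens = c("n", "class_mix", "epitope_length", "epitope_offset"),
  offsets = c("search_window", "length_range", "min_reads_per_length"),
  caller = c("codon_set", "min_count", "alpha", "exclusion_radius",
             "min_codons", "min_dispersion", "mt_scope"),
  match = c("mode", "tis_tolerance"),
  report = c("expression_thresholds")
)

#' Assemble and validate a pipeline configuration
#'
#' One schema-validated configuration drives the whole synthetic study:
#' unknown keys anywhere are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param out_dir Result directory (created if missing).
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_samples Number of simulated profiling samples (default 6).
#' @param sim Named list of [sim_config()] overrides.
#' @param antigens Named list: `n`, `class_mix`, `epitope_length`,
#'   `epitope_offset` for [plant_antigens()].
#' @param offsets Named list of [estimate_psite_offsets()] parameters.
#' @param caller Named list of [call_tis()] parameters (`codon_set` given as
#'   `"near_cognate"`/`"atg"`).
#' @param match Named list: `mode`, `tis_tolerance`.
#' @param report Named list: `expression_thresholds`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_samples = 6L,
                            sim = list(), antigens = list(),
                            offsets = list(), caller = list(),
                            match = list(), report = list()) {
  sections <- list(sim = sim, antigens = antigens, offsets = offsets,
                   caller = caller, match = match, report = report)
  for (nm in names(sections)) {
    unknown <- setdiff(names(sections[[nm]]), PIPELINE_SCHEMA[[nm]])
    if (length(unknown)) {
      abort(sprintf("unknown key(s) in config section '%s': %s",
                    nm, paste(unknown, collapse = ", ")))
    }
  }
  structure(c(list(out_dir = out_dir, seed = as.integer(seed),
                   n_samples = as.integer(n_samples)), sections),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; extension selects the parser. Unknown keys at
#'   any level are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), names(PIPELINE_SCHEMA))
  if (length(unknown)) {
    abort(sprintf("unknown top-level config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  for (nm in c("sim", "antigens", "caller")) {
    for (vec in c("planted_orf_mix", "offset_map", "read_length_weights",
                  "class_mix")) {
      if (!is.null(raw[[nm]][[vec]])) {
        raw[[nm]][[vec]] <- unlist(raw[[nm]][[vec]])
      }
    }
  }
  do.call(pipeline_config, raw)
}

write_provenance <- function(dir, stage, params, counts) {
  path <- file.path(dir, "provenance", paste0(stage, ".json"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(stage = stage,
         package = "ribotis",
         version = as.character(packageVersion("ribotis")),
         params = params, counts = counts),
    path, auto_unbox = TRUE, pretty = TRUE, force = TRUE, digits = NA)
  invisible(path)
}

#' Run the full synthetic study end to end
#'
#' simulate -> offsets -> tracks -> call -> build ORFs -> classify -> match
#' -> report, every stage writing its TSV plus a JSON provenance record
#' (parameters and record counts) under `config$out_dir`. Deterministic for
#' a given config: sample `i` uses seed `config$seed + i`.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the key result objects
#'   (`sim`, `catalog`, `calls`, `dm`, `sensitivity_any`,
#'   `sensitivity_all`, `histogram`, `strata`, `class_summary`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$out_dir)) {
    abort(sprintf("cannot create output directory %s", config$out_dir))
  }
  scfg <- do.call(sim_config,
                  modifyList(list(seed = config$seed), config$sim))
  sim <- simulate_transcriptome(scfg)
  write_transcriptome(sim$transcripts,
                      file.path(config$out_dir, "transcriptome.fa"),
                      file.path(config$out_dir, "annotation.tsv"))
  write_expression(sim$expression,
                   file.path(config$out_dir, "expression.tsv"))
  readr::write_tsv(sim$planted,
                   file.path(config$out_dir, "ground_truth.tsv"))
  write_provenance(config$out_dir, "simulate", unclass(scfg)[
    setdiff(names(scfg), c("offset_map", "read_length_weights"))],
    list(n_transcripts = nrow(sim$transcripts),
         n_planted = nrow(sim$planted)))

  acfg <- modifyList(list(n = 10, epitope_length = 9), config$antigens)
  catalog <- plant_antigens(sim, n = acfg$n, class_mix = acfg$class_mix,
                            epitope_length = acfg$epitope_length,
                            epitope_offset = acfg$epitope_offset,
                            seed = config$seed)
  readr::write_tsv(catalog, file.path(config$out_dir, "antigen_catalog.tsv"))
  write_provenance(config$out_dir, "antigens", acfg,
                   list(n_antigens = nrow(catalog)))

  ccfg <- modifyList(list(codon_set = "near_cognate", min_count = 5,
                          alpha = 0.05), config$caller)
  codons <- tis_codon_set(ccfg$codon_set)
  sample_ids <- sprintf("sample%d", seq_len(config$n_samples))
  calls_by_sample <- list()
  for (i in seq_len(config$n_samples)) {
    sid <- sample_ids[i]
    fp <- simulate_footprints(sim, seed = config$seed + i)
    fp_path <- file.path(config$out_dir, paste0(sid, ".footprints.tsv"))
    write_footprints(fp, fp_path)
    fp <- read_footprints(fp_path, sim$transcripts)
    off <- do.call(estimate_psite_offsets,
                   c(list(fp, sim$transcripts), config$offsets))
    readr::write_tsv(off, file.path(config$out_dir,
                                    paste0(sid, ".offsets.tsv")))
    tracks <- psite_tracks(fp, sim$transcripts, off)
    calls <- do.call(call_tis, c(
      list(tracks, sim$transcripts, codon_set = codons),
      ccfg[setdiff(names(ccfg), "codon_set")]))
    orfs <- build_orfs(calls, sim$transcripts) |>
      classify_orfs(sim$transcripts) |>
      dplyr::mutate(sample_id = sid)
    readr::write_tsv(orfs, file.path(config$out_dir,
                                     paste0(sid, ".orf_calls.tsv")))
    write_provenance(config$out_dir, paste0("call_", sid),
                     ccfg, c(as.list(glance(calls)),
                             list(n_footprints = nrow(fp),
                                  n_orfs = nrow(orfs))))
    calls_by_sample[[sid]] <- orfs
  }

  mcfg <- modifyList(list(mode = "peptide_containment", tis_tolerance = 0),
                     config$match)
  dm <- detection_matrix(catalog, calls_by_sample, mode = mcfg$mode,
                         tis_tolerance = mcfg$tis_tolerance)
  readr::write_tsv(tidy(dm), file.path(config$out_dir,
                                       "detection_matrix.tsv"))

  rcfg <- modifyList(list(expression_thresholds = c(1, 10)), config$report)
  all_calls <- purrr::list_rbind(calls_by_sample)
  summ <- class_summary(all_calls)
  sens_any <- detection_sensitivity(dm, "any_sample")
  sens_all <- detection_sensitivity(dm, "all_samples")
  hist <- detection_histogram(dm)
  strata <- expression_strata(dm, sim$expression,
                              thresholds = rcfg$expression_thresholds)
  readr::write_tsv(summ, file.path(config$out_dir, "class_summary.tsv"))
  readr::write_tsv(dplyr::bind_rows(sens_any, sens_all),
                   file.path(config$out_dir, "sensitivity.tsv"))
  readr::write_tsv(hist, file.path(config$out_dir, "histogram.tsv"))
  readr::write_tsv(strata, file.path(config$out_dir, "strata.tsv"))
  jsonlite::write_json(
    list(pooled_sensitivity_any_pct =
           sens_any$sensitivity_pct[sens_any$class_label == "pooled"],
         pooled_sensitivity_all_pct =
           sens_all$sensitivity_pct[sens_all$class_label == "pooled"],
         n_orfs = glance(dm)$n_orfs,
         n_samples = config$n_samples),
    file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA)
  write_provenance(config$out_dir, "report", rcfg,
                   list(n_orfs = glance(dm)$n_orfs))
  invisible(list(sim = sim, catalog = catalog, calls = all_calls, dm = dm,
                 sensitivity_any = sens_any, sensitivity_all = sens_all,
                 histogram = hist, strata = strata, class_summary = summ,
                 out_dir = config$out_dir))
}
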