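# Workflow commands tying the stages together, plus the result writers.
# Each cmd_* function is a thin, scriptable wrapper used by the
# exec/peakdecoder command-line entry point.

#' Write the FDR-threshold and annotation result files
#'
#' Emits `PeakDecoder-FDR-thresholds_<dataset>.csv` (score threshold /
#' estimated FDR pairs) and `PeakDecoder-annotations_<dataset>.csv` (one
#' row per metabolite x run with score, error dimensions and pass flag)
#' under `path_prefix`.
#'
#' @param annotations annotation data frame (with `passed` flag), or `NULL`
#' @param fdr_table data frame from [build_fdr_table()], or `NULL`
#' @param path_prefix output directory (created if needed)
#' @param dataset_tag tag inserted into the file names
#' @return named character vector of the files written
#' @export
write_results <- function(annotations, fdr_table, path_prefix,
                          dataset_tag = "dataset") {
  dir.create(path_prefix, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  if (!is.null(fdr_table)) {
    p <- file.path(path_prefix,
                   sprintf("PeakDecoder-FDR-thresholds_%s.csv", dataset_tag))
    write_csv_c(fdr_table[, c("score_threshold", "fdr")], p)
    out["fdr_thresholds"] <- p
  }
  if (!is.null(annotations)) {
    p <- file.path(path_prefix,
                   sprintf("PeakDecoder-annotations_%s.csv", dataset_tag))
    write_csv_c(annotations, p)
    out["annotations"] <- p
  }
  out
}

#' Workflow command: simulate a labelled dataset
#'
#' @param out_dir output directory
#' @param cfg a [simulation_config()]
#' @return see [simulate_peakgroups()]
#' @export
cmd_simulate <- function(out_dir, cfg = simulation_config()) {
  res <- simulate_peakgroups(cfg, out_dir)
  message(sprintf("simulate: %d true + %d false groups x %d runs -> %s",
                  cfg$n_true_groups, cfg$n_false_groups, cfg$n_runs,
                  out_dir))
  invisible(res)
}

#' Workflow command: select targets, pair them and write decoy transitions
#'
#' Runs target selection, pairing within the representative run and decoy
#' generation, then writes the combined target/decoy transition list.
#'
#' @param alignment_path feature-alignment export
#' @param out_path transition-list CSV to write
#' @param dialect alignment dialect, see [read_feature_alignment()]
#' @param seed integer seed for the swap randomization
#' @param min_sn,min_fragments,rel_intensity_range,top_n see
#'   [select_targets()]
#' @param mz_window,min_rt_gap see [pair_targets()]
#' @param swap_fraction_range see [generate_decoys()]
#' @return invisibly, a list with `targets`, `pairs`, `decoys`,
#'   `transitions` and the per-stage counts `summary`
#' @export
cmd_make_decoys <- function(alignment_path, out_path,
                            dialect = "simple_tsv", seed = 1L,
                            min_sn = 15, min_fragments = 3,
                            rel_intensity_range = c(0.01, 1.30), top_n = 16,
                            mz_window = 50, min_rt_gap = 3,
                            swap_fraction_range = c(0.4, 0.6)) {
  features <- read_feature_alignment(alignment_path, dialect)
  targets <- select_targets(features, min_sn, min_fragments,
                            rel_intensity_range, top_n)
  if (length(targets) == 0)
    warning("no targets selected from ", alignment_path)
  paired <- pair_targets(targets, mz_window, min_rt_gap)
  dec <- generate_decoys(paired$pairs, swap_fraction_range, seed)
  kept_targets <- unlist(lapply(dec$pairs, function(p) list(p$a, p$b)),
                         recursive = FALSE)
  tr <- transition_table(kept_targets, dec$decoys)
  write_transition_list(tr, out_path)
  summary <- c(features = length(features), targets = length(targets),
               paired = 2L * length(paired$pairs),
               unpaired = length(paired$unpaired) + length(dec$rejected),
               decoys = length(dec$decoys))
  message(sprintf(
    "make-decoys: %d features -> %d targets -> %d paired, %d decoys (seed %d)",
    summary["features"], summary["targets"], summary["paired"],
    summary["decoys"], seed))
  invisible(list(targets = targets, pairs = dec$pairs,
                 decoys = dec$decoys, transitions = tr, summary = summary))
}

#' Workflow command: filter, train and write the FDR table
#'
#' @param xic_path training XIC report
#' @param out_dir output directory for the model archive and threshold CSV
#' @param dataset_tag tag for the output file names
#' @param seed integer seed
#' @param min_precursor_sn,min_good_fragments,min_total_fragments,thresholds
#'   see [filter_training_set()]
#' @param fdr_scores score the FDR table from the full `"training"` set (as
#'   the original method does) or from out-of-fold `"crossval"` scores,
#'   which avoid the optimistic bias of in-sample scoring (see
#'   [crossval_scores()])
#' @return invisibly, a list with `model`, `fdr_table`, `descriptors`,
#'   `filter_audit` and output `files`
#' @export
cmd_train <- function(xic_path, out_dir, dataset_tag = "dataset",
                      seed = 1L, min_precursor_sn = 20,
                      min_good_fragments = 2, min_total_fragments = 3,
                      thresholds = quality_thresholds(),
                      fdr_scores = c("training", "crossval")) {
  fdr_scores <- match.arg(fdr_scores)
  groups <- read_xic_report(xic_path)
  flt <- filter_training_set(groups, min_precursor_sn, min_good_fragments,
                             min_total_fragments, thresholds)
  desc <- descriptor_matrix(flt$groups)
  model <- train_peakdecoder(desc, seed = seed)
  fdr_table <- if (fdr_scores == "crossval")
    build_fdr_table(model, desc, scores = crossval_scores(desc, seed))
  else build_fdr_table(model, desc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model_path <- file.path(out_dir,
                          sprintf("PeakDecoder-model_%s.rds", dataset_tag))
  save_peakdecoder(model, model_path)
  files <- write_results(NULL, fdr_table, out_dir, dataset_tag)
  audit_path <- file.path(out_dir,
                          sprintf("PeakDecoder-filter-audit_%s.tsv",
                                  dataset_tag))
  utils::write.table(flt$audit, audit_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message(sprintf(
    "train: %d groups -> %d after filtering; CV accuracy %.2f%% (seed %d)",
    length(groups), length(flt$groups), model$cv_accuracy, seed))
  invisible(list(model = model, fdr_table = fdr_table, descriptors = desc,
                 filter_audit = flt$audit,
                 files = c(model = model_path, files,
                           filter_audit = audit_path)))
}

#' Workflow command: score query metabolites and apply cutoffs
#'
#' @param xic_path query XIC report
#' @param library_path MSP library
#' @param model_path model archive from [cmd_train()]
#' @param out_dir output directory
#' @param dataset_tag tag for output file names
#' @param fdr_table_path optional threshold CSV; when given, the score
#'   cutoff is taken at `fdr_target`
#' @param fdr_target requested FDR
#' @param max_mass_ppm,max_rt_error,max_ccs_pct,min_score see
#'   [apply_id_cutoffs()]
#' @return invisibly, a list with `annotations`, `identified` and output
#'   `files`
#' @export
cmd_score <- function(xic_path, library_path, model_path, out_dir,
                      dataset_tag = "dataset", fdr_table_path = NULL,
                      fdr_target = 0.01, max_mass_ppm = 18,
                      max_rt_error = 0.4, max_ccs_pct = 0.8,
                      min_score = 0.8) {
  if (!file.exists(model_path)) stop("model file not found: ", model_path)
  model <- load_peakdecoder(model_path)
  groups <- read_xic_report(xic_path)
  library <- read_library_msp(library_path)
  ann <- score_queries(model, groups, library)
  fdr_table <- NULL
  if (!is.null(fdr_table_path)) {
    tab <- utils::read.csv(fdr_table_path)
    fdr_table <- data.frame(score_threshold = tab$score_threshold,
                            fdr = tab$fdr)
  }
  res <- apply_id_cutoffs(ann, max_mass_ppm, max_rt_error, max_ccs_pct,
                          min_score, fdr_table, fdr_target)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- write_results(res$annotations, NULL, out_dir, dataset_tag)
  id_path <- file.path(out_dir,
                       sprintf("PeakDecoder-identifications_%s.csv",
                               dataset_tag))
  write_csv_c(res$identified, id_path)
  message(sprintf("score: %d annotations, %d identified (score cutoff %.4g)",
                  nrow(res$annotations), nrow(res$identified),
                  res$min_score))
  invisible(list(annotations = res$annotations,
                 identified = res$identified,
                 min_score = res$min_score,
                 files = c(files, identifications = id_path)))
}

#' Workflow command: annotation-selectivity match counts
#'
#' @param alignment_path feature-alignment export
#' @param library_path MSP library
#' @param out_path TSV to write
#' @param dialect alignment dialect
#' @param mass_tol,rt_tol,ccs_tol_pct see [match_features()]
#' @return invisibly, the match-count data frame
#' @export
cmd_match <- function(alignment_path, library_path, out_path,
                      dialect = "simple_tsv", mass_tol = 0.01,
                      rt_tol = 0.2, ccs_tol_pct = 0.8) {
  features <- read_feature_alignment(alignment_path, dialect)
  library <- read_library_msp(library_path)
  counts <- match_features(features, library, mass_tol, rt_tol,
                           ccs_tol_pct)
  utils::write.table(counts, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message(sprintf("match: %d features x %d library entries -> %s",
                  length(features), length(library), out_path))
  invisible(counts)
}
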