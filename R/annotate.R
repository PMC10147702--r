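# Query scoring, identification cutoffs and annotation selectivity.
#
# Query peak-groups extracted at library coordinates are scored with the
# trained model using the library fragment intensities as the expected
# vector; precursor mass, RT and CCS errors are computed against the
# library, and a metabolite is identified when at least one run passes all
# cutoffs.  match_features() quantifies how combining mass, RT and CCS
# tolerances narrows the candidate feature space.

#' Score query metabolites against all runs
#'
#' For every query peak-group (grouped per run), fragment transitions are
#' matched to the library entry of the same name by m/z and the library
#' intensities become the expected vector for the descriptors.  Groups
#' lacking enough scorable fragments are annotated at the MS1-only
#' `RT-CCS` level with a missing score; groups with fragment evidence get
#' level `RT-CCS-DIA`.
#'
#' @param model a [train_peakdecoder()] model
#' @param groups list of [peak_group()] objects with label `"query"` whose
#'   `group_id` equals the library entry name
#' @param library list of [library_entry()] objects
#' @param intensity_mode use the library's `"raw"` fragment intensities or
#'   the max-100 `"normalized"` ones as the expected vector
#' @param mz_tol m/z tolerance (Th) for matching report fragments to
#'   library fragments
#' @return data frame with one row per metabolite x run: `metabolite`,
#'   `run_id`, `score`, `mass_error_ppm`, `rt_error`, `ccs_error_pct`,
#'   `n_fragments`, `level`
#' @export
score_queries <- function(model, groups, library,
                          intensity_mode = c("raw", "normalized"),
                          mz_tol = 0.01) {
  intensity_mode <- match.arg(intensity_mode)
  lib <- stats::setNames(library, vapply(library, `[[`, "", "name"))
  rows <- list()
  for (g in groups) {
    if (g$label != "query") next
    entry <- lib[[g$group_id]]
    if (is.null(entry)) {
      message("query group ", g$group_id, " absent from library; skipped")
      next
    }
    expected <- rep(NA_real_, nrow(g$fragments))
    if (nrow(g$fragments) > 0 && nrow(entry$fragments) > 0) {
      for (i in seq_len(nrow(g$fragments))) {
        d <- abs(entry$fragments$mz - g$fragments$mz[i])
        j <- which.min(d)
        if (length(j) == 1 && d[j] <= mz_tol)
          expected[i] <- if (intensity_mode == "raw")
            entry$fragments$intensity[j] else entry$fragments$rel_intensity[j]
      }
    }
    desc <- compute_descriptors(g, expected = expected)
    scorable <- all(is.finite(desc))
    score <- if (scorable)
      peakdecoder_score(model, as.data.frame(as.list(desc)))
    else NA_real_
    exp_rt <- if (!is.na(g$expected_rt)) g$expected_rt else entry$rt
    exp_ccs <- if (!is.na(g$expected_ccs)) g$expected_ccs else entry$ccs
    rows[[length(rows) + 1L]] <- data.frame(
      metabolite = g$group_id, run_id = g$run_id, score = score,
      mass_error_ppm = g$precursor$mass_error_ppm,
      rt_error = g$precursor$rt - exp_rt,
      ccs_error_pct = if (!is.na(g$observed_ccs) && !is.na(exp_ccs))
        100 * (g$observed_ccs - exp_ccs) / exp_ccs else NA_real_,
      n_fragments = sum(!is.na(expected) & !is.na(g$fragments$area)),
      level = if (scorable) "RT-CCS-DIA" else "RT-CCS")
  }
  if (length(rows) == 0)
    return(data.frame(metabolite = character(), run_id = character(),
                      score = numeric(), mass_error_ppm = numeric(),
                      rt_error = numeric(), ccs_error_pct = numeric(),
                      n_fragments = integer(), level = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the identification cutoffs
#'
#' A metabolite is identified when, in at least one run, all cutoffs are
#' met: absolute precursor mass error below `max_mass_ppm`, absolute RT
#' error below `max_rt_error`, absolute CCS error below `max_ccs_pct`, and
#' PeakDecoder score above `min_score` (or above the threshold for
#' `fdr_target` when an FDR table is supplied).  Error comparisons use
#' absolute values; a missing error dimension cannot pass its cutoff.
#'
#' @param annotations data frame from [score_queries()]
#' @param max_mass_ppm precursor mass-error cutoff (ppm)
#' @param max_rt_error precursor RT-error cutoff (minutes)
#' @param max_ccs_pct CCS-error cutoff (percent)
#' @param min_score PeakDecoder score cutoff
#' @param fdr_table optional table from [build_fdr_table()]; replaces
#'   `min_score` by the threshold at `fdr_target` and attaches a q-value
#' @param fdr_target requested FDR when `fdr_table` is given
#' @return list with `annotations` (input plus `passed` flag and, with an
#'   FDR table, `q_value`), `identified` (best-replicate summary of the
#'   identified metabolites) and `min_score` (the score cutoff used)
#' @export
apply_id_cutoffs <- function(annotations, max_mass_ppm = 18,
                             max_rt_error = 0.4, max_ccs_pct = 0.8,
                             min_score = 0.8, fdr_table = NULL,
                             fdr_target = 0.01) {
  a <- annotations
  if (!is.null(fdr_table)) {
    thr <- fdr_score_threshold(fdr_table, fdr_target)
    min_score <- thr$score_threshold
    a$q_value <- fdr_at_score(fdr_table, a$score)
  }
  in_band <- function(x, cut) !is.na(x) & abs(x) < cut
  a$passed <- in_band(a$mass_error_ppm, max_mass_ppm) &
    in_band(a$rt_error, max_rt_error) &
    in_band(a$ccs_error_pct, max_ccs_pct) &
    !is.na(a$score) & a$score > min_score
  passed <- a[a$passed, , drop = FALSE]
  identified <- if (nrow(passed) > 0) {
    best <- do.call(rbind, lapply(split(passed, passed$metabolite),
                                  function(d) d[which.max(d$score), ]))
    rownames(best) <- NULL
    best[order(-best$score), , drop = FALSE]
  } else passed
  list(annotations = a, identified = identified, min_score = min_score)
}

#' Annotation selectivity: feature matches per library entry
#'
#' Counts, for every library entry, the untargeted features matching by
#' accurate mass alone, mass + RT, mass + CCS, and mass + RT + CCS.  The
#' mass tolerance is absolute (Th), the RT tolerance is minutes, and the
#' CCS tolerance is relative (percent).  Features lacking CCS contribute
#' only to the mass and mass-RT counts.
#'
#' @param features list of [deconvoluted_feature()] objects
#' @param library list of [library_entry()] objects
#' @param mass_tol m/z tolerance (Th)
#' @param rt_tol RT tolerance (minutes)
#' @param ccs_tol_pct CCS tolerance (percent, relative to the library CCS)
#' @return data frame with one row per library entry: `name`, `mass_only`,
#'   `mass_rt`, `mass_ccs`, `mass_rt_ccs`
#' @export
match_features <- function(features, library, mass_tol = 0.01,
                           rt_tol = 0.2, ccs_tol_pct = 0.8) {
  fmz <- vapply(features, `[[`, 0, "precursor_mz")
  frt <- vapply(features, `[[`, 0, "rt")
  fcc <- vapply(features, `[[`, 0, "ccs")
  rows <- lapply(library, function(e) {
    m <- abs(fmz - e$precursor_mz) <= mass_tol
    r <- !is.na(frt) & !is.na(e$rt) & abs(frt - e$rt) <= rt_tol
    c_ok <- !is.na(fcc) & !is.na(e$ccs) &
      100 * abs(fcc - e$ccs) / e$ccs <= ccs_tol_pct
    data.frame(name = e$name, mass_only = sum(m), mass_rt = sum(m & r),
               mass_ccs = sum(m & c_ok), mass_rt_ccs = sum(m & r & c_ok))
  })
  out <- if (length(rows) > 0) do.call(rbind, rows)
  else data.frame(name = character(), mass_only = integer(),
                  mass_rt = integer(), mass_ccs = integer(),
                  mass_rt_ccs = integer())
  rownames(out) <- NULL
  out
}
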