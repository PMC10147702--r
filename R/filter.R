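# Training-set quality filter.
#
# The preliminary target/decoy set is refined per run: fragments with
# unassigned height are removed, each remaining fragment is scored against
# five quality rules, low-S/N precursors are dropped, and targets keep their
# good fragments plus a bounded number of the least-bad ones (deliberately
# retaining some interference-like fragments).  Decoys survive only when
# their paired target survived with the same fragment subset, and the target
# fragment heights become the expected intensities of both members.

#' Default fragment-quality thresholds
#'
#' @return named list: `min_rel_height` (fraction of precursor height),
#'   `max_mass_error_ppm`, `max_rt_diff` (minutes), `fwhm_mult` (multiple of
#'   the precursor FWHM)
#' @export
quality_thresholds <- function() {
  list(min_rel_height = 0.01, max_mass_error_ppm = 15,
       max_rt_diff = 0.1, fwhm_mult = 2)
}

#' Flag low-quality fragment metrics within a peak-group
#'
#' A fragment metric is flagged when: area <= 0 (or missing); height below
#' `min_rel_height` of the precursor height; absolute mass error above
#' `max_mass_error_ppm`; RT difference to the precursor above
#' `max_rt_diff`; or FWHM difference to the precursor above `fwhm_mult`
#' times the precursor FWHM.  Fragments with unassigned height (missing or
#' zero) must be removed beforehand, see [drop_unassigned_height()].
#'
#' @param group a [peak_group()]
#' @param thresholds list as returned by [quality_thresholds()]
#' @return data frame with one row per fragment: logical columns
#'   `bad_area`, `bad_height`, `bad_mass`, `bad_rt`, `bad_fwhm` and the
#'   count `n_bad`
#' @export
flag_fragment_quality <- function(group, thresholds = quality_thresholds()) {
  f <- group$fragments
  p <- group$precursor
  na_true <- function(x) ifelse(is.na(x), TRUE, x)
  bad_area <- na_true(f$area <= 0)
  bad_height <- na_true(f$height < thresholds$min_rel_height * p$height)
  bad_mass <- na_true(abs(f$mass_error_ppm) > thresholds$max_mass_error_ppm)
  bad_rt <- na_true(abs(f$rt - p$rt) > thresholds$max_rt_diff)
  bad_fwhm <- na_true(abs(f$fwhm - p$fwhm) > thresholds$fwhm_mult * p$fwhm)
  data.frame(bad_area = bad_area, bad_height = bad_height,
             bad_mass = bad_mass, bad_rt = bad_rt, bad_fwhm = bad_fwhm,
             n_bad = bad_area + bad_height + bad_mass + bad_rt + bad_fwhm)
}

#' Remove fragments with unassigned height from a peak-group
#'
#' @param group a [peak_group()]
#' @return the group with fragments having missing or zero height removed
#' @export
drop_unassigned_height <- function(group) {
  keep <- !is.na(group$fragments$height) & group$fragments$height != 0
  group$fragments <- group$fragments[keep, , drop = FALSE]
  group
}

#' Filter the training set to high-quality peak-groups
#'
#' Applies, per run: (i) targets with precursor S/N below
#' `min_precursor_sn` are dropped; (ii) targets with fewer than
#' `min_good_fragments` fragments with zero flagged metrics are dropped;
#' (iii) within a kept target, fragments are ordered by (number of flags
#' ascending, height descending) and fragments ranked beyond twice the
#' number of zero-flag fragments are removed -- this intentionally keeps
#' some low-quality fragments to represent interferences; (iv) targets with
#' fewer than `min_total_fragments` surviving fragments are dropped; (v) a
#' decoy survives only if its paired target survived in the same run and
#' the decoy can mirror the target's surviving fragment subset (matched by
#' intensity rank), and targets whose decoy cannot are dropped too, so
#' target:decoy counts stay equal; (vi) the target fragment heights become
#' the expected intensities of both the target and its decoy.
#'
#' @param groups list of [peak_group()] objects labelled target/decoy
#' @param min_precursor_sn minimum precursor S/N
#' @param min_good_fragments minimum number of zero-flag fragments
#' @param min_total_fragments minimum surviving fragments per target
#' @param thresholds fragment-quality thresholds, see
#'   [quality_thresholds()]
#' @return list with `groups` (the surviving target and decoy peak-groups)
#'   and `audit` (data frame `group_id, run_id, rule` naming the rule that
#'   removed each dropped group)
#' @export
filter_training_set <- function(groups, min_precursor_sn = 20,
                                min_good_fragments = 2,
                                min_total_fragments = 3,
                                thresholds = quality_thresholds()) {
  labels <- vapply(groups, `[[`, "", "label")
  targets <- groups[labels == "target"]
  decoys <- groups[labels == "decoy"]
  dk <- vapply(decoys, function(g)
    paste(g$partner_id, g$run_id, sep = "\r"), "")

  audit <- list()
  note <- function(g, rule)
    audit[[length(audit) + 1L]] <<- data.frame(group_id = g$group_id,
                                               run_id = g$run_id,
                                               rule = rule)
  kept <- list()
  for (tg in targets) {
    tg <- drop_unassigned_height(tg)
    if (is.na(tg$precursor$sn) || tg$precursor$sn < min_precursor_sn) {
      note(tg, "low_precursor_sn"); next
    }
    if (nrow(tg$fragments) == 0) { note(tg, "no_assigned_fragments"); next }
    fl <- flag_fragment_quality(tg, thresholds)
    n_good <- sum(fl$n_bad == 0)
    if (n_good < min_good_fragments) { note(tg, "few_good_fragments"); next }
    ord <- order(fl$n_bad, -tg$fragments$height)
    keep_idx <- ord[seq_len(min(nrow(tg$fragments), 2L * n_good))]
    tg$fragments <- tg$fragments[keep_idx, , drop = FALSE]
    if (nrow(tg$fragments) < min_total_fragments) {
      note(tg, "few_total_fragments"); next
    }
    # paired decoy must mirror the surviving subset in this run
    di <- match(paste(tg$group_id, tg$run_id, sep = "\r"), dk)
    dec <- NULL
    if (!is.na(di)) {
      dec <- drop_unassigned_height(decoys[[di]])
      ranks <- tg$fragments$rank
      dmatch <- match(ranks, dec$fragments$rank)
      if (anyNA(dmatch)) {
        note(dec, "decoy_subset_mismatch")
        dec <- NULL
      } else {
        dec$fragments <- dec$fragments[dmatch, , drop = FALSE]
        # target fragment height becomes the expected intensity of both
        dec$fragments$expected_intensity <- tg$fragments$height
      }
    }
    if (is.null(dec)) { note(tg, "decoy_unavailable"); next }
    tg$fragments$expected_intensity <- tg$fragments$height
    kept <- c(kept, list(tg, dec))
  }
  # decoys whose target never survived
  kept_ids <- vapply(kept, function(g)
    paste(g$group_id, g$run_id, sep = "\r"), "")
  for (d in decoys) {
    if (!paste(d$group_id, d$run_id, sep = "\r") %in% kept_ids)
      note(d, "orphan_decoy")
  }
  list(groups = kept,
       audit = if (length(audit) > 0) do.call(rbind, audit)
       else data.frame(group_id = character(), run_id = character(),
                       rule = character()))
}
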