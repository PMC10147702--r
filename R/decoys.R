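# Target selection and decoy generation.
#
# Decoys are built directly from deconvoluted experimental peak-groups:
# targets are associated in pairs of similar precursor mass but distant
# retention time, and a pair of decoys is generated by keeping each
# precursor's properties and exchanging the m/z values of 40-60% of the
# fragments between the two members, matched by intensity rank.  The paired
# construction guarantees that decoy precursor m/z, RT, CCS and
# fragment-count distributions equal the targets' exactly.

#' Select target peak-groups from deconvoluted features
#'
#' Keeps features with sufficient signal-to-noise and at least
#' `min_fragments` fragments whose intensity falls within
#' `rel_intensity_range` of the precursor height.  Out-of-band fragments are
#' removed and at most `top_n` of the most intense fragments are retained
#' (re-ranked).
#'
#' @param features list of [deconvoluted_feature()] objects
#' @param min_sn minimum precursor S/N (kept when `sn >= min_sn`)
#' @param min_fragments minimum number of in-band fragments
#' @param rel_intensity_range fragment intensity band as a fraction of the
#'   precursor height, inclusive
#' @param top_n maximum number of fragments retained per target
#' @return list of selected features with filtered fragment lists
#' @export
select_targets <- function(features, min_sn = 15, min_fragments = 3,
                           rel_intensity_range = c(0.01, 1.30),
                           top_n = 16) {
  out <- list()
  for (f in features) {
    if (is.na(f$sn) || f$sn < min_sn) next
    if (is.na(f$height) || f$height <= 0) next
    rel <- f$fragments$intensity / f$height
    keep <- !is.na(rel) & rel >= rel_intensity_range[1] &
      rel <= rel_intensity_range[2]
    frg <- f$fragments[keep, c("mz", "intensity"), drop = FALSE]
    if (nrow(frg) < min_fragments) next
    frg <- rank_fragments(frg)
    if (nrow(frg) > top_n)
      frg <- frg[frg$rank <= top_n, , drop = FALSE]
    f$fragments <- frg
    out[[length(out) + 1L]] <- f
  }
  out
}

#' Pair targets for decoy generation
#'
#' Pairs are formed within one representative run in a greedy one-pass over
#' targets in descending precursor height; each target may appear in at most
#' one pair.  An eligible partner has the same fragment count, a precursor
#' m/z within `mz_window`, and a retention-time difference of at least
#' `min_rt_gap`; among eligible partners, the one with the largest RT
#' difference is chosen (ties: smaller m/z difference).
#'
#' @param targets list of selected target features
#' @param mz_window maximum precursor m/z difference (Th)
#' @param min_rt_gap minimum RT difference (minutes), guards against pairing
#'   a repeated feature from a large tailing peak
#' @param representative_run run id to pair within; default the run
#'   contributing the most targets
#' @return list with elements `pairs` (list of lists with members `a`, `b`)
#'   and `unpaired` (character vector of feature ids)
#' @export
pair_targets <- function(targets, mz_window = 50, min_rt_gap = 3,
                         representative_run = NULL) {
  if (length(targets) == 0)
    return(list(pairs = list(), unpaired = character()))
  runs <- vapply(targets, `[[`, "", "run_id")
  if (is.null(representative_run))
    representative_run <- names(sort(table(runs), decreasing = TRUE))[1]
  targets <- targets[runs == representative_run]

  mz <- vapply(targets, `[[`, 0, "precursor_mz")
  rt <- vapply(targets, `[[`, 0, "rt")
  ht <- vapply(targets, `[[`, 0, "height")
  nf <- vapply(targets, function(f) nrow(f$fragments), 0L)
  ord <- order(-ht)
  used <- logical(length(targets))
  pairs <- list()
  for (i in ord) {
    if (used[i]) next
    cand <- which(!used & seq_along(targets) != i & nf == nf[i] &
                    abs(mz - mz[i]) <= mz_window &
                    abs(rt - rt[i]) >= min_rt_gap)
    if (length(cand) == 0) next
    dd <- abs(rt[cand] - rt[i])
    best <- cand[order(-dd, abs(mz[cand] - mz[i]))][1]
    used[c(i, best)] <- TRUE
    pairs[[length(pairs) + 1L]] <- list(a = targets[[i]],
                                        b = targets[[best]])
  }
  unpaired <- vapply(targets[!used], `[[`, "", "feature_id")
  list(pairs = pairs, unpaired = unpaired)
}

#' Generate paired decoys by fragment m/z swapping
#'
#' For each target pair, two decoys are generated that keep every precursor
#' property (m/z, RT, CCS, S/N, height) and the member's own fragment
#' intensities, while the m/z values of k fragments are exchanged between
#' the pair at matching intensity rank.  k is drawn uniformly from
#' `ceil(f_lo * n) .. floor(f_hi * n)` and the swapped positions are sampled
#' without replacement from the `swap_pool` most intense ranks; the same
#' positions are used for both decoys of a pair.  Pairs whose admissible k
#' set is empty (n = 1 or n = 3 under the default 40-60% band) are rejected.
#'
#' @param pairs `pairs` element from [pair_targets()]
#' @param swap_fraction_range fraction of fragments to swap, inclusive
#' @param seed integer seed; identical inputs and seed give identical decoys
#' @param swap_pool swap positions are restricted to this many top ranks
#' @return list with `decoys` (features named `DECOY_<target id>`, carrying
#'   a `partner_id` attribute and `swap_ranks` attribute), `pairs` (the
#'   accepted pairs), and `rejected` (feature ids of rejected pairs)
#' @export
generate_decoys <- function(pairs, swap_fraction_range = c(0.4, 0.6),
                            seed = 1L, swap_pool = 16) {
  set.seed(as.integer(seed))
  decoys <- list()
  kept <- list()
  rejected <- character()
  for (p in pairs) {
    n <- nrow(p$a$fragments)
    stopifnot(n == nrow(p$b$fragments))
    lo <- ceiling(swap_fraction_range[1] * n)
    hi <- floor(swap_fraction_range[2] * n)
    if (n < 2 || lo > hi) {
      rejected <- c(rejected, p$a$feature_id, p$b$feature_id)
      next
    }
    k <- if (lo == hi) lo else sample(seq(lo, hi), 1L)
    pool <- seq_len(min(n, swap_pool))
    ranks <- sort(sample(pool, k))
    mk <- function(f, other) {
      d <- f
      d$feature_id <- paste0("DECOY_", f$feature_id)
      idx <- match(ranks, d$fragments$rank)
      oth <- match(ranks, other$fragments$rank)
      d$fragments$mz[idx] <- other$fragments$mz[oth]
      attr(d, "partner_id") <- f$feature_id
      attr(d, "swap_ranks") <- ranks
      d
    }
    decoys <- c(decoys, list(mk(p$a, p$b), mk(p$b, p$a)))
    p$n_swap <- k
    p$swap_positions <- ranks
    kept[[length(kept) + 1L]] <- p
  }
  list(decoys = decoys, pairs = kept, rejected = rejected)
}
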