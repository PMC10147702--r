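# The seven co-elution descriptors (the classifier's feature vector) and the
# fragment drift-time offset model.

.descriptor_names <- c("cos_sim", "rtdiff_sd", "rtdiff_mean",
                       "fwhmdiff_sd", "fwhmdiff_mean",
                       "masserror_sd", "masserror_mean")

#' Cosine similarity between two non-negative intensity vectors
#'
#' `dot(a, b) / (||a|| * ||b||)`; lies in [0, 1] for non-negative inputs and
#' is invariant under positive scaling of either vector.  A zero-norm vector
#' (degenerate peak-group) yields 0 with a warning.
#'
#' @param observed non-negative numeric vector (integrated fragment areas)
#' @param expected non-negative numeric vector (expected intensities), same
#'   length
#' @return numeric scalar in [0, 1]
#' @export
cosine_similarity <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) >= 1)
  if (any(observed < 0, na.rm = TRUE) || any(expected < 0, na.rm = TRUE))
    stop("cosine similarity requires non-negative vectors")
  na <- sqrt(sum(observed^2)); nb <- sqrt(sum(expected^2))
  if (na == 0 || nb == 0) {
    warning("zero-norm vector in cosine similarity; returning 0")
    return(0)
  }
  sum(observed * expected) / (na * nb)
}

#' Compute the seven scoring descriptors of a peak-group
#'
#' Descriptors: `cos_sim` -- cosine similarity between fragment areas and
#' expected intensities; `rtdiff_sd`/`rtdiff_mean` -- sample sd and mean of
#' the signed differences (precursor RT - fragment RT); `fwhmdiff_sd`/
#' `fwhmdiff_mean` -- likewise for LC peak FWHM; `masserror_sd`/
#' `masserror_mean` -- sample sd and mean of the fragment ppm mass errors.
#' Fragments with a flagged-missing metric are excluded pairwise from the
#' vector for that descriptor; a group is unscorable (all `NA`) when any
#' descriptor is left with fewer than two usable fragments.
#'
#' @param group a [peak_group()]
#' @param expected optional replacement expected-intensity vector aligned
#'   with `group$fragments` (e.g. library intensities for query scoring);
#'   default uses the group's own `expected_intensity` column
#' @return named numeric vector of length 7 (`NA`s when unscorable)
#' @export
compute_descriptors <- function(group, expected = NULL) {
  f <- group$fragments
  p <- group$precursor
  out <- stats::setNames(rep(NA_real_, 7L), .descriptor_names)
  if (nrow(f) < 2) return(out)
  exp_int <- if (is.null(expected)) f$expected_intensity else expected
  stopifnot(length(exp_int) == nrow(f))

  use_cos <- !is.na(f$area) & !is.na(exp_int)
  use_rt <- !is.na(f$rt)
  use_fwhm <- !is.na(f$fwhm)
  use_mass <- !is.na(f$mass_error_ppm)
  if (sum(use_cos) < 2 || sum(use_rt) < 2 || sum(use_fwhm) < 2 ||
      sum(use_mass) < 2 || is.na(p$rt) || is.na(p$fwhm))
    return(out)

  rtd <- p$rt - f$rt[use_rt]
  fwd <- p$fwhm - f$fwhm[use_fwhm]
  mer <- f$mass_error_ppm[use_mass]
  out["cos_sim"] <- cosine_similarity(f$area[use_cos], exp_int[use_cos])
  out["rtdiff_sd"] <- stats::sd(rtd); out["rtdiff_mean"] <- mean(rtd)
  out["fwhmdiff_sd"] <- stats::sd(fwd); out["fwhmdiff_mean"] <- mean(fwd)
  out["masserror_sd"] <- stats::sd(mer); out["masserror_mean"] <- mean(mer)
  out
}

#' Descriptor matrix for a list of peak-groups
#'
#' @param groups list of [peak_group()] objects
#' @return data frame with `group_id`, `run_id`, `label`, the seven
#'   descriptor columns and a logical `scorable` flag
#' @export
descriptor_matrix <- function(groups) {
  rows <- lapply(groups, function(g) {
    d <- compute_descriptors(g)
    cbind(data.frame(group_id = g$group_id, run_id = g$run_id,
                     label = g$label), as.data.frame(as.list(d)))
  })
  out <- do.call(rbind, rows)
  out$scorable <- stats::complete.cases(out[, .descriptor_names])
  rownames(out) <- NULL
  out
}

#' Fragment drift-time offset from its precursor
#'
#' In drift-tube IM with alternating-energy DIA, fragment ions arrive
#' slightly earlier than their precursor because lighter ions traverse the
#' post-drift-cell region faster during the high-energy frames.  The offset
#' (milliseconds) is modelled as
#' `((fragment_mz - precursor_mz) / precursor_mz) * 0.7 - precursor_mz * 1e-4`
#' and is applied when constructing extraction windows, so fragments are
#' sought at the precursor drift time plus this (negative) offset.
#'
#' @param precursor_mz precursor m/z (Th), > 0
#' @param fragment_mz fragment m/z (Th), > 0 (vectorized)
#' @return drift-time offset in milliseconds
#' @export
mobility_offset <- function(precursor_mz, fragment_mz) {
  stopifnot(all(precursor_mz > 0), all(fragment_mz > 0))
  ((fragment_mz - precursor_mz) / precursor_mz) * 0.7 -
    precursor_mz * 1e-4
}
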