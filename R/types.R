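#' @title Domain objects for DIA peak-group scoring
#' @description Constructors and validators for the objects the workflow
#'   passes between stages: deconvoluted precursor features with their
#'   pseudo-MS2 fragment lists, extracted peak-groups with XIC metrics, and
#'   reference library entries.
#' @name peakdecoder-types
NULL

# Tokens accepted as an explicitly-missing numeric cell.  Missing values are
# never coerced to 0 anywhere in the package.
.missing_tokens <- c("", "NA", "N/A", "#N/A", "NaN", "nan", "null")

#' Parse a numeric vector allowing explicit missing-value tokens
#'
#' @param x character vector
#' @return numeric vector with `NA` for missing tokens
#' @keywords internal
parse_numeric <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% .missing_tokens] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Rank fragment ions by intensity
#'
#' Rank 1 is the most intense fragment; intensity ties are broken by
#' ascending m/z so that ranking is deterministic and dialect-independent.
#'
#' @param fragments data frame with columns `mz` and `intensity`
#' @return the data frame sorted by descending intensity with a 1-based
#'   `rank` column
#' @export
rank_fragments <- function(fragments) {
  stopifnot(is.data.frame(fragments),
            all(c("mz", "intensity") %in% names(fragments)))
  ord <- order(-fragments$intensity, fragments$mz)
  fragments <- fragments[ord, , drop = FALSE]
  fragments$rank <- seq_len(nrow(fragments))
  rownames(fragments) <- NULL
  fragments
}

#' Construct a deconvoluted precursor feature
#'
#' One untargeted-feature-detection (UFD) precursor with its deconvoluted
#' pseudo-MS2 fragment list; the unit from which targets are selected and
#' decoys are built.
#'
#' @param feature_id opaque identifier
#' @param run_id source run name
#' @param precursor_mz precursor m/z (Th), > 0
#' @param rt retention time (minutes), >= 0
#' @param ccs collision cross-section (A^2), > 0 or `NA`
#' @param sn precursor signal-to-noise ratio
#' @param height precursor apex height (counts)
#' @param fragments data frame with columns `mz`, `intensity`; ranked on
#'   construction
#' @return object of class `deconvoluted_feature`
#' @export
deconvoluted_feature <- function(feature_id, run_id, precursor_mz, rt,
                                 ccs = NA_real_, sn = NA_real_,
                                 height = NA_real_,
                                 fragments = data.frame(mz = numeric(),
                                                        intensity = numeric())) {
  stopifnot(length(feature_id) == 1L, length(precursor_mz) == 1L)
  if (!is.na(precursor_mz) && precursor_mz <= 0)
    stop("precursor_mz must be > 0 for feature ", feature_id)
  if (!is.na(rt) && rt < 0)
    stop("rt must be >= 0 for feature ", feature_id)
  if (!is.na(ccs) && ccs <= 0)
    stop("ccs must be > 0 when present for feature ", feature_id)
  if (nrow(fragments) > 0) {
    if (any(fragments$mz <= 0)) stop("fragment mz must be > 0")
    if (any(fragments$intensity < 0)) stop("fragment intensity must be >= 0")
    fragments <- rank_fragments(fragments)
  } else {
    fragments$rank <- integer()
  }
  structure(list(feature_id = as.character(feature_id),
                 run_id = as.character(run_id),
                 precursor_mz = as.numeric(precursor_mz),
                 rt = as.numeric(rt), ccs = as.numeric(ccs),
                 sn = as.numeric(sn), height = as.numeric(height),
                 fragments = fragments),
            class = "deconvoluted_feature")
}

#' @export
print.deconvoluted_feature <- function(x, ...) {
  cat(sprintf("<feature %s> run=%s m/z=%.4f RT=%.2f min, %d fragments\n",
              x$feature_id, x$run_id, x$precursor_mz, x$rt,
              nrow(x$fragments)))
  invisible(x)
}

#' Construct an extracted peak-group
#'
#' Per-run XIC metrics for one precursor and its fragment transitions; the
#' unit that is scored.  Numeric metrics use `NA` for flagged-missing cells.
#'
#' @param group_id peak-group identifier
#' @param run_id run (replicate) name
#' @param label one of `"target"`, `"decoy"`, `"query"`
#' @param precursor named list with elements `mz`, `area`, `height`, `fwhm`,
#'   `rt`, `mass_error_ppm`, `sn`
#' @param fragments data frame with columns `mz`, `expected_intensity`,
#'   `area`, `height`, `fwhm`, `rt`, `mass_error_ppm`; ranked by
#'   `expected_intensity` on construction
#' @param expected_rt library/alignment retention time (minutes)
#' @param expected_ccs library/alignment CCS (A^2)
#' @param observed_ccs CCS measured at the IM peak apex in this run (A^2,
#'   may be `NA` when the extraction tool does not report it)
#' @param partner_id for decoys, the group id of the paired target
#' @return object of class `peak_group`
#' @export
peak_group <- function(group_id, run_id, label, precursor, fragments,
                       expected_rt = NA_real_, expected_ccs = NA_real_,
                       observed_ccs = NA_real_, partner_id = NA_character_) {
  label <- match.arg(label, c("target", "decoy", "query"))
  if (label != "query" && nrow(fragments) < 1L)
    stop("peak-group ", group_id, " must have at least one fragment")
  if (nrow(fragments) > 0) {
    frg <- fragments
    ord <- order(-frg$expected_intensity, frg$mz)
    frg <- frg[ord, , drop = FALSE]
    frg$rank <- seq_len(nrow(frg))
    rownames(frg) <- NULL
    fragments <- frg
  } else {
    fragments$rank <- integer()
  }
  structure(list(group_id = as.character(group_id),
                 run_id = as.character(run_id), label = label,
                 precursor = precursor, fragments = fragments,
                 expected_rt = as.numeric(expected_rt),
                 expected_ccs = as.numeric(expected_ccs),
                 observed_ccs = as.numeric(observed_ccs),
                 partner_id = as.character(partner_id)),
            class = "peak_group")
}

#' @export
print.peak_group <- function(x, ...) {
  cat(sprintf("<peak-group %s> run=%s label=%s, %d fragments\n",
              x$group_id, x$run_id, x$label, nrow(x$fragments)))
  invisible(x)
}

#' Construct a metabolite library entry
#'
#' Reference coordinates (precursor m/z, RT, CCS) and fragment spectrum for
#' one metabolite/adduct, as read from an MSP library.  Raw fragment
#' intensities are preserved; intensities normalized to max = 100 are kept
#' alongside in column `rel_intensity`.
#'
#' @param name metabolite name
#' @param formula molecular formula string
#' @param adduct ion species, e.g. `"[M-H]-"`
#' @param precursor_mz precursor m/z (Th)
#' @param rt retention time (minutes)
#' @param ccs collision cross-section (A^2)
#' @param fragments data frame with columns `mz`, `intensity` (may have zero
#'   rows for MS1-only entries)
#' @return object of class `library_entry`
#' @export
library_entry <- function(name, formula = NA_character_,
                          adduct = NA_character_, precursor_mz,
                          rt = NA_real_, ccs = NA_real_,
                          fragments = data.frame(mz = numeric(),
                                                 intensity = numeric())) {
  if (is.na(precursor_mz) || precursor_mz <= 0)
    stop("library entry ", name, " lacks a valid precursor m/z")
  if (nrow(fragments) > 0) {
    fragments <- rank_fragments(fragments)
    fragments$rel_intensity <- 100 * fragments$intensity /
      max(fragments$intensity)
  } else {
    fragments$rank <- integer()
    fragments$rel_intensity <- numeric()
  }
  structure(list(name = as.character(name), formula = as.character(formula),
                 adduct = as.character(adduct),
                 precursor_mz = as.numeric(precursor_mz),
                 rt = as.numeric(rt), ccs = as.numeric(ccs),
                 fragments = fragments),
            class = "library_entry")
}

#' @export
print.library_entry <- function(x, ...) {
  cat(sprintf("<library entry %s %s> m/z=%.5f RT=%.2f CCS=%.2f, %d fragments\n",
              x$name, x$adduct, x$precursor_mz, x$rt, x$ccs,
              nrow(x$fragments)))
  invisible(x)
}
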