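# Reader for untargeted feature-detection alignment exports.
#
# Two dialects are supported: the canonical "simple_tsv" layout written by the
# synthetic-data generator, and an MS-DIAL-style alignment export.  Column
# vocabularies of vendor exports drift across versions, so headers are matched
# case-insensitively against a small alias table.

.alignment_aliases <- list(
  simple_tsv = list(
    feature_id = "featureid", run_id = "runid", precursor_mz = "precursormz",
    rt = "rt", ccs = "ccs", sn = "sn", height = "height", ms2 = "ms2"),
  msdial_alignment = list(
    feature_id = c("alignment id", "alignmentid", "peak id"),
    run_id = c("spectrum reference file name", "reference file"),
    precursor_mz = c("average mz", "precursor mz"),
    rt = c("average rt(min)", "rt (min)", "average rt"),
    ccs = c("ccs", "average ccs"),
    sn = c("s/n average", "s/n", "signal/noise"),
    height = c("height", "average intensity"),
    ms2 = c("ms/ms spectrum", "msms spectrum", "ms2 spectrum"))
)

.match_columns <- function(header, aliases, dialect) {
  norm <- tolower(trimws(header))
  idx <- lapply(aliases, function(a) {
    hit <- which(norm %in% tolower(a))
    if (length(hit) == 0) NA_integer_ else hit[1]
  })
  required <- c("feature_id", "precursor_mz", "rt")
  missing <- names(idx)[vapply(idx, is.na, logical(1))]
  bad <- intersect(required, missing)
  if (length(bad) > 0)
    stop("malformed ", dialect, " header: missing column(s) ",
         paste(bad, collapse = ", "))
  idx
}

#' Parse a deconvoluted MS2 fragment string
#'
#' Fragment lists are encoded as whitespace- or semicolon-separated
#' `mz:intensity` tokens.  Unparsable tokens are skipped with a warning.
#'
#' @param s character scalar (may be empty or `NA`)
#' @param context label used in warnings
#' @return data frame with columns `mz`, `intensity`
#' @export
parse_ms2_string <- function(s, context = "") {
  if (length(s) == 0 || is.na(s) || !nzchar(trimws(s)))
    return(data.frame(mz = numeric(), intensity = numeric()))
  tokens <- strsplit(trimws(s), "[;[:space:]]+")[[1]]
  parts <- strsplit(tokens, ":", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) == 2L
  mz <- suppressWarnings(as.numeric(vapply(parts[ok], `[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts[ok], `[`, "", 2L)))
  good <- !is.na(mz) & !is.na(it)
  if (any(!ok) || any(!good))
    warning("skipped ", sum(!ok) + sum(!good),
            " unparsable fragment token(s)",
            if (nzchar(context)) paste0(" in ", context) else "")
  data.frame(mz = mz[good], intensity = it[good])
}

#' Read an untargeted feature-alignment export
#'
#' Returns one [deconvoluted_feature()] per table row.  Rows without an MS2
#' field are returned with an empty fragment list; fragments are sorted by
#' descending intensity and given 1-based intensity ranks.
#'
#' @param path path to a tab-separated alignment export
#' @param dialect `"simple_tsv"` (canonical layout: FeatureId, RunId,
#'   PrecursorMz, RT, CCS, SN, Height, MS2) or `"msdial_alignment"`
#' @return list of `deconvoluted_feature` objects
#' @export
read_feature_alignment <- function(path,
                                   dialect = c("simple_tsv",
                                               "msdial_alignment")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", sep = "\t",
                           na.strings = NULL)
  idx <- .match_columns(names(tab), .alignment_aliases[[dialect]], dialect)
  col <- function(field) {
    i <- idx[[field]]
    if (is.na(i)) rep(NA_character_, nrow(tab)) else tab[[i]]
  }
  feats <- vector("list", nrow(tab))
  fid <- col("feature_id"); rid <- col("run_id")
  pmz <- parse_numeric(col("precursor_mz")); rt <- parse_numeric(col("rt"))
  ccs <- parse_numeric(col("ccs")); sn <- parse_numeric(col("sn"))
  ht <- parse_numeric(col("height")); ms2 <- col("ms2")
  for (i in seq_len(nrow(tab))) {
    feats[[i]] <- deconvoluted_feature(
      feature_id = fid[i],
      run_id = if (is.na(rid[i])) "run1" else rid[i],
      precursor_mz = pmz[i], rt = rt[i], ccs = ccs[i], sn = sn[i],
      height = ht[i],
      fragments = parse_ms2_string(ms2[i], context = paste0("row ", i)))
  }
  feats
}
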