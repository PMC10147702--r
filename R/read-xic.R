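# Reader and writer for the targeted-extraction (TDX) XIC report: a long
# table with one row per transition per run, carrying the XIC summary metrics
# (area, height, FWHM, apex RT, ppm mass error) plus expected RT/CCS and the
# CCS observed at the IM peak apex.

.xic_columns <- c("GroupId", "ReplicateName", "Label", "PartnerGroupId",
                  "IsPrecursor", "Mz", "ExpectedIntensity", "Area", "Height",
                  "Fwhm", "RetentionTime", "MassErrorPPM", "ExpectedRT",
                  "ExpectedCCS", "ObservedCCS", "SignalToNoise")

#' Read a targeted-extraction XIC report
#'
#' Rows are grouped by (group id, run); within each group-run exactly one row
#' must be flagged as the precursor, the remainder are fragment transitions.
#' Missing numeric cells (`""`, `"NA"`, `"#N/A"`, `"NaN"`) are flagged
#' missing (`NA`), never coerced to 0.
#'
#' @param path path to a CSV report (columns `GroupId, ReplicateName, Label,
#'   PartnerGroupId, IsPrecursor, Mz, ExpectedIntensity, Area, Height, Fwhm,
#'   RetentionTime, MassErrorPPM, ExpectedRT, ExpectedCCS, ObservedCCS,
#'   SignalToNoise`)
#' @return list of [peak_group()] objects
#' @export
read_xic_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", na.strings = NULL)
  missing <- setdiff(.xic_columns, names(tab))
  if (length(missing) > 0)
    stop("malformed XIC report header: missing column(s) ",
         paste(missing, collapse = ", "))
  num <- c("Mz", "ExpectedIntensity", "Area", "Height", "Fwhm",
           "RetentionTime", "MassErrorPPM", "ExpectedRT", "ExpectedCCS",
           "ObservedCCS", "SignalToNoise")
  for (cn in num) tab[[cn]] <- parse_numeric(tab[[cn]])
  tab$IsPrecursor <- toupper(trimws(tab$IsPrecursor)) %in%
    c("TRUE", "T", "1", "YES")

  key <- paste(tab$GroupId, tab$ReplicateName, sep = "\r")
  pieces <- split(seq_len(nrow(tab)), key)

  bad <- names(pieces)[vapply(pieces, function(i) sum(tab$IsPrecursor[i]) != 1L,
                              logical(1))]
  if (length(bad) > 0)
    stop("XIC report group(s) without exactly one precursor row: ",
         paste(unique(sub("\r.*", "", bad)), collapse = ", "))

  groups <- lapply(pieces, function(i) {
    sub <- tab[i, , drop = FALSE]
    p <- sub[sub$IsPrecursor, , drop = FALSE]
    f <- sub[!sub$IsPrecursor, , drop = FALSE]
    peak_group(
      group_id = p$GroupId, run_id = p$ReplicateName,
      label = tolower(p$Label),
      precursor = list(mz = p$Mz, area = p$Area, height = p$Height,
                       fwhm = p$Fwhm, rt = p$RetentionTime,
                       mass_error_ppm = p$MassErrorPPM, sn = p$SignalToNoise),
      fragments = data.frame(mz = f$Mz,
                             expected_intensity = f$ExpectedIntensity,
                             area = f$Area, height = f$Height, fwhm = f$Fwhm,
                             rt = f$RetentionTime,
                             mass_error_ppm = f$MassErrorPPM),
      expected_rt = p$ExpectedRT, expected_ccs = p$ExpectedCCS,
      observed_ccs = p$ObservedCCS,
      partner_id = if (nzchar(trimws(p$PartnerGroupId)))
        p$PartnerGroupId else NA_character_)
  })
  unname(groups)
}

#' Write a list of peak-groups as an XIC report
#'
#' Inverse of [read_xic_report()]; used by the synthetic-data generator and
#' for round-trip testing.
#'
#' @param groups list of [peak_group()] objects
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_xic_report <- function(groups, path) {
  rows <- lapply(groups, function(g) {
    p <- g$precursor
    prec <- data.frame(
      GroupId = g$group_id, ReplicateName = g$run_id, Label = g$label,
      PartnerGroupId = if (is.na(g$partner_id)) "" else g$partner_id,
      IsPrecursor = TRUE, Mz = p$mz, ExpectedIntensity = NA_real_,
      Area = p$area, Height = p$height, Fwhm = p$fwhm,
      RetentionTime = p$rt, MassErrorPPM = p$mass_error_ppm,
      ExpectedRT = g$expected_rt, ExpectedCCS = g$expected_ccs,
      ObservedCCS = g$observed_ccs, SignalToNoise = p$sn)
    if (nrow(g$fragments) == 0) return(prec)
    f <- g$fragments
    frag <- data.frame(
      GroupId = g$group_id, ReplicateName = g$run_id, Label = g$label,
      PartnerGroupId = if (is.na(g$partner_id)) "" else g$partner_id,
      IsPrecursor = FALSE, Mz = f$mz, ExpectedIntensity = f$expected_intensity,
      Area = f$area, Height = f$height, Fwhm = f$fwhm, RetentionTime = f$rt,
      MassErrorPPM = f$mass_error_ppm, ExpectedRT = g$expected_rt,
      ExpectedCCS = g$expected_ccs, ObservedCCS = g$observed_ccs,
      SignalToNoise = NA_real_)
    rbind(prec, frag)
  })
  out <- do.call(rbind, rows)
  write_csv_c(out[, .xic_columns], path)
  invisible(path)
}

# RFC-4180 CSV writer with '.' decimal separator and locale-independent
# number formatting (15 significant digits, so numeric round trips are exact
# to well below any metric's precision).
write_csv_c <- function(df, path) {
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- vapply(x, function(v) {
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                       trim = TRUE, decimal.mark = ".")
      }, "")
      out
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "NA"
      needs <- grepl('[",\n]', x)
      x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
      x
    }
  }
  cols <- lapply(df, fmt)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
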