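# NIST MSP text-format spectral library reader/writer.
#
# Records are blocks of "Field: value" lines followed by a numbered peak
# list ("mz intensity" per line), separated by blank lines.  Field names are
# matched case-insensitively with the common synonym spellings.

.msp_field <- function(fields, keys) {
  hit <- keys[keys %in% names(fields)]
  if (length(hit) == 0) NA_character_ else fields[[hit[1]]]
}

#' Read a metabolite library in NIST MSP format
#'
#' One [library_entry()] per MSP record.  Raw fragment intensities are
#' preserved and intensities normalized to max = 100 are stored alongside.
#' Records lacking a precursor m/z are skipped with a warning.
#'
#' @param path path to an MSP text file
#' @return list of `library_entry` objects
#' @export
read_library_msp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # split into records at blank lines
  blank <- !nzchar(trimws(lines))
  rec_id <- cumsum(c(TRUE, blank[-length(blank)])) * !blank
  recs <- split(lines[!blank], rec_id[!blank])
  entries <- list()
  skipped <- 0L
  for (rec in recs) {
    is_field <- grepl("^[A-Za-z][A-Za-z0-9 _/-]*:", rec)
    kv <- strsplit(rec[is_field], ":", fixed = TRUE)
    fields <- stats::setNames(
      vapply(kv, function(p) trimws(paste(p[-1], collapse = ":")), ""),
      tolower(vapply(kv, function(p) trimws(p[1]), "")))
    peaks <- rec[!is_field]
    pm <- parse_numeric(.msp_field(fields, c("precursormz", "precursor_mz",
                                             "precursor m/z")))
    if (is.na(pm)) { skipped <- skipped + 1L; next }
    frag <- data.frame(mz = numeric(), intensity = numeric())
    if (length(peaks) > 0) {
      toks <- strsplit(trimws(peaks), "[[:space:]]+")
      mz <- parse_numeric(vapply(toks, `[`, "", 1L))
      it <- parse_numeric(vapply(toks, function(t)
        if (length(t) >= 2) t[2] else NA_character_, ""))
      keep <- !is.na(mz) & !is.na(it)
      frag <- data.frame(mz = mz[keep], intensity = it[keep])
    }
    entries[[length(entries) + 1L]] <- library_entry(
      name = .msp_field(fields, c("name", "compound name")),
      formula = .msp_field(fields, c("formula", "molecular formula")),
      adduct = .msp_field(fields, c("precursortype", "precursor_type",
                                    "adduct", "adductpositive",
                                    "ion mode adduct")),
      precursor_mz = pm,
      rt = parse_numeric(.msp_field(fields, c("retentiontime", "rt",
                                              "retention_time"))),
      ccs = parse_numeric(.msp_field(fields, c("ccs", "collisioncrosssection"))),
      fragments = frag)
  }
  if (skipped > 0)
    warning(skipped, " MSP record(s) without PrecursorMZ skipped")
  entries
}

#' Write a metabolite library in NIST MSP format
#'
#' Inverse of [read_library_msp()] for the fields this package consumes.
#'
#' @param entries list of [library_entry()] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_library_msp <- function(entries, path) {
  blocks <- vapply(entries, function(e) {
    head <- c(paste0("NAME: ", e$name),
              if (!is.na(e$formula)) paste0("FORMULA: ", e$formula),
              if (!is.na(e$adduct)) paste0("PRECURSORTYPE: ", e$adduct),
              paste0("PRECURSORMZ: ",
                     format(e$precursor_mz, digits = 10, trim = TRUE)),
              if (!is.na(e$rt)) paste0("RETENTIONTIME: ",
                                       format(e$rt, digits = 6, trim = TRUE)),
              if (!is.na(e$ccs)) paste0("CCS: ",
                                        format(e$ccs, digits = 6, trim = TRUE)),
              paste0("Num Peaks: ", nrow(e$fragments)))
    pk <- if (nrow(e$fragments) > 0)
      paste(format(e$fragments$mz, digits = 10, trim = TRUE),
            format(e$fragments$intensity, digits = 10, trim = TRUE))
    else character()
    paste(c(head, pk, ""), collapse = "\n")
  }, "")
  writeLines(blocks, path, useBytes = TRUE)
  invisible(path)
}
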