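# Skyline-style small-molecule transition list: the hand-off between decoy
# generation and targeted data extraction.  One row per transition; the
# precursor transition is the row whose Fragment Name is "precursor".  The
# Note column carries, for decoys, the id of the paired target group.

.transition_columns <- c("Molecule List Name", "Molecule Name",
                         "Precursor m/z", "Product m/z", "Fragment Name",
                         "Library Intensity", "Explicit Retention Time",
                         "Explicit CCS",
                         "Explicit Drift Time Offset (msec)", "Note")

#' Build a transition table from target and decoy features
#'
#' Each feature contributes one precursor transition plus one transition per
#' fragment.  Fragment drift-time offsets are filled from
#' [mobility_offset()] so extraction windows can seek fragments at the
#' precursor drift time plus offset.
#'
#' @param targets list of [deconvoluted_feature()] objects
#' @param decoys list of decoy features (as produced by [generate_decoys()]);
#'   may be empty
#' @return data frame with columns `group_id, label, is_precursor,
#'   precursor_mz, mz, expected_intensity, explicit_rt, explicit_ccs,
#'   dt_offset, partner_id`
#' @export
transition_table <- function(targets, decoys = list()) {
  one <- function(f, label) {
    partner <- attr(f, "partner_id")
    if (is.null(partner)) partner <- NA_character_
    n <- nrow(f$fragments)
    data.frame(
      group_id = f$feature_id, label = label,
      is_precursor = c(TRUE, rep(FALSE, n)),
      precursor_mz = f$precursor_mz,
      mz = c(f$precursor_mz, f$fragments$mz),
      expected_intensity = c(f$height, f$fragments$intensity),
      explicit_rt = f$rt, explicit_ccs = f$ccs,
      dt_offset = c(0, mobility_offset(f$precursor_mz, f$fragments$mz)),
      partner_id = partner)
  }
  rows <- c(lapply(targets, one, label = "target"),
            lapply(decoys, one, label = "decoy"))
  if (length(rows) == 0)
    return(data.frame(group_id = character(), label = character(),
                      is_precursor = logical(), precursor_mz = numeric(),
                      mz = numeric(), expected_intensity = numeric(),
                      explicit_rt = numeric(), explicit_ccs = numeric(),
                      dt_offset = numeric(), partner_id = character()))
  do.call(rbind, rows)
}

#' Write a transition list in Skyline-style CSV format
#'
#' @param transitions data frame as returned by [transition_table()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_transition_list <- function(transitions, path) {
  tr <- transitions
  if (nrow(tr) > 0) {
    per_group <- ave(as.integer(!tr$is_precursor), tr$group_id,
                     FUN = cumsum)
    frag_name <- ifelse(tr$is_precursor, "precursor",
                        paste0("frag_", per_group))
  } else frag_name <- character()
  out <- data.frame(
    check.names = FALSE,
    `Molecule List Name` = paste0(toupper(substring(tr$label, 1, 1)),
                                  substring(tr$label, 2)),
    `Molecule Name` = tr$group_id,
    `Precursor m/z` = tr$precursor_mz,
    `Product m/z` = tr$mz,
    `Fragment Name` = frag_name,
    `Library Intensity` = tr$expected_intensity,
    `Explicit Retention Time` = tr$explicit_rt,
    `Explicit CCS` = tr$explicit_ccs,
    `Explicit Drift Time Offset (msec)` = tr$dt_offset,
    `Note` = ifelse(is.na(tr$partner_id), "", tr$partner_id))
  if (nrow(tr) == 0) out <- out[0, , drop = FALSE]
  write_csv_c(out[, .transition_columns, drop = FALSE], path)
  invisible(path)
}

#' Read a transition list written by [write_transition_list()]
#'
#' @param path CSV path
#' @return data frame in the [transition_table()] layout
#' @export
read_transition_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", na.strings = NULL)
  missing <- setdiff(.transition_columns, names(tab))
  if (length(missing) > 0)
    stop("malformed transition list: missing column(s) ",
         paste(missing, collapse = ", "))
  data.frame(
    group_id = tab$`Molecule Name`,
    label = tolower(tab$`Molecule List Name`),
    is_precursor = tab$`Fragment Name` == "precursor",
    precursor_mz = parse_numeric(tab$`Precursor m/z`),
    mz = parse_numeric(tab$`Product m/z`),
    expected_intensity = parse_numeric(tab$`Library Intensity`),
    explicit_rt = parse_numeric(tab$`Explicit Retention Time`),
    explicit_ccs = parse_numeric(tab$`Explicit CCS`),
    dt_offset = parse_numeric(tab$`Explicit Drift Time Offset (msec)`),
    partner_id = ifelse(nzchar(trimws(tab$Note)), tab$Note, NA_character_))
}
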