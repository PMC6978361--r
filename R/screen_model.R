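WELL_ROWS <- LETTERS[1:16]
WELL_COLS <- 1:24
ROLES <- c("drug", "negative_control", "positive_control", "excluded")

#' Construct a screen table from per-well records
#'
#' A screen table is the atomic container of a drug sensitivity screen: one
#' row per well of one or more 384-well plates, carrying the plate identity,
#' well position, the condition role (drug-treated, DMSO negative control,
#' benzethonium-chloride positive control, or excluded), and the start and
#' endpoint viability readouts (luminescence). An optional toxicity readout
#' (fluorescence) may accompany each well.
#'
#' Validation enforces the plate geometry (rows A-P, columns 1-24), role
#' consistency (drug wells must carry a drug name and a positive molar
#' concentration; control wells must not), uniqueness of (plate, well)
#' pairs, and finite non-negative readouts. Wells with a start readout of
#' exactly zero are accepted but flagged (the fold change of such a well is
#' undefined and metric computations reject it).
#'
#' @param wells data.frame with columns `plate_id`, `well` (e.g. "A01"),
#'   `role`, `label` (raw condition label as printed on the plate map),
#'   `drug_name`, `concentration` (molar), `start_readout`, `end_readout`
#'   and optionally `toxicity_readout`.
#' @param metadata named list of free-form screen annotations (cell line,
#'   time points, replicate label, ...).
#' @return A `screen_table`: a data.frame with a `metadata` attribute.
#' @export
screen_table <- function(wells, metadata = list()) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  if (!"label" %in% names(wells)) {
    wells$label <- ifelse(wells$role == "drug", wells$drug_name, NA_character_)
  }
  if (!"toxicity_readout" %in% names(wells)) {
    wells$toxicity_readout <- NA_real_
  }
  needed <- c("plate_id", "well", "role", "label", "drug_name",
              "concentration", "start_readout", "end_readout",
              "toxicity_readout")
  missing <- setdiff(needed, names(wells))
  if (length(missing)) {
    stop_ndr(paste0("missing well fields: ", paste(missing, collapse = ", ")),
             "ndr_validation_error")
  }
  wells <- wells[needed]
  wells$well <- normalize_well(wells$well)
  out <- validate_screen_table(wells)
  attr(out, "metadata") <- metadata
  class(out) <- c("screen_table", "data.frame")
  out
}

# canonical well id: row letter + zero-padded column ("A1" -> "A01")
normalize_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  row <- substr(well, 1, 1)
  col <- suppressWarnings(as.integer(substring(well, 2)))
  ifelse(is.na(col), well, sprintf("%s%02d", row, col))
}

well_row <- function(well) substr(well, 1, 1)
well_col <- function(well) suppressWarnings(as.integer(substring(well, 2)))

validate_screen_table <- function(wells) {
  n <- nrow(wells)
  problems <- character(0)
  row_ok <- well_row(wells$well) %in% WELL_ROWS
  col_ok <- !is.na(well_col(wells$well)) & well_col(wells$well) %in% WELL_COLS
  bad_pos <- which(!(row_ok & col_ok))
  if (length(bad_pos)) {
    problems <- c(problems, sprintf(
      "row %d: well '%s' outside 384-well bounds (A-P x 1-24)",
      bad_pos, wells$well[bad_pos]))
  }
  bad_role <- which(!wells$role %in% ROLES)
  if (length(bad_role)) {
    problems <- c(problems, sprintf(
      "row %d: unknown role '%s'", bad_role, wells$role[bad_role]))
  }
  is_drug <- wells$role == "drug"
  bad_drug <- which(is_drug & (is.na(wells$drug_name) |
                    is.na(wells$concentration) | wells$concentration <= 0))
  if (length(bad_drug)) {
    problems <- c(problems, sprintf(
      "row %d: drug well requires drug_name and positive concentration",
      bad_drug))
  }
  is_ctrl <- wells$role %in% c("negative_control", "positive_control")
  bad_ctrl <- which(is_ctrl & (!is.na(wells$drug_name) |
                               !is.na(wells$concentration)))
  if (length(bad_ctrl)) {
    problems <- c(problems, sprintf(
      "row %d: control well must not carry drug_name/concentration",
      bad_ctrl))
  }
  for (fld in c("start_readout", "end_readout")) {
    v <- wells[[fld]]
    bad <- which(is.na(v) | !is.finite(v) | v < 0)
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "row %d: %s must be finite and >= 0", bad, fld))
    }
  }
  key <- paste(wells$plate_id, wells$well)
  dup <- which(duplicated(key))
  if (length(dup)) {
    problems <- c(problems, sprintf(
      "row %d: duplicate well %s on plate %s",
      dup, wells$well[dup], wells$plate_id[dup]))
  }
  if (length(problems)) {
    stop_ndr(paste0("invalid screen table:\n  ",
                    paste(problems, collapse = "\n  ")),
             "ndr_validation_error")
  }
  flagged <- !is.na(wells$start_readout) & wells$start_readout == 0
  if (any(flagged)) {
    warn_ndr(sprintf(
      "%d well(s) have start_readout = 0; fold change is undefined for them",
      sum(flagged)), "ndr_zero_start_warning")
  }
  wells$zero_start_flag <- flagged
  rownames(wells) <- NULL
  wells
}

#' Column-name mapping for reading per-well screen tables
#'
#' The raw-data layouts exported by plate readers differ; the reader is
#' therefore configured with a column-name mapping rather than assuming one
#' fixed header. When the file has no explicit role column, roles are
#' derived from the condition label: wells labelled with `negative_label`
#' (default "DMSO") become negative controls, `positive_label` (default
#' "BzCl") positive controls, and everything else a drug well.
#'
#' @param plate_id,well,drug_name,concentration,start_readout,end_readout
#'   column names in the file.
#' @param role optional column holding the role directly.
#' @param toxicity_readout optional column with the fluorescence toxicity
#'   readout.
#' @param negative_label,positive_label condition labels recognized as
#'   negative / positive controls when `role` is absent.
#' @return a `screen_format` configuration list.
#' @export
screen_format <- function(plate_id = "plate_id", well = "well",
                          drug_name = "drug_name",
                          concentration = "concentration",
                          start_readout = "start_readout",
                          end_readout = "end_readout",
                          role = NULL, toxicity_readout = NULL,
                          negative_label = "DMSO",
                          positive_label = "BzCl") {
  structure(list(plate_id = plate_id, well = well, drug_name = drug_name,
                 concentration = concentration,
                 start_readout = start_readout, end_readout = end_readout,
                 role = role, toxicity_readout = toxicity_readout,
                 negative_label = negative_label,
                 positive_label = positive_label),
            class = "screen_format")
}

#' Read a per-well screen table from CSV
#'
#' Reads a comma-separated, UTF-8, headered table of per-well readouts and
#' returns a validated [screen_table()]. Rows violating the well invariants
#' are rejected with row-level diagnostics.
#'
#' @param path path to a CSV file.
#' @param format_config a [screen_format()] mapping file columns to fields.
#' @return a `screen_table`.
#' @export
read_screen_table <- function(path, format_config = screen_format()) {
  if (!file.exists(path)) {
    stop_ndr(paste0("file not found: ", path), "ndr_config_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  fc <- format_config
  wanted <- c(fc$plate_id, fc$well, fc$drug_name, fc$concentration,
              fc$start_readout, fc$end_readout, fc$role, fc$toxicity_readout)
  missing <- setdiff(wanted, names(raw))
  if (length(missing)) {
    stop_ndr(paste0("mapped column(s) absent from ", path, ": ",
                    paste(missing, collapse = ", ")),
             "ndr_config_error")
  }
  num_col <- function(col) {
    v <- raw[[col]]
    if (is.numeric(v)) return(as.numeric(v))
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(parsed))
    if (length(bad)) {
      stop_ndr(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                       v[bad[1]], col, bad[1]),
               "ndr_parse_error")
    }
    parsed
  }
  label <- as.character(raw[[fc$drug_name]])
  label[label == ""] <- NA_character_
  if (!is.null(fc$role)) {
    role <- as.character(raw[[fc$role]])
  } else {
    role <- ifelse(label %in% fc$negative_label, "negative_control",
            ifelse(label %in% fc$positive_label, "positive_control", "drug"))
  }
  conc <- num_col(fc$concentration)
  wells <- data.frame(
    plate_id = as.character(raw[[fc$plate_id]]),
    well = as.character(raw[[fc$well]]),
    role = role,
    label = label,
    drug_name = ifelse(role == "drug", label, NA_character_),
    concentration = ifelse(role == "drug", conc, NA_real_),
    start_readout = num_col(fc$start_readout),
    end_readout = num_col(fc$end_readout),
    stringsAsFactors = FALSE
  )
  if (!is.null(fc$toxicity_readout)) {
    wells$toxicity_readout <- num_col(fc$toxicity_readout)
  }
  screen_table(wells)
}

#' Exclude wells by condition label
#'
#' Marks every well whose condition label matches one of `labels` as
#' excluded, so that all downstream computations (control aggregation,
#' response scoring, classification, QC) ignore it. Typical use: dropping
#' artifact conditions such as cross-contaminated positive controls or
#' drug-combination wells that do not belong in a single-agent analysis.
#'
#' Exclusion is idempotent and a no-op for labels not present in the table
#' (reported via a message).
#'
#' @param table a `screen_table`.
#' @param labels character vector of condition labels to exclude.
#' @return the table with matching wells re-marked `role = "excluded"`.
#' @export
exclude_wells <- function(table, labels) {
  stopifnot(inherits(table, "screen_table"))
  labels <- as.character(labels)
  if (length(labels) == 0) return(table)
  hit <- !is.na(table$label) & table$label %in% labels
  unmatched <- setdiff(labels, table$label[hit])
  if (length(unmatched)) {
    message("exclude_wells: no wells matched label(s): ",
            paste(unmatched, collapse = ", "))
  }
  table$role[hit] <- "excluded"
  table$drug_name[hit] <- NA_character_
  table$concentration[hit] <- NA_real_
  table
}

#' Write a (scored) screen table to CSV
#'
#' @param table a `screen_table`, possibly carrying response columns added
#'   by [score_screen()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  df <- as.data.frame(table)
  df$zero_start_flag <- NULL
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_ndr(paste0("cannot write ", path, ": ", conditionMessage(ok)),
             "ndr_io_error")
  }
  invisible(path)
}

#' @export
print.screen_table <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("screen_table: %d wells, %d plate(s)\n",
              nrow(x), length(unique(x$plate_id))))
  tab <- table(x$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(md)) {
    cat("  metadata:", paste(sprintf("%s=%s", names(md), unlist(md)),
                             collapse = ", "), "\n")
  }
  invisible(x)
}
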