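# md5 of the packaged treatment-table transcription, frozen at transcription
# time; guards against silent edits to the fixture
TABLE1_MD5 <- "1cd6ad1f87aa295ce776f6b1a9b3411c"

required_table_columns <- c("treatment_id", "study_label", "cell_line",
                            "inoculum", "dose_ug_per_ml", "regimen_text",
                            "control_phases", "treated_phases")

#' One row of the treatment table
#'
#' A single treatment: cell line, inoculated cell count (C0 x h), docetaxel
#' dose, regimen description, and the control and treated volume
#' trajectories.
#'
#' @param treatment_id Integer id (1..N).
#' @param study_label Source study label.
#' @param cell_line Injected cell line.
#' @param inoculum Inoculated cell count C0 x h, >= 1.
#' @param dose_ug_per_ml Docetaxel dose in ug/ml, > 0.
#' @param regimen_text Regimen description (may be empty for synthetic
#'   cohorts without schedule information).
#' @param control,treated \code{\link{trajectory}} objects for each arm.
#' @return An object of class \code{treatment_record}.
#' @export
treatment_record <- function(treatment_id, study_label, cell_line, inoculum,
                             dose_ug_per_ml, regimen_text, control, treated) {
  if (!is.numeric(inoculum) || !is.finite(inoculum) || inoculum < 1)
    stop("inoculum must be a cell count >= 1")
  if (!is.numeric(dose_ug_per_ml) || !is.finite(dose_ug_per_ml) || dose_ug_per_ml <= 0)
    stop("dose_ug_per_ml must be > 0")
  stopifnot(inherits(control, "trajectory"), inherits(treated, "trajectory"))
  structure(list(treatment_id = as.integer(treatment_id),
                 study_label = as.character(study_label),
                 cell_line = as.character(cell_line),
                 inoculum = as.numeric(inoculum),
                 dose_ug_per_ml = as.numeric(dose_ug_per_ml),
                 regimen_text = as.character(regimen_text),
                 control = control, treated = treated),
            class = "treatment_record")
}

#' @export
print.treatment_record <- function(x, ...) {
  cat(sprintf("<treatment_record> #%d %s (%s), %g cells, %g ug/ml\n",
              x$treatment_id, x$cell_line, x$study_label, x$inoculum,
              x$dose_ug_per_ml))
  cat("  control:", format_phase_string(x$control), "\n")
  cat("  treated:", format_phase_string(x$treated), "\n")
  invisible(x)
}

#' Load a treatment table from CSV
#'
#' Reads a comma-separated UTF-8 table with columns \code{treatment_id},
#' \code{study_label}, \code{cell_line}, \code{inoculum},
#' \code{dose_ug_per_ml}, \code{regimen_text}, \code{control_phases},
#' \code{treated_phases} and returns one validated
#' \code{\link{treatment_record}} per row. Phase strings are parsed with
#' \code{\link{parse_phase_string}}; validation failures are reported with
#' the offending row number.
#'
#' @param path Path to the CSV file.
#' @return A list of \code{treatment_record} objects (empty for a
#'   header-only file).
#' @export
load_treatment_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  missing <- setdiff(required_table_columns, names(df))
  if (length(missing) > 0L)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tryCatch({
      num <- function(col) {
        x <- suppressWarnings(as.numeric(row[[col]]))
        if (is.na(x)) stop(sprintf("unparseable number in column '%s'", col))
        x
      }
      treatment_record(
        treatment_id = num("treatment_id"),
        study_label = row$study_label,
        cell_line = row$cell_line,
        inoculum = num("inoculum"),
        dose_ug_per_ml = num("dose_ug_per_ml"),
        regimen_text = row$regimen_text,
        control = parse_phase_string(row$control_phases, arm = "control"),
        treated = parse_phase_string(row$treated_phases, arm = "treated"))
    }, error = function(e) {
      stop(sprintf("row %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
  })
}

#' The packaged treatment table
#'
#' Loads the transcription of the source treatment table (14 docetaxel
#' xenograft treatments across 10 cell-line models) shipped with the
#' package. The file's md5 checksum is verified against the value frozen at
#' transcription time so accidental edits are caught.
#'
#' @param check Verify the transcription checksum (default TRUE).
#' @return A list of 14 \code{\link{treatment_record}} objects.
#' @examples
#' records <- dtec_table1()
#' length(records)
#' @export
dtec_table1 <- function(check = TRUE) {
  path <- system.file("extdata", "table1.csv", package = "dtec", mustWork = TRUE)
  if (check) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, TABLE1_MD5))
      stop("packaged treatment table fails its transcription checksum")
  }
  load_treatment_table(path)
}

#' Path to the packaged treatment-table CSV
#' @export
dtec_table1_path <- function() {
  system.file("extdata", "table1.csv", package = "dtec", mustWork = TRUE)
}

#' Write analysis results to disk
#'
#' Writes the per-treatment results table as a flat CSV (numerics at full
#' double precision, locale-independent) and a JSON provenance document
#' recording every strategy and tolerance choice plus the package version.
#'
#' @param results A data.frame of per-treatment results (e.g. from
#'   \code{\link{run_pipeline}}), non-empty.
#' @param path Output CSV path; the provenance JSON is written next to it
#'   with suffix \code{_provenance.json}.
#' @param provenance Named list of analysis choices; defaults to the
#'   \code{provenance} attribute of \code{results} if present.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, path, provenance = attr(results, "provenance")) {
  if (is.null(results) || !is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a non-empty data.frame; nothing written")
  out <- results
  numcols <- vapply(out, is.numeric, logical(1))
  out[numcols] <- lapply(out[numcols], function(x) sprintf("%.15g", x))
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                            fileEncoding = "UTF-8"),
           error = function(e) stop("cannot write report to '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  if (is.null(provenance)) provenance <- list()
  provenance$package_version <- as.character(utils::packageVersion("dtec"))
  json_path <- sub("\\.csv$", "", path)
  json_path <- paste0(json_path, "_provenance.json")
  jsonlite::write_json(provenance, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = path, provenance = json_path))
}
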