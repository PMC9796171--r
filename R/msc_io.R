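#' Read cell-length profiles from delimited text
#'
#' Reads a TSV/CSV file with columns `root_id`, `cell_index`, `length_um`
#' (one row per cortical cell, `cell_index` contiguous from 1 within each
#' root, counted from the QC-adjacent initial cell) and validates it.
#'
#' @param path Path to a tab- or comma-separated file with a header row.
#' @return A validated tibble of profiles.
#' @seealso [validate_profiles()], [write_profiles()]
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE
  )
  validate_profiles(data)
}

#' Write cell-length profiles to TSV
#'
#' @param data Profiles data frame (`root_id`, `cell_index`, `length_um`).
#' @param path Output path; written as UTF-8 TSV with a header row and `.`
#'   as the decimal separator.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(data, path) {
  data <- validate_profiles(data)
  readr::write_tsv(data, path)
  invisible(path)
}

#' Validate a profiles table
#'
#' Checks the schema used by the MSC analysis: required columns present,
#' lengths positive and finite, and `cell_index` contiguous from 1 within
#' every root. Problems are reported with the offending root ids and row
#' numbers.
#'
#' @param data A data frame of profiles.
#' @return The validated data (as a tibble, ordered by root and cell
#'   index); errors on any violation.
#' @export
#' @examples
#' validate_profiles(generate_profile(profile_spec("wt_like"), seed = 1))
validate_profiles <- function(data) {
  if (!is.data.frame(data)) {
    stop("profiles must be a data frame", call. = FALSE)
  }
  required <- c("root_id", "cell_index", "length_um")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop(
      "missing required column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  problems <- character(0)
  bad_len <- which(!is.finite(data$length_um) | data$length_um <= 0)
  if (length(bad_len) > 0) {
    problems <- c(problems, paste0(
      "non-positive or non-finite length_um at row(s) ",
      paste(utils::head(bad_len, 5), collapse = ", "),
      if (length(bad_len) > 5) sprintf(" (and %d more)", length(bad_len) - 5) else ""
    ))
  }
  for (id in unique(data$root_id)) {
    idx <- sort(data$cell_index[data$root_id == id])
    if (!identical(as.integer(idx), seq_len(length(idx)))) {
      problems <- c(problems, paste0(
        "cell_index not contiguous from 1 for root_id '", id, "'"
      ))
    }
  }
  if (length(problems) > 0) {
    stop(
      "invalid profiles table:\n  - ",
      paste(problems, collapse = "\n  - "),
      call. = FALSE
    )
  }
  data <- tibble::as_tibble(data)
  data[order(match(data$root_id, unique(data$root_id)), data$cell_index), ]
}
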