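#' Read landmark annotation tables
#'
#' Readers for the two annotation dialects (CSV or JSON array of records):
#' chessboard calibration annotations (`session_id`, `pose_id`, `pair_id`,
#' `endpoint`, `frame`, `u`, `v`, `squares_spanned`) and fish landmark
#' annotations (`fish_id`, `frame`, `landmark`, `u`, `v`, optional
#' `confidence`).
#'
#' @param path File path (`.csv` or `.json`).
#' @return A tibble.
#' @export
read_calibration_annotations <- function(path) {
  ann <- read_table_auto(path)
  required <- c("session_id", "pose_id", "pair_id", "endpoint", "frame",
                "u", "v", "squares_spanned")
  check_columns(ann, required, path)
  ann
}

#' @rdname read_calibration_annotations
#' @export
read_fish_annotations <- function(path) {
  ann <- read_table_auto(path)
  check_columns(ann, c("fish_id", "frame", "landmark", "u", "v"), path)
  ann
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

check_columns <- function(df, required, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}

#' Read a one-column table of sizes
#'
#' Accepts a CSV with any single numeric column (or picks the first numeric
#' column of a wider table); used by the distribution-comparison command.
#'
#' @param path File path.
#' @return Numeric vector.
#' @export
read_size_column <- function(path) {
  df <- read_table_auto(path)
  num <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(num) == 0) stop("no numeric column found in ", path)
  as.numeric(num[[1]])
}
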