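# Delimited-text I/O for record and result tables. TSV, UTF-8, header row
# required; unknown columns are preserved.

RECORD_REQUIRED <- c("id", "aabc", "ga", "bw", "sex", "tpn")

#' Write a table as TSV
#'
#' @param x Data frame or tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a newborn record table
#'
#' Reads the TSV record dialect written by [write_table()] /
#' [generate_cohort()]. The required covariate columns must be present
#' (missing ones raise a schema error naming the absentees); unknown
#' columns are preserved. Numeric fields are validated row by row and a
#' malformed value is rejected with its line number. Fractional AaBC hours
#' are floored on ingest.
#'
#' @param path Path to a TSV file with a header row.
#' @return Tibble of newborn records (possibly zero rows).
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dat <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(RECORD_REQUIRED, names(dat))
  if (length(missing_cols) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- c("aabc", "ga", "bw",
                    setdiff(names(dat), record_covariate_columns()))
  for (cc in numeric_cols) {
    raw <- dat[[cc]]
    blank <- is.na(raw) | raw == ""
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(val))
    if (length(bad) > 0) {
      stop("schema error: non-numeric '", cc, "' at line ", bad[1] + 1L,
           ": \"", raw[bad[1]], "\"", call. = FALSE)
    }
    dat[[cc]] <- val
  }
  for (cc in setdiff(names(dat), numeric_cols)) {
    dat[[cc]][dat[[cc]] == ""] <- NA
  }
  if (nrow(dat) > 0) {
    dat$aabc <- as.integer(floor(dat$aabc))
    dat$ga <- as.integer(dat$ga)
  } else {
    dat$aabc <- integer(0)
    dat$ga <- integer(0)
  }
  dat
}

#' Serialize an effect-size matrix as TSV
#'
#' Analyte rows, comparison-bin columns; first column `metabolite`.
#'
#' @param matrix An [effect_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effect_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "effect_size_matrix"))
  tab <- tibble::as_tibble(matrix$d, rownames = "metabolite")
  write_table(tab, path)
}
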