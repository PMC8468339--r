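#' Read a questionnaire response file (23-column layout)
#'
#' Reads CSV (or, when \pkg{readxl} is installed, XLSX) files in the
#' deposited layout: participant id, test phase, group, then 20 response
#' cells encoded as `1` (hit), `-1/3` in any decimal rendering (error) and
#' `0` or empty/none (the "I do not know" answer). Phase and group accept
#' the common spellings (`pre`/`pre-test`, `post`/`post-test`,
#' `control`/`CG`/`C`, `experimental`/`EG`/`X`).
#'
#' @param path file path (.csv, .tsv or .xlsx).
#' @return a validated `response_table`.
#' @export
read_responses <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      abort_invalid("reading .xlsx requires the 'readxl' package",
                    class = "mrisim_format_error")
    as.data.frame(readxl::read_excel(path, col_types = "text"))
  } else {
    utils::read.table(path, header = TRUE, sep = if (ext == "tsv") "\t" else ",",
                      colClasses = "character", check.names = FALSE)
  }
  if (ncol(raw) != 23L)
    abort_invalid(sprintf("expected 23 columns (id, test, group, 20 items), got %d",
                          ncol(raw)), class = "mrisim_format_error")
  items <- raw[, 4:23, drop = FALSE]
  decoded <- items
  for (j in seq_len(20)) {
    cell <- trimws(items[[j]])
    out <- rep(NA_character_, length(cell))
    low <- tolower(cell)
    num <- suppressWarnings(as.numeric(sub("^-1/3$", "-0.3333333", cell)))
    out[low %in% c("", "none", "na", "dontknow")] <- "dontknow"
    out[!is.na(num) & abs(num) < 1e-9] <- "dontknow"
    out[!is.na(num) & abs(num - 1) < 1e-9] <- "hit"
    out[!is.na(num) & abs(num + 1 / 3) < 1e-3] <- "error"
    if (anyNA(out)) {
      i <- which(is.na(out))[1]
      abort_invalid(sprintf("unrecognized cell value '%s' at row %d, item column %d",
                            cell[i], i, j), class = "mrisim_parse_error")
    }
    decoded[[j]] <- out
  }
  response_table(raw[[1]], raw[[2]], raw[[3]], decoded)
}

#' Write a response table in the 23-column CSV layout
#'
#' Inverse of [read_responses()]: responses are encoded as `1` (hit),
#' `-0.3333333` (error) and `0` ("I do not know").
#'
#' @param responses a `response_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  stopifnot(inherits(responses, "response_table"))
  enc <- responses
  for (cc in item_cols())
    enc[[cc]] <- c(hit = "1", error = "-0.3333333", dontknow = "0")[enc[[cc]]]
  names(enc) <- c("participant", "test", "group", item_cols())
  utils::write.csv(enc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
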