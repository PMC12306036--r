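#' Read an APC count table from delimited text
#'
#' Expects a header with columns `age`, `period` (or `year`), `deaths` and
#' `population`.  `age` may hold numeric midpoints or band labels such as
#' `"25-29"`; a band covering integer ages `lo..hi` is mapped to the midpoint
#' of the interval `[lo, hi + 1)`, e.g. `"10-14"` to 12.5.
#'
#' @param path File path.
#' @param sep Field separator (default `,`).
#' @return An [as_apc_data()] tibble with its grid attached.
#' @export
read_apc <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if ("year" %in% names(raw) && !"period" %in% names(raw)) {
    raw$period <- raw$year
  }
  need <- c("age", "period", "deaths", "population")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("File lacks columns: ", paste(miss, collapse = ", "), "."))
  }
  if (is.character(raw$age)) {
    bands <- regmatches(raw$age, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", raw$age))
    bad <- vapply(bands, length, 1L) == 0 & is.na(suppressWarnings(as.numeric(raw$age)))
    if (any(bad)) {
      abort(sprintf(
        "Unparseable age label(s) at line(s): %s.",
        paste(head(which(bad) + 1L, 5), collapse = ", ")
      ))
    }
    raw$age <- vapply(seq_along(raw$age), function(i) {
      b <- bands[[i]]
      if (length(b) == 3) (as.numeric(b[2]) + as.numeric(b[3]) + 1) / 2
      else as.numeric(raw$age[i])
    }, numeric(1))
  }
  as_apc_data(raw)
}

#' Write an APC count table (and its grid metadata) to delimited text
#'
#' Writes the cell table as CSV; with `meta = TRUE` the grid parameters
#' (I, J, M, interval origins and widths) are prepended as `#`-prefixed
#' comment lines so a run is reproducible from the file alone.
#'
#' @param data An `apc_df` (or plain data frame accepted by [as_apc_data()]).
#' @param path Output file path.
#' @param meta Write the grid metadata block? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_apc <- function(data, path, meta = TRUE) {
  data <- as_apc_data(data)
  g <- attr(data, "grid")
  con <- file(path, "w")
  on.exit(close(con))
  if (meta) {
    writeLines(sprintf(
      "# apc_grid I=%d J=%d M=%d age_start=%g age_width=%g period_start=%g period_width=%g",
      g$I, g$J, g$M, g$age_start, g$age_width, g$period_start, g$period_width
    ), con)
  }
  utils::write.table(
    data[, c("age", "period", "deaths", "population")],
    con, sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
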