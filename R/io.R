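#' Read a GBD-results-style CSV
#'
#' Reads the CSV dialect produced by the public GBD Results Tool: columns
#' `measure_name`, `location_name`, `sex_name`, `age_name`, `cause_name`,
#' `rei_name` (optional), `metric_name`, `year`, `val`, `upper`, `lower`.
#' Rows violating `lower <= val <= upper` (or with non-finite values) are
#' dropped, reported in a warning, and returned — with their file line
#' numbers — in the `rejected` attribute of the result. A missing required
#' column is a schema error.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated rows, with attribute `rejected` (tibble with
#'   columns `line`, `reason`).
#' @export
read_gbd_results <- function(path) {
  if (!file.exists(path)) {
    abort_craburden(sprintf("File not found: %s", path), "io")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("measure_name", "location_name", "sex_name", "age_name",
                "cause_name", "metric_name", "year", "val", "upper", "lower")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort_craburden(
      sprintf("Missing required column(s): %s.", paste(missing, collapse = ", ")),
      "schema"
    )
  }
  # numeric columns go through strtod (correctly rounded), so that values
  # written at full precision round-trip bit for bit
  tbl$year <- as.integer(tbl$year)
  for (col in c("val", "upper", "lower")) tbl[[col]] <- as.numeric(tbl[[col]])

  bad_order <- tbl$lower > tbl$upper
  bad_val <- tbl$val < tbl$lower | tbl$val > tbl$upper
  bad_finite <- !is.finite(tbl$val) | !is.finite(tbl$lower) | !is.finite(tbl$upper)
  bad <- bad_finite | (!bad_finite & (bad_order | bad_val))
  rejected <- tibble(
    line = which(bad) + 1L, # +1 for the header row
    reason = dplyr::case_when(
      bad_finite[bad] ~ "non-finite value",
      bad_order[bad] ~ "lower > upper",
      TRUE ~ "val outside [lower, upper]"
    )
  )
  if (nrow(rejected) > 0) {
    rlang::warn(sprintf(
      "Rejected %d malformed row(s) (file lines %s).",
      nrow(rejected), paste(utils::head(rejected$line, 10), collapse = ", ")
    ))
    tbl <- tbl[!bad, ]
  }
  attr(tbl, "rejected") <- rejected
  tbl
}

#' Write a GBD-results-style CSV
#'
#' UTF-8, comma-separated, header row, doubles serialized with the shortest
#' decimal representation that round-trips exactly — so `write` then `read`
#' is the identity on the numeric columns.
#'
#' @param tbl A tibble in the dialect of [read_gbd_results()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gbd_results <- function(tbl, path) {
  out <- tbl
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- .shortest_repr(out[[col]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# shortest decimal string whose parse recovers the double bit-for-bit
.shortest_repr <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) {
      return(as.character(v))
    }
    for (d in c(15L, 16L, 17L)) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) {
        return(s)
      }
    }
    as.character(v)
  }, character(1))
}

#' Convert internal estimate tables to the GBD-results dialect
#'
#' Maps pipeline tables (columns `risk`, `cause`, `location`, `year`, `sex`,
#' `age_group`, `val`, `lower`, `upper`) onto the results-tool column names.
#' PAFs are stored internally as proportions and written as `Percent` on the
#' 0-100 scale; the conversion happens only here, at the I/O boundary.
#'
#' @param tbl Internal estimate tibble.
#' @param measure_name Measure label (e.g. `"DALYs"`).
#' @param metric_name `"Number"`, `"Rate"`, or `"Percent"`.
#' @return A tibble in the dialect of [read_gbd_results()].
#' @export
as_gbd_rows <- function(tbl, measure_name, metric_name) {
  scale <- if (metric_name == "Percent") 100 else 1
  lw <- if ("lower" %in% names(tbl)) tbl$lower else tbl$val
  up <- if ("upper" %in% names(tbl)) tbl$upper else tbl$val
  tibble(
    measure_name = measure_name,
    location_name = if ("location" %in% names(tbl)) tbl$location else "Global",
    sex_name = if ("sex" %in% names(tbl)) tbl$sex else "Both",
    age_name = if ("age_group" %in% names(tbl)) tbl$age_group else "All ages",
    cause_name = if ("cause" %in% names(tbl)) tbl$cause else "All causes",
    rei_name = if ("risk" %in% names(tbl)) tbl$risk else NA_character_,
    metric_name = metric_name,
    year = as.integer(tbl$year),
    val = tbl$val * scale,
    upper = up * scale,
    lower = lw * scale
  )
}
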