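#' Column schema of a health-resource panel
#'
#' The canonical on-disk format is a UTF-8 CSV with exactly these columns, one
#' row per region-year: `region_id`, `year`, `population`, `area_km2`, four
#' resource counts (`beds`, `health_technicians`, `licensed_physicians`,
#' `registered_nurses`) and two service-utilisation counts (`consultations`,
#' `admissions`).
#'
#' Counts are stored as real numbers rather than integers because statistical
#' yearbook series may report annual averages; validation only enforces
#' non-negativity.
#'
#' @format A character vector of the ten column names, in canonical order.
#' @export
panel_schema <- c("region_id", "year", "population", "area_km2",
                  "beds", "health_technicians", "licensed_physicians",
                  "registered_nurses", "consultations", "admissions")

#' Names of the resource columns used as equity indicators and DEA inputs
#' @format Character vector of four column names.
#' @export
resource_vars <- c("beds", "health_technicians", "licensed_physicians",
                   "registered_nurses")

#' Names of the service-utilisation columns used as DEA outputs
#' @format Character vector of two column names.
#' @export
utilization_vars <- c("consultations", "admissions")

#' Validate and normalise a health-resource panel
#'
#' Coerces a data frame to the canonical panel layout: checks the schema,
#' validates every record (positive population and area, non-negative finite
#' counts, unique region-year pairs) and sorts rows by (`region_id`, `year`)
#' with regions kept in order of first appearance. Input row order therefore
#' never changes analysis results.
#'
#' @param x A data frame holding the columns of [panel_schema].
#' @return A `health_panel`: the validated data frame with attributes
#'   `regions` (distinct region ids in first-appearance order), `years`
#'   (sorted distinct years) and `complete` (`TRUE` when every region-year
#'   combination occurs exactly once).
#' @examples
#' p <- as_panel(data.frame(
#'   region_id = c("A", "B"), year = 2020, population = c(1e5, 2e5),
#'   area_km2 = c(1000, 4000), beds = c(150, 260),
#'   health_technicians = c(140, 300), licensed_physicians = c(60, 110),
#'   registered_nurses = c(50, 100), consultations = c(2e5, 4e5),
#'   admissions = c(4000, 7000)))
#' attr(p, "complete")
#' @export
as_panel <- function(x) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(panel_schema, names(x))
  if (length(missing_cols) > 0L) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[panel_schema]
  x$region_id <- as.character(x$region_id)
  x$year <- as.integer(x$year)
  num_cols <- setdiff(panel_schema, c("region_id", "year"))
  for (cl in num_cols) x[[cl]] <- as.numeric(x[[cl]])

  bad_num <- !vapply(x[num_cols], function(v) all(is.finite(v)), logical(1))
  if (any(bad_num)) {
    stop("non-finite values in column(s): ",
         paste(num_cols[bad_num], collapse = ", "), call. = FALSE)
  }
  for (cl in c("population", "area_km2")) {
    bad <- which(x[[cl]] <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("%s must be > 0; violated at (%s, %d)", cl,
                   x$region_id[bad[1]], x$year[bad[1]]), call. = FALSE)
    }
  }
  for (cl in c(resource_vars, utilization_vars)) {
    bad <- which(x[[cl]] < 0)
    if (length(bad) > 0L) {
      stop(sprintf("%s must be >= 0; violated at (%s, %d)", cl,
                   x$region_id[bad[1]], x$year[bad[1]]), call. = FALSE)
    }
  }
  key <- paste(x$region_id, x$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicate (region_id, year) pair: (%s, %d)",
                 d$region_id[1], d$year[1]), call. = FALSE)
  }

  regions <- unique(x$region_id)       # first-appearance order
  years <- sort(unique(x$year))
  x <- x[order(match(x$region_id, regions), x$year), , drop = FALSE]
  rownames(x) <- NULL
  complete <- nrow(x) == length(regions) * length(years)
  structure(x, regions = regions, years = years, complete = complete,
            class = c("health_panel", "data.frame"))
}

#' Read a health-resource panel from disk
#'
#' Reads the canonical CSV layout (see [panel_schema]) or, with
#' `format = "xlsx"`, an Excel sheet whose columns are mapped onto the schema
#' through `col_map`. Population and area may live in a separate file (they
#' are typically sourced from a different yearbook than the facility counts);
#' pass it as `merge_with` and the two tables are joined on
#' (`region_id`, `year`).
#'
#' @param path Path to the file.
#' @param format `"csv"` (default) or `"xlsx"`. The Excel reader requires the
#'   readxl package and is a thin adapter: values are mapped into the CSV
#'   schema and then validated identically.
#' @param sheet Sheet name or index for `format = "xlsx"`.
#' @param col_map Named character vector for `format = "xlsx"`: names are
#'   schema column names, values the source headers. Defaults to the identity
#'   mapping.
#' @param merge_with Optional path to a second CSV carrying `region_id`,
#'   `year` and any schema columns missing from the main file.
#' @return A validated `health_panel` (see [as_panel]).
#' @export
read_panel <- function(path, format = c("csv", "xlsx"), sheet = 1,
                       col_map = NULL, merge_with = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    x <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the 'readxl' package; ",
           "export the sheet to the canonical CSV instead", call. = FALSE)
    }
    x <- as.data.frame(readxl::read_excel(path, sheet = sheet))
    if (!is.null(col_map)) {
      found <- match(col_map, names(x))
      if (anyNA(found)) {
        stop("col_map source header(s) not in sheet: ",
             paste(col_map[is.na(found)], collapse = ", "), call. = FALSE)
      }
      names(x)[found] <- names(col_map)
    }
  }
  if (!is.null(merge_with)) {
    y <- utils::read.csv(merge_with, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
    if (!all(c("region_id", "year") %in% names(y))) {
      stop("merge_with file must carry region_id and year", call. = FALSE)
    }
    x <- merge(x, y, by = c("region_id", "year"), all.x = TRUE)
  }
  as_panel(x)
}

#' Write a health-resource panel to the canonical CSV
#'
#' @param panel A `health_panel` or coercible data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- as_panel(panel)
  out <- as.data.frame(panel)[panel_schema]
  # 17 significant digits: doubles survive the round trip bit-exactly
  for (cl in setdiff(panel_schema, c("region_id", "year"))) {
    out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Aggregate a panel year to a single province-level record
#'
#' Sums every numeric field across regions for one year, returning a single
#' record labelled `"TOTAL"`. Used to build the province-level DMU series in
#' which each calendar year is one decision-making unit.
#'
#' @param panel A `health_panel`.
#' @param year Calendar year present in the panel.
#' @return A one-row data frame in the panel schema.
#' @export
aggregate_totals <- function(panel, year) {
  panel <- as_panel(panel)
  year <- as.integer(year)
  rows <- panel[panel$year == year, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("year ", year, " not present in panel", call. = FALSE)
  }
  out <- data.frame(region_id = "TOTAL", year = year)
  for (cl in setdiff(panel_schema, c("region_id", "year"))) {
    out[[cl]] <- sum(rows[[cl]])
  }
  out[panel_schema]
}

#' @export
print.health_panel <- function(x, ...) {
  cat(sprintf("health panel: %d regions x %d years (%d records%s)\n",
              length(attr(x, "regions")), length(attr(x, "years")), nrow(x),
              if (isTRUE(attr(x, "complete"))) ", complete" else ", INCOMPLETE"))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more rows\n", sep = "")
  invisible(x)
}
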