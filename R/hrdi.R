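#' Health resource density index (HRDI)
#'
#' The HRDI combines demographic and geographic access to a resource as the
#' geometric mean of its two densities,
#' \deqn{\mathrm{HRDI} = \sqrt{\frac{\text{resource}}{\text{population}/1000}
#'   \times \frac{\text{resource}}{\text{area (km}^2)}},}
#' which is unit-coherent and particularly informative for sparsely populated
#' regions, where a purely per-capita view overstates access. The bare
#' product of the two densities (no square root) is available via
#' `method = "product"` for sensitivity checks.
#'
#' @param resource_count Non-negative resource count(s).
#' @param population Population(s), > 0.
#' @param area Geographic area(s) in km², > 0.
#' @param method `"geometric"` (default) or `"product"`.
#' @return Numeric density value(s); zero exactly when the count is zero.
#' @examples
#' hrdi(8, 4000, 1)   # per-1000 density 2, per-km2 density 8 -> 4
#' @export
hrdi <- function(resource_count, population, area,
                 method = c("geometric", "product")) {
  method <- match.arg(method)
  resource_count <- as.numeric(resource_count)
  population <- as.numeric(population)
  area <- as.numeric(area)
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("population must be > 0", call. = FALSE)
  }
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("area must be > 0", call. = FALSE)
  }
  if (any(!is.finite(resource_count)) || any(resource_count < 0)) {
    stop("resource_count must be >= 0", call. = FALSE)
  }
  prod <- (resource_count / population * 1000) * (resource_count / area)
  if (method == "geometric") sqrt(prod) else prod
}

#' Standardised density index W relative to a province standard
#'
#' W is a region's HRDI divided by the HRDI of a standard; `W > 1` means the
#' region is allocated above the standard level, `W < 1` below it. The
#' default standard is the province aggregate — total resource, total
#' population and total area for the same year — which is the only
#' construction under which a region shaped exactly like the whole province
#' gets `W = 1`.
#'
#' @param resource_count,population,area Region-level inputs (see [hrdi()]).
#' @param std_resource_count,std_population,std_area Standard-level inputs.
#' @param method Passed to [hrdi()].
#' @return Numeric W value(s).
#' @examples
#' w_index(10, 5000, 50, 100, 50000, 500)   # region identical in shape -> 1
#' @export
w_index <- function(resource_count, population, area,
                    std_resource_count, std_population, std_area,
                    method = c("geometric", "product")) {
  method <- match.arg(method)
  std <- hrdi(std_resource_count, std_population, std_area, method = method)
  if (any(std == 0)) {
    stop("standard HRDI is zero; W undefined", call. = FALSE)
  }
  hrdi(resource_count, population, area, method = method) / std
}

#' W table: standardised density index per region, resource and year
#'
#' Computes W for every region-resource-year of a panel against the chosen
#' province standard, and flags the regions the conventional report calls
#' out: those whose W stays below 1 for every resource and year (allocation
#' below the province level throughout) and those whose W stays above 1.8
#' (far above it).
#'
#' @param panel A `health_panel`.
#' @param resources Resource columns; defaults to [resource_vars].
#' @param standard `"aggregate"` (default): the standard is built from
#'   province totals per year. `"mean"`: the standard HRDI is the unweighted
#'   mean of the regional HRDIs for that year.
#' @param method Passed to [hrdi()].
#' @return Long data frame `region_id`, `year`, `resource`, `hrdi`,
#'   `hrdi_standard`, `w`, with attributes `all_below_1` and `all_above_1.8`
#'   (character vectors of region ids).
#' @export
w_table <- function(panel, resources = resource_vars,
                    standard = c("aggregate", "mean"),
                    method = c("geometric", "product")) {
  panel <- as_panel(panel)
  standard <- match.arg(standard)
  method <- match.arg(method)
  out <- do.call(rbind, lapply(attr(panel, "years"), function(yr) {
    rows <- panel[panel$year == yr, , drop = FALSE]
    do.call(rbind, lapply(resources, function(rs) {
      h <- hrdi(rows[[rs]], rows$population, rows$area_km2, method = method)
      h_std <- if (standard == "aggregate") {
        hrdi(sum(rows[[rs]]), sum(rows$population), sum(rows$area_km2),
             method = method)
      } else {
        mean(h)
      }
      if (h_std == 0) stop("standard HRDI is zero; W undefined", call. = FALSE)
      data.frame(region_id = rows$region_id, year = yr, resource = rs,
                 hrdi = h, hrdi_standard = h_std, w = h / h_std)
    }))
  }))
  rownames(out) <- NULL
  by_region <- split(out$w, out$region_id)
  structure(out,
            all_below_1 = names(by_region)[vapply(by_region, function(w) all(w < 1), logical(1))],
            all_above_1.8 = names(by_region)[vapply(by_region, function(w) all(w > 1.8), logical(1))],
            standard = standard, method = method)
}

#' Per-region resource densities for one year
#'
#' The per-1000-population and per-km² densities behind the usual regional
#' bar-chart summaries, one row per region and resource.
#'
#' @param panel A `health_panel`.
#' @param year Calendar year; defaults to the last year of the panel.
#' @param resources Resource columns; defaults to [resource_vars].
#' @return Data frame `region_id`, `year`, `resource`, `per_1000_pop`,
#'   `per_km2`.
#' @export
density_table <- function(panel, year = NULL, resources = resource_vars) {
  panel <- as_panel(panel)
  if (is.null(year)) year <- max(attr(panel, "years"))
  rows <- panel[panel$year == year, , drop = FALSE]
  if (nrow(rows) == 0L) stop("year ", year, " not present in panel", call. = FALSE)
  out <- do.call(rbind, lapply(resources, function(rs) {
    data.frame(region_id = rows$region_id, year = year, resource = rs,
               per_1000_pop = rows[[rs]] / rows$population * 1000,
               per_km2 = rows[[rs]] / rows$area_km2)
  }))
  rownames(out) <- NULL
  out
}
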