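#' Configuration for the full equity-and-efficiency analysis
#'
#' Bundles the options of [run_all()] into one validated object, so a whole
#' analysis is reproducible from a single configuration value.
#'
#' @param input Path to a panel CSV (see [read_panel()]), or a
#'   `health_panel` / data frame.
#' @param out_dir Output directory; created if absent.
#' @param resources Resource columns to analyse.
#' @param bases Allocation bases for the equity tables.
#' @param dea_tol Efficiency tolerance passed to [dea()].
#' @param dea_slack_from Frontier whose phase-2 slacks are reported.
#' @param w_standard Standard construction for [w_table()].
#' @param density_year Year for the density bar-chart data; `NULL` = last.
#' @param plots Write Lorenz-curve PNGs.
#' @param display_digits Named list of display roundings (gini, w, dea).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input, out_dir = "hrequity-output",
                            resources = resource_vars,
                            bases = c("population", "geography"),
                            dea_tol = 1e-6,
                            dea_slack_from = c("crs", "vrs"),
                            w_standard = c("aggregate", "mean"),
                            density_year = NULL,
                            plots = TRUE,
                            display_digits = list(gini = 2, w = 2, dea = 3)) {
  stopifnot(all(bases %in% c("population", "geography")))
  structure(list(input = input, out_dir = out_dir, resources = resources,
                 bases = bases, dea_tol = dea_tol,
                 dea_slack_from = match.arg(dea_slack_from),
                 w_standard = match.arg(w_standard),
                 density_year = density_year, plots = plots,
                 display_digits = display_digits),
            class = "analysis_config")
}

# wide, display-rounded Gini table: one row per year, resources nested under
# each base
.gini_wide <- function(gt, digits) {
  years <- sort(unique(gt$year))
  wide <- data.frame(year = years)
  for (bs in unique(gt$base)) {
    for (rs in unique(gt$resource)) {
      cl <- paste(rs, "by", bs, sep = "_")
      v <- gt$gini[gt$base == bs & gt$resource == rs]
      wide[[cl]] <- round(v[match(years, gt$year[gt$base == bs & gt$resource == rs])],
                          digits)
    }
  }
  wide
}

# region x resource-year grid of display-rounded W values
.w_wide <- function(wt, digits) {
  regions <- unique(wt$region_id)
  wide <- data.frame(region_id = regions)
  for (rs in unique(wt$resource)) {
    for (yr in sort(unique(wt$year))) {
      sub <- wt[wt$resource == rs & wt$year == yr, ]
      wide[[paste(rs, yr, sep = "_")]] <-
        round(sub$w[match(regions, sub$region_id)], digits)
    }
  }
  wide
}

#' Run the complete equity-and-efficiency analysis
#'
#' One call reproduces the standard report bundle of a provincial
#' equity-and-efficiency study: the year-by-resource Gini table under both
#' allocation bases, the region-by-resource-year W table, the province
#' DEA-by-year table with slacks ("relaxation") and returns to scale, the
#' per-region DEA cross-sections, the per-region density data behind the
#' usual bar charts, Lorenz-curve data (and plots), and a metadata record.
#' Display tables are pure roundings of the machine-precision tables, which
#' are written alongside them, so re-running an identical configuration
#' yields byte-identical outputs.
#'
#' @param config An [analysis_config()], or anything `analysis_config()`
#'   accepts as `input` (a path, panel or data frame), in which case the
#'   remaining arguments are the defaults.
#' @param ... Passed to [analysis_config()] when `config` is not already one.
#' @return Invisibly, a list with every table: `panel`, `gini_long`,
#'   `gini_wide`, `w_long`, `w_wide`, `dea_by_year`, `dea_by_region`,
#'   `density`, `lorenz_points`, and the paths written.
#' @export
run_all <- function(config, ...) {
  if (!inherits(config, "analysis_config")) {
    config <- analysis_config(config, ...)
  }
  panel <- if (is.character(config$input)) {
    read_panel(config$input)
  } else {
    as_panel(config$input)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dd <- config$display_digits
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    paths[[name]] <<- p
  }

  gini_long <- gini_table(panel, resources = config$resources)
  gini_long <- gini_long[gini_long$base %in% config$bases, ]
  gini_wide <- .gini_wide(gini_long, dd$gini)
  emit(gini_long, "gini_table_long.csv")
  emit(gini_wide, "gini_table.csv")

  w_long <- w_table(panel, resources = config$resources,
                    standard = config$w_standard)
  w_wide <- .w_wide(w_long, dd$w)
  emit(w_long, "w_table_long.csv")
  emit(w_wide, "w_table.csv")

  by_year <- run_dea(panel, "years_as_dmus_on_totals", tol = config$dea_tol,
                     slack_from = config$dea_slack_from)
  dea_year_tab <- cbind(
    by_year$results[c("dmu", "overall", "technical", "scale", "rts")],
    by_year$input_slacks, by_year$output_slacks,
    status = by_year$results$status)
  names(dea_year_tab)[1] <- "year"
  emit(dea_year_tab, "dea_by_year_full.csv")
  disp <- dea_year_tab
  num <- vapply(disp, is.numeric, logical(1))
  disp[num] <- lapply(disp[num], round, dd$dea)
  emit(disp, "dea_by_year.csv")

  by_region <- run_dea(panel, "regions_as_dmus_per_year",
                       tol = config$dea_tol,
                       slack_from = config$dea_slack_from)
  dea_region_long <- do.call(rbind, lapply(names(by_region), function(yr) {
    r <- by_region[[yr]]$results
    data.frame(region_id = r$dmu, year = as.integer(yr),
               overall = r$overall, technical = r$technical,
               scale = r$scale, rts = r$rts, status = r$status)
  }))
  emit(dea_region_long, "dea_by_region_full.csv")
  disp <- dea_region_long
  disp[c("overall", "technical", "scale")] <-
    lapply(disp[c("overall", "technical", "scale")], round, dd$dea)
  emit(disp, "dea_by_region.csv")

  dens <- density_table(panel, year = config$density_year,
                        resources = config$resources)
  emit(dens, "density_by_region.csv")

  years <- attr(panel, "years")
  lorenz_points <- do.call(rbind, lapply(years, function(yr) {
    rows <- panel[panel$year == yr, , drop = FALSE]
    do.call(rbind, lapply(config$bases, function(bs) {
      base_col <- if (bs == "population") "population" else "area_km2"
      do.call(rbind, lapply(config$resources, function(rs) {
        lc <- lorenz_curve(rows[[rs]], rows[[base_col]], base_kind = bs,
                           resource = rs, year = yr)
        data.frame(year = yr, base = bs, resource = rs,
                   cum_base_share = lc$x, cum_resource_share = lc$y)
      }))
    }))
  }))
  emit(lorenz_points, "lorenz_points.csv")

  if (isTRUE(config$plots)) {
    for (yr in c(min(years), max(years))) {
      p <- file.path(config$out_dir, sprintf("lorenz_%d.png", yr))
      grDevices::png(p, width = 1400, height = 700, res = 130)
      graphics::par(mfrow = c(1, length(config$bases)))
      rows <- panel[panel$year == yr, , drop = FALSE]
      cols <- grDevices::hcl.colors(length(config$resources), "Dark 3")
      for (bs in config$bases) {
        base_col <- if (bs == "population") "population" else "area_km2"
        first <- TRUE
        for (i in seq_along(config$resources)) {
          rs <- config$resources[i]
          lc <- lorenz_curve(rows[[rs]], rows[[base_col]], base_kind = bs,
                             resource = rs, year = yr)
          plot(lc, add = !first, col = cols[i])
          if (first) graphics::title(main = sprintf("%s base, %d", bs, yr))
          first <- FALSE
        }
        graphics::legend("topleft", legend = config$resources, col = cols,
                         lwd = 2, bty = "n", cex = 0.8)
      }
      grDevices::dev.off()
      paths[[basename(p)]] <- p
    }
  }

  meta <- list(
    package = "hrequity",
    version = as.character(utils::packageVersion("hrequity")),
    n_regions = length(attr(panel, "regions")),
    years = years,
    resources = config$resources,
    bases = config$bases,
    dea = list(tol = config$dea_tol, slack_from = config$dea_slack_from,
               orientation = "input"),
    w_standard = config$w_standard,
    display_digits = dd)
  mp <- file.path(config$out_dir, "run_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths[["run_metadata.json"]] <- mp

  invisible(list(panel = panel, gini_long = gini_long, gini_wide = gini_wide,
                 w_long = w_long, w_wide = w_wide,
                 dea_by_year = dea_year_tab, dea_by_region = dea_region_long,
                 density = dens, lorenz_points = lorenz_points,
                 paths = paths))
}
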