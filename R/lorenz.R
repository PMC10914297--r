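#' Build a Lorenz curve for one resource under one allocation base
#'
#' Regions are ranked in ascending order of resource per unit of the
#' allocation base (per capita when `base_kind = "population"`, per km² when
#' `base_kind = "geography"`); cumulative shares of base and resource are then
#' accumulated along that order and the origin (0, 0) is prepended. Ordering
#' by the rate of the *active* base is the standard Lorenz construction and
#' guarantees a convex polyline lying on or below the diagonal, hence a
#' non-negative Gini coefficient. Ties in the rate keep input order; the
#' curve, and therefore the Gini coefficient, is unaffected by tie order.
#'
#' @param values Non-negative resource count per region.
#' @param bases Positive allocation base per region (population or area).
#' @param base_kind `"population"` or `"geography"`; label only, stored on the
#'   curve.
#' @param resource,year Optional labels stored on the curve.
#' @return A `lorenz_curve`: list with `x` and `y` (cumulative share
#'   coordinates, both starting at 0 and ending at 1), `order` (permutation
#'   applied), and the labels.
#' @examples
#' lc <- lorenz_curve(c(1, 2, 3), c(1, 1, 1))
#' cbind(lc$x, lc$y)   # (0,0), (1/3,1/6), (2/3,1/2), (1,1)
#' @seealso [gini()], [plot.lorenz_curve()]
#' @export
lorenz_curve <- function(values, bases,
                         base_kind = c("population", "geography"),
                         resource = NULL, year = NULL) {
  base_kind <- match.arg(base_kind)
  values <- as.numeric(values)
  bases <- as.numeric(bases)
  if (length(values) != length(bases)) {
    stop("values and bases must have the same length", call. = FALSE)
  }
  if (length(values) < 2L) stop("need at least 2 regions", call. = FALSE)
  if (!all(is.finite(values)) || !all(is.finite(bases))) {
    stop("values and bases must be finite", call. = FALSE)
  }
  if (any(bases <= 0)) stop("all bases must be > 0", call. = FALSE)
  if (any(values < 0)) stop("all values must be >= 0", call. = FALSE)
  if (sum(values) == 0) {
    stop("degenerate Lorenz curve: resource total is zero", call. = FALSE)
  }
  ord <- order(values / bases)           # stable: ties keep input order
  x <- c(0, cumsum(bases[ord]) / sum(bases))
  y <- c(0, cumsum(values[ord]) / sum(values))
  structure(list(x = x, y = y, order = ord, base_kind = base_kind,
                 resource = resource, year = year, n = length(values)),
            class = "lorenz_curve")
}

#' Gini coefficient from a Lorenz curve
#'
#' Computes the Gini coefficient by the trapezoid rule on the Lorenz polyline,
#' \deqn{G = 2 \left[0.5 - \tfrac{1}{2}\sum_{i=1}^{n} (X_i - X_{i-1})(Y_i + Y_{i-1})\right],}
#' i.e. twice the area between the curve and the diagonal of perfect equity.
#' `gini()` is generic: apply it to a [lorenz_curve()] or directly to
#' per-region values and bases.
#'
#' A tiny negative result arising from floating-point cancellation (within
#' 1e-12) is clipped to zero.
#'
#' @param x A `lorenz_curve`, or a numeric vector of per-region resource
#'   values.
#' @param bases For the default method, positive per-region allocation bases.
#' @param ... Passed on to [lorenz_curve()] by the default method.
#' @return A `gini_result`: list with `value` (in \[0, 1)), `band` (equity
#'   label, see [classify_equity()]) and `n_regions`.
#' @examples
#' gini(c(1, 2, 3), c(1, 1, 1))$value   # 2/9
#' @export
gini <- function(x, ...) UseMethod("gini")

#' @rdname gini
#' @export
gini.default <- function(x, bases, ...) {
  gini(lorenz_curve(x, bases, ...))
}

#' @rdname gini
#' @export
gini.lorenz_curve <- function(x, ...) {
  dx <- diff(x$x)
  ysum <- x$y[-1] + x$y[-length(x$y)]
  g <- 2 * (0.5 - 0.5 * sum(dx * ysum))
  if (g < 0 && g > -1e-12) g <- 0
  structure(list(value = g, band = classify_equity(g), n_regions = x$n,
                 base_kind = x$base_kind, resource = x$resource,
                 year = x$year),
            class = "gini_result")
}

#' @export
print.gini_result <- function(x, ...) {
  lbl <- paste(c(x$resource, x$base_kind, x$year), collapse = ", ")
  cat(sprintf("Gini coefficient: %.4f (%s)%s\n", x$value, x$band,
              if (nzchar(lbl)) paste0(" [", lbl, "]") else ""))
  invisible(x)
}

#' Equity band of a Gini coefficient
#'
#' Classifies a Gini coefficient into the conventional equity bands used in
#' health-resource allocation studies: below 0.2 absolute equity, 0.2–0.3
#' relatively fair, 0.3–0.4 basically reasonable, 0.5 and above a wide gap,
#' and 0.6 and above a dangerous state of high inequality. Boundaries are
#' left-closed: `g = 0.2` is already `"relatively_fair"`, `g = 0.6` is
#' `"dangerous_inequality"`.
#'
#' @param g Gini coefficient(s) in \[0, 1\]; vectorised.
#' @return Character vector of band labels among `"absolute_equity"`,
#'   `"relatively_fair"`, `"basically_reasonable"`, `"gap_0.4_0.5"`,
#'   `"wide_gap"`, `"dangerous_inequality"`.
#' @examples
#' classify_equity(c(0.14, 0.35, 0.66))
#' @export
classify_equity <- function(g) {
  g <- as.numeric(g)
  if (any(!is.finite(g)) || any(g < 0) || any(g > 1)) {
    stop("Gini coefficient must lie in [0, 1]", call. = FALSE)
  }
  labs <- c("absolute_equity", "relatively_fair", "basically_reasonable",
            "gap_0.4_0.5", "wide_gap", "dangerous_inequality")
  labs[findInterval(g, c(0.2, 0.3, 0.4, 0.5, 0.6)) + 1L]
}

#' Gini coefficients for every year, resource and allocation base of a panel
#'
#' Each calendar year is treated as an independent cross-section; for each of
#' the four resource indicators a Gini coefficient is computed under the
#' population base and under the geography base, giving the classic
#' year-by-resource-by-base equity table.
#'
#' @param panel A `health_panel` (see [as_panel()]).
#' @param resources Resource columns to include; defaults to [resource_vars].
#' @return A long data frame with columns `year`, `resource`, `base`, `gini`,
#'   `band`. Use [run_all()] to also emit the wide display table.
#' @export
gini_table <- function(panel, resources = resource_vars) {
  panel <- as_panel(panel)
  stopifnot(all(resources %in% setdiff(panel_schema, c("region_id", "year"))))
  years <- attr(panel, "years")
  grid <- expand.grid(base = c("population", "geography"),
                      resource = resources, year = years,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("year", "resource", "base")]
  res <- mapply(function(yr, rs, bs) {
    rows <- panel[panel$year == yr, , drop = FALSE]
    base_col <- if (bs == "population") "population" else "area_km2"
    g <- gini(lorenz_curve(rows[[rs]], rows[[base_col]], base_kind = bs,
                           resource = rs, year = yr))
    c(g$value, g$band)
  }, grid$year, grid$resource, grid$base)
  grid$gini <- as.numeric(res[1, ])
  grid$band <- res[2, ]
  rownames(grid) <- NULL
  grid
}

#' Plot a Lorenz curve against the line of perfect equity
#'
#' @param x A `lorenz_curve`.
#' @param add Add to an existing plot instead of starting a new one.
#' @param col Curve colour.
#' @param ... Further arguments passed to [graphics::plot()] / `lines()`.
#' @return `x`, invisibly.
#' @export
plot.lorenz_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  xl <- if (x$base_kind == "population") {
    "Cumulative share of population"
  } else {
    "Cumulative share of geographic area"
  }
  if (!add) {
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey40",
                   xlab = xl, ylab = "Cumulative share of resource",
                   main = if (!is.null(x$resource)) {
                     paste0(x$resource, if (!is.null(x$year)) paste0(", ", x$year))
                   } else "Lorenz curve",
                   xaxs = "i", yaxs = "i", ...)
  }
  graphics::lines(x$x, x$y, col = col, lwd = 2)
  invisible(x)
}

#' @export
print.lorenz_curve <- function(x, ...) {
  cat(sprintf("Lorenz curve (%s base, %d regions%s%s)\n", x$base_kind, x$n,
              if (!is.null(x$resource)) paste0(", ", x$resource) else "",
              if (!is.null(x$year)) paste0(", ", x$year) else ""))
  cat("G =", format(gini(x)$value, digits = 6), "\n")
  invisible(x)
}
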