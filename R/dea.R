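#' Define a DEA envelopment problem
#'
#' Validates and packages the input and output matrices of a data envelopment
#' analysis. DMUs (decision-making units) are rows; inputs and outputs are
#' columns. Every DMU must have at least one strictly positive input and one
#' strictly positive output, and no entry may be negative.
#'
#' @param inputs Numeric matrix (or coercible) of n DMUs × m inputs.
#' @param outputs Numeric matrix of n DMUs × s outputs.
#' @param labels DMU labels; defaults to the row names of `inputs`, else
#'   `DMU1..DMUn`.
#' @return A `dea_model`: list with `inputs`, `outputs`, `labels`, `n`, `m`,
#'   `s`.
#' @seealso [dea()] for the full analysis; [solve_envelopment()] and
#'   [solve_slacks()] for the individual linear programs.
#' @export
dea_model <- function(inputs, outputs, labels = NULL) {
  inputs <- as.matrix(inputs)
  outputs <- as.matrix(outputs)
  storage.mode(inputs) <- "double"
  storage.mode(outputs) <- "double"
  if (nrow(inputs) != nrow(outputs)) {
    stop("inputs and outputs must have one row per DMU", call. = FALSE)
  }
  n <- nrow(inputs)
  if (n < 1L) stop("need at least one DMU", call. = FALSE)
  if (ncol(inputs) < 1L || ncol(outputs) < 1L) {
    stop("need at least one input and one output", call. = FALSE)
  }
  if (!all(is.finite(inputs)) || !all(is.finite(outputs))) {
    stop("inputs and outputs must be finite", call. = FALSE)
  }
  if (any(inputs < 0) || any(outputs < 0)) {
    stop("inputs and outputs must be non-negative", call. = FALSE)
  }
  if (any(rowSums(inputs > 0) == 0)) {
    stop("every DMU needs at least one strictly positive input", call. = FALSE)
  }
  if (any(rowSums(outputs > 0) == 0)) {
    stop("every DMU needs at least one strictly positive output", call. = FALSE)
  }
  if (is.null(labels)) labels <- rownames(inputs)
  if (is.null(labels)) labels <- paste0("DMU", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have one entry per DMU", call. = FALSE)
  rownames(inputs) <- rownames(outputs) <- labels
  if (is.null(colnames(inputs))) {
    colnames(inputs) <- paste0("input", seq_len(ncol(inputs)))
  }
  if (is.null(colnames(outputs))) {
    colnames(outputs) <- paste0("output", seq_len(ncol(outputs)))
  }
  structure(list(inputs = inputs, outputs = outputs, labels = labels,
                 n = n, m = ncol(inputs), s = ncol(outputs)),
            class = "dea_model")
}

#' @export
print.dea_model <- function(x, ...) {
  cat(sprintf("DEA model: %d DMUs, %d inputs, %d outputs\n", x$n, x$m, x$s))
  invisible(x)
}

# Rescale each input/output column to mean 1 (radial efficiencies are units
# invariant, so this only conditions the LP); returns the scaled model plus
# the factors needed to map slacks back to original units.
.dea_condition <- function(model) {
  fx <- colMeans(model$inputs)
  fy <- colMeans(model$outputs)
  fx[fx == 0] <- 1
  fy[fy == 0] <- 1
  list(X = sweep(model$inputs, 2, fx, "/"),
       Y = sweep(model$outputs, 2, fy, "/"),
       fx = fx, fy = fy)
}

.frontier_ok <- function(frontier) {
  match.arg(frontier, c("crs", "vrs", "nirs"))
}

#' Solve the phase-1 (radial) envelopment program for one DMU
#'
#' Input-oriented envelopment LP: minimise the radial contraction factor
#' \eqn{\theta} subject to \eqn{\sum_j \lambda_j x_{ij} \le \theta x_{i0}}
#' for every input i, \eqn{\sum_j \lambda_j y_{rj} \ge y_{r0}} for every
#' output r and \eqn{\lambda \ge 0}, with \eqn{\sum_j \lambda_j = 1} under
#' the VRS frontier (BCC model) or \eqn{\sum_j \lambda_j \le 1} under NIRS.
#' With no convexity row the frontier is CRS (CCR model). The optimum lies
#' in (0, 1].
#'
#' @param model A [dea_model()].
#' @param dmu_index Index of the DMU under evaluation.
#' @param frontier `"crs"`, `"vrs"` or `"nirs"`.
#' @return List with `theta` (optimal radial efficiency) and `lambda`
#'   (an optimal peer-weight vector, named by DMU label).
#' @examples
#' m <- dea_model(matrix(c(1, 3)), matrix(c(1, 2)))
#' solve_envelopment(m, 2, "crs")$theta   # 2/3
#' solve_envelopment(m, 2, "vrs")$theta   # 1
#' @export
solve_envelopment <- function(model, dmu_index, frontier = "crs") {
  stopifnot(inherits(model, "dea_model"))
  frontier <- .frontier_ok(frontier)
  j0 <- as.integer(dmu_index)
  if (j0 < 1L || j0 > model$n) stop("dmu_index out of range", call. = FALSE)
  sc <- .dea_condition(model)
  X <- sc$X; Y <- sc$Y
  n <- model$n; m <- model$m; s <- model$s

  # variables: (theta, lambda_1..lambda_n)
  obj <- c(1, rep(0, n))
  A <- rbind(cbind(-X[j0, ], t(X)),          # inputs:  X'lambda - theta x0 <= 0
             cbind(0, t(Y)))                 # outputs: Y'lambda >= y0
  dir <- c(rep("<=", m), rep(">=", s))
  rhs <- c(rep(0, m), Y[j0, ])
  if (frontier == "vrs") {
    A <- rbind(A, c(0, rep(1, n))); dir <- c(dir, "="); rhs <- c(rhs, 1)
  } else if (frontier == "nirs") {
    A <- rbind(A, c(0, rep(1, n))); dir <- c(dir, "<="); rhs <- c(rhs, 1)
  }
  sol <- lp_solve(obj, A, dir, rhs, maximize = FALSE)
  if (sol$status != "optimal") {
    stop("envelopment LP not solved to optimality (status: ", sol$status,
         "); check the model for degenerate data", call. = FALSE)
  }
  theta <- min(max(sol$value, 0), 1)         # clip solver noise at the ends
  lambda <- sol$x[-1]
  names(lambda) <- model$labels
  list(theta = theta, lambda = lambda)
}

#' Solve the phase-2 (slack-maximisation) program for one DMU
#'
#' Given the phase-1 optimum \eqn{\theta^*}, maximises the sum of input and
#' output slacks over the peers attaining that radial contraction:
#' \eqn{\max \sum_i s_i^- + \sum_r s_r^+} subject to
#' \eqn{\sum_j \lambda_j x_{ij} + s_i^- = \theta^* x_{i0}},
#' \eqn{\sum_j \lambda_j y_{rj} - s_r^+ = y_{r0}}, all variables
#' non-negative, with the same frontier constraint as phase 1. This two-phase
#' construction avoids the arbitrary small epsilon of the single-LP
#' formulation. Internally the slack variables are eliminated (they are
#' affine in \eqn{\lambda}), leaving an LP in \eqn{\lambda} alone. Slacks
#' are maximised on mean-scaled data and reported back in original units.
#'
#' @param model A [dea_model()].
#' @param dmu_index Index of the DMU under evaluation.
#' @param theta Phase-1 optimal efficiency for this DMU and frontier.
#' @param frontier `"crs"`, `"vrs"` or `"nirs"`.
#' @return List with `input_slacks` (length m), `output_slacks` (length s),
#'   both in the units of the data, and `lambda`.
#' @export
solve_slacks <- function(model, dmu_index, theta, frontier = "crs") {
  stopifnot(inherits(model, "dea_model"))
  frontier <- .frontier_ok(frontier)
  j0 <- as.integer(dmu_index)
  if (j0 < 1L || j0 > model$n) stop("dmu_index out of range", call. = FALSE)
  if (!is.finite(theta) || theta <= 0 || theta > 1 + 1e-9) {
    stop("theta must be the phase-1 optimum in (0, 1]", call. = FALSE)
  }
  sc <- .dea_condition(model)
  X <- sc$X; Y <- sc$Y
  n <- model$n; m <- model$m; s <- model$s

  # variables: lambda only. Total slack = sum_i (theta x0_i - (X'l)_i)
  #                                      + sum_r ((Y'l)_r - y0_r); maximise it.
  obj <- colSums(t(Y)) - colSums(t(X))       # per-lambda_j contribution
  A <- rbind(t(X), t(Y))
  dir <- c(rep("<=", m), rep(">=", s))
  rhs <- c(theta * X[j0, ], Y[j0, ])
  if (frontier == "vrs") {
    A <- rbind(A, rep(1, n)); dir <- c(dir, "="); rhs <- c(rhs, 1)
  } else if (frontier == "nirs") {
    A <- rbind(A, rep(1, n)); dir <- c(dir, "<="); rhs <- c(rhs, 1)
  }
  sol <- lp_solve(obj, A, dir, rhs, maximize = TRUE)
  if (sol$status != "optimal") {
    stop("slack LP not solved to optimality (status: ", sol$status, ")",
         call. = FALSE)
  }
  lambda <- sol$x
  names(lambda) <- model$labels
  s_in <- theta * X[j0, ] - drop(lambda %*% X)
  s_out <- drop(lambda %*% Y) - Y[j0, ]
  s_in[s_in < 0] <- 0                        # solver-level noise only
  s_out[s_out < 0] <- 0
  list(input_slacks = s_in * sc$fx, output_slacks = s_out * sc$fy,
       lambda = lambda)
}

#' Returns-to-scale classification from the three frontier scores
#'
#' Standard NIRS comparison: a DMU operates at constant returns to scale when
#' its CRS and VRS scores agree; otherwise it is on the decreasing side when
#' the NIRS score agrees with the VRS score, and on the increasing side when
#' it does not.
#'
#' @param theta_crs,theta_vrs,theta_nirs Radial efficiencies in (0, 1].
#' @param tol Comparison tolerance on the scores.
#' @return `"constant"`, `"decreasing"` or `"increasing"` (vectorised).
#' @examples
#' returns_to_scale(1, 1, 1)        # constant
#' returns_to_scale(0.991, 1, 1)    # decreasing: NIRS agrees with VRS
#' @export
returns_to_scale <- function(theta_crs, theta_vrs, theta_nirs, tol = 1e-6) {
  stopifnot(length(theta_crs) == length(theta_vrs),
            length(theta_vrs) == length(theta_nirs))
  ifelse(abs(theta_crs - theta_vrs) <= tol, "constant",
         ifelse(abs(theta_nirs - theta_vrs) <= tol, "decreasing",
                "increasing"))
}

#' Input-oriented DEA: overall, technical and scale efficiency
#'
#' Fits the full input-oriented data envelopment analysis to a set of DMUs:
#' the CRS (CCR) envelopment gives overall efficiency, the VRS (BCC)
#' envelopment gives pure technical efficiency, their ratio is scale
#' efficiency, and the NIRS envelopment classifies returns to scale. A
#' second-phase LP maximises the remaining input/output slacks
#' ("relaxation"); by default slacks are reported from the CRS model (set
#' `slack_from = "vrs"` for BCC slacks). A DMU is DEA-effective when its
#' overall efficiency is 1 and all slacks vanish.
#'
#' @param inputs n × m matrix of inputs (DMUs as rows), or a [dea_model()].
#' @param outputs n × s matrix of outputs; ignored when `inputs` is a model.
#' @param labels DMU labels.
#' @param tol Tolerance for efficiency ties and slack-zero tests; slack
#'   comparisons are scaled by each column's mean so the test is
#'   units-free.
#' @param slack_from `"crs"` (default) or `"vrs"`: frontier whose phase-2
#'   slacks are reported.
#' @return A `dea` object: list with `results` (data frame of efficiencies,
#'   RTS and status per DMU), `input_slacks`, `output_slacks`, `lambda`
#'   (peer-weight matrix from the slack phase), `model`, `tol`,
#'   `slack_from`, `call`. Methods: `print`, `summary`, `plot`,
#'   [efficiencies()], `residuals` (input slacks), `predict` (efficient
#'   targets).
#' @examples
#' fit <- dea(matrix(c(1, 3)), matrix(c(1, 2)), labels = c("A", "B"))
#' fit$results
#' @export
dea <- function(inputs, outputs = NULL, labels = NULL, tol = 1e-6,
                slack_from = c("crs", "vrs")) {
  slack_from <- match.arg(slack_from)
  model <- if (inherits(inputs, "dea_model")) inputs else {
    dea_model(inputs, outputs, labels)
  }
  n <- model$n
  th_crs <- th_vrs <- th_nirs <- numeric(n)
  s_in <- matrix(0, n, model$m, dimnames = list(model$labels,
                                                colnames(model$inputs)))
  s_out <- matrix(0, n, model$s, dimnames = list(model$labels,
                                                 colnames(model$outputs)))
  lam <- matrix(0, n, n, dimnames = list(model$labels, model$labels))
  for (j in seq_len(n)) {
    th_crs[j] <- solve_envelopment(model, j, "crs")$theta
    th_vrs[j] <- solve_envelopment(model, j, "vrs")$theta
    th_nirs[j] <- solve_envelopment(model, j, "nirs")$theta
    th_slack <- if (slack_from == "crs") th_crs[j] else th_vrs[j]
    ph2 <- solve_slacks(model, j, th_slack, slack_from)
    s_in[j, ] <- ph2$input_slacks
    s_out[j, ] <- ph2$output_slacks
    lam[j, ] <- ph2$lambda
  }
  # numerical guards: theta_vrs >= theta_nirs >= theta_crs by construction
  th_vrs <- pmax(th_vrs, th_crs)
  th_nirs <- pmin(pmax(th_nirs, th_crs), th_vrs)
  scale_eff <- th_crs / th_vrs
  rts <- returns_to_scale(th_crs, th_vrs, th_nirs, tol)
  slack_scale <- c(colMeans(model$inputs), colMeans(model$outputs))
  slack_scale[slack_scale == 0] <- 1
  slack_zero <- apply(cbind(s_in, s_out), 1,
                      function(sl) all(sl <= tol * slack_scale))
  eff <- th_crs >= 1 - tol & slack_zero
  results <- data.frame(
    dmu = model$labels,
    overall = th_crs, technical = th_vrs, nirs = th_nirs,
    scale = scale_eff, rts = rts,
    efficient = eff,
    status = ifelse(eff, "Efficient", "Inefficient"),
    stringsAsFactors = FALSE)
  rownames(results) <- NULL
  structure(list(results = results, input_slacks = s_in,
                 output_slacks = s_out, lambda = lam, model = model,
                 tol = tol, slack_from = slack_from,
                 call = match.call()),
            class = "dea")
}

#' Extract efficiency scores from a DEA fit
#'
#' @param object A `dea` object.
#' @param type `"overall"` (CRS), `"technical"` (VRS), `"scale"` or
#'   `"nirs"`.
#' @param ... Unused.
#' @return Named numeric vector of scores.
#' @export
efficiencies <- function(object, ...) UseMethod("efficiencies")

#' @rdname efficiencies
#' @export
efficiencies.dea <- function(object,
                             type = c("overall", "technical", "scale", "nirs"),
                             ...) {
  type <- match.arg(type)
  stats::setNames(object$results[[type]], object$results$dmu)
}

#' @export
print.dea <- function(x, digits = 3, ...) {
  cat(sprintf("Input-oriented DEA: %d DMUs, %d inputs, %d outputs (slacks: %s)\n",
              x$model$n, x$model$m, x$model$s, toupper(x$slack_from)))
  out <- x$results[c("dmu", "overall", "technical", "scale", "rts", "status")]
  out[c("overall", "technical", "scale")] <-
    round(out[c("overall", "technical", "scale")], digits)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dea <- function(object, ...) {
  structure(list(fit = object), class = "summary.dea")
}

#' @export
print.summary.dea <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nSlacks (", toupper(f$slack_from), " phase 2):\n", sep = "")
  print(round(cbind(f$input_slacks, f$output_slacks), digits))
  cat("\nMean overall efficiency:",
      format(mean(f$results$overall), digits = 4),
      "| efficient DMUs:", sum(f$results$efficient), "of", f$model$n, "\n")
  invisible(x)
}

#' @export
plot.dea <- function(x, ...) {
  r <- x$results
  graphics::barplot(rbind(overall = r$overall, technical = r$technical,
                          scale = r$scale),
                    beside = TRUE, names.arg = r$dmu, las = 2,
                    ylim = c(0, 1.05), col = c("steelblue", "grey70", "orange"),
                    ylab = "Efficiency score",
                    legend.text = c("overall (CRS)", "technical (VRS)", "scale"),
                    args.legend = list(x = "bottomright", bg = "white"), ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' @export
residuals.dea <- function(object, ...) {
  cbind(object$input_slacks, object$output_slacks)
}

#' Efficient targets (projections) of the DMUs
#'
#' The input-oriented projection of each DMU onto the strongly efficient
#' frontier: inputs are contracted radially by the efficiency score and then
#' reduced by the remaining input slacks; outputs are augmented by the output
#' slacks.
#'
#' @param object A `dea` object.
#' @param ... Unused.
#' @return List with `inputs` and `outputs` matrices of efficient targets.
#' @export
predict.dea <- function(object, ...) {
  th <- if (object$slack_from == "crs") object$results$overall else
    object$results$technical
  list(inputs = object$model$inputs * th - object$input_slacks,
       outputs = object$model$outputs + object$output_slacks)
}

#' Run DEA on a health-resource panel
#'
#' Applies [dea()] to a panel under one of two DMU schemes. With
#' `"years_as_dmus_on_totals"` the panel is aggregated to province totals per
#' year ([aggregate_totals()]) and each calendar year becomes one DMU — the
#' layout of a province-by-year efficiency table. With
#' `"regions_as_dmus_per_year"` each year is an independent cross-section
#' with the regions as DMUs — the layout of a per-region efficiency table.
#' Inputs are the four resource indicators, outputs the two utilisation
#' indicators.
#'
#' @param panel A `health_panel`; must be complete (every region × year
#'   present).
#' @param dmu_scheme `"years_as_dmus_on_totals"` or
#'   `"regions_as_dmus_per_year"`.
#' @param tol,slack_from Passed to [dea()].
#' @return For the totals scheme, a single `dea` fit with years as DMUs. For
#'   the per-year scheme, a named list of `dea` fits, one per year.
#' @export
run_dea <- function(panel,
                    dmu_scheme = c("years_as_dmus_on_totals",
                                   "regions_as_dmus_per_year"),
                    tol = 1e-6, slack_from = c("crs", "vrs")) {
  dmu_scheme <- match.arg(dmu_scheme)
  slack_from <- match.arg(slack_from)
  panel <- as_panel(panel)
  if (!isTRUE(attr(panel, "complete"))) {
    stop("panel is incomplete: every region x year combination is required ",
         "for DEA", call. = FALSE)
  }
  years <- attr(panel, "years")
  if (dmu_scheme == "years_as_dmus_on_totals") {
    tot <- do.call(rbind, lapply(years, function(yr) aggregate_totals(panel, yr)))
    X <- as.matrix(tot[resource_vars])
    Y <- as.matrix(tot[utilization_vars])
    rownames(X) <- rownames(Y) <- as.character(tot$year)
    dea(X, Y, tol = tol, slack_from = slack_from)
  } else {
    fits <- lapply(years, function(yr) {
      rows <- panel[panel$year == yr, , drop = FALSE]
      X <- as.matrix(rows[resource_vars])
      Y <- as.matrix(rows[utilization_vars])
      rownames(X) <- rownames(Y) <- rows$region_id
      dea(X, Y, tol = tol, slack_from = slack_from)
    })
    names(fits) <- as.character(years)
    fits
  }
}
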