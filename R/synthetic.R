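#' Lognormal sigma reproducing a target Gini coefficient
#'
#' For a lognormal population of rates the Gini coefficient has the closed
#' form \eqn{G = 2\Phi(\sigma/\sqrt{2}) - 1}, so the dispersion needed to hit
#' a target Gini is \eqn{\sigma = \sqrt{2}\,\Phi^{-1}((G+1)/2)}. This is the
#' calibration used by [generate_panel()].
#'
#' @param g Target Gini coefficient(s) in \[0, 1).
#' @return Lognormal sigma value(s), >= 0.
#' @examples
#' sigma_for_target_gini(0)      # 0: degenerate distribution
#' sigma_for_target_gini(0.5)    # sqrt(2) * qnorm(0.75)
#' @export
sigma_for_target_gini <- function(g) {
  g <- as.numeric(g)
  if (any(!is.finite(g)) || any(g < 0) || any(g >= 1)) {
    stop("target Gini must lie in [0, 1)", call. = FALSE)
  }
  sqrt(2) * stats::qnorm((g + 1) / 2)
}

# Conditional means of a mean-1 lognormal(sigma) over the probability
# intervals defined by `shares` (which sum to 1): the region-level
# discretisation of the continuous rate distribution, ascending.
.cond_mean_profile <- function(shares, sigma) {
  n <- length(shares)
  if (sigma <= 0) return(rep(1, n))
  u <- c(0, pmin(cumsum(shares), 1))
  u[n + 1L] <- 1
  du <- diff(u)
  r <- diff(stats::pnorm(stats::qnorm(u) - sigma)) / du
  # far tails can underflow to 0/0 at large sigma; fall back to the
  # midpoint quantile of the interval (same mean-1 lognormal)
  bad <- !is.finite(r) | r <= 0
  if (any(bad)) {
    mid <- pmin(pmax((u[-1L] + u[-(n + 1L)]) / 2, 1e-16), 1 - 1e-16)
    r[bad] <- exp(-sigma^2 / 2 + sigma * stats::qnorm(mid[bad]))
  }
  r
}

# base-weighted Gini of per-base rates (values = rate * base)
.weighted_gini <- function(rates, bases) {
  gini(lorenz_curve(rates * bases, bases))$value
}

# sigma such that the *discrete, base-weighted* Gini of the conditional-mean
# profile over `shares` equals the target exactly
.solve_sigma_pop <- function(shares, target, start) {
  if (target == 0) return(0)
  f <- function(sig) {
    .weighted_gini(.cond_mean_profile(shares, sig), shares) - target
  }
  stats::uniroot(f, lower = 0, upper = max(4 * start, 1), extendInt = "upX",
                 tol = 1e-12)$root
}

# Geography dimension: counts are fixed; find densities d (a conditional-mean
# lognormal profile over *area* shares, areas = counts/d) whose area-weighted
# Gini hits the target. The area shares depend on d, so the profile is
# resolved by a short fixed-point inside the sigma root-finder.
.solve_geography <- function(counts, target, start) {
  n <- length(counts)
  areas_for <- function(sig) {
    d <- rep(1, n)
    for (it in 1:200) {
      a <- counts / d
      d_new <- .cond_mean_profile(a / sum(a), sig)
      if (max(abs(d_new - d)) < 1e-13) break
      d <- (d + d_new) / 2
    }
    counts / d
  }
  if (target == 0) return(areas_for(0))
  f <- function(sig) {
    a <- areas_for(sig)
    .weighted_gini(counts / a, a) - target
  }
  sig <- stats::uniroot(f, lower = 0, upper = max(4 * start, 1),
                        extendInt = "upX", tol = 1e-12)$root
  areas_for(sig)
}

# run expr with a private RNG stream; restores the caller's stream after
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic regional health-resource panel
#'
#' Emulates the statistical structure of a provincial panel of township-level
#' health resources: a heavy-tailed distribution of per-km² resource
#' densities (high geography-base Gini) together with near-uniform per-capita
#' rates (low population-base Gini), as is typical when populous regions are
#' compact and sparse regions are vast.
#'
#' The targets refer to the quantity the equity module actually measures: the
#' region-level, base-share-weighted Gini coefficient. An iid lognormal draw
#' calibrated with the closed-form [sigma_for_target_gini()] misses that
#' quantity badly once base weights are heavy-tailed (a province-sized panel
#' has population weights spanning nearly two orders of magnitude), so the
#' generator instead *discretises* the lognormal rate distribution at the
#' region level: regions are laid out in a random order along the cumulative
#' base-share axis and each receives the conditional mean of a lognormal over
#' its share interval, with sigma solved numerically so the weighted Gini of
#' the resulting panel equals the target essentially exactly. Populations are
#' drawn log-uniform in `population_range`; areas are derived from a density
#' profile calibrated the same way against the geography target (area =
#' count/density), which automatically makes sparse regions large — the
#' negative density/area correlation seen in real provinces. All resources
#' share one regional rate profile, scaled by `mean_rate_per_1000` and
#' perturbed by a small lognormal jitter (`resource_jitter_sd`) so they are
#' correlated but not collinear; with jitter 0 the targets are recovered to
#' machine precision. Utilisation outputs are noisy monotone functions of
#' the resources (consultations driven by health technicians, admissions by
#' beds) with multiplicative lognormal noise, so DEA inputs and outputs stay
#' strictly positive. Resource and utilisation counts grow by a common
#' factor per year, which keeps the cross-sectional Gini structure constant
#' across years.
#'
#' With `equal_bases = TRUE` populations and areas are all equal (uniform
#' weights); the population-base target is still hit exactly and the
#' geography-base Gini then coincides with it, so `target_gini_geography` is
#' ignored. Use this mode for exact distributional tests.
#'
#' @param n_regions Number of regions (>= 2). Default 21.
#' @param years Calendar years of the panel. Default 2017:2021.
#' @param seed Integer seed; fixes the entire stream.
#' @param target_gini_population Target population-base Gini. Default 0.15.
#' @param target_gini_geography Target geography-base Gini. Default 0.65.
#' @param mean_rate_per_1000 Named vector of mean resource rates per 1000
#'   population, one per resource column.
#' @param population_range,area_range Positive bounds for the log-uniform
#'   population draw and the area scale.
#' @param consult_per_technician,admissions_per_bed Mean utilisation yields.
#' @param resource_jitter_sd Lognormal sd of the per-resource rate jitter
#'   (0 = resources exactly proportional, targets exact).
#' @param utilization_noise_sd Lognormal sd of the utilisation noise.
#' @param growth Common annual growth factor of counts and utilisation.
#' @param equal_bases Equal populations and areas (exact calibration mode).
#' @return A `health_panel` with attribute `params` (the generating
#'   parameters, for parameter-recovery tests).
#' @examples
#' p <- generate_panel(seed = 1)
#' gini_table(p)[1:4, ]
#' @export
generate_panel <- function(n_regions = 21,
                           years = 2017:2021,
                           seed = 1,
                           target_gini_population = 0.15,
                           target_gini_geography = 0.65,
                           mean_rate_per_1000 = c(beds = 1.5,
                                                  health_technicians = 1.4,
                                                  licensed_physicians = 0.55,
                                                  registered_nurses = 0.5),
                           population_range = c(2e5, 1.6e7),
                           area_range = c(1500, 150000),
                           consult_per_technician = 1300,
                           admissions_per_bed = 25,
                           resource_jitter_sd = 0.05,
                           utilization_noise_sd = 0.08,
                           growth = 1.03,
                           equal_bases = FALSE) {
  stopifnot(n_regions >= 2, length(years) >= 1,
            all(population_range > 0), all(area_range > 0),
            diff(population_range) >= 0, diff(area_range) >= 0,
            consult_per_technician > 0, admissions_per_bed > 0,
            resource_jitter_sd >= 0, utilization_noise_sd >= 0, growth > 0)
  if (!all(resource_vars %in% names(mean_rate_per_1000))) {
    stop("mean_rate_per_1000 must name all resource columns", call. = FALSE)
  }
  sig_pop0 <- sigma_for_target_gini(target_gini_population)
  sig_geo0 <- sigma_for_target_gini(target_gini_geography)
  .with_seed(seed, {
    if (equal_bases) {
      population <- rep(exp(mean(log(population_range))), n_regions)
    } else {
      population <- exp(stats::runif(n_regions, log(population_range[1]),
                                     log(population_range[2])))
    }
    w_pop <- population / sum(population)

    # regional per-capita rate profile (mean 1): lognormal conditional means
    # over the population-share intervals, in a random rank order, with
    # sigma solved so the weighted Gini is the target exactly
    rank_pop <- sample.int(n_regions)       # rank_pop[k] = region in rank k
    sig_pop <- .solve_sigma_pop(w_pop[rank_pop], target_gini_population,
                                sig_pop0)
    profile <- numeric(n_regions)
    profile[rank_pop] <- .cond_mean_profile(w_pop[rank_pop], sig_pop)

    # areas: density profile over area shares, calibrated to the geography
    # target on the reference counts (= profile * population)
    ref_counts <- profile * population / 1000
    if (equal_bases) {
      area <- rep(exp(mean(log(area_range))), n_regions)
    } else {
      rank_geo <- sample.int(n_regions)
      a_rank <- .solve_geography(ref_counts[rank_geo],
                                 target_gini_geography, sig_geo0)
      area <- numeric(n_regions)
      area[rank_geo] <- a_rank
      area <- area * exp(mean(log(area_range)) - mean(log(area)))
    }
    base <- data.frame(region_id = sprintf("R%02d", seq_len(n_regions)),
                       population = population, area_km2 = area)
    jitter <- function(sd) {
      if (sd == 0) rep(1, n_regions) else exp(stats::rnorm(n_regions, -sd^2 / 2, sd))
    }
    rates <- sapply(resource_vars, function(rs) {
      mean_rate_per_1000[[rs]] * profile * jitter(resource_jitter_sd)
    })
    counts0 <- rates * population / 1000          # n_regions x 4
    noise <- function() {
      exp(stats::rnorm(n_regions, -utilization_noise_sd^2 / 2,
                       utilization_noise_sd))
    }
    cons0 <- consult_per_technician * counts0[, "health_technicians"] * noise()
    admi0 <- admissions_per_bed * counts0[, "beds"] * noise()
    records <- do.call(rbind, lapply(seq_along(years), function(t) {
      gf <- growth^(t - 1)
      df <- data.frame(region_id = base$region_id, year = years[t],
                       population = base$population, area_km2 = base$area_km2)
      for (rs in resource_vars) df[[rs]] <- counts0[, rs] * gf
      df$consultations <- cons0 * gf
      df$admissions <- admi0 * gf
      df
    }))
    panel <- as_panel(records)
    attr(panel, "params") <- list(
      n_regions = n_regions, years = years, seed = seed,
      target_gini_population = target_gini_population,
      target_gini_geography = target_gini_geography,
      mean_rate_per_1000 = mean_rate_per_1000,
      population_range = population_range, area_range = area_range,
      consult_per_technician = consult_per_technician,
      admissions_per_bed = admissions_per_bed,
      resource_jitter_sd = resource_jitter_sd,
      utilization_noise_sd = utilization_noise_sd,
      growth = growth, equal_bases = equal_bases)
    panel
  })
}

#' Generate a DEA problem with planted efficiencies
#'
#' Builds a set of DMUs whose true input-oriented overall efficiencies are
#' known by construction: frontier DMUs are placed on the stated technology
#' and each DMU with planted \eqn{\theta^* < 1} has all its inputs inflated
#' by \eqn{1/\theta^*}, so that under a CRS technology the measured radial
#' efficiency equals \eqn{\theta^*} exactly.
#'
#' Technologies: `"ray"` places all frontier DMUs on a single constant
#' -returns ray (scaled copies of one activity), the case with an exact
#' planted-efficiency guarantee; `"cobb_douglas"` (single output) puts
#' frontier DMUs on \eqn{y = A \prod_k x_k^{\beta_k}} with
#' \eqn{\sum_k \beta_k} = `returns`, useful for exercising variable-returns
#' behaviour (an oversized DMU on a `returns < 1` technology shows
#' decreasing returns to scale and scale efficiency < 1).
#'
#' @param n_dmu Number of DMUs.
#' @param n_inputs,n_outputs Dimensions; `"cobb_douglas"` requires
#'   `n_outputs = 1`.
#' @param planted_thetas Efficiencies in (0, 1\], one per DMU; at least one
#'   must equal 1.
#' @param technology `"ray"` or `"cobb_douglas"`.
#' @param returns Sum of Cobb-Douglas exponents (returns-to-scale
#'   parameter).
#' @param seed Integer seed.
#' @return List with `model` (a [dea_model()]), `planted_thetas`,
#'   `technology`.
#' @examples
#' g <- generate_dea_set(5, planted_thetas = c(1, 0.8, 0.5, 1, 0.9), seed = 2)
#' fit <- dea(g$model)
#' round(fit$results$overall - g$planted_thetas, 8)
#' @export
generate_dea_set <- function(n_dmu,
                             n_inputs = 4, n_outputs = 2,
                             planted_thetas = rep(1, n_dmu),
                             technology = c("ray", "cobb_douglas"),
                             returns = 1,
                             seed = 1) {
  technology <- match.arg(technology)
  stopifnot(n_dmu >= 1, n_inputs >= 1, n_outputs >= 1,
            length(planted_thetas) == n_dmu, returns > 0)
  if (any(planted_thetas <= 0) || any(planted_thetas > 1)) {
    stop("planted thetas must lie in (0, 1]", call. = FALSE)
  }
  if (!any(planted_thetas == 1)) {
    stop("at least one planted theta must equal 1 (a frontier DMU)",
         call. = FALSE)
  }
  if (technology == "cobb_douglas" && n_outputs != 1) {
    stop("cobb_douglas technology requires a single output", call. = FALSE)
  }
  .with_seed(seed, {
    if (technology == "ray") {
      x_star <- stats::runif(n_inputs, 1, 10)
      y_star <- stats::runif(n_outputs, 1, 10)
      sc <- exp(stats::runif(n_dmu, log(0.5), log(5)))
      X <- outer(sc, x_star)
      Y <- outer(sc, y_star)
    } else {
      beta <- stats::runif(n_inputs)
      beta <- beta / sum(beta) * returns
      X <- matrix(exp(stats::runif(n_dmu * n_inputs, log(1), log(10))),
                  n_dmu, n_inputs)
      Y <- matrix(exp(drop(log(X) %*% beta)), n_dmu, 1)
    }
    X <- X / planted_thetas          # inflate inputs of inefficient DMUs
    colnames(X) <- paste0("input", seq_len(n_inputs))
    colnames(Y) <- paste0("output", seq_len(n_outputs))
    list(model = dea_model(X, Y),
         planted_thetas = planted_thetas, technology = technology)
  })
}
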