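test_that("dea_model validates the envelopment problem", {
  expect_error(dea_model(matrix(1:4, 2), matrix(1:2)), NA)
  expect_error(dea_model(rbind(c(0, 0), c(1, 1)), matrix(c(1, 1))),
               "positive input")
  expect_error(dea_model(matrix(c(1, 2), 1), matrix(c(0, 1), 1)), NA)
  expect_error(dea_model(matrix(c(1, 1), 2), matrix(c(0, 0), 2)),
               "positive output")
  expect_error(dea_model(matrix(-1), matrix(1)), "non-negative")
  expect_error(dea_model(matrix(1:4, 2), matrix(1:3)), "one row per DMU")
})

test_that("the worked two-DMU example gives the textbook frontier scores", {
  m <- dea_model(matrix(c(1, 3)), matrix(c(1, 2)), labels = c("A", "B"))
  expect_equal(solve_envelopment(m, 2, "crs")$theta, 2/3, tolerance = 1e-10)
  expect_equal(solve_envelopment(m, 2, "vrs")$theta, 1, tolerance = 1e-10)
  expect_equal(solve_envelopment(m, 2, "nirs")$theta, 1, tolerance = 1e-10)
  fit <- dea(m)
  expect_identical(fit$results$rts, c("constant", "decreasing"))
  # VRS convexity forces lambda_B = 1 for B
  lam <- solve_envelopment(m, 2, "vrs")$lambda
  expect_equal(unname(lam), c(0, 1), tolerance = 1e-9)
  # single-DMU problem: trivially efficient, lambda = 1
  m1 <- dea_model(matrix(2), matrix(3))
  e1 <- solve_envelopment(m1, 1, "crs")
  expect_equal(e1$theta, 1)
  expect_equal(unname(e1$lambda), 1)
})

test_that("CRS efficiencies equal the productivity-ratio closed form (1 in, 1 out)", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    x <- runif(n, 0.5, 8); y <- runif(n, 0.5, 8)
    j <- sample(n, 1)
    th <- solve_envelopment(dea_model(matrix(x), matrix(y)), j, "crs")$theta
    expect_equal(th, (y[j] / x[j]) / max(y / x), tolerance = 1e-10)
  }
})

test_that("envelopment optima match brute-force vertex enumeration", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(2:4, 1); m <- sample(1:2, 1); s <- sample(1:2, 1)
    X <- matrix(runif(n * m, 0.5, 5), n)
    Y <- matrix(runif(n * s, 0.5, 5), n)
    md <- dea_model(X, Y)
    for (fr in c("crs", "vrs", "nirs")) {
      j <- sample(n, 1)
      expect_equal(solve_envelopment(md, j, fr)$theta,
                   dea_bruteforce(X, Y, j, fr), tolerance = 1e-8)
    }
  }
  # the 3-DMU mixed-input case: C = (2,2) against A = (1,2), B = (2,1)
  X <- matrix(c(1, 2, 2, 1, 2, 2), 3, byrow = TRUE)
  Y <- matrix(c(1, 1, 1))
  expect_equal(solve_envelopment(dea_model(X, Y), 3, "crs")$theta, 0.75,
               tolerance = 1e-10)
})

test_that("phase-2 slacks expose weak efficiency and vanish on the strong frontier", {
  # D = (1, 2) has theta_vrs = 1 but input-2 slack 1 against A = (1, 1)
  m <- dea_model(matrix(c(1, 1, 1, 2), 2, byrow = TRUE), matrix(c(1, 1)),
                 labels = c("A", "D"))
  e <- solve_envelopment(m, 2, "vrs")
  expect_equal(e$theta, 1, tolerance = 1e-10)
  sl <- solve_slacks(m, 2, e$theta, "vrs")
  expect_equal(unname(sl$input_slacks), c(0, 1), tolerance = 1e-8)
  # strongly efficient DMU: all slacks zero
  slA <- solve_slacks(m, 1, solve_envelopment(m, 1, "vrs")$theta, "vrs")
  expect_true(all(abs(c(slA$input_slacks, slA$output_slacks)) < 1e-8))
  expect_error(solve_slacks(m, 1, 2), "phase-1 optimum")
})

test_that("returns_to_scale applies the NIRS comparison rule", {
  expect_identical(returns_to_scale(1, 1, 1), "constant")
  expect_identical(returns_to_scale(0.991, 1, 1), "decreasing")
  expect_identical(returns_to_scale(2/3, 1, 1), "decreasing")
  expect_identical(returns_to_scale(0.8, 1, 0.8), "increasing")
  expect_identical(
    returns_to_scale(c(1, 0.9), c(1, 1), c(1, 1)),
    c("constant", "decreasing"))
})

test_that("frontier scores are ordered and units invariant; scale <= 1", {
  set.seed(23)
  for (i in 1:5) {
    n <- sample(6:15, 1)
    X <- matrix(exp(rnorm(n * 3)), n)
    Y <- matrix(exp(rnorm(n * 2)), n)
    fit <- dea(X, Y)
    r <- fit$results
    expect_true(all(r$overall > 0 & r$overall <= 1))
    expect_true(all(r$technical >= r$overall - 1e-9))
    expect_true(all(r$nirs >= r$overall - 1e-9 & r$nirs <= r$technical + 1e-9))
    expect_true(all(r$scale <= 1 + 1e-9))
    expect_true(any(r$technical > 1 - 1e-9))     # someone spans the VRS frontier
    expect_identical(r$rts, returns_to_scale(r$overall, r$technical, r$nirs))
    # rescaling any input or output row leaves every theta unchanged
    X2 <- X; X2[, 1] <- X2[, 1] * 500
    Y2 <- Y; Y2[, 2] <- Y2[, 2] / 300
    r2 <- dea(X2, Y2)$results
    expect_equal(r2$overall, r$overall, tolerance = 1e-8)
    expect_equal(r2$technical, r$technical, tolerance = 1e-8)
  }
})

test_that("adding a dominated DMU never helps anyone and is itself inefficient", {
  set.seed(9)
  X <- matrix(runif(8 * 2, 1, 5), 8)
  Y <- matrix(runif(8 * 2, 1, 5), 8)
  base <- dea(X, Y)$results$overall
  X2 <- rbind(X, X[3, ] * 1.4)          # more input,
  Y2 <- rbind(Y, Y[3, ] * 0.7)          # less output: strictly dominated
  aug <- dea(X2, Y2)$results$overall
  expect_true(all(aug[1:8] <= base + 1e-9))
  expect_lt(aug[9], 1)
})

test_that("run_dea supports year-totals and per-year region schemes", {
  p <- generate_panel(seed = 13, n_regions = 7)
  by_year <- run_dea(p, "years_as_dmus_on_totals")
  expect_equal(by_year$model$n, 5)
  expect_equal(by_year$model$m, 4)
  expect_equal(by_year$model$s, 2)
  expect_identical(by_year$results$dmu, as.character(2017:2021))

  by_region <- run_dea(p, "regions_as_dmus_per_year")
  expect_named(by_region, as.character(2017:2021))
  expect_equal(by_region[["2019"]]$model$n, 7)

  # proportional DMUs on a common CRS ray: everyone efficient
  df <- make_tiny_panel()
  sc <- df$population / 1e5
  for (cl in c(resource_vars, utilization_vars)) df[[cl]] <- 10 * sc
  fits <- run_dea(as_panel(df), "regions_as_dmus_per_year")
  for (f in fits) expect_true(all(f$results$overall > 1 - 1e-9))

  expect_error(run_dea(as_panel(make_tiny_panel()[-1, ])), "incomplete")
})

test_that("dea methods expose scores, slacks and efficient targets", {
  g <- generate_dea_set(6, planted_thetas = c(1, 0.8, 0.6, 1, 0.9, 0.7),
                        seed = 4)
  fit <- dea(g$model)
  expect_equal(unname(efficiencies(fit)), g$planted_thetas, tolerance = 1e-7)
  expect_equal(unname(efficiencies(fit, "scale")),
               fit$results$overall / fit$results$technical, tolerance = 1e-9)
  expect_identical(dim(residuals(fit)), c(6L, 6L))   # 4 inputs + 2 outputs
  proj <- predict(fit)
  # projections are feasible: no more input, no less output than target
  expect_true(all(proj$inputs <= fit$model$inputs + 1e-8))
  expect_true(all(proj$outputs >= fit$model$outputs - 1e-8))
  expect_output(print(fit), "Input-oriented DEA")
  expect_output(print(summary(fit)), "Slacks")
})
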