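test_that("sigma_for_target_gini matches the lognormal closed form", {
  expect_equal(sigma_for_target_gini(0), 0)
  expect_equal(sigma_for_target_gini(0.5), sqrt(2) * qnorm(0.75))
  expect_error(sigma_for_target_gini(-0.1), "\\[0, 1\\)")
  expect_error(sigma_for_target_gini(1), "\\[0, 1\\)")

  # Monte-Carlo round trip: the Gini of lognormal draws with sigma(g) is g
  set.seed(2024)
  for (g in c(0.1, 0.3, 0.5, 0.7)) {
    z <- sort(rlnorm(2e5, 0, sigma_for_target_gini(g)))
    n <- length(z)
    g_mc <- 2 * sum(seq_len(n) * z) / (n * sum(z)) - (n + 1) / n
    expect_equal(g_mc, g, tolerance = 0.01)
  }
})

test_that("generate_panel is deterministic under seed and schema-valid", {
  p1 <- generate_panel(seed = 77)
  p2 <- generate_panel(seed = 77)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- generate_panel(seed = 78)
  expect_false(identical(p1$beds, p3$beds))
  expect_s3_class(p1, "health_panel")           # emission passed validation
  expect_true(attr(p1, "complete"))
  expect_true(all(p1$consultations > 0) && all(p1$admissions > 0))
  # the generator restores the caller's RNG stream
  set.seed(1); before <- runif(5)
  set.seed(1); invisible(generate_panel(seed = 99)); after <- runif(5)
  expect_identical(before, after)
})

test_that("generated panels hit their Gini targets", {
  # jitter-free mode: targets are met to machine precision
  p <- generate_panel(seed = 3, resource_jitter_sd = 0)
  gt <- gini_table(p)
  expect_equal(gt$gini[gt$base == "population"], rep(0.15, 20),
               tolerance = 1e-9)
  expect_equal(gt$gini[gt$base == "geography"], rep(0.65, 20),
               tolerance = 1e-9)

  # degenerate target: zero population-base Gini exactly
  p0 <- generate_panel(seed = 4, target_gini_population = 0,
                       resource_jitter_sd = 0)
  gt0 <- gini_table(p0)
  expect_true(all(gt0$gini[gt0$base == "population"] < 1e-12))

  # equal-base mode: uniform weights, both bases at the population target
  pe <- generate_panel(seed = 5, equal_bases = TRUE, resource_jitter_sd = 0)
  expect_equal(length(unique(pe$population)), 1)
  gte <- gini_table(pe)
  expect_equal(gte$gini, rep(0.15, 40), tolerance = 1e-9)

  # default jitter: targets recovered within a small neighbourhood
  gtj <- gini_table(generate_panel(seed = 6), resources = "beds")
  expect_equal(gtj$gini[gtj$base == "population"], rep(0.15, 5),
               tolerance = 0.05)
  expect_equal(gtj$gini[gtj$base == "geography"], rep(0.65, 5),
               tolerance = 0.05)
})

test_that("generate_dea_set plants exact overall efficiencies on a CRS ray", {
  th <- c(1, 0.8, 0.5)
  g <- generate_dea_set(3, planted_thetas = th, seed = 21)
  expect_equal(dea(g$model)$results$overall, th, tolerance = 1e-6)

  # all planted at 1: everyone efficient
  g1 <- generate_dea_set(6, planted_thetas = rep(1, 6), seed = 22)
  fit1 <- dea(g1$model)
  expect_true(all(fit1$results$overall > 1 - 1e-9))

  expect_error(generate_dea_set(3, planted_thetas = c(0.9, 0.8, 0.7)),
               "frontier DMU")
  expect_error(generate_dea_set(2, planted_thetas = c(1, 1.2)), "\\(0, 1\\]")
})

test_that("an oversized DMU on a diminishing-returns technology shows DRS", {
  g <- generate_dea_set(8, n_inputs = 2, n_outputs = 1,
                        planted_thetas = rep(1, 8),
                        technology = "cobb_douglas", returns = 0.6, seed = 30)
  fit <- dea(g$model)
  big <- which.max(rowSums(g$model$inputs))
  expect_lt(fit$results$scale[big], 1)
  expect_identical(fit$results$rts[big], "decreasing")
})
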