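test_that("lorenz_curve produces the hand-computed polyline", {
  lc <- lorenz_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(lc$x, c(0, 1/3, 2/3, 1))
  expect_equal(lc$y, c(0, 1/6, 1/2, 1))

  # equal per-base rates: the curve is the diagonal
  lc2 <- lorenz_curve(c(2, 4, 8), c(1, 2, 4))
  expect_equal(lc2$x, lc2$y)

  # extreme concentration: hugs the x-axis until the final segment
  lc3 <- lorenz_curve(c(0, 0, 0, 5), rep(1, 4))
  expect_equal(lc3$y, c(0, 0, 0, 0, 1))

  expect_error(lorenz_curve(c(0, 0), c(1, 1)), "degenerate")
  expect_error(lorenz_curve(c(1, 2), c(1, 0)), "> 0")
  expect_error(lorenz_curve(c(1, 2, 3), c(1, 1)), "length")
  expect_error(lorenz_curve(3, 1), "at least 2")
})

test_that("lorenz curves are monotone, convex and lie below the diagonal", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:15, 1)
    lc <- lorenz_curve(rgamma(n, 0.7), runif(n, 0.2, 5),
                       base_kind = sample(c("population", "geography"), 1))
    expect_equal(c(lc$x[1], lc$y[1]), c(0, 0))
    expect_equal(c(lc$x[length(lc$x)], lc$y[length(lc$y)]), c(1, 1))
    expect_true(all(diff(lc$x) >= -1e-12) && all(diff(lc$y) >= -1e-12))
    expect_true(all(lc$y <= lc$x + 1e-12))
    # convexity: slopes (rates) non-decreasing along the curve
    slopes <- diff(lc$y) / diff(lc$x)
    expect_true(all(diff(slopes) >= -1e-9 * max(slopes)))
  }
})

test_that("gini matches hand values and the pairwise oracle", {
  expect_equal(gini(c(1, 2, 3), c(1, 1, 1))$value, 2/9)
  expect_equal(gini(c(0, 1), c(1, 1))$value, 0.5)
  expect_equal(gini(c(5, 10, 20), c(1, 2, 4))$value, 0)    # diagonal

  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    v <- rgamma(n, shape = 0.8) + 1e-3
    b <- runif(n, 0.1, 10)
    expect_equal(gini(v, b)$value, gini_mad_oracle(v, b), tolerance = 1e-12)
  }
})

test_that("gini is invariant to scaling and region order, monotone in transfers", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    v <- rgamma(n, 1) + 1e-3
    b <- runif(n, 0.5, 4)
    g <- gini(v, b)$value
    expect_equal(gini(v * 17.3, b)$value, g, tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(gini(v[perm], b[perm])$value, g, tolerance = 1e-12)
    # regressive transfer: move resource from the poorest-rate region to the
    # richest-rate region
    r <- v / b
    lo <- which.min(r); hi <- which.max(r)
    d <- v[lo] / 2
    v2 <- v; v2[lo] <- v2[lo] - d; v2[hi] <- v2[hi] + d
    expect_gte(gini(v2, b)$value, g - 1e-12)
  }
  # ties in per-base rates: tie order cannot change G
  v <- c(2, 1, 1, 4); b <- c(2, 1, 1, 1)   # regions 2 and 3 tied at rate 1
  expect_equal(gini(v, b)$value, gini(v[c(1, 3, 2, 4)], b[c(1, 3, 2, 4)])$value)
})

test_that("equity bands follow the conventional cut-points, left-closed", {
  expect_identical(classify_equity(0.14), "absolute_equity")
  expect_identical(classify_equity(0.35), "basically_reasonable")
  expect_identical(classify_equity(0.66), "dangerous_inequality")
  expect_identical(
    classify_equity(c(0, 0.2, 0.3, 0.4, 0.5, 0.6)),
    c("absolute_equity", "relatively_fair", "basically_reasonable",
      "gap_0.4_0.5", "wide_gap", "dangerous_inequality"))
  expect_error(classify_equity(-0.1), "\\[0, 1\\]")
  expect_error(classify_equity(1.2), "\\[0, 1\\]")
})

test_that("gini_table covers every year-resource-base cell", {
  p <- generate_panel(seed = 5, n_regions = 8)
  gt <- gini_table(p)
  expect_equal(nrow(gt), 5 * 4 * 2)                       # 40 Gini values
  expect_true(all(gt$gini >= 0 & gt$gini < 1))
  expect_identical(gt$band, classify_equity(gt$gini))

  # identical per-capita rates everywhere: population-base entries all zero
  df <- make_tiny_panel()
  for (rs in resource_vars) df[[rs]] <- df$population / 1000
  gt0 <- gini_table(as_panel(df))
  expect_true(all(gt0$gini[gt0$base == "population"] < 1e-12))
})
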