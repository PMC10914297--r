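test_that("a well-formed panel validates, sorts and flags completeness", {
  df <- make_tiny_panel()
  p <- as_panel(df)
  expect_s3_class(p, "health_panel")
  expect_identical(attr(p, "regions"), c("A", "B", "C"))   # first appearance
  expect_identical(attr(p, "years"), c(2020L, 2021L))
  expect_true(attr(p, "complete"))
  expect_identical(p$region_id, rep(c("A", "B", "C"), each = 2))

  # shuffled input: region order follows first appearance, but analytics
  # are order-invariant
  shuf <- df[c(4, 1, 6, 3, 2, 5), ]
  ps <- as_panel(shuf)
  expect_identical(sort(attr(ps, "regions")), c("A", "B", "C"))
  expect_identical(attr(ps, "regions"), unique(shuf$region_id))
  expect_equal(gini_table(ps)$gini, gini_table(p)$gini)

  # incomplete: drop one record
  p2 <- as_panel(df[-1, ])
  expect_false(attr(p2, "complete"))

  # 21 x 5 synthetic panel has 105 records and is complete
  big <- generate_panel(seed = 1)
  expect_equal(nrow(big), 105)
  expect_true(attr(big, "complete"))
})

test_that("schema and record validation report the offending column/record", {
  df <- make_tiny_panel()
  expect_error(as_panel(df[setdiff(names(df), "area_km2")]), "area_km2")
  bad <- df; bad$population[3] <- 0
  expect_error(as_panel(bad), "population.*B, 2020")
  bad <- df; bad$beds[2] <- -1
  expect_error(as_panel(bad), "beds.*A, 2021")
  bad <- df; bad$consultations[5] <- NaN
  expect_error(as_panel(bad), "consultations")
  dup <- rbind(df, df[4, ])
  expect_error(as_panel(dup), "duplicate.*B, 2021")
})

test_that("write_panel/read_panel round-trips a panel exactly", {
  p <- generate_panel(seed = 42, n_regions = 6, years = 2019:2021)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path)
  p2 <- read_panel(path)
  expect_identical(dim(p2), dim(p))
  for (cl in panel_schema) expect_identical(p2[[cl]], p[[cl]])
  expect_error(read_panel(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("read_panel merges population/area supplied in a second file", {
  df <- make_tiny_panel()
  main <- df[setdiff(names(df), c("population", "area_km2"))]
  aux <- unique(df[c("region_id", "year", "population", "area_km2")])
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(main, f1, row.names = FALSE)
  write.csv(aux, f2, row.names = FALSE)
  p <- read_panel(f1, merge_with = f2)
  expect_true(attr(p, "complete"))
  expect_equal(sum(p$population), sum(df$population))
})

test_that("aggregate_totals sums every field and ignores region order", {
  df <- make_tiny_panel()
  tot <- aggregate_totals(df, 2020)
  expect_identical(tot$region_id, "TOTAL")
  expect_equal(tot$beds, 150 + 260 + 410)
  expect_equal(tot$admissions, 4000 + 7000 + 10000)
  # permutation invariance
  tot2 <- aggregate_totals(df[sample(nrow(df)), ], 2020)
  expect_equal(tot, tot2)
  # single-region panel: identity
  one <- df[df$region_id == "B", ]
  t1 <- aggregate_totals(one, 2021)
  expect_equal(t1$beds, one$beds[one$year == 2021])
  expect_error(aggregate_totals(df, 1999), "1999")
})
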