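catalog <- variable_catalog(treatments = TRUE)

test_that("outlier filtering drops implausible values and is idempotent", {
  events <- ev(1, c(1, 2, 3, 4), c("Weight", "MeanBP", "HR", "HR"),
               c(350, -5, 80, 400))
  f <- filter_outliers(events, catalog)
  expect_equal(nrow(f), 1L)
  expect_equal(f$variable, "HR")
  expect_equal(f$value, 80)
  removed <- attr(f, "removed")
  expect_equal(unname(removed[c("Weight", "MeanBP", "HR")]), c(1L, 1L, 1L))
  f2 <- filter_outliers(f, catalog)
  expect_equal(f2$value, f$value)
  expect_error(filter_outliers(ev(1, 1, "NotAVar", 1), catalog), "NotAVar")
})

test_that("binning aggregates by the catalog rule and drops out-of-window", {
  onset <- c("1" = 24)
  events <- rbind(
    ev(1, c(0.5, 1.5), "HR", c(80, 90)),            # bin 1: mean -> 85
    ev(1, c(2.0, 3.0), "Vasopressor", c(0.1, 0.3)), # bin 1: max -> 0.3
    ev(1, c(1.0, 2.5), "Fluids", c(100, 200)),      # bin 1: sum -> 300
    ev(1, 100, "HR", 70)                            # beyond +48h: dropped
  )
  g <- bin_events(events, onset, catalog)
  expect_equal(g$values["1", 1, "HR"], 85)
  expect_equal(g$values["1", 1, "Vasopressor"], 0.3)
  expect_equal(g$values["1", 1, "Fluids"], 300)
  expect_true(all(is.na(g$values["1", 2:18, "HR"])))
  # onset sits at the left edge of bin 7
  g2 <- bin_events(ev(1, 24.0, "HR", 77), onset, catalog)
  expect_equal(g2$values["1", 7, "HR"], 77)
  # permutation invariance within a bin
  perm <- events[sample(nrow(events)), ]
  gp <- bin_events(perm, onset, catalog)
  expect_equal(gp$values, g$values)
})

test_that("hold, interpolation and kNN stages fill in the documented order", {
  onset <- c("1" = 24, "2" = 24, "3" = 24, "4" = 24)
  # stay 1: HR (hold 8h = 2 bins) at bin 1 = 10 and bin 5 = 20
  base <- rbind(
    ev(1, 0.5, "HR", 10), ev(1, 16.5, "HR", 20),
    ev(2, seq(0.5, 71, by = 4), "HR", rep(50, 18)),
    ev(3, seq(0.5, 71, by = 4), "HR", rep(52, 18)),
    ev(4, seq(0.5, 71, by = 4), "HR", rep(48, 18)))
  g <- bin_events(base, onset, catalog["HR", , drop = FALSE])
  gi <- impute_grid(g, catalog, k_neighbors = 3)
  # bins 2-3 by hold (8 h limit = 2 bins)
  expect_equal(gi$values["1", 2, "HR"], 10)
  expect_equal(gi$values["1", 3, "HR"], 10)
  # bin 4 by linear interpolation between the held bin 3 and observed bin 5
  expect_equal(gi$values["1", 4, "HR"], 15)
  expect_false(anyNA(gi$values))
  # original mask untouched
  expect_equal(sum(gi$mask["1", , "HR"]), 2L)
})

test_that("kNN fills an entirely missing stay-variable from nearest rows", {
  onset <- c("1" = 24, "2" = 24, "3" = 24, "4" = 24, "5" = 24)
  cat2 <- catalog[c("HR", "RR"), ]
  # stay 1 has RR missing everywhere; HR identifies its nearest neighbours
  events <- rbind(
    ev(1, 0.5, "HR", 60),
    ev(2, 0.5, "HR", 61), ev(2, 0.5, "RR", 12),
    ev(3, 0.5, "HR", 59), ev(3, 0.5, "RR", 14),
    ev(4, 0.5, "HR", 62), ev(4, 0.5, "RR", 16),
    ev(5, 0.5, "HR", 100), ev(5, 0.5, "RR", 40))
  g <- bin_events(events, onset, cat2, bins = 1L)
  gi <- impute_grid(g, cat2, k_neighbors = 3)
  # brute-force oracle: 3 nearest rows by standardized HR are stays 2-4
  expect_equal(gi$values["1", 1, "RR"], mean(c(12, 14, 16)))
})

test_that("imputation is the identity on fully observed grids", {
  cfg <- quick_config(seed = 2, missing_rate = 0, outlier_rate = 0)
  coh <- generate_cohort(cfg)
  onset <- setNames(coh$metadata$onset_true, coh$metadata$stay_id)
  clin <- catalog[catalog$group != "treatment", ]
  g <- bin_events(coh$events, onset, clin, bins = cfg$bins)
  expect_false(anyNA(g$values))
  gi <- impute_grid(g, clin)
  expect_equal(gi$values, g$values)
})

test_that("hold never propagates across gaps longer than the limit", {
  onset <- c("1" = 24, "2" = 24)
  cat2 <- catalog[c("HR", "RR"), ]
  # HR holds 8 h (2 bins); stay 1's HR observed only in bin 1. RR marks
  # stay 1's later bins as close to stay 2 and far from its own early bins.
  events <- rbind(
    ev(1, 0.5, "HR", 200),
    ev(1, seq(0.5, 11, by = 4), "RR", rep(30, 3)),
    ev(1, seq(12.5, 71, by = 4), "RR", rep(100, 15)),
    ev(2, seq(0.5, 71, by = 4), "HR", rep(60, 18)),
    ev(2, seq(0.5, 71, by = 4), "RR", rep(100, 18)))
  g <- bin_events(events, onset, cat2)
  gi <- impute_grid(g, cat2, k_neighbors = 1)
  expect_equal(unname(gi$values["1", 2:3, "HR"]), c(200, 200))
  # beyond the hold limit the fill comes from the nearest neighbour row
  expect_equal(unname(gi$values["1", 4:18, "HR"]), rep(60, 15))
})
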