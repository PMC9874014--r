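test_that("replicate normalization equalizes experiment means", {
  df <- tibble::tibble(
    experiment = rep(c("e1", "e2"), each = 3),
    value = c(8, 10, 12, 16, 20, 24)   # means 10 and 20, grand mean 15
  )
  out <- normalize_replicates(df)
  expect_equal(mean(out$value[out$experiment == "e1"]), 15)
  expect_equal(mean(out$value[out$experiment == "e2"]), 15)
  expect_equal(mean(out$value), 15)     # grand mean preserved
  # a single experiment, or all-equal values, pass through unchanged
  one <- tibble::tibble(experiment = "e1", value = c(3, 5, 7))
  expect_equal(normalize_replicates(one)$value, c(3, 5, 7))
  flat <- tibble::tibble(experiment = c("e1", "e2"), value = c(4, 4))
  expect_equal(normalize_replicates(flat)$value, c(4, 4))
  expect_error(normalize_replicates(
    tibble::tibble(experiment = "e1", value = c(-1, 1))), "zero mean")
})

test_that("daily rates difference against the previous day's average", {
  tc <- tibble::tibble(
    condition = "WT", replicate = 1L, analyte = "lactate",
    day = c(0, 1, 2), value = c(0, 10, 20)
  )
  out <- daily_flux(tc)
  expect_equal(out$rates$rate_per_ml, c(10, 10))
  # constant values give zero rates
  flat <- dplyr::mutate(tc, value = 7)
  expect_equal(daily_flux(flat)$rates$rate_per_ml, c(0, 0))
  # consumption is negative
  glc <- dplyr::mutate(tc, value = c(25, 15, 5))
  expect_equal(daily_flux(glc)$rates$rate_per_ml, c(-10, -10))
})

test_that("daily rates use replicate averages at the earlier day", {
  tc <- tibble::tibble(
    condition = "WT", replicate = rep(1:2, 3), analyte = "a",
    day = rep(c(0, 1, 2), each = 2), value = c(0, 2, 10, 14, 20, 26)
  )
  out <- daily_flux(tc)
  d1 <- out$rates[out$rates$day == 1, ]
  # previous-day mean is 1; replicates keep their own value at day d
  expect_equal(sort(d1$rate_per_ml), c(10 - 1, 14 - 1))
})

test_that("per-cell and per-protein normalizations divide by two-day means", {
  tc <- tibble::tibble(condition = "WT", replicate = 1L, analyte = "a",
                       day = 0:3, value = c(0, 10, 30, 60))
  cells <- tibble::tibble(condition = "WT", day = 0:3,
                          cells_per_ml = c(1, 3, 5, 7))
  prot <- tibble::tibble(condition = "WT", day = 0:3,
                         ng_per_cell = c(2, 2, 2, 2))
  out <- daily_flux(tc, cells, prot)
  r <- out$rates
  expect_equal(r$rate_per_cell, r$rate_per_ml / c(2, 4, 6))
  expect_equal(r$rate_per_ng, r$rate_per_cell / 2)
  # comparison window for model fluxes: mean of day-2 and day-3 rates
  expect_equal(out$fba_comparison$rate,
               mean(r$rate_per_ng[r$day %in% c(2, 3)]))
})

test_that("rates are linear in the analyte values", {
  tc <- tibble::tibble(condition = "WT", replicate = 1L, analyte = "a",
                       day = 0:3, value = c(1, 4, 9, 16))
  r1 <- daily_flux(tc)$rates$rate_per_ml
  tc2 <- dplyr::mutate(tc, value = 3 * value)
  expect_equal(daily_flux(tc2)$rates$rate_per_ml, 3 * r1)
})

test_that("net protein synthesis is the two-day difference", {
  expect_equal(net_protein_synthesis(100, 300), 100)
  expect_equal(net_protein_synthesis(100, 100), 0)
  expect_lt(net_protein_synthesis(300, 100), 0)
  expect_equal(net_protein_synthesis(100, 300, normalized = TRUE), 0.5)
  expect_error(net_protein_synthesis(0, 10), "positive")
})
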