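make_small_dataset <- function(values, attention = NULL, days = NULL) {
  # values: matrix (days x p) for one person, possibly with NA
  p <- ncol(values)
  if (is.null(days)) days <- seq_len(nrow(values))
  if (is.null(attention)) attention <- rep(TRUE, nrow(values))
  d <- data.frame(person_id = "P1", day = days)
  v <- paste0("V", seq_len(p))
  d[v] <- as.data.frame(values)
  d$attention_pass <- attention
  esm_dataset(d, v, discretized = FALSE)
}

test_that("attention-check filtering removes failing records", {
  ds <- make_small_dataset(matrix(1:6, 3, 2))
  expect_identical(filter_attention_checks(ds)$data, ds$data)

  ds1 <- make_small_dataset(matrix(1:6, 3, 2), attention = c(TRUE, FALSE, TRUE))
  out <- filter_attention_checks(ds1)
  expect_identical(nrow(out$data), 2L)
  expect_identical(out$data$day, c(1L, 3L))

  ds2 <- make_small_dataset(matrix(1:6, 3, 2), attention = rep(FALSE, 3))
  out2 <- filter_attention_checks(ds2)
  expect_identical(nrow(out2$data), 0L)
  expect_identical(nrow(build_lagged_design(out2, "listwise")$rows), 0L)

  # absent flag counts as failing
  ds3 <- make_small_dataset(matrix(1:6, 3, 2), attention = c(TRUE, NA, TRUE))
  expect_identical(nrow(filter_attention_checks(ds3)$data), 2L)
})

test_that("moving-average imputation follows the stated window rule", {
  expect_equal(moving_average_impute(c(1, NA, 3), window = 1), c(1, 2, 3))
  expect_equal(moving_average_impute(c(5, 6, 7), window = 1), c(5, 6, 7))
  # edge: only the right neighbor is inside the window
  expect_equal(moving_average_impute(c(NA, 2, 4), window = 1), c(2, 2, 4))
  # empty window expands symmetrically until an observed value appears
  expect_equal(moving_average_impute(c(NA, NA, NA, 5), window = 1),
               c(5, 5, 5, 5))
  # means use original observed values only, never imputed ones
  expect_equal(moving_average_impute(c(1, NA, NA, 7), window = 1),
               c(1, 1, 7, 7))
  expect_error(moving_average_impute(c(NA, NA), window = 1), "all-missing")
})

test_that("imputation is idempotent and preserves observed entries", {
  set.seed(21)
  for (rep in 1:20) {
    y <- rnorm(30)
    y[sample(30, 8)] <- NA
    imp <- moving_average_impute(y, window = 2)
    expect_false(anyNA(imp))
    expect_equal(imp[!is.na(y)], y[!is.na(y)])
    expect_identical(moving_average_impute(imp, window = 2), imp)
  }
})

test_that("lagged rows pair consecutive calendar days only", {
  ds <- make_small_dataset(matrix(1:6, 3, 2))
  expect_identical(nrow(build_lagged_design(ds, "listwise")$rows), 2L)

  gap <- make_small_dataset(matrix(1:8, 4, 2), days = c(1, 2, 4, 5))
  rows <- build_lagged_design(gap, "listwise")$rows
  expect_identical(rows$day, c(2L, 5L)) # the 2 -> 4 transition is invalid
  expect_equal(rows$x_V1, c(1, 3))

  # a missing day-2 cell drops both rows touching it: the 2 -> 3 row
  # (missing predictor) and the 1 -> 2 row (missing outcome); 3 -> 4 survives
  m <- matrix(as.numeric(1:8), 4, 2); m[2, 1] <- NA
  rows2 <- build_lagged_design(make_small_dataset(m), "listwise")$rows
  expect_identical(nrow(rows2), 1L)
  expect_identical(rows2$day, 4L)

  one_day <- make_small_dataset(matrix(1:2, 1, 2))
  expect_identical(nrow(build_lagged_design(one_day, "listwise")$rows), 0L)
})

test_that("every retained row audits as an exact one-day transition", {
  params <- default_gad_parameters()
  ds <- inject_missingness(
    simulate_esm_dataset(params, 10, 20, seed = 31), 0.1, seed = 32)
  design <- build_lagged_design(ds, "listwise")
  d <- ds$data
  for (r in seq_len(nrow(design$rows))) {
    row <- design$rows[r, ]
    prev <- d[d$person_id == row$person_id & d$day == row$day - 1L, ]
    expect_identical(nrow(prev), 1L)
    expect_equal(as.numeric(row[paste0("x_", params$variable_names)]),
                 as.numeric(prev[params$variable_names]))
  }
})

test_that("added missingness never increases retained listwise rows", {
  params <- default_gad_parameters()
  ds <- simulate_esm_dataset(params, 15, 25, seed = 41)
  n_prev <- nrow(build_lagged_design(ds, "listwise")$rows)
  for (rate in c(0.05, 0.15, 0.4)) {
    n_now <- nrow(build_lagged_design(
      inject_missingness(ds, rate, seed = 42), "listwise")$rows)
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("within-person centering is exact", {
  params <- default_gad_parameters()
  ds <- simulate_esm_dataset(params, 12, 20, seed = 51)
  design <- within_person_center(build_lagged_design(ds, "listwise"))
  xcols <- paste0("x_", params$variable_names)
  for (d in split(design$rows[xcols], design$rows$person_id))
    expect_true(all(abs(colMeans(d)) < 1e-10))
  # constant person centers to zero; level shifts cancel
  const <- make_small_dataset(matrix(4, 5, 2))
  cd <- within_person_center(build_lagged_design(const, "listwise"))
  expect_true(all(cd$rows[c("x_V1", "x_V2")] == 0))

  two <- rbind(
    data.frame(person_id = "A", day = 1:5, V1 = c(3, 4, 2, 3, 3) + 0,
               V2 = 3, attention_pass = TRUE),
    data.frame(person_id = "B", day = 1:5, V1 = c(3, 4, 2, 3, 3) + 2,
               V2 = 5, attention_pass = TRUE))
  d2 <- within_person_center(build_lagged_design(
    esm_dataset(two, c("V1", "V2"), discretized = FALSE), "listwise"))
  a <- d2$rows[d2$rows$person_id == "A", c("x_V1", "x_V2")]
  b <- d2$rows[d2$rows$person_id == "B", c("x_V1", "x_V2")]
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)))
})

test_that("KPSS statistic matches the direct-summation oracle", {
  set.seed(61)
  for (rep in 1:25) {
    T_ <- sample(20:300, 1)
    y <- cumsum(rnorm(T_)) * sample(c(0, 1), 1) + rnorm(T_)
    L <- sample(0:8, 1)
    r <- kpss_statistic(y, lag_truncation = L)
    expect_equal(r$statistic, kpss_oracle(y, L), tolerance = 1e-10)
    expect_gte(r$statistic, 0)
  }
  # default truncation rule
  y <- rnorm(150)
  expect_identical(kpss_statistic(y)$lag_truncation,
                   as.integer(floor(4 * (150 / 100)^0.25)))
})

test_that("KPSS degenerate and decision rules behave as specified", {
  expect_identical(kpss_statistic(rep(2, 50))$statistic, 0)
  expect_true(kpss_decision(kpss_statistic(rep(2, 50)), 0.05))
  # deterministic trend is flagged non-stationary at the 5% level
  trend <- kpss_statistic(as.numeric(1:200))
  expect_gt(trend$statistic, 0.463)
  expect_false(kpss_decision(trend, 0.05))
  # boundary statistic rejects; smaller levels use larger critical values
  expect_false(kpss_decision(list(statistic = 0.463), 0.05))
  expect_true(kpss_decision(list(statistic = 0.40), 0.01))
  expect_error(kpss_decision(list(statistic = 0.1), 0.07), "level")
  expect_error(kpss_statistic(rnorm(5)), "length")
  expect_error(kpss_statistic(c(rnorm(10), NA)), "observed")
})

test_that("KPSS size is close to nominal on i.i.d. noise", {
  set.seed(62)
  rej <- vapply(1:1000, function(i) {
    !kpss_decision(kpss_statistic(rnorm(200)), 0.05)
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("per-person stationarity report aggregates to variable passes", {
  params <- default_gad_parameters()
  ds <- simulate_esm_dataset(params, 25, 50, seed = 71)
  rep <- kpss_report(ds, level = 0.05)
  expect_setequal(unique(rep$series$variable), params$variable_names)
  expect_true(all(rep$series$statistic >= 0))
  expect_equal(rep$variables$prop_pass,
               with(rep$series,
                    tapply(stationary, variable, mean)[rep$variables$variable]),
               ignore_attr = TRUE)
  # stationary generator: the vast majority of person-series pass; the
  # 95% variable-level rule itself operates near the nominal test size,
  # so it is not asserted here
  expect_true(all(rep$variables$prop_pass > 0.8))
})

test_that("daily Cronbach's alpha matches hand arithmetic", {
  # all items identical within person, varying across persons -> alpha = 1
  d <- data.frame(person_id = paste0("P", 1:4), day = 1,
                  V1 = c(1, 3, 5, 7), V2 = c(1, 3, 5, 7), V3 = c(1, 3, 5, 7),
                  attention_pass = TRUE)
  ds <- esm_dataset(d, c("V1", "V2", "V3"))
  expect_equal(cronbach_alpha_daily(ds)$alpha, 1)

  # 3-item, 4-person toy table, expected value by explicit sums
  m <- rbind(c(1, 2, 3), c(2, 4, 5), c(3, 5, 6), c(4, 4, 4))
  item_var <- 0
  for (j in 1:3) {
    mu <- sum(m[, j]) / 4
    item_var <- item_var + sum((m[, j] - mu)^2) / 3
  }
  tot <- m[, 1] + m[, 2] + m[, 3]
  tot_var <- sum((tot - sum(tot) / 4)^2) / 3
  expected <- 3 / 2 * (1 - item_var / tot_var)
  d2 <- data.frame(person_id = paste0("P", 1:4), day = 1,
                   V1 = m[, 1], V2 = m[, 2], V3 = m[, 3],
                   attention_pass = TRUE)
  ds2 <- esm_dataset(d2, c("V1", "V2", "V3"))
  expect_equal(cronbach_alpha_daily(ds2)$alpha, expected, tolerance = 1e-12)

  # mutually independent items with equal variances -> alpha near 0
  set.seed(81)
  n <- 2000
  d3 <- data.frame(person_id = paste0("P", 1:n), day = 1,
                   V1 = rnorm(n), V2 = rnorm(n), V3 = rnorm(n),
                   attention_pass = TRUE)
  ds3 <- esm_dataset(d3, c("V1", "V2", "V3"), discretized = FALSE)
  expect_lt(abs(cronbach_alpha_daily(ds3)$alpha), 0.1)

  # days with < 2 complete responders are undefined
  d4 <- d2
  d4[2:4, c("V1", "V2")] <- NA
  ds4 <- esm_dataset(d4, c("V1", "V2", "V3"))
  expect_true(is.na(cronbach_alpha_daily(ds4)$alpha))
})
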