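test_that("one-hot cultivar encoding places a single 1 at the roster position", {
  expect_equal(unname(one_hot_cultivar("B", c("A", "B", "C"))), c(0L, 1L, 0L))
  roster <- default_roster()
  expect_length(roster, 45L)
  for (nm in roster[c(1, 17, 45)]) {
    v <- one_hot_cultivar(nm, roster)
    expect_equal(sum(v), 1L)
    expect_equal(which(v == 1L), match(nm, roster), ignore_attr = TRUE)
  }
  expect_error(one_hot_cultivar("Reisling", roster), "Riesling",
               class = "hardivine_validation_error")
})

test_that("days in season counts from 1 September", {
  expect_equal(days_in_season(as.Date("2021-09-01")), 0L)
  expect_equal(days_in_season(as.Date("2021-09-02")), 1L)
  expect_equal(days_in_season(as.Date("2022-01-01")), 122L)
  # date-difference oracle over random dormancy dates
  dates <- as.Date("2019-09-01") + sample(0:600, 40)
  yr <- as.integer(format(dates, "%Y")) - (as.integer(format(dates, "%m")) < 9)
  oracle <- as.integer(dates - as.Date(paste0(yr, "-09-01")))
  expect_equal(days_in_season(dates), oracle)
})

test_that("EWMA and REWMA match brute-force weight enumeration", {
  expect_equal(ewma(c(10, 20), 2), 17.5)
  expect_equal(rewma(c(10, 20), 2), 12.5)
  expect_equal(ewma(rep(3.7, 15), 6), 3.7)
  expect_equal(rewma(rep(3.7, 15), 6), 3.7)

  set.seed(31)
  x <- rnorm(40, mean = -5, sd = 6)
  for (n in seq(2, 20, by = 2)) {
    expect_equal(ewma(x, n), oracle_ewma(x, n), tolerance = 1e-12)
    win <- x[(length(x) - n + 1):length(x)]
    expect_equal(rewma(x, n), oracle_ewma(rev(win), n), tolerance = 1e-12)
    # convexity: within window range
    expect_gte(ewma(x, n), min(win))
    expect_lte(ewma(x, n), max(win))
  }
  # partial windows: truncated, renormalized weights
  expect_equal(ewma(x[1:3], 8), oracle_ewma(x[1:3], 8), tolerance = 1e-12)
})

test_that("EWMA ordering flips with trend direction and alpha limits hold", {
  inc <- seq(-10, 10, length.out = 12)
  expect_gt(ewma(inc, 10), rewma(inc, 10))
  expect_lt(ewma(rev(inc), 10), rewma(rev(inc), 10))
  expect_equal(ewma(rep(2, 12), 10), rewma(rep(2, 12), 10))
  # weight-limit behaviour at surrogate alpha values
  w_flat <- hardivine:::ewma_weights(8, alpha = 1e-12)
  expect_equal(w_flat, rep(1 / 8, 8), tolerance = 1e-9)
  w_spike <- hardivine:::ewma_weights(8, alpha = 1 - 1e-12)
  expect_equal(w_spike[8], 1, tolerance = 1e-9)
})

test_that("chilling models reproduce their published weight tables", {
  expect_equal(utah_chill(rep(5, 10)), 10)
  expect_equal(utah_chill(rep(-5, 10)), 0)
  expect_equal(utah_chill(rep(20, 5)), -5)
  expect_equal(utah_chill(rep(10, 4)), 2)    # 9.2-12.4 C band, weight 0.5

  expect_equal(nc_chill(rep(-8, 12)), 0)     # below lower threshold
  expect_equal(nc_chill(rep(5, 10)), 10)     # optimum band, peak weight 1
  expect_equal(nc_chill(rep(23, 4)), -8)     # above 22.1 C, weight -2
  expect_equal(nc_chill(rep(5, 10)), nc_chill(rep(5, 10)))

  expect_equal(chill_hours(rep(5, 10)), 10)
  expect_equal(chill_hours(rep(10, 10)), 0)
  expect_equal(chill_hours(c(rep(3, 5), rep(9, 5))), 5)
})

test_that("degree-hour accumulators follow their definitions and are additive", {
  expect_equal(gdh(rep(8, 24), base = 10), 0)
  expect_equal(gdh(rep(12, 10), base = 10), 20)
  expect_equal(freezing_degree_hours(c(-3, -1, 2)), 4)

  set.seed(77)
  temps <- rnorm(480, 5, 10)
  a <- temps[1:200]; b <- temps[201:480]
  for (f in list(utah_chill, nc_chill, chill_hours,
                 function(v) gdh(v, base = 10), freezing_degree_hours)) {
    expect_equal(f(temps), f(a) + f(b))
  }
  # GDH is non-decreasing as coverage advances
  partial <- vapply(seq(24, 480, by = 24), function(k) gdh(temps[1:k], base = 4),
                    numeric(1))
  expect_true(all(diff(partial) >= 0))
})

test_that("assembled feature vectors have the fixed 117-column layout", {
  wx <- one_season_weather(seed = 8)
  hourly <- interpolate_hourly(wx)
  cfg <- feature_config()
  fn <- feature_names(cfg)
  expect_length(fn, 117L)

  fv <- assemble_features(hourly, "Concord", as.Date("2016-02-01"), cfg)
  expect_length(fv, 117L)
  expect_identical(names(fv), fn)
  cult <- fv[startsWith(names(fv), "cultivar_")]
  expect_length(cult, 45L)
  expect_equal(sum(cult), 1)
  expect_length(fv[grepl("^r?ewma_", names(fv))], 60L)
  expect_true(all(is.finite(fv)))

  # determinism
  expect_identical(fv, assemble_features(hourly, "Concord",
                                         as.Date("2016-02-01"), cfg))

  # K x 117 matrix with stable column order
  samples <- data.frame(date = as.Date("2016-01-10") + c(0, 7, 14),
                        cultivar = c("Concord", "Riesling", "Marquette"))
  fm <- build_feature_matrix(hourly, samples, cfg)
  expect_equal(dim(fm), c(3L, 117L))
  expect_identical(colnames(fm), fn)
  expect_equal(unname(fm[1, ]), unname(assemble_features(
    hourly, "Concord", as.Date("2016-01-10"), cfg)))
})

test_that("feature assembly rejects samples outside season coverage", {
  wx <- one_season_weather(seed = 8)
  hourly <- interpolate_hourly(wx)
  expect_error(
    assemble_features(hourly, "Concord", max(wx$date) + 30),
    class = "hardivine_validation_error")
  # series starting after the season opening cannot serve that season
  late <- interpolate_hourly(wx[wx$date >= as.Date("2015-11-01"), ])
  expect_error(
    assemble_features(late, "Concord", as.Date("2016-01-15")),
    "coverage", class = "hardivine_validation_error")
})

test_that("cumulative features agree with direct accumulator calls", {
  wx <- one_season_weather(seed = 21)
  hourly <- interpolate_hourly(wx)
  date <- as.Date("2015-12-15")
  fv <- assemble_features(hourly, "Riesling", date)
  temps <- hourly$temp[hourly$date <= date]
  expect_equal(unname(fv["chill_utah"]), utah_chill(temps))
  expect_equal(unname(fv["chill_nc"]), nc_chill(temps))
  expect_equal(unname(fv["chill_hours"]), chill_hours(temps))
  expect_equal(unname(fv["gdh_base10"]), gdh(temps, base = 10))
  expect_equal(unname(fv["fdh"]), freezing_degree_hours(temps))
  expect_equal(unname(fv["days_in_season"]),
               as.numeric(days_in_season(date)))
  day_means <- tapply(hourly$temp[hourly$date <= date],
                      hourly$date[hourly$date <= date], mean)
  expect_equal(unname(fv["ewma_mean_12"]), ewma(as.numeric(day_means), 12))
  expect_equal(unname(fv["rewma_mean_12"]), rewma(as.numeric(day_means), 12))
})
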