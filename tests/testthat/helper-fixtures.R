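# Shared fixtures: tiny weather tables, fast learner menus, and cached
# mid-size objects reused across test files.

make_daily <- function(dates, tmin, tmax) {
  daily_weather(data.frame(date = as.Date(dates), tmin = tmin, tmax = tmax))
}

# A single synthetic season of daily weather (deterministic given seed).
one_season_weather <- function(seed = 42, mean_winter_min = -12) {
  wx <- simulate_weather(climate_spec(mean_winter_min = mean_winter_min),
                         n_seasons = 1, seed = seed)
  wx[wx$season == wx$season[1], , drop = FALSE]
}

# Fast learner menu for structural tests (no tree fitting).
fast_learners <- function() default_learners()[c("ridge", "knn")]

# Small labelled dataset with a known linear signal in named features.
linear_dataset <- function(n = 120, p = 5, beta = c(2, -1, 0.5, 0, 0),
                           noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- as.numeric(x %*% beta) + rnorm(n, 0, noise_sd)
    hardiness_dataset(x, y, data.frame(site = rep(c("a", "b"), length.out = n)))
  })
}

# Brute-force EWMA oracle: explicit weight enumeration, independent of the
# package implementation.
oracle_ewma <- function(x, n) {
  m <- min(n, length(x))
  win <- x[(length(x) - m + 1):length(x)]   # oldest .. newest
  a <- 2 / (n + 1)
  w <- vapply(seq_len(m), function(i) (1 - a)^(m - i), numeric(1))
  sum(w * win) / sum(w)
}

# Exact Shapley values by subset enumeration with the background-marginal
# value function (tractable for p <= 8).
oracle_shapley <- function(predict_fun, instance, background) {
  p <- length(instance)
  idx <- seq_len(p)
  v <- function(s) {
    z <- background
    for (j in s) z[, j] <- instance[j]
    mean(predict_fun(z))
  }
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(mask) idx[bitwAnd(mask, 2^(idx - 1)) > 0])
  for (j in idx) {
    for (s in subsets) {
      if (j %in% s) next
      k <- length(s)
      wgt <- factorial(k) * factorial(p - k - 1) / factorial(p)
      phi[j] <- phi[j] + wgt * (v(c(s, j)) - v(s))
    }
  }
  phi
}

# Cached small benchmark shared by model/importance tests.
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_benchmark(n_sites = 2, n_cultivars = 3, n_seasons = 1,
                               seed = 99)
    cache
  }
})
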