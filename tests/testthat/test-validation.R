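make_series <- function(gfp_mat, od = 1, lambda_gfp = 360, dt = 840) {
  n_t <- ncol(gfp_mat); n_p <- nrow(gfp_mat)
  out <- tibble::tibble(
    promoter = rep(sprintf("p%02d", seq_len(n_p)), each = n_t),
    t = rep(seq_len(n_t), n_p),
    time_s = rep((seq_len(n_t) - 1) * dt, n_p),
    od = rep(rep_len(od, n_t), n_p),
    gfp = as.vector(t(gfp_mat))
  )
  attr(out, "lambda_gfp") <- lambda_gfp
  attr(out, "dt") <- dt
  out
}

test_that("stationary activities rescale OD-normalized gains by 1 - f", {
  gfp <- matrix(seq(0, 50, by = 10), 1)  # constant increments of 10
  s <- make_series(rbind(gfp, gfp * 2, gfp * 3), od = 2, lambda_gfp = 360,
                   dt = 840)
  a <- stationary_activity(s)
  f <- reporter_carryover(360, 840)
  expect_equal(unique(round(a$activity[a$promoter == "p01"], 12)),
               round(10 / 840 / 2 * (1 - f), 12))
  # f = 0 limit: raw dGFP/dt/OD
  a0 <- stationary_activity(s, lambda_gfp = 1e-9)
  expect_equal(a0$activity[a0$promoter == "p01"], rep(10 / 840 / 2, 5))
  bad <- dplyr::mutate(s, od = 0)
  expect_error(stationary_activity(bad), "positive")
})

test_that("lag correction reduces to the raw rate for long lags and stays
           proportional to the stationary estimate at steady state", {
  gfp <- matrix(cumsum(c(0, rep(8, 9))), 1)
  s <- make_series(rbind(gfp, gfp * 2, gfp * 5), od = 1)
  stat <- stationary_activity(s)
  for (lg in c(1, 3, 6)) {
    nlag <- nonstationary_activity(s, lag = lg)
    j <- dplyr::inner_join(stat, nlag, by = c("promoter", "t"),
                           suffix = c("_s", "_n"))
    ratio <- j$activity_n / j$activity_s
    expect_lt(diff(range(ratio)), 1e-9)  # proportional at every defined t
  }
  # vanishing carryover: the raw OD-normalized rate remains
  nl <- nonstationary_activity(s, lag = 8, carryover = 0)
  expect_equal(unique(nl$activity[nl$promoter == "p01"]), 8 / 840)
  expect_error(nonstationary_activity(s, lag = 0), "at least 1")
  expect_error(nonstationary_activity(s, lag = 40), "no defined")
})

test_that("lag-1 correction agrees with a fine-grained two-compartment ODE", {
  # oracle: Euler integration of dm/dt = a(t) - k m, dGFP/dt = c * m at a
  # step 100x finer than the readings, constant OD
  dt <- 840; lambda <- 360; k <- log(2) / lambda; n_t <- 20
  a_fun <- function(t) 0.05 * (1 + 0.5 * sin(2 * pi * t / (n_t * dt)))
  fine <- dt / 100
  tgrid <- seq(0, (n_t - 1) * dt, by = fine)
  m <- numeric(length(tgrid)); gfp <- numeric(length(tgrid))
  m[1] <- a_fun(0) / k
  for (i in seq_along(tgrid)[-1]) {
    m[i] <- m[i - 1] + fine * (a_fun(tgrid[i - 1]) - k * m[i - 1])
    gfp[i] <- gfp[i - 1] + fine * m[i - 1]
  }
  idx <- seq(1, length(tgrid), by = 100)
  s <- make_series(matrix(gfp[idx], 1), od = 1, lambda_gfp = lambda, dt = dt)
  est <- nonstationary_activity(s, lag = 1)
  # the discrete estimator reports a_t * dt-integrated initiation per pool
  # turnover; compare shapes against the true activity at the readings
  truth <- a_fun(tgrid[idx][est$t - 1])
  scaled <- est$activity * (k / (1 - exp(-k * dt)))
  expect_lt(max(abs(scaled / truth - 1)), 0.05)
})

test_that("stationarity robustness is perfect at steady state and needs
           enough promoters", {
  gfp <- outer(c(1, 2, 7, 3, 5), seq(0, 11))  # exactly steady increments
  s <- make_series(gfp)
  rep_ <- stationarity_robustness(s, max_lag = 4)
  expect_true(all(rep_$rho > 1 - 1e-9))
  expect_error(stationarity_robustness(make_series(gfp[1:2, ])), "3 promoters")
})

test_that("rank agreement decays with the correction lag on drifting data", {
  meds <- purrr::map_dfr(1:3, function(sd) {
    rs <- generate_reporter_series(150, seed = 40 + sd, noise_cv = 0.05)
    stationarity_robustness(rs, max_lag = 10) |>
      dplyr::summarise(med = median(rho), .by = lag) |>
      dplyr::mutate(seed = sd)
  })
  wide <- tidyr::pivot_wider(meds, names_from = lag, values_from = med)
  expect_true(all(wide$`1` >= wide$`10`))
  expect_true(all(wide$`1` > 0.98))
})

test_that("clearance fitting recovers speeds, flags boundaries and ignores
           abundance scale", {
  cohort <- make_operon_cohort(n_operons = 4, seed = 51)
  fit <- clearance_lag_fit(cohort$series)
  m <- dplyr::inner_join(fit$fits, cohort$operon_speeds, by = "operon")
  expect_true(all(abs(m$best_speed - m$true_speed) <= 1))
  expect_false(any(m$at_boundary))
  # abundance scale invariance (log-shift)
  scaled <- dplyr::mutate(cohort$series, abundance = abundance * 537)
  expect_equal(clearance_lag_fit(scaled)$fits$best_speed, fit$fits$best_speed)
  # a true speed below the grid floors at the minimum with the flag set
  g <- generate_genome(3, operon_size_dist = 3, length_dist = 2000, seed = 52)
  tr <- generate_truth(g, seed = 53)
  tr$true_speed <- 0.5
  dec <- generate_decay_series(g, tr, timepoints = seq(0, 4000, 200))
  slow <- clearance_lag_fit(dec)
  expect_true(slow$fits$at_boundary)
  expect_lte(slow$fits$best_speed, 2)
  # operons below the gene minimum are skipped with a warning
  expect_warning(
    expect_error(clearance_lag_fit(dplyr::filter(dec, gene == "g0001")),
                 "no operon"),
    "fewer than")
})

test_that("the grid scorer matches the brute-force profile under noise", {
  cohort <- make_operon_cohort(n_operons = 1, seed = 61, noise_cv = 0.1,
                               timepoints = seq(0, 420, by = 60))
  fit <- clearance_lag_fit(cohort$series, grid = 1:90)
  brute <- brute_clearance_profile(cohort$series, 1:90)
  expect_equal(fit$profiles$r2, brute, tolerance = 1e-10)
  expect_equal(fit$fits$best_speed, (1:90)[which.max(brute)])
})

test_that("noisy clearance fits land near the truth across seeds", {
  # 8 samplings spread over the range of clearance lags the speed range
  # implies (roughly 25 s to 25 min)
  tp <- c(0, 120, 240, 420, 660, 960, 1320, 1740)
  err <- vapply(1:50, function(s) {
    cohort <- make_operon_cohort(n_operons = 1, genes_per_operon = 3,
                                 seed = 600 + s, noise_cv = 0.1,
                                 timepoints = tp)
    fit <- clearance_lag_fit(cohort$series)
    abs(fit$fits$best_speed - cohort$operon_speeds$true_speed)
  }, numeric(1))
  expect_lte(median(err), 5)
})

test_that("zero-intercept fits match theory and a grid-search oracle", {
  x <- c(1, 5, 9, 14, 22)
  ident <- zero_intercept_fit(x, x)
  expect_equal(ident$slope, 1)
  expect_lt(ident$se, 1e-12)
  expect_equal(zero_intercept_fit(x, 2 * x)$slope, 2)
  set.seed(7)
  xr <- runif(40, 1, 60); yr <- 0.9 * xr + rnorm(40, 0, 4)
  fit <- zero_intercept_fit(xr, yr)
  expect_equal(fit$slope, brute_zero_intercept_slope(xr, yr),
               tolerance = 1e-4)
  expect_equal(fit$slope, sum(xr * yr) / sum(xr^2))
  expect_lt(fit$conf_low, fit$slope)
  expect_error(zero_intercept_fit(1:2, 1:2), "3 finite")
  expect_error(zero_intercept_fit(rep(0, 5), 1:5), "all zero")
})
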