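#' Carryover fraction of reporter mRNA between readings
#'
#' The share of an unstable reporter mRNA still present one reading
#' interval later: \eqn{f = 0.5^{dt/\lambda_{gfp}}}.  With the 6-min
#' half-life of the gfp reporter mRNA and 14-min readings, about 20% of
#' each step's fluorescence gain is inherited from the previous step.
#'
#' @param lambda_gfp reporter-mRNA half-life in seconds.
#' @param dt reading interval in seconds.
#' @return The carryover fraction in \[0, 1\].
#' @examples
#' reporter_carryover(360, 840)  # ~0.198
#' @export
reporter_carryover <- function(lambda_gfp, dt) {
  if (lambda_gfp <= 0) abort("`lambda_gfp` must be positive.")
  carryover_fraction(lambda_gfp, dt)
}

#' Promoter activities under the stationarity assumption
#'
#' Activity at each reading is the OD-normalized fluorescence gain with
#' the inherited share removed: \eqn{a_t = (\Delta GFP_t / dt / OD_t)(1-f)}
#' with \eqn{f = 0.5^{dt/\lambda_{gfp}}}.
#'
#' @param series a `reporter_series` tibble (see
#'   [generate_reporter_series()]) or any tibble with `promoter`, `t`,
#'   `od`, `gfp` columns.
#' @param lambda_gfp reporter-mRNA half-life in seconds; defaults to the
#'   series attribute.
#' @param dt reading interval in seconds; defaults to the series attribute.
#' @return Tibble `promoter`, `t`, `activity`; the first reading has no
#'   increment and is dropped.
#' @export
stationary_activity <- function(series, lambda_gfp = NULL, dt = NULL) {
  lambda_gfp <- lambda_gfp %||% attr(series, "lambda_gfp")
  dt <- dt %||% attr(series, "dt")
  if (is.null(lambda_gfp) || is.null(dt)) {
    abort("`lambda_gfp` and `dt` must be given or carried by the series.")
  }
  if (any(series$od <= 0)) abort("optical density must be positive.")
  f <- carryover_fraction(lambda_gfp, dt)
  series |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$promoter) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(activity = (.data$gfp - dplyr::lag(.data$gfp)) / dt /
                    .data$od * (1 - f)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$activity)) |>
    dplyr::select("promoter", "t", "activity")
}

#' Promoter activities with an explicit non-stationarity correction
#'
#' Instead of assuming the mRNA pool is at steady state, the inherited
#' share of each fluorescence gain is subtracted explicitly:
#' \eqn{a_t \propto (\Delta GFP_t - f\, \Delta GFP_{t-lag}) / dt / OD_t}
#' with the one-step carryover \eqn{f = 0.5^{dt/\lambda_{gfp}}}.  At
#' lag 1 this inverts the reporter recurrence exactly.  Larger lags keep
#' the same carryover fraction but take it from an increasingly stale
#' increment, emulating a sparser time series with larger fluctuations
#' between consecutive readings.
#'
#' @inheritParams stationary_activity
#' @param lag correction lag in readings (>= 1, default 1).
#' @param carryover the fraction of the lagged increment subtracted;
#'   defaults to the one-step carryover `0.5^(dt/lambda_gfp)`.
#' @return Tibble `promoter`, `t`, `activity`; the first `lag + 1`
#'   readings are undefined and dropped.
#' @export
nonstationary_activity <- function(series, lag = 1, lambda_gfp = NULL,
                                   dt = NULL, carryover = NULL) {
  lambda_gfp <- lambda_gfp %||% attr(series, "lambda_gfp")
  dt <- dt %||% attr(series, "dt")
  if (is.null(lambda_gfp) || is.null(dt)) {
    abort("`lambda_gfp` and `dt` must be given or carried by the series.")
  }
  if (lag < 1) abort("`lag` must be at least 1 reading.")
  n_t <- length(unique(series$t))
  if (lag >= n_t - 1) abort("`lag` leaves no defined readings in the series.")
  if (any(series$od <= 0)) abort("optical density must be positive.")
  f_lag <- carryover %||% carryover_fraction(lambda_gfp, dt)
  series |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$promoter) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(
      .inc = .data$gfp - dplyr::lag(.data$gfp),
      activity = (.data$.inc - f_lag * dplyr::lag(.data$.inc, lag)) / dt /
        .data$od
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$activity)) |>
    dplyr::select("promoter", "t", "activity")
}

#' Rank agreement between stationary and lag-corrected activities
#'
#' For each correction lag and each reading, the Spearman correlation
#' across promoters between the stationarity-assuming activities and the
#' explicitly lag-corrected ones.  High correlations mean the stationarity
#' assumption distorts at most the scale, not the ranking, of promoter
#' activities.
#'
#' @inheritParams stationary_activity
#' @param max_lag largest correction lag in readings (default 10).
#' @return A `stationarity_report` tibble: `lag`, `t`, `rho`.  Has an
#'   [autoplot()] method.
#' @export
stationarity_robustness <- function(series, max_lag = 10, lambda_gfp = NULL,
                                    dt = NULL) {
  if (length(unique(series$promoter)) < 3) {
    abort("need at least 3 promoters to correlate across promoters.")
  }
  stat <- stationary_activity(series, lambda_gfp, dt)
  out <- purrr::map_dfr(seq_len(max_lag), function(lg) {
    nonstat <- nonstationary_activity(series, lg, lambda_gfp, dt)
    dplyr::inner_join(stat, nonstat, by = c("promoter", "t"),
                      suffix = c("_stat", "_lag")) |>
      dplyr::summarise(
        rho = cor(.data$activity_stat, .data$activity_lag,
                  method = "spearman"),
        .by = "t") |>
      dplyr::mutate(lag = lg, .before = 1)
  })
  class(out) <- c("stationarity_report", class(out))
  out
}

#' Fit clearance lags over a speed grid
#'
#' After transcription initiation stops, each gene's log-abundance is flat
#' until the clearance lag (promoter-to-3'-end distance / speed) and then
#' falls linearly.  For each candidate speed the lag is imposed per gene
#' and a plateau-then-line model (intercept plus slope on
#' \eqn{\max(0, t - \mathrm{lag})}) is fitted to the full series; the
#' operon's speed is the grid value maximizing the mean R-squared across
#' its genes (ties broken toward the smaller speed).  Candidates leaving a
#' gene with fewer than 2 post-lag points are excluded.  Only operons with
#' at least 3 genes are fitted — shorter operons constrain the lag too
#' weakly.
#'
#' @param series a `decay_series` tibble (`gene`, `operon`, `distance`,
#'   `time_s`, `abundance`), e.g. from [generate_decay_series()].
#' @param grid candidate speeds in nt/s (default `1:90`).
#' @param min_genes minimum genes per fitted operon (default 3).
#' @return A `clearance_fit` object: list with `fits` (tibble `operon`,
#'   `best_speed`, `best_r2`, `at_boundary`), `profiles` (tibble `operon`,
#'   `speed`, `r2`) and `delays` (per-gene clearance lag at the best
#'   speed).  Has [tidy()] and [autoplot()] methods.
#' @export
clearance_lag_fit <- function(series, grid = 1:90, min_genes = 3) {
  grid <- sort(grid)
  genes <- dplyr::distinct(series, .data$gene, .data$operon, .data$distance)
  sizes <- dplyr::count(genes, .data$operon)
  small <- sizes$operon[sizes$n < min_genes]
  if (length(small) > 0) {
    warn(paste0(length(small), " operon(s) with fewer than ", min_genes,
                " genes skipped: ", paste(head(small, 5), collapse = ", ")))
  }
  keep <- setdiff(sizes$operon, small)
  if (length(keep) == 0) abort("no operon has enough genes for a clearance fit.")

  npts <- dplyr::count(series, .data$gene)
  if (any(npts$n < 4)) abort("every gene needs at least 4 timepoints.")

  profiles <- purrr::map_dfr(keep, function(op) {
    sub <- dplyr::filter(series, .data$operon == op, .data$abundance > 0)
    per_gene <- split(sub[, c("time_s", "abundance", "distance")], sub$gene)
    r2 <- vapply(grid, function(v) {
      scores <- vapply(per_gene, function(g) {
        delayed_line_r2(g$time_s, log(g$abundance), g$distance[1] / v)
      }, numeric(1))
      if (any(!is.finite(scores))) -Inf else mean(scores)
    }, numeric(1))
    tibble::tibble(operon = op, speed = grid, r2 = r2)
  })
  fits <- profiles |>
    dplyr::summarise(
      best_speed = .data$speed[which.max(.data$r2)],
      best_r2 = max(.data$r2),
      # at the edge of the feasible candidate range: the truth may lie
      # outside the grid or outside what the time window can resolve
      at_boundary = {
        feasible <- .data$speed[is.finite(.data$r2)]
        .data$speed[which.max(.data$r2)] %in% range(feasible)
      },
      .by = "operon")
  delays <- genes |>
    dplyr::filter(.data$operon %in% keep) |>
    dplyr::left_join(fits[, c("operon", "best_speed")], by = "operon") |>
    dplyr::mutate(delay = .data$distance / .data$best_speed) |>
    dplyr::select("gene", "operon", "distance", "delay")
  structure(list(fits = fits, profiles = profiles, delays = delays),
            class = "clearance_fit")
}

# R^2 of a plateau-then-line fit: intercept plus slope on max(0, t - lag).
# A single regressor, so R^2 is the squared Pearson correlation with the
# regressor. Requires >= 2 points beyond the lag to pin the slope; -Inf
# otherwise.
delayed_line_r2 <- function(time_s, log_abund, lag) {
  x <- pmax(0, time_s - lag)
  if (sum(time_s > lag) < 2) return(-Inf)
  if (var(log_abund) == 0) return(1)  # flat series: the flat model is exact
  if (var(x) == 0) return(0)
  cor(x, log_abund)^2
}

#' @export
print.clearance_fit <- function(x, ...) {
  cat("Clearance-lag fit over", length(unique(x$profiles$speed)),
      "candidate speeds\n")
  print(x$fits)
  invisible(x)
}

#' @export
tidy.clearance_fit <- function(x, ...) x$fits

#' Zero-intercept agreement fit between two speed sets
#'
#' Least-squares line through the origin, \eqn{y = s x}: slope
#' \eqn{s = \sum x y / \sum x^2}, with a 95% confidence interval from the
#' no-intercept regression standard error on n - 1 degrees of freedom.
#' When two independent routes to the same speeds agree, the CI encloses
#' slope 1.
#'
#' @param x,y paired speeds in nt/s (at least 3 finite pairs; `x` not all
#'   zero).
#' @param level confidence level (default 0.95).
#' @return A `zero_intercept_fit` object with [tidy()] and [glance()]
#'   methods; fields `slope`, `se`, `conf_low`, `conf_high`, `n`.
#' @export
zero_intercept_fit <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 finite pairs.")
  if (all(x == 0)) abort("`x` is all zero; the slope is undefined.")
  fit <- lm(y ~ 0 + x)
  s <- unname(coef(fit))
  se <- sqrt(sum(fit$residuals^2) / (length(x) - 1) / sum(x^2))
  tq <- qt(1 - (1 - level) / 2, df = length(x) - 1)
  structure(list(slope = s, se = se, conf_low = s - tq * se,
                 conf_high = s + tq * se, n = length(x), level = level),
            class = "zero_intercept_fit")
}

#' @export
print.zero_intercept_fit <- function(x, ...) {
  cat(sprintf("Zero-intercept fit: slope = %.3f (%d%% CI %.3f - %.3f, n = %d)\n",
              x$slope, round(100 * x$level), x$conf_low, x$conf_high, x$n))
  invisible(x)
}

#' @export
tidy.zero_intercept_fit <- function(x, ...) {
  tibble::tibble(term = "slope", estimate = x$slope, std.error = x$se,
                 conf.low = x$conf_low, conf.high = x$conf_high)
}

#' @export
glance.zero_intercept_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, conf.low = x$conf_low,
                 conf.high = x$conf_high, n = x$n, level = x$level)
}
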