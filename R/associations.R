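#' Spearman rank correlation between two per-gene variables
#'
#' Rank correlation with mean-of-tied-ranks handling and a two-sided
#' p-value (asymptotic; ties allowed), via [stats::cor.test()].  Pairs
#' with a missing value on either side are dropped.
#'
#' @param data data frame holding both variables per gene.
#' @param x,y column names (tidy-eval) of the two variables.
#' @return One-row tibble: `feature` (name of `x`), `rho`, `p`, `n`.
#'   `rho` is `NA` when either side has zero rank variance.
#' @export
spearman_assoc <- function(data, x, y) {
  xq <- rlang::ensym(x); yq <- rlang::ensym(y)
  xv <- data[[rlang::as_string(xq)]]
  yv <- data[[rlang::as_string(yq)]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("need at least 3 paired finite values.")
  if (length(unique(xv)) < 2 || length(unique(yv)) < 2) {
    return(tibble::tibble(feature = rlang::as_string(xq), rho = NA_real_,
                          p = NA_real_, n = length(xv)))
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = "spearman", exact = FALSE))
  tibble::tibble(feature = rlang::as_string(xq),
                 rho = unname(ct$estimate), p = ct$p.value, n = length(xv))
}

#' Run the Spearman battery over many features
#'
#' Correlates each feature column against the response, then adjusts the
#' p-values for multiple testing (Benjamini-Hochberg) and flags
#' significance at adjusted p <= 0.05.
#'
#' @param data data frame with the response and feature columns.
#' @param features character vector of feature column names.
#' @param response response column name (default `"v"`, the scaled speed).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return Tibble `feature`, `rho`, `p`, `p_adj`, `n`, `significant`,
#'   sorted by `p`.
#' @export
association_battery <- function(data, features, response = "v",
                                alpha = 0.05) {
  out <- purrr::map_dfr(features, function(f) {
    spearman_assoc(data, !!rlang::sym(f), !!rlang::sym(response))
  })
  out$p_adj <- bh_adjust(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  dplyr::arrange(out, .data$p)
}

#' Two-group comparison with the Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test via
#' [stats::wilcox.test()], reported together with the group means — the
#' location summary used when contrasting gene classes (e.g. essential
#' vs. non-essential speeds).
#'
#' @param values_a,values_b numeric vectors (each non-empty, at least 3
#'   values combined).
#' @return One-row tibble: `mean_a`, `mean_b`, `n_a`, `n_b`, `statistic`
#'   (the U statistic for the first group), `p`.
#' @export
group_test <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both groups must contain at least one finite value.")
  }
  if (length(values_a) + length(values_b) < 3) {
    abort("need at least 3 values across both groups.")
  }
  wt <- suppressWarnings(wilcox.test(values_a, values_b,
                                     alternative = "two.sided"))
  tibble::tibble(mean_a = mean(values_a), mean_b = mean(values_b),
                 n_a = length(values_a), n_b = length(values_b),
                 statistic = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1) via
#' [stats::p.adjust()]; `NA` p-values are passed through.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Predict regulation order from calculated delays
#'
#' Observed regulation-interval labels and calculated operon delays share
#' an order but not a scale, so prediction assigns labels by rank while
#' preserving the observed class sizes: the operons with the shortest
#' delays fill the earliest interval, and so on.  The confusion matrix of
#' observed vs. predicted labels then has row and column sums equal to
#' the observed class sizes by construction.
#'
#' @param data data frame with one row per operon.
#' @param delay column (tidy-eval) of calculated delays in seconds.
#' @param observed column (tidy-eval) of observed interval labels.
#' @param levels interval labels in temporal order; defaults to the
#'   levels of `observed` when it is an ordered factor (required
#'   otherwise).
#' @return A `regulation_order` object: list with `result` (tibble
#'   `operon` columns plus `predicted`), `confusion` (observed x
#'   predicted matrix) and `n_correct`.  Has a [tidy()] method.
#' @export
delay_order_prediction <- function(data, delay, observed, levels = NULL) {
  dv <- data[[rlang::as_string(rlang::ensym(delay))]]
  ov <- data[[rlang::as_string(rlang::ensym(observed))]]
  if (is.null(levels)) {
    if (is.ordered(ov)) levels <- base::levels(ov)
    else abort("`levels` must give the interval labels in temporal order.")
  }
  if (!all(ov %in% levels)) {
    abort("observed labels outside the configured interval set.")
  }
  if (nrow(data) < 2) abort("need at least 2 operons.")
  sizes <- table(factor(ov, levels = levels))
  ord <- order(dv)  # ties keep input order (stable)
  predicted <- character(nrow(data))
  predicted[ord] <- rep(levels, times = as.integer(sizes))
  confusion <- table(
    observed = factor(ov, levels = levels),
    predicted = factor(predicted, levels = levels)
  )
  res <- tibble::as_tibble(data)
  res$predicted <- predicted
  structure(list(result = res, confusion = confusion,
                 n_correct = sum(diag(confusion))),
            class = "regulation_order")
}

#' @export
print.regulation_order <- function(x, ...) {
  cat("Regulation-order prediction:", x$n_correct, "of",
      sum(x$confusion), "operons in the observed interval\n")
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.regulation_order <- function(x, ...) x$result
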