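RF_FEATURES <- c("cai", "tai", "gc1", "gc3", "length", "n_r_z", "d_p",
                 "mrna_rnap_ratio")

#' Assemble the feature matrix for random-forest speed estimation
#'
#' Inner-joins the speed table, codon features and external per-gene
#' features (CAI, tAI) on gene id and derives the predictor set used for
#' half-life-free speed estimation: CAI, tAI, first- and third-position
#' GC content, gene length, z-scored mRNA level, RNAP density and the
#' mRNA/RNAP ratio.  Rows with any missing value are dropped and counted.
#'
#' @param speed_table filtered speed table (`gene`, `n_r`, `d_p`, `v`);
#'   only `passes_filter` rows are used if the column is present.
#' @param codon_features tibble from [codon_features()] (`gene`, `gc1`,
#'   `gc3`, `length`).
#' @param external_features tibble with `gene`, `cai`, `tai` columns.
#' @return Tibble `gene`, the eight predictors, and `v` (the target).
#' @export
build_features <- function(speed_table, codon_features, external_features) {
  tb <- speed_table
  if ("passes_filter" %in% names(tb)) tb <- dplyr::filter(tb, .data$passes_filter)
  joined <- tb |>
    dplyr::select("gene", "n_r", "d_p", "v") |>
    dplyr::inner_join(dplyr::select(codon_features, "gene", "gc1", "gc3",
                                    "length"),
                      by = "gene") |>
    dplyr::inner_join(dplyr::select(external_features, "gene", "cai", "tai"),
                      by = "gene")
  if (nrow(joined) == 0) abort("joining the feature sources left no genes.")
  out <- joined |>
    dplyr::mutate(
      n_r_z = as.vector(scale(.data$n_r)),
      mrna_rnap_ratio = .data$n_r / .data$d_p
    ) |>
    dplyr::select("gene", dplyr::all_of(RF_FEATURES), "v")
  complete <- complete.cases(out)
  if (any(!complete)) {
    message(sum(!complete), " gene(s) dropped for missing feature values.")
  }
  out[complete, ]
}

#' Cross-validated random-forest speed estimation
#'
#' Trains a regression random forest ([randomForest::randomForest()] with
#' its default parameters) on the feature matrix and evaluates it by
#' k-fold cross-validation.  Folds are assigned by a seeded shuffle
#' stratified on speed quartiles so every fold spans the speed range.
#' Reported are the mean over folds of the out-of-fold R-squared, the
#' pooled root relative squared error
#' \eqn{RRSE = \sqrt{\sum(y-\hat y)^2 / \sum(y-\bar y)^2}} (1 means "no
#' better than predicting the mean") and the forest's internal variable
#' importance averaged over folds.
#'
#' @param features tibble from [build_features()].
#' @param k number of folds (default 5); needs at least `5 * k` rows.
#' @param seed integer seed for the fold shuffle and forests.
#' @return An `rf_speed_cv` object: list with `metrics` (one-row tibble
#'   `r2_mean`, `rrse`, `k`, `n`), `importance` (tibble `feature`,
#'   `importance`, sorted), `folds` (per-fold R-squared) and
#'   `predictions` (out-of-fold `gene`, `v`, `v_pred`).  Has [tidy()]
#'   and [glance()] methods.
#' @export
cv_train <- function(features, k = 5, seed = NULL) {
  n <- nrow(features)
  if (n < 5 * k) abort(paste0("need at least ", 5 * k, " rows for ", k,
                              "-fold cross-validation."))
  x <- as.data.frame(features[, RF_FEATURES])
  y <- features$v
  with_seed(seed, {
    fold <- stratified_folds(y, k)
    oof <- numeric(n)
    r2_fold <- numeric(k)
    imp <- matrix(0, length(RF_FEATURES), k,
                  dimnames = list(RF_FEATURES, NULL))
    for (f in seq_len(k)) {
      test <- fold == f
      rf <- randomForest::randomForest(x[!test, , drop = FALSE], y[!test])
      oof[test] <- predict(rf, x[test, , drop = FALSE])
      r2_fold[f] <- 1 - sum((y[test] - oof[test])^2) /
        sum((y[test] - mean(y[test]))^2)
      imp[, f] <- rf$importance[RF_FEATURES, 1]
    }
    rrse <- sqrt(sum((y - oof)^2) / sum((y - mean(y))^2))
    structure(list(
      metrics = tibble::tibble(r2_mean = mean(r2_fold), rrse = rrse,
                               k = k, n = n),
      importance = tibble::tibble(feature = RF_FEATURES,
                                  importance = rowMeans(imp)) |>
        dplyr::arrange(dplyr::desc(.data$importance)),
      folds = tibble::tibble(fold = seq_len(k), r2 = r2_fold),
      predictions = tibble::tibble(gene = features$gene, v = y, v_pred = oof)
    ), class = "rf_speed_cv")
  })
}

# Quartile-stratified fold assignment: shuffle within speed strata and
# deal folds round-robin so each fold covers the whole speed range.
stratified_folds <- function(y, k) {
  breaks <- unique(quantile(y, 0:4 / 4))
  strata <- if (length(breaks) > 2) {
    cut(y, breaks, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, length(y))
  fold <- integer(length(y))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' @export
print.rf_speed_cv <- function(x, ...) {
  cat(sprintf("Random-forest speed estimation, %d-fold CV on %d genes\n",
              x$metrics$k, x$metrics$n))
  cat(sprintf("  mean out-of-fold R2: %.3f   pooled RRSE: %.3f\n",
              x$metrics$r2_mean, x$metrics$rrse))
  invisible(x)
}

#' @export
glance.rf_speed_cv <- function(x, ...) x$metrics

#' @export
tidy.rf_speed_cv <- function(x, ...) x$importance
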