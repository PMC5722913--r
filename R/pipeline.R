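#' Run the full speed-inference pipeline
#'
#' Composes the stages end to end: normalize the expression and RNAP
#' probe tracks, aggregate them to genes, join the half-lives, compute
#' per-gene promoter activities and speeds, optionally rescale to the
#' reference gene, apply the analysis filter, attach operon regulation
#' delays, and (optionally) run the molecule census.  Every stage logs
#' its row counts via [message()] so gene tallies are auditable.
#'
#' @param config a named list (see [default_config()] for the knobs), or
#'   a path to a YAML file with the same structure.  Inputs (`annotation`,
#'   `expression_track`, `rnap_track`, `half_lives`) may be file paths or
#'   in-memory tibbles; a tibble of half-lives must already be in seconds.
#' @return List with `speed_table` (filtered, delayed), `measurements`
#'   and, when a census anchor is configured, `census`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_config(), config)

  annotation <- load_input(cfg$annotation, read_gene_annotation)
  expr <- load_input(cfg$expression_track, read_probe_track)
  rnap <- load_input(cfg$rnap_track, read_probe_track)
  half <- load_input(cfg$half_lives, read_half_lives)

  log_n <- function(stage, n) message(sprintf("[%s] %d rows", stage, n))
  log_n("annotation", nrow(annotation))

  # expression: quantile-normalize replicates, average, optional constant
  # offset (mean of off-target probes), strand max
  if (length(unique(expr$replicate)) > 1) expr <- quantile_normalize(expr)
  expr <- average_replicates(expr, cfg$replicates)
  if (cfg$expression_offset > 0) {
    expr$intensity <- pmax(0, expr$intensity - cfg$expression_offset)
  }
  expr <- strand_max(expr)
  log_n("expression probes", nrow(expr))

  # RNAP: median-scale each array, quantile-normalize, average,
  # running-quantile background subtraction
  if (isTRUE(cfg$rnap_scale_median)) rnap <- scale_median(rnap, 1)
  if (length(unique(rnap$replicate)) > 1) rnap <- quantile_normalize(rnap)
  rnap <- average_replicates(rnap, cfg$replicates)
  rnap <- running_quantile_background(rnap, cfg$window, cfg$quantile)
  log_n("rnap probes", nrow(rnap))

  expr_genes <- aggregate_probes_to_genes(expr, annotation, cfg$aggregate)
  rnap_genes <- aggregate_probes_to_genes(rnap, annotation, cfg$aggregate)

  measurements <- annotation |>
    dplyr::select("gene", "length",
                  dplyr::any_of(c("operon", "operon_pos"))) |>
    dplyr::inner_join(dplyr::rename(expr_genes[, c("gene", "value")],
                                    n_r = "value"), by = "gene") |>
    dplyr::inner_join(dplyr::rename(rnap_genes[, c("gene", "value")],
                                    d_p = "value"), by = "gene") |>
    dplyr::inner_join(half, by = "gene")
  dropped <- nrow(annotation) - nrow(measurements)
  if (dropped > 0) {
    message(sprintf("[join] %d gene(s) absent from some input dropped", dropped))
  }
  log_n("measurements", nrow(measurements))

  speeds <- transcription_speed(measurements, cfg$footprint)
  if (!is.null(cfg$reference_gene)) {
    speeds <- scale_speeds(speeds, cfg$reference_gene, cfg$reference_speed)
  }
  speeds <- filter_genes(speeds, cfg$min_rnap_signal)
  message(sprintf("[filter] %d of %d genes pass", sum(speeds$passes_filter),
                  nrow(speeds)))
  if (all(c("operon", "operon_pos") %in% names(speeds))) {
    speeds <- regulation_delay(speeds)
  }

  out <- list(speed_table = speeds, measurements = measurements)
  if (!is.null(cfg$census_total_rnap) || !is.null(cfg$census_total_mrna)) {
    out$census <- molecule_census(speeds,
                                  total_rnap = cfg$census_total_rnap,
                                  total_mrna = cfg$census_total_mrna,
                                  footprint = cfg$footprint)
  }
  out
}

#' Default pipeline configuration
#'
#' @return Named list of the tunable parameters with their defaults:
#'   RNAP footprint 40 nt, reference speed 49.5 nt/s, background window
#'   30 kb at the 10% quantile, mean probe aggregation, RNAP-signal
#'   filter floor 0.5, no census anchor, no replicate whitelist, no
#'   constant expression offset.
#' @export
default_config <- function() {
  list(
    footprint = 40,
    reference_gene = NULL,
    reference_speed = 49.5,
    window = 30000,
    quantile = 0.10,
    aggregate = "mean",
    rnap_scale_median = TRUE,
    min_rnap_signal = 0.5,
    replicates = NULL,
    expression_offset = 0,
    census_total_rnap = NULL,
    census_total_mrna = NULL
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return Named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configs requires the yaml package.")
  }
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  yaml::read_yaml(path)
}

load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(paste0("input file not found: ", x))
    return(reader(x))
  }
  if (is.data.frame(x)) {
    tb <- tibble::as_tibble(x)
    if (identical(reader, read_gene_annotation) && !"length" %in% names(tb)) {
      tb$length <- tb$end - tb$start + 1
    }
    return(tb)
  }
  abort("inputs must be file paths or data frames.")
}
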