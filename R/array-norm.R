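#' Quantile-normalize replicate probe tracks
#'
#' Forces every replicate track onto the identical intensity distribution
#' (the per-rank mean across replicates), removing array-wide intensity
#' differences while preserving within-track rank order.  Ties take the
#' mean of the tied ranks.  The computation is delegated to
#' [limma::normalizeQuantiles()].
#'
#' @param track probe tibble with columns `coordinate`, `strand`,
#'   `replicate`, `intensity`; every replicate must cover the identical
#'   (coordinate, strand) grid.
#' @return The track with normalized intensities.
#' @examples
#' tr <- tibble::tibble(coordinate = rep(1:3, 2), strand = "+",
#'                      replicate = rep(1:2, each = 3),
#'                      intensity = c(1, 2, 3, 4, 5, 6))
#' quantile_normalize(tr)$intensity  # both replicates become 2.5 3.5 4.5
#' @export
quantile_normalize <- function(track) {
  reps <- sort(unique(track$replicate))
  if (length(reps) < 2) abort("need at least 2 replicate tracks to quantile-normalize.")
  wide <- track |>
    dplyr::arrange(.data$replicate, .data$strand, .data$coordinate)
  counts <- table(wide$replicate)
  if (length(unique(counts)) != 1) {
    abort("replicate tracks differ in length; identical probe grids required.")
  }
  grids <- split(paste(wide$coordinate, wide$strand), wide$replicate)
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    abort("replicate tracks cover different (coordinate, strand) grids.")
  }
  mat <- matrix(wide$intensity, ncol = length(reps))
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  wide$intensity <- as.vector(norm)
  dplyr::arrange(wide, .data$strand, .data$coordinate, .data$replicate)
}

#' Average replicate tracks at each probe coordinate
#'
#' @param track probe tibble with a `replicate` column.
#' @param replicates optional whitelist of replicate ids to keep (e.g. to
#'   drop an array that differs systematically from the others).
#' @return Probe tibble with one mean intensity per (coordinate, strand),
#'   `replicate` set to 1.
#' @export
average_replicates <- function(track, replicates = NULL) {
  if (!is.null(replicates)) {
    track <- dplyr::filter(track, .data$replicate %in% replicates)
    if (nrow(track) == 0) abort("replicate whitelist removed every probe.")
  }
  track |>
    dplyr::summarise(intensity = mean(.data$intensity),
                     .by = c("coordinate", "strand")) |>
    dplyr::mutate(replicate = 1L) |>
    dplyr::arrange(.data$strand, .data$coordinate)
}

#' Per-coordinate maximum over strands
#'
#' Transcriptome tiling arrays read both strands; the expressed strand is
#' taken as the larger of the two intensities at each coordinate.
#'
#' @param track probe tibble containing strands `+` and `-` on matched
#'   coordinates (single replicate).
#' @return Probe tibble with `strand = "both"` and the element-wise
#'   maximum intensity.
#' @export
strand_max <- function(track) {
  fwd <- dplyr::arrange(dplyr::filter(track, .data$strand == "+"), .data$coordinate)
  rev <- dplyr::arrange(dplyr::filter(track, .data$strand == "-"), .data$coordinate)
  if (!identical(fwd$coordinate, rev$coordinate)) {
    abort("forward and reverse strand tracks cover different coordinates.")
  }
  tibble::tibble(
    coordinate = fwd$coordinate,
    strand = "both",
    replicate = fwd$replicate %||% 1L,
    intensity = pmax(fwd$intensity, rev$intensity)
  )
}

#' Scale a track to a target median
#'
#' @param track probe tibble; scaling is applied per replicate (each array
#'   is one measurement whose global level is arbitrary).
#' @param target target median intensity (default 1).
#' @return The rescaled track.
#' @export
scale_median <- function(track, target = 1) {
  scaled <- track |>
    dplyr::mutate(.med = median(.data$intensity), .by = "replicate")
  if (any(scaled$.med <= 0)) {
    abort("track median must be positive to scale to a target median.")
  }
  scaled |>
    dplyr::mutate(intensity = .data$intensity / .data$.med * target) |>
    dplyr::select(-".med")
}

#' Subtract a running-quantile background
#'
#' Estimates a slowly varying background as the q-quantile of probe
#' intensities in a centered window (in nt, truncated at the track edges)
#' and subtracts it, flooring results at zero.  A wide window (default
#' 30 kb) avoids eroding long transcription units while still tracking
#' regional drift.
#'
#' @param track probe tibble (applied per strand and replicate).
#' @param window window width in nt (default 30000).
#' @param q background quantile (default 0.10).
#' @return The background-corrected track.
#' @export
running_quantile_background <- function(track, window = 30000, q = 0.10) {
  if (window <= 0) abort("`window` must be positive (nt).")
  if (q <= 0 || q >= 1) abort("`q` must be strictly between 0 and 1.")
  track |>
    dplyr::group_by(.data$strand, .data$replicate) |>
    dplyr::arrange(.data$coordinate, .by_group = TRUE) |>
    dplyr::mutate(intensity = subtract_running_quantile(
      .data$coordinate, .data$intensity, window, q)) |>
    dplyr::ungroup()
}

subtract_running_quantile <- function(coord, x, window, q) {
  if (length(x) == 0) return(x)
  half <- window / 2
  lo <- findInterval(coord - half, coord, left.open = TRUE) + 1
  hi <- findInterval(coord + half, coord)
  bg <- vapply(seq_along(x), function(i) {
    if (hi[i] < lo[i]) return(0)  # empty window: pass through
    quantile(x[lo[i]:hi[i]], q, names = FALSE)
  }, numeric(1))
  pmax(0, x - bg)
}

#' Aggregate probe intensities to per-gene signals
#'
#' One value per gene: the mean (or median) of probe intensities whose
#' coordinate falls inside the gene body.  Genes covered by no probe are
#' omitted with a warning.  Stranded tracks contribute only probes on the
#' gene's strand; `strand = "both"` tracks contribute everywhere.
#'
#' @param track probe tibble (single replicate; average first).
#' @param genome annotation tibble with `gene`, `start`, `end`, `strand`.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return Tibble `gene`, `value`, `n_probes`.
#' @export
aggregate_probes_to_genes <- function(track, genome,
                                      statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  agg <- if (statistic == "mean") mean else median
  stranded <- !any(track$strand == "both")
  out <- purrr::pmap_dfr(
    genome[, c("gene", "start", "end", "strand")],
    function(gene, start, end, strand) {
      probes <- track$intensity[
        track$coordinate >= start & track$coordinate <= end &
          (!stranded | track$strand == strand)]
      tibble::tibble(gene = gene, value = agg(probes),
                     n_probes = length(probes))
    })
  dropped <- out$gene[out$n_probes == 0]
  if (length(dropped) > 0) {
    warn(paste0(length(dropped), " gene(s) covered by no probe were omitted: ",
                paste(head(dropped, 5), collapse = ", ")))
  }
  dplyr::filter(out, .data$n_probes > 0)
}
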