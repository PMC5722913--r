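#' Promoter activity from mRNA level and half-life
#'
#' Under the steady-state assumption the mRNA synthesised per second equals
#' the mRNA decayed per second.  The fraction of the pool surviving one
#' second is \eqn{0.5^{1/\lambda}}, so the activity (initiations/s,
#' cumulative over all promoters feeding the gene) is
#' \eqn{a = n_r (1 - 0.5^{1/\lambda})}.
#'
#' @param n_r mRNA level (arbitrary units, >= 0). Vectorized.
#' @param half_life mRNA half-life in seconds (> 0). Recycled against `n_r`.
#' @return Promoter activity in 1/s, same length as `n_r`.
#' @examples
#' promoter_activity(1, 1)    # half the pool decays per second -> 0.5
#' promoter_activity(10, 300)
#' @export
promoter_activity <- function(n_r, half_life) {
  if (any(!is.finite(half_life) | half_life <= 0)) {
    abort("`half_life` must be positive and finite (seconds).")
  }
  n_r * (1 - 0.5^(1 / half_life))
}

#' RNA polymerase count from occupancy density
#'
#' Converts an occupancy density (fraction of the gene physically coverable
#' by elongating polymerases) into a molecule count via the polymerase
#' footprint: \eqn{n_p = (l / \mathrm{footprint}) d_p}.
#'
#' @param length gene length in nt (> 0). Vectorized.
#' @param d_p RNAP density (dimensionless fraction, or arbitrary units
#'   before census scaling).
#' @param footprint elongating RNAP footprint in nt (default 40).
#' @return RNAP molecule count per gene.
#' @examples
#' rnap_count(400, 0.1)  # 1 polymerase
#' @export
rnap_count <- function(length, d_p, footprint = 40) {
  if (any(!is.finite(length) | length <= 0)) {
    abort("`length` must be positive (nt).")
  }
  (length / footprint) * d_p
}

#' Per-gene transcription speed from steady-state measurements
#'
#' The central model step.  For each gene the promoter activity
#' \eqn{a = n_r(1 - 0.5^{1/\lambda})} and the polymerase count
#' \eqn{n_p = (l/40) d_p} combine into the elongation rate
#' \eqn{v = a \cdot 40 / d_p} (equivalently \eqn{a\, l / n_p}) in nt/s.
#' Genes with \eqn{d_p = 0} get `NA` speed (undefined, not zero) and are
#' excluded by [filter_genes()] downstream.
#'
#' @param measurements data frame with columns `gene`, `n_r` (mRNA level),
#'   `d_p` (RNAP density), `half_life` (s) and `length` (nt).
#' @param footprint RNAP footprint in nt (default 40). Speeds scale
#'   linearly in it.
#' @return A tibble (the speed table) with the input columns plus
#'   `activity` (1/s), `n_p` (molecules, input units), `v_raw` (nt/s before
#'   reference scaling) and `v` (nt/s, equal to `v_raw` until
#'   [scale_speeds()] is applied).
#' @examples
#' m <- tibble::tibble(gene = "g1", n_r = 1, d_p = 1, half_life = 1, length = 1000)
#' transcription_speed(m)$v  # 0.5 * 40 = 20 nt/s
#' @export
transcription_speed <- function(measurements, footprint = 40) {
  req <- c("gene", "n_r", "d_p", "half_life", "length")
  miss <- setdiff(req, names(measurements))
  if (length(miss) > 0) {
    abort(paste0("`measurements` is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(measurements$d_p < 0, na.rm = TRUE)) {
    abort("negative RNAP density after correction; check background subtraction.")
  }
  measurements |>
    tibble::as_tibble() |>
    dplyr::mutate(
      activity = promoter_activity(.data$n_r, .data$half_life),
      n_p = rnap_count(.data$length, .data$d_p, footprint),
      v_raw = dplyr::if_else(.data$d_p > 0,
                             .data$activity * footprint / .data$d_p,
                             NA_real_),
      v = .data$v_raw
    )
}

#' Rescale speeds to a reference gene
#'
#' Array intensities carry an unknown linear scale, so raw speeds are only
#' defined up to a factor.  The factor is fixed by forcing a reference gene
#' (for the growth condition the model was built for: *infB* at
#' 49.5 nt/s, interpolated from published elongation measurements at
#' 60 min/doubling) to its externally known speed.  Ranks are unchanged.
#'
#' @param speed_table output of [transcription_speed()].
#' @param reference_gene gene id present in `speed_table` with `v_raw > 0`.
#' @param reference_speed known speed of the reference gene in nt/s
#'   (default 49.5).
#' @return The speed table with `v` multiplied by
#'   `reference_speed / v_raw[reference_gene]`; the factor is stored in
#'   `attr(, "scale_factor")`.
#' @export
scale_speeds <- function(speed_table, reference_gene, reference_speed = 49.5) {
  i <- which(speed_table$gene == reference_gene)
  if (length(i) != 1) {
    abort(paste0("reference gene '", reference_gene,
                 "' not found exactly once in the speed table."))
  }
  v_ref <- speed_table$v_raw[i]
  if (!is.finite(v_ref) || v_ref <= 0) {
    abort(paste0("reference gene '", reference_gene,
                 "' has no positive raw speed; cannot fix the scale."))
  }
  factor <- reference_speed / v_ref
  out <- dplyr::mutate(speed_table, v = .data$v_raw * factor)
  attr(out, "scale_factor") <- factor
  out
}

#' Flag genes passing the analysis filter
#'
#' Keeps genes with a defined non-zero speed and a background-corrected,
#' unscaled RNAP signal strictly above a floor (default 0.5), below which
#' the density is dominated by measurement error.
#'
#' @param speed_table a speed table; the unscaled corrected RNAP signal is
#'   its `d_p` column.
#' @param min_rnap_signal strict lower bound on the unscaled RNAP signal
#'   (default 0.5).
#' @return The speed table with a logical `passes_filter` column.
#' @export
filter_genes <- function(speed_table, min_rnap_signal = 0.5) {
  dplyr::mutate(
    speed_table,
    passes_filter = !is.na(.data$v) & .data$v > 0 & .data$d_p > min_rnap_signal
  )
}

#' Regulation delays along operons
#'
#' The delay between initiation at the operon promoter and the existence of
#' a complete transcript of gene k is the summed traversal time of all
#' operon genes up to and including it:
#' \eqn{\mathrm{delay}_k = \sum_{i=1}^{k} l_i / v_i}.  Operon order comes
#' from the annotation (`operon`, `operon_pos` columns), never from row
#' order.  A gene with undefined or zero speed makes its own delay and all
#' downstream delays in the operon `NA`.
#'
#' @param speed_table a speed table with `v` and `length` columns.
#' @param genome annotation data frame with `gene`, `operon`, `operon_pos`
#'   columns (e.g. from [generate_genome()]). If `NULL`, the speed table
#'   must carry these columns itself.
#' @return The speed table with a `delay` column in seconds.
#' @examples
#' tb <- tibble::tibble(gene = c("a", "b"), length = c(1000, 2000),
#'                      v = c(10, 20), operon = "op1", operon_pos = 1:2)
#' regulation_delay(tb)$delay  # 100, 200
#' @export
regulation_delay <- function(speed_table, genome = NULL) {
  tb <- speed_table
  if (!is.null(genome)) {
    tb <- dplyr::left_join(
      dplyr::select(tb, -dplyr::any_of(c("operon", "operon_pos"))),
      dplyr::select(genome, "gene", "operon", "operon_pos"),
      by = "gene"
    )
  }
  if (!all(c("operon", "operon_pos") %in% names(tb))) {
    abort("operon structure required: supply `genome` or `operon`/`operon_pos` columns.")
  }
  tb |>
    dplyr::group_by(.data$operon) |>
    dplyr::arrange(.data$operon_pos, .by_group = TRUE) |>
    dplyr::mutate(
      delay = cumsum(.data$length / dplyr::if_else(
        is.na(.data$v) | .data$v <= 0, NA_real_, .data$v))
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$gene, speed_table$gene))
}

#' Absolute molecule census from one per-cell anchor
#'
#' Array units are arbitrary, but once speeds are reference-scaled a single
#' per-cell total pins down both absolute scales.  Anchoring on a total
#' number of transcribing RNAP fixes the density unit
#' (\eqn{\sum n_p = } `total_rnap`); the absolute mRNA count then follows
#' per gene from the speed model,
#' \eqn{n_r = v\, d_p / (40 (1 - 0.5^{1/\lambda}))}, and vice versa for an
#' mRNA anchor.  Exactly one anchor must be given.
#'
#' @param speed_table a filtered, reference-scaled speed table; only rows
#'   with `passes_filter` (if present) and finite `v` enter the census.
#' @param total_rnap total transcribing RNAP molecules per cell
#'   (default 1300; set `NULL` to anchor on mRNA instead).
#' @param total_mrna total mRNA molecules per cell (alternative anchor).
#' @param footprint RNAP footprint in nt (default 40).
#' @return An object of class `molecule_census`: list with `genes` (tibble
#'   of per-gene absolute `n_p_abs`, `n_r_abs` and `d_p_percent`),
#'   `total_rnap`, `total_mrna` and `anchor`. Has [glance()] and [tidy()]
#'   methods.
#' @export
molecule_census <- function(speed_table, total_rnap = 1300, total_mrna = NULL,
                            footprint = 40) {
  if (is.null(total_rnap) == is.null(total_mrna)) {
    abort("give exactly one anchor: `total_rnap` or `total_mrna`.")
  }
  tb <- speed_table
  if ("passes_filter" %in% names(tb)) tb <- dplyr::filter(tb, .data$passes_filter)
  tb <- dplyr::filter(tb, is.finite(.data$v), .data$v > 0)
  if (nrow(tb) == 0) abort("no genes available for the census after filtering.")

  turnover <- 1 - 0.5^(1 / tb$half_life)
  np_arb <- (tb$length / footprint) * tb$d_p
  if (!is.null(total_rnap)) {
    beta <- total_rnap / sum(np_arb)
    d_p_abs <- beta * tb$d_p
    n_p_abs <- (tb$length / footprint) * d_p_abs
    n_r_abs <- tb$v * d_p_abs / (footprint * turnover)
  } else {
    gamma <- total_mrna / sum(tb$n_r)
    n_r_abs <- gamma * tb$n_r
    d_p_abs <- n_r_abs * turnover * footprint / tb$v
    n_p_abs <- (tb$length / footprint) * d_p_abs
  }
  structure(
    list(
      genes = tibble::tibble(
        gene = tb$gene,
        n_p_abs = n_p_abs,
        n_r_abs = n_r_abs,
        d_p_percent = 100 * d_p_abs
      ),
      total_rnap = sum(n_p_abs),
      total_mrna = sum(n_r_abs),
      anchor = if (is.null(total_rnap)) "mrna" else "rnap"
    ),
    class = "molecule_census"
  )
}

#' @export
print.molecule_census <- function(x, ...) {
  cat("Molecule census (anchored on total", x$anchor, "per cell)\n")
  cat(sprintf("  genes: %d\n", nrow(x$genes)))
  cat(sprintf("  total transcribing RNAP: %.0f\n", x$total_rnap))
  cat(sprintf("  total mRNA molecules:    %.0f\n", x$total_mrna))
  invisible(x)
}

#' @export
glance.molecule_census <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    total_rnap = x$total_rnap,
    total_mrna = x$total_mrna,
    anchor = x$anchor
  )
}

#' @export
tidy.molecule_census <- function(x, ...) x$genes

#' Genes whose mRNA pool is dominated by nascent transcripts
#'
#' High RNAP density combined with a low absolute mRNA copy number means
#' most measured mRNA is still being synthesised.  Both thresholds are
#' strict and presuppose census scaling ([molecule_census()]): density as a
#' percentage of full coverage, copy number in molecules per cell.
#'
#' @param census_genes the `genes` tibble of a [molecule_census()] result
#'   (columns `gene`, `d_p_percent`, `n_r_abs`).
#' @param d_p_min strict lower bound on RNAP density in percent
#'   (default 1.8).
#' @param n_r_max strict upper bound on mRNA copies per cell
#'   (default 0.97).
#' @return Tibble of qualifying genes.
#' @export
nascent_share_genes <- function(census_genes, d_p_min = 1.8, n_r_max = 0.97) {
  if (inherits(census_genes, "molecule_census")) census_genes <- census_genes$genes
  if (!all(c("d_p_percent", "n_r_abs") %in% names(census_genes))) {
    abort("census-scaled input required: run `molecule_census()` first.")
  }
  dplyr::filter(census_genes,
                .data$d_p_percent > d_p_min, .data$n_r_abs < n_r_max)
}
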