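#' Generate steady-state observables consistent with the speed model
#'
#' Inverts the speed model: from each gene's true activity, speed and
#' half-life it derives the mRNA level \eqn{n_r = a / (1 - 0.5^{1/\lambda})}
#' and the RNAP density \eqn{d_p = a \cdot \mathrm{footprint} / v}, then
#' applies independent multiplicative log-normal noise (unit mean, given
#' CV) to both.  With `noise_cv = 0`, feeding the measurements to
#' [transcription_speed()] returns the true speeds to machine precision.
#' Probe-level tracks tile the genome at a fixed spacing, carrying the
#' gene value inside genes and a background (plus optional smooth drift)
#' outside, so the normalization stage can be exercised.
#'
#' @param genome annotation tibble from [generate_genome()].
#' @param truth truth tibble from [generate_truth()]; must cover every gene.
#' @param noise_cv coefficient of variation of the multiplicative noise on
#'   `n_r` and `d_p` (default 0).
#' @param probe_spacing probe spacing in nt (default 25, typical tiling
#'   density).
#' @param footprint RNAP footprint in nt (default 40).
#' @param background off-gene probe intensity (default 0.05).
#' @param drift_amplitude amplitude of a smooth low-frequency background
#'   drift added to the RNAP track (default 0; exercise
#'   [running_quantile_background()] with values > 0).
#' @param n_replicates replicate tracks to emit (default 2).
#' @param probe_noise_cv extra per-probe multiplicative noise CV
#'   (default 0).
#' @param seed integer seed.
#' @return List with `measurements` (tibble `gene`, `n_r`, `d_p`,
#'   `half_life`, `length`), `expression_track` and `rnap_track` (probe
#'   tibbles `coordinate`, `strand`, `replicate`, `intensity`).
#' @export
generate_observables <- function(genome, truth, noise_cv = 0,
                                 probe_spacing = 25, footprint = 40,
                                 background = 0.05, drift_amplitude = 0,
                                 n_replicates = 2, probe_noise_cv = 0,
                                 seed = NULL) {
  missing_genes <- setdiff(genome$gene, truth$gene)
  if (length(missing_genes) > 0) {
    abort(paste0("truth table is missing gene(s): ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  tb <- dplyr::left_join(genome, truth, by = "gene")
  with_seed(seed, {
    n <- nrow(tb)
    turnover <- 1 - 0.5^(1 / tb$true_half_life)
    n_r_true <- tb$true_activity / turnover
    d_p_true <- tb$true_activity * footprint / tb$true_speed
    measurements <- tibble::tibble(
      gene = tb$gene,
      n_r = n_r_true * lnorm_noise(n, noise_cv),
      d_p = d_p_true * lnorm_noise(n, noise_cv),
      half_life = tb$true_half_life,
      length = tb$length
    )
    glen <- attr(genome, "genome_length") %||% max(genome$end)
    expression_track <- probe_tiling(
      genome, measurements$n_r, glen, probe_spacing, background,
      drift_amplitude = 0, stranded = TRUE,
      n_replicates = n_replicates, probe_noise_cv = probe_noise_cv
    )
    rnap_track <- probe_tiling(
      genome, measurements$d_p, glen, probe_spacing, background,
      drift_amplitude = drift_amplitude, stranded = FALSE,
      n_replicates = n_replicates, probe_noise_cv = probe_noise_cv
    )
    list(measurements = measurements,
         expression_track = expression_track,
         rnap_track = rnap_track)
  })
}

# Tile the genome with probes carrying per-gene values. Stranded tracks get
# the gene value on the gene's strand and background on the other; the
# unstranded (ChIP-like) track reports both strands identically.
probe_tiling <- function(genome, gene_values, genome_length, spacing,
                         background, drift_amplitude, stranded,
                         n_replicates, probe_noise_cv) {
  coords <- seq(1L, as.integer(genome_length), by = as.integer(spacing))
  idx <- genome_interval_index(genome, coords)
  base_plus <- ifelse(!is.na(idx) & (!stranded | genome$strand[pmax(idx, 1L)] == "+"),
                      gene_values[pmax(idx, 1L)], background)
  base_minus <- ifelse(!is.na(idx) & (!stranded | genome$strand[pmax(idx, 1L)] == "-"),
                       gene_values[pmax(idx, 1L)], background)
  if (drift_amplitude > 0) {
    drift <- drift_amplitude *
      (0.6 + 0.25 * sin(2 * pi * coords / genome_length) +
         0.15 * sin(2 * pi * coords / (genome_length / 3) + 1))
    base_plus <- base_plus + drift
    base_minus <- base_minus + drift
  }
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    tibble::tibble(
      coordinate = rep(coords, 2),
      strand = rep(c("+", "-"), each = length(coords)),
      replicate = r,
      intensity = c(base_plus, base_minus) *
        lnorm_noise(2 * length(coords), probe_noise_cv)
    )
  })
}

# For each coordinate, the row index of the covering gene (NA if none).
# Genes do not overlap, so a sorted interval lookup suffices.
genome_interval_index <- function(genome, coords) {
  ord <- order(genome$start)
  starts <- genome$start[ord]
  ends <- genome$end[ord]
  j <- findInterval(coords, starts)
  hit <- j >= 1 & coords <= ends[pmax(j, 1L)]
  out <- rep(NA_integer_, length(coords))
  out[hit] <- ord[j[hit]]
  out
}

#' Generate promoter-reporter GFP time series
#'
#' Emulates a plate-reader experiment in which each promoter drives a
#' stable GFP through an unstable reporter mRNA: fluorescence and optical
#' density are read every `dt` seconds for `n_timepoints` readings.  The
#' reporter-mRNA pool at step t is \eqn{m_t = a_t + f\, m_{t-1}} with
#' carryover \eqn{f = 0.5^{dt/\lambda_{gfp}}}, and the GFP gain over the
#' step is \eqn{OD_t\, m_{t-1}\, dt}, so part of each step's fluorescence
#' gain is inherited from earlier activity — the non-stationarity the
#' activity estimators must cope with.
#'
#' @param n_promoters number of promoters.
#' @param activity_profiles `NULL` for the built-in smooth-drift sampler,
#'   a matrix (`n_promoters` x `n_timepoints - 1`) of activities in 1/s,
#'   or a function `(n_promoters, n_steps) -> matrix`.
#' @param lambda_gfp reporter-mRNA half-life in seconds (default 360).
#' @param n_timepoints number of readings (default 54).
#' @param dt reading interval in seconds (default 840, i.e. 14 min).
#' @param noise_cv multiplicative noise CV on each GFP increment.
#' @param od0 initial optical density (default 0.05).
#' @param od_growth exponential OD growth rate 1/s (default
#'   `log(2)/3600`, a 60-min doubling, saturating logistically at
#'   `od_max`); 0 keeps OD constant.
#' @param od_max OD carrying capacity (default 1.5).
#' @param seed integer seed.
#' @return A `reporter_series` tibble: `promoter`, `t` (1-based reading
#'   index), `time_s`, `od`, `gfp` (cumulative intensity).  The true
#'   activity matrix, `lambda_gfp` and `dt` are kept as attributes.
#' @export
generate_reporter_series <- function(n_promoters, activity_profiles = NULL,
                                     lambda_gfp = 360, n_timepoints = 54,
                                     dt = 840, noise_cv = 0, od0 = 0.05,
                                     od_growth = log(2) / 3600, od_max = 1.5,
                                     seed = NULL) {
  if (!is.finite(lambda_gfp) || lambda_gfp <= 0) {
    abort("`lambda_gfp` must be a positive half-life in seconds.")
  }
  if (n_timepoints < 2) abort("need at least 2 timepoints.")
  n_steps <- n_timepoints - 1
  with_seed(seed, {
    act <- resolve_activities(activity_profiles, n_promoters, n_steps)
    f <- carryover_fraction(lambda_gfp, dt)
    times <- (seq_len(n_timepoints) - 1) * dt
    od <- if (od_growth == 0) rep(od0, n_timepoints) else {
      od_max / (1 + ((od_max - od0) / od0) * exp(-od_growth * times))
    }
    # reporter-mRNA recurrence, then cumulative GFP per promoter; the pool
    # starts at the steady state of the initial activity (the culture was
    # already growing before the first reading)
    m <- matrix(0, n_promoters, n_steps)
    m[, 1] <- act[, 1] / (1 - f)
    for (j in seq_len(n_steps)[-1]) m[, j] <- act[, j] + f * m[, j - 1]
    inc <- sweep(m, 2, od[-1] * dt, `*`) *
      matrix(lnorm_noise(n_promoters * n_steps, noise_cv), n_promoters)
    gfp <- cbind(0, t(apply(inc, 1, cumsum)))
    out <- tibble::tibble(
      promoter = rep(sprintf("p%04d", seq_len(n_promoters)),
                     each = n_timepoints),
      t = rep(seq_len(n_timepoints), n_promoters),
      time_s = rep(times, n_promoters),
      od = rep(od, n_promoters),
      gfp = as.vector(t(gfp))
    )
    attr(out, "lambda_gfp") <- lambda_gfp
    attr(out, "dt") <- dt
    attr(out, "activity") <- act
    class(out) <- c("reporter_series", class(out))
    out
  })
}

# Default activity profiles: per-promoter log-normal baseline modulated by
# a slow sinusoid with random phase — smooth drift, no jumps.
resolve_activities <- function(spec, n_promoters, n_steps) {
  if (is.matrix(spec)) {
    if (!all(dim(spec) == c(n_promoters, n_steps))) {
      abort("activity matrix must be n_promoters x (n_timepoints - 1).")
    }
    return(spec)
  }
  if (is.function(spec)) return(spec(n_promoters, n_steps))
  if (!is.null(spec)) abort("`activity_profiles` must be NULL, a matrix or a function.")
  base <- rlnorm(n_promoters, log(0.05), 1)
  phase <- runif(n_promoters, 0, 2 * pi)
  amp <- runif(n_promoters, 0.2, 0.6)
  steps <- seq_len(n_steps) / n_steps
  base * exp(outer(seq_len(n_promoters), steps, function(i, s) {
    amp[i] * sin(2 * pi * s + phase[i])
  }))
}

#' Generate post-initiation-stop mRNA decay series
#'
#' After transcription initiation stops, a gene's mRNA level stays flat
#' until the last polymerase that initiated before the stop clears the
#' gene — the clearance lag, equal to the distance from the operon
#' promoter to the gene's 3' end divided by the elongation speed — and
#' then decays exponentially with the gene's half-life.  On a log scale
#' each series is a plateau followed by a straight line.
#'
#' @param genome annotation tibble from [generate_genome()].
#' @param truth truth tibble from [generate_truth()].
#' @param timepoints sampling times in seconds after the initiation stop;
#'   strictly increasing, at least 4 (a delayed line cannot be fitted on
#'   fewer).
#' @param noise_cv multiplicative noise CV on abundances.
#' @param seed integer seed.
#' @return A `decay_series` tibble: `gene`, `operon`, `distance` (nt from
#'   operon promoter to gene 3' end), `time_s`, `abundance`.
#' @export
generate_decay_series <- function(genome, truth,
                                  timepoints = seq(0, 480, by = 30),
                                  noise_cv = 0, seed = NULL) {
  if (length(timepoints) < 4) {
    abort("need at least 4 timepoints to resolve a delayed decay line.")
  }
  if (any(diff(timepoints) <= 0)) abort("`timepoints` must be strictly increasing.")
  tb <- dplyr::left_join(genome, truth, by = "gene")
  tb <- tb |>
    dplyr::group_by(.data$operon) |>
    dplyr::mutate(distance = dplyr::if_else(
      .data$strand == "+",
      .data$end - min(.data$start) + 1,
      max(.data$end) - .data$start + 1
    )) |>
    dplyr::ungroup()
  with_seed(seed, {
    nt <- length(timepoints)
    delay <- tb$distance / tb$true_speed
    a0 <- tb$true_activity / (1 - 0.5^(1 / tb$true_half_life))
    out <- tibble::tibble(
      gene = rep(tb$gene, each = nt),
      operon = rep(tb$operon, each = nt),
      distance = rep(tb$distance, each = nt),
      time_s = rep(timepoints, nrow(tb)),
      abundance = rep(a0, each = nt) *
        0.5^(pmax(0, rep(timepoints, nrow(tb)) - rep(delay, each = nt)) /
               rep(tb$true_half_life, each = nt)) *
        lnorm_noise(nrow(tb) * nt, noise_cv)
    )
    class(out) <- c("decay_series", class(out))
    out
  })
}
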