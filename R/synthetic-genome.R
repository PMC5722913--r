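#' Generate a synthetic operon-structured genome
#'
#' Lays out genes on a linear genome as non-overlapping operons, each with a
#' random strand, so that downstream stages (probe aggregation, operon
#' delays, clearance fitting) can be exercised against known structure.
#' Defaults emulate a bacterial annotation: most operons are single genes
#' and gene lengths span roughly 200-6000 nt on a log scale.
#'
#' @param n_genes number of genes (>= 1).
#' @param operon_size_dist operon size sampler: a single integer for a
#'   constant size, or a function `n -> integer vector` of candidate sizes.
#'   Default samples sizes 1-6 with probabilities 0.55, 0.20, 0.12, 0.07,
#'   0.04, 0.02 (monocistronic majority, mean ~1.9).
#' @param length_dist gene length sampler: a single number for constant
#'   length, or a function `n -> numeric vector` in nt. Default is
#'   log-uniform on \[200, 6000\] nt.
#' @param seed integer seed; the same seed reproduces the genome exactly.
#' @param intergenic gap between genes within an operon, nt (default 40).
#' @param operon_gap gap between operons, nt (default 150).
#' @return A tibble with columns `gene`, `start`, `end`, `strand`,
#'   `length`, `operon`, `operon_pos` (1 = first transcribed gene;
#'   coordinates are 1-based inclusive) and attribute `genome_length`.
#'   Within a minus-strand operon, `operon_pos` increases right to left.
#' @examples
#' g <- generate_genome(9, operon_size_dist = 3, length_dist = 1000, seed = 1)
#' table(g$operon)
#' @export
generate_genome <- function(n_genes, operon_size_dist = NULL,
                            length_dist = NULL, seed = NULL,
                            intergenic = 40, operon_gap = 150) {
  if (length(n_genes) != 1 || !is.finite(n_genes) || n_genes < 1) {
    abort("`n_genes` must be a single positive integer.")
  }
  n_genes <- as.integer(n_genes)
  size_fun <- make_sampler(operon_size_dist, default = function(n) {
    sample(1:6, n, replace = TRUE,
           prob = c(0.55, 0.20, 0.12, 0.07, 0.04, 0.02))
  })
  len_fun <- make_sampler(length_dist, default = function(n) {
    round(exp(runif(n, log(200), log(6000))))
  })

  with_seed(seed, {
    sizes <- integer(0)
    while (sum(sizes) < n_genes) sizes <- c(sizes, as.integer(size_fun(n_genes)))
    # trim the operon list to exactly n_genes
    cum <- cumsum(sizes)
    k <- which(cum >= n_genes)[1]
    sizes <- sizes[seq_len(k)]
    sizes[k] <- sizes[k] - (cum[k] - n_genes)
    sizes <- sizes[sizes > 0]

    lengths <- pmax(30, round(len_fun(n_genes)))
    strands <- sample(c("+", "-"), length(sizes), replace = TRUE)

    rows <- vector("list", length(sizes))
    cursor <- operon_gap + 1
    gi <- 0
    for (o in seq_along(sizes)) {
      k_o <- sizes[o]
      ls <- lengths[gi + seq_len(k_o)]
      starts <- cursor + cumsum(c(0, head(ls, -1) + intergenic))
      ends <- starts + ls - 1
      pos <- if (strands[o] == "+") seq_len(k_o) else rev(seq_len(k_o))
      rows[[o]] <- tibble::tibble(
        gene = sprintf("g%04d", gi + seq_len(k_o)),
        start = starts, end = ends, strand = strands[o], length = ls,
        operon = sprintf("op%03d", o), operon_pos = pos
      )
      cursor <- max(ends) + operon_gap + 1
      gi <- gi + k_o
    }
    genome <- dplyr::bind_rows(rows)
    attr(genome, "genome_length") <- cursor + operon_gap
    genome
  })
}

# Turn a constant or a function into a sampler function.
make_sampler <- function(spec, default) {
  if (is.null(spec)) return(default)
  if (is.function(spec)) return(spec)
  if (is.numeric(spec) && length(spec) == 1) {
    return(function(n) rep(spec, n))
  }
  abort("distribution spec must be NULL, a single number, or a function(n).")
}

#' Draw ground-truth speeds, activities and half-lives for a genome
#'
#' Samples the hidden per-gene quantities the estimator is meant to
#' recover.  True speeds are log-uniform over the physiological range
#' (~1-90 nt/s by default), promoter activities log-normal (most genes
#' initiate far less than once per second), and half-lives log-normal
#' around 5 min, the typical bacterial mRNA scale.
#'
#' @param genome annotation tibble from [generate_genome()].
#' @param seed integer seed.
#' @param speed_range range of true speeds in nt/s (log-uniform draw).
#' @param activity_meanlog,activity_sdlog log-normal parameters of the
#'   true promoter activity in 1/s.
#' @param half_life_meanlog,half_life_sdlog log-normal parameters of the
#'   true mRNA half-life in seconds.
#' @param per_operon_speed if `TRUE`, one speed is drawn per operon and
#'   shared by its genes — the geometry the clearance-lag fit assumes
#'   (the same polymerases traverse the whole operon).
#' @return Tibble `gene`, `true_speed` (nt/s), `true_activity` (1/s),
#'   `true_half_life` (s).
#' @export
generate_truth <- function(genome, seed = NULL, speed_range = c(1, 90),
                           activity_meanlog = log(0.02), activity_sdlog = 1,
                           half_life_meanlog = log(300),
                           half_life_sdlog = 0.35,
                           per_operon_speed = FALSE) {
  n <- nrow(genome)
  with_seed(seed, {
    speeds <- if (per_operon_speed) {
      ops <- unique(genome$operon)
      v_op <- setNames(
        exp(runif(length(ops), log(speed_range[1]), log(speed_range[2]))),
        ops)
      unname(v_op[genome$operon])
    } else {
      exp(runif(n, log(speed_range[1]), log(speed_range[2])))
    }
    tibble::tibble(
      gene = genome$gene,
      true_speed = speeds,
      true_activity = rlnorm(n, activity_meanlog, activity_sdlog),
      true_half_life = rlnorm(n, half_life_meanlog, half_life_sdlog)
    )
  })
}
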