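# Shared fixture builders; all inputs are generated in code.

# A cohort of equal-size operons with one true speed per operon, plus its
# noise-free decay series — the clearance-correspondence setup.
make_operon_cohort <- function(n_operons = 20, genes_per_operon = 3,
                               speed_range = c(5, 60), seed = 101,
                               noise_cv = 0,
                               timepoints = seq(0, 1800, by = 60)) {
  genome <- generate_genome(
    n_operons * genes_per_operon,
    operon_size_dist = genes_per_operon,
    length_dist = function(n) round(runif(n, 500, 2500)),
    seed = seed
  )
  truth <- generate_truth(genome, seed = seed + 1, speed_range = speed_range,
                          per_operon_speed = TRUE)
  series <- generate_decay_series(genome, truth, timepoints = timepoints,
                                  noise_cv = noise_cv, seed = seed + 2)
  operon_speeds <- dplyr::distinct(
    dplyr::inner_join(genome[, c("gene", "operon")], truth, by = "gene"),
    operon, true_speed)
  list(genome = genome, truth = truth, series = series,
       operon_speeds = operon_speeds)
}

# Minimal measurement table with hand-pickable values.
toy_measurements <- function(n_r, d_p, half_life, length = 1000) {
  tibble::tibble(gene = sprintf("g%d", seq_along(n_r)),
                 n_r = n_r, d_p = d_p, half_life = half_life,
                 length = length)
}
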