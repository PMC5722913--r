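# Run code with a temporary RNG state so generators are reproducible per
# seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Multiplicative log-normal noise with unit mean and a given coefficient
# of variation; cv = 0 returns exact ones.
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# GFP-mRNA carryover fraction: share of one step's reporter mRNA still
# present after `dt` seconds given half-life `lambda_gfp`.
carryover_fraction <- function(lambda_gfp, dt) {
  0.5^(dt / lambda_gfp)
}
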