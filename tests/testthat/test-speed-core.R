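test_that("promoter activity follows the steady-state turnover formula", {
  expect_equal(promoter_activity(1, 1), 0.5)
  expect_equal(promoter_activity(0, 100), 0)
  expect_equal(promoter_activity(10, 300), 0.023078, tolerance = 1e-4)
  expect_error(promoter_activity(1, 0), "positive")
  expect_error(promoter_activity(1, -5), "positive")
  # a <= n_r always; first-order limit for long half-lives
  set.seed(1)
  n_r <- rlnorm(200); lam <- rlnorm(200, log(900), 0.5)
  a <- promoter_activity(n_r, lam)
  expect_true(all(a <= n_r))
  long <- lam > 700
  expect_lt(max(abs(a[long] / (n_r[long] * log(2) / lam[long]) - 1)), 1e-3)
})

test_that("polymerase counts scale with length over the footprint", {
  expect_equal(rnap_count(400, 0.1), 1)
  expect_equal(rnap_count(1000, 0), 0)
  expect_equal(rnap_count(2500, 0.016), 1)
  expect_error(rnap_count(0, 0.1), "positive")
})

test_that("transcription speed computes v = a * footprint / d_p", {
  m <- toy_measurements(n_r = 1, d_p = 1, half_life = 1)
  expect_equal(transcription_speed(m)$v, 20)
  expect_equal(transcription_speed(toy_measurements(10, 0.02, 300))$v,
               46.16, tolerance = 1e-4)
  # linear in n_r, inverse in d_p
  expect_equal(transcription_speed(toy_measurements(2, 1, 1))$v, 40)
  expect_equal(transcription_speed(toy_measurements(1, 2, 1))$v, 10)
  # d_p = 0: undefined, not zero
  expect_true(is.na(transcription_speed(toy_measurements(1, 0, 1))$v))
  expect_error(transcription_speed(toy_measurements(1, -0.1, 1)), "negative")
})

test_that("the density route and the count route to speed agree exactly", {
  set.seed(2)
  m <- toy_measurements(n_r = rlnorm(300), d_p = rlnorm(300, -2, 1),
                        half_life = rlnorm(300, log(300), 0.4),
                        length = round(runif(300, 200, 6000)))
  st <- transcription_speed(m)
  v_via_counts <- st$activity * m$length / st$n_p
  expect_equal(st$v_raw, v_via_counts, tolerance = 1e-14)
})

test_that("reference scaling fixes the anchor gene and preserves ranks", {
  m <- toy_measurements(n_r = c(5, 1, 3), d_p = c(0.5, 0.2, 0.1),
                        half_life = c(120, 300, 240))
  st <- transcription_speed(m)
  st$v_raw[1] <- 10; st$v[1] <- 10  # pin the reference raw speed
  out <- scale_speeds(st, "g1")
  expect_equal(attr(out, "scale_factor"), 4.95)
  expect_equal(out$v[1], 49.5)
  expect_equal(cor(out$v, st$v_raw, method = "spearman"), 1)
  # already at the reference: identity
  st2 <- st; st2$v_raw[1] <- 49.5
  expect_equal(scale_speeds(st2, "g1")$v[1], 49.5)
  expect_equal(scale_speeds(st2, "g1")$v[-1], st2$v_raw[-1] * 1)
  expect_error(scale_speeds(st, "nope"), "not found")
  st3 <- st; st3$v_raw[1] <- 0
  expect_error(scale_speeds(st3, "g1"), "positive")
})

test_that("the analysis filter uses strict thresholds on speed and signal", {
  tb <- tibble::tibble(gene = paste0("g", 1:5),
                       d_p = c(1, 0.5, 0.4, 2, 0.51),
                       v = c(10, 10, 10, 0, NA))
  out <- filter_genes(tb)
  expect_equal(out$passes_filter, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(sum(out$passes_filter), 1)
  tb2 <- tibble::tibble(gene = paste0("g", 1:5),
                        d_p = c(1, 1, 0.6, 0.7, 0.2),
                        v = c(5, 0, 3, 2, 9))
  expect_equal(sum(filter_genes(tb2)$passes_filter), 3)
})

test_that("regulation delays accumulate along the operon in annotation order", {
  tb <- tibble::tibble(gene = "a", length = 1000, v = 10,
                       operon = "op", operon_pos = 1)
  expect_equal(regulation_delay(tb)$delay, 100)

  two <- tibble::tibble(gene = c("a", "b"), length = c(1000, 2000),
                        v = c(10, 20), operon = "op", operon_pos = 1:2)
  expect_equal(regulation_delay(two)$delay, c(100, 200))
  # input row order must not matter: operon order comes from the annotation
  shuffled <- two[2:1, ]
  out <- regulation_delay(shuffled)
  expect_equal(out$delay[match(c("a", "b"), out$gene)], c(100, 200))
  # delays are additive increments of l/v
  set.seed(3)
  g <- generate_genome(30, seed = 16)
  st <- dplyr::mutate(g, v = rlnorm(30, 3, 0.5))
  out2 <- regulation_delay(st) |>
    dplyr::group_by(operon) |> dplyr::arrange(operon_pos, .by_group = TRUE)
  incs <- dplyr::mutate(out2, inc = delay - dplyr::lag(delay, default = 0))
  expect_equal(incs$inc, incs$length / incs$v, tolerance = 1e-12)
  # zero speed poisons that gene and all downstream genes
  bad <- tibble::tibble(gene = c("a", "b", "c"), length = 100,
                        v = c(5, 0, 5), operon = "op", operon_pos = 1:3)
  d <- regulation_delay(bad)$delay
  expect_equal(is.na(d), c(FALSE, TRUE, TRUE))
})

test_that("the molecule census recovers totals known by construction", {
  set.seed(4)
  # build a world with known absolute numbers, present it in arbitrary units
  n <- 10
  length <- round(runif(n, 500, 4000))
  d_p_abs <- runif(n, 0.005, 0.05)
  half_life <- runif(n, 120, 600)
  v <- runif(n, 5, 50)
  n_r_abs <- v * d_p_abs / (40 * (1 - 0.5^(1 / half_life)))
  true_rnap_total <- sum(length / 40 * d_p_abs)
  tb <- tibble::tibble(gene = paste0("g", 1:n), length = length,
                       d_p = d_p_abs * 37.3,      # arbitrary array units
                       n_r = n_r_abs * 0.81,
                       half_life = half_life, v = v)
  cen <- molecule_census(tb, total_rnap = true_rnap_total)
  expect_equal(cen$total_rnap, true_rnap_total)
  expect_equal(cen$total_mrna, sum(n_r_abs), tolerance = 1e-10)
  expect_equal(cen$genes$n_p_abs, length / 40 * d_p_abs, tolerance = 1e-10)
  # hand summation check of the density-unit fix
  beta <- true_rnap_total / sum(length / 40 * tb$d_p)
  expect_equal(cen$genes$d_p_percent, 100 * beta * tb$d_p)
  # anchoring on the mRNA side inverts the same relations
  cen2 <- molecule_census(tb, total_rnap = NULL, total_mrna = sum(n_r_abs))
  expect_equal(cen2$total_rnap, true_rnap_total, tolerance = 1e-10)
  # linearity: doubling the RNAP anchor doubles the inferred mRNA total
  cen3 <- molecule_census(tb, total_rnap = 2 * true_rnap_total)
  expect_equal(cen3$total_mrna, 2 * cen$total_mrna)
  expect_error(molecule_census(tb, total_rnap = NULL, total_mrna = NULL),
               "exactly one")
  expect_error(molecule_census(tb, total_rnap = 10, total_mrna = 10),
               "exactly one")
})

test_that("nascent-share gene selection applies strict census thresholds", {
  cg <- tibble::tibble(gene = paste0("g", 1:6),
                       d_p_percent = c(2.0, 1.8, 2.5, 1.0, 3.0, 2.1),
                       n_r_abs = c(0.5, 0.5, 0.97, 0.5, 0.2, 1.5))
  out <- nascent_share_genes(cg)
  expect_equal(out$gene, c("g1", "g5"))
  expect_error(nascent_share_genes(tibble::tibble(gene = "g", d_p = 1)),
               "census")
})
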