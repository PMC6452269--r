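# short configs keep the dynamics tests fast
short_cfg <- function(...) sim_config(days = 6L, ...)

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(transfer_dilution = 0), "0,1")
  expect_error(sim_config(transfer_dilution = 1.2), "\\[0,1\\]")
  expect_error(sim_config(acquisition_prob = -0.1), "\\[0,1\\]")
  expect_error(sim_config(days = 0), "non-negative|positive")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("without phage, hosts grow to carrying capacity and stay wild type", {
  ref <- small_genome()
  cfg <- short_cfg(initial_pfu = 0, acquisition_prob = 0, mutation_prob = 0)
  run <- run_serial_transfer(ref, cfg, rng_seed = 1)
  expect_true(all(run$trajectory$pfu_per_ml == 0))
  final <- run$trajectory$cfu_per_ml[cfg$days]
  expect_gt(final, 0.9 * cfg$carrying_capacity)
  for (st in run$states) {
    expect_equal(st$hosts$genotype_key, "")
  }
})

test_that("a single expectation-update step matches hand arithmetic", {
  ref <- planted_genome()
  # one generation per day, one day; alpha = mu = 0 so no innovation
  cfg <- sim_config(days = 1L, generations_per_day = 1, acquisition_prob = 0,
                    mutation_prob = 0, growth_rate = 1, burst_size = 50,
                    adsorption_prob = 0.02, carrying_capacity = 1e9,
                    initial_cfu = 1e8, initial_pfu = 1e6,
                    transfer_dilution = 0.5)
  run <- run_serial_transfer(ref, cfg, rng_seed = 1)
  # hand computation of the same step:
  n0 <- 1e8 * 2^(1 * (1 - 1e8 / 1e9))                 # logistic growth
  f <- n0 / 1e9
  enc <- 0.02 * 4 * f * (1 - f)                       # productive encounters
  e_tot <- 1e6 * enc                                  # all hosts sensitive
  act <- min(1, 4 * f * (1 - f))
  realized <- min(e_tot, n0 * act)
  n1 <- n0 - realized
  p1 <- 1e6 - realized + 50 * realized
  expect_equal(run$trajectory$cfu_per_ml[1], n1, tolerance = 1e-12)
  expect_equal(run$trajectory$pfu_per_ml[1], p1, tolerance = 1e-12)
})

test_that("trajectories are bit-identical per seed and finite throughout", {
  ref <- small_genome()
  cfg <- short_cfg()
  a <- run_serial_transfer(ref, cfg, rng_seed = 11)
  b <- run_serial_transfer(ref, cfg, rng_seed = 11)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$states[[6]]$hosts, b$states[[6]]$hosts)
  expect_true(all(is.finite(a$trajectory$cfu_per_ml)))
  expect_true(all(is.finite(a$trajectory$pfu_per_ml)))
  expect_true(all(a$trajectory$cfu_per_ml >= 0))
  expect_true(all(a$trajectory$pfu_per_ml >= 0))
  for (st in a$states) {
    expect_true(all(st$hosts$n >= 0))
    expect_true(all(st$phage$n >= 0))
  }
})

test_that("genotype keys only grow: every prefix of a spacer tuple occurs", {
  ref <- small_genome()
  cfg <- short_cfg(prune_threshold = 0)      # keep every ancestor around
  run <- run_serial_transfer(ref, cfg, rng_seed = 3)
  seen <- character()
  for (st in run$states) {
    for (li in st$hosts$loci) {
      if (length(li) >= 1) {
        parent <- paste(li[-length(li)], collapse = "|")
        expect_true(parent %in% c("", seen))
      }
    }
    seen <- union(seen, st$hosts$genotype_key)
  }
})

test_that("extinction day is the start of the first quiet window", {
  expect_equal(detect_extinction_day(c(1e6, 1e5, 1e4, 199, 150, 100, 50),
                                     window = 4L), 4L)
  # below the limit from day 5 for four consecutive days
  pfu <- c(1e6, 1e6, 1e6, 1e6, 100, 100, 100, 100, 1e6)
  expect_equal(detect_extinction_day(pfu, window = 4L), 5L)
  # a three-day dip does not count
  pfu2 <- c(1e6, 100, 100, 100, 1e6, 1e6, 1e6, 1e6, 1e6)
  expect_true(is.na(detect_extinction_day(pfu2, window = 4L)))
})

test_that("extinction summaries follow hand arithmetic and censoring", {
  tbl <- tibble::tibble(replicate = c("a", "b", "c"),
                        extinction_day = c(2L, 2L, 2L))
  s <- time_to_extinction_summary(tbl)
  expect_equal(s$mean_day, 2)
  expect_equal(s$se_day, 0)
  tbl2 <- tibble::tibble(replicate = c("a", "b", "c"),
                         extinction_day = c(7L, 9L, 14L))
  s2 <- time_to_extinction_summary(tbl2)
  expect_equal(s2$mean_day, 10)
  expect_equal(s2$se_day, sd(c(7, 9, 14)) / sqrt(3))
  tbl3 <- tibble::tibble(replicate = c("a", "b"),
                         extinction_day = c(NA_integer_, NA_integer_))
  s3 <- time_to_extinction_summary(tbl3)
  expect_true(is.na(s3$mean_day))
  expect_equal(s3$n_censored, 2L)
  expect_error(time_to_extinction_summary(tbl3[0, ]), "at least one")
})

test_that("clone sampling is multinomial in abundance and seed-stable", {
  state <- list(
    day = 4L,
    hosts = tibble::tibble(genotype_key = c("", "5"),
                           loci = list(integer(), 5L),
                           n = c(0.5, 0.5)),
    phage = tibble::tibble(genotype_key = "", snps = list(
      tibble::tibble(position = integer(), ref = character(),
                     alt = character())), n = 1)
  )
  ref <- small_genome()
  # single-genotype phage population: all clones identical
  cl <- sample_clones(state, ref, n_host = 0, n_phage = 12, rng_seed = 1)
  expect_equal(nrow(cl$phages), 12L)
  expect_equal(unique(cl$phages$genotype_key), "")
  # 50/50 host genotypes at large n: fraction within 3 binomial SE of 0.5
  big <- sample_clones(state, ref, n_host = 10000, n_phage = 0, rng_seed = 2)
  frac <- mean(big$hosts$genotype_key == "")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  # deterministic per seed
  again <- sample_clones(state, ref, n_host = 10000, n_phage = 0,
                         rng_seed = 2)
  expect_identical(big$hosts, again$hosts)
  # empty population errors
  empty <- state
  empty$phage <- empty$phage[0, ]
  expect_error(sample_clones(empty, ref, n_host = 0, n_phage = 1,
                             rng_seed = 1), "empty")
})

test_that("no-mutation limit: spacered hosts are predicted unreachable", {
  ref <- small_genome()
  cfg <- sim_config(days = 9L, mutation_prob = 0)
  run <- run_serial_transfer(ref, cfg, rng_seed = 5)
  st <- run$states[[9]]
  expect_true(sum(st$phage$n) > 0)
  cl <- sample_clones(st, ref, n_host = 12, n_phage = 12, rng_seed = 9,
                      dpi = 9L)
  spacered <- vapply(cl$hosts$spacers, nrow, integer(1)) > 0
  expect_true(any(spacered))
  m <- predict_matrix(cl$hosts, cl$phages, ref)
  hit <- m$infected[m$host_clone %in% cl$hosts$clone_id[spacered]]
  expect_true(all(hit == 0L))
})

test_that("panel simulation keeps persisting replicates and full designs", {
  cfg <- sim_config(days = 10L)
  panel <- simulate_panel(cfg, n_replicates = 3L, keep = 2L, rng_seed = 21)
  expect_lte(length(panel$kept_replicates), 2L)
  r <- panel$kept_replicates[1]
  sub <- panel$predicted[panel$predicted$replicate == r, ]
  expect_equal(nrow(sub), 36L * 36L)
  expect_equal(sort(unique(sub$host_dpi)), c(1L, 4L, 9L))
  # 12 host and 12 phage clones per dpi
  hh <- panel$hosts[panel$hosts$replicate == r, ]
  expect_equal(unname(table(hh$dpi)), rep(12L, 3), ignore_attr = TRUE)
  # determinism of the whole panel
  again <- simulate_panel(cfg, n_replicates = 3L, keep = 2L, rng_seed = 21)
  expect_identical(panel$predicted, again$predicted)
  expect_identical(panel$measured, again$measured)
})
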