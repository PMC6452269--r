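test_that("background classification follows the time-shift design", {
  expect_equal(classify_background(4, 1), "past")
  expect_equal(classify_background(1, 9), "future")
  expect_equal(classify_background(9, 9), "present")
  # full 3x3 design
  grid <- expand.grid(host = c(1, 4, 9), phage = c(1, 4, 9))
  bg <- classify_background(grid$host, grid$phage)
  expect_equal(sum(bg == "past"), 3)
  expect_equal(sum(bg == "present"), 3)
  expect_equal(sum(bg == "future"), 3)
  # antisymmetry under swapping host and phage days
  swapped <- classify_background(grid$phage, grid$host)
  expect_equal(bg == "past", swapped == "future")
  expect_equal(bg == "present", swapped == "present")
})

test_that("time-shift cells equal brute-force group means", {
  set.seed(5)
  m <- matrix(rbinom(36 * 36, 1, 0.5), 36, 36)
  dpis <- rep(c(1L, 4L, 9L), each = 12)
  tbl <- matrix_tbl(m, host_dpi = dpis, phage_dpi = dpis)
  ts <- timeshift_table(tbl, bootstrap_spec(reps = 50, rng_seed = 1))
  expect_equal(nrow(ts$cells), 9L)
  for (k in seq_len(9)) {
    hd <- ts$cells$host_dpi[k]
    pd <- ts$cells$phage_dpi[k]
    expect_equal(ts$cells$mean[k],
                 mean(m[dpis == hd, dpis == pd]))
  }
  # background means pool the right cells
  past <- with(expand.grid(hi = 1:36, pj = 1:36),
               m[cbind(hi, pj)][dpis[pj] < dpis[hi]])
  expect_equal(ts$backgrounds$mean[ts$backgrounds$background == "past"],
               mean(past))
  # all-ones matrix: every cell 1.0
  ones <- timeshift_table(matrix_tbl(matrix(1L, 6, 6),
                                     host_dpi = rep(c(1L, 4L, 9L), 2),
                                     phage_dpi = rep(c(1L, 4L, 9L), 2)),
                          bootstrap_spec(reps = 20, rng_seed = 1))
  expect_true(all(ones$cells$mean == 1))
})

test_that("balanced two-way decomposition matches the definitional sums", {
  # 2x2 layout, 2 replicates per cell, hand-enumerable
  y <- c(1, 1, 0, 1, 1, 0, 0, 0)
  tbl <- tibble::tibble(
    replicate = "R1",
    host_clone = rep(c("H1", "H2"), each = 4),
    host_dpi = 4L,
    phage_clone = sprintf("P%d", 1:8),
    phage_dpi = rep(rep(c(1L, 9L), each = 2), 2),
    infected = as.integer(y))
  dec <- anova_ms(tbl, "R1", 4L)
  grand <- mean(y)
  gi <- tapply(y, rep(c("H1", "H2"), each = 4), mean)
  ej <- tapply(y, rep(rep(c(1, 9), each = 2), 2), mean)
  cm <- tapply(y, list(rep(c("H1", "H2"), each = 4),
                       rep(rep(c(1, 9), each = 2), 2)), mean)
  ss_g <- 2 * 2 * sum((gi - grand)^2)
  ss_e <- 2 * 2 * sum((ej - grand)^2)
  ss_gxe <- 2 * sum((cm - outer(gi, rep(1, 2)) -
                       outer(rep(1, 2), ej) + grand)^2)
  expect_equal(unname(dec$ss["g"]), ss_g)
  expect_equal(unname(dec$ss["e"]), ss_e)
  expect_equal(unname(dec$ss["gxe"]), ss_gxe)
  expect_equal(unname(dec$df), c(1, 1, 1, 4))
  # total SS additivity
  expect_equal(sum(dec$ss), dec$ss_total, tolerance = 1e-12)
})

test_that("decomposition agrees with stats::aov on random balanced layouts", {
  set.seed(6)
  for (rep in 1:10) {
    g <- sample(2:5, 1)
    e <- sample(2:3, 1)
    r <- sample(2:4, 1)
    y <- rbinom(g * e * r, 1, runif(1, 0.2, 0.8))
    tbl <- tibble::tibble(
      replicate = "R1",
      host_clone = rep(sprintf("H%d", seq_len(g)), each = e * r),
      host_dpi = 1L,
      phage_clone = sprintf("P%d", seq_len(g * e * r)),
      phage_dpi = rep(rep(c(1L, 4L, 9L)[seq_len(e)], each = r), g),
      infected = as.integer(y))
    dec <- anova_ms(tbl, "R1", 1L)
    fit <- stats::aov(infected ~ factor(host_clone) * factor(phage_dpi),
                      data = tbl)
    ss <- summary(fit)[[1]][["Sum Sq"]]
    expect_equal(unname(dec$ss), unname(ss), tolerance = 1e-9)
    expect_equal(sum(dec$ss), dec$ss_total, tolerance = 1e-9)
  }
})

test_that("constant and additive layouts have zero interaction", {
  ones <- matrix_tbl(matrix(1L, 4, 4), host_dpi = rep(4L, 4),
                     phage_dpi = rep(c(1L, 9L), each = 2))
  dec <- anova_ms(ones, "R1", 4L)
  expect_equal(unname(dec$ss[c("g", "e", "gxe")]), c(0, 0, 0))
  # additive layout (cell mean = e_j for every genotype): no interaction,
  # environment signal only
  additive <- rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  tbl <- matrix_tbl(additive, host_dpi = rep(4L, 3),
                    phage_dpi = rep(c(1L, 9L), each = 2))
  dec2 <- anova_ms(tbl, "R1", 4L)
  expect_equal(unname(dec2$ss["gxe"]), 0, tolerance = 1e-12)
  expect_equal(unname(dec2$ss["g"]), 0, tolerance = 1e-12)
  expect_gt(unname(dec2$ss["e"]), 0)
})

test_that("unbalanced layouts are refused", {
  tbl <- matrix_tbl(matrix(1L, 4, 5), host_dpi = rep(4L, 4),
                    phage_dpi = c(1L, 1L, 9L, 9L, 9L))
  expect_error(anova_ms(tbl, "R1", 4L), "unbalanced")
  expect_error(anova_ms(tbl, "R1", 9L), "no challenges")
})

test_that("ratio series recomposes anova_ms and flags degenerate cells", {
  set.seed(8)
  dpis <- rep(c(1L, 4L, 9L), each = 4)
  tbls <- lapply(c("R1", "R2"), function(r) {
    matrix_tbl(matrix(rbinom(144, 1, 0.5), 12, 12), replicate = r,
               host_dpi = dpis, phage_dpi = dpis)
  })
  g <- gxe_ratio_series(tbls, bootstrap_spec(reps = 50, rng_seed = 2))
  expect_equal(nrow(g$ratios), 6L)
  for (k in seq_len(nrow(g$ratios))) {
    dec <- anova_ms(dplyr::bind_rows(tbls), g$ratios$replicate[k],
                    g$ratios$host_dpi[k])
    expect_equal(g$ratios$ratio[k],
                 unname(dec$ms["gxe"] / dec$ms["e"]))
  }
  # identical E-marginals but genotype-specific crossing: ms_e = 0, flagged
  cross <- matrix(c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L), 4, 2)
  tblc <- matrix_tbl(cross, host_dpi = rep(4L, 4),
                     phage_dpi = c(1L, 9L))
  expect_warning(
    expect_message(gc <- gxe_ratio_series(tblc,
                                          bootstrap_spec(reps = 10,
                                                         rng_seed = 1)),
                   "flagged"),
    "all cells flagged")
  expect_true(all(gc$ratios$flagged))
})

test_that("tidy and glance methods expose the decomposition", {
  ones <- matrix_tbl(matrix(1L, 4, 4), host_dpi = rep(4L, 4),
                     phage_dpi = rep(c(1L, 9L), each = 2))
  dec <- anova_ms(ones, "R1", 4L)
  td <- tidy(dec)
  expect_equal(td$term, c("genotype", "environment", "genotype:environment",
                          "residual"))
  expect_equal(td$sumsq, unname(dec$ss))
  gl <- glance(dec)
  expect_true(gl$flagged)          # ms_e = 0 for the constant layout
  expect_true(is.na(gl$ratio))
  gl_rec <- glance(dec, reciprocal = TRUE)
  expect_true(is.na(gl_rec$ratio)) # ms_gxe = 0 too
})
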