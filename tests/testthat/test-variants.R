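ref <- planted_genome()
c1 <- ref$loci[ref$loci$crispr_system == "CRISPR1", ]

test_that("SNP calling equals position-wise comparison", {
  expect_equal(nrow(call_snps("ACGT", "ACGT")), 0L)
  one <- call_snps("ACGTTA", "ACGTCA", region_offset = 100L)
  expect_equal(one$position, 104L)
  expect_equal(one$ref, "C")
  expect_equal(one$alt, "T")
  expect_error(call_snps("ACG", "ACGT"), "alignment")
  # random mutated copies against a zip-compare oracle
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    refseq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    chars <- strsplit(refseq, "")[[1]]
    k <- sample(0:5, 1)
    pos <- if (k > 0) sample.int(n, k) else integer()
    mut <- chars
    for (p in pos) mut[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    off <- sample(0:1000, 1)
    snps <- call_snps(paste(mut, collapse = ""), refseq, off)
    oracle <- which(mut != chars)
    expect_equal(snps$position, as.integer(off + oracle - 1))
    expect_equal(snps$ref, chars[oracle])
    expect_equal(snps$alt, mut[oracle])
  }
})

test_that("mutation classes partition positions with pam > seed priority", {
  snp_at <- function(p) tibble::tibble(position = as.integer(p), ref = "A",
                                       alt = "C")
  expect_equal(classify_mutations(snp_at(c1$pam_start + 1L), c1)$summary,
               "pam")
  expect_equal(classify_mutations(snp_at(c1$seed_start), c1)$summary, "seed")
  expect_equal(classify_mutations(snp_at(c1$start), c1)$summary,
               "protospacer_nonseed")
  expect_equal(classify_mutations(snp_at(0L), c1)$summary, "outside")
  expect_equal(classify_mutations(NULL, c1)$summary, "none")
  # priority: pam beats seed beats the rest in the clone-level summary
  multi <- snp_at(c(0L, c1$start, c1$seed_start, c1$pam_start))
  cls <- classify_mutations(multi, c1)
  expect_equal(cls$summary, "pam")
  expect_equal(sort(unique(cls$per_snp$class)),
               c("outside", "pam", "protospacer_nonseed", "seed"))
  # every position gets exactly one label
  expect_equal(nrow(cls$per_snp), 4L)
})

test_that("contingency analysis reproduces the published worked example", {
  # counts (242, 107, 106, 241): predictive value 241/348, concordance
  # (242+241)/696
  pred <- rep(c(0L, 0L, 1L, 1L), c(242, 106, 107, 241))
  meas <- rep(c(0L, 1L, 0L, 1L), c(242, 106, 107, 241))
  tbl <- tibble::tibble(replicate = "R1",
                        host_clone = sprintf("H%03d", seq_along(pred)),
                        host_dpi = 1L,
                        phage_clone = sprintf("P%03d", seq_along(pred)),
                        phage_dpi = 1L, infected = pred)
  mtbl <- tbl
  mtbl$infected <- meas
  ct <- contingency_analysis(tbl, mtbl)
  expect_equal(unname(ct$counts),
               c(242L, 106L, 107L, 241L))
  expect_equal(ct$predictive_value, 241 / 348)
  expect_equal(ct$concordance, (242 + 241) / 696)
  expect_equal(ct$total, 696L)
  # tidy/glance views
  expect_equal(tidy(ct)$n, c(242L, 106L, 107L, 241L))
  expect_equal(glance(ct)$predictive_value, 241 / 348)
})

test_that("contingency marginals equal independent matrix tallies", {
  set.seed(22)
  g <- small_genome()
  panel <- random_panel(g, n_host = 8, n_phage = 8)
  pred <- predict_matrix(panel$hosts, panel$phages, g)
  meas <- simulate_measured_matrix(pred, 0.3, 0.1, rng_seed = 4)
  ct <- contingency_analysis(pred, meas)
  expect_equal(unname(ct$counts["n_pred1_meas0"] + ct$counts["n_pred1_meas1"]),
               sum(pred$infected))
  expect_equal(unname(ct$counts["n_pred0_meas1"] + ct$counts["n_pred1_meas1"]),
               sum(meas$infected))
  expect_equal(ct$total, nrow(pred))
  # identity when measured == predicted
  ct0 <- contingency_analysis(pred, pred)
  expect_equal(unname(ct0$counts[c("n_pred0_meas1", "n_pred1_meas0")]),
               c(0L, 0L))
  expect_equal(ct0$concordance, 1)
  # mismatched clone sets are refused
  expect_error(contingency_analysis(pred, meas[-1, ]), "different")
})

test_that("infectivity splits by SNP status and unevolved-target count", {
  g <- planted_genome()
  cc1 <- g$loci[1, ]
  cc3 <- g$loci[2, ]
  hosts <- dplyr::bind_rows(
    host_clone(g, integer(), clone_id = "WT"),
    host_clone(g, 1L, clone_id = "H1"),
    host_clone(g, c(1L, 2L), clone_id = "H12"))
  phages <- dplyr::bind_rows(
    phage_clone(integer(), clone_id = "Pnone"),
    phage_clone(cc1$pam_start, g, clone_id = "Ppam"),
    phage_clone(c(cc1$pam_start, cc3$seed_start), g, clone_id = "Pboth"))
  pred <- predict_matrix(hosts, phages, g)
  out <- infectivity_by_snp_status(phages, hosts, pred, g,
                                   bootstrap_spec(reps = 50, rng_seed = 1))
  bs <- out$by_status
  # noiseless: phage with no SNP infect only the WT host (1 of 3)
  expect_equal(bs$mean[bs$status == "none"], 1 / 3)
  # protospacer-associated phage infect more hosts on average
  expect_gt(bs$mean[bs$status == "protospacer_associated"],
            bs$mean[bs$status == "none"])
  bt <- out$by_targets
  # zero unevolved targets <=> predicted infection (mean exactly 1)
  expect_equal(bt$mean[bt$unevolved_targets == 0], 1)
  expect_true(all(bt$mean[bt$unevolved_targets > 0] == 0))
})

test_that("noisy group means approach their Bernoulli expectations", {
  g <- planted_genome()
  hosts <- dplyr::bind_rows(lapply(1:40, function(i) {
    host_clone(g, 1L, clone_id = sprintf("H%02d", i))
  }))
  phages <- dplyr::bind_rows(lapply(1:40, function(i) {
    phage_clone(g$loci$pam_start[1], g, clone_id = sprintf("P%02d", i))
  }))
  pred <- predict_matrix(hosts, phages, g)
  expect_true(all(pred$infected == 1L))
  fn <- 107 / 348
  meas <- simulate_measured_matrix(pred, fn_rate = fn, fp_rate = 0,
                                   rng_seed = 8)
  out <- infectivity_by_snp_status(phages, hosts, meas, g,
                                   bootstrap_spec(reps = 50, rng_seed = 2))
  mean_meas <- out$by_targets$mean[out$by_targets$unevolved_targets == 0]
  se <- sqrt(fn * (1 - fn) / nrow(pred))
  expect_lt(abs(mean_meas - (1 - fn)), 4 * se)
})
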