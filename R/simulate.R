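#' Serial-transfer coevolution simulation settings
#'
#' Bundles the parameters of the daily-transfer co-culture model. Defaults
#' reflect the experimental design the simulator emulates: 30 daily 1:100
#' transfers, about `log2(100) = 6.64` bacterial generations per day, a
#' starting inoculum of 1e6 CFU and 1e8 PFU, and a plaque-assay detection
#' limit of 200 PFU/ml with phage declared extinct after four consecutive
#' days below it. Demographic rates (burst size, adsorption, spacer
#' acquisition, protospacer mutation) are not reported by serial-transfer
#' studies at this resolution; the defaults are literature-scale placeholders
#' and are documented as such.
#'
#' @param days Number of daily transfers to simulate.
#' @param transfer_dilution Daily dilution fraction (1:100 transfer = 0.01).
#' @param generations_per_day Host generations between transfers; the default
#'   `log2(100)` is implied by regrowth from a 1:100 dilution.
#' @param initial_cfu Starting bacterial density (cells/ml).
#' @param initial_pfu Starting phage density (PFU/ml); the experimental
#'   treatments used 1e6, 1e7, 1e8 or 1e9.
#' @param carrying_capacity Bacterial carrying capacity (cells/ml).
#' @param growth_rate Host doublings per update step at low density; the
#'   logistic brake scales this toward zero at carrying capacity. The default
#'   2 lets a 1:100-diluted culture regrow to stationary phase within one
#'   day, as overnight serial-transfer cultures do.
#' @param burst_size Phage progeny per lysed cell.
#' @param adsorption_prob Peak per-phage, per-step probability of a
#'   productive encounter. Productive adsorption requires actively growing
#'   cells, so the realized probability is
#'   `adsorption_prob * 4 * f * (1 - f)` with `f = N_host /
#'   carrying_capacity`: it peaks at half capacity and vanishes in
#'   stationary phase, confining phage amplification to the post-transfer
#'   regrowth window.
#' @param acquisition_prob Probability an infected sensitive cell survives and
#'   acquires one new spacer instead of lysing.
#' @param mutation_prob Per-protospacer, per-replication probability that a
#'   progeny phage gains a SNP uniformly placed in the protospacer-plus-PAM
#'   interval.
#' @param detection_limit Plaque-assay detection limit (PFU/ml).
#' @param extinction_window Consecutive days below `detection_limit` that
#'   define phage extinction.
#' @param spacer_length,seed_length Spacer and seed-window lengths (nt).
#' @param pam_motifs Named IUPAC PAM motifs per CRISPR system.
#' @param genome_length Reference genome length used by
#'   [simulate_panel()] when it builds a genome.
#' @param innovation_slots Maximum distinct new spacer genotypes spawned per
#'   parent host genotype per generation (book-keeping cap).
#' @param mutation_slots Maximum distinct escape-mutant genotypes spawned per
#'   parent phage genotype per generation; loci are chosen weighted by the
#'   abundance of hosts carrying them, and unspawned mutant mass stays with
#'   the parent (phenotypically neutral book-keeping cap).
#' @param acquisition_threshold Minimum expected surviving-cell mass (per
#'   ml, per parent genotype per step) required to found a new
#'   spacer genotype; an approximation to demographic stochasticity that
#'   keeps spacer sweeps near-clonal, as observed genotype richness implies.
#' @param mutant_threshold Minimum expected escape-mutant mass (per ml)
#'   required to instantiate a mutant phage genotype.
#' @param prune_threshold Genotypes below this density (per ml) are dropped.
#' @param fn_rate,fp_rate Default phenotype-noise rates passed to
#'   [simulate_measured_matrix()] by [simulate_panel()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(days = 30L,
                       transfer_dilution = 0.01,
                       generations_per_day = log2(100),
                       initial_cfu = 1e6,
                       initial_pfu = 1e8,
                       carrying_capacity = 1e9,
                       growth_rate = 2,
                       burst_size = 200,
                       adsorption_prob = 0.05,
                       acquisition_prob = 1e-4,
                       mutation_prob = 1e-6,
                       detection_limit = 200,
                       extinction_window = 4L,
                       spacer_length = 30L,
                       seed_length = 10L,
                       pam_motifs = c(CRISPR1 = "NNAGAAW", CRISPR3 = "NGGNG"),
                       genome_length = 34704L,
                       innovation_slots = 1L,
                       mutation_slots = 6L,
                       acquisition_threshold = 2000,
                       mutant_threshold = 0.05,
                       prune_threshold = 1e-3,
                       fn_rate = 107 / 348,
                       fp_rate = 106 / 348) {
  cfg <- as.list(environment())
  probs <- c(cfg$transfer_dilution, cfg$adsorption_prob, cfg$acquisition_prob,
             cfg$mutation_prob, cfg$fn_rate, cfg$fp_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  if (cfg$transfer_dilution <= 0 || cfg$transfer_dilution >= 1) {
    stop("transfer_dilution must lie in (0,1)", call. = FALSE)
  }
  if (cfg$days < 1 || cfg$initial_cfu < 0 || cfg$initial_pfu < 0 ||
      cfg$carrying_capacity <= 0 || cfg$burst_size < 0) {
    stop("counts must be non-negative (and capacity/days positive)",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$days, " days, 1:", round(1 / x$transfer_dilution),
      " transfers, ", round(x$generations_per_day, 2), " gen/day, ",
      format(x$initial_pfu, scientific = TRUE), " PFU inoculum\n", sep = "")
  invisible(x)
}

# --- internal genotype-count state ------------------------------------------
# hosts:  list(key = chr, loci = list of int vectors (ordered catalog row
#         indices), n = dbl)
# phage:  list(key = chr, snps = list of tibbles, escaped = list of int
#         vectors (catalog row indices escaped), n = dbl)

host_key <- function(loci_idx) paste(loci_idx, collapse = "|")
snp_key <- function(snps) {
  if (nrow(snps) == 0L) return("")
  paste(sprintf("%d%s>%s", sort(snps$position),
                snps$ref[order(snps$position)],
                snps$alt[order(snps$position)]), collapse = ";")
}

# escaped catalog row indices for a SNP set (consistent with escapes_spacer)
escaped_rows <- function(snps, loci) {
  if (nrow(snps) == 0L) return(integer())
  pos <- snps$position
  which(vapply(seq_len(nrow(loci)), function(i) {
    any(pos >= loci$seed_start[i] & pos < loci$seed_end[i]) ||
      any(pos >= loci$pam_start[i] & pos < loci$pam_end[i])
  }, logical(1)))
}

#' Simulate one serial-transfer co-culture replicate
#'
#' Genotype-count model of the daily-transfer arms race. Each day runs
#' `generations_per_day` update steps (the fractional remainder as a
#' fractionally weighted step) of: logistic host growth toward carrying
#' capacity; mass-action phage-host encounters; infection of hosts the phage's
#' SNP set can overcome (every acquired spacer escaped), with probability
#' `acquisition_prob` the infected cell surviving and appending one new spacer
#' drawn uniformly from the protospacer catalog, otherwise lysing into
#' `burst_size` progeny whose protospacer loci mutate with probability
#' `mutation_prob` (SNP position uniform over the protospacer-plus-PAM
#' interval); encounters with resistant hosts remove the phage. Both
#' populations are then diluted by `transfer_dilution`. Densities are recorded
#' daily before dilution. Phage are declared extinct on the first day of a run
#' of `extinction_window` consecutive days below `detection_limit`, and are no
#' longer tracked after that.
#'
#' Abundances are updated in expectation (deterministic given the genotype
#' table); randomness enters through which locus a new spacer or SNP hits, so
#' the run is bit-identical per seed.
#'
#' @param genome A `phage_ref` whose catalog defines the protospacer loci.
#' @param config A [sim_config()].
#' @param rng_seed Integer seed for this replicate.
#' @param replicate Identifier recorded in the outputs.
#' @return A list of class `coevo_run` with elements `trajectory` (tibble:
#'   `replicate`, `day`, `cfu_per_ml`, `pfu_per_ml`), `states` (per-day
#'   genotype tables as tibbles with list-columns), `extinction_day` (integer
#'   or `NA`), `replicate`, `config`.
#' @export
run_serial_transfer <- function(genome, config = sim_config(), rng_seed = 1L,
                                replicate = "R1") {
  stopifnot(inherits(genome, "phage_ref"), inherits(config, "sim_config"))
  withr_seed(rng_seed)
  loci <- genome$loci
  n_loci <- nrow(loci)
  hosts <- list(key = "", loci = list(integer()), n = config$initial_cfu)
  phage <- list(key = "", snps = list(empty_snps()), escaped = list(integer()),
                n = config$initial_pfu)
  if (config$initial_pfu == 0) {
    phage <- list(key = character(), snps = list(), escaped = list(),
                  n = numeric())
  }
  gens_full <- floor(config$generations_per_day)
  gen_frac <- config$generations_per_day - gens_full
  traj <- tibble::tibble(day = seq_len(config$days), cfu_per_ml = NA_real_,
                         pfu_per_ml = NA_real_)
  states <- vector("list", config$days)
  below <- 0L
  phage_alive <- length(phage$n) > 0

  for (day in seq_len(config$days)) {
    weights <- c(rep(1, gens_full), if (gen_frac > 1e-9) gen_frac)
    for (w in weights) {
      st <- step_generation(hosts, phage, loci, config, w)
      hosts <- st$hosts
      phage <- st$phage
    }
    cfu <- sum(hosts$n)
    pfu <- if (phage_alive) sum(phage$n) else 0
    if (!is.finite(cfu) || !is.finite(pfu) || cfu < 0 || pfu < 0) {
      stop("non-finite or negative abundance at day ", day, call. = FALSE)
    }
    traj$cfu_per_ml[day] <- cfu
    traj$pfu_per_ml[day] <- pfu
    states[[day]] <- list(
      day = day,
      hosts = tibble::tibble(genotype_key = hosts$key, loci = hosts$loci,
                             n = hosts$n),
      phage = tibble::tibble(genotype_key = phage$key, snps = phage$snps,
                             n = phage$n)
    )
    below <- if (pfu < config$detection_limit) below + 1L else 0L
    if (phage_alive && below >= config$extinction_window) {
      # extinct: stop tracking phage for the rest of the run
      phage <- list(key = character(), snps = list(), escaped = list(),
                    n = numeric())
      phage_alive <- FALSE
    }
    # daily 1:100 transfer into fresh medium
    hosts$n <- hosts$n * config$transfer_dilution
    if (phage_alive) phage$n <- phage$n * config$transfer_dilution
    hosts <- prune_genotypes(hosts, config$prune_threshold)
    phage <- prune_genotypes(phage, config$prune_threshold)
    phage_alive <- phage_alive && length(phage$n) > 0
  }
  traj <- dplyr::mutate(traj, replicate = replicate, .before = 1)
  extinction_day <- detect_extinction_day(traj$pfu_per_ml,
                                          config$detection_limit,
                                          config$extinction_window)
  structure(list(trajectory = traj, states = states,
                 extinction_day = extinction_day, replicate = replicate,
                 config = config),
            class = "coevo_run")
}

prune_genotypes <- function(pop, threshold) {
  keep <- pop$n >= threshold
  if (all(keep)) return(pop)
  out <- lapply(pop, function(f) f[keep])
  out$n <- pop$n[keep]
  out
}

# One expectation-update generation of weight w in (0,1].
step_generation <- function(hosts, phage, loci, config, w) {
  n_loci <- nrow(loci)
  n_tot <- sum(hosts$n)
  # logistic growth: growth_rate doublings per unit step far below capacity
  if (n_tot > 0) {
    growth <- 2^(config$growth_rate * w *
                   max(0, 1 - n_tot / config$carrying_capacity))
    hosts$n <- hosts$n * growth
    n_tot <- sum(hosts$n)
  }
  p_tot <- sum(phage$n)
  if (p_tot <= 0 || n_tot <= 0) {
    return(list(hosts = hosts, phage = phage))
  }
  # productive encounters require metabolically active (growing) cells:
  # activity peaks at half capacity and vanishes in stationary phase, so
  # phage amplify in the post-transfer growth window and stall overnight
  frac <- n_tot / config$carrying_capacity
  enc_prob <- min(1, config$adsorption_prob * 4 * frac * max(0, 1 - frac)) * w
  if (enc_prob <= 0) return(list(hosts = hosts, phage = phage))
  nh <- length(hosts$n)
  np <- length(phage$n)
  # encounters of phage genotype i with host genotype j (expected counts)
  enc <- outer(phage$n * enc_prob, hosts$n / n_tot)
  # infection indicator: phage escaped every locus of the host. Computed
  # over the universe of currently targeted loci via a violation count:
  # host j resists phage i iff j carries a locus i has not escaped.
  targeted <- sort(unique(unlist(hosts$loci)))
  L <- length(targeted)
  if (L == 0L) {
    inf <- matrix(TRUE, np, nh)
  } else {
    H <- matrix(0, nh, L)
    for (j in seq_len(nh)) H[j, match(hosts$loci[[j]], targeted)] <- 1
    E <- matrix(0, np, L)
    for (i in seq_len(np)) {
      hit <- match(intersect(phage$escaped[[i]], targeted), targeted)
      if (length(hit)) E[i, hit] <- 1
    }
    inf <- t(H %*% t(1 - E)) == 0
  }
  # cap realized infections of each host genotype at its actively growing
  # slice: stationary-phase cells are a refuge, so phage can at most burn
  # through the vulnerable fraction of a genotype per step
  act <- min(1, 4 * frac * max(0, 1 - frac)) * w
  inf_enc <- enc * inf
  tot_inf <- colSums(inf_enc)
  vulnerable <- hosts$n * act
  scale <- ifelse(tot_inf > vulnerable,
                  vulnerable / pmax(tot_inf, 1e-300), 1)
  realized <- sweep(inf_enc, 2, scale, `*`)
  # phage losses: adsorption to resistant hosts + consumed infecting particles
  phage$n <- phage$n - rowSums(enc * !inf) - rowSums(realized)
  phage$n <- pmax(phage$n, 0)
  # host losses: every infected cell leaves its genotype
  infected_h <- colSums(realized)
  hosts$n <- pmax(hosts$n - infected_h, 0)
  # survivors acquire one new spacer each (uniform over the catalog)
  survivors <- infected_h * config$acquisition_prob
  new_hosts <- list(loci = list(), n = numeric())
  for (j in seq_len(nh)) {
    if (survivors[j] < config$acquisition_threshold) next
    k <- min(config$innovation_slots, n_loci)
    picks <- sample.int(n_loci, k)
    for (l in picks) {
      new_hosts$loci[[length(new_hosts$loci) + 1L]] <-
        c(hosts$loci[[j]], l)
      new_hosts$n <- c(new_hosts$n, survivors[j] / k)
    }
  }
  # lysis progeny and escape-mutant spawning; only loci targeted by extant
  # host spacers are tracked as explicit mutant genotypes (mutations elsewhere
  # are phenotypically neutral and stay folded into the parent's count), and
  # at most mutation_slots loci per parent per step, chosen weighted by the
  # abundance of hosts carrying each locus (mutation supply is uniform, but
  # only these mutants have dynamical consequence).
  progeny <- config$burst_size * (1 - config$acquisition_prob) * rowSums(realized)
  loc_weight <- vapply(targeted, function(l) {
    sum(hosts$n[vapply(hosts$loci, function(x) l %in% x, logical(1))])
  }, numeric(1))
  new_phage <- list(snps = list(), escaped = list(), n = numeric())
  for (i in seq_len(np)) {
    if (progeny[i] <= 0) next
    m <- progeny[i] * config$mutation_prob
    if (m < config$mutant_threshold) {
      phage$n[i] <- phage$n[i] + progeny[i]
      next
    }
    keep_l <- !(targeted %in% phage$escaped[[i]]) & loc_weight > 0
    cand <- targeted[keep_l]
    mut_mass <- 0
    if (length(cand)) {
      k <- min(config$mutation_slots, length(cand))
      picks <- if (length(cand) == 1L) cand else
        sample(cand, k, prob = loc_weight[keep_l])
      for (l in picks) {
        snps_new <- dplyr::bind_rows(phage$snps[[i]], draw_snp(loci[l, ]))
        new_phage$snps[[length(new_phage$snps) + 1L]] <- snps_new
        new_phage$escaped[[length(new_phage$escaped) + 1L]] <-
          escaped_rows(snps_new, loci)
        new_phage$n <- c(new_phage$n, m)
        mut_mass <- mut_mass + m
      }
    }
    phage$n[i] <- phage$n[i] + progeny[i] - mut_mass
  }
  hosts <- merge_new_hosts(hosts, new_hosts)
  phage <- merge_new_phage(phage, new_phage)
  list(hosts = hosts, phage = phage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A SNP uniformly placed in the protospacer-plus-PAM interval of a locus.
# Ref/alt bases are resolved against the genome at clone-export time
# (finalize_snp_bases()); the state machine only needs the position.
draw_snp <- function(locus) {
  lo <- min(locus$start, locus$pam_start)
  hi <- max(locus$end, locus$pam_end)
  pos <- lo + sample.int(hi - lo, 1L) - 1L
  tibble::tibble(position = as.integer(pos), ref = NA_character_,
                 alt = NA_character_)
}

merge_new_hosts <- function(hosts, new_hosts) {
  if (!length(new_hosts$n)) return(hosts)
  keys <- vapply(new_hosts$loci, host_key, character(1))
  for (i in seq_along(keys)) {
    hit <- match(keys[i], hosts$key)
    if (!is.na(hit)) {
      hosts$n[hit] <- hosts$n[hit] + new_hosts$n[i]
    } else {
      hosts$key <- c(hosts$key, keys[i])
      hosts$loci <- c(hosts$loci, new_hosts$loci[i])
      hosts$n <- c(hosts$n, new_hosts$n[i])
    }
  }
  hosts
}

merge_new_phage <- function(phage, new_phage) {
  if (!length(new_phage$n)) return(phage)
  keys <- vapply(new_phage$snps,
                 function(s) paste(sort(s$position), collapse = ";"),
                 character(1))
  for (i in seq_along(keys)) {
    hit <- match(keys[i], phage$key)
    if (!is.na(hit)) {
      phage$n[hit] <- phage$n[hit] + new_phage$n[i]
    } else {
      phage$key <- c(phage$key, keys[i])
      phage$snps <- c(phage$snps, new_phage$snps[i])
      phage$escaped <- c(phage$escaped, new_phage$escaped[i])
      phage$n <- c(phage$n, new_phage$n[i])
    }
  }
  phage
}

# Fill in ref/alt bases for simulator-drawn SNPs from the genome sequence.
finalize_snp_bases <- function(snps, genome, rng) {
  if (nrow(snps) == 0L) return(snps)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(snps))) {
    if (is.na(snps$ref[i])) {
      refb <- substr(genome$sequence, snps$position[i] + 1L,
                     snps$position[i] + 1L)
      snps$ref[i] <- refb
      snps$alt[i] <- sample(setdiff(bases, refb), 1L)
    }
  }
  snps
}

#' Sample clones from a recorded population state
#'
#' Multinomial sampling of clone genotypes proportional to abundance,
#' emulating picking random colonies and plaques at a time point.
#'
#' @param state One element of a `coevo_run`'s `states` list.
#' @param genome The `phage_ref` used in the simulation (needed to resolve
#'   spacer sequences and SNP ref/alt bases).
#' @param n_host,n_phage Clones to draw (default 12 each).
#' @param rng_seed Integer seed; deterministic per seed.
#' @param replicate,dpi Metadata stamped on the clones.
#' @return A list with tibbles `hosts` (`clone_id`, `replicate`, `dpi`,
#'   `genotype_key`, `spacers` list-column) and `phages` (`clone_id`,
#'   `replicate`, `dpi`, `genotype_key`, `snps` list-column).
#' @export
sample_clones <- function(state, genome, n_host = 12L, n_phage = 12L,
                          rng_seed = 1L, replicate = "R1", dpi = state$day) {
  withr_seed(rng_seed)
  if (n_host > 0 && (nrow(state$hosts) == 0L || sum(state$hosts$n) <= 0)) {
    stop("cannot sample hosts: population empty", call. = FALSE)
  }
  if (n_phage > 0 && (nrow(state$phage) == 0L || sum(state$phage$n) <= 0)) {
    stop("cannot sample phage: population empty", call. = FALSE)
  }
  loci <- genome$loci
  hosts <- NULL
  if (n_host > 0) {
    idx <- sample.int(nrow(state$hosts), n_host, replace = TRUE,
                      prob = state$hosts$n)
    hosts <- tibble::tibble(
      clone_id = sprintf("%s_d%d_H%02d", replicate, dpi, seq_len(n_host)),
      replicate = replicate, dpi = as.integer(dpi),
      genotype_key = state$hosts$genotype_key[idx],
      spacers = lapply(idx, function(i) {
        li <- state$hosts$loci[[i]]
        tibble::tibble(crispr_system = loci$crispr_system[li],
                       locus_id = loci$locus_id[li],
                       spacer = loci$protospacer[li])
      })
    )
  }
  phages <- NULL
  if (n_phage > 0) {
    idx <- sample.int(nrow(state$phage), n_phage, replace = TRUE,
                      prob = state$phage$n)
    phages <- tibble::tibble(
      clone_id = sprintf("%s_d%d_P%02d", replicate, dpi, seq_len(n_phage)),
      replicate = replicate, dpi = as.integer(dpi),
      genotype_key = state$phage$genotype_key[idx],
      snps = lapply(idx, function(i) {
        finalize_snp_bases(state$phage$snps[[i]], genome)
      })
    )
    phages$genotype_key <- vapply(phages$snps, snp_key, character(1))
  }
  list(hosts = hosts, phages = phages)
}

#' Summarize time to phage extinction across replicates
#'
#' @param trajectories Either a list of `coevo_run` objects or a tibble with
#'   columns `replicate` and `extinction_day` (`NA` = persisted to the end).
#' @return A one-row tibble: `n`, `n_extinct`, `n_censored`, `mean_day`,
#'   `se_day` (`NA` when no replicate went extinct).
#' @export
time_to_extinction_summary <- function(trajectories) {
  if (is.list(trajectories) && !is.data.frame(trajectories) &&
      all(vapply(trajectories, inherits, logical(1), "coevo_run"))) {
    days <- vapply(trajectories, function(r) {
      as.integer(r$extinction_day %||% NA_integer_)
    }, integer(1))
  } else {
    stopifnot(is.data.frame(trajectories),
              "extinction_day" %in% names(trajectories))
    days <- trajectories$extinction_day
  }
  if (length(days) == 0L) stop("need at least one trajectory", call. = FALSE)
  ext <- days[!is.na(days)]
  tibble::tibble(
    n = length(days),
    n_extinct = length(ext),
    n_censored = sum(is.na(days)),
    mean_day = if (length(ext)) mean(ext) else NA_real_,
    se_day = if (length(ext) > 1) stats::sd(ext) / sqrt(length(ext))
             else if (length(ext) == 1) NA_real_ else NA_real_
  )
}

#' Find the extinction day in a PFU series
#'
#' The first day of the first run of `window` consecutive days with titres
#' below the detection limit, or `NA` if no such run occurs.
#'
#' @param pfu Numeric vector of daily PFU/ml, day 1 first.
#' @param detection_limit Detection limit (PFU/ml).
#' @param window Run length defining extinction (days).
#' @return Integer day or `NA`.
#' @export
detect_extinction_day <- function(pfu, detection_limit = 200, window = 4L) {
  below <- pfu < detection_limit
  run <- 0L
  for (d in seq_along(below)) {
    run <- if (below[d]) run + 1L else 0L
    if (run >= window) return(as.integer(d - window + 1L))
  }
  NA_integer_
}

#' Simulate a full clone-panel experiment
#'
#' Runs `n_replicates` independent serial-transfer co-cultures, retains up to
#' `keep` replicates in which phage persisted through the last sampling day
#' (mirroring the experimental selection of replicates with at least 9 days of
#' coexistence), samples `n_clones` host and phage clones at each sampling
#' day, predicts the full infection matrix from the genotypes and overlays
#' phenotype noise.
#'
#' @param config A [sim_config()].
#' @param n_replicates Co-cultures to run.
#' @param dpi Sampling days (default `c(1, 4, 9)`).
#' @param n_clones Clones of each kind per replicate per day.
#' @param keep Maximum replicates retained for clone work.
#' @param rng_seed Root seed; every replicate and stage draws from a child
#'   seed derived from it.
#' @param genome Optional `phage_ref`; built from `config` when `NULL`.
#' @return A list of class `coevo_panel`: `genome`, `config`, `runs` (all
#'   `coevo_run`s), `trajectory` (bound tibble), `extinctions` (tibble),
#'   `hosts`, `phages` (clone tibbles over retained replicates), `predicted`
#'   and `measured` (long infection tibbles), `kept_replicates`, `root_seed`,
#'   `child_seeds`.
#' @export
simulate_panel <- function(config = sim_config(), n_replicates = 12L,
                           dpi = c(1L, 4L, 9L), n_clones = 12L, keep = 8L,
                           rng_seed = 1L, genome = NULL) {
  if (max(dpi) > config$days) {
    stop("sampling day ", max(dpi), " lies beyond the ", config$days,
         " simulated days", call. = FALSE)
  }
  withr_seed(rng_seed)
  child <- sample.int(.Machine$integer.max - 1L, n_replicates + 2L)
  if (is.null(genome)) {
    genome <- build_reference_genome(config$genome_length,
                                     pam_motifs = config$pam_motifs,
                                     spacer_length = config$spacer_length,
                                     seed_length = config$seed_length,
                                     rng_seed = child[n_replicates + 1L])
  }
  reps <- sprintf("R%02d", seq_len(n_replicates))
  runs <- lapply(seq_len(n_replicates), function(i) {
    run_serial_transfer(genome, config, rng_seed = child[i],
                        replicate = reps[i])
  })
  names(runs) <- reps
  persisted <- vapply(runs, function(r) {
    all(r$trajectory$pfu_per_ml[dpi] > 0) &&
      all(vapply(dpi, function(d) sum(r$states[[d]]$phage$n) > 0, logical(1)))
  }, logical(1))
  kept <- reps[persisted][seq_len(min(keep, sum(persisted)))]
  hosts <- list()
  phages <- list()
  for (r in kept) {
    for (d in dpi) {
      cl <- sample_clones(runs[[r]]$states[[d]], genome,
                          n_host = n_clones, n_phage = n_clones,
                          rng_seed = (child[match(r, reps)] + 7L * d) %%
                            .Machine$integer.max,
                          replicate = r, dpi = d)
      hosts[[length(hosts) + 1L]] <- cl$hosts
      phages[[length(phages) + 1L]] <- cl$phages
    }
  }
  hosts <- if (length(hosts)) dplyr::bind_rows(hosts) else NULL
  phages <- if (length(phages)) dplyr::bind_rows(phages) else NULL
  predicted <- if (!is.null(hosts)) predict_matrix(hosts, phages, genome)
               else NULL
  measured <- if (!is.null(predicted)) {
    simulate_measured_matrix(predicted, fn_rate = config$fn_rate,
                             fp_rate = config$fp_rate,
                             rng_seed = child[n_replicates + 2L])
  } else NULL
  extinctions <- tibble::tibble(
    replicate = reps,
    extinction_day = vapply(runs, function(r) {
      as.integer(r$extinction_day %||% NA_integer_)
    }, integer(1))
  )
  structure(list(
    genome = genome, config = config, runs = runs,
    trajectory = dplyr::bind_rows(lapply(runs, `[[`, "trajectory")),
    extinctions = extinctions,
    hosts = hosts, phages = phages,
    predicted = predicted, measured = measured,
    kept_replicates = kept, root_seed = as.integer(rng_seed),
    child_seeds = child
  ), class = "coevo_panel")
}

#' @export
print.coevo_panel <- function(x, ...) {
  cat("<coevo_panel> ", length(x$runs), " runs, ", length(x$kept_replicates),
      " kept; ", if (!is.null(x$hosts)) nrow(x$hosts) else 0, " host clones, ",
      if (!is.null(x$phages)) nrow(x$phages) else 0, " phage clones, ",
      if (!is.null(x$predicted)) nrow(x$predicted) else 0,
      " predicted challenges\n", sep = "")
  invisible(x)
}
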