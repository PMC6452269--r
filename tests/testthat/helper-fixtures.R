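# Shared fixtures, built in code.

# A genome with known planted protospacer+PAM sites on a fixed background of
# a single repeated non-motif base pattern, so the catalog is fully
# predictable. PAM motifs are the type II-A defaults.
planted_genome <- function(spacer_length = 30L, seed_length = 10L) {
  # background free of AGAAA/AGAAT (CRISPR1 core) and GG (CRISPR3 core)
  bg <- function(n) paste(rep_len(c("A", "C", "T", "C"), n), collapse = "")
  spacer1 <- paste(rep_len(c("A", "C"), spacer_length), collapse = "")
  spacer3 <- paste(rep_len(c("T", "C"), spacer_length), collapse = "")
  seqn <- paste0(bg(50), spacer1, "TTAGAAA",   # CRISPR1 PAM (NNAGAAW)
                 bg(40), spacer3, "TGGTG",     # CRISPR3 PAM (NGGNG)
                 bg(50))
  phage_ref_from_sequence(seqn, spacer_length = spacer_length,
                          seed_length = seed_length,
                          genome_id = "planted")
}

# small random genome with a decent catalog
small_genome <- function(length = 4000L, rng_seed = 99L) {
  build_reference_genome(length, rng_seed = rng_seed)
}

host_clone <- function(genome, locus_rows, clone_id = "H1", replicate = "R1",
                       dpi = 4L) {
  loci <- genome$loci[locus_rows, , drop = FALSE]
  tibble::tibble(
    clone_id = clone_id, replicate = replicate, dpi = as.integer(dpi),
    genotype_key = paste(loci$locus_id, collapse = "|"),
    spacers = list(tibble::tibble(crispr_system = loci$crispr_system,
                                  locus_id = loci$locus_id,
                                  spacer = loci$protospacer))
  )
}

phage_clone <- function(positions, genome = NULL, clone_id = "P1",
                        replicate = "R1", dpi = 4L) {
  snps <- if (length(positions) == 0) {
    tibble::tibble(position = integer(), ref = character(), alt = character())
  } else {
    ref <- if (is.null(genome)) rep("A", length(positions)) else
      vapply(positions, function(p) substr(genome$sequence, p + 1, p + 1),
             character(1))
    alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                  character(1), USE.NAMES = FALSE)
    tibble::tibble(position = as.integer(positions), ref = ref, alt = alt)
  }
  tibble::tibble(clone_id = clone_id, replicate = replicate,
                 dpi = as.integer(dpi), genotype_key = "k", snps = list(snps))
}

# random clone panel over a genome: n_host hosts with 0..3 spacers, n_phage
# phages with 0..4 SNPs placed in/near random loci
random_panel <- function(genome, n_host = 6L, n_phage = 6L, replicate = "R1") {
  n_loci <- nrow(genome$loci)
  hosts <- dplyr::bind_rows(lapply(seq_len(n_host), function(i) {
    k <- sample(0:3, 1)
    rows <- if (k > 0) sample.int(n_loci, k) else integer()
    host_clone(genome, rows, clone_id = sprintf("H%02d", i),
               replicate = replicate, dpi = sample(c(1L, 4L, 9L), 1))
  }))
  phages <- dplyr::bind_rows(lapply(seq_len(n_phage), function(i) {
    k <- sample(0:4, 1)
    pos <- if (k > 0) {
      rows <- sample.int(n_loci, k, replace = TRUE)
      vapply(rows, function(r) {
        lo <- min(genome$loci$start[r], genome$loci$pam_start[r])
        hi <- max(genome$loci$end[r], genome$loci$pam_end[r])
        as.integer(sample(lo:(hi - 1), 1))
      }, integer(1))
    } else integer()
    phage_clone(unique(pos), genome, clone_id = sprintf("P%02d", i),
                replicate = replicate, dpi = sample(c(1L, 4L, 9L), 1))
  }))
  list(hosts = hosts, phages = phages)
}

# brute-force per-pair infection oracle, written independently of the
# package's vectorized path: direct interval checks per (spacer, SNP)
oracle_infects <- function(phage_row, host_row, genome) {
  sp <- host_row$spacers[[1]]
  if (nrow(sp) == 0) return(TRUE)
  snps <- phage_row$snps[[1]]
  for (i in seq_len(nrow(sp))) {
    loc <- genome$loci[genome$loci$protospacer == sp$spacer[i], ]
    stopifnot(nrow(loc) == 1)
    escaped <- FALSE
    for (p in snps$position) {
      in_seed <- p >= loc$seed_start && p < loc$seed_end
      in_pam <- p >= loc$pam_start && p < loc$pam_end
      if (in_seed || in_pam) escaped <- TRUE
    }
    if (!escaped) return(FALSE)
  }
  TRUE
}

# tiny infection tibble built from an explicit 0/1 matrix
matrix_tbl <- function(m, replicate = "R1",
                       host_dpi = rep(1L, nrow(m)),
                       phage_dpi = rep(1L, ncol(m))) {
  hosts <- sprintf("H%02d", seq_len(nrow(m)))
  phages <- sprintf("P%02d", seq_len(ncol(m)))
  grid <- expand.grid(hi = seq_len(nrow(m)), pj = seq_len(ncol(m)))
  tibble::tibble(replicate = replicate,
                 host_clone = hosts[grid$hi],
                 host_dpi = as.integer(host_dpi[grid$hi]),
                 phage_clone = phages[grid$pj],
                 phage_dpi = as.integer(phage_dpi[grid$pj]),
                 infected = as.integer(m[cbind(grid$hi, grid$pj)]))
}
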