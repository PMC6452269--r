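#' Call SNPs between a clone region and the reference region
#'
#' Position-wise comparison of two equal-length sequences (indels are out of
#' scope); mismatches are reported as genome-coordinate SNPs.
#'
#' @param clone_region,reference_region Equal-length DNA strings.
#' @param region_offset 0-based genome coordinate of the first position of
#'   the region.
#' @return A tibble: `position` (0-based genome coordinate), `ref`, `alt`.
#' @export
call_snps <- function(clone_region, reference_region, region_offset = 0L) {
  clone_region <- toupper(clone_region)
  reference_region <- toupper(reference_region)
  if (nchar(clone_region) != nchar(reference_region)) {
    stop("alignment error: clone region (", nchar(clone_region),
         " nt) and reference region (", nchar(reference_region),
         " nt) differ in length", call. = FALSE)
  }
  a <- strsplit(clone_region, "")[[1]]
  b <- strsplit(reference_region, "")[[1]]
  hit <- which(a != b)
  tibble::tibble(position = as.integer(region_offset + hit - 1L),
                 ref = b[hit], alt = a[hit])
}

#' Classify SNPs relative to a protospacer locus
#'
#' Labels each SNP by its position against the locus geometry, testing the
#' intervals in priority order PAM > seed > protospacer-outside-seed >
#' outside, and summarises the clone-locus combination by the
#' highest-priority label present (`"none"` when the SNP set is empty).
#'
#' @param snps SNP tibble (`position` column; may be empty).
#' @param locus One catalog row.
#' @return A list with `per_snp` (tibble `position`, `class`) and `summary`
#'   (one of `"none"`, `"pam"`, `"seed"`, `"protospacer_nonseed"`,
#'   `"outside"`).
#' @export
classify_mutations <- function(snps, locus) {
  priority <- c("pam", "seed", "protospacer_nonseed", "outside")
  if (is.null(snps) || nrow(snps) == 0L) {
    return(list(per_snp = tibble::tibble(position = integer(),
                                         class = character()),
                summary = "none"))
  }
  cls <- vapply(snps$position, function(p) {
    if (p >= locus$pam_start && p < locus$pam_end) "pam"
    else if (p >= locus$seed_start && p < locus$seed_end) "seed"
    else if (p >= locus$start && p < locus$end) "protospacer_nonseed"
    else "outside"
  }, character(1))
  list(per_snp = tibble::tibble(position = snps$position, class = cls),
       summary = priority[min(match(cls, priority))])
}

#' Predicted-versus-measured contingency table
#'
#' Cross-tabulates every challenge of a predicted and a measured infection
#' matrix over the same clones, with the derived concordance
#' `(n00 + n11) / total` and positive predictive value `n11 / (n10 + n11)`.
#'
#' @param predicted,measured Long infection tibbles over identical clone
#'   pairs (matched by replicate and clone ids).
#' @return A list of class `contingency_2x2`: `counts` (named
#'   `n_pred0_meas0`, `n_pred0_meas1`, `n_pred1_meas0`, `n_pred1_meas1`),
#'   `total`, `concordance`, `predictive_value`.
#' @export
contingency_analysis <- function(predicted, measured) {
  check_infection_tbl(predicted)
  check_infection_tbl(measured)
  key <- function(x) paste(x$replicate, x$host_clone, x$phage_clone)
  if (nrow(predicted) != nrow(measured) ||
      !all(sort(key(predicted)) == sort(key(measured)))) {
    stop("predicted and measured matrices cover different challenges",
         call. = FALSE)
  }
  m <- measured$infected[match(key(predicted), key(measured))]
  p <- predicted$infected
  counts <- c(n_pred0_meas0 = sum(p == 0 & m == 0),
              n_pred0_meas1 = sum(p == 0 & m == 1),
              n_pred1_meas0 = sum(p == 1 & m == 0),
              n_pred1_meas1 = sum(p == 1 & m == 1))
  total <- sum(counts)
  structure(list(
    counts = counts, total = total,
    concordance = unname((counts["n_pred0_meas0"] + counts["n_pred1_meas1"]) /
                           total),
    predictive_value = unname(counts["n_pred1_meas1"] /
                                (counts["n_pred1_meas0"] +
                                   counts["n_pred1_meas1"]))
  ), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  tab <- matrix(x$counts, 2, 2, byrow = TRUE,
                dimnames = list(predicted = c("-", "+"),
                                measured = c("-", "+")))
  print(tab)
  cat(sprintf("concordance %.3f, predictive value %.3f (n = %d)\n",
              x$concordance, x$predictive_value, x$total))
  invisible(x)
}

#' @rdname contingency_analysis
#' @param x A `contingency_2x2`.
#' @param ... Unused.
#' @export
tidy.contingency_2x2 <- function(x, ...) {
  tibble::tibble(predicted = c(0L, 0L, 1L, 1L), measured = c(0L, 1L, 0L, 1L),
                 n = unname(x$counts))
}

#' @rdname contingency_analysis
#' @export
glance.contingency_2x2 <- function(x, ...) {
  tibble::tibble(total = x$total, concordance = x$concordance,
                 predictive_value = x$predictive_value)
}

# classify each phage clone against the loci its hosts' spacers target:
# does it carry any protospacer-associated (pam or seed) SNP at any catalog
# locus?
phage_snp_status <- function(phages, genome) {
  vapply(seq_len(nrow(phages)), function(i) {
    snps <- phage_snps(phages[i, ])
    if (nrow(snps) == 0L) return("none")
    if (length(escaped_locus_ids(snps, genome)) > 0L) "protospacer_associated"
    else "random"
  }, character(1))
}

#' Infectivity grouped by SNP status and by unevolved-target count
#'
#' Groups each challenge of a measured (or predicted) infection matrix by
#' (a) whether the phage clone carries a protospacer-associated SNP (seed or
#' PAM at any catalog locus) versus no SNP at all, and (b) the number of the
#' host's spacer targets the phage has not escaped, and reports per-group
#' mean infection proportions with percentile bootstrap CIs (challenges
#' resampled within group). Empty groups are dropped with a warning.
#'
#' @param phages,hosts Clone tibbles.
#' @param matrices Long infection tibble over those clones.
#' @param genome A `phage_ref`.
#' @param spec A [bootstrap_spec()].
#' @return A list of class `snp_status_summary` with tibbles `by_status`
#'   (`status`, `mean`, `ci_low`, `ci_high`, `n_challenges`) and `by_targets`
#'   (`unevolved_targets`, `mean`, `ci_low`, `ci_high`, `n_challenges`).
#' @export
infectivity_by_snp_status <- function(phages, hosts, matrices, genome,
                                      spec = bootstrap_spec()) {
  if (is.list(matrices) && !is.data.frame(matrices)) {
    matrices <- dplyr::bind_rows(matrices)
  }
  check_infection_tbl(matrices)
  status <- tibble::tibble(phage_clone = phages$clone_id,
                           replicate = phages$replicate,
                           status = phage_snp_status(phages, genome))
  m <- dplyr::left_join(matrices, status, by = c("replicate", "phage_clone"))
  if (anyNA(m$status)) {
    stop("matrix references phage clones absent from the clone table",
         call. = FALSE)
  }
  # unevolved-target count per challenge
  host_ix <- match(paste(m$replicate, m$host_clone),
                   paste(hosts$replicate, hosts$clone_id))
  phage_ix <- match(paste(m$replicate, m$phage_clone),
                    paste(phages$replicate, phages$clone_id))
  if (anyNA(host_ix) || anyNA(phage_ix)) {
    stop("matrix references clones absent from the clone tables",
         call. = FALSE)
  }
  h_loci <- lapply(seq_len(nrow(hosts)), function(i) {
    sp <- host_spacers(hosts[i, ])
    if (nrow(sp) == 0L) character() else
      vapply(sp$spacer, function(s) find_protospacer(genome, s)$locus_id,
             character(1), USE.NAMES = FALSE)
  })
  p_escaped <- lapply(seq_len(nrow(phages)), function(j) {
    escaped_locus_ids(phage_snps(phages[j, ]), genome)
  })
  m$unevolved_targets <- mapply(function(hi, pj) {
    sum(!(h_loci[[hi]] %in% p_escaped[[pj]]))
  }, host_ix, phage_ix)

  withr_seed(spec$rng_seed)
  boot_group <- function(tbl, var) {
    groups <- split(tbl, tbl[[var]], drop = TRUE)
    dplyr::bind_rows(lapply(groups, function(g) {
      if (nrow(g) == 0L) return(NULL)
      draws <- vapply(seq_len(spec$reps), function(b) {
        mean(sample(g$infected, nrow(g), replace = TRUE))
      }, numeric(1))
      out <- tibble::tibble(mean = mean(g$infected),
                            ci_low = stats::quantile(draws, spec$alpha / 2,
                                                     names = FALSE),
                            ci_high = stats::quantile(draws,
                                                      1 - spec$alpha / 2,
                                                      names = FALSE),
                            n_challenges = nrow(g))
      out[[var]] <- g[[var]][1]
      dplyr::relocate(out, dplyr::all_of(var))
    }))
  }
  by_status <- boot_group(m[m$status %in% c("none", "protospacer_associated"),
                            , drop = FALSE], "status")
  if (any(m$status == "random")) {
    warning(sum(m$status == "random"),
            " challenge(s) with only non-seed/non-PAM SNPs omitted from the ",
            "status contrast", call. = FALSE)
  }
  by_targets <- boot_group(m, "unevolved_targets")
  by_targets$unevolved_targets <- as.integer(by_targets$unevolved_targets)
  structure(list(by_status = by_status, by_targets = by_targets),
            class = "snp_status_summary")
}

#' @export
print.snp_status_summary <- function(x, ...) {
  cat("<snp_status_summary>\nBy SNP status:\n")
  print(as.data.frame(x$by_status), row.names = FALSE)
  cat("By unevolved-target count:\n")
  print(as.data.frame(x$by_targets), row.names = FALSE)
  invisible(x)
}
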