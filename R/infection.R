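#' Locate the protospacer targeted by a spacer
#'
#' Exact-match search of a spacer against the catalog of PAM-flanked
#' protospacer loci of a reference genome. Minus-strand loci are matched via
#' the reverse complement, so the spacer always equals the locus's
#' strand-oriented `protospacer` sequence. Near-matches are not tolerated:
#' a spacer that matches no catalog protospacer returns `NULL`, and a spacer
#' matching more than one distinct locus raises an ambiguity error rather than
#' silently picking one.
#'
#' @param genome A `phage_ref`.
#' @param spacer Spacer sequence (character scalar, same length as the
#'   catalog's protospacers).
#' @return A one-row tibble (the catalog row) or `NULL` when absent.
#' @export
find_protospacer <- function(genome, spacer) {
  stopifnot(inherits(genome, "phage_ref"))
  spacer <- toupper(spacer)
  if (nchar(spacer) != genome$spacer_length) {
    stop("spacer length ", nchar(spacer), " != configured length ",
         genome$spacer_length, call. = FALSE)
  }
  hit <- genome$loci[genome$loci$protospacer == spacer, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  if (nrow(hit) > 1L) {
    stop("spacer ", spacer, " matches ", nrow(hit),
         " distinct catalog loci (", paste(hit$locus_id, collapse = ", "),
         "); ambiguous mapping", call. = FALSE)
  }
  hit
}

# Positions (0-based) whose mutation abolishes interference for a locus row:
# the seed window union the PAM interval.
escape_positions <- function(locus) {
  c(seq.int(locus$seed_start, locus$seed_end - 1L),
    seq.int(locus$pam_start, locus$pam_end - 1L))
}

#' Does a phage clone escape a given spacer's locus?
#'
#' A phage escapes a spacer when it carries at least one SNP inside the
#' locus's seed window or PAM. SNPs elsewhere in the protospacer do not
#' confer escape (they are classified by [classify_mutations()] but are inert
#' here).
#'
#' @param phage One row of a phage clone tibble, or any list with an element
#'   `snps`: a tibble with a 0-based `position` column (possibly empty).
#' @param locus A one-row tibble from the genome catalog.
#' @return Logical scalar.
#' @export
escapes_spacer <- function(phage, locus) {
  snps <- phage_snps(phage)
  if (nrow(snps) == 0L) return(FALSE)
  any(snps$position %in% escape_positions(locus))
}

phage_snps <- function(phage) {
  snps <- phage$snps
  if (is.list(snps) && !is.data.frame(snps)) snps <- snps[[1]]
  if (is.null(snps)) snps <- empty_snps()
  snps
}

empty_snps <- function() {
  tibble::tibble(position = integer(), ref = character(), alt = character())
}

host_spacers <- function(host) {
  sp <- host$spacers
  if (is.list(sp) && !is.data.frame(sp)) sp <- sp[[1]]
  if (is.null(sp)) sp <- tibble::tibble(crispr_system = character(),
                                        locus_id = character(),
                                        spacer = character())
  sp
}

#' Predict the outcome of one phage x host challenge
#'
#' Mechanistic genotype-to-phenotype rule: the phage is predicted to infect a
#' host iff it escapes (seed or PAM SNP) *every* acquired spacer in the host's
#' CRISPR arrays. Hosts with no acquired spacers are always predicted
#' infected: the wild-type arrays carry no spacer complementary to the phage.
#'
#' @param phage One row of a phage clone tibble (with `snps` list-column).
#' @param host One row of a host clone tibble (with `spacers` list-column
#'   carrying a `spacer` sequence column).
#' @param genome A `phage_ref`; every acquired spacer must map to its catalog
#'   (an unmappable spacer is an error naming the offending sequence).
#' @return Logical scalar: `TRUE` = infection predicted.
#' @seealso [count_unevolved_targets()], which this equals zero of.
#' @export
predict_infection <- function(phage, host, genome) {
  count_unevolved_targets(phage, host, genome) == 0L
}

#' Count a host's spacer targets the phage has not escaped
#'
#' The number of the host's acquired spacers whose protospacer loci carry no
#' phage SNP in the seed or PAM. Zero iff [predict_infection()] is `TRUE`.
#'
#' @inheritParams predict_infection
#' @return Non-negative integer.
#' @export
count_unevolved_targets <- function(phage, host, genome) {
  sp <- host_spacers(host)
  if (nrow(sp) == 0L) return(0L)
  snps <- phage_snps(phage)
  unescaped <- 0L
  for (i in seq_len(nrow(sp))) {
    locus <- find_protospacer(genome, sp$spacer[i])
    if (is.null(locus)) {
      stop("spacer ", sp$spacer[i], " does not map to any catalog locus",
           call. = FALSE)
    }
    hit <- nrow(snps) > 0L && any(snps$position %in% escape_positions(locus))
    if (!hit) unescaped <- unescaped + 1L
  }
  unescaped
}

#' Predict a full infection matrix from clone genotypes
#'
#' Applies [predict_infection()] to every host x phage pair within each
#' replicate, returning the matrix in long (tidy) form.
#'
#' @param hosts Host clone tibble: `clone_id`, `replicate`, `dpi`, `spacers`
#'   list-column.
#' @param phages Phage clone tibble: `clone_id`, `replicate`, `dpi`, `snps`
#'   list-column.
#' @param genome A `phage_ref`.
#' @return A tibble with one row per challenge: `replicate`, `host_clone`,
#'   `host_dpi`, `phage_clone`, `phage_dpi`, `infected` (integer 0/1).
#' @export
predict_matrix <- function(hosts, phages, genome) {
  stopifnot(all(c("clone_id", "replicate", "dpi") %in% names(hosts)),
            all(c("clone_id", "replicate", "dpi") %in% names(phages)))
  out <- vector("list", length(unique(hosts$replicate)))
  reps <- sort(unique(hosts$replicate))
  for (k in seq_along(reps)) {
    h <- hosts[hosts$replicate == reps[k], , drop = FALSE]
    p <- phages[phages$replicate == reps[k], , drop = FALSE]
    # precompute per-host locus sets and per-phage escaped locus sets
    h_loci <- lapply(seq_len(nrow(h)), function(i) {
      sp <- host_spacers(h[i, ])
      if (nrow(sp) == 0L) return(character())
      vapply(sp$spacer, function(s) {
        locus <- find_protospacer(genome, s)
        if (is.null(locus)) {
          stop("spacer ", s, " does not map to any catalog locus",
               call. = FALSE)
        }
        locus$locus_id
      }, character(1), USE.NAMES = FALSE)
    })
    p_escaped <- lapply(seq_len(nrow(p)),
                        function(j) escaped_locus_ids(phage_snps(p[j, ]), genome))
    grid <- tidyr::expand_grid(hi = seq_len(nrow(h)), pj = seq_len(nrow(p)))
    grid$infected <- as.integer(mapply(function(hi, pj) {
      all(h_loci[[hi]] %in% p_escaped[[pj]])
    }, grid$hi, grid$pj))
    out[[k]] <- tibble::tibble(
      replicate = reps[k],
      host_clone = h$clone_id[grid$hi], host_dpi = h$dpi[grid$hi],
      phage_clone = p$clone_id[grid$pj], phage_dpi = p$dpi[grid$pj],
      infected = grid$infected
    )
  }
  dplyr::bind_rows(out)
}

# Locus ids of every catalog locus whose seed/PAM region contains >=1 SNP.
escaped_locus_ids <- function(snps, genome) {
  if (nrow(snps) == 0L) return(character())
  loci <- genome$loci
  pos <- snps$position
  in_seed <- vapply(seq_len(nrow(loci)), function(i) {
    any(pos >= loci$seed_start[i] & pos < loci$seed_end[i]) ||
      any(pos >= loci$pam_start[i] & pos < loci$pam_end[i])
  }, logical(1))
  loci$locus_id[in_seed]
}

#' Overlay phenotype noise on a predicted infection matrix
#'
#' Flips each predicted-infective cell to resistant with probability `fn_rate`
#' and each predicted-resistant cell to infective with probability `fp_rate`,
#' independently per cell. The default rates are calibrated to the observed
#' discordance between sequence-predicted and plate-measured infections
#' (107/348 predicted infections not measured; 106/348 measured infections not
#' predicted), attributed to partial CRISPR interference and assay error.
#'
#' @param predicted Long infection tibble from [predict_matrix()].
#' @param fn_rate Probability a predicted 1 is measured as 0.
#' @param fp_rate Probability a predicted 0 is measured as 1.
#' @param rng_seed Integer seed; deterministic per seed.
#' @return A tibble of the same shape with `infected` resampled.
#' @export
simulate_measured_matrix <- function(predicted, fn_rate = 107 / 348,
                                     fp_rate = 106 / 348, rng_seed = 1L) {
  stopifnot(fn_rate >= 0, fn_rate <= 1, fp_rate >= 0, fp_rate <= 1,
            all(predicted$infected %in% c(0L, 1L)))
  withr_seed(rng_seed)
  flip_p <- ifelse(predicted$infected == 1L, fn_rate, fp_rate)
  flip <- stats::runif(nrow(predicted)) < flip_p
  out <- predicted
  out$infected <- as.integer(ifelse(flip, 1L - predicted$infected,
                                    predicted$infected))
  out
}
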