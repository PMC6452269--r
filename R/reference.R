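#' Build a random phage reference genome with a protospacer catalog
#'
#' Generates a random DNA sequence and catalogs every PAM-flanked protospacer
#' locus on both strands, mimicking a lytic phage genome as seen by a type II-A
#' CRISPR-Cas host. A protospacer is the `spacer_length`-nt window immediately
#' 5' of a PAM match on the PAM's strand; the seed window is the
#' `seed_length` PAM-proximal nucleotides of the protospacer. All coordinates
#' are 0-based half-open on the plus strand; minus-strand loci carry
#' `strand == "-"` with plus-strand coordinates.
#'
#' @param length Genome length in nucleotides.
#' @param pam_motifs Named character vector of IUPAC PAM motifs, one per CRISPR
#'   system, e.g. `c(CRISPR1 = "NNAGAAW", CRISPR3 = "NGGNG")`.
#' @param spacer_length Protospacer (= spacer) length in nt.
#' @param seed_length Seed-window length in nt (PAM-proximal).
#' @param rng_seed Integer seed; the genome and catalog are deterministic per
#'   seed.
#' @param genome_id Identifier stored with the genome.
#'
#' @return An object of class `phage_ref`: a list with elements `genome_id`,
#'   `sequence` (uppercase character scalar) and `loci`, a tibble with one row
#'   per catalog locus (`locus_id`, `start`, `end`, `strand`, `pam_start`,
#'   `pam_end`, `seed_start`, `seed_end`, `crispr_system`, `protospacer`).
#' @export
#' @examples
#' ref <- build_reference_genome(5000, rng_seed = 1)
#' nrow(ref$loci)
build_reference_genome <- function(length,
                                   pam_motifs = c(CRISPR1 = "NNAGAAW",
                                                  CRISPR3 = "NGGNG"),
                                   spacer_length = 30L,
                                   seed_length = 10L,
                                   rng_seed = 1L,
                                   genome_id = "synthetic_phage") {
  max_pam <- max(nchar(pam_motifs))
  if (length < spacer_length + max_pam) {
    stop("genome length (", length, ") must be at least spacer_length + ",
         "longest PAM (", spacer_length + max_pam, ")", call. = FALSE)
  }
  stopifnot(seed_length <= spacer_length, !is.null(names(pam_motifs)))
  withr_seed(rng_seed)
  sequence <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
  new_phage_ref(genome_id, sequence, pam_motifs, spacer_length, seed_length)
}

#' Construct a `phage_ref` from a given sequence
#'
#' Catalogs PAM-flanked protospacer loci in an explicitly supplied genome
#' sequence. Lowercase input is normalized to uppercase.
#'
#' @inheritParams build_reference_genome
#' @param sequence DNA string over `{A,C,G,T}`.
#' @return A `phage_ref` (see [build_reference_genome()]).
#' @export
phage_ref_from_sequence <- function(sequence,
                                    pam_motifs = c(CRISPR1 = "NNAGAAW",
                                                   CRISPR3 = "NGGNG"),
                                    spacer_length = 30L,
                                    seed_length = 10L,
                                    genome_id = "user_phage") {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L || grepl("[^ACGT]", sequence)) {
    stop("sequence must be a non-empty string over {A,C,G,T}", call. = FALSE)
  }
  new_phage_ref(genome_id, sequence, pam_motifs, spacer_length, seed_length)
}

new_phage_ref <- function(genome_id, sequence, pam_motifs, spacer_length,
                          seed_length) {
  loci <- scan_protospacer_loci(sequence, pam_motifs, spacer_length, seed_length)
  structure(
    list(genome_id = genome_id, sequence = sequence, loci = loci,
         spacer_length = as.integer(spacer_length),
         seed_length = as.integer(seed_length), pam_motifs = pam_motifs),
    class = "phage_ref"
  )
}

#' @export
print.phage_ref <- function(x, ...) {
  cat("<phage_ref> ", x$genome_id, ": ", nchar(x$sequence), " nt, ",
      nrow(x$loci), " protospacer loci (",
      paste(names(table(x$loci$crispr_system)),
            table(x$loci$crispr_system), sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# Catalog every PAM match on both strands and derive the protospacer, seed and
# PAM intervals. Biostrings does the IUPAC matching; coordinates are converted
# from its 1-based closed intervals to 0-based half-open.
scan_protospacer_loci <- function(sequence, pam_motifs, spacer_length,
                                  seed_length) {
  subject <- Biostrings::DNAString(sequence)
  n <- nchar(sequence)
  rows <- list()
  for (sys in names(pam_motifs)) {
    motif <- pam_motifs[[sys]]
    m <- nchar(motif)
    # plus strand: protospacer immediately 5' of the PAM
    hits <- Biostrings::matchPattern(motif, subject, fixed = FALSE)
    for (s1 in Biostrings::start(hits)) {
      pam_start <- s1 - 1L             # 0-based
      start <- pam_start - spacer_length
      if (start < 0L) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = start, end = pam_start, strand = "+",
        pam_start = pam_start, pam_end = pam_start + m,
        seed_start = pam_start - seed_length, seed_end = pam_start,
        crispr_system = sys,
        protospacer = substr(sequence, start + 1L, pam_start)
      )
    }
    # minus strand: match the reverse complement of the motif on the plus
    # strand; the protospacer sits 5' of the PAM when read on the minus strand,
    # i.e. at higher plus-strand coordinates.
    rc_motif <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
    hits_rc <- Biostrings::matchPattern(rc_motif, subject, fixed = FALSE)
    for (s1 in Biostrings::start(hits_rc)) {
      pam_start <- s1 - 1L
      pam_end <- pam_start + m
      start <- pam_end
      end <- start + spacer_length
      if (end > n) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = start, end = end, strand = "-",
        pam_start = pam_start, pam_end = pam_end,
        seed_start = start, seed_end = start + seed_length,
        crispr_system = sys,
        protospacer = revcomp(substr(sequence, start + 1L, end))
      )
    }
  }
  loci <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(start = integer(), end = integer(), strand = character(),
                   pam_start = integer(), pam_end = integer(),
                   seed_start = integer(), seed_end = integer(),
                   crispr_system = character(), protospacer = character())
  loci <- dplyr::arrange(loci, .data$start, .data$strand, .data$crispr_system)
  loci <- dplyr::mutate(
    loci,
    locus_id = sprintf("L%04d_%s%s", dplyr::row_number(),
                       substr(.data$crispr_system, nchar(.data$crispr_system),
                              nchar(.data$crispr_system)),
                       ifelse(.data$strand == "+", "p", "m")),
    dplyr::across(c("start", "end", "pam_start", "pam_end",
                    "seed_start", "seed_end"), as.integer)
  )
  dplyr::relocate(loci, "locus_id")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Seed the session RNG reproducibly without leaking state decisions elsewhere.
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}
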