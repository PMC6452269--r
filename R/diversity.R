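#' Expand a host clone into acquired-spacer records
#'
#' One record per acquired spacer, each mapped onto the reference protospacer
#' catalog via [find_protospacer()]. Wild-type clones (no acquired spacers)
#' yield an empty tibble. Spacers that do not map are kept with `mapped =
#' FALSE` rather than dropped.
#'
#' @param clone One row of a host clone tibble.
#' @param genome A `phage_ref`.
#' @return A tibble: `clone_id`, `replicate`, `dpi`, `crispr_system`,
#'   `spacer`, `mapped`, `locus_id`, `start`, `end`, `strand`.
#' @export
detect_expansion <- function(clone, genome) {
  sp <- host_spacers(clone)
  if (nrow(sp) == 0L) {
    return(tibble::tibble(clone_id = character(), replicate = character(),
                          dpi = integer(), crispr_system = character(),
                          spacer = character(), mapped = logical(),
                          locus_id = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  rows <- lapply(seq_len(nrow(sp)), function(i) {
    locus <- find_protospacer(genome, sp$spacer[i])
    tibble::tibble(
      clone_id = clone$clone_id, replicate = clone$replicate,
      dpi = as.integer(clone$dpi), crispr_system = sp$crispr_system[i],
      spacer = sp$spacer[i], mapped = !is.null(locus),
      locus_id = if (is.null(locus)) NA_character_ else locus$locus_id,
      start = if (is.null(locus)) NA_integer_ else locus$start,
      end = if (is.null(locus)) NA_integer_ else locus$end,
      strand = if (is.null(locus)) NA_character_ else locus$strand
    )
  })
  dplyr::bind_rows(rows)
}

#' Acquired-spacer records for a whole clone table
#'
#' @param clones Host clone tibble (with `spacers` list-column).
#' @param genome A `phage_ref`.
#' @return Bound tibble of [detect_expansion()] records.
#' @export
spacer_records <- function(clones, genome) {
  dplyr::bind_rows(lapply(seq_len(nrow(clones)),
                          function(i) detect_expansion(clones[i, ], genome)))
}

clone_spacer_sets <- function(clones) {
  lapply(seq_len(nrow(clones)), function(i) host_spacers(clones[i, ])$spacer)
}

#' Pairwise-difference diversity of acquired spacers
#'
#' Token mode (default) treats each clone as a multiset of acquired spacer
#' sequences and averages, over all unordered clone pairs, `1 - |shared| /
#' max(set sizes)`: 0 when every clone carries the same spacers, 1 when no
#' pair shares any. A pair of spacer-free clones counts as identical
#' (distance 0). Nucleotide mode instead averages the normalized Hamming
#' distance over all unordered pairs of distinct-clone spacer sequences.
#'
#' @param clones Host clone tibble (needs >= 2 rows).
#' @param mode `"token"` or `"nucleotide"`.
#' @return Numeric in `[0, 1]`, or `NA` (with a warning) when fewer than two
#'   clones are supplied.
#' @export
pwd <- function(clones, mode = c("token", "nucleotide")) {
  mode <- match.arg(mode)
  n <- nrow(clones)
  if (n < 2L) {
    warning("pwd undefined for fewer than 2 clones", call. = FALSE)
    return(NA_real_)
  }
  sets <- clone_spacer_sets(clones)
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (mode == "token") {
        a <- sets[[i]]
        b <- sets[[j]]
        if (length(a) == 0L && length(b) == 0L) {
          vals <- c(vals, 0)
        } else {
          shared <- length(multiset_intersect(a, b))
          vals <- c(vals, 1 - shared / max(length(a), length(b)))
        }
      } else {
        pairs <- expand.grid(a = sets[[i]], b = sets[[j]],
                             stringsAsFactors = FALSE)
        if (nrow(pairs) == 0L) next
        hd <- mapply(hamming_frac, pairs$a, pairs$b)
        vals <- c(vals, hd)
      }
    }
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

multiset_intersect <- function(a, b) {
  out <- character()
  b_pool <- b
  for (x in a) {
    hit <- match(x, b_pool)
    if (!is.na(hit)) {
      out <- c(out, x)
      b_pool <- b_pool[-hit]
    }
  }
  out
}

hamming_frac <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("nucleotide-mode pwd needs equal-length spacers", call. = FALSE)
  }
  mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' CRISPR genotype richness
#'
#' Number of distinct CRISPR alleles: ordered acquired-spacer tuples over
#' both loci (acquisition order matters).
#'
#' @param clones Host clone tibble.
#' @return Non-negative integer.
#' @export
genotype_richness <- function(clones) {
  if (nrow(clones) == 0L) return(0L)
  keys <- if ("genotype_key" %in% names(clones)) clones$genotype_key else
    vapply(clone_spacer_sets(clones), paste, character(1), collapse = "|")
  length(unique(keys))
}

#' Genome-position histogram of acquired spacers
#'
#' Counts spacer-target midpoints per genome bin, stratified by replicate and
#' sampling day. Unmapped records are excluded with a message.
#'
#' @param records Tibble from [spacer_records()].
#' @param bin_size Bin width in nucleotides.
#' @return A tibble: `replicate`, `dpi`, `bin_start`, `count`.
#' @export
location_histogram <- function(records, bin_size = 1000L) {
  stopifnot(bin_size >= 1)
  n_unmapped <- sum(!records$mapped)
  if (n_unmapped > 0) {
    message(n_unmapped, " unmapped spacer record(s) excluded from histogram")
  }
  rec <- records[records$mapped, , drop = FALSE]
  if (nrow(rec) == 0L) {
    warning("no mapped records; empty histogram", call. = FALSE)
    return(tibble::tibble(replicate = character(), dpi = integer(),
                          bin_start = integer(), count = integer()))
  }
  mid <- floor((rec$start + rec$end) / 2)
  rec$bin_start <- as.integer(floor(mid / bin_size) * bin_size)
  dplyr::summarise(dplyr::group_by(rec, .data$replicate, .data$dpi,
                                   .data$bin_start),
                   count = dplyr::n(), .groups = "drop")
}

#' Diversity summary per replicate and time point
#'
#' Pairwise difference, genotype richness, clone count and the acquired
#' spacer-count distribution for each (replicate, dpi) clone panel.
#'
#' @param clones Host clone tibble over one or more replicates and days.
#' @param mode PWD mode, see [pwd()].
#' @return A tibble of class `diversity_summary`: `replicate`, `dpi`, `pwd`,
#'   `richness`, `n_clones`, `mean_spacers`, and `spacer_count_histogram`
#'   (list-column of tibbles `n_spacers`, `frequency` summing to 1).
#' @export
diversity_summary <- function(clones, mode = "token") {
  groups <- split(clones, list(clones$replicate, clones$dpi), drop = TRUE)
  out <- dplyr::bind_rows(lapply(groups, function(g) {
    counts <- vapply(clone_spacer_sets(g), length, integer(1))
    hist <- as.data.frame(table(counts), stringsAsFactors = FALSE)
    tibble::tibble(
      replicate = g$replicate[1], dpi = as.integer(g$dpi[1]),
      pwd = if (nrow(g) >= 2) pwd(g, mode) else NA_real_,
      richness = genotype_richness(g),
      n_clones = nrow(g),
      mean_spacers = mean(counts),
      spacer_count_histogram = list(tibble::tibble(
        n_spacers = as.integer(hist$counts),
        frequency = hist$Freq / sum(hist$Freq)))
    )
  }))
  out <- dplyr::arrange(out, .data$replicate, .data$dpi)
  class(out) <- c("diversity_summary", class(out))
  out
}
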