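#' Read and write pipeline files
#'
#' All on-disk coordinates are 0-based half-open; minus-strand loci store
#' plus-strand coordinates with `strand = "-"`. Infection matrices are
#' written as wide CSV (first column host clone ids, remaining columns one
#' per phage clone, cells 0/1) with a sidecar clone-metadata TSV, so that
#' `read_infection_csv(write_infection_csv(x)) == x`.
#'
#' @name spacerace-io
NULL

#' @rdname spacerace-io
#' @param genome A `phage_ref`.
#' @param path Output file.
#' @return `write_*` functions return `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$genome_id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' @rdname spacerace-io
#' @param pam_motifs,spacer_length,seed_length Catalog parameters used to
#'   rebuild the locus table from the sequence.
#' @export
read_genome_fasta <- function(path,
                              pam_motifs = c(CRISPR1 = "NNAGAAW",
                                             CRISPR3 = "NGGNG"),
                              spacer_length = 30L, seed_length = 10L) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop("expected exactly one sequence in ", path, call. = FALSE)
  }
  phage_ref_from_sequence(as.character(set[[1]]), pam_motifs = pam_motifs,
                          spacer_length = spacer_length,
                          seed_length = seed_length,
                          genome_id = names(set)[1])
}

#' @rdname spacerace-io
#' @export
write_locus_catalog <- function(genome, path) {
  readr::write_tsv(genome$loci, path)
  invisible(path)
}

#' @rdname spacerace-io
#' @export
read_locus_catalog <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    locus_id = "c", start = "i", end = "i", strand = "c",
                    pam_start = "i", pam_end = "i", seed_start = "i",
                    seed_end = "i", crispr_system = "c", protospacer = "c"))
}

#' @rdname spacerace-io
#' @param matrix Long infection tibble.
#' @export
write_infection_csv <- function(matrix, path) {
  check_infection_tbl(matrix)
  wide <- tidyr::pivot_wider(
    dplyr::select(matrix, "host_clone", "phage_clone", "infected"),
    names_from = "phage_clone", values_from = "infected")
  readr::write_csv(wide, path)
  meta <- dplyr::bind_rows(
    dplyr::distinct(matrix, clone_id = .data$host_clone,
                    replicate = .data$replicate, dpi = .data$host_dpi,
                    kind = "host"),
    dplyr::distinct(matrix, clone_id = .data$phage_clone,
                    replicate = .data$replicate, dpi = .data$phage_dpi,
                    kind = "phage"))
  readr::write_tsv(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_clones.tsv")
}

#' @rdname spacerace-io
#' @export
read_infection_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  meta <- readr::read_tsv(sidecar_path(path), show_col_types = FALSE,
                          col_types = readr::cols(clone_id = "c",
                                                  replicate = "c", dpi = "i",
                                                  kind = "c"))
  long <- tidyr::pivot_longer(wide, -"host_clone",
                              names_to = "phage_clone",
                              values_to = "infected")
  hosts <- meta[meta$kind == "host", ]
  phages <- meta[meta$kind == "phage", ]
  hx <- match(long$host_clone, hosts$clone_id)
  px <- match(long$phage_clone, phages$clone_id)
  if (anyNA(hx) || anyNA(px)) {
    stop("clone metadata sidecar does not cover all matrix clones",
         call. = FALSE)
  }
  tibble::tibble(replicate = hosts$replicate[hx],
                 host_clone = long$host_clone, host_dpi = hosts$dpi[hx],
                 phage_clone = long$phage_clone, phage_dpi = phages$dpi[px],
                 infected = as.integer(long$infected))
}

#' @rdname spacerace-io
#' @param hosts Host clone tibble.
#' @export
write_host_clones_tsv <- function(hosts, path) {
  flat <- dplyr::bind_rows(lapply(seq_len(nrow(hosts)), function(i) {
    sp <- host_spacers(hosts[i, ])
    if (nrow(sp) == 0L) {
      tibble::tibble(clone_id = hosts$clone_id[i],
                     replicate = hosts$replicate[i],
                     dpi = as.integer(hosts$dpi[i]), spacer_index = NA_integer_,
                     crispr_system = NA_character_, locus_id = NA_character_,
                     spacer = NA_character_)
    } else {
      tibble::tibble(clone_id = hosts$clone_id[i],
                     replicate = hosts$replicate[i],
                     dpi = as.integer(hosts$dpi[i]),
                     spacer_index = seq_len(nrow(sp)),
                     crispr_system = sp$crispr_system,
                     locus_id = sp$locus_id, spacer = sp$spacer)
    }
  }))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname spacerace-io
#' @export
read_host_clones_tsv <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            clone_id = "c", replicate = "c", dpi = "i",
                            spacer_index = "i", crispr_system = "c",
                            locus_id = "c", spacer = "c"))
  groups <- split(flat, factor(flat$clone_id, levels = unique(flat$clone_id)))
  dplyr::bind_rows(lapply(groups, function(g) {
    sp <- g[!is.na(g$spacer_index), , drop = FALSE]
    sp <- sp[order(sp$spacer_index), , drop = FALSE]
    tibble::tibble(clone_id = g$clone_id[1], replicate = g$replicate[1],
                   dpi = g$dpi[1],
                   genotype_key = paste(sp$locus_id, collapse = "|"),
                   spacers = list(tibble::tibble(
                     crispr_system = sp$crispr_system,
                     locus_id = sp$locus_id, spacer = sp$spacer)))
  }))
}

#' @rdname spacerace-io
#' @param phages Phage clone tibble.
#' @export
write_phage_clones_tsv <- function(phages, path) {
  flat <- dplyr::bind_rows(lapply(seq_len(nrow(phages)), function(i) {
    sn <- phage_snps(phages[i, ])
    if (nrow(sn) == 0L) {
      tibble::tibble(clone_id = phages$clone_id[i],
                     replicate = phages$replicate[i],
                     dpi = as.integer(phages$dpi[i]), position = NA_integer_,
                     ref = NA_character_, alt = NA_character_)
    } else {
      tibble::tibble(clone_id = phages$clone_id[i],
                     replicate = phages$replicate[i],
                     dpi = as.integer(phages$dpi[i]),
                     position = as.integer(sn$position), ref = sn$ref,
                     alt = sn$alt)
    }
  }))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname spacerace-io
#' @export
read_phage_clones_tsv <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            clone_id = "c", replicate = "c", dpi = "i",
                            position = "i", ref = "c", alt = "c"))
  groups <- split(flat, factor(flat$clone_id, levels = unique(flat$clone_id)))
  dplyr::bind_rows(lapply(groups, function(g) {
    sn <- g[!is.na(g$position), , drop = FALSE]
    snps <- tibble::tibble(position = sn$position, ref = sn$ref, alt = sn$alt)
    tibble::tibble(clone_id = g$clone_id[1], replicate = g$replicate[1],
                   dpi = g$dpi[1], genotype_key = snp_key(snps),
                   snps = list(snps))
  }))
}

#' @rdname spacerace-io
#' @param trajectory Trajectory tibble.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(trajectory[, c("replicate", "day", "cfu_per_ml",
                                  "pfu_per_ml")], path)
  invisible(path)
}

#' @rdname spacerace-io
#' @export
read_trajectory_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(replicate = "c", day = "i",
                                          cfu_per_ml = "d", pfu_per_ml = "d"))
}

#' @rdname spacerace-io
#' @param config A [sim_config()] (or plain named list).
#' @export
write_config_yaml <- function(config, path) {
  lst <- unclass(config)
  lst$pam_motifs <- as.list(lst$pam_motifs)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname spacerace-io
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$pam_motifs)) lst$pam_motifs <- unlist(lst$pam_motifs)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, lst)
}

#' Write a run manifest
#'
#' Records the configuration, root and child seeds, package version and an
#' md5 inventory of the files in an output directory, sufficient to
#' reproduce a pipeline run bit-identically.
#'
#' @param outdir Directory whose files are inventoried.
#' @param config The [sim_config()] used.
#' @param root_seed Integer root seed.
#' @param child_seeds Integer vector of derived stage/replicate seeds.
#' @param path Manifest destination (default `manifest.json` in `outdir`).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(outdir, config, root_seed, child_seeds = integer(),
                           path = file.path(outdir, "manifest.json")) {
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        basename(path)), method = "radix")
  inventory <- lapply(files, function(f) {
    list(file = f,
         md5 = unname(tools::md5sum(file.path(outdir, f))),
         bytes = file.size(file.path(outdir, f)))
  })
  cfg <- unclass(config)
  cfg$pam_motifs <- as.list(cfg$pam_motifs)
  manifest <- list(
    artifact = "spacerace",
    version = as.character(utils::packageVersion("spacerace")),
    root_seed = as.integer(root_seed),
    child_seeds = as.integer(child_seeds),
    config = cfg,
    files = inventory
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
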