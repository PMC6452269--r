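#' Run the full coevolution analysis pipeline
#'
#' Executes simulate -> predict -> phenotype -> time-shift / G-by-E ->
#' diversity -> variants and writes every stage artifact plus a reproducing
#' manifest to `outdir`. Each stage is also available as a stand-alone
#' function on in-memory tibbles or on the written files. A stage failure
#' halts the pipeline with a stage-tagged error; artifacts written by earlier
#' stages are preserved.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @param rng_seed Root seed for every source of randomness.
#' @param n_replicates,dpi,n_clones,keep Passed to [simulate_panel()].
#' @param boot_reps Bootstrap resamples for all interval estimates.
#' @param use_measured Analyse the noise-overlaid measured matrices (default)
#'   rather than the noiseless predicted ones.
#' @return A list of class `coevo_pipeline` with elements `panel`,
#'   `infectivity`, `resistance`, `timeshift`, `gxe`, `diversity`,
#'   `contingency`, `snp_status`, `extinction`, `outdir`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL, rng_seed = 1L,
                         n_replicates = 12L, dpi = c(1L, 4L, 9L),
                         n_clones = 12L, keep = 8L, boot_reps = 200L,
                         use_measured = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  withr_seed(rng_seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 8L)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  log_stage <- function(...) message("[spacerace] ", ...)

  log_stage("simulate: ", n_replicates, " replicates, ", config$days, " days")
  panel <- stage("simulate", simulate_panel(
    config, n_replicates = n_replicates, dpi = dpi, n_clones = n_clones,
    keep = keep, rng_seed = stage_seeds[1]))
  if (is.null(panel$hosts)) {
    stop("stage 'simulate' failed: no replicate retained phage through day ",
         max(dpi), call. = FALSE)
  }
  log_stage("simulate: kept ", length(panel$kept_replicates), " replicates, ",
            nrow(panel$hosts), " host clones, ", nrow(panel$phages),
            " phage clones")
  mat <- if (use_measured) panel$measured else panel$predicted
  spec_of <- function(i) bootstrap_spec(reps = boot_reps,
                                        rng_seed = stage_seeds[i])

  log_stage("phenotype: ", nrow(mat), " challenges")
  infectivity <- stage("phenotype",
                       summarize_by_timepoint(mat, "infectivity", spec_of(2)))
  resistance <- stage("phenotype",
                      summarize_by_timepoint(mat, "resistance", spec_of(3)))
  log_stage("timeshift/gxe")
  timeshift <- stage("timeshift", timeshift_table(mat, spec_of(4)))
  gxe <- stage("gxe", gxe_ratio_series(mat, spec_of(5)))
  log_stage("diversity: ", nrow(panel$hosts), " host clones")
  diversity <- stage("diversity", diversity_summary(panel$hosts))
  records <- stage("diversity", spacer_records(panel$hosts, panel$genome))
  histogram <- stage("diversity", location_histogram(records))
  log_stage("variants: ", nrow(panel$predicted), " predicted challenges")
  contingency <- stage("variants",
                       contingency_analysis(panel$predicted, panel$measured))
  snp_status <- stage("variants", infectivity_by_snp_status(
    panel$phages, panel$hosts, mat, panel$genome, spec_of(6)))
  extinction <- stage("report", time_to_extinction_summary(panel$extinctions))

  if (!is.null(outdir)) {
    stage("report", {
      write_genome_fasta(panel$genome, file.path(outdir, "genome.fasta"))
      write_locus_catalog(panel$genome, file.path(outdir, "catalog.tsv"))
      write_trajectory_csv(panel$trajectory,
                           file.path(outdir, "trajectory.csv"))
      write_host_clones_tsv(panel$hosts, file.path(outdir, "host_clones.tsv"))
      write_phage_clones_tsv(panel$phages,
                             file.path(outdir, "phage_clones.tsv"))
      for (r in panel$kept_replicates) {
        write_infection_csv(
          panel$measured[panel$measured$replicate == r, , drop = FALSE],
          file.path(outdir, paste0("matrix_measured_", r, ".csv")))
        write_infection_csv(
          panel$predicted[panel$predicted$replicate == r, , drop = FALSE],
          file.path(outdir, paste0("matrix_predicted_", r, ".csv")))
      }
      readr::write_tsv(dplyr::bind_rows(infectivity, resistance),
                       file.path(outdir, "range_summary.tsv"))
      readr::write_tsv(timeshift$cells, file.path(outdir, "timeshift.tsv"))
      readr::write_tsv(gxe$ratios, file.path(outdir, "gxe.tsv"))
      readr::write_tsv(
        dplyr::select(diversity, -"spacer_count_histogram"),
        file.path(outdir, "diversity.tsv"))
      readr::write_tsv(histogram, file.path(outdir, "spacer_histogram.tsv"))
      jsonlite::write_json(
        list(counts = as.list(contingency$counts),
             concordance = contingency$concordance,
             predictive_value = contingency$predictive_value),
        file.path(outdir, "contingency.json"), auto_unbox = TRUE, digits = NA)
      write_config_yaml(config, file.path(outdir, "config.yaml"))
      write_manifest(outdir, config, rng_seed, stage_seeds)
    })
    log_stage("report: wrote ", length(list.files(outdir)), " files to ",
              outdir)
  }
  structure(list(panel = panel, infectivity = infectivity,
                 resistance = resistance, timeshift = timeshift, gxe = gxe,
                 diversity = diversity, spacer_histogram = histogram,
                 contingency = contingency, snp_status = snp_status,
                 extinction = extinction, outdir = outdir,
                 root_seed = as.integer(rng_seed)),
            class = "coevo_pipeline")
}

#' @export
print.coevo_pipeline <- function(x, ...) {
  cat("<coevo_pipeline> seed ", x$root_seed, "\n", sep = "")
  cat("Infectivity / resistance by dpi:\n")
  print(as.data.frame(dplyr::bind_rows(x$infectivity, x$resistance)),
        row.names = FALSE)
  cat("Time-shift background means:\n")
  print(as.data.frame(x$timeshift$backgrounds), row.names = FALSE)
  cat(sprintf("Contingency: concordance %.3f, predictive value %.3f\n",
              x$contingency$concordance, x$contingency$predictive_value))
  invisible(x)
}
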