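#' Bootstrap settings
#'
#' @param reps Bootstrap resamples.
#' @param alpha Two-sided level; CIs are `100 * (1 - alpha)` percent
#'   percentile intervals.
#' @param rng_seed Integer seed; intervals are deterministic per seed.
#' @return A list of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(reps = 1000L, alpha = 0.05, rng_seed = 1L) {
  stopifnot(reps >= 1, alpha > 0, alpha < 1)
  structure(list(reps = as.integer(reps), alpha = alpha,
                 rng_seed = as.integer(rng_seed)),
            class = "bootstrap_spec")
}

check_infection_tbl <- function(x) {
  need <- c("replicate", "host_clone", "host_dpi", "phage_clone", "phage_dpi",
            "infected")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("infection tibble lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(x$infected %in% c(0L, 1L))) {
    stop("infected entries must be 0/1", call. = FALSE)
  }
  invisible(x)
}

#' Infectivity range of one phage clone
#'
#' The proportion of all host clones in the matrix (all time points of the
#' same replicate) that the phage clone infects.
#'
#' @param matrix Long infection tibble (see [predict_matrix()]).
#' @param phage_clone Clone id.
#' @return Fraction in `[0, 1]`.
#' @export
infectivity_range <- function(matrix, phage_clone) {
  check_infection_tbl(matrix)
  rows <- matrix[matrix$phage_clone == phage_clone, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown phage clone ", phage_clone, call. = FALSE)
  mean(rows$infected)
}

#' Resistance range of one host clone
#'
#' The proportion of all phage clones in the matrix (all time points of the
#' same replicate) that the host clone resists.
#'
#' @param matrix Long infection tibble.
#' @param host_clone Clone id.
#' @return Fraction in `[0, 1]`.
#' @export
resistance_range <- function(matrix, host_clone) {
  check_infection_tbl(matrix)
  rows <- matrix[matrix$host_clone == host_clone, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown host clone ", host_clone, call. = FALSE)
  mean(1L - rows$infected)
}

# per-clone ranges in tidy form, one row per clone
clone_ranges <- function(matrix, statistic = c("infectivity", "resistance")) {
  statistic <- match.arg(statistic)
  check_infection_tbl(matrix)
  if (statistic == "infectivity") {
    dplyr::summarise(
      dplyr::group_by(matrix, .data$replicate, clone = .data$phage_clone,
                      dpi = .data$phage_dpi),
      range = mean(.data$infected), n_challenges = dplyr::n(), .groups = "drop")
  } else {
    dplyr::summarise(
      dplyr::group_by(matrix, .data$replicate, clone = .data$host_clone,
                      dpi = .data$host_dpi),
      range = mean(1L - .data$infected), n_challenges = dplyr::n(),
      .groups = "drop")
  }
}

# Two-level percentile bootstrap of a per-(replicate, dpi) clone-mean summary:
# resample replicates (outer) then clones within each sampled replicate
# (inner), recompute the grand mean per dpi.
boot_grand_mean <- function(per_clone, spec) {
  reps <- unique(per_clone$clone_tbl$replicate)
  dpis <- sort(unique(per_clone$clone_tbl$dpi))
  split_rep <- split(per_clone$clone_tbl, per_clone$clone_tbl$replicate)
  draws <- matrix(NA_real_, nrow = spec$reps, ncol = length(dpis),
                  dimnames = list(NULL, dpis))
  for (b in seq_len(spec$reps)) {
    picked <- sample(reps, length(reps), replace = TRUE)
    vals <- lapply(picked, function(r) {
      tbl <- split_rep[[as.character(r)]]
      rows <- unlist(lapply(split(seq_len(nrow(tbl)), tbl$dpi), function(ix) {
        sample(ix, length(ix), replace = TRUE)
      }), use.names = FALSE)
      tbl[rows, c("dpi", "range")]
    })
    vals <- dplyr::bind_rows(
      lapply(vals, function(tb) stats::aggregate(range ~ dpi, tb, mean)))
    m <- tapply(vals$range, vals$dpi, mean)
    draws[b, names(m)] <- m
  }
  draws
}

#' Per-time-point mean infectivity or resistance with bootstrap CIs
#'
#' For each sampling day, the grand mean over replicates of the replicate-mean
#' clone ranges, with a two-level percentile bootstrap (replicates resampled
#' in the outer level, clones within replicate in the inner level).
#'
#' @param matrices Long infection tibble (may hold several replicates) or a
#'   list of such tibbles, which are bound together.
#' @param statistic `"infectivity"` (phage clones) or `"resistance"` (host
#'   clones).
#' @param spec A [bootstrap_spec()].
#' @return A tibble of class `range_summary`: `dpi`, `statistic`, `mean`,
#'   `ci_low`, `ci_high`, `n_replicates`, `n_clones`.
#' @export
summarize_by_timepoint <- function(matrices,
                                   statistic = c("infectivity", "resistance"),
                                   spec = bootstrap_spec()) {
  statistic <- match.arg(statistic)
  if (is.list(matrices) && !is.data.frame(matrices)) {
    matrices <- dplyr::bind_rows(matrices)
  }
  tbl <- clone_ranges(matrices, statistic)
  point <- dplyr::summarise(
    dplyr::group_by(
      dplyr::summarise(dplyr::group_by(tbl, .data$replicate, .data$dpi),
                       rep_mean = mean(.data$range),
                       n_clones = dplyr::n(), .groups = "drop"),
      .data$dpi),
    mean = mean(.data$rep_mean), n_replicates = dplyr::n(),
    n_clones = sum(.data$n_clones), .groups = "drop")
  withr_seed(spec$rng_seed)
  draws <- boot_grand_mean(list(clone_tbl = tbl), spec)
  qs <- apply(draws, 2, stats::quantile,
              probs = c(spec$alpha / 2, 1 - spec$alpha / 2), na.rm = TRUE)
  out <- dplyr::mutate(
    point,
    statistic = statistic,
    ci_low = qs[1, as.character(.data$dpi)],
    ci_high = qs[2, as.character(.data$dpi)]
  )
  out <- dplyr::select(out, "dpi", "statistic", "mean", "ci_low", "ci_high",
                       "n_replicates", "n_clones")
  class(out) <- c("range_summary", class(out))
  out
}
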