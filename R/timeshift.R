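#' Classify a challenge as past, present or future
#'
#' Background of the phage relative to the host: phage sampled before the
#' host are its past, the same day its present, later its future.
#'
#' @param host_dpi,phage_dpi Sampling days (vectorized).
#' @return Character vector over `{"past", "present", "future"}`.
#' @export
classify_background <- function(host_dpi, phage_dpi) {
  dplyr::case_when(
    phage_dpi < host_dpi ~ "past",
    phage_dpi == host_dpi ~ "present",
    TRUE ~ "future"
  )
}

#' Time-shift susceptibility table
#'
#' Mean proportion of challenges won by the phage, per (host day, phage day)
#' cell and pooled by past/present/future background, with two-level
#' percentile bootstrap CIs (replicates outer, challenges within replicate
#' inner).
#'
#' @param matrices Long infection tibble or list of tibbles.
#' @param spec A [bootstrap_spec()].
#' @return A list of class `timeshift_table` with tibbles `cells`
#'   (`host_dpi`, `phage_dpi`, `background`, `mean`, `ci_low`, `ci_high`,
#'   `n_challenges`) and `backgrounds` (`background`, `mean`, `ci_low`,
#'   `ci_high`, `n_challenges`).
#' @export
timeshift_table <- function(matrices, spec = bootstrap_spec()) {
  if (is.list(matrices) && !is.data.frame(matrices)) {
    matrices <- dplyr::bind_rows(matrices)
  }
  check_infection_tbl(matrices)
  m <- dplyr::mutate(matrices,
                     background = classify_background(.data$host_dpi,
                                                      .data$phage_dpi))
  cells <- dplyr::summarise(
    dplyr::group_by(m, .data$host_dpi, .data$phage_dpi, .data$background),
    mean = mean(.data$infected), n_challenges = dplyr::n(), .groups = "drop")
  bgs <- dplyr::summarise(
    dplyr::group_by(m, .data$background),
    mean = mean(.data$infected), n_challenges = dplyr::n(), .groups = "drop")

  withr_seed(spec$rng_seed)
  reps <- unique(m$replicate)
  split_rep <- split(m, m$replicate)
  cell_key <- function(d) paste(d$host_dpi, d$phage_dpi)
  cell_levels <- cell_key(cells)
  bg_levels <- c("past", "present", "future")
  cell_draws <- matrix(NA_real_, spec$reps, length(cell_levels),
                       dimnames = list(NULL, cell_levels))
  bg_draws <- matrix(NA_real_, spec$reps, 3, dimnames = list(NULL, bg_levels))
  for (b in seq_len(spec$reps)) {
    picked <- sample(reps, length(reps), replace = TRUE)
    boot <- dplyr::bind_rows(lapply(picked, function(r) {
      tbl <- split_rep[[as.character(r)]]
      tbl[sample.int(nrow(tbl), nrow(tbl), replace = TRUE), ]
    }))
    ck <- cell_key(boot)
    mm <- tapply(boot$infected, ck, mean)
    cell_draws[b, names(mm)] <- mm
    mb <- tapply(boot$infected, boot$background, mean)
    bg_draws[b, names(mb)] <- mb
  }
  qfun <- function(draws, keys) {
    qs <- apply(draws, 2, stats::quantile,
                probs = c(spec$alpha / 2, 1 - spec$alpha / 2), na.rm = TRUE)
    list(low = qs[1, keys], high = qs[2, keys])
  }
  qc <- qfun(cell_draws, cell_levels)
  cells$ci_low <- unname(qc$low)
  cells$ci_high <- unname(qc$high)
  present_bgs <- intersect(bg_levels, bgs$background)
  qb <- qfun(bg_draws[, present_bgs, drop = FALSE], present_bgs)
  bgs <- bgs[match(present_bgs, bgs$background), ]
  bgs$ci_low <- unname(qb$low)
  bgs$ci_high <- unname(qb$high)
  structure(list(cells = cells, backgrounds = bgs, spec = spec),
            class = "timeshift_table")
}

#' @export
print.timeshift_table <- function(x, ...) {
  cat("<timeshift_table>\nBackground means:\n")
  print(as.data.frame(x$backgrounds), row.names = FALSE)
  cat("Cells:\n")
  print(as.data.frame(x$cells), row.names = FALSE)
  invisible(x)
}

#' Balanced two-way ANOVA decomposition of one replicate's sub-matrix
#'
#' Classical sums of squares for the layout with G = the host clones sampled
#' on `host_dpi` (genotype), E = phage sampling day (environment), and the
#' phage clones within each day as replication. The response is the binary
#' infection outcome. Computed directly from cell and marginal means; the
#' design must be balanced (equal phage clones per day, complete grid).
#'
#' @param matrix Long infection tibble (one or more replicates).
#' @param replicate Replicate id to analyse.
#' @param host_dpi Host sampling day defining the G levels.
#' @return An object of class `gxe_anova`: list with `ss` / `df` / `ms`
#'   named vectors (`g`, `e`, `gxe`, `resid`), `ss_total`, `grand_mean`,
#'   `replicate`, `host_dpi`.
#' @export
anova_ms <- function(matrix, replicate, host_dpi) {
  check_infection_tbl(matrix)
  sub <- matrix[matrix$replicate == replicate &
                  matrix$host_dpi == host_dpi, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no challenges for replicate ", replicate, ", host_dpi ", host_dpi,
         call. = FALSE)
  }
  counts <- table(sub$host_clone, sub$phage_dpi)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0)) {
    stop("unbalanced layout: unequal phage clones per (host, phage day) cell",
         call. = FALSE)
  }
  r <- unique(as.vector(counts))
  g_lab <- rownames(counts)
  e_lab <- colnames(counts)
  g <- length(g_lab)
  e <- length(e_lab)
  y <- sub$infected
  grand <- mean(y)
  gi <- tapply(y, sub$host_clone, mean)[g_lab]
  ej <- tapply(y, as.character(sub$phage_dpi), mean)[e_lab]
  cellm <- tapply(y, list(sub$host_clone, as.character(sub$phage_dpi)),
                  mean)[g_lab, e_lab, drop = FALSE]
  ss_g <- e * r * sum((gi - grand)^2)
  ss_e <- g * r * sum((ej - grand)^2)
  inter <- sweep(sweep(cellm, 1, gi), 2, ej) + grand
  ss_gxe <- r * sum(inter^2)
  fitted <- cellm[cbind(match(sub$host_clone, g_lab),
                        match(as.character(sub$phage_dpi), e_lab))]
  ss_resid <- sum((y - fitted)^2)
  df <- c(g = g - 1, e = e - 1, gxe = (g - 1) * (e - 1), resid = g * e * (r - 1))
  ss <- c(g = ss_g, e = ss_e, gxe = ss_gxe, resid = ss_resid)
  ms <- ifelse(df > 0, ss / df, NA_real_)
  structure(list(ss = ss, df = df, ms = ms,
                 ss_total = sum((y - grand)^2), grand_mean = grand,
                 replicate = replicate, host_dpi = host_dpi,
                 g_levels = g, e_levels = e, cell_reps = r),
            class = "gxe_anova")
}

#' @export
print.gxe_anova <- function(x, ...) {
  cat("<gxe_anova> replicate ", x$replicate, ", host day ", x$host_dpi, "\n",
      sep = "")
  print(data.frame(term = names(x$ss), df = x$df, sumsq = x$ss, meansq = x$ms,
                   row.names = NULL))
  invisible(x)
}

#' @rdname anova_ms
#' @param x A `gxe_anova`.
#' @param ... Unused.
#' @export
tidy.gxe_anova <- function(x, ...) {
  tibble::tibble(term = c("genotype", "environment", "genotype:environment",
                          "residual"),
                 df = unname(x$df), sumsq = unname(x$ss),
                 meansq = unname(x$ms))
}

#' @rdname anova_ms
#' @param reciprocal Report `ms_e / ms_gxe` instead of the default
#'   `ms_gxe / ms_e`.
#' @export
glance.gxe_anova <- function(x, reciprocal = FALSE, ...) {
  ms_e <- unname(x$ms["e"])
  ms_gxe <- unname(x$ms["gxe"])
  flagged <- !is.finite(ms_e) || ms_e <= .Machine$double.eps
  ratio <- if (flagged && !reciprocal) NA_real_
    else if (reciprocal) {
      if (!is.finite(ms_gxe) || ms_gxe <= .Machine$double.eps) NA_real_
      else ms_e / ms_gxe
    } else ms_gxe / ms_e
  tibble::tibble(replicate = x$replicate, host_dpi = x$host_dpi,
                 ms_e = ms_e, ms_gxe = ms_gxe, ratio = ratio,
                 flagged = flagged)
}

#' G-by-E mean-square ratio per replicate and host time point
#'
#' Ratio of the interaction mean square to the environment (phage day) mean
#' square from [anova_ms()], for every (replicate, host day) combination in
#' the data. Large ratios indicate genotype-specific responses to phage from
#' different times (fluctuating selection); small ratios indicate a uniform
#' time trend (arms race). Combinations with a zero environment mean square
#' are flagged and excluded from the per-day means, with the excluded count
#' reported via a message.
#'
#' @param matrices Long infection tibble or list of tibbles.
#' @param spec A [bootstrap_spec()] for the per-day CIs (replicates
#'   resampled).
#' @param reciprocal Report `ms_e / ms_gxe` instead (the reciprocal reading).
#' @return A list of class `gxe_series`: `ratios` tibble (`replicate`,
#'   `host_dpi`, `ms_e`, `ms_gxe`, `ratio`, `flagged`) and `summary` tibble
#'   (`host_dpi`, `mean_ratio`, `ci_low`, `ci_high`, `n`, `n_flagged`).
#' @export
gxe_ratio_series <- function(matrices, spec = bootstrap_spec(),
                             reciprocal = FALSE) {
  if (is.list(matrices) && !is.data.frame(matrices)) {
    matrices <- dplyr::bind_rows(matrices)
  }
  check_infection_tbl(matrices)
  combos <- dplyr::distinct(matrices, .data$replicate, .data$host_dpi)
  ratios <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    glance(anova_ms(matrices, combos$replicate[i], combos$host_dpi[i]),
           reciprocal = reciprocal)
  }))
  n_flagged <- sum(ratios$flagged)
  if (n_flagged > 0) {
    message(n_flagged, " (replicate, host day) cell(s) flagged: ",
            "zero environment mean square; excluded from summaries")
  }
  ok <- ratios[!ratios$flagged & is.finite(ratios$ratio), , drop = FALSE]
  if (nrow(ok) == 0L) {
    warning("all cells flagged; no ratio summary computed", call. = FALSE)
    summary <- tibble::tibble(host_dpi = integer(), mean_ratio = double(),
                              ci_low = double(), ci_high = double(),
                              n = integer(), n_flagged = integer())
  } else {
    withr_seed(spec$rng_seed)
    summary <- dplyr::bind_rows(lapply(split(ok, ok$host_dpi), function(tb) {
      draws <- vapply(seq_len(spec$reps), function(b) {
        mean(sample(tb$ratio, nrow(tb), replace = TRUE))
      }, numeric(1))
      tibble::tibble(host_dpi = tb$host_dpi[1], mean_ratio = mean(tb$ratio),
                     ci_low = stats::quantile(draws, spec$alpha / 2,
                                              names = FALSE),
                     ci_high = stats::quantile(draws, 1 - spec$alpha / 2,
                                               names = FALSE),
                     n = nrow(tb),
                     n_flagged = sum(ratios$flagged[ratios$host_dpi ==
                                                      tb$host_dpi[1]]))
    }))
  }
  structure(list(ratios = ratios, summary = summary),
            class = "gxe_series")
}

#' @export
print.gxe_series <- function(x, ...) {
  cat("<gxe_series>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
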