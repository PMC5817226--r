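# Convergence diagnostics: score trajectories, RSD, population profiling,
# occupancy footprints, and the between-generation improvement test.

better_fraction_scores <- function(fitness, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  ord <- order_by_score(fitness)
  k <- ceiling(fraction * nrow(fitness))
  fitness$score[ord[seq_len(k)]]
}

fitness_scores <- function(fitness, objective = NULL) {
  if (is.null(objective)) return(fitness$score)
  col <- paste0("term.", objective)
  if (!col %in% names(fitness))
    stop("objective '", objective, "' not present in fitness result",
         call. = FALSE)
  fitness[[col]]
}

#' Per-generation score trajectories
#'
#' For each generation: the mean score over the whole population, the mean
#' over the better-performing fraction (top `ceiling(fraction * N)` by
#' score), and the best individual score. These are the three curves a user
#' watches to decide termination. Per-objective normalized terms can be
#' tracked instead of the total score.
#'
#' @param history List of [generation_record()]s, each with fitness computed.
#' @param fraction Better-performing fraction, in (0, 1] (default 0.5).
#' @param objective Optional objective name; if given, that objective's
#'   normalized term is used in place of the total score.
#' @return Data frame: `generation`, `mean_all`, `mean_better`, `best`.
#' @export
score_trajectories <- function(history, fraction = 0.5, objective = NULL) {
  stopifnot(length(history) >= 1L)
  rows <- lapply(history, function(rec) {
    if (is.null(rec$fitness))
      stop("generation ", rec$generation, " has no fitness computed",
           call. = FALSE)
    f <- rec$fitness
    s <- fitness_scores(f, objective)
    ord <- order(-s, f$condition_id)
    k <- ceiling(fraction * length(s))
    if (fraction <= 0 || fraction > 1)
      stop("fraction must be in (0, 1]", call. = FALSE)
    data.frame(generation = rec$generation,
               mean_all = mean(s),
               mean_better = mean(s[ord[seq_len(k)]]),
               best = max(s))
  })
  do.call(rbind, rows)
}

#' Relative standard deviation of scores
#'
#' Sample standard deviation (denominator `n - 1`) divided by the mean. Its
#' decline over generations, computed on the better-performing fraction,
#' signals contraction of the search onto an optimal sub-space.
#'
#' @param scores Numeric vector of at least 2 scores with nonzero mean.
#' @return The RSD (dimensionless).
#' @export
relative_standard_deviation <- function(scores) {
  if (length(scores) < 2L)
    stop("RSD requires at least 2 scores", call. = FALSE)
  m <- mean(scores)
  if (m == 0) stop("RSD undefined: mean score is zero", call. = FALSE)
  stats::sd(scores) / m
}

#' Population profile of factor levels
#'
#' Tabulates, per factor and generation, the absolute frequency with which
#' each encoded level appears in the population. Convergence of the search
#' reads as the frequency mass concentrating on few levels of each factor as
#' generations progress. Levels never assigned are omitted unless
#' `include_zero = TRUE`.
#'
#' @param history List of [generation_record()]s (fitness not required).
#' @param space The [design_space()].
#' @param include_zero Report zero-frequency levels too? Default FALSE.
#' @return Data frame: `factor`, `generation`, `level_index` (0-based),
#'   `level_value`, `frequency`.
#' @export
population_profile <- function(history, space, include_zero = FALSE) {
  stopifnot(length(history) >= 1L, inherits(space, "design_space"))
  rows <- list()
  for (rec in history) {
    idx_mat <- vapply(rec$population, function(ch)
      chromosome_level_indices(space, ch$bits),
      integer(length(space$factors)))
    if (is.null(dim(idx_mat))) idx_mat <- matrix(idx_mat, nrow = 1L)
    for (i in seq_along(space$factors)) {
      f <- space$factors[[i]]
      counts <- tabulate(idx_mat[i, ] + 1L, nbins = n_levels(f))
      lev <- seq_len(n_levels(f)) - 1L
      keep <- if (include_zero) rep(TRUE, length(lev)) else counts > 0L
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f$name, generation = rec$generation,
        level_index = lev[keep],
        level_value = level_values(f)[keep],
        frequency = counts[keep])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Occupancy footprint of the better-performing fraction
#'
#' Restricts the final (or any) generation to its top `fraction` by score and
#' reports, per factor, the percentage of that subset occupying each level.
#' The footprint is how optimal factor settings are read off at the end of a
#' search: a level holding most of the occupancy is the converged value.
#'
#' @param record A [generation_record()] with fitness computed.
#' @param space The [design_space()].
#' @param fraction Better-performing fraction, in (0, 1] (default 0.5).
#' @return Data frame: `factor`, `level_index`, `level_value`, `percent`
#'   (summing to 100 within each factor).
#' @export
occupancy_footprint <- function(record, space, fraction = 0.5) {
  stopifnot(inherits(record, "generation_record"),
            inherits(space, "design_space"))
  if (is.null(record$fitness))
    stop("generation ", record$generation,
         " has no fitness computed; ingest results first", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  ord <- order_by_score(record$fitness)
  k <- ceiling(fraction * nrow(record$fitness))
  top_ids <- record$fitness$condition_id[ord[seq_len(k)]]
  by_id <- stats::setNames(record$population,
                           vapply(record$population, `[[`, "", "id"))
  idx_mat <- vapply(by_id[top_ids], function(ch)
    chromosome_level_indices(space, ch$bits),
    integer(length(space$factors)))
  if (is.null(dim(idx_mat))) idx_mat <- matrix(idx_mat, nrow = 1L)
  rows <- lapply(seq_along(space$factors), function(i) {
    f <- space$factors[[i]]
    counts <- tabulate(idx_mat[i, ] + 1L, nbins = n_levels(f))
    keep <- counts > 0L
    data.frame(factor = f$name,
               level_index = (seq_len(n_levels(f)) - 1L)[keep],
               level_value = level_values(f)[keep],
               percent = 100 * counts[keep] / k)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-generation improvement test
#'
#' One-sided two-sample Welch t-test of whether the mean score of the next
#' generation exceeds that of the previous one; intended for the
#' better-performing fractions of adjacent generations. Termination guidance
#' in practice: continue while the improvement is significant and stop once
#' p exceeds about 0.1. If both groups are completely degenerate (all scores
#' identical) the test is uninformative and p = 1 is reported with a warning.
#'
#' @param scores_prev,scores_next Numeric score vectors (length >= 2 each).
#' @param test `"welch"` (default) or `"wilcoxon"` (one-sided Mann-Whitney),
#'   for users preferring a rank test.
#' @return The one-sided p-value.
#' @export
improvement_test <- function(scores_prev, scores_next,
                             test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (length(scores_prev) < 2L || length(scores_next) < 2L)
    stop("improvement_test requires >= 2 scores per group", call. = FALSE)
  all_equal <- length(unique(c(scores_prev, scores_next))) == 1L
  both_const <- stats::var(scores_prev) == 0 && stats::var(scores_next) == 0
  if (all_equal) {
    warning("degenerate score groups (all values identical); p reported as 1",
            call. = FALSE)
    return(1.0)
  }
  if (both_const && test == "welch") {
    # two distinct constants: no within-group variance, the t statistic is
    # unbounded; report the limiting p in the direction of the shift
    warning("no within-group variance; limiting p-value reported",
            call. = FALSE)
    return(if (mean(scores_next) > mean(scores_prev)) 0.0 else 1.0)
  }
  p <- if (test == "welch") {
    stats::t.test(scores_next, scores_prev, alternative = "greater",
                  var.equal = FALSE)$p.value
  } else {
    stats::wilcox.test(scores_next, scores_prev, alternative = "greater",
                       exact = FALSE)$p.value
  }
  unname(p)
}
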