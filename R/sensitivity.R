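# Perturbation sensitivity over model batches: which factors drive each
# objective near the determined optimum.

#' Relative response of a model batch to a factor perturbation
#'
#' For every model in the batch the factor is shifted from its optimum value
#' by `±delta` (default ±10 %), the other factors held fixed, and the
#' relative response is `max(|y+ - y0|, |y- - y0|) / |y0|` where `y0` is the
#' prediction at the optimum. A near-zero baseline prediction (`|y0| <
#' 1e-12`) makes the ratio meaningless; `Inf` is reported for that model with
#' a warning.
#'
#' @param batch A `model_batch` (see [fit_batch()]).
#' @param optimum Named numeric vector or list covering every model factor.
#' @param factor Name of the factor to perturb.
#' @param delta Relative shift (default 0.10).
#' @return Numeric vector of relative responses, one per model.
#' @export
perturb_and_score <- function(batch, optimum, factor, delta = 0.10) {
  stopifnot(inherits(batch, "model_batch"), delta > 0)
  optimum <- as.list(optimum)
  vars <- batch$models[[1]]$var_names
  if (!factor %in% vars)
    stop("unknown factor '", factor, "' (model factors: ",
         paste(vars, collapse = ", "), ")", call. = FALSE)
  missing <- setdiff(vars, names(optimum))
  if (length(missing))
    stop("optimum lacks value(s) for factor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x0 <- optimum[vars]
  xp <- x0; xp[[factor]] <- x0[[factor]] * (1 + delta)
  xm <- x0; xm[[factor]] <- x0[[factor]] * (1 - delta)
  vapply(batch$models, function(m) {
    y0 <- predict(m, x0)
    if (abs(y0) < 1e-12) {
      warning("baseline prediction ~0 at the optimum; response reported Inf",
              call. = FALSE)
      return(Inf)
    }
    max(abs(predict(m, xp) - y0), abs(predict(m, xm) - y0)) / abs(y0)
  }, 0)
}

#' Classify major contributor factors
#'
#' Runs the perturbation analysis for every (objective, factor) pair over
#' batches of models and flags a factor as a major contributor to an
#' objective when enough models of the batch show a relative response at or
#' above `threshold` (default 10 %). The aggregation rule over the batch is
#' `"majority"` (at least half the models, the default), `"any"`, or
#' `"all"`. Factors listed as not applicable for an objective (e.g. an
#' induction-phase carbon source absent from the pre-induction medium) are
#' excluded from classification and reported as such.
#'
#' @param batches Named list of `model_batch` objects, one per objective
#'   (names are the objective names).
#' @param optimum Named numeric vector/list: the determined optimum
#'   condition.
#' @param threshold Relative response required to count a model (default
#'   0.10).
#' @param delta Relative shift applied to each factor (default 0.10).
#' @param batch_rule `"majority"`, `"any"` or `"all"`.
#' @param not_applicable Named list: objective name -> character vector of
#'   factors not applicable for that objective.
#' @return Data frame of class `sensitivity_report`: `objective`, `factor`,
#'   `median_response`, `prop_responding`, `major_contributor` (logical),
#'   `not_applicable` (logical).
#' @export
classify_contributors <- function(batches, optimum, threshold = 0.10,
                                  delta = 0.10,
                                  batch_rule = c("majority", "any", "all"),
                                  not_applicable = list()) {
  batch_rule <- match.arg(batch_rule)
  if (!length(batches)) stop("empty batch list", call. = FALSE)
  if (is.null(names(batches)) || any(!nzchar(names(batches))))
    stop("batches must be a named list (objective names)", call. = FALSE)
  rows <- list()
  for (obj in names(batches)) {
    batch <- batches[[obj]]
    if (!inherits(batch, "model_batch") || !length(batch$models))
      stop("batch for objective '", obj, "' is empty or invalid",
           call. = FALSE)
    vars <- batch$models[[1]]$var_names
    na_factors <- not_applicable[[obj]]
    for (f in vars) {
      if (!is.null(na_factors) && f %in% na_factors) {
        rows[[length(rows) + 1L]] <- data.frame(
          objective = obj, factor = f, median_response = NA_real_,
          prop_responding = NA_real_, major_contributor = FALSE,
          not_applicable = TRUE)
        next
      }
      resp <- perturb_and_score(batch, optimum, f, delta)
      prop <- mean(resp >= threshold)
      flag <- switch(batch_rule,
                     majority = prop >= 0.5,
                     any = prop > 0,
                     all = prop == 1)
      rows[[length(rows) + 1L]] <- data.frame(
        objective = obj, factor = f,
        median_response = stats::median(resp),
        prop_responding = prop, major_contributor = flag,
        not_applicable = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  needed <- c("objective", "factor", "major_contributor", "not_applicable")
  if (!all(needed %in% names(x))) {   # subsetted report: plain printing
    print.data.frame(x, row.names = FALSE)
    return(invisible(x))
  }
  cat("<sensitivity_report> major contributors per objective\n")
  grid <- contributor_grid(x)
  print.data.frame(grid, row.names = FALSE)
  invisible(x)
}

#' Contributor grid (objective x factor)
#'
#' Reshapes a sensitivity report into the compact yes/no/n-a summary grid:
#' one row per factor, one column per objective.
#'
#' @param report A `sensitivity_report`.
#' @return Data frame: `factor` plus one character column per objective with
#'   entries `"yes"`, `""` or `"n/a"`.
#' @export
contributor_grid <- function(report) {
  stopifnot(inherits(report, "sensitivity_report"))
  objs <- unique(report$objective)
  facs <- unique(report$factor)
  out <- data.frame(factor = facs, stringsAsFactors = FALSE)
  for (obj in objs) {
    sub <- report[report$objective == obj, ]
    cell <- vapply(facs, function(f) {
      row <- sub[sub$factor == f, ]
      if (!nrow(row)) return("")
      if (row$not_applicable[1]) "n/a" else if (row$major_contributor[1])
        "yes" else ""
    }, "")
    out[[obj]] <- unname(cell)
  }
  out
}
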