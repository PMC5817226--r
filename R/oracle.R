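# Synthetic wet-lab oracle: deterministic nonlinear response surfaces with
# multiplicative measurement noise, replication and occasional single missing
# values, so the whole optimization workflow can run without experiments.

gauss_bell <- function(x, center, width) exp(-0.5 * ((x - center) / width)^2)
saturating <- function(x, k) x / (x + k)

#' Construct a synthetic oracle
#'
#' An oracle binds a [design_space()] to one deterministic response function
#' per objective and a noise model: replicate measurements are the noiseless
#' response times lognormal noise with a given coefficient of variation, and
#' cells go missing independently with a small probability (never more than
#' one replicate per (condition, objective) cell, so the single-missing-value
#' repair rule always applies). At construction the oracle normalizes each
#' objective over the representable grid (exact enumeration for small
#' spaces, a large fixed-seed sample plus coordinate ascent otherwise) and
#' locates the condition maximizing the weighted composite score — the
#' ground-truth optimum used by recovery tests.
#'
#' @param space A [design_space()].
#' @param responses Named list of vectorized functions, one per objective;
#'   each takes a data frame of factor columns and returns a numeric vector.
#' @param cv Coefficient of variation of the multiplicative lognormal noise
#'   (default 0.1).
#' @param replicates Replicates per condition (default 3).
#' @param missing_prob Probability that a (condition, objective) cell loses
#'   one replicate (default 0.02).
#' @param noise `"lognormal"` (default) or `"gaussian"` (additive, sd =
#'   `cv * |response|`).
#' @param name Oracle label.
#' @return An object of class `oracle_spec`.
#' @export
oracle_spec <- function(space, responses, cv = 0.1, replicates = 3L,
                        missing_prob = 0.02, noise = c("lognormal", "gaussian"),
                        name = "oracle") {
  stopifnot(inherits(space, "design_space"), cv >= 0, replicates >= 1L,
            missing_prob >= 0, missing_prob <= 1)
  noise <- match.arg(noise)
  onames <- names(space$objectives)
  if (!setequal(names(responses), onames))
    stop("responses must be named exactly by the objectives: ",
         paste(onames, collapse = ", "), call. = FALSE)
  spec <- structure(
    list(space = space, responses = responses[onames], cv = cv,
         replicates = as.integer(replicates), missing_prob = missing_prob,
         noise = noise, name = name,
         norm_ranges = NULL, optimum = NULL),
    class = "oracle_spec")
  spec <- oracle_calibrate(spec)
  spec
}

#' @export
print.oracle_spec <- function(x, ...) {
  cat(sprintf("<oracle_spec '%s'> %d factors, %d objectives; CV %.2g, %d replicates, missing prob %.2g\n",
              x$name, length(x$space$factors), length(x$space$objectives),
              x$cv, x$replicates, x$missing_prob))
  opt <- x$optimum$values
  cat("  optimum:", paste(sprintf("%s=%.4g", names(opt), opt), collapse = ", "),
      sprintf("(composite %.4f)\n", x$optimum$composite))
  invisible(x)
}

#' Noiseless oracle responses
#'
#' @param spec An [oracle_spec()].
#' @param conditions Data frame with one column per factor.
#' @return Data frame with one column per objective.
#' @export
oracle_noiseless <- function(spec, conditions) {
  stopifnot(inherits(spec, "oracle_spec"))
  missing <- setdiff(names(spec$space$factors), names(conditions))
  if (length(missing))
    stop("conditions lack factor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- lapply(spec$responses, function(f) f(conditions))
  as.data.frame(out)
}

#' Composite ground-truth score of conditions
#'
#' The weighted sum of the noiseless objective responses, each min-max
#' normalized over the oracle's construction-time range for that objective
#' (minimize objectives contribute one minus the normalized term; terms are
#' clamped to \[0, 1\]). This is the fixed-normalization analogue of the
#' per-generation fitness and serves as an absolute yardstick across
#' generations in tests.
#'
#' @param spec An [oracle_spec()].
#' @param conditions Data frame with one column per factor.
#' @return Numeric vector of composite scores in \[0, 1\].
#' @export
oracle_composite <- function(spec, conditions) {
  resp <- oracle_noiseless(spec, conditions)
  score <- numeric(nrow(conditions))
  for (obj in spec$space$objectives) {
    rg <- spec$norm_ranges[[obj$name]]
    term <- (resp[[obj$name]] - rg[1]) / (rg[2] - rg[1])
    term <- pmin(1, pmax(0, term))
    if (obj$direction == "minimize") term <- 1 - term
    score <- score + obj$weight * term
  }
  score
}

#' Enumerate the full representable grid of a design space
#'
#' All `prod(2^bits)` condition sets, one row each. Only sensible for small
#' spaces; refuses above `max_points`.
#'
#' @param space A [design_space()].
#' @param max_points Guard against combinatorial explosion (default 65536).
#' @return Data frame with one column per factor.
#' @export
enumerate_grid <- function(space, max_points = 65536) {
  stopifnot(inherits(space, "design_space"))
  if (space_size(space) > max_points)
    stop("grid has ", space_size(space), " points; refusing above ",
         max_points, call. = FALSE)
  grids <- lapply(space$factors, level_values)
  out <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(out) <- names(space$factors)
  out
}

# Conditions data frame for a set of 0-based level-index vectors (rows).
indices_to_conditions <- function(space, idx_mat) {
  out <- lapply(seq_along(space$factors), function(i) {
    f <- space$factors[[i]]
    f$min_value + idx_mat[, i] * (f$max_value - f$min_value) /
      (2L^f$bits - 1L)
  })
  names(out) <- names(space$factors)
  as.data.frame(out)
}

# Construction-time calibration: objective normalization ranges + the
# grid-optimal condition for the weighted composite.
oracle_calibrate <- function(spec) {
  space <- spec$space
  small <- space_size(space) <= 65536
  old <- set_local_seed(760421L)   # fixed internal seed: calibration is part
  on.exit(restore_seed(old))       # of the oracle definition, not a dial
  if (small) {
    grid <- enumerate_grid(space)
    sample_df <- grid
  } else {
    n <- 4096L
    sample_df <- as.data.frame(lapply(space$factors, function(f)
      stats::runif(n, f$min_value, f$max_value)))
    names(sample_df) <- names(space$factors)
  }
  resp <- as.data.frame(lapply(spec$responses, function(f) f(sample_df)))
  spec$norm_ranges <- lapply(names(space$objectives), function(o)
    range(resp[[o]]))
  names(spec$norm_ranges) <- names(space$objectives)

  if (small) {
    comp <- oracle_composite_of(spec, grid)
    best <- which.max(comp)
    idx <- vapply(seq_along(space$factors), function(i) {
      f <- space$factors[[i]]
      which.min(abs(level_values(f) - grid[best, i])) - 1L
    }, 0L)
    spec$optimum <- list(values = stats::setNames(as.numeric(unlist(grid[best, ])),
                                                  names(space$factors)),
                         level_indices = stats::setNames(idx,
                                                         names(space$factors)),
                         composite = comp[best])
  } else {
    spec$optimum <- oracle_coordinate_ascent(spec, sample_df)
  }
  spec$optimum$objectives <- as.data.frame(
    lapply(spec$responses, function(f)
      f(as.data.frame(as.list(spec$optimum$values)))))
  spec
}

# composite before spec$optimum exists (used during calibration)
oracle_composite_of <- function(spec, conditions) {
  resp <- as.data.frame(lapply(spec$responses, function(f) f(conditions)))
  score <- numeric(nrow(conditions))
  for (obj in spec$space$objectives) {
    rg <- spec$norm_ranges[[obj$name]]
    term <- (resp[[obj$name]] - rg[1]) / (rg[2] - rg[1])
    term <- pmin(1, pmax(0, term))
    if (obj$direction == "minimize") term <- 1 - term
    score <- score + obj$weight * term
  }
  score
}

oracle_coordinate_ascent <- function(spec, sample_df) {
  space <- spec$space
  nf <- length(space$factors)
  snap <- function(values) {
    vapply(seq_len(nf), function(i) {
      f <- space$factors[[i]]
      which.min(abs(level_values(f) - values[[i]])) - 1L
    }, 0L)
  }
  ascend <- function(idx) {
    repeat {
      moved <- FALSE
      for (i in seq_len(nf)) {
        f <- space$factors[[i]]
        cand <- matrix(rep(idx, each = n_levels(f)), nrow = n_levels(f))
        cand[, i] <- seq_len(n_levels(f)) - 1L
        comp <- oracle_composite_of(spec, indices_to_conditions(space, cand))
        best <- which.max(comp)
        if (cand[best, i] != idx[i]) {
          idx[i] <- cand[best, i]
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    idx
  }
  mid <- vapply(space$factors, function(f) n_levels(f) %/% 2L, 0L)
  comp_sample <- oracle_composite_of(spec, sample_df)
  starts <- list(mid, snap(as.numeric(unlist(sample_df[which.max(comp_sample), ]))))
  for (r in 1:3) {
    starts[[length(starts) + 1L]] <-
      vapply(space$factors, function(f) sample.int(n_levels(f), 1L) - 1L, 0L)
  }
  results <- lapply(starts, ascend)
  comps <- vapply(results, function(idx)
    oracle_composite_of(spec, indices_to_conditions(space,
                                                    matrix(idx, nrow = 1))), 0)
  best <- results[[which.max(comps)]]
  cond <- indices_to_conditions(space, matrix(best, nrow = 1))
  list(values = stats::setNames(as.numeric(unlist(cond[1, ])), names(space$factors)),
       level_indices = stats::setNames(best, names(space$factors)),
       composite = max(comps))
}

#' Ground-truth optimum of an oracle
#'
#' @param spec An [oracle_spec()].
#' @return List: `values` (named condition), `level_indices` (0-based encoded
#'   levels), `objectives` (noiseless responses there), `composite` (its
#'   composite score).
#' @export
true_optimum <- function(spec) {
  stopifnot(inherits(spec, "oracle_spec"))
  spec$optimum
}

#' Simulate measurement of a proposed design
#'
#' Produces a replicate results table for a proposed design, in exactly the
#' schema the ingest step expects: per condition and objective, the noiseless
#' response times independent lognormal noise of the stated CV, replicated;
#' cells lose at most one replicate each, independently with the stated
#' missing-value probability. Deterministic given `seed`.
#'
#' @param spec An [oracle_spec()].
#' @param design Data frame with `condition_id` plus one column per factor
#'   (the propose-step output).
#' @param seed Integer seed.
#' @return Data frame: `condition_id`, `replicate`, one column per objective
#'   (`NA` = missing).
#' @export
oracle_respond <- function(spec, design, seed = 1L) {
  stopifnot(inherits(spec, "oracle_spec"))
  if (!"condition_id" %in% names(design))
    stop("design must have a condition_id column", call. = FALSE)
  fnames <- names(spec$space$factors)
  missing <- setdiff(fnames, names(design))
  if (length(missing))
    stop("design lacks factor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(design), c("condition_id", "generation", fnames))
  if (length(extra))
    stop("design has unexpected column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  base <- oracle_noiseless(spec, design[, fnames, drop = FALSE])
  n <- nrow(design); r <- spec$replicates
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  out <- data.frame(
    condition_id = rep(as.character(design$condition_id), each = r),
    replicate = rep(seq_len(r), times = n),
    stringsAsFactors = FALSE)
  sdlog <- sqrt(log(1 + spec$cv^2))
  for (obj in names(spec$space$objectives)) {
    mu <- rep(base[[obj]], each = r)
    vals <- if (spec$cv == 0) {
      mu
    } else if (spec$noise == "lognormal") {
      mu * stats::rlnorm(n * r, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      mu + stats::rnorm(n * r, 0, spec$cv * abs(mu))
    }
    if (spec$missing_prob > 0 && r >= 2L) {
      # at most one blanked replicate per (condition, objective) cell
      hit <- stats::runif(n) < spec$missing_prob
      which_rep <- sample.int(r, n, replace = TRUE)
      for (i in which(hit)) vals[(i - 1L) * r + which_rep[i]] <- NA_real_
    }
    out[[obj]] <- vals
  }
  out
}

#' Case-study-style nine-factor oracle
#'
#' Emulates a fed-batch-free small-culture optimization of a
#' methanol-inducible recombinant-protein system: nine factors (eight medium
#' components plus pH) and four objectives — pre-induction biomass `ODbi`
#' (maximize), induction-phase biomass increase `ODd` (minimize), secreted
#' enzyme activity `Ea` (maximize), and specific productivity `P = Ea /
#' (ODbi + ODd)` (maximize), all equally weighted. Responses combine
#' saturating (Monod-style) uptake terms, Gaussian pH optima and their
#' products, so that some factors interact, several factors (potassium,
#' magnesium, iron, calcium) are deliberately null, and plain linear
#' regression underfits the surface. Gene length defaults to 3 bits so
#' level grids stay small in tests; the physical optimum does not depend on
#' the discretization.
#'
#' @param bits Bits per factor gene (default 3).
#' @param cv Noise CV (default 0.1).
#' @param replicates Replicates per condition (default 3).
#' @param missing_prob Missing-cell probability (default 0.02).
#' @return An [oracle_spec()].
#' @export
case_study_oracle <- function(bits = 3L, cv = 0.1, replicates = 3L,
                              missing_prob = 0.02) {
  factors <- list(
    factor_spec("ammonium", 0.5, 15, bits, "g/L"),
    factor_spec("potassium", 0.5, 8, bits, "g/L"),
    factor_spec("magnesium", 0.1, 6, bits, "g/L"),
    factor_spec("iron", 0.01, 0.5, bits, "g/L"),
    factor_spec("calcium", 0.05, 2, bits, "g/L"),
    factor_spec("glycerol", 1, 20, bits, "g/L"),
    factor_spec("methanol", 0.5, 12, bits, "g/L"),
    factor_spec("sorbitol", 0, 15, bits, "g/L"),
    factor_spec("pH", 2.6, 7.0, bits, "pH"))
  objectives <- list(
    objective_spec("ODbi", "maximize", 0.25),
    objective_spec("ODd", "minimize", 0.25),
    objective_spec("Ea", "maximize", 0.25),
    objective_spec("P", "maximize", 0.25))
  space <- design_space(factors, objectives)
  # Each objective prefers a different window of the shared factors
  # (glycerol overflow above ~9 g/L hurts growth; methanol is inducing at
  # ~5 g/L but toxic beyond; the activity pH optimum sits above the growth
  # one), so the composite optimum lies on an informative slope of every
  # objective rather than on a flat saturation plateau.
  odbi <- function(d) 2 + 28 * gauss_bell(d$glycerol, 9, 2.5) *
    (0.4 + 0.6 * saturating(d$ammonium, 2)) * gauss_bell(d$pH, 5.5, 1.2)
  odd <- function(d) 1 + 0.08 * d$methanol^2 * gauss_bell(d$pH, 6.2, 2.0) +
    2.5 * saturating(d$sorbitol, 7)
  ea <- function(d) 150 * gauss_bell(d$methanol, 5, 2.0) *
    gauss_bell(d$pH, 6.6, 0.8) * (0.5 + 0.5 * gauss_bell(d$glycerol, 6, 3.0))
  responses <- list(
    ODbi = odbi,
    ODd = odd,
    Ea = ea,
    P = function(d) ea(d) / (odbi(d) + odd(d)))
  oracle_spec(space, responses, cv = cv, replicates = replicates,
              missing_prob = missing_prob, name = "case_study")
}

#' Two-driver factor-recovery oracle
#'
#' A nine-factor oracle in which only pH and glycerol enter the response
#' functions — the other seven factors are exactly null. The two objectives
#' (secreted activity, to maximize, and overflow byproduct, to minimize)
#' place their pH and glycerol optima at different locations, so the
#' composite optimum sits on a steep flank of both factors and their true
#' perturbation responses are far above the 10 % classification threshold.
#' This is the benchmark for end-to-end sensitivity recovery: a correct
#' pipeline must flag pH and glycerol and nothing else.
#'
#' @inheritParams case_study_oracle
#' @return An [oracle_spec()].
#' @export
sensitivity_oracle <- function(bits = 3L, cv = 0.1, replicates = 3L,
                               missing_prob = 0.02) {
  factors <- list(
    factor_spec("ammonium", 0.5, 15, bits, "g/L"),
    factor_spec("potassium", 0.5, 8, bits, "g/L"),
    factor_spec("magnesium", 0.1, 6, bits, "g/L"),
    factor_spec("iron", 0.01, 0.5, bits, "g/L"),
    factor_spec("calcium", 0.05, 2, bits, "g/L"),
    factor_spec("glycerol", 1, 20, bits, "g/L"),
    factor_spec("methanol", 0.5, 12, bits, "g/L"),
    factor_spec("sorbitol", 0, 15, bits, "g/L"),
    factor_spec("pH", 2.6, 7.0, bits, "pH"))
  objectives <- list(
    objective_spec("activity", "maximize", 0.5),
    objective_spec("overflow", "minimize", 0.5))
  space <- design_space(factors, objectives)
  responses <- list(
    activity = function(d) 100 * gauss_bell(d$pH, 6.5, 0.6) *
      gauss_bell(d$glycerol, 9, 1.8),
    overflow = function(d) 2 + 15 * gauss_bell(d$glycerol, 14, 3.5) *
      gauss_bell(d$pH, 7.5, 1.0))
  oracle_spec(space, responses, cv = cv, replicates = replicates,
              missing_prob = missing_prob, name = "two_driver")
}

#' Tiny two-factor unimodal oracle
#'
#' A noiseless (by default) single-objective bell-shaped surface over two
#' 3-bit factors: 64 grid points, exhaustively enumerable, with a unique
#' known optimum. The work-horse of brute-force search-quality tests.
#'
#' @param bits Bits per factor (default 3).
#' @param cv Noise CV (default 0, i.e. noiseless).
#' @param replicates Replicates per condition (default 3).
#' @param missing_prob Missing-cell probability (default 0).
#' @return An [oracle_spec()].
#' @export
tiny_oracle <- function(bits = 3L, cv = 0, replicates = 3L,
                        missing_prob = 0) {
  space <- design_space(
    factors = list(factor_spec("x1", 0, 10, bits),
                   factor_spec("x2", 2, 8, bits)),
    objectives = list(objective_spec("y", "maximize", 1)))
  responses <- list(
    y = function(d) 10 * gauss_bell(d$x1, 6.5, 2.2) * gauss_bell(d$x2, 4.0, 1.6))
  oracle_spec(space, responses, cv = cv, replicates = replicates,
              missing_prob = missing_prob, name = "tiny")
}
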