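# Multigene genetic-programming symbolic regression.
#
# A model is an intercept plus a least-squares-weighted sum of several
# evolved expression trees ("genes"). Tree structure evolves by tournament
# selection, subtree crossover, high-level gene swaps and subtree mutation;
# gene weights are re-fit by ordinary least squares at every evaluation, so
# the GP searches model structure while linear algebra handles coefficients.

# ---- expression trees -------------------------------------------------------

node_op <- function(op, l, r) list(type = "op", op = op, l = l, r = r)
node_var <- function(name) list(type = "var", var = name)
node_const <- function(value) list(type = "const", value = value)

SR_OPS <- c("add", "sub", "mul", "div")

#' Evaluate an expression tree
#'
#' Recursively evaluates a tree over vectors of factor values. The four
#' allowed operations are addition, subtraction, multiplication and protected
#' division: when the denominator magnitude falls below `1e-12` the division
#' returns the numerator unchanged, so evaluation never raises and never
#' returns a non-finite value for finite inputs.
#'
#' @param tree An expression tree (as built by the SR engine).
#' @param x Named list or data frame supplying one numeric vector (or
#'   scalar) per factor referenced by the tree.
#' @return Numeric vector of evaluated values.
#' @export
evaluate_tree <- function(tree, x) {
  switch(tree$type,
    const = tree$value,
    var = {
      if (is.null(x[[tree$var]]))
        stop("tree references unknown factor '", tree$var, "'", call. = FALSE)
      x[[tree$var]]
    },
    op = {
      a <- evaluate_tree(tree$l, x)
      b <- evaluate_tree(tree$r, x)
      switch(tree$op,
        add = a + b,
        sub = a - b,
        mul = a * b,
        div = ifelse(abs(b) < 1e-12, a, a / b))
    },
    stop("malformed tree node", call. = FALSE))
}

tree_depth <- function(tree) {
  if (tree$type != "op") return(1L)
  1L + max(tree_depth(tree$l), tree_depth(tree$r))
}

# Flatten to a preorder list of nodes with their depth (for random picks).
tree_nodes <- function(tree, depth = 1L, path = integer()) {
  self <- list(list(path = path, depth = depth, type = tree$type))
  if (tree$type != "op") return(self)
  c(self,
    tree_nodes(tree$l, depth + 1L, c(path, 1L)),
    tree_nodes(tree$r, depth + 1L, c(path, 2L)))
}

get_subtree <- function(tree, path) {
  for (step in path) tree <- if (step == 1L) tree$l else tree$r
  tree
}

set_subtree <- function(tree, path, sub) {
  if (!length(path)) return(sub)
  if (path[1] == 1L) tree$l <- set_subtree(tree$l, path[-1], sub)
  else tree$r <- set_subtree(tree$r, path[-1], sub)
  tree
}

# Random tree generation ("grow" may stop early, "full" reaches max_depth).
random_tree <- function(vars, max_depth, method = "grow",
                        const_range = c(-10, 10), p_const = 0.25) {
  make <- function(depth_left) {
    terminal <- if (depth_left <= 1L) TRUE
      else if (method == "full") FALSE
      else stats::runif(1) < 0.3
    if (terminal) {
      if (stats::runif(1) < p_const)
        node_const(stats::runif(1, const_range[1], const_range[2]))
      else
        node_var(sample(vars, 1L))
    } else {
      node_op(sample(SR_OPS, 1L), make(depth_left - 1L), make(depth_left - 1L))
    }
  }
  make(max_depth)
}

tree_to_string <- function(tree) {
  switch(tree$type,
    const = formatC(tree$value, format = "g", digits = 4),
    var = tree$var,
    op = {
      sym <- c(add = "+", sub = "-", mul = "*", div = "/")[[tree$op]]
      paste0("(", tree_to_string(tree$l), " ", sym, " ",
             tree_to_string(tree$r), ")")
    })
}

# ---- least-squares gene weighting ------------------------------------------

# OLS of y on columns of G with intercept; minimal-norm solution when the
# design is rank deficient. p_predictors enters the adjusted R^2.
ols_fit <- function(G, y, p_predictors = ncol(G)) {
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, G)
  qr_x <- qr(X)
  if (qr_x$rank == ncol(X)) {
    coef <- qr.coef(qr_x, y)
    rank_deficient <- FALSE
  } else {
    sv <- svd(X)
    keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    coef <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
    coef <- drop(coef)
    names(coef) <- colnames(X)
    rank_deficient <- TRUE
  }
  fitted <- drop(X %*% coef)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("response is constant; R^2 set to ",
            if (ss_res < 1e-24) "1" else "0", call. = FALSE)
    r2 <- if (ss_res < 1e-24) 1.0 else 0.0
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  p <- p_predictors
  adj_r2 <- if (n > p + 1) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  list(coefficients = coef, fitted = fitted, r2 = r2, adj_r2 = adj_r2,
       rmse = sqrt(ss_res / n), rank_deficient = rank_deficient)
}

#' Fit least-squares weights for a set of genes
#'
#' Evaluates each expression tree on the training data and regresses the
#' response on the gene outputs (with intercept) by ordinary least squares.
#' A rank-deficient gene design (e.g. duplicate genes) is solved by the
#' minimal-norm pseudo-inverse solution. The number of predictors in the
#' adjusted R-squared is the number of genes.
#'
#' @param genes List of expression trees.
#' @param x Data frame of factor values (one column per factor).
#' @param y Numeric response vector.
#' @return A `gp_model`: genes, intercept, per-gene weights, and training
#'   `r2`, `adj_r2`, `rmse`.
#' @export
fit_weights <- function(genes, x, y) {
  stopifnot(length(genes) >= 1L, is.data.frame(x), nrow(x) == length(y),
            length(y) >= 1L, all(is.finite(y)))
  G <- vapply(genes, function(g) rep_len(evaluate_tree(g, x), nrow(x)),
              numeric(nrow(x)))
  if (is.null(dim(G))) G <- matrix(G, nrow = nrow(x))
  colnames(G) <- paste0("gene", seq_along(genes))
  fit <- ols_fit(G, y, p_predictors = length(genes))
  new_gp_model(genes, fit, names(x), length(y))
}

new_gp_model <- function(genes, fit, var_names, n_train) {
  structure(list(genes = genes,
                 intercept = unname(fit$coefficients[1]),
                 weights = unname(fit$coefficients[-1]),
                 r2 = fit$r2, adj_r2 = fit$adj_r2, rmse = fit$rmse,
                 rank_deficient = fit$rank_deficient,
                 var_names = var_names, n_train = n_train),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model> %d gene(s); R^2 = %.4f, adj R^2 = %.4f, RMSE = %.4g\n",
              length(x$genes), x$r2, x$adj_r2, x$rmse))
  cat(sprintf("  y = %.4g\n", x$intercept))
  for (i in seq_along(x$genes)) {
    cat(sprintf("    %+.4g * %s\n", x$weights[i], tree_to_string(x$genes[[i]])))
  }
  invisible(x)
}

#' Predict from a multigene model
#'
#' @param object A `gp_model`.
#' @param newdata Data frame or named list of factor values.
#' @param ... Unused.
#' @return Numeric vector of predictions
#'   `intercept + sum_g weight_g * gene_g(x)`.
#' @export
predict.gp_model <- function(object, newdata, ...) {
  n <- if (is.data.frame(newdata)) nrow(newdata)
       else max(lengths(newdata))
  pred <- rep(object$intercept, n)
  for (i in seq_along(object$genes)) {
    pred <- pred + object$weights[i] *
      rep_len(evaluate_tree(object$genes[[i]], newdata), n)
  }
  pred
}

# ---- SR parameters ----------------------------------------------------------

#' Symbolic-regression parameters
#'
#' Defaults follow standard multigene-GP practice: up to 5 genes of depth at
#' most 4, tournament size 2, operator mix 0.85/0.10/0.05
#' (crossover/mutation/reproduction), one elite model per generation, and a
#' population of 500 evolved for 500 generations (reduce both for small
#' datasets or quick exploratory fits).
#'
#' @param population_size Number of candidate models per generation.
#' @param generations Number of generations to evolve.
#' @param max_genes Maximum genes per model.
#' @param max_depth Maximum tree depth (a lone terminal has depth 1).
#' @param tournament_size Tournament size for parent selection.
#' @param p_crossover,p_mutation,p_reproduction Operator probabilities
#'   (must sum to 1).
#' @param p_gene_swap Probability that a crossover is a high-level gene swap
#'   rather than a subtree crossover, when both parents have >= 2 genes.
#' @param elitism Number of best models copied unchanged each generation.
#' @param const_range Range for random numeric constants in trees.
#' @param seed Integer RNG seed; identical seed, identical model.
#' @return An object of class `sr_params`.
#' @export
sr_params <- function(population_size = 500L, generations = 500L,
                      max_genes = 5L, max_depth = 4L, tournament_size = 2L,
                      p_crossover = 0.85, p_mutation = 0.10,
                      p_reproduction = 0.05, p_gene_swap = 0.2,
                      elitism = 1L, const_range = c(-10, 10), seed = 1L) {
  probs <- c(p_crossover, p_mutation, p_reproduction)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("operator probabilities must be >= 0 and sum to 1", call. = FALSE)
  stopifnot(population_size >= 2L, generations >= 1L, max_genes >= 1L,
            max_depth >= 1L, tournament_size >= 1L, elitism >= 0L,
            length(const_range) == 2L, const_range[1] < const_range[2])
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 max_genes = as.integer(max_genes),
                 max_depth = as.integer(max_depth),
                 tournament_size = as.integer(tournament_size),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 p_reproduction = p_reproduction, p_gene_swap = p_gene_swap,
                 elitism = as.integer(elitism),
                 const_range = as.numeric(const_range),
                 seed = as.integer(seed)),
            class = "sr_params")
}

# ---- evolution --------------------------------------------------------------

# Internal individual: genes + cached gene-evaluation matrix + OLS fit.
sr_individual <- function(genes, x, y, G = NULL, refit = seq_along(genes)) {
  n <- nrow(x)
  if (is.null(G)) G <- matrix(NA_real_, n, length(genes))
  if (ncol(G) != length(genes)) {
    G2 <- matrix(NA_real_, n, length(genes))
    keep <- seq_len(min(ncol(G), length(genes)))
    G2[, keep] <- G[, keep]
    G <- G2
  }
  for (j in refit) G[, j] <- rep_len(evaluate_tree(genes[[j]], x), n)
  if (!all(is.finite(G))) {
    return(list(genes = genes, G = G, fit = NULL, rmse = Inf))
  }
  fit <- ols_fit(G, y, p_predictors = length(genes))
  rmse <- if (is.finite(fit$rmse)) fit$rmse else Inf
  list(genes = genes, G = G, fit = fit, rmse = rmse)
}

tournament_pick <- function(pop, k) {
  idx <- sample.int(length(pop), k, replace = TRUE)
  rmses <- vapply(pop[idx], `[[`, 0, "rmse")
  idx[which.min(rmses)]
}

sr_mutate_ind <- function(ind, vars, params, x, y) {
  genes <- ind$genes
  u <- stats::runif(1)
  if (u < 0.2 && length(genes) < params$max_genes) {
    # add a fresh gene
    genes[[length(genes) + 1L]] <- random_tree(vars, params$max_depth, "grow",
                                               params$const_range)
    return(sr_individual(genes, x, y, G = ind$G, refit = length(genes)))
  }
  if (u < 0.3 && length(genes) > 1L) {
    # delete a random gene
    j <- sample.int(length(genes), 1L)
    genes[[j]] <- NULL
    return(sr_individual(genes, x, y))
  }
  # subtree mutation within a random gene
  j <- sample.int(length(genes), 1L)
  nodes <- tree_nodes(genes[[j]])
  pick <- nodes[[sample.int(length(nodes), 1L)]]
  budget <- max(1L, params$max_depth - pick$depth + 1L)
  sub <- random_tree(vars, budget, "grow", params$const_range)
  genes[[j]] <- set_subtree(genes[[j]], pick$path, sub)
  sr_individual(genes, x, y, G = ind$G, refit = j)
}

sr_crossover_ind <- function(ind1, ind2, vars, params, x, y) {
  g1 <- ind1$genes; g2 <- ind2$genes
  if (length(g1) >= 2L && length(g2) >= 2L &&
      stats::runif(1) < params$p_gene_swap) {
    # high-level gene swap: replace one whole gene of parent 1 by one of
    # parent 2
    j1 <- sample.int(length(g1), 1L)
    j2 <- sample.int(length(g2), 1L)
    g1[[j1]] <- g2[[j2]]
    return(sr_individual(g1, x, y, G = ind1$G, refit = j1))
  }
  # subtree crossover within one random gene of each parent
  j1 <- sample.int(length(g1), 1L)
  j2 <- sample.int(length(g2), 1L)
  n1 <- tree_nodes(g1[[j1]])
  n2 <- tree_nodes(g2[[j2]])
  pick1 <- n1[[sample.int(length(n1), 1L)]]
  pick2 <- n2[[sample.int(length(n2), 1L)]]
  donor <- get_subtree(g2[[j2]], pick2$path)
  candidate <- set_subtree(g1[[j1]], pick1$path, donor)
  if (tree_depth(candidate) > params$max_depth) {
    # depth cap exceeded: keep parent 1's gene (hoist-style fallback)
    return(sr_individual(g1, x, y, G = ind1$G, refit = integer()))
  }
  g1[[j1]] <- candidate
  sr_individual(g1, x, y, G = ind1$G, refit = j1)
}

#' Evolve a multigene symbolic-regression model
#'
#' Runs the GP search: ramped half-and-half initialization; per generation,
#' tournament selection followed by subtree crossover (with an occasional
#' high-level gene swap between models), subtree mutation (which may also add
#' or drop a gene), and reproduction, with the best model preserved by
#' elitism. Model fitness is training RMSE after least-squares gene
#' weighting. The run is fully determined by `params$seed`.
#'
#' @param x Data frame of factor values (columns are the model variables).
#' @param y Numeric response vector (one value per row of `x`).
#' @param params An [sr_params()].
#' @return The best `gp_model` found (by training RMSE).
#' @export
evolve_models <- function(x, y, params = sr_params()) {
  stopifnot(is.data.frame(x), nrow(x) == length(y), all(is.finite(y)))
  if (nrow(unique(x)) < 2L)
    stop("training data needs at least 2 distinct rows", call. = FALSE)
  vars <- names(x)
  old <- set_local_seed(params$seed)
  on.exit(restore_seed(old))

  n_pop <- params$population_size
  depths <- rep(seq(2L, max(2L, params$max_depth)), length.out = n_pop)
  pop <- lapply(seq_len(n_pop), function(i) {
    n_genes <- sample.int(params$max_genes, 1L)
    method <- if (i %% 2L == 0L) "full" else "grow"
    genes <- lapply(seq_len(n_genes), function(j)
      random_tree(vars, depths[i], method, params$const_range))
    sr_individual(genes, x, y)
  })

  for (gen in seq_len(params$generations)) {
    rmses <- vapply(pop, `[[`, 0, "rmse")
    newpop <- vector("list", n_pop)
    n_elite <- min(params$elitism, n_pop)
    if (n_elite > 0L) {
      elite_idx <- order(rmses)[seq_len(n_elite)]
      newpop[seq_len(n_elite)] <- pop[elite_idx]
    }
    i <- n_elite
    while (i < n_pop) {
      i <- i + 1L
      op <- stats::runif(1)
      if (op < params$p_crossover) {
        p1 <- pop[[tournament_pick(pop, params$tournament_size)]]
        p2 <- pop[[tournament_pick(pop, params$tournament_size)]]
        newpop[[i]] <- sr_crossover_ind(p1, p2, vars, params, x, y)
      } else if (op < params$p_crossover + params$p_mutation) {
        p1 <- pop[[tournament_pick(pop, params$tournament_size)]]
        newpop[[i]] <- sr_mutate_ind(p1, vars, params, x, y)
      } else {
        p1 <- pop[[tournament_pick(pop, params$tournament_size)]]
        newpop[[i]] <- p1
      }
    }
    pop <- newpop
  }
  rmses <- vapply(pop, `[[`, 0, "rmse")
  best <- pop[[which.min(rmses)]]
  if (is.null(best$fit))
    stop("symbolic regression failed to produce a finite model", call. = FALSE)
  new_gp_model(best$genes, best$fit, vars, length(y))
}

#' Fit a batch of independently evolved models
#'
#' Runs [evolve_models()] `batch_size` times with distinct seeds derived from
#' `seed`, all on the same dataset, and returns the models sorted by training
#' R-squared (best first). A batch captures run-to-run variability of the GP
#' search; downstream sensitivity analysis asks how many models of a batch
#' agree on a factor's influence.
#'
#' @param x Data frame of factor values.
#' @param y Numeric response vector.
#' @param params An [sr_params()] (its `seed` is ignored in favour of the
#'   derived per-run seeds).
#' @param batch_size Number of independent runs (default 10).
#' @param seed Base seed for the batch.
#' @param objective Optional objective name carried in the result.
#' @return An object of class `model_batch`.
#' @export
fit_batch <- function(x, y, params = sr_params(), batch_size = 10L,
                      seed = params$seed, objective = NA_character_) {
  stopifnot(batch_size >= 1L)
  seeds <- vapply(seq_len(batch_size), function(i) derive_seed(seed, i, 7L), 0L)
  models <- lapply(seeds, function(s) {
    p <- params; p$seed <- s
    evolve_models(x, y, p)
  })
  r2s <- vapply(models, `[[`, 0, "r2")
  ord <- order(-r2s)
  structure(list(objective = objective, models = models[ord],
                 seeds = seeds[ord]),
            class = "model_batch")
}

#' @export
print.model_batch <- function(x, ...) {
  r2s <- vapply(x$models, `[[`, 0, "r2")
  cat(sprintf("<model_batch> %s: %d models, best R^2 = %.4f (median %.4f)\n",
              if (is.na(x$objective)) "(unnamed objective)" else x$objective,
              length(x$models), max(r2s), stats::median(r2s)))
  invisible(x)
}

#' Multiple linear regression baseline
#'
#' Ordinary least squares of the response on the raw factor values with an
#' intercept — the model a conventional DOE analysis would fit, used as the
#' comparison baseline for symbolic regression. A singular design is solved
#' by the minimal-norm solution with a warning. The adjusted R-squared uses
#' the number of factors as the number of predictors.
#'
#' @param x Data frame of factor values.
#' @param y Numeric response vector.
#' @return An object of class `mlr_model` with `coefficients`, `r2`,
#'   `adj_r2`, `rmse`.
#' @export
fit_mlr <- function(x, y) {
  stopifnot(is.data.frame(x), nrow(x) == length(y))
  if (nrow(x) <= ncol(x) + 1L)
    stop("MLR needs more rows than factors + 1", call. = FALSE)
  X <- as.matrix(x)
  fit <- ols_fit(X, y, p_predictors = ncol(x))
  if (fit$rank_deficient)
    warning("singular MLR design; minimal-norm solution used", call. = FALSE)
  structure(list(coefficients = fit$coefficients, r2 = fit$r2,
                 adj_r2 = fit$adj_r2, rmse = fit$rmse,
                 var_names = names(x)),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model> %d predictors; R^2 = %.4f, adj R^2 = %.4f\n",
              length(x$var_names), x$r2, x$adj_r2))
  invisible(x)
}

#' Predict from an MLR baseline model
#'
#' @param object An `mlr_model`.
#' @param newdata Data frame of factor values.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata[, object$var_names, drop = FALSE]))
  drop(X %*% object$coefficients)
}

# ---- model (de)serialization ------------------------------------------------

tree_to_plain <- function(tree) {
  switch(tree$type,
    const = list(type = "const", value = tree$value),
    var = list(type = "var", var = tree$var),
    op = list(type = "op", op = tree$op,
              l = tree_to_plain(tree$l), r = tree_to_plain(tree$r)))
}

tree_from_plain <- function(pl) {
  switch(pl$type,
    const = node_const(as.numeric(pl$value)),
    var = node_var(as.character(pl$var)),
    op = node_op(as.character(pl$op), tree_from_plain(pl$l),
                 tree_from_plain(pl$r)))
}

#' Write a model batch to JSON
#'
#' Machine-readable serialization of a batch (trees, weights, fit
#' statistics) for the sensitivity step or archival.
#'
#' @param batch A `model_batch`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_batch <- function(batch, path) {
  stopifnot(inherits(batch, "model_batch"))
  payload <- list(
    objective = batch$objective,
    seeds = batch$seeds,
    models = lapply(batch$models, function(m) list(
      genes = lapply(m$genes, tree_to_plain),
      intercept = m$intercept, weights = m$weights,
      r2 = m$r2, adj_r2 = m$adj_r2, rmse = m$rmse,
      var_names = m$var_names, n_train = m$n_train)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model batch from JSON
#'
#' @param path File written by [write_model_batch()].
#' @return A `model_batch`.
#' @export
read_model_batch <- function(path) {
  pl <- jsonlite::read_json(path)
  models <- lapply(pl$models, function(m) {
    structure(list(
      genes = lapply(m$genes, tree_from_plain),
      intercept = as.numeric(m$intercept),
      weights = as.numeric(unlist(m$weights)),
      r2 = as.numeric(m$r2), adj_r2 = as.numeric(m$adj_r2),
      rmse = as.numeric(m$rmse),
      rank_deficient = FALSE,
      var_names = as.character(unlist(m$var_names)),
      n_train = as.integer(m$n_train)), class = "gp_model")
  })
  structure(list(objective = if (is.null(pl$objective)) NA_character_
                             else pl$objective,
                 models = models,
                 seeds = as.integer(unlist(pl$seeds))),
            class = "model_batch")
}
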