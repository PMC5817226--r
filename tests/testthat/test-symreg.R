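# helpers to build trees by hand
op_ <- function(op, l, r) evodoe:::node_op(op, l, r)
var_ <- function(v) evodoe:::node_var(v)
const_ <- function(x) evodoe:::node_const(x)

test_that("expression trees evaluate with protected division", {
  tr <- op_("mul", op_("add", var_("x1"), var_("x2")), var_("x3"))
  expect_equal(evaluate_tree(tr, list(x1 = 1, x2 = 2, x3 = 3)), 9)
  # vectorized over data columns
  d <- data.frame(x1 = c(1, 2), x2 = c(2, 0), x3 = c(3, 10))
  expect_equal(evaluate_tree(tr, d), c(9, 20))
  # protected division returns the numerator at near-zero denominators
  dv <- op_("div", var_("x1"), var_("x2"))
  expect_equal(evaluate_tree(dv, list(x1 = 5, x2 = 0)), 5)
  expect_equal(evaluate_tree(dv, list(x1 = 5, x2 = 2)), 2.5)
  expect_equal(evaluate_tree(const_(3.5), list(x1 = 99)), 3.5)
  expect_error(evaluate_tree(var_("zz"), list(x1 = 1)), "unknown factor")
})

test_that("gene weights are fit by least squares with exact recovery", {
  x <- data.frame(x = seq(-3, 3, length.out = 20))
  y <- 2 * x$x + 1
  m <- fit_weights(list(var_("x")), x, y)
  expect_equal(m$weights, 2, tolerance = 1e-10)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  # uncorrelated noise against a constant gene: R^2 ~ 0
  set.seed(4)
  y2 <- rnorm(20)
  m2 <- fit_weights(list(const_(2)), x, y2)
  expect_lt(m2$r2, 1e-8)
})

test_that("duplicate genes get finite minimal-norm weights, same prediction", {
  x <- data.frame(x = seq(1, 5, length.out = 12))
  y <- 3 * x$x - 2
  m1 <- fit_weights(list(var_("x")), x, y)
  m2 <- fit_weights(list(var_("x"), var_("x")), x, y)
  expect_true(all(is.finite(m2$weights)))
  expect_equal(predict(m2, x), predict(m1, x), tolerance = 1e-8)
  # oracle: explicit pseudo-inverse solution of the duplicated design
  X <- cbind(1, x$x, x$x)
  sv <- svd(X)
  keep <- sv$d > 1e-10
  coef_pinv <- sv$v[, keep] %*% (crossprod(sv$u[, keep], y) / sv$d[keep])
  expect_equal(unname(c(m2$intercept, m2$weights)), drop(coef_pinv),
               tolerance = 1e-8)
})

test_that("R-squared conventions: adjusted formula and constant response", {
  x <- data.frame(a = rnorm(15), b = rnorm(15))
  set.seed(9)
  y <- x$a + rnorm(15, sd = 0.5)
  m <- fit_weights(list(var_("a"), var_("b")), x, y)
  expect_equal(m$adj_r2,
               1 - (1 - m$r2) * (15 - 1) / (15 - 2 - 1), tolerance = 1e-12)
  expect_lte(m$adj_r2, m$r2)
  expect_warning(mc <- fit_weights(list(var_("a")), x, rep(2, 15)),
                 "constant")
  expect_equal(mc$r2, 1.0)   # SSres = 0 on a constant response
})

test_that("adding a gene never increases the training RMSE", {
  set.seed(31)
  x <- data.frame(x1 = runif(30, -2, 2), x2 = runif(30, -2, 2))
  y <- x$x1^2 - x$x2 + rnorm(30, sd = 0.3)
  for (rep in 1:10) {
    genes <- lapply(seq_len(sample(1:4, 1)), function(i)
      evodoe:::random_tree(c("x1", "x2"), 3))
    extra <- evodoe:::random_tree(c("x1", "x2"), 3)
    rmse_small <- fit_weights(genes, x, y)$rmse
    rmse_big <- fit_weights(c(genes, list(extra)), x, y)$rmse
    expect_lte(rmse_big, rmse_small + 1e-9)
  }
})

test_that("evolution is deterministic and handles a constant target", {
  x <- data.frame(x1 = seq(0, 1, length.out = 10),
                  x2 = seq(2, 3, length.out = 10))
  y <- 2 * x$x1 + x$x2
  p <- sr_params(population_size = 30, generations = 8, seed = 77)
  m1 <- evolve_models(x, y, p)
  m2 <- evolve_models(x, y, p)
  expect_equal(m1, m2)
  y_const <- rep(5, 10)
  mc <- suppressWarnings(
    evolve_models(x, y_const, sr_params(population_size = 20,
                                        generations = 1, seed = 3)))
  expect_equal(mc$r2, 1.0)     # intercept alone suffices in generation 1
  expect_equal(unname(predict(mc, x)), y_const, tolerance = 1e-8)
  expect_error(evolve_models(x[c(1, 1), ], y[c(1, 1)], p), "distinct")
})

test_that("evolved predictions stay finite on the training domain", {
  set.seed(21)
  x <- data.frame(x1 = runif(40, 0, 10), x2 = runif(40, 0, 10))
  y <- x$x1 / (1 + x$x2) + rnorm(40, sd = 0.1)
  m <- evolve_models(x, y, sr_params(population_size = 60, generations = 15,
                                     seed = 5))
  grid <- expand.grid(x1 = seq(0, 10, length.out = 25),
                      x2 = seq(0, 10, length.out = 25))
  expect_true(all(is.finite(predict(m, grid))))
})

test_that("batches hold independently seeded models sorted by fit", {
  set.seed(8)
  x <- data.frame(x1 = runif(25, -1, 1), x2 = runif(25, -1, 1))
  y <- x$x1 * x$x2 + rnorm(25, sd = 0.2)
  p <- sr_params(population_size = 40, generations = 10)
  b <- fit_batch(x, y, p, batch_size = 4, seed = 10, objective = "y")
  expect_s3_class(b, "model_batch")
  expect_length(b$models, 4)
  r2s <- vapply(b$models, `[[`, 0, "r2")
  expect_equal(r2s, sort(r2s, decreasing = TRUE))
  rmses <- vapply(b$models, `[[`, 0, "rmse")
  expect_gte(length(unique(round(rmses, 10))), 2)  # distinct seeded runs
  # a batch of one equals a single evolve_models call with the derived seed
  b1 <- fit_batch(x, y, p, batch_size = 1, seed = 10)
  p1 <- p; p1$seed <- evodoe:::derive_seed(10, 1L, 7L)
  expect_equal(b1$models[[1]], evolve_models(x, y, p1))
})

test_that("batches survive a JSON round trip", {
  x <- data.frame(x1 = seq(0, 2, length.out = 12))
  y <- x$x1^2
  b <- fit_batch(x, y, sr_params(population_size = 30, generations = 8),
                 batch_size = 2, seed = 3, objective = "act")
  path <- tempfile(fileext = ".json")
  write_model_batch(b, path)
  b2 <- read_model_batch(path)
  expect_equal(b2$objective, "act")
  grid <- data.frame(x1 = seq(0, 2, length.out = 7))
  for (i in seq_along(b$models))
    expect_equal(predict(b2$models[[i]], grid), predict(b$models[[i]], grid),
                 tolerance = 1e-12)
})

test_that("MLR misses a pure interaction that symbolic regression captures", {
  g <- expand.grid(x1 = seq(-2, 2, length.out = 8),
                   x2 = seq(-2, 2, length.out = 8))
  y <- g$x1 * g$x2
  mlr <- fit_mlr(g, y)
  expect_lt(abs(mlr$r2), 1e-10)         # symmetric grid: no linear signal
  m <- evolve_models(g, y, sr_params(population_size = 100, generations = 30,
                                     seed = 2))
  expect_gt(m$r2, 0.9)
  # MLR basics: exact linear fit, adjusted <= raw
  y_lin <- 2 * g$x1 - g$x2 + 1
  mlr_lin <- fit_mlr(g, y_lin)
  expect_equal(mlr_lin$r2, 1, tolerance = 1e-12)
  expect_lte(mlr_lin$adj_r2, mlr_lin$r2)
  expect_error(fit_mlr(g[1:3, ], y[1:3]), "more rows")
})

test_that("a larger GP budget does not hurt the recovery target", {
  g <- expand.grid(x1 = seq(-2, 2, length.out = 4),
                   x2 = seq(-2, 2, length.out = 4),
                   x3 = seq(-2, 2, length.out = 4))
  y <- 3 * g$x1 + 2 * g$x1 * g$x2 - g$x3
  r2_at <- function(pop, gens, seed) {
    evolve_models(g, y, sr_params(population_size = pop, generations = gens,
                                  seed = seed))$r2
  }
  small <- vapply(1:3, function(s) r2_at(50, 50, 100 + s), 0)
  big <- vapply(1:3, function(s) r2_at(500, 500, 100 + s), 0)
  expect_gte(stats::median(big), stats::median(small) - 1e-9)
})
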