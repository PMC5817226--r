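test_that("replicate aggregation takes the median after single-value repair", {
  obj <- "y"
  tab <- data.frame(condition_id = rep(c("a", "b", "c"), each = 3),
                    replicate = rep(1:3, 3),
                    y = c(2, 4, 6,            # plain odd-count median
                          2, NA, 6,           # repair to (2, 4, 6)
                          1, 10, 100))        # robust to the outlier
  agg <- aggregate_replicates(tab, obj)
  expect_equal(agg$y[agg$condition_id == "a"], 4)
  expect_equal(agg$y[agg$condition_id == "b"], 4)
  expect_equal(agg$y[agg$condition_id == "c"], 10)
})

test_that("aggregation refuses unrepairable cells, naming them", {
  tab <- data.frame(condition_id = rep("a", 3), replicate = 1:3,
                    y = c(NA, NA, 6))
  expect_error(aggregate_replicates(tab, "y"), "a.*y")
  expect_error(aggregate_replicates(
    data.frame(condition_id = character(), replicate = integer(),
               y = numeric()), "y"), NA)  # empty table -> empty result
  tab1 <- data.frame(condition_id = "a", replicate = 1, y = NA_real_)
  expect_error(aggregate_replicates(tab1, "y"), "missing")
})

test_that("fitness is the weighted sum of per-generation min-max terms", {
  # one maximize objective, weight 1: values (10, 15, 20) -> (0, 0.5, 1)
  sp1 <- design_space(list(factor_spec("f", 0, 1)),
                      list(objective_spec("y", "maximize", 1)))
  agg <- data.frame(condition_id = c("a", "b", "c"), y = c(10, 15, 20))
  fit <- evaluate_fitness(sp1, agg)
  expect_equal(fit$score, c(0, 0.5, 1))

  # four objectives with equal weights; an individual at the favourable
  # extreme of every objective scores exactly 1, the opposite one exactly 0
  sp4 <- reference_space()
  agg4 <- data.frame(condition_id = c("best", "worst", "mid"),
                     ODbi = c(9, 3, 6), ODd = c(1, 5, 3),
                     Ea = c(80, 20, 50), P = c(12, 2, 7))
  fit4 <- evaluate_fitness(sp4, agg4)
  expect_equal(fit4$score[fit4$condition_id == "best"], 1)
  expect_equal(fit4$score[fit4$condition_id == "worst"], 0)
  # hand evaluation of the middle individual
  hand <- 0.25 * ((6 - 3) / 6 + (1 - (3 - 1) / 4) + (50 - 20) / 60 +
                    (7 - 2) / 10)
  expect_equal(fit4$score[fit4$condition_id == "mid"], hand)
  expect_true(all(fit4$score >= 0 & fit4$score <= 1))
})

test_that("a constant objective contributes 0.5 with a warning", {
  sp <- design_space(list(factor_spec("f", 0, 1)),
                     list(objective_spec("a", "maximize", 0.5),
                          objective_spec("b", "maximize", 0.5)))
  agg <- data.frame(condition_id = c("x", "y"), a = c(1, 2), b = c(3, 3))
  expect_warning(fit <- evaluate_fitness(sp, agg), "constant")
  expect_equal(fit$term.b, c(0.5, 0.5))
  expect_equal(fit$score, 0.5 * c(0, 1) + 0.5 * 0.5)
})

test_that("roulette selection within the truncated pool is score-proportional", {
  sp <- design_space(list(factor_spec("f", 0, 1)),
                     list(objective_spec("y", "maximize", 1)))
  fit <- structure(data.frame(condition_id = c("hi", "lo"),
                              term.y = c(1, 1 / 3), score = c(3, 1)),
                   class = c("fitness_result", "data.frame"))
  params <- ga_params(2, selection_fraction = 1)
  n <- 4000
  firsts <- vapply(seq_len(n), function(i)
    select_parent_pairs(fit, params, seed = i)[[1]][1], "")
  counts <- table(factor(firsts, levels = c("hi", "lo")))
  # expected 3:1; chi-square goodness of fit must not reject at p = 0.01
  expect_gt(stats::chisq.test(counts, p = c(0.75, 0.25))$p.value, 0.01)

  # all-equal scores: uniform within sampling error
  fit0 <- structure(data.frame(condition_id = c("a", "b", "c", "d"),
                               term.y = 1, score = c(2, 2, 2, 2)),
                    class = c("fitness_result", "data.frame"))
  params4 <- ga_params(4, selection_fraction = 1)
  firsts0 <- vapply(seq_len(n), function(i)
    select_parent_pairs(fit0, params4, seed = i)[[1]][1], "")
  expect_gt(stats::chisq.test(table(firsts0))$p.value, 0.01)
})

test_that("selection returns ceiling(N/2) pairs of distinct parents", {
  sp <- reference_space()
  fit <- structure(data.frame(condition_id = sprintf("G1_%02d", 1:16),
                              score = seq(0, 1, length.out = 16)),
                   class = c("fitness_result", "data.frame"))
  params <- ga_params(16)
  pairs <- select_parent_pairs(fit, params, seed = 7)
  expect_length(pairs, 8)
  expect_true(all(vapply(pairs, function(p) p[1] != p[2], TRUE)))
  # pool is the top half: the 8 lowest scorers never appear
  used <- unique(unlist(pairs))
  expect_true(all(used %in% sprintf("G1_%02d", 9:16)))
  # all-zero scores degrade to uniform draws without error
  fit0 <- fit; fit0$score <- 0
  expect_silent(select_parent_pairs(fit0, params, seed = 7))
})

test_that("single-point crossover swaps suffixes and conserves bits", {
  p1 <- chromosome(rep(0L, 6)); p2 <- chromosome(rep(1L, 6))
  # force the crossover branch and enumerate cut points via seeds
  seen <- character()
  for (s in 1:50) {
    set.seed(s)
    kids <- crossover(p1, p2, rate = 1)
    b1 <- kids[[1]]$bits; b2 <- kids[[2]]$bits
    # complementary halves: bitwise sum at each position conserved
    expect_equal(b1 + b2, rep(1L, 6))
    # child 1 is zeros then ones
    expect_true(all(diff(b1) >= 0))
    seen <- c(seen, paste(b1, collapse = ""))
  }
  expect_setequal(unique(seen),
                  c("000001", "000011", "000111", "001111", "011111"))
  set.seed(1)
  kids0 <- crossover(p1, p2, rate = 0)
  expect_equal(kids0[[1]]$bits, p1$bits)
  expect_equal(kids0[[2]]$bits, p2$bits)
  expect_error(crossover(p1, chromosome(rep(1L, 5)), 1), "different")
})

test_that("mutation flips exactly one bit with the stated probability", {
  ch <- chromosome(rep(0L, 10))
  set.seed(42)
  m1 <- mutate(ch, rate = 1)
  expect_equal(sum(m1$bits != ch$bits), 1L)
  expect_equal(sum(ch$bits), 0L)        # input untouched
  m0 <- mutate(ch, rate = 0)
  expect_equal(m0$bits, ch$bits)
  # Monte-Carlo: mutated fraction within the binomial 99 % interval of 0.1
  set.seed(7)
  n <- 10000
  mutated <- vapply(seq_len(n), function(i)
    any(mutate(ch, rate = 0.1)$bits != ch$bits), TRUE)
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.1) / n
  expect_gte(mean(mutated), ci[1])
  expect_lte(mean(mutated), ci[2])
})

test_that("generation turnover preserves size, length and determinism", {
  space <- reference_space()
  params <- ga_params(16, mutation_rate = 0.1, seed = 99)
  rec <- random_population(space, params)
  expect_equal(length(rec$population), 16L)
  expect_true(all(vapply(rec$population, function(ch)
    length(ch$bits), 0L) == 45L))
  agg <- data.frame(condition_id = vapply(rec$population, `[[`, "", "id"),
                    ODbi = runif(16, 1, 9), ODd = runif(16, 1, 5),
                    Ea = runif(16, 10, 90), P = runif(16, 1, 12))
  rec$fitness <- evaluate_fitness(space, agg)
  nxt1 <- next_generation(rec, params)
  nxt2 <- next_generation(rec, params)
  expect_equal(nxt1, nxt2)              # same state + seed -> identical
  expect_equal(length(nxt1$population), 16L)
  expect_equal(nxt1$generation, 2L)
  expect_false(any(duplicated(vapply(nxt1$population, `[[`, "", "id"))))
  expect_error(next_generation(random_population(space, params), params),
               "ingest")
})

test_that("zero-rate operators reproduce selected parents verbatim", {
  space <- small_space()
  params <- ga_params(6, crossover_rate = 0, mutation_rate = 0, seed = 5)
  rec <- random_population(space, params)
  agg <- data.frame(condition_id = vapply(rec$population, `[[`, "", "id"),
                    y = seq_len(6))
  rec$fitness <- evaluate_fitness(space, agg)
  nxt <- next_generation(rec, params)
  parent_strings <- vapply(rec$population, function(ch)
    paste(ch$bits, collapse = ""), "")
  child_strings <- vapply(nxt$population, function(ch)
    paste(ch$bits, collapse = ""), "")
  expect_true(all(child_strings %in% parent_strings))
})

test_that("random populations have fair-coin bits and differ across seeds", {
  space <- reference_space()
  params <- ga_params(200, seed = 3)
  rec <- random_population(space, params)
  bits <- unlist(lapply(rec$population, `[[`, "bits"))
  n <- length(bits)                      # 200 x 45 = 9000 draws
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(mean(bits), ci[1])
  expect_lte(mean(bits), ci[2])
  rec2 <- random_population(space, ga_params(200, seed = 4))
  expect_false(identical(lapply(rec$population, `[[`, "bits"),
                         lapply(rec2$population, `[[`, "bits")))
})
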