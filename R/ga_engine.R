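# GA engine: fitness evaluation, selection, crossover, mutation, turnover.

#' GA parameters
#'
#' Operational parameters of the genetic algorithm. Defaults follow common
#' practice for laboratory optimization problems: the fitter half of the
#' population forms the mating pool (selection fraction 0.5), single-point
#' crossover at rate 0.9 per offspring pair, and single-bit mutation at rate
#' 0.01 per offspring chromosome (medium-optimization studies typically raise
#' this to about 0.1 to keep variability high in small populations).
#'
#' @param population_size Number of chromosomes per generation.
#' @param selection_fraction Fraction of the population (by score rank)
#'   admitted to the mating pool; in (0, 1].
#' @param crossover_rate Probability of a single-point crossover per pair.
#' @param mutation_rate Probability that an offspring chromosome receives a
#'   single-bit mutation.
#' @param elitism Number of best individuals copied unchanged into the next
#'   generation (0 = off, the default).
#' @param seed Integer seed for the session RNG stream.
#' @return An object of class `ga_params`.
#' @export
ga_params <- function(population_size, selection_fraction = 0.5,
                      crossover_rate = 0.9, mutation_rate = 0.01,
                      elitism = 0L, seed = 1L) {
  population_size <- as.integer(population_size)
  if (is.na(population_size) || population_size < 2L)
    stop("population_size must be an integer >= 2", call. = FALSE)
  if (!is.numeric(selection_fraction) || selection_fraction <= 0 ||
      selection_fraction > 1)
    stop("selection_fraction must be in (0, 1]", call. = FALSE)
  if (!is.numeric(crossover_rate) || crossover_rate < 0 || crossover_rate > 1)
    stop("crossover_rate must be in [0, 1]", call. = FALSE)
  if (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]", call. = FALSE)
  elitism <- as.integer(elitism)
  if (is.na(elitism) || elitism < 0L || elitism >= population_size)
    stop("elitism must be an integer in [0, population_size)", call. = FALSE)
  structure(list(population_size = population_size,
                 selection_fraction = selection_fraction,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = elitism,
                 seed = as.integer(seed)),
            class = "ga_params")
}

#' @export
print.ga_params <- function(x, ...) {
  cat(sprintf(paste0("<ga_params> N = %d, selection %.2f, crossover %.2f, ",
                     "mutation %.2f, elitism %d, seed %d\n"),
              x$population_size, x$selection_fraction, x$crossover_rate,
              x$mutation_rate, x$elitism, x$seed))
  invisible(x)
}

# Deterministic derived seeds: one session seed fans out to independent
# per-(generation, operation) streams, all < 2^31.
derive_seed <- function(base, generation, op_offset = 0L) {
  m <- 2147483647                      # 2^31 - 1
  s <- (as.numeric(base) %% m)
  s <- (s * 48271 + as.numeric(generation) * 1299709 +
          as.numeric(op_offset) * 15485863) %% m
  as.integer(s)
}

chromosome_ids <- function(generation, n) {
  sprintf("G%d_%02d", generation, seq_len(n))
}

#' Create a generation record
#'
#' Bundles one generation's population with its (optional) measurements and
#' fitness, the unit of the session history.
#'
#' @param generation Generation index (1-based).
#' @param population List of [chromosome()] objects.
#' @param measurements Ingested replicate measurements (data frame) or NULL.
#' @param fitness [evaluate_fitness()] result or NULL.
#' @param seed Seed used to create this population.
#' @return An object of class `generation_record`.
#' @export
generation_record <- function(generation, population, measurements = NULL,
                              fitness = NULL, seed = NA_integer_) {
  stopifnot(length(population) >= 1L,
            all(vapply(population, inherits, TRUE, "chromosome")))
  structure(list(generation = as.integer(generation), population = population,
                 measurements = measurements, fitness = fitness,
                 seed = as.integer(seed)),
            class = "generation_record")
}

#' @export
print.generation_record <- function(x, ...) {
  cat(sprintf("<generation %d> %d chromosomes; measurements: %s; fitness: %s\n",
              x$generation, length(x$population),
              if (is.null(x$measurements)) "absent" else "ingested",
              if (is.null(x$fitness)) "absent" else "computed"))
  invisible(x)
}

#' Random initial population
#'
#' Generation 1 of a session: `population_size` chromosomes with independent
#' fair-coin bits.
#'
#' @param space A [design_space()].
#' @param params A [ga_params()].
#' @param seed Optional seed override (defaults to the stream derived from
#'   `params$seed` for generation 1).
#' @return A [generation_record()] with generation index 1.
#' @export
random_population <- function(space, params, seed = NULL) {
  stopifnot(inherits(space, "design_space"), inherits(params, "ga_params"))
  if (is.null(seed)) seed <- derive_seed(params$seed, 1L, 0L)
  L <- chromosome_length(space)
  N <- params$population_size
  ids <- chromosome_ids(1L, N)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  population <- lapply(seq_len(N), function(i)
    chromosome(sample(0:1, L, replace = TRUE), ids[i]))
  generation_record(1L, population, seed = seed)
}

# Minimal local-seed helpers (no withr dependency in the hot path).
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Aggregate replicate measurements
#'
#' Collapses replicate raw measurements to one value per (chromosome,
#' objective): a single missing replicate is first repaired by the arithmetic
#' mean of the remaining replicates of that cell, then the median across
#' replicates is taken. Two or more missing replicates in one cell are a data
#' error (the repair rule covers single missing values only).
#'
#' @param table Data frame with columns `condition_id`, `replicate`, and one
#'   column per objective; `NA` marks a missing measurement.
#' @param objectives Character vector of objective column names.
#' @return Data frame: `condition_id` plus one aggregated column per
#'   objective.
#' @export
aggregate_replicates <- function(table, objectives) {
  stopifnot(is.data.frame(table),
            all(c("condition_id", "replicate") %in% names(table)))
  missing_cols <- setdiff(objectives, names(table))
  if (length(missing_cols))
    stop("measurement table lacks objective column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ids <- unique(as.character(table$condition_id))
  out <- data.frame(condition_id = ids, stringsAsFactors = FALSE)
  for (obj in objectives) {
    agg <- vapply(ids, function(id) {
      v <- table[[obj]][as.character(table$condition_id) == id]
      if (length(v) == 0L)
        stop("no replicates for condition '", id, "', objective '", obj, "'",
             call. = FALSE)
      n_miss <- sum(is.na(v))
      if (n_miss >= length(v) || n_miss >= 2L)
        stop(n_miss, " missing replicate(s) of ", length(v),
             " for condition '", id, "', objective '", obj,
             "': at most one missing value per cell is repairable",
             call. = FALSE)
      if (n_miss == 1L) v[is.na(v)] <- mean(v[!is.na(v)])
      stats::median(v)
    }, 0)
    out[[obj]] <- unname(agg)
  }
  out
}

#' Evaluate the weighted multi-objective fitness
#'
#' The fitness of each chromosome is the weighted sum, over objectives, of
#' per-generation min–max normalized terms: for a maximize objective
#' `(x - min_i) / (max_i - min_i)`, for a minimize objective one minus that,
#' where `min_i`/`max_i` are the extremes of the aggregated values over the
#' current generation only. With normalized weights every total score lies in
#' \[0, 1\]. If an objective is constant across the generation (`max_i ==
#' min_i`) it is uninformative: its term is fixed at 0.5 for every individual
#' and a warning is issued.
#'
#' @param space A [design_space()].
#' @param aggregated Output of [aggregate_replicates()] covering every
#'   chromosome of the generation.
#' @return Data frame of class `fitness_result`: `condition_id`, one
#'   `term.<objective>` column per objective, and `score`.
#' @export
evaluate_fitness <- function(space, aggregated) {
  stopifnot(inherits(space, "design_space"), is.data.frame(aggregated))
  onames <- names(space$objectives)
  missing_cols <- setdiff(onames, names(aggregated))
  if (length(missing_cols))
    stop("aggregated table lacks objective column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- data.frame(condition_id = as.character(aggregated$condition_id),
                    stringsAsFactors = FALSE)
  score <- numeric(nrow(aggregated))
  for (obj in space$objectives) {
    x <- aggregated[[obj$name]]
    if (anyNA(x))
      stop("aggregated values for objective '", obj$name, "' contain NA",
           call. = FALSE)
    lo <- min(x); hi <- max(x)
    if (hi == lo) {
      warning("objective '", obj$name,
              "' is constant over this generation; term set to 0.5",
              call. = FALSE)
      term <- rep(0.5, length(x))
    } else {
      term <- (x - lo) / (hi - lo)
      if (obj$direction == "minimize") term <- 1 - term
    }
    out[[paste0("term.", obj$name)]] <- term
    score <- score + obj$weight * term
  }
  out$score <- score
  class(out) <- c("fitness_result", "data.frame")
  out
}

# Rank a fitness table best-first; ties broken by condition_id order.
order_by_score <- function(fitness) {
  order(-fitness$score, fitness$condition_id)
}

#' Select parent pairs by truncation plus roulette wheel
#'
#' The mating pool is the top `selection_fraction` of the population by score
#' (ties broken by chromosome id); within the pool each parent is drawn by
#' roulette wheel with probability proportional to its score, and the two
#' parents of a pair are forced distinct by redrawing the second. If every
#' pool score is zero the draws are uniform over the pool. `ceiling(N / 2)`
#' pairs are returned.
#'
#' @param fitness A `fitness_result` for the generation.
#' @param params A [ga_params()].
#' @param seed Integer seed for the draws.
#' @return List of length-2 character vectors of parent condition ids.
#' @export
select_parent_pairs <- function(fitness, params, seed = 1L) {
  stopifnot(inherits(fitness, "fitness_result"), inherits(params, "ga_params"))
  N <- nrow(fitness)
  if (N < 2L) stop("need a population of >= 2 to select parents", call. = FALSE)
  ord <- order_by_score(fitness)
  pool_n <- ceiling(params$selection_fraction * N)
  if (pool_n < 2L) {
    warning("mating pool smaller than 2 after truncation; expanded to top 2",
            call. = FALSE)
    pool_n <- 2L
  }
  pool <- fitness[ord[seq_len(pool_n)], , drop = FALSE]
  w <- pool$score
  if (all(w == 0)) w <- rep(1, pool_n)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  n_pairs <- ceiling(N / 2)
  lapply(seq_len(n_pairs), function(i) {
    p1 <- sample.int(pool_n, 1L, prob = w)
    # second parent must be a distinct individual: drop p1 from the wheel
    # (uniform over the rest if no other weight remains)
    w2 <- w
    w2[p1] <- 0
    if (all(w2 == 0)) w2[-p1] <- 1
    p2 <- sample.int(pool_n, 1L, prob = w2)
    c(pool$condition_id[p1], pool$condition_id[p2])
  })
}

#' Single-point crossover
#'
#' With probability `rate` a cut point is drawn uniformly from the `L - 1`
#' internal positions and the suffixes of the two parents are exchanged;
#' otherwise the parents are returned as copies. Children never alias their
#' parents.
#'
#' @param parent1,parent2 [chromosome()] objects of equal length `L >= 2`.
#' @param rate Crossover probability in \[0, 1\].
#' @return List of two child [chromosome()]s (ids empty).
#' @export
crossover <- function(parent1, parent2, rate) {
  b1 <- chromosome_bits(parent1); b2 <- chromosome_bits(parent2)
  L <- length(b1)
  if (length(b2) != L)
    stop("parents have different chromosome lengths (", L, " vs ",
         length(b2), ")", call. = FALSE)
  if (L < 2L) stop("crossover requires chromosome length >= 2", call. = FALSE)
  if (stats::runif(1) < rate) {
    cut <- sample.int(L - 1L, 1L)
    c1 <- c(b1[seq_len(cut)], b2[(cut + 1L):L])
    c2 <- c(b2[seq_len(cut)], b1[(cut + 1L):L])
  } else {
    c1 <- b1; c2 <- b2
  }
  list(chromosome(c1), chromosome(c2))
}

#' Single-bit mutation
#'
#' With probability `rate`, exactly one uniformly chosen bit of the
#' chromosome is flipped; otherwise the chromosome is returned unchanged.
#' The input object is never modified in place.
#'
#' @param child A [chromosome()].
#' @param rate Mutation probability in \[0, 1\].
#' @return A [chromosome()] (same id).
#' @export
mutate <- function(child, rate) {
  bits <- chromosome_bits(child)
  if (stats::runif(1) < rate) {
    pos <- sample.int(length(bits), 1L)
    bits[pos] <- 1L - bits[pos]
  }
  chromosome(bits, if (inherits(child, "chromosome")) child$id else "")
}

#' Produce the next generation
#'
#' Applies selection, crossover and mutation to a generation whose fitness
#' has been computed, yielding a fresh population of the same size with new
#' unique ids. Optional elitism copies the best `elitism` chromosomes
#' unchanged. Duplicates among offspring are permitted. The derived seed used
#' is stored on the returned record, so identical state and seed reproduce
#' the offspring bit for bit.
#'
#' @param record A [generation_record()] with fitness computed.
#' @param params A [ga_params()].
#' @param seed Optional seed override (defaults to the stream derived from
#'   `params$seed` and the new generation index).
#' @return A [generation_record()] for generation `record$generation + 1`.
#' @export
next_generation <- function(record, params, seed = NULL) {
  stopifnot(inherits(record, "generation_record"), inherits(params, "ga_params"))
  if (is.null(record$fitness))
    stop("generation ", record$generation,
         " has no fitness; ingest results first", call. = FALSE)
  g_next <- record$generation + 1L
  if (is.null(seed)) seed <- derive_seed(params$seed, g_next, 0L)
  N <- params$population_size
  pairs <- select_parent_pairs(record$fitness, params,
                               seed = derive_seed(seed, 0L, 1L))
  by_id <- stats::setNames(record$population,
                           vapply(record$population, `[[`, "", "id"))
  old <- set_local_seed(derive_seed(seed, 0L, 2L))
  on.exit(restore_seed(old))
  offspring <- list()
  if (params$elitism > 0L) {
    ord <- order_by_score(record$fitness)
    elite_ids <- record$fitness$condition_id[ord[seq_len(params$elitism)]]
    offspring <- lapply(by_id[elite_ids], function(ch) chromosome(ch$bits))
  }
  for (pair in pairs) {
    kids <- crossover(by_id[[pair[1]]], by_id[[pair[2]]], params$crossover_rate)
    kids <- lapply(kids, mutate, rate = params$mutation_rate)
    offspring <- c(offspring, kids)
    if (length(offspring) >= N) break
  }
  offspring <- offspring[seq_len(N)]
  ids <- chromosome_ids(g_next, N)
  offspring <- Map(function(ch, id) chromosome(ch$bits, id), offspring, ids)
  generation_record(g_next, unname(offspring), seed = seed)
}
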