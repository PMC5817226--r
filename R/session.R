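# Interactive optimization session: configure once, then propose -> measure
# -> ingest -> step until the user decides to stop. State is versioned JSON;
# designs and results travel as plain CSV for spreadsheet interoperability.

STATE_VERSION <- 1L

canonical_config <- function(space, ga, seed) {
  list(
    factors = lapply(space$factors, function(f)
      list(name = f$name, min = f$min_value, max = f$max_value,
           bits = f$bits, units = f$units)),
    objectives = lapply(space$objectives, function(o)
      list(name = o$name, direction = o$direction, weight = o$weight)),
    encoding = space$encoding,
    ga = list(population_size = ga$population_size,
              selection_fraction = ga$selection_fraction,
              crossover_rate = ga$crossover_rate,
              mutation_rate = ga$mutation_rate,
              elitism = ga$elitism),
    seed = seed)
}

config_hash <- function(space, ga, seed) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canonical_config(space, ga, seed), tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Initialize an optimization session
#'
#' Locks in the design space and GA parameters (they cannot be altered for
#' the lifetime of the session), creates the random generation-1 population,
#' and — if a state path is given — writes the session state file. An
#' existing state file is never overwritten unless `force = TRUE`.
#'
#' @param config Path to a YAML/JSON design configuration (see
#'   [read_design_config()]), or the list it returns, or a [design_space()].
#' @param seed Session seed; every stochastic draw of the session derives
#'   from it.
#' @param ga Optional [ga_params()] overriding the config's `ga` block. If
#'   neither gives a population size, the `2 * n_factors - 2` rule applies.
#' @param state_path Optional path for the persistent state file.
#' @param force Overwrite an existing state file? Default FALSE.
#' @return An object of class `evodoe_session`.
#' @export
init_session <- function(config, seed = 1L, ga = NULL, state_path = NULL,
                         force = FALSE) {
  if (is.character(config)) config <- read_design_config(config)
  if (inherits(config, "design_space")) config <- list(space = config, ga = list())
  space <- config$space
  stopifnot(inherits(space, "design_space"))
  if (is.null(ga)) {
    gb <- config$ga
    pick <- function(key, default) if (is.null(gb[[key]])) default else gb[[key]]
    ga <- ga_params(
      population_size = pick("population_size",
                             population_size_rule(length(space$factors))),
      selection_fraction = pick("selection_fraction", 0.5),
      crossover_rate = pick("crossover_rate", 0.9),
      mutation_rate = pick("mutation_rate", 0.01),
      elitism = pick("elitism", 0L),
      seed = seed)
  } else {
    ga$seed <- as.integer(seed)
  }
  if (!is.null(state_path) && file.exists(state_path) && !force)
    stop("state file '", state_path,
         "' already exists; pass force = TRUE to re-initialize",
         call. = FALSE)
  session <- structure(
    list(space = space, ga = ga, seed = as.integer(seed),
         config_hash = config_hash(space, ga, seed),
         history = list(random_population(space, ga)),
         audit = list(), state_path = state_path),
    class = "evodoe_session")
  session <- audit_append(session, "init", 1L,
                          sprintf("population of %d proposed",
                                  ga$population_size))
  save_session_if_bound(session)
  session
}

audit_append <- function(session, op, generation, detail = "") {
  session$audit[[length(session$audit) + 1L]] <-
    list(seq = length(session$audit) + 1L, op = op,
         generation = as.integer(generation), detail = detail)
  session
}

current_record <- function(session) session$history[[length(session$history)]]

#' @export
print.evodoe_session <- function(x, ...) {
  rec <- current_record(x)
  cat(sprintf(paste0("<evodoe_session> seed %d, %d factor(s), %d objective(s), ",
                     "N = %d\n  generation %d (%s)\n"),
              x$seed, length(x$space$factors), length(x$space$objectives),
              x$ga$population_size, rec$generation,
              if (is.null(rec$fitness)) "awaiting results" else "scored"))
  invisible(x)
}

#' Propose the current generation's experiments
#'
#' Emits the decoded physical conditions for every chromosome of the current
#' generation — the plate/tube list to take to the bench. Proposing is
#' idempotent until results are ingested; afterwards it refuses and directs
#' to [step()].
#'
#' @param session An `evodoe_session`.
#' @return Data frame: `condition_id`, `generation`, one column per factor
#'   (full precision; [write_design_csv()] rounds to 4 significant digits).
#' @export
propose <- function(session) {
  stopifnot(inherits(session, "evodoe_session"))
  rec <- current_record(session)
  if (!is.null(rec$measurements))
    stop("results already ingested for generation ", rec$generation,
         "; run step() to create the next generation", call. = FALSE)
  vals <- t(vapply(rec$population, function(ch)
    decode_chromosome(session$space, ch),
    numeric(length(session$space$factors))))
  out <- data.frame(condition_id = vapply(rec$population, `[[`, "", "id"),
                    generation = rec$generation,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(vals))
}

#' Write a proposed design as CSV
#'
#' @param design Output of [propose()].
#' @param path Output CSV path. Factor values are printed with 4 significant
#'   digits (state keeps full precision).
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  out <- design
  for (nm in setdiff(names(out), c("condition_id", "generation")))
    out[[nm]] <- signif(out[[nm]], 4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results CSV
#'
#' @param path CSV with columns `condition_id`, `replicate`, then one column
#'   per objective; empty cells mark missing measurements.
#' @return Data frame ready for [ingest()].
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

validate_results <- function(session, results) {
  errs <- character()
  req <- c("condition_id", "replicate")
  missing_req <- setdiff(req, names(results))
  if (length(missing_req)) {
    errs <- c(errs, paste("missing column(s):",
                          paste(missing_req, collapse = ", ")))
  }
  onames <- names(session$space$objectives)
  missing_obj <- setdiff(onames, names(results))
  if (length(missing_obj))
    errs <- c(errs, paste("missing objective column(s):",
                          paste(missing_obj, collapse = ", ")))
  if (length(errs)) return(errs)

  rec <- current_record(session)
  expected <- vapply(rec$population, `[[`, "", "id")
  got <- unique(as.character(results$condition_id))
  unknown <- setdiff(got, expected)
  absent <- setdiff(expected, got)
  if (length(unknown))
    errs <- c(errs, paste("unknown condition id(s):",
                          paste(unknown, collapse = ", ")))
  if (length(absent))
    errs <- c(errs, paste("missing condition id(s):",
                          paste(absent, collapse = ", ")))
  for (obj in onames) {
    col <- results[[obj]]
    if (!is.numeric(col) && !is.logical(col)) {
      bad <- unique(col[!is.na(col) & is.na(suppressWarnings(as.numeric(col)))])
      errs <- c(errs, paste0("non-numeric value(s) in objective '", obj, "': ",
                             paste(utils::head(bad, 3), collapse = ", ")))
      next
    }
    for (id in intersect(got, expected)) {
      v <- col[as.character(results$condition_id) == id]
      if (sum(is.na(v)) >= 2L || sum(is.na(v)) >= length(v))
        errs <- c(errs, paste0(sum(is.na(v)), " missing replicates for (",
                               id, ", ", obj, "); at most one is repairable"))
    }
  }
  errs
}

#' Ingest experimental results for the current generation
#'
#' Validates the replicate results table against the current generation (all
#' ids present, none unknown, numeric values, at most one missing replicate
#' per cell), then stores the measurements, aggregates replicates
#' (single-missing-value repair, then median) and computes the fitness of
#' every chromosome. Validation failures are itemized and nothing is
#' committed — the session (and its state file) are unchanged on error.
#'
#' @param session An `evodoe_session`.
#' @param results Data frame or path to a results CSV
#'   (see [read_results_csv()]).
#' @return The updated session.
#' @export
ingest <- function(session, results) {
  stopifnot(inherits(session, "evodoe_session"))
  if (is.character(results)) results <- read_results_csv(results)
  rec <- current_record(session)
  if (!is.null(rec$measurements))
    stop("results already ingested for generation ", rec$generation,
         call. = FALSE)
  errs <- validate_results(session, results)
  if (length(errs))
    stop("invalid results (nothing ingested):\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  onames <- names(session$space$objectives)
  agg <- aggregate_replicates(results, onames)
  # align aggregation to population order
  ord <- match(vapply(rec$population, `[[`, "", "id"), agg$condition_id)
  agg <- agg[ord, , drop = FALSE]
  fitness <- evaluate_fitness(session$space, agg)
  rec$measurements <- results
  rec$fitness <- fitness
  session$history[[length(session$history)]] <- rec
  session <- audit_append(session, "ingest", rec$generation,
                          sprintf("%d rows, %d conditions scored",
                                  nrow(results), nrow(fitness)))
  save_session_if_bound(session)
  session
}

#' Advance the session to the next generation
#'
#' Runs selection, crossover and mutation on the scored current generation
#' and appends the offspring generation to the history. Termination is
#' advisory and stays with the user: the returned convergence report (also
#' printed unless `quiet = TRUE`) carries the score trajectories, the
#' better-fraction RSD per generation, and the one-sided improvement-test
#' p-value between the last two generations — in practice one stops once the
#' improvement p-value exceeds about 0.1.
#'
#' @param session An `evodoe_session`.
#' @param quiet Suppress printing of the report? Default FALSE.
#' @return The updated session (report in `attr(, "report")`).
#' @export
step <- function(session, quiet = FALSE) {
  stopifnot(inherits(session, "evodoe_session"))
  rec <- current_record(session)
  if (is.null(rec$fitness))
    stop("no fitness for generation ", rec$generation,
         "; ingest results first", call. = FALSE)
  nxt <- next_generation(rec, session$ga)
  session$history[[length(session$history) + 1L]] <- nxt
  session <- audit_append(session, "step", nxt$generation,
                          sprintf("seed %d", nxt$seed))
  save_session_if_bound(session)
  report <- convergence_report(session)
  if (!quiet) print_convergence_report(report)
  attr(session, "report") <- report
  session
}

#' Convergence report over the scored history
#'
#' @param session An `evodoe_session` (at least one scored generation).
#' @param fraction Better-performing fraction (default 0.5).
#' @return List: `trajectories` (from [score_trajectories()] augmented with
#'   the better-fraction RSD per generation) and `improvement_p` (one-sided
#'   p-value of the last scored generation improving on the previous one;
#'   `NA` with fewer than two scored generations).
#' @export
convergence_report <- function(session, fraction = 0.5) {
  scored <- Filter(function(r) !is.null(r$fitness), session$history)
  if (!length(scored))
    stop("no scored generations yet", call. = FALSE)
  traj <- score_trajectories(scored, fraction)
  traj$rsd_better <- vapply(scored, function(r) {
    s <- better_fraction_scores(r$fitness, fraction)
    # undefined for singleton fractions or zero-mean scores
    if (length(s) < 2L || mean(s) == 0) NA_real_
    else relative_standard_deviation(s)
  }, 0)
  p <- NA_real_
  if (length(scored) >= 2L) {
    n <- length(scored)
    prev <- better_fraction_scores(scored[[n - 1L]]$fitness, fraction)
    nxt <- better_fraction_scores(scored[[n]]$fitness, fraction)
    if (length(prev) >= 2L && length(nxt) >= 2L)
      p <- improvement_test(prev, nxt)
  }
  list(trajectories = traj, improvement_p = p)
}

print_convergence_report <- function(report) {
  cat("Convergence report\n")
  print.data.frame(report$trajectories, row.names = FALSE, digits = 4)
  if (!is.na(report$improvement_p))
    cat(sprintf("improvement p (last vs previous better fraction): %.4g%s\n",
                report$improvement_p,
                if (report$improvement_p > 0.1)
                  "  [no significant improvement; consider stopping]" else ""))
  invisible(report)
}

# ---- persistence ------------------------------------------------------------

session_to_state <- function(session) {
  list(
    version = STATE_VERSION,
    config = canonical_config(session$space, session$ga, session$seed),
    config_hash = session$config_hash,
    history = lapply(session$history, function(rec) list(
      generation = rec$generation,
      ids = vapply(rec$population, `[[`, "", "id"),
      bits = vapply(rec$population, function(ch)
        paste(ch$bits, collapse = ""), ""),
      seed = rec$seed,
      measurements = rec$measurements,
      fitness = if (is.null(rec$fitness)) NULL else
        as.data.frame(unclass(rec$fitness)))),
    audit = session$audit)
}

save_session_if_bound <- function(session) {
  if (!is.null(session$state_path)) save_session(session, session$state_path)
  invisible(session)
}

#' Save a session state file
#'
#' Versioned JSON: configuration (with hash), every generation's bit strings
#' verbatim, all measurements and fitness tables, seeds, and the audit log.
#' The write is atomic (temp file + rename).
#'
#' @param session An `evodoe_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(session_to_state(session), tmp, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Load a session state file
#'
#' Reconstructs the session and verifies the stored configuration hash; a
#' mismatch (a tampered or hand-edited configuration) is rejected.
#'
#' @param path State file written by [save_session()].
#' @return An `evodoe_session` (re-bound to `path`).
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop("state file not found: ", path, call. = FALSE)
  st <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  cfg <- st$config
  fl <- cfg$factors
  if (is.data.frame(fl)) {
    factors <- lapply(seq_len(nrow(fl)), function(i)
      factor_spec(fl$name[i], fl$min[i], fl$max[i], fl$bits[i],
                  if (is.null(fl$units)) "" else fl$units[i]))
  } else {
    factors <- lapply(fl, function(f)
      factor_spec(f$name, f$min, f$max, f$bits, f$units))
  }
  ol <- cfg$objectives
  if (is.data.frame(ol)) {
    objectives <- lapply(seq_len(nrow(ol)), function(i)
      objective_spec(ol$name[i], ol$direction[i], ol$weight[i]))
  } else {
    objectives <- lapply(ol, function(o)
      objective_spec(o$name, o$direction, o$weight))
  }
  space <- design_space(factors, objectives, encoding = cfg$encoding)
  ga <- ga_params(population_size = cfg$ga$population_size,
                  selection_fraction = cfg$ga$selection_fraction,
                  crossover_rate = cfg$ga$crossover_rate,
                  mutation_rate = cfg$ga$mutation_rate,
                  elitism = cfg$ga$elitism,
                  seed = cfg$seed)
  expected_hash <- config_hash(space, ga, cfg$seed)
  if (!identical(unname(expected_hash), unname(st$config_hash)))
    stop("state file configuration hash mismatch; refusing to load",
         call. = FALSE)
  hist_raw <- st$history
  if (is.data.frame(hist_raw))
    hist_raw <- lapply(seq_len(nrow(hist_raw)), function(i)
      lapply(hist_raw, function(col) col[[i]]))
  history <- lapply(hist_raw, function(h) {
    ids <- unlist(h$ids)
    bits <- unlist(h$bits)
    population <- Map(function(b, id)
      chromosome(as.integer(strsplit(b, "")[[1]]), id), bits, ids)
    as_stored_df <- function(v) {
      # absent tables round-trip as JSON null -> scalar NA
      if (is.null(v)) return(NULL)
      if (!is.data.frame(v)) {
        if (length(v) <= 1L && all(is.na(unlist(v)))) return(NULL)
        v <- as.data.frame(v)
      }
      if (!nrow(v)) NULL else v
    }
    meas <- as_stored_df(h$measurements)
    fit <- as_stored_df(h$fitness)
    if (!is.null(fit)) class(fit) <- c("fitness_result", "data.frame")
    generation_record(h$generation, unname(population), meas, fit,
                      seed = if (is.null(h$seed)) NA_integer_ else h$seed)
  })
  audit <- st$audit
  if (is.data.frame(audit))
    audit <- lapply(seq_len(nrow(audit)), function(i) as.list(audit[i, ]))
  structure(list(space = space, ga = ga, seed = as.integer(cfg$seed),
                 config_hash = st$config_hash, history = history,
                 audit = audit, state_path = path),
            class = "evodoe_session")
}

# ---- scripted simulation -----------------------------------------------------

#' Drive a full session against a synthetic oracle
#'
#' Scripted propose -> simulate measurement -> ingest -> step loop: the
#' desk-scale stand-in for the wet-lab cycle, used by tests and the
#' `simulate` CLI command.
#'
#' @param oracle An [oracle_spec()].
#' @param generations Number of scored generations to run.
#' @param seed Session seed (also drives the oracle noise, via derived
#'   per-generation seeds).
#' @param ga Optional [ga_params()] override.
#' @param state_path Optional state file path.
#' @return The finished `evodoe_session` (all `generations` scored; no
#'   unscored trailing proposal).
#' @export
simulate_session <- function(oracle, generations = 3L, seed = 1L, ga = NULL,
                             state_path = NULL) {
  stopifnot(inherits(oracle, "oracle_spec"), generations >= 1L)
  session <- init_session(list(space = oracle$space, ga = list()),
                          seed = seed, ga = ga, state_path = state_path)
  for (g in seq_len(generations)) {
    design <- propose(session)
    results <- oracle_respond(oracle, design,
                              seed = derive_seed(seed, g, 99L))
    session <- ingest(session, results)
    if (g < generations) session <- step(session, quiet = TRUE)
  }
  session
}
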