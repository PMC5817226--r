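# Shared fixtures built in code.

# Nine 5-bit factors, four equally weighted objectives: the reference
# configuration of a multi-component medium + pH optimization.
reference_space <- function(bits = 5L) {
  design_space(
    factors = list(
      factor_spec("ammonium", 0.5, 15, bits, "g/L"),
      factor_spec("potassium", 0.5, 8, bits, "g/L"),
      factor_spec("magnesium", 0.1, 6, bits, "g/L"),
      factor_spec("iron", 0.01, 0.5, bits, "g/L"),
      factor_spec("calcium", 0.05, 2, bits, "g/L"),
      factor_spec("glycerol", 1, 20, bits, "g/L"),
      factor_spec("methanol", 0.5, 12, bits, "g/L"),
      factor_spec("sorbitol", 0, 15, bits, "g/L"),
      factor_spec("pH", 2.6, 7.0, bits, "pH")),
    objectives = list(
      objective_spec("ODbi", "maximize", 0.25),
      objective_spec("ODd", "minimize", 0.25),
      objective_spec("Ea", "maximize", 0.25),
      objective_spec("P", "maximize", 0.25)))
}

# Two-factor space for small exhaustive checks.
small_space <- function(bits = 3L) {
  design_space(
    factors = list(factor_spec("x1", 0, 10, bits),
                   factor_spec("x2", 2, 8, bits)),
    objectives = list(objective_spec("y", "maximize", 1)))
}

# A measurement table in the ingest schema for given ids.
make_results <- function(ids, objectives, values_fn, replicates = 3L) {
  rows <- expand.grid(replicate = seq_len(replicates),
                      condition_id = ids, stringsAsFactors = FALSE)
  out <- data.frame(condition_id = rows$condition_id,
                    replicate = rows$replicate, stringsAsFactors = FALSE)
  for (obj in objectives) out[[obj]] <- values_fn(rows$condition_id, obj)
  out
}

# Training data (decoded conditions + aggregated objectives) pooled over all
# measured generations of a session.
session_training_data <- function(session) {
  onames <- names(session$space$objectives)
  fnames <- names(session$space$factors)
  rows <- list()
  for (rec in session$history) {
    if (is.null(rec$measurements)) next
    x <- as.data.frame(t(vapply(rec$population, function(ch)
      decode_chromosome(session$space, ch), numeric(length(fnames)))))
    agg <- aggregate_replicates(rec$measurements, onames)
    ord <- match(vapply(rec$population, `[[`, "", "id"), agg$condition_id)
    rows[[length(rows) + 1L]] <- cbind(x, agg[ord, onames, drop = FALSE])
  }
  do.call(rbind, rows)
}

# Best composite score visited anywhere in a session, by the oracle's
# ground-truth yardstick.
best_visited_composite <- function(session, oracle) {
  best <- -Inf
  for (rec in session$history) {
    conds <- as.data.frame(t(vapply(rec$population, function(ch)
      decode_chromosome(session$space, ch),
      numeric(length(session$space$factors)))))
    best <- max(best, max(oracle_composite(oracle, conds)))
  }
  best
}
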