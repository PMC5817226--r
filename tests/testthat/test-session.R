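case_config_yaml <- function() {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "factors:",
    "  - {name: ammonium,  min: 0.5,  max: 15, units: g/L}",
    "  - {name: potassium, min: 0.5,  max: 8,  units: g/L}",
    "  - {name: magnesium, min: 0.1,  max: 6,  units: g/L}",
    "  - {name: iron,      min: 0.01, max: 0.5, units: g/L}",
    "  - {name: calcium,   min: 0.05, max: 2,  units: g/L}",
    "  - {name: glycerol,  min: 1,    max: 20, units: g/L}",
    "  - {name: methanol,  min: 0.5,  max: 12, units: g/L}",
    "  - {name: sorbitol,  min: 0,    max: 15, units: g/L}",
    "  - {name: pH,        min: 2.6,  max: 7.0}",
    "objectives:",
    "  - {name: ODbi, direction: maximize, weight: 0.25}",
    "  - {name: ODd,  direction: minimize, weight: 0.25}",
    "  - {name: Ea,   direction: maximize, weight: 0.25}",
    "  - {name: P,    direction: maximize, weight: 0.25}",
    "ga: {mutation_rate: 0.1}"), path)
  path
}

test_that("session init locks the reference configuration: N = 16, L = 45", {
  session <- init_session(case_config_yaml(), seed = 1)
  expect_equal(session$ga$population_size, 16L)   # 2 x 9 - 2 rule
  expect_equal(chromosome_length(session$space), 45L)
  expect_equal(session$ga$mutation_rate, 0.1)
  design <- propose(session)
  expect_equal(dim(design), c(16L, 11L))          # id, generation, 9 factors
  # every proposed value within its declared range
  for (f in session$space$factors) {
    expect_true(all(design[[f$name]] >= f$min_value &
                      design[[f$name]] <= f$max_value))
  }
})

test_that("re-initializing over an existing state requires force", {
  state <- tempfile(fileext = ".json")
  init_session(case_config_yaml(), seed = 1, state_path = state)
  expect_true(file.exists(state))
  expect_error(init_session(case_config_yaml(), seed = 1, state_path = state),
               "force")
  expect_silent(init_session(case_config_yaml(), seed = 2,
                             state_path = state, force = TRUE))
})

test_that("proposing is idempotent until results arrive, then refused", {
  orc <- tiny_oracle()
  session <- init_session(list(space = orc$space, ga = list()), seed = 6)
  d1 <- propose(session)
  d2 <- propose(session)
  expect_identical(d1, d2)
  session <- ingest(session, oracle_respond(orc, d1, seed = 1))
  expect_error(propose(session), "step")
  expect_error(ingest(session, oracle_respond(orc, d1, seed = 1)),
               "already ingested")
})

test_that("ingest validates atomically: bad files leave no trace", {
  orc <- tiny_oracle()
  state <- tempfile(fileext = ".json")
  session <- init_session(list(space = orc$space, ga = list()), seed = 6,
                          state_path = state)
  before_bytes <- readBin(state, "raw", file.size(state))
  design <- propose(session)
  good <- oracle_respond(orc, design, seed = 1)

  # unknown id
  bad1 <- good; bad1$condition_id[1] <- "G9_99"
  expect_error(ingest(session, bad1), "unknown condition")
  # a condition missing entirely
  bad2 <- good[good$condition_id != design$condition_id[1], ]
  expect_error(ingest(session, bad2), "missing condition")
  # two missing replicates in one cell
  bad3 <- good; bad3$y[bad3$condition_id == design$condition_id[2]][1:2] <- NA
  expect_error(ingest(session, bad3), "at most one")
  # non-numeric objective values
  bad4 <- good; bad4$y <- as.character(bad4$y); bad4$y[3] <- "oops"
  expect_error(ingest(session, bad4), "non-numeric")

  after_bytes <- readBin(state, "raw", file.size(state))
  expect_identical(before_bytes, after_bytes)     # state file untouched
  expect_null(session$history[[1]]$measurements)  # session object untouched

  # a single missing replicate is repairable and accepted
  ok <- good; ok$y[ok$condition_id == design$condition_id[2]][1] <- NA
  expect_s3_class(ingest(session, ok), "evodoe_session")
})

test_that("step requires fitness and reports convergence metrics", {
  orc <- tiny_oracle()
  # population of 6 so the better fraction holds >= 2 scores for the
  # improvement test and RSD
  session <- init_session(list(space = orc$space, ga = list()), seed = 6,
                          ga = ga_params(6))
  expect_error(step(session), "ingest")
  session <- ingest(session, oracle_respond(orc, propose(session), seed = 1))
  session <- step(session, quiet = TRUE)
  expect_equal(length(session$history), 2L)
  expect_equal(session$history[[2]]$generation, 2L)
  r <- attr(session, "report")
  expect_named(r, c("trajectories", "improvement_p"))
  session <- ingest(session, oracle_respond(orc, propose(session), seed = 2))
  r2 <- convergence_report(session)
  expect_equal(nrow(r2$trajectories), 2L)
  expect_false(is.na(r2$improvement_p))
})

test_that("state files round-trip and replay bit-identically", {
  orc <- tiny_oracle(cv = 0.1, missing_prob = 0.02)
  state <- tempfile(fileext = ".json")
  run_session <- function(path) {
    session <- init_session(list(space = orc$space, ga = list()),
                            seed = 31, state_path = path, force = TRUE)
    for (g in 1:3) {
      res <- oracle_respond(orc, propose(session), seed = 100 + g)
      session <- ingest(session, res)
      if (g < 3) session <- step(session, quiet = TRUE)
    }
    session
  }
  s1 <- run_session(state)
  loaded <- load_session(state)
  expect_equal(length(loaded$history), length(s1$history))
  for (i in seq_along(s1$history)) {
    expect_equal(
      vapply(loaded$history[[i]]$population, function(ch)
        paste(ch$bits, collapse = ""), ""),
      vapply(s1$history[[i]]$population, function(ch)
        paste(ch$bits, collapse = ""), ""))
    expect_equal(loaded$history[[i]]$fitness$score,
                 s1$history[[i]]$fitness$score, tolerance = 1e-12)
  }
  # full replay from scratch with the same seed: identical state bytes
  state2 <- tempfile(fileext = ".json")
  s2 <- run_session(state2)
  expect_identical(readBin(state, "raw", file.size(state)),
                   readBin(state2, "raw", file.size(state2)))
})

test_that("a tampered configuration hash is rejected on load", {
  orc <- tiny_oracle()
  state <- tempfile(fileext = ".json")
  init_session(list(space = orc$space, ga = list()), seed = 3,
               state_path = state)
  st <- jsonlite::read_json(state)
  st$config$ga$mutation_rate <- 0.5
  jsonlite::write_json(st, state, auto_unbox = TRUE, digits = NA)
  expect_error(load_session(state), "hash mismatch")
})

test_that("scripted simulation runs the full loop and writes design CSVs", {
  orc <- tiny_oracle()
  session <- simulate_session(orc, generations = 3, seed = 12)
  expect_equal(length(session$history), 3L)
  expect_true(all(vapply(session$history, function(r)
    !is.null(r$fitness), TRUE)))
  # design CSV export rounds to 4 significant digits
  design <- propose(init_session(list(space = orc$space, ga = list()),
                                 seed = 12))
  csv <- tempfile(fileext = ".csv")
  write_design_csv(design, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$x1, signif(design$x1, 4))
})

test_that("the command-line surface drives a session end to end", {
  cli <- system.file("cli", "evodoe.R", package = "evodoe")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  state <- tempfile(fileext = ".json")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  run_cli <- function(...) {
    suppressWarnings(system2(rscript, c(cli, ...), stdout = TRUE,
                             stderr = TRUE, env = env))
  }
  out <- run_cli("init", "--config", case_config_yaml(), "--seed", "5",
                 "--state", state)
  expect_true(file.exists(state))
  design_csv <- tempfile(fileext = ".csv")
  run_cli("propose", "--state", state, "--out", design_csv)
  design <- utils::read.csv(design_csv)
  expect_equal(nrow(design), 16L)
  out2 <- run_cli("space-size", "--state", state)
  expect_true(any(grepl("45 bits", out2)))
  expect_true(any(grepl("3.51844e\\+13", out2)))
})
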