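# Design space: factors, objectives, and the bit-string <-> condition bijection.

#' Define an experimental factor
#'
#' A factor is one tunable experimental parameter (a medium component
#' concentration, pH, temperature, ...) explored over a closed range
#' `[min_value, max_value]`. It is encoded on the chromosome as a gene of
#' `bits` binary digits, giving `2^bits` evenly spaced representable levels.
#'
#' @param name Factor name (unique within a design space).
#' @param min_value,max_value Physical range bounds; `min_value < max_value`.
#' @param bits Gene length in bits (default 5, i.e. 32 levels).
#' @param units Free-text units label (e.g. `"g/L"`), documentation only.
#' @return An object of class `factor_spec`.
#' @seealso [design_space()], [decode_factor()]
#' @export
factor_spec <- function(name, min_value, max_value, bits = 5L, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(min_value) || !is.numeric(max_value) ||
      length(min_value) != 1L || length(max_value) != 1L ||
      !is.finite(min_value) || !is.finite(max_value)) {
    stop("factor '", name, "': min_value and max_value must be finite numbers",
         call. = FALSE)
  }
  if (min_value >= max_value) {
    stop("factor '", name, "': min_value must be < max_value", call. = FALSE)
  }
  bits <- as.integer(bits)
  if (is.na(bits) || bits < 1L) {
    stop("factor '", name, "': bits must be a positive integer", call. = FALSE)
  }
  structure(
    list(name = name, min_value = as.numeric(min_value),
         max_value = as.numeric(max_value), bits = bits,
         units = as.character(units)),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor> %s: [%g, %g] %s, %d bits (%d levels)\n",
              x$name, x$min_value, x$max_value, x$units, x$bits, 2L^x$bits))
  invisible(x)
}

#' Define an optimization objective
#'
#' One term of the weighted multi-objective fitness function: a named measured
#' response with a direction (`"maximize"` or `"minimize"`) and a non-negative
#' weight. Weights are renormalized to sum to one when the design space is
#' assembled.
#'
#' @param name Objective name (must match a column of ingested results).
#' @param direction `"maximize"` or `"minimize"`.
#' @param weight Non-negative relative weight.
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(name, direction = c("maximize", "minimize"),
                           weight = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  direction <- match.arg(direction)
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight < 0) {
    stop("objective '", name, "': weight must be a finite number >= 0",
         call. = FALSE)
  }
  structure(list(name = name, direction = direction,
                 weight = as.numeric(weight)),
            class = "objective_spec")
}

#' Assemble a design space
#'
#' Binds the ordered factor list and the objective list into the immutable
#' description of the optimization problem. Objective weights are normalized
#' to sum to one. The chromosome is the straight concatenation of the factor
#' genes in declared order, of total length `L = sum(bits)`.
#'
#' @param factors List of [factor_spec()] objects (order defines gene order).
#' @param objectives List of [objective_spec()] objects.
#' @param encoding `"binary"` (plain base-2, default) or `"gray"` (reflected
#'   Gray code) mapping between gene bit patterns and level indices.
#' @return An object of class `design_space`.
#' @examples
#' sp <- design_space(
#'   factors = list(factor_spec("glycerol", 1, 20, units = "g/L"),
#'                  factor_spec("pH", 2.6, 7.0)),
#'   objectives = list(objective_spec("activity", "maximize", 1))
#' )
#' chromosome_length(sp)
#' @export
design_space <- function(factors, objectives, encoding = c("binary", "gray")) {
  encoding <- match.arg(encoding)
  if (length(factors) < 1L || !all(vapply(factors, inherits, TRUE, "factor_spec")))
    stop("factors must be a non-empty list of factor_spec objects", call. = FALSE)
  if (length(objectives) < 1L ||
      !all(vapply(objectives, inherits, TRUE, "objective_spec")))
    stop("objectives must be a non-empty list of objective_spec objects",
         call. = FALSE)
  fnames <- vapply(factors, `[[`, "", "name")
  onames <- vapply(objectives, `[[`, "", "name")
  if (anyDuplicated(fnames))
    stop("duplicate factor names: ",
         paste(unique(fnames[duplicated(fnames)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(onames))
    stop("duplicate objective names: ",
         paste(unique(onames[duplicated(onames)]), collapse = ", "),
         call. = FALSE)
  w <- vapply(objectives, `[[`, 0, "weight")
  if (sum(w) <= 0)
    stop("objective weights must have a positive sum (cannot normalize)",
         call. = FALSE)
  w <- w / sum(w)
  objectives <- Map(function(o, wi) { o$weight <- wi; o }, objectives, w)
  names(factors) <- fnames
  names(objectives) <- onames
  structure(list(factors = factors, objectives = objectives,
                 encoding = encoding),
            class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat(sprintf("<design_space> %d factors, %d objectives, L = %d bits (%s encoding)\n",
              length(x$factors), length(x$objectives), chromosome_length(x),
              x$encoding))
  for (f in x$factors) print(f)
  for (o in x$objectives) {
    cat(sprintf("<objective> %s: %s, weight %.4g\n", o$name, o$direction,
                o$weight))
  }
  invisible(x)
}

#' Total chromosome length of a design space
#'
#' @param space A [design_space()].
#' @return Integer, the sum of all factor gene lengths in bits.
#' @export
chromosome_length <- function(space) {
  stopifnot(inherits(space, "design_space"))
  sum(vapply(space$factors, `[[`, 0L, "bits"))
}

#' Number of representable levels of a factor
#'
#' @param factor A [factor_spec()].
#' @return Integer `2^bits`.
#' @export
n_levels <- function(factor) {
  stopifnot(inherits(factor, "factor_spec"))
  as.integer(2^factor$bits)
}

#' All representable level values of a factor
#'
#' @param factor A [factor_spec()].
#' @return Numeric vector of length `2^bits`, evenly spaced on
#'   `[min_value, max_value]`.
#' @export
level_values <- function(factor) {
  stopifnot(inherits(factor, "factor_spec"))
  seq(factor$min_value, factor$max_value, length.out = n_levels(factor))
}

#' Size of the equivalent full-factorial design
#'
#' The number of distinct condition sets representable in the design space,
#' i.e. the number of experiments a full-factorial design over the same grid
#' would require (`prod(2^bits)`). Returned as a double since it overflows
#' integers quickly (e.g. `32^9` for nine 5-bit factors).
#'
#' @param space A [design_space()].
#' @return A double.
#' @export
space_size <- function(space) {
  stopifnot(inherits(space, "design_space"))
  prod(2 ^ vapply(space$factors, `[[`, 0L, "bits"))
}

#' Default population size rule
#'
#' Population sizing heuristic `2 * n_factors - 2`: within the upper part of
#' the recommended `[n, 2n]` band for n factors, e.g. 16 individuals for a
#' nine-factor design. A user-supplied population size always overrides it.
#'
#' @param n_factors Number of factors (>= 2).
#' @return Integer population size.
#' @export
population_size_rule <- function(n_factors) {
  n_factors <- as.integer(n_factors)
  if (is.na(n_factors) || n_factors < 2L)
    stop("population_size_rule requires n_factors >= 2 (got ", n_factors, ")",
         call. = FALSE)
  2L * n_factors - 2L
}

# Gray <-> binary level-index maps (integer k in 0..2^b-1).
binary_to_gray_index <- function(k) bitwXor(k, k %/% 2L)
gray_to_binary_index <- function(g) {
  k <- g
  shift <- g %/% 2L
  while (any(shift > 0L)) {
    k <- bitwXor(k, shift)
    shift <- shift %/% 2L
  }
  k
}

bits_to_int <- function(bits) {
  as.integer(sum(bits * 2^(rev(seq_along(bits)) - 1L)))
}

int_to_bits <- function(k, nbits) {
  as.integer(intToBits(k))[nbits:1]
}

# Level index (0-based) encoded by a gene, honouring the space encoding.
gene_to_level_index <- function(factor, gene_bits, encoding = "binary") {
  k <- bits_to_int(gene_bits)
  if (encoding == "gray") k <- gray_to_binary_index(k)
  k
}

level_index_to_gene <- function(factor, k, encoding = "binary") {
  if (encoding == "gray") k <- binary_to_gray_index(k)
  int_to_bits(k, factor$bits)
}

check_gene_bits <- function(factor, gene_bits) {
  if (length(gene_bits) != factor$bits)
    stop("gene for factor '", factor$name, "' must have ", factor$bits,
         " bits, got ", length(gene_bits), call. = FALSE)
  gene_bits <- as.integer(gene_bits)
  if (anyNA(gene_bits) || !all(gene_bits %in% c(0L, 1L)))
    stop("gene for factor '", factor$name, "' contains non-binary values",
         call. = FALSE)
  gene_bits
}

#' Decode a gene to a physical level value
#'
#' Maps the bit pattern of one gene to the physical value of its factor:
#' `min_value + k * (max_value - min_value) / (2^bits - 1)` where `k` is the
#' level index encoded by the gene (base-2 by default, Gray code if the
#' space says so). Levels are therefore evenly spaced and include both range
#' endpoints.
#'
#' @param factor A [factor_spec()].
#' @param gene_bits Integer 0/1 vector of length `factor$bits`.
#' @param encoding `"binary"` or `"gray"`.
#' @return The decoded physical value, always within `[min_value, max_value]`.
#' @examples
#' f <- factor_spec("pH", 2.6, 7.0, bits = 5)
#' decode_factor(f, c(1, 1, 1, 0, 1))  # level 29 -> 6.716...
#' @export
decode_factor <- function(factor, gene_bits, encoding = "binary") {
  stopifnot(inherits(factor, "factor_spec"))
  gene_bits <- check_gene_bits(factor, gene_bits)
  k <- gene_to_level_index(factor, gene_bits, encoding)
  factor$min_value + k * (factor$max_value - factor$min_value) /
    (2L^factor$bits - 1L)
}

#' Encode a physical value as the nearest representable gene
#'
#' Inverse of [decode_factor()] up to grid rounding: returns the gene whose
#' decoded level is closest to `value`; exact midpoints between two levels
#' round toward the lower level index.
#'
#' @inheritParams decode_factor
#' @param value Physical value within `[min_value, max_value]`.
#' @return Integer 0/1 vector of length `factor$bits`.
#' @export
encode_level <- function(factor, value, encoding = "binary") {
  stopifnot(inherits(factor, "factor_spec"))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("value for factor '", factor$name, "' must be a finite number",
         call. = FALSE)
  if (value < factor$min_value || value > factor$max_value)
    stop("value ", value, " outside range [", factor$min_value, ", ",
         factor$max_value, "] of factor '", factor$name, "'", call. = FALSE)
  step <- (factor$max_value - factor$min_value) / (2L^factor$bits - 1L)
  t <- (value - factor$min_value) / step
  k <- ceiling(t - 0.5)              # ties (t = k + 0.5) round down
  k <- max(0L, min(2L^factor$bits - 1L, as.integer(round(k))))
  level_index_to_gene(factor, k, encoding)
}

#' Decode a full chromosome into physical conditions
#'
#' Partitions the chromosome bit vector into consecutive genes in declared
#' factor order and decodes each.
#'
#' @param space A [design_space()].
#' @param chromosome A [chromosome()] or a plain 0/1 vector of length `L`.
#' @return Named numeric vector, one physical value per factor.
#' @export
decode_chromosome <- function(space, chromosome) {
  stopifnot(inherits(space, "design_space"))
  bits <- chromosome_bits(chromosome)
  L <- chromosome_length(space)
  if (length(bits) != L)
    stop("chromosome has ", length(bits), " bits; design space requires ", L,
         call. = FALSE)
  idx <- chromosome_level_indices(space, bits)
  vals <- vapply(seq_along(space$factors), function(i) {
    f <- space$factors[[i]]
    f$min_value + idx[i] * (f$max_value - f$min_value) / (2L^f$bits - 1L)
  }, 0)
  names(vals) <- names(space$factors)
  vals
}

# 0-based level index per factor for a raw bit vector.
chromosome_level_indices <- function(space, bits) {
  offsets <- c(0L, cumsum(vapply(space$factors, `[[`, 0L, "bits")))
  idx <- vapply(seq_along(space$factors), function(i) {
    f <- space$factors[[i]]
    gene <- bits[(offsets[i] + 1L):offsets[i + 1L]]
    gene_to_level_index(f, check_gene_bits(f, gene), space$encoding)
  }, 0L)
  names(idx) <- names(space$factors)
  idx
}

#' Construct a chromosome
#'
#' A chromosome is a bit string encoding one complete set of experimental
#' conditions (one gene per factor), plus an identifier unique within its
#' generation.
#'
#' @param bits Integer 0/1 vector.
#' @param id Character identifier.
#' @return An object of class `chromosome`.
#' @export
chromosome <- function(bits, id = "") {
  bits <- as.integer(bits)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("chromosome bits must all be 0 or 1", call. = FALSE)
  structure(list(id = as.character(id), bits = bits), class = "chromosome")
}

chromosome_bits <- function(x) {
  if (inherits(x, "chromosome")) x$bits else as.integer(x)
}

#' @export
print.chromosome <- function(x, ...) {
  cat(sprintf("<chromosome %s> %s\n", x$id, paste(x$bits, collapse = "")))
  invisible(x)
}

#' Encode physical condition values as a chromosome
#'
#' @param space A [design_space()].
#' @param values Named numeric vector covering every factor.
#' @param id Identifier for the new chromosome.
#' @return A [chromosome()] on the nearest representable grid point.
#' @export
encode_chromosome <- function(space, values, id = "") {
  stopifnot(inherits(space, "design_space"))
  missing <- setdiff(names(space$factors), names(values))
  if (length(missing))
    stop("values missing for factor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bits <- unlist(lapply(space$factors, function(f)
    encode_level(f, unname(values[[f$name]]), space$encoding)))
  chromosome(bits, id)
}

#' Read a design configuration file
#'
#' Parses a YAML (or JSON) configuration into a [design_space()] plus GA
#' parameters. Expected top-level keys: `factors` (list of name/min/max and
#' optional bits/units), `objectives` (list of name/direction/weight) and an
#' optional `ga` block (population_size, selection_fraction, crossover_rate,
#' mutation_rate, elitism). Validation failures are reported together,
#' naming each offending entry.
#'
#' @param path Path to the configuration file.
#' @return List with elements `space` (a `design_space`) and `ga`
#'   (a named list of GA parameter overrides, possibly empty).
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  parse_design_config(cfg)
}

parse_design_config <- function(cfg) {
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)
  factors <- list()
  if (is.null(cfg$factors) || !length(cfg$factors)) {
    note("config must declare at least one factor")
  } else {
    for (i in seq_along(cfg$factors)) {
      f <- cfg$factors[[i]]
      nm <- if (is.null(f$name)) sprintf("<factor #%d>", i) else f$name
      if (is.null(f$name)) note(sprintf("factor #%d: missing name", i))
      if (is.null(f$min) || is.null(f$max)) {
        note(sprintf("factor '%s': missing min or max", nm))
        next
      }
      res <- tryCatch(
        factor_spec(nm, f$min, f$max,
                    bits = if (is.null(f$bits)) 5L else f$bits,
                    units = if (is.null(f$units)) "" else f$units),
        error = function(e) conditionMessage(e))
      if (is.character(res)) note(res) else factors[[length(factors) + 1L]] <- res
    }
  }
  objectives <- list()
  if (is.null(cfg$objectives) || !length(cfg$objectives)) {
    note("config must declare at least one objective")
  } else {
    for (i in seq_along(cfg$objectives)) {
      o <- cfg$objectives[[i]]
      nm <- if (is.null(o$name)) sprintf("<objective #%d>", i) else o$name
      if (is.null(o$name)) note(sprintf("objective #%d: missing name", i))
      res <- tryCatch(
        objective_spec(nm,
                       direction = if (is.null(o$direction)) "maximize" else o$direction,
                       weight = if (is.null(o$weight)) 1 else o$weight),
        error = function(e) conditionMessage(e))
      if (is.character(res)) note(res) else
        objectives[[length(objectives) + 1L]] <- res
    }
  }
  if (length(errs))
    stop("invalid design configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  encoding <- if (is.null(cfg$encoding)) "binary" else cfg$encoding
  space <- design_space(factors, objectives, encoding = encoding)
  ga <- if (is.null(cfg$ga)) list() else cfg$ga
  list(space = space, ga = ga)
}
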