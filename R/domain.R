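#' Continuous optimization variable
#'
#' Declares a continuous reaction parameter (residence time, temperature,
#' catalyst loading, ...) with its bounds in native units. Inputs are
#' min-max scaled to \[0, 1\] by these bounds before any kernel evaluation,
#' so one shared set of length-scale priors is sensible across variables
#' with very different units.
#'
#' @param name Variable name; must be unique within a domain.
#' @param lower,upper Bounds in native units; `lower < upper` is required.
#' @param units Free-text unit label (e.g. `"min"`, `"C"`, `"mol%"`).
#' @return An object of class `continuous_variable`.
#' @export
#' @examples
#' continuous_variable("time", 5, 60, "min")
continuous_variable <- function(name, lower, upper, units = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("variable name must be a non-empty string")
  if (!is_scalar_number(lower) || !is_scalar_number(upper))
    stopf("bounds for '%s' must be finite numbers", name)
  if (lower >= upper)
    stopf("variable '%s': lower bound (%g) must be < upper bound (%g)",
          name, lower, upper)
  structure(list(name = name, lower = lower, upper = upper, units = units),
            class = c("continuous_variable", "domain_variable"))
}

#' Categorical optimization variable
#'
#' Declares a categorical reaction parameter (solvent, ligand, catalyst).
#' The level order is fixed at declaration because the one-hot encoding
#' depends on it.
#'
#' @param name Variable name.
#' @param levels Character vector of at least two distinct level labels.
#' @return An object of class `categorical_variable`.
#' @export
#' @examples
#' categorical_variable("solvent",
#'   c("toluene", "DMA", "acetonitrile", "DMSO", "NMP"))
categorical_variable <- function(name, levels) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("variable name must be a non-empty string")
  levels <- as.character(levels)
  if (length(levels) < 2L)
    stopf("variable '%s' needs at least 2 levels", name)
  if (anyDuplicated(levels))
    stopf("variable '%s' has duplicated levels", name)
  structure(list(name = name, levels = levels),
            class = c("categorical_variable", "domain_variable"))
}

#' Reaction condition domain
#'
#' The searchable condition space: an ordered list of continuous and
#' categorical variables plus the objective declaration. The encoded
#' feature dimension is the number of continuous variables plus the total
#' number of categorical levels (one-hot blocks).
#'
#' @param variables List of [continuous_variable()] / [categorical_variable()].
#' @param objective Name of the objective column (default `"yield"`).
#' @param maximize Logical; `TRUE` for yield maximization.
#' @return An object of class `reaction_domain`.
#' @export
reaction_domain <- function(variables, objective = "yield", maximize = TRUE) {
  if (length(variables) < 1L) stopf("a domain needs at least one variable")
  ok <- vapply(variables, inherits, logical(1), "domain_variable")
  if (!all(ok)) stopf("all domain entries must be domain variables")
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stopf("duplicated variable name: '%s'",
                                nms[duplicated(nms)][1])
  if (objective %in% nms)
    stopf("objective name '%s' collides with a variable name", objective)
  names(variables) <- nms
  structure(list(variables = variables, objective = objective,
                 maximize = isTRUE(maximize)),
            class = "reaction_domain")
}

#' @export
print.reaction_domain <- function(x, ...) {
  cat("Reaction domain (", length(x$variables), " variables, encoded dim ",
      encoded_dim(x), ")\n", sep = "")
  for (v in x$variables) {
    if (inherits(v, "continuous_variable")) {
      cat(sprintf("  %s: continuous [%g, %g] %s\n", v$name, v$lower, v$upper,
                  v$units))
    } else {
      cat(sprintf("  %s: categorical {%s}\n", v$name,
                  paste(v$levels, collapse = ", ")))
    }
  }
  cat(sprintf("  objective: %s (%s)\n", x$objective,
              if (x$maximize) "maximize" else "minimize"))
  invisible(x)
}

variable_names <- function(domain) names(domain$variables)

is_continuous <- function(v) inherits(v, "continuous_variable")

continuous_names <- function(domain) {
  names(domain$variables)[vapply(domain$variables, is_continuous, logical(1))]
}

categorical_names <- function(domain) {
  names(domain$variables)[!vapply(domain$variables, is_continuous, logical(1))]
}

#' Encoded feature dimension of a domain
#'
#' @param domain A [reaction_domain()].
#' @return Integer: number of continuous variables plus the total number of
#'   categorical levels.
#' @export
encoded_dim <- function(domain) {
  sum(vapply(domain$variables, function(v) {
    if (is_continuous(v)) 1L else length(v$levels)
  }, integer(1)))
}

validate_condition <- function(condition, domain, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" (", where, ")")
  for (v in domain$variables) {
    if (!v$name %in% names(condition))
      stopf("condition is missing variable '%s'%s", v$name, ctx)
    val <- condition[[v$name]]
    if (is_continuous(v)) {
      if (!is_scalar_number(val))
        stopf("variable '%s' must be a finite number%s", v$name, ctx)
      if (val < v$lower || val > v$upper)
        stopf("variable '%s' value %g outside bounds [%g, %g]%s",
              v$name, val, v$lower, v$upper, ctx)
    } else {
      if (!is.character(val) && !is.factor(val))
        stopf("variable '%s' must be a level label%s", v$name, ctx)
      val <- as.character(val)
      if (length(val) != 1L || !val %in% v$levels)
        stopf("variable '%s': unknown level '%s'%s", v$name,
              paste(val, collapse = ","), ctx)
    }
  }
  invisible(TRUE)
}

#' Encode a condition as a feature vector
#'
#' Continuous variables are min-max scaled to \[0, 1\] by their declared
#' bounds; each categorical variable is expanded into a one-hot block in
#' declared level order. `decode_vector()` inverts the map exactly.
#'
#' @param condition Named list (or one-row data frame) with one entry per
#'   domain variable.
#' @param domain A [reaction_domain()].
#' @return Numeric vector of length `encoded_dim(domain)`.
#' @export
#' @examples
#' d <- reaction_domain(list(continuous_variable("temperature", 50, 150)))
#' encode_condition(list(temperature = 100), d)  # 0.5
encode_condition <- function(condition, domain) {
  if (is.data.frame(condition)) condition <- as.list(condition[1, , drop = FALSE])
  validate_condition(condition, domain)
  out <- numeric(0)
  for (v in domain$variables) {
    val <- condition[[v$name]]
    if (is_continuous(v)) {
      out <- c(out, (val - v$lower) / (v$upper - v$lower))
    } else {
      block <- as.numeric(v$levels == as.character(val))
      out <- c(out, block)
    }
  }
  unname(out)
}

#' Decode a feature vector back to a condition
#'
#' Inverse of [encode_condition()]. One-hot blocks must be exact indicator
#' vectors unless `categorical = "argmax"`, in which case a relaxed block
#' (as produced by continuous acquisition optimization) is resolved to the
#' level with the largest weight, ties broken by the lowest declared level
#' index.
#'
#' @param vector Numeric vector of length `encoded_dim(domain)`.
#' @param domain A [reaction_domain()].
#' @param categorical `"strict"` (default) or `"argmax"`.
#' @return Named list: one entry per domain variable, in native units/labels.
#' @export
decode_vector <- function(vector, domain, categorical = c("strict", "argmax")) {
  categorical <- match.arg(categorical)
  if (length(vector) != encoded_dim(domain))
    stopf("feature vector has length %d, expected %d",
          length(vector), encoded_dim(domain))
  out <- list()
  i <- 1L
  for (v in domain$variables) {
    if (is_continuous(v)) {
      out[[v$name]] <- v$lower + vector[i] * (v$upper - v$lower)
      i <- i + 1L
    } else {
      k <- length(v$levels)
      block <- vector[i:(i + k - 1L)]
      if (categorical == "strict") {
        if (!all(block %in% c(0, 1)) || sum(block) != 1)
          stopf("invalid one-hot block for variable '%s'", v$name)
        idx <- which(block == 1)
      } else {
        idx <- which.max(block)  # which.max takes the first maximum: lowest index
      }
      out[[v$name]] <- v$levels[idx]
      i <- i + k
    }
  }
  out
}

# Encode every row of a condition data frame into an N x d matrix.
encode_conditions <- function(df, domain, where_prefix = "row") {
  n <- nrow(df)
  X <- matrix(NA_real_, n, encoded_dim(domain))
  for (r in seq_len(n)) {
    cond <- as.list(df[r, variable_names(domain), drop = FALSE])
    X[r, ] <- tryCatch(encode_condition(cond, domain),
                       error = function(e)
                         stopf("%s %d: %s", where_prefix, r, conditionMessage(e)))
  }
  X
}

#' Build an experiment table
#'
#' The universal interchange record: one row per experiment, with one
#' column per domain variable, an objective column (yield, percent in
#' \[0, 100\]) named by the domain's objective, and a `task` label column.
#' Single-task tables use one constant task label.
#'
#' @param data A data frame with the columns described above. A missing
#'   `task` column is filled with `"main"`.
#' @param domain A [reaction_domain()].
#' @return An object of class `experiment_table` (a validated data frame
#'   with the domain attached as an attribute).
#' @export
experiment_table <- function(data, domain) {
  data <- as.data.frame(data)
  need <- c(variable_names(domain), domain$objective)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stopf("experiment table is missing column '%s'", miss[1])
  if (!"task" %in% names(data)) data$task <- rep("main", nrow(data))
  data$task <- as.character(data$task)
  y <- data[[domain$objective]]
  if (!is.numeric(y)) {
    yn <- suppressWarnings(as.numeric(as.character(y)))
    bad <- which(is.na(yn) & !is.na(y))
    if (length(bad))
      stopf("row %d: non-numeric %s value '%s'", bad[1], domain$objective,
            as.character(y)[bad[1]])
    y <- yn
    data[[domain$objective]] <- y
  }
  bad <- which(!is.finite(y) | y < 0 | y > 100)
  if (length(bad))
    stopf("row %d: %s value %s outside [0, 100]", bad[1], domain$objective,
          format(y[bad[1]]))
  for (r in seq_len(nrow(data))) {
    validate_condition(as.list(data[r, variable_names(domain), drop = FALSE]),
                       domain, where = paste("row", r))
  }
  data <- data[, c(variable_names(domain), domain$objective, "task")]
  structure(data, domain = domain, class = c("experiment_table", "data.frame"))
}

table_domain <- function(table) attr(table, "domain")

#' Read an experiment table from CSV
#'
#' Expects a UTF-8 CSV with a header row: one column per domain variable
#' (level labels as text for categoricals), the objective column, and
#' optionally a `task` column. Rows failing validation are rejected with
#' their row number.
#'
#' @param path Path to the CSV file.
#' @param domain A [reaction_domain()].
#' @return An `experiment_table`.
#' @export
read_table <- function(path, domain) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        encoding = "UTF-8")
  experiment_table(df, domain)
}

#' Write an experiment table to CSV
#'
#' Round-trips losslessly with [read_table()] for values printed at full
#' precision.
#'
#' @param table An `experiment_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Read a domain from a JSON config
#'
#' Config format:
#' \preformatted{
#' {"variables": [
#'    {"name": "time", "type": "continuous", "lower": 5, "upper": 60,
#'     "units": "min"},
#'    {"name": "solvent", "type": "categorical",
#'     "levels": ["toluene", "DMA"]}],
#'  "objective": {"name": "yield", "maximize": true}}
#' }
#'
#' @param path Path to the JSON file.
#' @return A [reaction_domain()].
#' @export
read_domain <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$variables)) stopf("domain config has no 'variables' entry")
  vars <- lapply(cfg$variables, function(v) {
    if (identical(v$type, "continuous")) {
      continuous_variable(v$name, v$lower, v$upper, v$units %||% "")
    } else if (identical(v$type, "categorical")) {
      categorical_variable(v$name, unlist(v$levels))
    } else {
      stopf("variable '%s': unknown type '%s'", v$name %||% "?",
            v$type %||% "?")
    }
  })
  obj <- cfg$objective %||% list(name = "yield", maximize = TRUE)
  reaction_domain(vars, objective = obj$name %||% "yield",
                  maximize = obj$maximize %||% TRUE)
}

#' Write a domain to a JSON config
#'
#' @param domain A [reaction_domain()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domain <- function(domain, path) {
  vars <- lapply(domain$variables, function(v) {
    if (is_continuous(v)) {
      list(name = v$name, type = "continuous", lower = v$lower,
           upper = v$upper, units = v$units)
    } else {
      list(name = v$name, type = "categorical", levels = as.list(v$levels))
    }
  })
  cfg <- list(variables = unname(vars),
              objective = list(name = domain$objective,
                               maximize = domain$maximize))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
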