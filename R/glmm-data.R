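#' Read a long-format repeated-measures table
#'
#' Reads a comma-separated file with one row per clinical encounter and
#' validates it against a column schema.  Categorical levels are recorded
#' in order of first appearance; identifier columns are kept as character
#' labels.
#'
#' @param path Path to a CSV file (header row, `.` decimal separator).
#' @param schema A list describing the expected columns:
#'   `id` (character vector of identifier columns, e.g. patient and
#'   facility), `event` (name of the non-negative integer outcome column,
#'   optional), `duration` (name of the positive exposure column, optional),
#'   `covariates` (named character vector mapping column name to
#'   `"numeric"` or `"categorical"`).
#' @return A `data.frame` of class `long_table` with rows in file order.
#'   Categorical columns are factors with levels in first-appearance order;
#'   the schema is attached as attribute `"schema"`.
#' @export
read_long_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = NULL, colClasses = "character")
  as_long_table(raw, schema)
}

#' Validate a data frame as a long-format table
#'
#' @param df A data frame (character or typed columns).
#' @param schema See [read_long_table()].
#' @return A `long_table` data frame.
#' @export
as_long_table <- function(df, schema) {
  schema$id <- schema$id %||% character()
  schema$covariates <- schema$covariates %||% character()
  declared <- c(schema$id, schema$event, schema$duration, names(schema$covariates))
  missing_cols <- setdiff(declared, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))

  parse_num <- function(col, what) {
    x <- df[[col]]
    if (is.numeric(x)) return(x)
    bad <- x == "" | toupper(x) == "NA"
    if (any(bad))
      stop("parse error in column '", col, "': missing value at row ",
           which(bad)[1])
    out <- suppressWarnings(as.numeric(x))
    if (anyNA(out))
      stop("parse error in column '", col, "': non-numeric value at row ",
           which(is.na(out))[1])
    out
  }

  out <- df[declared]
  for (id in schema$id) out[[id]] <- as.character(df[[id]])
  if (!is.null(schema$event)) {
    ev <- parse_num(schema$event, "event")
    if (any(ev < 0) || any(ev != round(ev)))
      stop("validation error: column '", schema$event,
           "' must contain non-negative integer counts")
    out[[schema$event]] <- ev
  }
  if (!is.null(schema$duration)) {
    du <- parse_num(schema$duration, "duration")
    if (any(du <= 0))
      stop("validation error: column '", schema$duration,
           "' must be strictly positive (row ", which(du <= 0)[1], ")")
    out[[schema$duration]] <- du
  }
  for (cov in names(schema$covariates)) {
    if (schema$covariates[[cov]] == "numeric") {
      out[[cov]] <- parse_num(cov, "covariate")
    } else {
      x <- as.character(df[[cov]])
      out[[cov]] <- factor(x, levels = unique(x))
    }
  }
  class(out) <- c("long_table", "data.frame")
  attr(out, "schema") <- schema
  out
}

#' Write a long-format table back to CSV
#'
#' Inverse of [read_long_table()]: `read_long_table(write_long_table(x, f),
#' schema)` reproduces the parsed values exactly (factor columns are written
#' as their labels).
#'
#' @param x A `long_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(x, path) {
  y <- as.data.frame(x)
  for (j in seq_along(y)) if (is.factor(y[[j]])) y[[j]] <- as.character(y[[j]])
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode per-encounter survival as a Poisson outcome with log-exposure offset
#'
#' Repeated encounters of one patient are a string of zeros (alive at the
#' end of each encounter), possibly terminated by a one if the patient died
#' during the final encounter.  Modelling this vector as Poisson with the
#' log encounter duration as offset is the standard piecewise-exponential
#' device linking Poisson regression and survival analysis.
#'
#' @param alive_at_end Logical vector over one patient's encounters in time
#'   order; only the last entry may be `FALSE`.
#' @param duration_days Positive exposure durations, same length.
#' @return A list with `event` (0/1 integer vector) and `offset`
#'   (`log(duration_days)`).
#' @examples
#' encode_survival_poisson(c(TRUE, TRUE, FALSE), c(5, 2, 10))
#' @export
encode_survival_poisson <- function(alive_at_end, duration_days) {
  n <- length(alive_at_end)
  if (length(duration_days) != n) stop("length mismatch")
  if (any(duration_days <= 0))
    stop("validation error: durations must be positive")
  dead <- which(!alive_at_end)
  if (length(dead) > 1L || (length(dead) == 1L && dead != n))
    stop("ordering error: death must terminate the encounter sequence")
  list(event = as.integer(!alive_at_end), offset = log(duration_days))
}

#' Natural cubic spline basis
#'
#' Thin wrapper around [splines::ns()] that fixes the knot-placement rule
#' used throughout the package: boundary knots at the 1st and 99th
#' percentiles of the observed values and `df - 1` internal knots at
#' equally spaced quantiles between them.  Explicit knots may be supplied
#' instead, which makes the basis reproducible on new data (prediction,
#' risk-curve grids).
#'
#' @param values Numeric vector to evaluate the basis at.
#' @param df Number of basis columns (>= 1).
#' @param boundary Optional length-2 boundary knots; defaults to the
#'   1st/99th percentiles of `values`.
#' @param knots Optional internal knots (overrides the quantile rule).
#' @return An object of class `spline_basis`: list with the evaluated
#'   `matrix` (length(values) x df), `df`, `boundary`, `knots`.
#' @export
natural_spline_basis <- function(values, df = 3, boundary = NULL, knots = NULL) {
  if (df < 1) stop("df must be >= 1")
  if (is.null(boundary))
    boundary <- unname(stats::quantile(values, c(0.01, 0.99), type = 7))
  if (is.null(knots)) {
    if (df > 1) {
      probs <- seq_len(df - 1) / df
      finite <- values[values >= boundary[1] & values <= boundary[2]]
      if (length(unique(finite)) < df + 1)
        stop("degenerate input: fewer distinct values than required knots")
      knots <- unname(stats::quantile(finite, probs, type = 7))
    } else {
      knots <- numeric()
    }
  }
  mat <- splines::ns(values, knots = knots, Boundary.knots = boundary)
  mat <- unclass(mat)[, , drop = FALSE]
  attributes(mat) <- list(dim = dim(mat))
  structure(
    list(matrix = mat, df = ncol(mat), boundary = boundary, knots = knots),
    class = "spline_basis"
  )
}

#' Evaluate an existing spline basis at new values
#'
#' @param basis A `spline_basis`.
#' @param values New numeric values; values beyond the boundary knots are
#'   extrapolated linearly (the natural-spline constraint).
#' @return Matrix with `basis$df` columns.
#' @export
eval_spline_basis <- function(basis, values) {
  mat <- splines::ns(values, knots = basis$knots, Boundary.knots = basis$boundary)
  mat <- unclass(mat)[, , drop = FALSE]
  attributes(mat) <- list(dim = dim(mat))
  mat
}

#' Assemble a GLMM dataset (response, designs, offsets) from a long table
#'
#' Builds the fixed-effect design matrix `X` (intercept first, categorical
#' covariates dummy-coded against their first-appearance level, linear
#' terms, natural-spline blocks) and the sparse random-intercept design `Z`
#' (one indicator block per grouping factor) from a long-format table.
#'
#' @param table A `long_table` (or plain data frame).
#' @param config Model configuration: list with
#'   * `family`: `"poisson"`, `"bernoulli"` or `"gaussian"`,
#'   * `response`: name of the outcome column,
#'   * `offset_from`: optional duration column; the offset is its natural
#'     logarithm (0 when absent — pure count model),
#'   * `fixed`: list of terms, each `list(name=, type=)` with type
#'     `"linear"`, `"categorical"` or `"spline"` (spline terms take `df`,
#'     optional `boundary`/`knots`),
#'   * `groups`: character vector of grouping-factor columns (e.g. patient
#'     and facility identifiers).
#' @return An object of class `glmm_data`: list with `y`, `X` (dense),
#'   `Z` (sparse `dgCMatrix`, column blocks per grouping factor), `offset`,
#'   `family` (an [hlik_family()]), `groups` (per factor: `name`, `levels`,
#'   `index` of each row), and `terms` (column map of `X`, including fitted
#'   spline bases for later prediction).
#' @export
build_design <- function(table, config) {
  df <- as.data.frame(table)
  need <- c(config$response, config$offset_from,
            vapply(config$fixed, `[[`, "", "name"), config$groups)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))

  n <- nrow(df)
  y <- as.numeric(df[[config$response]])
  offset <- if (!is.null(config$offset_from)) {
    d <- as.numeric(df[[config$offset_from]])
    if (any(d <= 0)) stop("validation error: offset durations must be positive")
    log(d)
  } else rep(0, n)

  cols <- list(`(Intercept)` = rep(1, n))
  terms <- list(list(name = "(Intercept)", type = "intercept",
                     columns = "(Intercept)"))
  for (term in config$fixed) {
    nm <- term$name
    x <- df[[nm]]
    if (term$type == "linear") {
      cols[[nm]] <- as.numeric(x)
      terms[[length(terms) + 1L]] <- list(name = nm, type = "linear",
                                          columns = nm)
    } else if (term$type == "categorical") {
      f <- if (is.factor(x)) x else factor(x, levels = unique(as.character(x)))
      levs <- levels(f)
      cn <- character(0)
      for (lv in levs[-1]) {
        cname <- paste0(nm, lv)
        cols[[cname]] <- as.numeric(f == lv)
        cn <- c(cn, cname)
      }
      terms[[length(terms) + 1L]] <- list(name = nm, type = "categorical",
                                          columns = cn, levels = levs)
    } else if (term$type == "spline") {
      xv <- as.numeric(x)
      if (length(unique(xv)) < 2)
        stop("degenerate input: spline requested for constant covariate '",
             nm, "'")
      basis <- natural_spline_basis(xv, df = term$df %||% 3,
                                    boundary = term$boundary,
                                    knots = term$knots)
      cn <- paste0("ns(", nm, ")", seq_len(basis$df))
      for (k in seq_len(basis$df)) cols[[cn[k]]] <- basis$matrix[, k]
      terms[[length(terms) + 1L]] <- list(name = nm, type = "spline",
                                          columns = cn, basis = basis)
    } else stop("unknown term type: ", term$type)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  groups <- list()
  Zblocks <- list()
  for (g in config$groups) {
    x <- as.character(df[[g]])
    # sorted levels: the random-effects design is invariant to row order
    levs <- sort(unique(x), method = "radix")
    idx <- match(x, levs)
    groups[[g]] <- list(name = g, levels = levs, index = idx)
    Zblocks[[g]] <- Matrix::sparseMatrix(i = seq_len(n), j = idx, x = 1,
                                         dims = c(n, length(levs)))
  }
  Z <- if (length(Zblocks)) do.call(cbind, Zblocks) else
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                         dims = c(n, 0))

  glmm_data(y = y, X = X, Z = Z, offset = offset,
            family = hlik_family(config$family), groups = groups,
            terms = terms)
}

#' Construct a GLMM dataset directly from components
#'
#' Low-level constructor used by [build_design()], the simulators and the
#' test suite.  Validates the dimensional invariants: matching row counts
#' and indicator structure of the random-effects design (each row of every
#' grouping-factor block has exactly one entry equal to 1).
#'
#' @param y Response vector (length N).
#' @param X Dense fixed-effects design (N x p).
#' @param Z Sparse random-intercept design (N x q) or `NULL` to build it
#'   from `groups`.
#' @param offset Offset vector (length N; recycled scalar allowed).
#' @param family An [hlik_family()] or family name.
#' @param groups List of grouping factors, each `list(name, levels, index)`
#'   where `index[i]` is the level number of row i.
#' @param terms Optional term map (see [build_design()]).
#' @return A `glmm_data` object.
#' @export
glmm_data <- function(y, X, Z = NULL, offset = 0, family = "gaussian",
                      groups = list(), terms = NULL) {
  if (!is_hlik_family(family)) family <- hlik_family(family)
  n <- length(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != n) stop("contract error: nrow(X) != length(y)")
  if (is.null(Z)) {
    blocks <- lapply(groups, function(g)
      Matrix::sparseMatrix(i = seq_len(n), j = g$index, x = 1,
                           dims = c(n, length(g$levels))))
    Z <- if (length(blocks)) do.call(cbind, blocks) else
      Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                           dims = c(n, 0))
  }
  Z <- methods::as(methods::as(Z, "CsparseMatrix"), "generalMatrix")
  if (nrow(Z) != n) stop("contract error: nrow(Z) != length(y)")
  offset <- rep_len(as.numeric(offset), n)
  sizes <- vapply(groups, function(g) length(g$levels), 1L)
  if (length(groups) && sum(sizes) != ncol(Z))
    stop("contract error: group level counts do not match ncol(Z)")
  obj <- structure(
    list(y = as.numeric(y), X = X, Z = Z, offset = offset, family = family,
         groups = groups, terms = terms, cache = new.env(parent = emptyenv())),
    class = "glmm_data"
  )
  validate_glmm_data(obj)
  obj
}

validate_glmm_data <- function(data) {
  start <- 0L
  for (g in data$groups) {
    q_k <- length(g$levels)
    block <- data$Z[, start + seq_len(q_k), drop = FALSE]
    rs <- Matrix::rowSums(block)
    if (any(abs(rs - 1) > 0))
      stop("contract error: rows of the '", g$name,
           "' block must have exactly one unit entry")
    start <- start + q_k
  }
  invisible(data)
}

#' @export
print.glmm_data <- function(x, ...) {
  cat("<glmm_data> ", length(x$y), " obs, p = ", ncol(x$X),
      ", q = ", ncol(x$Z), " (", x$family$name, ")\n", sep = "")
  for (g in x$groups)
    cat("  factor ", g$name, ": ", length(g$levels), " levels\n", sep = "")
  invisible(x)
}

#' Number of random-effect columns per grouping factor
#' @param data A `glmm_data`.
#' @return Integer vector of block sizes.
#' @export
group_sizes <- function(data)
  vapply(data$groups, function(g) length(g$levels), 1L)

#' Subsample patients from a long table
#'
#' Simple random sampling without replacement with the patient as the
#' sampling unit: all encounters of a sampled patient are retained.  Keeps
#' `floor(fraction * n_patients)` patients (all of them when
#' `fraction = 1`).
#'
#' @param table A `long_table` or data frame.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param id Name of the patient identifier column.
#' @return The subsampled table, rows in original order.
#' @export
subsample_patients <- function(table, fraction, seed, id = "patient_id") {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("validation error: fraction must be in (0, 1]")
  if (fraction == 1) return(table)
  ids <- unique(as.character(table[[id]]))
  n_keep <- floor(fraction * length(ids))
  keep <- with_seed(seed, sample(ids, n_keep))
  table[as.character(table[[id]]) %in% keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Serialize a GLMM dataset to JSON
#'
#' Writes the assembled container (response, dense X, coordinate-format
#' sparse Z, offset, family, grouping structure) to a single JSON file so
#' a design can be archived alongside results and rebuilt exactly.
#'
#' @param data A [glmm_data()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @seealso [read_glmm_data()]
#' @export
write_glmm_data <- function(data, path) {
  Zt <- methods::as(data$Z, "TsparseMatrix")
  out <- list(
    y = data$y,
    X = list(values = as.numeric(data$X), dim = dim(data$X),
             colnames = colnames(data$X)),
    Z = list(i = Zt@i + 1L, j = Zt@j + 1L, x = Zt@x, dim = dim(data$Z)),
    offset = data$offset,
    family = data$family$name,
    groups = lapply(data$groups, function(g)
      list(name = g$name, levels = g$levels, index = g$index)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild a GLMM dataset from its JSON serialization
#'
#' @param path Path written by [write_glmm_data()].
#' @return A [glmm_data()] identical (up to term metadata, which is not
#'   serialized) to the original.
#' @export
read_glmm_data <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- matrix(j$X$values, j$X$dim[1], j$X$dim[2],
              dimnames = list(NULL, j$X$colnames))
  Z <- Matrix::sparseMatrix(i = j$Z$i, j = j$Z$j, x = j$Z$x,
                            dims = j$Z$dim)
  groups <- lapply(j$groups, function(g)
    list(name = g$name, levels = g$levels, index = as.integer(g$index)))
  names(groups) <- vapply(groups, `[[`, "", "name")
  glmm_data(y = j$y, X = X, Z = Z, offset = j$offset, family = j$family,
            groups = groups)
}
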