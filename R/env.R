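#' Bundle environmental layers on a common grid
#'
#' An `env_stack` couples a [make_grid()] lattice with named layer matrices
#' (one value or `NA` per cell) and, after [standardize_stack()], the
#' per-variable mean/sd used for standardization.
#'
#' @param grid A `grid_spec`.
#' @param layers Named list of numeric matrices, each `n_rows x n_cols`.
#' @param standardization Optional data frame with columns `variable`,
#'   `mean`, `sd` recording the standardization applied.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, standardization = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named")
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop(sprintf("layer '%s' does not match the grid (%d x %d expected)",
                   nm, grid$n_rows, grid$n_cols))
  }
  structure(list(grid = grid, layers = layers,
                 standardization = standardization),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layers [%s] on %d x %d grid%s\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols,
              if (is.null(x$standardization)) "" else " (standardized)"))
  invisible(x)
}

shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Proportional-change gradient in a 3x3 moving window
#'
#' For each cell, the proportional change
#' `PC = (max - min) * 100 / max` is computed over the 3x3 neighbourhood of
#' grid cells centred on it (truncated at grid edges; missing neighbours are
#' ignored). `PC` lies in `[0, 100]` for non-negative layers, and measures
#' local heterogeneity: topographic features for bathymetry, frontal systems
#' for chlorophyll, SST and SSH.
#'
#' Degenerate cases: a constant neighbourhood gives 0; an all-zero
#' neighbourhood gives 0 by convention; a cell whose whole neighbourhood is
#' missing stays missing. Negative values are rejected (shift or transform
#' the layer first), since the statistic is meaningless across a sign change.
#'
#' @param values Numeric layer matrix with non-negative (or missing) values.
#' @return Matrix of the same shape with the gradient, in percent.
#' @export
gradient_pc <- function(values) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (any(values < 0, na.rm = TRUE))
    stop("gradient_pc requires non-negative values; shift or transform the layer first")
  mx <- values; mn <- values
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- shift_matrix(values, dr, dc)
    mx <- pmax(mx, s, na.rm = TRUE)
    mn <- pmin(mn, s, na.rm = TRUE)
  }
  pc <- (mx - mn) * 100 / mx
  pc[!is.na(mx) & mx == 0] <- 0   # all-zero neighbourhood
  pc
}

#' Standardize every layer of a stack
#'
#' Centres and scales each layer to mean 0 and sd 1 over its non-missing
#' cells (sample sd, n-1 denominator), recording the applied `(mean, sd)` so
#' values can be mapped back to natural units and so prediction-time
#' covariates can be screened against the training envelope.
#'
#' @param stack An `env_stack`.
#' @return The standardized `env_stack`, with `$standardization` filled in.
#' @export
standardize_stack <- function(stack) {
  stopifnot(inherits(stack, "env_stack"))
  std <- data.frame(variable = names(stack$layers),
                    mean = NA_real_, sd = NA_real_)
  for (i in seq_along(stack$layers)) {
    v <- stack$layers[[i]]
    ok <- !is.na(v)
    if (sum(ok) < 2)
      stop(sprintf("layer '%s' has fewer than 2 non-missing cells", std$variable[i]))
    mu <- mean(v[ok]); s <- stats::sd(v[ok])
    if (s == 0)
      stop(sprintf("layer '%s' is constant and cannot be standardized", std$variable[i]))
    stack$layers[[i]] <- (v - mu) / s
    std$mean[i] <- mu; std$sd[i] <- s
  }
  stack$standardization <- std
  stack
}

#' Pairwise Spearman collinearity screen
#'
#' Computes all pairwise Spearman rank correlations between layers over
#' cells where both members of a pair are non-missing, and flags strongly
#' correlated pairs (`|rs| > threshold`). The screen is diagnostic: it
#' reports, it does not drop variables.
#'
#' @param stack An `env_stack`.
#' @param threshold Absolute-correlation flag threshold (default 0.5).
#' @return Data frame with one row per unordered pair: `var1`, `var2`, `rs`,
#'   `flagged`.
#' @export
spearman_screen <- function(stack, threshold = 0.5) {
  stopifnot(inherits(stack, "env_stack"))
  vars <- names(stack$layers)
  x <- vapply(stack$layers, as.vector, numeric(n_cells(stack$grid)))
  pairs <- utils::combn(length(vars), 2)
  res <- data.frame(var1 = vars[pairs[1, ]], var2 = vars[pairs[2, ]],
                    rs = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- x[, pairs[1, k]]; b <- x[, pairs[2, k]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3)
      stop(sprintf("fewer than 3 overlapping cells for pair %s / %s",
                   res$var1[k], res$var2[k]))
    res$rs[k] <- stats::cor(a[ok], b[ok], method = "spearman")
  }
  res$flagged <- abs(res$rs) > threshold
  res
}

#' Temporal composite of monthly layers
#'
#' Per-cell mean over the months that have data; a cell is missing only if
#' it is missing in every month.
#'
#' @param monthly Non-empty list of layer matrices of a common shape.
#' @return A single composite layer matrix.
#' @export
temporal_composite <- function(monthly) {
  if (!is.list(monthly) || length(monthly) == 0)
    stop("need at least one monthly layer")
  dims <- dim(monthly[[1]])
  vals <- vapply(monthly, as.vector, numeric(prod(dims)))
  vals <- matrix(vals, nrow = prod(dims))
  out <- rowMeans(vals, na.rm = TRUE)
  out[rowSums(!is.na(vals)) == 0] <- NA_real_
  matrix(out, dims[1], dims[2])
}

#' Extract covariate values at cells
#'
#' @param stack An `env_stack`.
#' @param cells Integer cell ids.
#' @param vars Layer names to extract (default: all).
#' @return Data frame, one row per cell, one column per variable.
#' @export
stack_values_at <- function(stack, cells, vars = names(stack$layers)) {
  stopifnot(inherits(stack, "env_stack"))
  missing_vars <- setdiff(vars, names(stack$layers))
  if (length(missing_vars))
    stop("stack has no layer(s): ", paste(missing_vars, collapse = ", "))
  idx <- mat_index(stack$grid, cells)
  out <- lapply(vars, function(v) stack$layers[[v]][idx])
  names(out) <- vars
  as.data.frame(out, optional = TRUE)
}

#' Cells with complete environmental data
#'
#' @param stack An `env_stack`.
#' @param vars Layer names that must be non-missing (default: all).
#' @return Sorted integer vector of row-major cell ids where every requested
#'   layer is defined.
#' @export
env_complete_cells <- function(stack, vars = names(stack$layers)) {
  stopifnot(inherits(stack, "env_stack"))
  comp <- Reduce(`&`, lapply(stack$layers[vars], function(m) !is.na(m)))
  # which() on the transpose yields row-major ids
  as.integer(which(t(comp)))
}
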