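#' Training-range envelope of model covariates
#'
#' Per-covariate `[min, max]` box over the training cells; prediction-time
#' cells falling outside it are outside the model's environmental space and
#' are masked on the map.
#'
#' @param stack A standardized `env_stack`.
#' @param cells Training cell ids (presences plus pseudo-absences).
#' @param terms Covariates to bound.
#' @return Data frame with `term`, `min`, `max`.
#' @export
train_envelope <- function(stack, cells, terms) {
  x <- stack_values_at(stack, cells, terms)
  data.frame(term = terms,
             min = vapply(x, min, numeric(1), na.rm = TRUE),
             max = vapply(x, max, numeric(1), na.rm = TRUE))
}

#' Project a fitted model over the grid
#'
#' Evaluates the inverse-logit of the model's linear predictor in every
#' grid cell. Cells with any missing covariate, or (when an envelope is
#' supplied) with any covariate outside the training range, carry no
#' prediction — they are outside the model's environmental space.
#'
#' @param fit A `habitat_fit` (or any list with `terms` and named
#'   `coefficients` including `(Intercept)`).
#' @param stack A standardized `env_stack` containing every model term.
#' @param envelope Optional [train_envelope()] result used to mask cells
#'   outside the environmental space.
#' @return Object of class `prediction_map`: `grid`, `probability` matrix
#'   (`NA` where masked), `category` (`NULL` until [categorize_map()]), and
#'   `provenance` (terms, coefficients, envelope).
#' @export
predict_map <- function(fit, stack, envelope = NULL) {
  stopifnot(inherits(stack, "env_stack"))
  missing_vars <- setdiff(fit$terms, names(stack$layers))
  if (length(missing_vars))
    stop("stack has no layer(s): ", paste(missing_vars, collapse = ", "))
  grid <- stack$grid
  eta <- matrix(fit$coefficients[["(Intercept)"]], grid$n_rows, grid$n_cols)
  defined <- matrix(TRUE, grid$n_rows, grid$n_cols)
  for (v in fit$terms) {
    lay <- stack$layers[[v]]
    defined <- defined & !is.na(lay)
    if (!is.null(envelope)) {
      b <- envelope[envelope$term == v, ]
      inside <- !is.na(lay) & lay >= b$min & lay <= b$max
      defined <- defined & inside
    }
    lay0 <- lay; lay0[is.na(lay0)] <- 0
    eta <- eta + fit$coefficients[[v]] * lay0
  }
  prob <- stats::plogis(eta)
  prob[!defined] <- NA_real_
  structure(list(grid = grid, probability = prob, category = NULL,
                 provenance = list(terms = fit$terms,
                                   coefficients = fit$coefficients,
                                   envelope = envelope)),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  n_def <- sum(!is.na(x$probability))
  cat(sprintf("prediction_map: %d x %d grid, %d cells predicted (%.1f%%)%s\n",
              x$grid$n_rows, x$grid$n_cols, n_def,
              100 * n_def / n_cells(x$grid),
              if (is.null(x$category)) "" else ", categorized"))
  invisible(x)
}

#' Categorize a probability map into three classes
#'
#' Classes: low (`p < low`), medium (`low <= p <= high`, both endpoints
#' included), high (`p > high`). Masked cells stay masked. Codes are
#' 0 = low, 1 = medium, 2 = high.
#'
#' @param map A `prediction_map`.
#' @param low,high Class thresholds (defaults 0.33 and 0.66).
#' @return The map with `$category` filled in (integer matrix with
#'   `levels` attribute `c("low", "medium", "high")`).
#' @export
categorize_map <- function(map, low = 0.33, high = 0.66) {
  stopifnot(inherits(map, "prediction_map"))
  if (!(low < high)) stop("thresholds out of order: require low < high")
  p <- map$probability
  cat <- matrix(NA_integer_, nrow(p), ncol(p))
  cat[!is.na(p) & p < low] <- 0L
  cat[!is.na(p) & p >= low & p <= high] <- 1L
  cat[!is.na(p) & p > high] <- 2L
  attr(cat, "levels") <- c("low", "medium", "high")
  map$category <- cat
  map$thresholds <- c(low = low, high = high)
  map
}

#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south). Values
#' are written with 17 significant digits so a write/read round trip is
#' bit-exact for doubles.
#'
#' @param values Layer matrix on `grid` (row 1 = north).
#' @param grid A `grid_spec`.
#' @param file Output path.
#' @param nodata NODATA sentinel (default -9999).
#' @return The path, invisibly.
#' @export
write_ascii_grid <- function(values, grid, file, nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.17g", grid$lon_min),
           sprintf("yllcorner %.17g", grid$lat_min),
           sprintf("cellsize %.17g", grid$cell_deg),
           sprintf("NODATA_value %.17g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' Read an ESRI ASCII grid
#'
#' @param file Path to a `.asc` file written by [write_ascii_grid()] (or any
#'   conforming ESRI ASCII grid).
#' @return List with `values` (matrix, NODATA as `NA`) and `grid`
#'   (`grid_spec` reconstructed from the header).
#' @export
read_ascii_grid <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header")
  nc <- as.integer(vals["ncols"]); nr <- as.integer(vals["nrows"])
  data <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(data) != nr * nc) stop("ASCII grid data does not match header")
  m <- matrix(data, nr, nc, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA_real_
  grid <- make_grid(vals[["xllcorner"]], vals[["xllcorner"]] + nc * vals[["cellsize"]],
                    vals[["yllcorner"]], vals[["yllcorner"]] + nr * vals[["cellsize"]],
                    vals[["cellsize"]])
  list(values = m, grid = grid)
}

#' Export a prediction map to ASCII grid files
#'
#' Writes `<prefix>_probability.asc` (NODATA -9999) and, if the map is
#' categorized, `<prefix>_category.asc` with the documented encoding
#' masked = 255, low = 0, medium = 1, high = 2.
#'
#' @param map A `prediction_map`.
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
export_map <- function(map, prefix) {
  stopifnot(inherits(map, "prediction_map"))
  files <- paste0(prefix, "_probability.asc")
  write_ascii_grid(map$probability, map$grid, files[1], nodata = -9999)
  if (!is.null(map$category)) {
    f2 <- paste0(prefix, "_category.asc")
    write_ascii_grid(map$category + 0, map$grid, f2, nodata = 255)
    files <- c(files, f2)
  }
  invisible(files)
}
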