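#' Construct a presence set from cell ids
#'
#' Wraps an already-known set of occupied cells (e.g. drawn from a known
#' habitat model with [sample_presence_cells()]) in the `presence_set`
#' container used by the occurrence and modelling stages.
#'
#' @param cells Integer cell ids (duplicates collapsed).
#' @param colony Optional colony label.
#' @param window Optional length-2 date window.
#' @return Object of class `presence_set`.
#' @export
presence_set <- function(cells, colony = NA_character_, window = NULL) {
  cells <- sort(unique(as.integer(cells)))
  if (length(cells) == 0) stop("empty presence set")
  structure(list(cells = cells, colony = colony, window = window,
                 n_positions = length(cells),
                 n_outside_window = 0L, n_outside_grid = 0L),
            class = "presence_set")
}

#' Rasterize daily positions to presence cells
#'
#' Maps daily positions inside the modelling window onto the grid and
#' collapses duplicates: a presence cell is any cell holding at least one
#' in-window daily position (presence, not counts). Positions outside the
#' window or the grid are excluded and counted in the returned report.
#'
#' @param daily Daily-position data frame (`date`, `lon`, `lat`).
#' @param grid A `grid_spec`.
#' @param window_start,window_end Inclusive date window (default the
#'   1 January - 31 March 2008 modelling window).
#' @param colony Optional colony label carried on the result.
#' @return Object of class `presence_set`: sorted `cells`, the `window`,
#'   and exclusion counts.
#' @export
rasterize_presence <- function(daily, grid,
                               window_start = as.Date("2008-01-01"),
                               window_end = as.Date("2008-03-31"),
                               colony = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"))
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (window_start > window_end) stop("window_start is after window_end")
  dt <- as.Date(daily$date)
  in_win <- dt >= window_start & dt <= window_end
  ids <- cell_from_lonlat(grid, daily$lon[in_win], daily$lat[in_win])
  n_off_grid <- sum(is.na(ids))
  cells <- sort(unique(ids[!is.na(ids)]))
  if (length(cells) == 0)
    stop(sprintf(paste0("no presence cells: %d positions, %d outside the ",
                        "window, %d outside the grid"),
                 nrow(daily), sum(!in_win), n_off_grid))
  structure(list(cells = cells, colony = colony,
                 window = c(window_start, window_end),
                 n_positions = nrow(daily),
                 n_outside_window = sum(!in_win),
                 n_outside_grid = n_off_grid),
            class = "presence_set")
}

#' @export
print.presence_set <- function(x, ...) {
  cat(sprintf("presence_set: %d cells (%s), window %s..%s; excluded %d outside window, %d outside grid\n",
              length(x$cells), x$colony, x$window[1], x$window[2],
              x$n_outside_window, x$n_outside_grid))
  invisible(x)
}

#' Mask the surroundings of presence cells
#'
#' Returns the union of the 3x3 cell neighbourhoods (truncated at grid
#' edges) around every presence cell: the region treated as potentially
#' suitable and therefore off-limits to pseudo-absence sampling.
#'
#' @param presences A `presence_set` or integer vector of cell ids.
#' @param grid A `grid_spec`.
#' @return Sorted integer vector of masked cell ids (empty for an empty
#'   presence set).
#' @export
presence_mask <- function(presences, grid) {
  cells <- if (inherits(presences, "presence_set")) presences$cells else
    as.integer(presences)
  if (length(cells) == 0) return(integer(0))
  rc <- cell_to_rowcol(grid, cells)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  ids <- unlist(lapply(seq_len(nrow(off)), function(k) {
    r <- rc$row + off$dr[k]; c <- rc$col + off$dc[k]
    ok <- r >= 1 & r <= grid$n_rows & c >= 1 & c <= grid$n_cols
    (r[ok] - 1L) * grid$n_cols + c[ok]
  }))
  sort(unique(as.integer(ids)))
}

#' Draw replicate pseudo-absence sets
#'
#' Samples `n_sets` pseudo-absence sets, each the same size as the presence
#' set, uniformly without replacement from the candidate background: cells
#' with complete environmental data that are neither presences nor inside
#' the 3x3 presence mask. Sets are drawn independently of each other and
#' the whole design is deterministic under `seed`.
#'
#' @param presences A `presence_set`.
#' @param complete_cells Integer ids of cells with complete environmental
#'   data (see [env_complete_cells()]).
#' @param grid A `grid_spec`.
#' @param n_sets Number of sets (default 100).
#' @param seed Integer seed.
#' @return Object of class `pa_design`: `candidate_cells`, `sets` (list of
#'   sorted id vectors), `n_presences`, `seed`.
#' @export
sample_pseudo_absences <- function(presences, complete_cells, grid,
                                   n_sets = 100, seed) {
  stopifnot(inherits(presences, "presence_set"), n_sets >= 1)
  masked <- presence_mask(presences, grid)
  candidates <- setdiff(complete_cells, masked)
  n_pres <- length(presences$cells)
  if (length(candidates) < n_pres)
    stop(sprintf("only %d candidate cells for %d presences (deficit %d)",
                 length(candidates), n_pres, n_pres - length(candidates)))
  set.seed(seed)
  sets <- lapply(seq_len(n_sets),
                 function(i) sort(sample(candidates, n_pres)))
  structure(list(candidate_cells = sort(candidates), sets = sets,
                 n_presences = n_pres, seed = seed),
            class = "pa_design")
}

#' @export
print.pa_design <- function(x, ...) {
  cat(sprintf("pa_design: %d sets of %d cells from %d candidates (seed %s)\n",
              length(x$sets), x$n_presences, length(x$candidate_cells),
              format(x$seed)))
  invisible(x)
}

#' Write presence or pseudo-absence cells to CSV
#'
#' @param cells Integer cell ids, or a `pa_design` (every set is written,
#'   tagged by `set_index`).
#' @param grid A `grid_spec`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_cells_csv <- function(cells, grid, file) {
  if (inherits(cells, "pa_design")) {
    rows <- do.call(rbind, lapply(seq_along(cells$sets), function(i) {
      data.frame(cell_id = cells$sets[[i]], set_index = i)
    }))
  } else {
    rows <- data.frame(cell_id = as.integer(cells), set_index = NA_integer_)
  }
  rc <- cell_to_rowcol(grid, rows$cell_id)
  ctr <- cell_center(grid, rows$cell_id)
  out <- data.frame(cell_id = rows$cell_id, row = rc$row, col = rc$col,
                    lon_center = ctr$lon, lat_center = ctr$lat,
                    set_index = rows$set_index)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
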