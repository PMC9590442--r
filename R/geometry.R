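#' Describe the physical layout of flow-cell tiles
#'
#' A tile layout places each Illumina tile on a global canvas so that
#' per-tile pixel coordinates from read identifiers can be converted to
#' global positions in length units (micrometres by default). The origin is
#' the top-left corner, with y increasing downward. Tiles are arranged on a
#' rectangular grid, row-major by default.
#'
#' @param tile_ids Integer (or integer-like) tile identifiers, e.g. `1101`.
#' @param n_col Number of grid columns used for the default row-major
#'   assignment. Ignored when `grid` is supplied.
#' @param tile_width,tile_height Tile extent in length units. Must be > 0.
#' @param gap Spacing between adjacent tiles in length units (>= 0).
#' @param units_per_pixel Length units per instrument pixel; converts the
#'   local pixel coordinates of the read identifier into length units.
#' @param grid Optional data frame with columns `tile`, `row`, `col`
#'   (0-based row/col) giving an explicit assignment. Must be injective.
#'
#' @return A `tile_layout` object: a list with the geometry parameters and a
#'   tibble `grid` mapping tile to (row, col).
#' @examples
#' tile_layout(c(1101, 1102), n_col = 2, tile_width = 100, tile_height = 100)
#' @export
tile_layout <- function(tile_ids, n_col = NULL, tile_width, tile_height,
                        gap = 0, units_per_pixel = 1, grid = NULL) {
  check_scalar_number(tile_width, "tile_width", positive = TRUE)
  check_scalar_number(tile_height, "tile_height", positive = TRUE)
  check_scalar_number(gap, "gap")
  if (gap < 0) abort("`gap` must be >= 0.")
  check_scalar_number(units_per_pixel, "units_per_pixel", positive = TRUE)

  if (is.null(grid)) {
    tile_ids <- as.integer(tile_ids)
    if (anyNA(tile_ids) || anyDuplicated(tile_ids)) {
      abort("`tile_ids` must be unique integers.")
    }
    n_col <- n_col %||% length(tile_ids)
    check_scalar_number(n_col, "n_col", positive = TRUE, integerish = TRUE)
    idx <- seq_along(tile_ids) - 1L
    grid <- tibble(
      tile = tile_ids,
      row = idx %/% as.integer(n_col),
      col = idx %% as.integer(n_col)
    )
  } else {
    grid <- as_tibble(grid)
    need <- c("tile", "row", "col")
    if (!all(need %in% names(grid))) {
      abort("`grid` must have columns tile, row, col.")
    }
    grid$tile <- as.integer(grid$tile)
    if (anyDuplicated(grid$tile)) abort("`grid` assigns some tile twice.")
    if (anyDuplicated(grid[c("row", "col")])) {
      abort("`grid` assignment must be injective: two tiles share a cell.")
    }
  }

  structure(
    list(
      grid = grid, tile_width = tile_width, tile_height = tile_height,
      gap = gap, units_per_pixel = units_per_pixel
    ),
    class = "tile_layout"
  )
}

#' @export
print.tile_layout <- function(x, ...) {
  cat(sprintf(
    "<tile_layout> %d tiles, tile %g x %g, gap %g, %g units/pixel\n",
    nrow(x$grid), x$tile_width, x$tile_height, x$gap, x$units_per_pixel
  ))
  invisible(x)
}

#' Parse spatial coordinates out of Illumina read identifiers
#'
#' First-round Seq-Scope reads carry their flow-cell position in the standard
#' colon-delimited Illumina identifier
#' `instrument:run:flowcell:lane:tile:x:y` (trailing fields after `y` are
#' tolerated; anything after the first whitespace is ignored).
#'
#' @param read_id Character vector of read identifiers (without the leading
#'   `@`).
#' @return A tibble with columns `read_id`, `lane`, `tile`, `x_local`,
#'   `y_local` (integers, instrument pixel units).
#' @examples
#' parse_read_id("M0001:42:FC1:1:1101:5000:7000")
#' @export
parse_read_id <- function(read_id) {
  if (!is.character(read_id) || length(read_id) == 0L) {
    abort("`read_id` must be a non-empty character vector.")
  }
  id <- sub("\\s.*$", "", read_id)
  parts <- strsplit(id, ":", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields < 7L)
  if (length(bad)) {
    abort(sprintf(
      "Malformed read identifier (expected >= 7 ':' fields): '%s'",
      read_id[bad[1L]]
    ))
  }
  take <- function(k) suppressWarnings(as.integer(vapply(parts, `[[`, "", k)))
  out <- tibble(
    read_id = id,
    lane = take(4L), tile = take(5L), x_local = take(6L), y_local = take(7L)
  )
  bad <- which(is.na(out$lane) | is.na(out$tile) |
                 is.na(out$x_local) | is.na(out$y_local))
  if (length(bad)) {
    abort(sprintf(
      "Non-integer coordinate field in read identifier: '%s'",
      read_id[bad[1L]]
    ))
  }
  out
}

#' Convert per-tile pixel coordinates to global coordinates
#'
#' Places each read on the global canvas defined by a [tile_layout()]:
#' `x = col * (tile_width + gap) + x_local * units_per_pixel` and analogously
#' for `y` with rows. Takes and returns a data frame so parsed identifier
#' tables pipe straight through.
#'
#' @param coords Data frame with columns `tile`, `x_local`, `y_local`
#'   (e.g. from [parse_read_id()]).
#' @param layout A [tile_layout()].
#' @return The input tibble with global `x`, `y` columns (length units)
#'   appended.
#' @export
globalize <- function(coords, layout) {
  stopifnot(inherits(layout, "tile_layout"))
  coords <- as_tibble(coords)
  need <- c("tile", "x_local", "y_local")
  if (!all(need %in% names(coords))) {
    abort("`coords` must have columns tile, x_local, y_local.")
  }
  m <- match(coords$tile, layout$grid$tile)
  if (anyNA(m)) {
    unknown <- sort(unique(coords$tile[is.na(m)]))
    abort(sprintf(
      "Unknown tile(s) %s; layout knows tiles %s.",
      paste(unknown, collapse = ", "),
      paste(layout$grid$tile, collapse = ", ")
    ))
  }
  coords$x <- layout$grid$col[m] * (layout$tile_width + layout$gap) +
    coords$x_local * layout$units_per_pixel
  coords$y <- layout$grid$row[m] * (layout$tile_height + layout$gap) +
    coords$y_local * layout$units_per_pixel
  coords
}
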