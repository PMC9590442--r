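#' Construct a spatial digital expression matrix
#'
#' The central container: one or more sparse barcode-by-gene UMI count
#' layers (e.g. exonic-only `Gene`, `spliced`/`unspliced` from a
#' Velocyto-style quantification) sharing identical barcode and gene
#' orderings, plus one spatial coordinate per barcode in length units.
#'
#' @param counts A barcodes x genes sparse (or dense) non-negative integer
#'   matrix for the default layer, with barcode rownames.
#' @param coords Data frame with columns `barcode`, `x`, `y` covering every
#'   barcode in `counts`.
#' @param genes Optional tibble with columns `id`, `name`; defaults to using
#'   the column names of `counts` for both.
#' @param layers Optional named list of additional layers with identical
#'   dimnames (e.g. `spliced`, `unspliced`).
#' @param default_layer Name under which `counts` is stored (default
#'   `"Gene"`).
#' @return A `spatial_matrix` object.
#' @export
spatial_matrix <- function(counts, coords, genes = NULL, layers = NULL,
                           default_layer = "Gene") {
  counts <- as_count_layer(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have barcode rownames and gene colnames.")
  }
  if (is.null(genes)) {
    genes <- tibble(id = colnames(counts), name = colnames(counts))
  }
  genes <- as_tibble(genes)
  if (!all(c("id", "name") %in% names(genes))) {
    abort("`genes` must have columns id, name.")
  }
  if (nrow(genes) != ncol(counts)) abort("`genes` rows must match gene count.")

  coords <- as_tibble(coords)
  if (!all(c("barcode", "x", "y") %in% names(coords))) {
    abort("`coords` must have columns barcode, x, y.")
  }
  m <- match(rownames(counts), coords$barcode)
  if (anyNA(m)) abort("Every barcode in `counts` needs a coordinate.")
  coords <- coords[m, c("barcode", "x", "y")]

  all_layers <- c(setNames(list(counts), default_layer), layers %||% list())
  for (nm in names(all_layers)) {
    all_layers[[nm]] <- as_count_layer(all_layers[[nm]])
    if (!identical(dim(all_layers[[nm]]), dim(counts))) {
      abort(sprintf("Layer '%s' has a different shape.", nm))
    }
    dimnames(all_layers[[nm]]) <- dimnames(counts)
  }

  structure(
    list(
      barcodes = rownames(counts), genes = genes, coords = coords,
      layers = all_layers, default_layer = default_layer
    ),
    class = "spatial_matrix"
  )
}

as_count_layer <- function(m) {
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0)) abort("Counts must be non-negative.")
  m
}

#' @export
dim.spatial_matrix <- function(x) c(length(x$barcodes), nrow(x$genes))

#' @export
print.spatial_matrix <- function(x, ...) {
  cat(sprintf(
    "<spatial_matrix> %d barcodes x %d genes; layers: %s (default %s)\n",
    length(x$barcodes), nrow(x$genes),
    paste(names(x$layers), collapse = ", "), x$default_layer
  ))
  cat(sprintf("  total UMIs (%s): %.0f\n", x$default_layer,
              sum(x$layers[[x$default_layer]])))
  invisible(x)
}

#' Extract one count layer of a spatial matrix
#'
#' @param x A `spatial_matrix`.
#' @param name Layer name; default the object's default layer.
#' @return A barcodes x genes `dgCMatrix`.
#' @export
layer <- function(x, name = NULL) {
  stopifnot(inherits(x, "spatial_matrix"))
  name <- name %||% x$default_layer
  if (!name %in% names(x$layers)) {
    abort(sprintf("Unknown layer '%s'; available: %s.", name,
                  paste(names(x$layers), collapse = ", ")))
  }
  x$layers[[name]]
}

#' Subset a spatial matrix by barcodes, mask, or rectangular region
#'
#' All layers and the coordinate table are subset consistently. Region
#' rectangles are half-open `[xmin, xmax) x [ymin, ymax)` so adjacent tiles
#' of a partition never double-count a barcode.
#'
#' @param x A `spatial_matrix`.
#' @param barcodes Character vector of barcodes to keep.
#' @param mask Logical vector, one entry per barcode of `x`.
#' @param region Numeric `c(xmin, xmax, ymin, ymax)`.
#' @return A `spatial_matrix` restricted to the selection; selecting nothing
#'   is an error.
#' @export
subset_spatial <- function(x, barcodes = NULL, mask = NULL, region = NULL) {
  stopifnot(inherits(x, "spatial_matrix"))
  n_sel <- sum(!is.null(barcodes), !is.null(mask), !is.null(region))
  if (n_sel != 1L) abort("Supply exactly one of `barcodes`, `mask`, `region`.")
  if (!is.null(mask)) {
    if (!is.logical(mask) || length(mask) != length(x$barcodes)) {
      abort("`mask` must be logical with one entry per barcode.")
    }
    keep <- mask
  } else if (!is.null(barcodes)) {
    keep <- x$barcodes %in% barcodes
  } else {
    if (!is.numeric(region) || length(region) != 4L) {
      abort("`region` must be c(xmin, xmax, ymin, ymax).")
    }
    keep <- x$coords$x >= region[1] & x$coords$x < region[2] &
      x$coords$y >= region[3] & x$coords$y < region[4]
  }
  if (!any(keep)) abort("Selection matches no barcodes (empty subset).")
  layers <- lapply(x$layers, function(m) m[keep, , drop = FALSE])
  structure(
    list(
      barcodes = x$barcodes[keep], genes = x$genes,
      coords = x$coords[keep, , drop = FALSE],
      layers = layers, default_layer = x$default_layer
    ),
    class = "spatial_matrix"
  )
}

#' Tidy a spatial matrix into long format
#'
#' @param x A `spatial_matrix`.
#' @param layer Layer to tidy (default the default layer).
#' @param ... Unused.
#' @return A tibble with one row per nonzero count: `barcode`, `x`, `y`,
#'   `gene`, `count`.
#' @export
tidy.spatial_matrix <- function(x, layer = NULL, ...) {
  m <- as(subspot::layer(x, layer), "TsparseMatrix")
  cx <- x$coords$x
  cy <- x$coords$y
  gene_names <- x$genes$name
  tibble(
    barcode = x$barcodes[m@i + 1L],
    x = cx[m@i + 1L],
    y = cy[m@i + 1L],
    gene = gene_names[m@j + 1L],
    count = m@x
  )
}

#' @rdname tidy.spatial_matrix
#' @export
glance.spatial_matrix <- function(x, ...) {
  m <- x$layers[[x$default_layer]]
  rs <- Matrix::rowSums(m)
  tibble(
    n_barcodes = length(x$barcodes), n_genes = nrow(x$genes),
    n_layers = length(x$layers), total_umi = sum(rs),
    median_umi_per_barcode = stats::median(rs),
    extent_x = diff(range(x$coords$x)), extent_y = diff(range(x$coords$y))
  )
}
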