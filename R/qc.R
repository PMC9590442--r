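#' Rasterize UMI or barcode density over spatial coordinates
#'
#' Bins every barcode into a square raster cell via
#' `floor((coord - origin) / cell_size)` and accumulates either its UMI
#' total or a count of 1. The raster conserves totals: its sum equals the
#' total UMIs (or barcodes) of the input.
#'
#' @param x A [spatial_matrix()].
#' @param cell_size Raster cell edge in length units (> 0).
#' @param statistic `"umi"` (default) or `"barcode"`.
#' @param origin Raster origin `c(x0, y0)`; defaults to the data minimum
#'   corner.
#' @param layer Count layer used for UMI totals.
#' @return A `density_raster`: list with `origin`, `cell_size`, and a
#'   numeric matrix `values` (rows index y, columns index x).
#' @export
density_raster <- function(x, cell_size, statistic = c("umi", "barcode"),
                           origin = NULL, layer = NULL) {
  stopifnot(inherits(x, "spatial_matrix"))
  statistic <- match.arg(statistic)
  check_scalar_number(cell_size, "cell_size", positive = TRUE)
  origin <- origin %||% c(min(x$coords$x), min(x$coords$y))

  ix <- floor((x$coords$x - origin[1]) / cell_size)
  iy <- floor((x$coords$y - origin[2]) / cell_size)
  if (any(ix < 0 | iy < 0)) abort("Coordinates fall before the raster origin.")
  w <- if (statistic == "umi") Matrix::rowSums(layer(x, layer)) else
    rep(1, length(ix))
  nx <- max(ix) + 1L
  ny <- max(iy) + 1L
  values <- matrix(0, nrow = ny, ncol = nx)
  cell <- iy + 1L + ny * ix  # linear index into the ny x nx matrix
  agg <- rowsum(w, group = cell)
  values[as.integer(rownames(agg))] <- agg[, 1]
  structure(list(origin = origin, cell_size = cell_size, values = values,
                 statistic = statistic),
            class = "density_raster")
}

#' @export
print.density_raster <- function(x, ...) {
  cat(sprintf("<density_raster> %d x %d cells of %g units, total %g (%s)\n",
              ncol(x$values), nrow(x$values), x$cell_size, sum(x$values),
              x$statistic))
  invisible(x)
}

#' @rdname density_raster
#' @param ... Unused.
#' @return `tidy()` returns one row per raster cell with cell-center
#'   coordinates and the accumulated value.
#' @export
tidy.density_raster <- function(x, ...) {
  ny <- nrow(x$values)
  nx <- ncol(x$values)
  origin <- x$origin
  cs <- x$cell_size
  vals <- as.vector(x$values)
  tibble(
    x = origin[1] + (rep(seq_len(nx), each = ny) - 0.5) * cs,
    y = origin[2] + (rep(seq_len(ny), times = nx) - 0.5) * cs,
    value = vals
  )
}

#' @rdname density_raster
#' @param object A `density_raster`.
#' @export
autoplot.density_raster <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$x, .data$y,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = object$statistic) +
    ggplot2::labs(x = "x (length units)", y = "y (length units)")
}

#' Detect the tissue footprint on a density raster
#'
#' Thresholds the density raster (by a quantile of the nonzero cells, or by
#' Otsu's method), keeps the largest 4-connected component above threshold,
#' and returns its mask and bounding rectangle. This is a declared,
#' deterministic boundary rule for the coordinate-QC step.
#'
#' @param raster A [density_raster()].
#' @param method `"quantile"` (default: a cell passes if its density is at
#'   least the `q` quantile of nonzero cells) or `"otsu"`.
#' @param q Quantile for the quantile method (default 0.5).
#' @param threshold Explicit density threshold overriding `method`; cells
#'   pass when density >= threshold.
#' @return A `tissue_mask`: list with logical matrix `mask`, the bounding
#'   rectangle `bbox = c(xmin, xmax, ymin, ymax)` in length units
#'   (half-open, aligned to cell edges), the `threshold` used, and the
#'   source raster geometry.
#' @export
detect_tissue <- function(raster, method = c("quantile", "otsu"), q = 0.5,
                          threshold = NULL) {
  stopifnot(inherits(raster, "density_raster"))
  method <- match.arg(method)
  v <- raster$values
  if (all(v == 0)) abort("All-zero density raster: no tissue to detect.")
  if (is.null(threshold)) {
    threshold <- if (method == "quantile") {
      if (q < 0 || q > 1) abort("`q` must be in [0, 1].")
      stats::quantile(v[v > 0], q, names = FALSE)
    } else {
      rng <- range(v)
      EBImage::otsu(EBImage::Image((v - rng[1]) / diff(rng)), levels = 256) *
        diff(rng) + rng[1]
    }
  }
  above <- v >= threshold & v > 0
  if (!any(above)) {
    abort(sprintf("Threshold %g exceeds every cell density: no tissue.",
                  threshold))
  }
  lab <- EBImage::bwlabel(above * 1)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  idx <- which(mask, arr.ind = TRUE)
  bbox <- c(
    xmin = raster$origin[1] + (min(idx[, 2]) - 1) * raster$cell_size,
    xmax = raster$origin[1] + max(idx[, 2]) * raster$cell_size,
    ymin = raster$origin[2] + (min(idx[, 1]) - 1) * raster$cell_size,
    ymax = raster$origin[2] + max(idx[, 1]) * raster$cell_size
  )
  structure(list(mask = mask, bbox = bbox, threshold = threshold,
                 origin = raster$origin, cell_size = raster$cell_size),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf(
    "<tissue_mask> %d/%d cells in tissue; bbox [%g, %g) x [%g, %g)\n",
    sum(x$mask), length(x$mask), x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]
  ))
  invisible(x)
}

#' Per-barcode quality-control metrics
#'
#' Computes, for every spatial barcode, the UMI total, the number of genes
#' detected, and the fraction of UMIs from mitochondrial genes (identified
#' by case-insensitive gene-name prefixes, default `mt-`). These are the
#' inputs for standard violin-plot QC.
#'
#' @param x A [spatial_matrix()].
#' @param mito_patterns Character vector of gene-name prefixes counted as
#'   mitochondrial (matched case-insensitively).
#' @param layer Count layer to summarize.
#' @return A tibble with columns `barcode`, `x`, `y`, `umi_count`,
#'   `gene_count`, `mito_fraction`.
#' @export
per_barcode_qc <- function(x, mito_patterns = c("mt-"), layer = NULL) {
  stopifnot(inherits(x, "spatial_matrix"))
  m <- subspot::layer(x, layer)
  umi <- Matrix::rowSums(m)
  genes_detected <- Matrix::rowSums(m > 0)
  is_mito <- rep(FALSE, nrow(x$genes))
  for (p in mito_patterns) {
    is_mito <- is_mito | startsWith(tolower(x$genes$name), tolower(p))
  }
  mito_umi <- if (any(is_mito)) {
    Matrix::rowSums(m[, is_mito, drop = FALSE])
  } else rep(0, length(umi))
  cx <- x$coords$x
  cy <- x$coords$y
  tibble(
    barcode = x$barcodes, x = cx, y = cy,
    umi_count = unname(umi), gene_count = unname(genes_detected),
    mito_fraction = unname(mito_umi / pmax(umi, 1))
  )
}

#' Violin-style summary plot of per-barcode QC metrics
#'
#' @param qc A tibble from [per_barcode_qc()].
#' @return A ggplot with one violin per metric (UMIs, genes, mitochondrial
#'   fraction), each on its own scale.
#' @export
plot_qc_violin <- function(qc) {
  long <- tidyr::pivot_longer(
    qc[c("barcode", "umi_count", "gene_count", "mito_fraction")],
    -"barcode", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes("", .data$value)) +
    ggplot2::geom_violin(fill = "grey80") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
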