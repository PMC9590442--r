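#' Specify a marker-geneset RGB rendering
#'
#' Each color channel quantifies an arbitrary marker gene set, optionally
#' drawn from its own count layer (e.g. red from spliced and green from
#' unspliced reads of the same genes, for subcellular contrast). Channels
#' may be empty and render as zero, but at least one must name a gene.
#'
#' @param red,green,blue Character vectors of gene names per channel (may
#'   be empty).
#' @param layers Named list/character mapping `red`, `green`, `blue` to
#'   layer names; missing entries use the matrix's default layer.
#' @param pixel_size Pixel edge in length units (default 1, i.e. a
#'   1 square-micrometre pixel at micrometre coordinates).
#' @param q Quantile of the nonzero raw intensities used as the per-channel
#'   clipping value (default 0.99, robust to single hot pixels).
#' @return A `geneset_rgb` specification.
#' @export
geneset_rgb <- function(red = character(), green = character(),
                        blue = character(), layers = list(),
                        pixel_size = 1, q = 0.99) {
  check_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  check_scalar_number(q, "q")
  if (q <= 0 || q > 1) abort("`q` must be in (0, 1].")
  if (length(red) + length(green) + length(blue) == 0L) {
    abort("All three channels are empty; name at least one gene.")
  }
  structure(
    list(red = red, green = green, blue = blue, layers = as.list(layers),
         pixel_size = pixel_size, q = q),
    class = "geneset_rgb"
  )
}

#' Render an ultra-high-resolution RGB geneset image
#'
#' Rasterizes raw barcode-level counts — no binning, no smoothing — so the
#' image retains the full spatial resolution of the platform. Per pixel and
#' channel, the raw intensity is the sum of the channel's gene UMIs (from
#' the channel's layer) over barcodes falling in that pixel (half-open
#' floor rule, as in binning); each channel is then scaled by the
#' `q`-quantile of its nonzero raw intensities and clipped to `[0, 1]`.
#' Gene names not present in the matrix warn and are skipped.
#'
#' @param x A [spatial_matrix()].
#' @param spec A [geneset_rgb()].
#' @param region Rectangle `c(xmin, xmax, ymin, ymax)` (half-open);
#'   defaults to the full data extent.
#' @return An `rgb_render`: list with `image` (H x W x 3 array in `[0,1]`),
#'   `raw` (unscaled intensities), `origin`, `pixel_size`, and
#'   `channel_max_used`.
#' @export
render_rgb <- function(x, spec, region = NULL) {
  stopifnot(inherits(x, "spatial_matrix"), inherits(spec, "geneset_rgb"))
  if (is.null(region)) {
    region <- c(min(x$coords$x), max(x$coords$x) + spec$pixel_size,
                min(x$coords$y), max(x$coords$y) + spec$pixel_size)
  }
  if (region[2] <= region[1] || region[4] <= region[3]) {
    abort("`region` must satisfy xmin < xmax and ymin < ymax.")
  }
  inside <- x$coords$x >= region[1] & x$coords$x < region[2] &
    x$coords$y >= region[3] & x$coords$y < region[4]
  if (!any(inside)) abort("Region contains no barcodes.")

  W <- as.integer(ceiling((region[2] - region[1]) / spec$pixel_size))
  H <- as.integer(ceiling((region[4] - region[3]) / spec$pixel_size))
  px <- floor((x$coords$x[inside] - region[1]) / spec$pixel_size)
  py <- floor((x$coords$y[inside] - region[3]) / spec$pixel_size)
  pix <- py + 1L + H * px  # linear index, rows = y

  raw <- array(0, dim = c(H, W, 3L))
  channel_max <- c(red = 1, green = 1, blue = 1)
  for (ch_i in seq_along(c("red", "green", "blue"))) {
    ch <- c("red", "green", "blue")[ch_i]
    genes <- spec[[ch]]
    if (length(genes) == 0L) next
    known <- genes %in% x$genes$name
    if (any(!known)) {
      warn(sprintf("Skipping unknown %s-channel gene(s): %s", ch,
                   paste(genes[!known], collapse = ", ")))
      genes <- genes[known]
    }
    if (length(genes) == 0L) next
    lay <- layer(x, spec$layers[[ch]] %||% x$default_layer)
    cols <- which(x$genes$name %in% genes)
    v <- Matrix::rowSums(lay[, cols, drop = FALSE])[inside]
    nz <- v != 0
    if (any(nz)) {
      agg <- rowsum(v[nz], group = pix[nz])
      plane <- matrix(0, H, W)
      plane[as.integer(rownames(agg))] <- agg[, 1]
      raw[, , ch_i] <- plane
    }
  }
  image <- raw
  for (ch_i in 1:3) {
    plane <- raw[, , ch_i]
    nz <- plane[plane > 0]
    clip_value <- if (length(nz)) {
      stats::quantile(nz, spec$q, names = FALSE)
    } else 1
    channel_max[ch_i] <- clip_value
    image[, , ch_i] <- pmin(plane / clip_value, 1)
  }
  structure(
    list(image = image, raw = raw,
         origin = c(region[1], region[3]), pixel_size = spec$pixel_size,
         channel_max_used = channel_max),
    class = "rgb_render"
  )
}

#' @export
print.rgb_render <- function(x, ...) {
  cat(sprintf("<rgb_render> %d x %d pixels of %g units, channel max %s\n",
              dim(x$image)[2], dim(x$image)[1], x$pixel_size,
              paste(signif(x$channel_max_used, 3), collapse = "/")))
  invisible(x)
}

#' @rdname render_rgb
#' @param ... Unused.
#' @return `tidy()` on an `rgb_render` gives one row per pixel with
#'   pixel-center coordinates, scaled channel intensities, and the hex
#'   color.
#' @export
tidy.rgb_render <- function(x, ...) {
  H <- dim(x$image)[1]
  W <- dim(x$image)[2]
  origin <- x$origin
  ps <- x$pixel_size
  tibble(
    x = origin[1] + (rep(seq_len(W), each = H) - 0.5) * ps,
    y = origin[2] + (rep(seq_len(H), times = W) - 0.5) * ps,
    red = as.vector(x$image[, , 1]),
    green = as.vector(x$image[, , 2]),
    blue = as.vector(x$image[, , 3]),
    hex = grDevices::rgb(as.vector(x$image[, , 1]),
                         as.vector(x$image[, , 2]),
                         as.vector(x$image[, , 3]))
  )
}

#' @rdname render_rgb
#' @param object An `rgb_render`.
#' @export
autoplot.rgb_render <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$hex)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (length units)", y = "y (length units)")
}

#' Write a rendered image to PNG
#'
#' @param render An `rgb_render` or `cluster_map`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_render_png <- function(render, path) {
  img <- if (inherits(render, "rgb_render")) render$image else
    cluster_map_to_array(render)
  # EBImage expects x,y(,channel); our arrays are row = y
  EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Rasterize cluster labels into a spatial map
#'
#' Paints each bin as a square of side `step` centered on the bin center,
#' so sliding-window tracks render at step resolution — the source of the
#' finer label boundaries of the sliding-window track. Where squares of
#' overlapping windows would both cover a pixel, the nearest bin center
#' wins. Pixels covered by no bin stay background (`NA`).
#'
#' @param binned A `binned_matrix`.
#' @param labels Tibble with `bin_id` and `cluster` covering every bin
#'   (e.g. from [transfer_labels()] or `tidy()` of a model).
#' @param pixel_size Pixel edge in length units; defaults to the spec step.
#' @param palette Optional vector of colors, one per cluster.
#' @return A `cluster_map`: list with integer matrix `labels` (NA =
#'   background), `origin`, `pixel_size`, `palette`.
#' @export
render_cluster_map <- function(binned, labels, pixel_size = NULL,
                               palette = NULL) {
  stopifnot(inherits(binned, "binned_matrix"))
  m <- match(binned$bins$bin_id, labels$bin_id)
  if (anyNA(m)) {
    abort(sprintf("No label for bin '%s'.",
                  binned$bins$bin_id[which(is.na(m))[1L]]))
  }
  cl <- labels$cluster[m]
  pixel_size <- pixel_size %||% binned$spec$step
  check_scalar_number(pixel_size, "pixel_size", positive = TRUE)

  half <- binned$spec$step / 2
  cx <- binned$bins$center_x
  cy <- binned$bins$center_y
  x0 <- min(cx) - half
  y0 <- min(cy) - half
  W <- as.integer(ceiling((max(cx) + half - x0) / pixel_size))
  H <- as.integer(ceiling((max(cy) + half - y0) / pixel_size))
  pcx <- x0 + (rep(seq_len(W), each = H) - 0.5) * pixel_size
  pcy <- y0 + (rep(seq_len(H), times = W) - 0.5) * pixel_size
  nn <- FNN::get.knnx(cbind(cx, cy), cbind(pcx, pcy), k = 1L)
  covered <- pmax(abs(pcx - cx[nn$nn.index]),
                  abs(pcy - cy[nn$nn.index])) <= half + 1e-9
  lab <- rep(NA_integer_, H * W)
  lab[covered] <- cl[nn$nn.index[covered]]
  lab <- matrix(lab, nrow = H, ncol = W)

  k <- max(cl)
  palette <- palette %||% grDevices::hcl.colors(max(k, 2L), "Dark 3")[seq_len(k)]
  structure(list(labels = lab, origin = c(x0, y0), pixel_size = pixel_size,
                 palette = palette),
            class = "cluster_map")
}

cluster_map_to_array <- function(map) {
  H <- nrow(map$labels)
  W <- ncol(map$labels)
  col <- rep("#000000", H * W)
  ok <- !is.na(map$labels)
  col[ok] <- map$palette[map$labels[ok]]
  rgbm <- grDevices::col2rgb(col) / 255
  array(c(rgbm[1, ], rgbm[2, ], rgbm[3, ]), dim = c(H, W, 3L))
}

#' @rdname render_cluster_map
#' @param x A `cluster_map`.
#' @param ... Unused.
#' @export
tidy.cluster_map <- function(x, ...) {
  H <- nrow(x$labels)
  W <- ncol(x$labels)
  origin <- x$origin
  ps <- x$pixel_size
  out <- tibble(
    x = origin[1] + (rep(seq_len(W), each = H) - 0.5) * ps,
    y = origin[2] + (rep(seq_len(H), times = W) - 0.5) * ps,
    cluster = as.vector(x$labels)
  )
  out[!is.na(out$cluster), , drop = FALSE]
}

#' @rdname render_cluster_map
#' @param object A `cluster_map`.
#' @export
autoplot.cluster_map <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  fill = factor(.data$cluster))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = object$palette, name = "cluster") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (length units)", y = "y (length units)")
}

#' UMAP scatter of a bin embedding
#'
#' Computes a 2-D UMAP layout of the PCA embedding (delegated to the uwot
#' implementation, single-threaded with a fixed seed so layouts are
#' reproducible) and returns a scatter plot colored by cluster label. The
#' layout coordinates are available as the plot's `data`.
#'
#' @param embedding A bins x n_pcs matrix (e.g.
#'   `model$reference_embedding`).
#' @param labels Optional cluster labels, one per row.
#' @param seed Seed for the layout (default 0).
#' @param n_neighbors UMAP neighborhood size (default 15, capped at
#'   n rows - 1).
#' @return A ggplot; its `data` holds `umap1`, `umap2`, `cluster`.
#' @export
plot_umap <- function(embedding, labels = NULL, seed = 0, n_neighbors = 15) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) < 2L) abort("Need at least two points for a layout.")
  n_neighbors <- min(n_neighbors, nrow(embedding) - 1L)
  layout <- with_seed(seed, uwot::umap(
    embedding, n_neighbors = n_neighbors, n_threads = 1, n_sgd_threads = 0
  ))
  d <- tibble(
    umap1 = layout[, 1], umap2 = layout[, 2],
    cluster = if (is.null(labels)) factor(1) else factor(labels)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$umap1, .data$umap2,
                                       color = .data$cluster)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2")
  if (is.null(labels)) p <- p + ggplot2::guides(color = "none")
  p
}
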