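#' Square-bin geometry for spatial aggregation
#'
#' A bin specification fixes the window edge `side`, the anchor-to-anchor
#' `step`, and the anchor origin. `step == side` gives the non-overlapping
#' simple grid; `step < side` gives overlapping sliding windows whose
#' centers are `(side/step)^2`-fold denser per unit interior area — with the
#' Seq-Scope defaults of a 10 micrometre side and 2 micrometre step, a
#' 25-fold finer map. `side` must be an integer multiple of `step` so every
#' interior barcode falls in exactly `(side/step)^2` windows.
#'
#' @param side Window edge in length units (> 0).
#' @param step Anchor spacing in length units (0 < step <= side; side must
#'   be a multiple of step).
#' @param anchor Origin `c(x0, y0)` from which windows are anchored at
#'   `(x0 + i*step, y0 + j*step)`. `NULL` (default) defers to the binning
#'   call, which anchors at the tissue bounding box or data minimum corner.
#' @return A `bin_spec` object.
#' @examples
#' bin_spec(10, 2)
#' @export
bin_spec <- function(side, step = side, anchor = NULL) {
  check_scalar_number(side, "side", positive = TRUE)
  check_scalar_number(step, "step", positive = TRUE)
  if (step > side) abort("`step` must be <= `side`.")
  r <- side / step
  if (abs(r - round(r)) > 1e-9) {
    abort("`side` must be an integer multiple of `step`.")
  }
  if (!is.null(anchor)) {
    if (!is.numeric(anchor) || length(anchor) != 2L || !all(is.finite(anchor))) {
      abort("`anchor` must be c(x0, y0).")
    }
  }
  structure(list(side = side, step = step, anchor = anchor),
            class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  kind <- if (x$step == x$side) "simple grid" else
    sprintf("sliding window (%dx denser centers)", as.integer((x$side / x$step)^2))
  cat(sprintf("<bin_spec> side %g, step %g (%s)\n", x$side, x$step, kind))
  invisible(x)
}

resolve_anchor <- function(spec, x, anchor = NULL) {
  a <- anchor %||% spec$anchor %||% c(min(x$coords$x), min(x$coords$y))
  as.numeric(a)
}

# shared worker: assign barcodes to (possibly overlapping) windows and
# aggregate counts by sparse indicator multiply
bin_counts <- function(x, spec, min_umi, layer, anchor) {
  stopifnot(inherits(x, "spatial_matrix"), inherits(spec, "bin_spec"))
  check_scalar_number(min_umi, "min_umi")
  if (min_umi < 0) abort("`min_umi` must be >= 0.")
  a <- resolve_anchor(spec, x, anchor)
  layer_name <- layer %||% x$default_layer
  counts <- subspot::layer(x, layer_name)
  n <- nrow(counts)
  r <- as.integer(round(spec$side / spec$step))

  # the r consecutive window indices covering each coordinate: membership in
  # [anchor + k*step, anchor + k*step + side) means k in [kmax-r+1, kmax]
  kx_max <- floor((x$coords$x - a[1]) / spec$step)
  ky_max <- floor((x$coords$y - a[2]) / spec$step)
  ox <- rep(seq_len(r) - 1L, times = r)
  oy <- rep(seq_len(r) - 1L, each = r)
  r2 <- r * r
  bc <- rep(seq_len(n), each = r2)
  kx <- rep(kx_max, each = r2) - rep(ox, n)
  ky <- rep(ky_max, each = r2) - rep(oy, n)

  key <- paste0(kx, "_", ky)
  fac <- factor(key, levels = unique(key))
  bin_idx <- as.integer(fac)
  n_bins <- nlevels(fac)
  S <- sparseMatrix(i = bin_idx, j = bc, x = 1,
                    dims = c(n_bins, n))
  agg <- as(S %*% counts, "CsparseMatrix")

  first <- match(levels(fac), key)
  wx <- a[1] + kx[first] * spec$step
  wy <- a[2] + ky[first] * spec$step
  bins <- tibble(
    bin_id = sprintf("x%g_y%g_s%g", wx, wy, spec$side),
    wx = wx, wy = wy,
    center_x = wx + spec$side / 2, center_y = wy + spec$side / 2,
    n_barcodes = as.integer(Matrix::rowSums(S)),
    total_umi = unname(Matrix::rowSums(agg))
  )
  keep <- bins$total_umi >= min_umi
  if (!any(keep)) {
    abort(sprintf("No bins survive the min_umi >= %g filter.", min_umi))
  }
  agg <- agg[keep, , drop = FALSE]
  bins <- bins[keep, , drop = FALSE]
  ord <- order(bins$wy, bins$wx, method = "radix")
  bins <- bins[ord, , drop = FALSE]
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- bins$bin_id
  colnames(agg) <- x$genes$id

  structure(
    list(bins = bins, counts = agg,
         spec = bin_spec(spec$side, spec$step, anchor = a),
         genes = x$genes, source_layer = layer_name),
    class = "binned_matrix"
  )
}

#' Aggregate barcodes into a non-overlapping square grid
#'
#' Each barcode is assigned to the single bin
#' `(floor((x - x0)/side), floor((y - y0)/side))`; bin counts are the sums
#' of the member barcode counts. With `min_umi = 0` the grid conserves total
#' UMIs exactly. Bins containing no barcode are absent. This coarse track
#' captures enough transcripts per bin for cell-type clustering.
#'
#' @param x A [spatial_matrix()].
#' @param spec A [bin_spec()] with `step == side`, or a single number taken
#'   as the side.
#' @param min_umi Drop bins whose UMI total is below this (default 0).
#' @param layer Count layer to aggregate.
#' @param anchor Optional `c(x0, y0)` anchor overriding the spec (e.g. the
#'   min corner of a [detect_tissue()] bounding box); defaults to the data
#'   minimum corner.
#' @return A `binned_matrix`: bins tibble (`bin_id`, window corner `wx`,
#'   `wy`, centers, `n_barcodes`, `total_umi`), sparse bins x genes
#'   `counts`, the resolved spec, genes table, and source layer.
#' @export
simple_grid_bin <- function(x, spec, min_umi = 0, layer = NULL, anchor = NULL) {
  if (is.numeric(spec)) spec <- bin_spec(spec)
  if (spec$step != spec$side) {
    abort("simple_grid_bin() needs step == side; use sliding_window_bin().")
  }
  bin_counts(x, spec, min_umi, layer, anchor)
}

#' Aggregate barcodes into overlapping sliding windows
#'
#' Windows of edge `side` are anchored at every `(x0 + i*step, y0 + j*step)`
#' that contains at least one barcode, with half-open membership
#' `[w, w + side)` on both axes; every interior barcode therefore belongs to
#' exactly `(side/step)^2` windows. This is the resolution-preserving track:
#' window totals match the coarse grid statistics while centers are
#' `(side/step)^2`-fold denser, so labels can be assigned at step
#' resolution.
#'
#' @inheritParams simple_grid_bin
#' @param spec A [bin_spec()]; `step < side` for a genuine sliding window
#'   (with `step == side` the result equals [simple_grid_bin()]).
#' @return A `binned_matrix` (see [simple_grid_bin()]).
#' @export
sliding_window_bin <- function(x, spec, min_umi = 0, layer = NULL,
                               anchor = NULL) {
  if (is.numeric(spec)) abort("Supply a bin_spec(side, step).")
  bin_counts(x, spec, min_umi, layer, anchor)
}

#' Aggregate at several scales in one call
#'
#' @inheritParams simple_grid_bin
#' @param specs A named (or unnamed) list of [bin_spec()]s; unnamed entries
#'   are labelled `s<side>_<step>`.
#' @return A named list of `binned_matrix`, one per spec, independently
#'   computed.
#' @export
multiscale_bin <- function(x, specs, min_umi = 0, layer = NULL, anchor = NULL) {
  if (inherits(specs, "bin_spec")) specs <- list(specs)
  if (length(specs) == 0L) abort("Need at least one bin_spec.")
  nm <- names(specs) %||% rep("", length(specs))
  auto <- vapply(specs, function(s) sprintf("s%g_%g", s$side, s$step), "")
  nm[nm == ""] <- auto[nm == ""]
  out <- lapply(specs, function(s) bin_counts(x, s, min_umi, layer, anchor))
  names(out) <- nm
  out
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf(
    "<binned_matrix> %d bins x %d genes (side %g, step %g, layer %s)\n",
    nrow(x$bins), ncol(x$counts), x$spec$side, x$spec$step, x$source_layer
  ))
  invisible(x)
}

#' @export
dim.binned_matrix <- function(x) dim(x$counts)

#' Tidy and summarize binned matrices
#'
#' @param x A `binned_matrix`.
#' @param ... Unused.
#' @return `tidy()` returns the bins tibble (one row per bin with centers
#'   and totals); `glance()` a one-row summary.
#' @export
tidy.binned_matrix <- function(x, ...) x$bins

#' @rdname tidy.binned_matrix
#' @export
glance.binned_matrix <- function(x, ...) {
  tibble(
    n_bins = nrow(x$bins), n_genes = ncol(x$counts),
    side = x$spec$side, step = x$spec$step,
    total_umi = sum(x$bins$total_umi),
    median_umi_per_bin = stats::median(x$bins$total_umi),
    source_layer = x$source_layer
  )
}

#' Write a binned matrix as an MTX directory
#'
#' Reuses the 10x-style layout of [write_mtx_dir()], with bin identifiers in
#' place of barcodes and bin centers in the coordinates sidecar, so binned
#' tracks round-trip through [read_mtx_dir()] and load directly in external
#' tools.
#'
#' @param binned A `binned_matrix`.
#' @param path Output directory.
#' @return Invisibly, `path`.
#' @export
write_binned_mtx <- function(binned, path) {
  stopifnot(inherits(binned, "binned_matrix"))
  sm <- spatial_matrix(
    binned$counts,
    tibble(barcode = binned$bins$bin_id,
           x = binned$bins$center_x, y = binned$bins$center_y),
    genes = binned$genes
  )
  write_mtx_dir(sm, path)
  readr::write_tsv(binned$bins, file.path(path, "bins.tsv"), progress = FALSE)
  readr::write_lines(
    yaml::as.yaml(list(side = binned$spec$side, step = binned$spec$step,
                       anchor = binned$spec$anchor,
                       source_layer = binned$source_layer)),
    file.path(path, "bin_spec.yaml")
  )
  invisible(path)
}

#' Read a binned matrix written by [write_binned_mtx()]
#'
#' @param path Directory written by [write_binned_mtx()].
#' @return A `binned_matrix`.
#' @export
read_binned_mtx <- function(path) {
  sm <- read_mtx_dir(path)
  meta <- yaml::read_yaml(file.path(path, "bin_spec.yaml"))
  bins <- readr::read_tsv(file.path(path, "bins.tsv"),
                          col_types = readr::cols(bin_id = "c", .default = "d"),
                          progress = FALSE)
  m <- match(sm$barcodes, bins$bin_id)
  if (anyNA(m)) abort("bins.tsv does not cover every bin in the matrix.")
  counts <- layer(sm)
  structure(
    list(bins = bins[m, , drop = FALSE], counts = counts,
         spec = bin_spec(meta$side, meta$step, anchor = unlist(meta$anchor)),
         genes = sm$genes, source_layer = meta$source_layer),
    class = "binned_matrix"
  )
}
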