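#' Read a 10x-style MTX directory into a spatial matrix
#'
#' Expects the 10x Genomics triple `matrix.mtx(.gz)`, `barcodes.tsv(.gz)`,
#' `features.tsv(.gz)` with genes as MatrixMarket rows and barcodes as
#' columns. Optional Velocyto-style layers are discovered as subdirectories
#' named `spliced`, `unspliced`, `ambiguous`, each holding its own
#' `matrix.mtx` of identical shape. Coordinates come from a sidecar
#' `coordinates.tsv` (`barcode`, `x`, `y`) when present — explicit data beats
#' convention — otherwise they are decoded from barcode names in the
#' `lane_tile_x_y` dialect scaled by `coord_scale`. Barcodes without a
#' coordinate are dropped with a message.
#'
#' @param path Directory containing the triple.
#' @param coords Optional coordinates table (`barcode`, `x`, `y`) overriding
#'   both the sidecar and name decoding.
#' @param coord_scale Length units per barcode-name coordinate unit when
#'   decoding names (default 1).
#' @param default_layer Name for the main layer (default `"Gene"`).
#' @return A [spatial_matrix()].
#' @export
read_mtx_dir <- function(path, coords = NULL, coord_scale = 1,
                         default_layer = "Gene") {
  if (!dir.exists(path)) abort(sprintf("No such directory: %s", path))
  find1 <- function(base) {
    for (f in file.path(path, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    abort(sprintf("Missing %s(.gz) in %s", base, path))
  }
  read_maybe_gz_mm <- function(f) {
    m <- if (grepl("\\.gz$", f)) readMM(gzfile(f)) else readMM(f)
    as(as(m, "generalMatrix"), "CsparseMatrix")
  }
  mtx <- read_maybe_gz_mm(find1("matrix.mtx"))
  barcodes <- readr::read_lines(find1("barcodes.tsv"), progress = FALSE)
  feat <- readr::read_tsv(find1("features.tsv"), col_names = FALSE,
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  genes <- tibble(id = feat[[1]],
                  name = if (ncol(feat) >= 2) feat[[2]] else feat[[1]])
  if (nrow(mtx) != nrow(genes) || ncol(mtx) != length(barcodes)) {
    abort(sprintf(
      "matrix.mtx is %d x %d but features/barcodes list %d genes, %d barcodes.",
      nrow(mtx), ncol(mtx), nrow(genes), length(barcodes)
    ))
  }

  counts <- t(mtx)  # store barcodes x genes in memory
  dimnames(counts) <- list(barcodes, genes$id)

  layers <- list()
  for (nm in c("spliced", "unspliced", "ambiguous")) {
    sub <- file.path(path, nm)
    f <- file.path(sub, c("matrix.mtx", "matrix.mtx.gz"))
    f <- f[file.exists(f)]
    if (length(f)) {
      lm <- t(read_maybe_gz_mm(f[1]))
      if (!identical(dim(lm), dim(counts))) {
        abort(sprintf("Layer '%s' shape differs from the main matrix.", nm))
      }
      dimnames(lm) <- dimnames(counts)
      layers[[nm]] <- lm
    }
  }

  if (is.null(coords)) {
    sidecar <- file.path(path, c("coordinates.tsv", "coordinates.tsv.gz"))
    sidecar <- sidecar[file.exists(sidecar)]
    if (length(sidecar)) {
      coords <- readr::read_tsv(sidecar[1], col_types = readr::cols(
        barcode = readr::col_character(),
        x = readr::col_double(), y = readr::col_double()
      ), progress = FALSE)
    } else {
      coords <- decode_barcode_coords(barcodes, coord_scale)
      if (is.null(coords)) {
        abort(paste0("No coordinate source: no coordinates.tsv sidecar and ",
                     "barcode names do not follow the lane_tile_x_y dialect."))
      }
    }
  }
  coords <- as_tibble(coords)
  keep <- barcodes %in% coords$barcode
  if (!all(keep)) {
    inform(sprintf("Dropping %d barcode(s) lacking coordinates.", sum(!keep)))
    counts <- counts[keep, , drop = FALSE]
    layers <- lapply(layers, function(m) m[keep, , drop = FALSE])
    if (!any(keep)) abort("No barcode has a coordinate.")
  }
  spatial_matrix(counts, coords, genes = genes, layers = layers,
                 default_layer = default_layer)
}

# barcode names like "1_1101_5000_7000" -> lane, tile, x, y; NULL if the
# dialect does not apply to every name
decode_barcode_coords <- function(barcodes, coord_scale = 1) {
  ok <- grepl("^\\d+_\\d+_\\d+_\\d+$", barcodes)
  if (!all(ok)) return(NULL)
  parts <- matrix(as.numeric(unlist(strsplit(barcodes, "_", fixed = TRUE))),
                  ncol = 4L, byrow = TRUE)
  tibble(barcode = barcodes,
         x = parts[, 3] * coord_scale, y = parts[, 4] * coord_scale)
}

#' Write a spatial matrix as a 10x-style MTX directory
#'
#' Emits `matrix.mtx` (MatrixMarket integer coordinate format, genes as
#' rows, barcodes as columns, 1-based indices, entries in deterministic
#' row-major order), `barcodes.tsv`, `features.tsv`, and a `coordinates.tsv`
#' sidecar. Additional layers are written to subdirectories named after the
#' layer, each with its own `matrix.mtx`.
#'
#' @param x A [spatial_matrix()].
#' @param path Output directory (created if needed).
#' @return Invisibly, `path`.
#' @export
write_mtx_dir <- function(x, path) {
  stopifnot(inherits(x, "spatial_matrix"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("Cannot create directory: %s", path))

  write_mm_integer(t(layer(x)), file.path(path, "matrix.mtx"))
  readr::write_lines(x$barcodes, file.path(path, "barcodes.tsv"))
  readr::write_tsv(
    tibble(id = x$genes$id, name = x$genes$name, type = "Gene Expression"),
    file.path(path, "features.tsv"), col_names = FALSE, progress = FALSE
  )
  readr::write_tsv(x$coords, file.path(path, "coordinates.tsv"),
                   progress = FALSE)
  extra <- setdiff(names(x$layers), x$default_layer)
  for (nm in extra) {
    sub <- file.path(path, nm)
    dir.create(sub, showWarnings = FALSE)
    write_mm_integer(t(x$layers[[nm]]), file.path(sub, "matrix.mtx"))
  }
  invisible(path)
}

# MatrixMarket coordinate-integer writer. Matrix::writeMM only emits the
# "real" dialect, so the 10x-compatible integer header is written here;
# entries are sorted row-major (gene-major) for byte-stable output.
write_mm_integer <- function(m, path) {
  m <- as(as(m, "generalMatrix"), "TsparseMatrix")
  ord <- order(m@i, m@j, method = "radix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), length(m@x)), con)
  if (length(m@x)) {
    writeLines(sprintf("%d %d %d", m@i[ord] + 1L, m@j[ord] + 1L,
                       as.integer(round(m@x[ord]))), con)
  }
  invisible(path)
}
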