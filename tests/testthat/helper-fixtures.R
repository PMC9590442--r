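# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# write a FASTQ file from parallel id/sequence vectors
write_test_fastq <- function(ids, seqs, path = tempfile(fileext = ".fastq")) {
  qual <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}

# one-tile layout: 100 x 100 units, 1 unit per pixel
unit_layout <- function() {
  tile_layout(1101L, n_col = 1, tile_width = 100, tile_height = 100,
              gap = 0, units_per_pixel = 1)
}

# tiny spatial matrix: 3 barcodes x 3 genes with spliced/unspliced layers
tiny_spatial_matrix <- function() {
  counts <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 3), j = c(1, 2, 2, 3), x = c(2, 3, 4, 7),
    dims = c(3, 3),
    dimnames = list(c("AAA", "CCC", "GGG"), c("geneA", "mt-b1", "geneC"))
  )
  spliced <- Matrix::sparseMatrix(
    i = c(1, 2, 3), j = c(1, 2, 3), x = c(1, 2, 5), dims = c(3, 3),
    dimnames = dimnames(counts)
  )
  unspliced <- counts - spliced
  coords <- tibble::tibble(barcode = c("AAA", "CCC", "GGG"),
                           x = c(1, 12, 25), y = c(1, 3, 30))
  spatial_matrix(counts, coords,
                 layers = list(spliced = spliced, unspliced = Matrix::drop0(unspliced)))
}

# spatial matrix from explicit barcode positions and a dense count matrix
make_spatial <- function(x, y, counts, genes = NULL) {
  n <- length(x)
  barcodes <- sprintf("BC%03d", seq_len(n))
  counts <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(ncol(counts)))
  dimnames(counts) <- list(barcodes, genes)
  spatial_matrix(counts, tibble::tibble(barcode = barcodes, x = x, y = y))
}

# small striped simulation used by clustering tests (faster than default)
small_striped_sim <- function(seed = 11) {
  layout <- synthetic_layout(n_row = 1, n_col = 1, tile_pixels = 1500)
  model <- default_domain_model(n_genes = 60, n_domains = 3,
                                markers_per_domain = 10, seed = seed)
  truth <- generate_barcodes(3000, layout = layout, seed = seed + 1)
  truth <- assign_stripe_domains(truth, n_domains = 3, extent = c(0, 150))
  mat <- simulate_counts(truth, model, seed = seed + 2)
  list(truth = truth, matrix = mat, layout = layout,
       boundaries = attr(truth, "boundaries_x"))
}

# independent brute-force Hamming-distance corrector (test oracle)
brute_force_correct <- function(observed, whitelist) {
  vapply(observed, function(o) {
    oc <- strsplit(o, "")[[1]]
    d <- vapply(strsplit(whitelist, ""), function(w) sum(w != oc), 0)
    if (any(d == 0)) return(whitelist[which(d == 0)[1]])
    hits <- which(d == 1)
    if (length(hits) == 1L) whitelist[hits] else NA_character_
  }, "", USE.NAMES = FALSE)
}

# independent brute-force sliding-window binner (test oracle): double loop
# over candidate windows x barcodes with half-open membership
brute_force_windows <- function(x, y, counts, side, step, anchor) {
  kx <- seq(floor((min(x) - anchor[1] - side) / step),
            ceiling((max(x) - anchor[1]) / step))
  ky <- seq(floor((min(y) - anchor[2] - side) / step),
            ceiling((max(y) - anchor[2]) / step))
  out <- list()
  for (i in kx) for (j in ky) {
    wx <- anchor[1] + i * step
    wy <- anchor[2] + j * step
    members <- which(x >= wx & x < wx + side & y >= wy & y < wy + side)
    if (length(members)) {
      out[[length(out) + 1L]] <- list(
        wx = wx, wy = wy,
        counts = colSums(counts[members, , drop = FALSE]),
        n = length(members)
      )
    }
  }
  out
}
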