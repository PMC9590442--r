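#' Default synthetic flow-cell layout
#'
#' A 2 x 2 grid of tiles, each 1500 x 1500 instrument pixels at 0.1 length
#' units per pixel, i.e. a 300 x 300 micrometre capture area — a desk-scale
#' stand-in for a Seq-Scope flow cell whose real tiles hold millions of
#' clustered barcodes.
#'
#' @param n_row,n_col Tile grid dimensions.
#' @param tile_pixels Tile edge in instrument pixels.
#' @param units_per_pixel Length units per pixel.
#' @param gap Gap between tiles in length units.
#' @return A [tile_layout()] with tiles numbered `1101, 1102, ..., 1201,
#'   ...` (row-major).
#' @export
synthetic_layout <- function(n_row = 2, n_col = 2, tile_pixels = 1500,
                             units_per_pixel = 0.1, gap = 0) {
  tiles <- as.integer(outer(seq_len(n_col), seq_len(n_row),
                            function(c, r) 1000L + r * 100L + c))
  tile_layout(
    tile_ids = as.vector(tiles), n_col = n_col,
    tile_width = tile_pixels * units_per_pixel,
    tile_height = tile_pixels * units_per_pixel,
    gap = gap, units_per_pixel = units_per_pixel
  )
}

#' Generate ground-truth spatial barcodes
#'
#' Draws `n` unique random barcodes and places each at a uniform random
#' pixel of a random tile of the layout, recording both the local
#' (lane/tile/pixel) and global coordinates. Pixel positions are integers,
#' as on a real instrument, so identifiers round-trip exactly through
#' [write_first_seq_fastq()] and [build_barcode_map()]. Requires
#' `4^K >= 10 n` so rejection sampling of unique barcodes has headroom.
#'
#' @param n Number of barcodes (>= 1).
#' @param barcode_length Barcode length K (default 20, HDMI-like).
#' @param layout A [tile_layout()] (default [synthetic_layout()]).
#' @param tile_pixels Pixel extent of each tile (must match the layout
#'   geometry; default 1500).
#' @param seed RNG seed; the whole ground truth is a deterministic function
#'   of it.
#' @return A `ground truth` tibble: `barcode`, `lane`, `tile`, `x_local`,
#'   `y_local`, `x`, `y`.
#' @export
generate_barcodes <- function(n, barcode_length = 20, layout = synthetic_layout(),
                              tile_pixels = 1500, seed = 1) {
  check_scalar_number(n, "n", positive = TRUE, integerish = TRUE)
  check_scalar_number(barcode_length, "barcode_length", positive = TRUE,
                      integerish = TRUE)
  if (4^barcode_length < 10 * n) {
    abort(sprintf(
      "barcode_length %d gives only %.3g possible barcodes; need >= 10 * n = %g.",
      barcode_length, 4^barcode_length, 10 * n
    ))
  }
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    draw <- function(m) {
      apply(matrix(sample(bases, m * barcode_length, replace = TRUE),
                   nrow = m), 1, paste, collapse = "")
    }
    barcode <- unique(draw(n))
    while (length(barcode) < n) {
      barcode <- unique(c(barcode, draw(n - length(barcode))))
    }
    barcode <- barcode[seq_len(n)]
    tiles <- layout$grid$tile
    tile <- tiles[sample.int(length(tiles), n, replace = TRUE)]
    truth <- tibble(
      barcode = barcode,
      lane = 1L,
      tile = tile,
      x_local = sample.int(tile_pixels, n, replace = TRUE) - 1L,
      y_local = sample.int(tile_pixels, n, replace = TRUE) - 1L
    )
    globalize(truth, layout)
  })
}

#' Domain model for spatially structured expression
#'
#' Defines per-domain mean UMI rates per gene, a shared background rate,
#' and a per-gene spliced fraction — the generative model behind the
#' synthetic counts. The default model emulates zonated tissue: disjoint
#' marker-gene blocks per domain over a shared low background, plus a few
#' mitochondrial (`mt-`) genes expressed everywhere.
#'
#' @param rates A domains x genes matrix of mean UMI rates per barcode
#'   (dimnames required: domain names, gene names).
#' @param spliced_fraction Per-gene probability that a UMI is spliced, in
#'   `[0, 1]` (named by gene, or a single value recycled).
#' @param background_rate Rate added to every gene in every domain
#'   (default 0).
#' @return A `domain_model`.
#' @export
domain_model <- function(rates, spliced_fraction = 0.8, background_rate = 0) {
  rates <- as.matrix(rates)
  if (is.null(rownames(rates)) || is.null(colnames(rates))) {
    abort("`rates` needs domain rownames and gene colnames.")
  }
  if (any(rates < 0)) abort("Rates must be >= 0.")
  check_scalar_number(background_rate, "background_rate")
  if (background_rate < 0) abort("`background_rate` must be >= 0.")
  sf <- if (length(spliced_fraction) == 1L) {
    setNames(rep(spliced_fraction, ncol(rates)), colnames(rates))
  } else spliced_fraction
  if (!all(colnames(rates) %in% names(sf))) {
    abort("`spliced_fraction` must cover every gene.")
  }
  sf <- sf[colnames(rates)]
  if (any(sf < 0 | sf > 1)) abort("`spliced_fraction` must lie in [0, 1].")
  structure(list(rates = rates, spliced_fraction = sf,
                 background_rate = background_rate),
            class = "domain_model")
}

#' Default three-domain marker model
#'
#' @param n_genes Total genes (default 200); the last few are `mt-` genes.
#' @param n_domains Number of domains (default 3).
#' @param markers_per_domain Marker genes per domain (default 20).
#' @param marker_rate Mean UMI rate of a marker gene in its own domain
#'   (default 0.4 per barcode).
#' @param background_rate Baseline rate of every gene everywhere
#'   (default 0.02).
#' @param n_mito Number of `mt-` genes (default 5) at `mito_rate`
#'   (default 0.1) in all domains.
#' @param mito_rate Rate of the `mt-` genes.
#' @param seed Seed for the per-gene spliced fractions (Beta(8, 2), mean
#'   0.8 — most UMIs spliced).
#' @return A [domain_model()] whose gene names are `g001, g002, ...` and
#'   `mt-1, ...`.
#' @export
default_domain_model <- function(n_genes = 200, n_domains = 3,
                                 markers_per_domain = 20, marker_rate = 0.4,
                                 background_rate = 0.02, n_mito = 5,
                                 mito_rate = 0.1, seed = 1) {
  if (n_domains * markers_per_domain + n_mito > n_genes) {
    abort("Too few genes for the requested markers and mt- genes.")
  }
  gene_names <- c(sprintf("g%03d", seq_len(n_genes - n_mito)),
                  sprintf("mt-%d", seq_len(n_mito)))
  rates <- matrix(0, nrow = n_domains, ncol = n_genes,
                  dimnames = list(sprintf("domain%d", seq_len(n_domains)),
                                  gene_names))
  for (d in seq_len(n_domains)) {
    idx <- (d - 1L) * markers_per_domain + seq_len(markers_per_domain)
    rates[d, idx] <- marker_rate
  }
  rates[, n_genes - n_mito + seq_len(n_mito)] <- mito_rate
  sf <- with_seed(seed, setNames(rbeta(n_genes, 8, 2), gene_names))
  domain_model(rates, spliced_fraction = sf, background_rate = background_rate)
}

#' Assign striped domains to barcode positions
#'
#' Splits the x-extent into `n_domains` equal vertical stripes — a
#' desk-scale emulation of zonated tissue layers — and labels each barcode
#' with its stripe.
#'
#' The stripe boundaries default to 97% of the equal-split positions (the
#' last stripe absorbing the remainder) so that zonation boundaries fall in
#' general position relative to aggregation grids. Real tissue boundaries
#' do not coincide with analysis bin edges; exact alignment would hand the
#' coarse grid an artificial zero boundary error and make boundary-sharpness
#' comparisons between tracks meaningless.
#'
#' @param truth Ground-truth tibble from [generate_barcodes()].
#' @param n_domains Number of stripes (default 3).
#' @param extent Optional `c(xmin, xmax)`; defaults to the barcode x-range
#'   (max nudged so the last barcode falls inside).
#' @param boundaries_x Optional increasing vector of `n_domains - 1`
#'   boundary positions overriding the default placement.
#' @return `truth` with a `domain` column (`domain1`, ...), plus attribute
#'   `boundaries_x` giving the true stripe boundary positions.
#' @export
assign_stripe_domains <- function(truth, n_domains = 3, extent = NULL,
                                  boundaries_x = NULL) {
  extent <- extent %||% c(min(truth$x), max(truth$x) + 1e-9)
  boundaries_x <- boundaries_x %||%
    (extent[1] + 0.97 * diff(extent) * seq_len(n_domains - 1L) / n_domains)
  if (length(boundaries_x) != n_domains - 1L || is.unsorted(boundaries_x)) {
    abort("`boundaries_x` must be n_domains - 1 increasing positions.")
  }
  idx <- findInterval(truth$x, boundaries_x)
  truth$domain <- sprintf("domain%d", idx + 1L)
  attr(truth, "boundaries_x") <- boundaries_x
  truth
}

#' Simulate spatially structured sparse counts
#'
#' For every barcode and gene, draws total UMIs from a Poisson whose rate
#' is the barcode's domain rate plus the model background, then splits each
#' gene's UMIs into spliced and unspliced by a binomial with the per-gene
#' spliced fraction. The `Gene` layer is the spliced + unspliced sum, as an
#' exonic+intronic quantification would give. All draws are governed by
#' `seed`.
#'
#' @param truth Ground truth with a `domain` column (see
#'   [assign_stripe_domains()]).
#' @param model A [domain_model()].
#' @param seed RNG seed.
#' @return A [spatial_matrix()] with layers `Gene` (default), `spliced`,
#'   `unspliced`.
#' @export
simulate_counts <- function(truth, model, seed = 1) {
  stopifnot(inherits(model, "domain_model"))
  if (!"domain" %in% names(truth)) {
    abort("`truth` needs a domain column; see assign_stripe_domains().")
  }
  d_idx <- match(truth$domain, rownames(model$rates))
  if (anyNA(d_idx)) abort("Some domains are missing from the model rates.")
  n <- nrow(truth)
  G <- ncol(model$rates)
  with_seed(seed, {
    lam <- model$rates[d_idx, , drop = FALSE] + model$background_rate
    total <- rpois(n * G, as.vector(lam))
    nz <- which(total > 0L)
    gi <- ((nz - 1L) %/% n) + 1L  # gene index (column-major)
    bi <- ((nz - 1L) %% n) + 1L
    spl <- rbinom(length(nz), total[nz], model$spliced_fraction[gi])
    uns <- total[nz] - spl
    dims <- c(n, G)
    dn <- list(truth$barcode, colnames(model$rates))
    gene <- sparseMatrix(i = bi, j = gi, x = as.double(total[nz]),
                         dims = dims, dimnames = dn)
    spliced <- sparseMatrix(i = bi, j = gi, x = as.double(spl),
                            dims = dims, dimnames = dn)
    unspliced <- sparseMatrix(i = bi, j = gi, x = as.double(uns),
                              dims = dims, dimnames = dn)
    spatial_matrix(
      drop0(gene),
      coords = tibble(barcode = truth$barcode, x = truth$x, y = truth$y),
      layers = list(spliced = drop0(spliced), unspliced = drop0(unspliced))
    )
  })
}

#' Write a coordinate-encoded first-round FASTQ
#'
#' Emits one read per barcode whose identifier encodes lane, tile, and
#' local pixel position in the standard Illumina dialect and whose sequence
#' is the barcode. With `error_rate > 0`, each base is substituted
#' independently with that probability — the regime the whitelist-based
#' Hamming-1 correction is built for — and the returned table records the
#' intended barcode and the number of injected errors per read.
#'
#' @param truth Ground truth from [generate_barcodes()].
#' @param path Output FASTQ path (`.gz` suffix gzip-compresses).
#' @param layout The [tile_layout()] the truth was generated under; read
#'   positions must be invertible to (lane, tile, pixel) under it.
#' @param error_rate Per-base substitution probability (default 0).
#' @param reads_per_barcode Reads emitted per barcode (default 1).
#' @param seed RNG seed for error injection.
#' @return Invisibly, a tibble (`read_index`, `barcode_true`,
#'   `barcode_written`, `n_errors`).
#' @export
write_first_seq_fastq <- function(truth, path, layout = synthetic_layout(),
                                  error_rate = 0, reads_per_barcode = 1,
                                  seed = 1) {
  if (!all(truth$tile %in% layout$grid$tile)) {
    abort("Truth contains tiles outside the layout.")
  }
  if (error_rate < 0 || error_rate >= 1) abort("`error_rate` must be in [0, 1).")
  idx <- rep(seq_len(nrow(truth)), each = reads_per_barcode)
  t2 <- truth[idx, , drop = FALSE]
  written <- t2$barcode
  n_err <- integer(nrow(t2))
  if (error_rate > 0) {
    with_seed(seed, {
      K <- nchar(written[1L])
      chars <- matrix(unlist(strsplit(written, "", fixed = TRUE)),
                      nrow = length(written), byrow = TRUE)
      hit <- matrix(runif(length(chars)) < error_rate, nrow = nrow(chars))
      if (any(hit)) {
        alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))
        pos <- which(hit)
        chars[pos] <- vapply(chars[pos], function(b) sample(alt[[b]], 1L), "")
      }
      n_err <- as.integer(rowSums(hit))
      written <- apply(chars, 1, paste, collapse = "")
    })
  }
  ids <- sprintf("SIM:1:FCSYN:%d:%d:%d:%d",
                 t2$lane, t2$tile, t2$x_local, t2$y_local)
  qual <- strrep("I", nchar(written[1L]))
  readr::write_lines(
    as.vector(rbind(paste0("@", ids), written, "+", qual)), path
  )
  invisible(tibble(read_index = seq_along(idx), barcode_true = t2$barcode,
                   barcode_written = written, n_errors = n_err))
}

#' Simulate a complete desk-scale Seq-Scope-like experiment
#'
#' Convenience wrapper tying the generator together: barcodes on a 2 x 2
#' tile flow cell (300 x 300 length units), three vertical expression
#' domains, Poisson counts with spliced/unspliced layers. The defaults
#' (10,000 barcodes, 200 genes, 3 domains) are the package's standard study
#' conditions for end-to-end tests.
#'
#' @param n_barcodes Number of spatial barcodes (default 10,000).
#' @param n_genes Number of genes (default 200).
#' @param n_domains Number of striped domains (default 3).
#' @param barcode_length Barcode length (default 20).
#' @param seed Single seed governing every draw (default 0).
#' @param layout A [tile_layout()]; default [synthetic_layout()].
#' @param model A [domain_model()]; default [default_domain_model()].
#' @return A list: `truth` (with `domain` and `boundaries_x` attribute),
#'   `matrix` (a [spatial_matrix()]), `model`, `layout`.
#' @export
simulate_seqscope <- function(n_barcodes = 10000, n_genes = 200, n_domains = 3,
                              barcode_length = 20, seed = 0,
                              layout = synthetic_layout(), model = NULL) {
  model <- model %||% default_domain_model(
    n_genes = n_genes, n_domains = n_domains,
    markers_per_domain = min(20L, (n_genes - 5L) %/% n_domains),
    seed = seed + 1L
  )
  truth <- generate_barcodes(n_barcodes, barcode_length = barcode_length,
                             layout = layout, seed = seed + 2L)
  truth <- assign_stripe_domains(
    truth, n_domains = n_domains,
    extent = c(0, layout$tile_width * ncol_layout(layout))
  )
  mat <- simulate_counts(truth, model, seed = seed + 3L)
  list(truth = truth, matrix = mat, model = model, layout = layout)
}

ncol_layout <- function(layout) max(layout$grid$col) + 1L

#' Ground-truth domain labels for striped-fixture bins
#'
#' Assigns each bin the domain of its center and flags whether the bin
#' rectangle lies wholly inside one stripe (`pure`). Bins straddling a
#' boundary are genuine mixtures of two domains: they have no well-defined
#' single true label, so exact-recovery scoring should restrict to pure
#' bins, while boundary-displacement metrics are about precisely those
#' mixed locations.
#'
#' @param binned A `binned_matrix` over a striped fixture.
#' @param boundaries_x True vertical boundary positions (the
#'   `boundaries_x` attribute of [assign_stripe_domains()] output).
#' @return A tibble `bin_id`, `domain`, `pure`.
#' @export
stripe_bin_truth <- function(binned, boundaries_x) {
  stopifnot(inherits(binned, "binned_matrix"))
  lo <- findInterval(binned$bins$wx, boundaries_x)
  hi <- findInterval(binned$bins$wx + binned$spec$side - 1e-9, boundaries_x)
  ctr <- findInterval(binned$bins$center_x, boundaries_x)
  tibble(
    bin_id = binned$bins$bin_id,
    domain = sprintf("domain%d", ctr + 1L),
    pure = lo == hi
  )
}
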