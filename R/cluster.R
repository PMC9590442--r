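#' Log-normalize binned counts
#'
#' Seurat-style library-size normalization: each bin's counts are scaled to
#' `scale` total counts and log-transformed,
#' `value = ln(1 + scale * count / bin_total)`. Zeros stay zero, so sparsity
#' is preserved, and doubling every count in a bin leaves its normalized
#' profile unchanged.
#'
#' @param binned A `binned_matrix`, or a bins x genes (sparse) count matrix.
#' @param scale Target counts per bin (default 10,000).
#' @return A sparse bins x genes matrix of normalized values.
#' @export
normalize_bins <- function(binned, scale = 1e4) {
  check_scalar_number(scale, "scale", positive = TRUE)
  m <- if (inherits(binned, "binned_matrix")) binned$counts else
    as(as(as(binned, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  totals <- Matrix::rowSums(m)
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)[1L]
    id <- rownames(m)[bad] %||% as.character(bad)
    abort(sprintf("Bin '%s' has zero total counts; filter it before normalizing.",
                  id))
  }
  out <- as(m, "TsparseMatrix")
  out@x <- log1p(scale * out@x / totals[out@i + 1L])
  as(out, "CsparseMatrix")
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their normalized values across bins and
#' keeps the top `n_hvg`; ties are broken by gene order, and the selection
#' is capped at the number of available genes.
#'
#' @param normalized A bins x genes matrix from [normalize_bins()].
#' @param n_hvg Number of genes to keep (> 0).
#' @return Character vector of selected gene identifiers (column names), in
#'   decreasing-variance order.
#' @export
select_hvg <- function(normalized, n_hvg) {
  check_scalar_number(n_hvg, "n_hvg", positive = TRUE, integerish = TRUE)
  n <- nrow(normalized)
  if (n < 2L) abort("Need at least two bins to estimate gene variances.")
  mu <- Matrix::colMeans(normalized)
  ex2 <- Matrix::colSums(normalized^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  v <- pmax(v, 0)
  k <- min(as.integer(n_hvg), length(v))
  ord <- order(-v, seq_along(v), method = "radix")[seq_len(k)]
  cn <- colnames(normalized) %||% as.character(seq_along(v))
  cn[ord]
}

#' Fit the reference clustering model on the coarse grid track
#'
#' The two-track approach learns everything on the simple-grid bins, where
#' per-bin transcript counts are high enough for stable clustering:
#' log-normalization, highly variable gene selection, per-gene z-scoring
#' with clipping, centered PCA, a shared-nearest-neighbor (SNN) graph, and
#' modularity-based (Leiden) community detection. Every statistic needed to
#' project new bins out-of-sample — the HVG list, gene means/sds, PCA
#' loadings — is stored in the returned model.
#'
#' @param binned A `binned_matrix` from [simple_grid_bin()].
#' @param n_hvg Number of highly variable genes (default 2000, capped at
#'   the gene count).
#' @param n_pcs Number of principal components (default 20).
#' @param k_neighbors Neighbors for the SNN graph (default 20).
#' @param resolution Resolution of the modularity partition (default 0.5).
#' @param seed Seed fixing the community-detection randomness (default 0).
#' @param scale Normalization target (default 10,000).
#' @param clip Z-scores are clipped to `[-clip, clip]` (default 10).
#' @param snn_prune SNN edges with Jaccard weight below this are removed
#'   (default 1/15).
#' @return A `cluster_model` with elements `hvg`, `gene_means`, `gene_sds`,
#'   `loadings` (hvg x n_pcs, orthonormal columns), `reference_embedding`,
#'   `reference_labels` (tibble `bin_id`, `center_x`, `center_y`,
#'   `cluster`), and the fitting parameters.
#' @export
fit_reference <- function(binned, n_hvg = 2000, n_pcs = 20, k_neighbors = 20,
                          resolution = 0.5, seed = 0, scale = 1e4, clip = 10,
                          snn_prune = 1 / 15) {
  stopifnot(inherits(binned, "binned_matrix"))
  n_bins <- nrow(binned$counts)
  if (n_bins < k_neighbors + 1L) {
    abort(sprintf("Need at least k_neighbors + 1 = %d bins, have %d.",
                  k_neighbors + 1L, n_bins))
  }
  if (n_bins < n_pcs) {
    abort(sprintf("Fewer bins (%d) than n_pcs (%d); reduce n_pcs.",
                  n_bins, n_pcs))
  }
  norm <- normalize_bins(binned, scale = scale)
  hvg <- select_hvg(norm, n_hvg)
  sub <- norm[, hvg, drop = FALSE]
  mu <- Matrix::colMeans(sub)
  sd_ <- sqrt(pmax(Matrix::colSums(sub^2) / n_bins - mu^2, 0) *
                n_bins / (n_bins - 1))
  pos <- sd_ > 0
  if (!any(pos)) abort("All selected genes are constant across bins.")
  if (!all(pos)) {
    hvg <- hvg[pos]
    sub <- sub[, pos, drop = FALSE]
    mu <- mu[pos]
    sd_ <- sd_[pos]
  }
  z <- zscore_clip(sub, mu, sd_, clip)

  n_pcs <- min(n_pcs, ncol(z), n_bins - 1L)
  dec <- if (min(dim(z)) > 3L * n_pcs) {
    with_seed(seed, irlba::irlba(z, nv = n_pcs))
  } else {
    s <- svd(z, nu = n_pcs, nv = n_pcs)
    list(u = s$u, d = s$d[seq_len(n_pcs)], v = s$v)
  }
  # deterministic sign: largest-magnitude loading entry positive per column
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- dec$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  loadings <- sweep(dec$v, 2, flip, `*`)
  rownames(loadings) <- hvg
  embedding <- as.matrix(z %*% loadings)
  rownames(embedding) <- binned$bins$bin_id

  g <- snn_graph(embedding, k_neighbors, prune = snn_prune)
  membership <- with_seed(seed, igraph::membership(igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    weights = igraph::E(g)$weight, n_iterations = 10
  )))
  # stable labels: clusters numbered by decreasing size
  sizes <- sort(table(membership), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  cluster <- as.integer(relabel[as.character(membership)])

  structure(
    list(
      hvg = hvg, gene_means = mu, gene_sds = sd_, loadings = loadings,
      reference_embedding = embedding,
      reference_labels = tibble(
        bin_id = binned$bins$bin_id,
        center_x = binned$bins$center_x, center_y = binned$bins$center_y,
        cluster = cluster
      ),
      params = list(n_hvg = n_hvg, n_pcs = n_pcs, k_neighbors = k_neighbors,
                    resolution = resolution, seed = seed, scale = scale,
                    clip = clip, snn_prune = snn_prune)
    ),
    class = "cluster_model"
  )
}

zscore_clip <- function(m, mu, sd_, clip) {
  z <- sweep(sweep(as.matrix(m), 2, mu, `-`), 2, sd_, `/`)
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}

# shared-nearest-neighbor graph: Jaccard overlap of the (k+1)-neighborhoods
# (self included), edges below `prune` dropped
snn_graph <- function(embedding, k, prune = 1 / 15) {
  n <- nrow(embedding)
  nn <- FNN::get.knn(embedding, k = k)$nn.index
  A <- sparseMatrix(
    i = rep(seq_len(n), k + 1L),
    j = c(seq_len(n), as.vector(nn)),
    x = 1, dims = c(n, n)
  )
  inter <- Matrix::tcrossprod(A)
  inter <- as(as(inter, "generalMatrix"), "TsparseMatrix")
  keep <- inter@i < inter@j
  i <- inter@i[keep] + 1L
  j <- inter@j[keep] + 1L
  w <- inter@x[keep] / (2 * (k + 1) - inter@x[keep])
  sel <- w >= prune
  igraph::graph_from_data_frame(
    data.frame(from = i[sel], to = j[sel], weight = w[sel]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "<cluster_model> %d reference bins, %d clusters, %d HVGs, %d PCs\n",
    nrow(x$reference_labels), max(x$reference_labels$cluster),
    length(x$hvg), ncol(x$loadings)
  ))
  invisible(x)
}

#' Tidy and summarize a fitted cluster model
#'
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return `tidy()` returns the reference label table (`bin_id`,
#'   `center_x`, `center_y`, `cluster`); `glance()` a one-row fit summary.
#' @export
tidy.cluster_model <- function(x, ...) x$reference_labels

#' @rdname tidy.cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble(
    n_reference_bins = nrow(x$reference_labels),
    n_clusters = max(x$reference_labels$cluster),
    n_hvg = length(x$hvg), n_pcs = ncol(x$loadings),
    resolution = x$params$resolution, k_neighbors = x$params$k_neighbors,
    seed = x$params$seed
  )
}

#' Project query bins into a fitted reference space
#'
#' Applies the reference model's exact preprocessing to a new binned track
#' (typically the fine sliding-window bins): normalize with the stored
#' scale, restrict to the stored HVGs (genes absent from the query are
#' treated as zero counts), z-score with the stored means and sds, clip,
#' and multiply by the stored PCA loadings. Projecting the reference track
#' itself reproduces its embedding.
#'
#' @param model A [fit_reference()] model.
#' @param binned A `binned_matrix` (or bins x genes count matrix) to
#'   project.
#' @return A query x n_pcs embedding matrix.
#' @export
project_bins <- function(model, binned) {
  stopifnot(inherits(model, "cluster_model"))
  norm <- normalize_bins(binned, scale = model$params$scale)
  present <- intersect(model$hvg, colnames(norm))
  if (length(present) == 0L) {
    abort("Query genes share nothing with the model's HVG list.")
  }
  sub <- Matrix::Matrix(0, nrow = nrow(norm), ncol = length(model$hvg),
                        dimnames = list(rownames(norm), model$hvg),
                        sparse = TRUE)
  sub[, present] <- norm[, present, drop = FALSE]
  z <- zscore_clip(sub, model$gene_means, model$gene_sds, model$params$clip)
  emb <- z %*% model$loadings
  rownames(emb) <- rownames(norm) %||%
    (if (inherits(binned, "binned_matrix")) binned$bins$bin_id else NULL)
  emb
}

#' Transfer reference cluster labels to query bins
#'
#' Each query bin receives the majority cluster label among its `k` nearest
#' reference bins in the embedding space (Euclidean distance); majority
#' ties fall back to the label of the single nearest neighbor. Fully
#' deterministic.
#'
#' @param model A [fit_reference()] model.
#' @param query_embedding A query x n_pcs matrix from [project_bins()].
#' @param k Number of reference neighbors (default 5, capped at the
#'   reference size).
#' @return A tibble with `bin_id` (when available), `cluster`, and
#'   `nn_distance` (distance to the nearest reference bin).
#' @export
transfer_labels <- function(model, query_embedding, k = 5) {
  stopifnot(inherits(model, "cluster_model"))
  query_embedding <- as.matrix(query_embedding)
  if (nrow(query_embedding) == 0L) abort("Empty query embedding.")
  check_scalar_number(k, "k", positive = TRUE, integerish = TRUE)
  ref <- model$reference_embedding
  k <- min(as.integer(k), nrow(ref))
  nn <- FNN::get.knnx(ref, query_embedding, k = k)
  lab <- matrix(model$reference_labels$cluster[nn$nn.index], ncol = k)
  cluster <- vapply(seq_len(nrow(lab)), function(i) {
    counts <- table(lab[i, ])
    top <- counts[counts == max(counts)]
    if (length(top) > 1L) lab[i, 1L] else as.integer(names(top))
  }, 0L)
  tibble(
    bin_id = rownames(query_embedding) %||%
      as.character(seq_len(nrow(query_embedding))),
    cluster = cluster,
    nn_distance = nn$nn.dist[, 1L]
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1
#' means identical partitions, 0 the expected agreement of random
#' partitions. Used to score cluster-label recovery against ground truth.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Mean displacement of label boundaries from known stripe boundaries
#'
#' For spatial labelings of vertically striped domains: scans each row of
#' bin centers left to right, records the midpoint of every label
#' transition, and averages the distance from those midpoints to the
#' nearest true boundary. A finer track should place its transitions closer
#' to the truth, so a smaller value means sharper recovered boundaries.
#'
#' @param labels Tibble with `center_x`, `center_y`, `cluster` (e.g.
#'   `tidy()` of a model joined with transferred labels).
#' @param boundaries_x Numeric vector of true vertical boundary positions.
#' @param row_tol Centers whose `center_y` differ by less than this are
#'   treated as one row (default half the smallest center spacing).
#' @return Mean absolute displacement in length units (`NA` if no
#'   transitions exist).
#' @export
boundary_displacement <- function(labels, boundaries_x, row_tol = NULL) {
  stopifnot(all(c("center_x", "center_y", "cluster") %in% names(labels)))
  ys <- sort(unique(labels$center_y))
  row_tol <- row_tol %||% (if (length(ys) > 1L) min(diff(ys)) / 2 else 0.5)
  row_id <- cumsum(c(TRUE, diff(ys) > row_tol))
  row_of <- row_id[match(labels$center_y, ys)]
  disp <- unlist(lapply(split(labels, row_of), function(d) {
    d <- d[order(d$center_x), , drop = FALSE]
    if (nrow(d) < 2L) return(numeric(0))
    chg <- which(d$cluster[-1L] != d$cluster[-nrow(d)])
    if (!length(chg)) return(numeric(0))
    mid <- (d$center_x[chg] + d$center_x[chg + 1L]) / 2
    vapply(mid, function(m) min(abs(m - boundaries_x)), 0)
  }), use.names = FALSE)
  if (!length(disp)) return(NA_real_)
  mean(disp)
}
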