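test_that("log-normalization follows ln(1 + scale * count / total)", {
  m <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 2), x = c(10, 90, 50),
                            dims = c(2, 2),
                            dimnames = list(c("b1", "b2"), c("g1", "g2")))
  norm <- normalize_bins(m, scale = 1e4)
  expect_equal(norm[1, 1], log1p(1e4 * 10 / 100))
  expect_equal(norm[1, 1], 6.90875477932, tolerance = 1e-10)
  expect_equal(norm[2, 1], 0)  # zero counts stay zero

  # scale invariance of proportions: doubling a bin's counts changes nothing
  m2 <- m
  m2[1, ] <- m[1, ] * 2
  expect_equal(normalize_bins(m2), normalize_bins(m))

  m3 <- m
  m3[2, ] <- 0
  expect_error(normalize_bins(m3), "b2")
})

test_that("highly variable gene selection ranks by variance with stable ties", {
  norm <- Matrix::Matrix(cbind(
    g1 = c(0, 1), g2 = c(0, sqrt(0.2)), g3 = c(0, sqrt(1.8))
  ), sparse = TRUE)  # sample variances 0.5, 0.1, 0.9
  expect_equal(select_hvg(norm, 2), c("g3", "g1"))
  expect_equal(select_hvg(norm, 3), c("g3", "g1", "g2"))

  # a constant gene is never selected while alternatives exist
  norm2 <- Matrix::Matrix(cbind(flat = c(1, 1, 1), varying = c(0, 1, 2)),
                          sparse = TRUE)
  expect_equal(select_hvg(norm2, 1), "varying")
  # ties break by gene order
  norm3 <- Matrix::Matrix(cbind(a = c(0, 1), b = c(0, 1)), sparse = TRUE)
  expect_equal(select_hvg(norm3, 1), "a")
  expect_error(select_hvg(norm, 0), "n_hvg")
})

test_that("near-rank-1 data yields an equal-weight first loading", {
  # two genes, constant bin totals, gene2 = total - gene1: after z-scoring
  # the data lie on a line, so the first PC weights both genes equally
  v <- c(100, 110, 120, 130, 140, 150, 160, 170)
  counts <- cbind(g1 = v, g2 = 1000 - v)
  bm <- structure(list(
    bins = tibble::tibble(bin_id = sprintf("b%d", seq_along(v)),
                          wx = seq_along(v), wy = 0,
                          center_x = seq_along(v), center_y = 0,
                          n_barcodes = 1L, total_umi = rowSums(counts)),
    counts = as(Matrix::Matrix(counts, sparse = TRUE,
                               dimnames = list(sprintf("b%d", seq_along(v)),
                                               c("g1", "g2"))), "CsparseMatrix"),
    spec = bin_spec(1), genes = tibble::tibble(id = c("g1", "g2"),
                                               name = c("g1", "g2")),
    source_layer = "Gene"
  ), class = "binned_matrix")
  model <- fit_reference(bm, n_hvg = 2, n_pcs = 1, k_neighbors = 3,
                         seed = 0)
  l <- model$loadings[, 1]
  expect_equal(abs(unname(l)), c(1, 1) / sqrt(2), tolerance = 1e-2)
  expect_lt(l["g1"] * l["g2"], 0)  # opposite signs
  # loadings are orthonormal
  expect_equal(crossprod(model$loadings), diag(1), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("reference clustering recovers three striped domains", {
  sim <- small_striped_sim()
  g <- simple_grid_bin(sim$matrix, bin_spec(10))
  model <- fit_reference(g, seed = 0)
  expect_equal(max(model$reference_labels$cluster), 3L)

  truth <- stripe_bin_truth(g, sim$boundaries)
  pure <- truth$pure
  ari <- adjusted_rand_index(model$reference_labels$cluster[pure],
                             truth$domain[pure])
  expect_equal(ari, 1.0)
  # orthonormal loadings invariant at fitted size
  expect_equal(crossprod(model$loadings), diag(ncol(model$loadings)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("fitting is deterministic under a fixed seed", {
  sim <- small_striped_sim()
  g <- simple_grid_bin(sim$matrix, bin_spec(10))
  m1 <- fit_reference(g, seed = 3)
  m2 <- fit_reference(g, seed = 3)
  expect_identical(m1$reference_labels, m2$reference_labels)
  expect_equal(m1$reference_embedding, m2$reference_embedding)
})

test_that("degenerate fitting inputs raise informative errors", {
  sim <- small_striped_sim()
  g <- simple_grid_bin(sim$matrix, bin_spec(20))
  expect_error(fit_reference(g, n_pcs = 1000), "n_pcs")
  expect_error(fit_reference(g, k_neighbors = 10000), "k_neighbors")
})

test_that("projection reproduces the reference embedding and handles new bins", {
  sim <- small_striped_sim()
  g <- simple_grid_bin(sim$matrix, bin_spec(10))
  model <- fit_reference(g, seed = 0)
  self <- project_bins(model, g)
  expect_equal(as.matrix(self), model$reference_embedding, tolerance = 1e-8)

  # a query with a reference bin's exact raw profile gets its embedding row
  q <- g$counts[5, , drop = FALSE]
  rownames(q) <- "query"
  emb_q <- project_bins(model, q)
  expect_equal(as.vector(emb_q), unname(model$reference_embedding[5, ]),
               tolerance = 1e-10)
})

test_that("an all-zero-on-hvg query projects to the clipped-mean point", {
  sim <- small_striped_sim()
  g <- simple_grid_bin(sim$matrix, bin_spec(10))
  model <- fit_reference(g, n_hvg = 20, seed = 0)
  other <- setdiff(g$genes$id, model$hvg)[1]
  q <- Matrix::sparseMatrix(
    i = 1, j = which(g$genes$id == other), x = 5,
    dims = c(1, nrow(g$genes)), dimnames = list("q", g$genes$id)
  )
  emb <- project_bins(model, q)
  clip <- model$params$clip
  z_expected <- pmax(pmin(-model$gene_means / model$gene_sds, clip), -clip)
  expect_equal(as.vector(emb), as.vector(z_expected %*% model$loadings))

  bad <- Matrix::sparseMatrix(i = 1, j = 1, x = 5, dims = c(1, 1),
                              dimnames = list("q", "not_a_gene"))
  expect_error(project_bins(model, bad), "HVG")
})

test_that("label transfer uses kNN majority with nearest-neighbor tie-break", {
  ref_emb <- rbind(a = c(0, 0), b = c(10, 0), c = c(10.5, 0))
  model <- structure(list(
    reference_embedding = ref_emb,
    reference_labels = tibble::tibble(
      bin_id = c("a", "b", "c"), center_x = 0, center_y = 0,
      cluster = c(1L, 2L, 2L)
    )
  ), class = "cluster_model")
  # identical to a reference point, k = 1
  expect_equal(transfer_labels(model, ref_emb["a", , drop = FALSE],
                               k = 1)$cluster, 1L)
  # equidistant between clusters with k = 2: nearest single neighbor wins
  q <- matrix(c(5, 0), 1)
  out <- transfer_labels(model, q, k = 2)
  expect_equal(out$cluster, 1L)  # 'a' at distance 5 is the first neighbor
  # clear majority at k = 3
  expect_equal(transfer_labels(model, matrix(c(9, 0), 1), k = 3)$cluster, 2L)
  expect_error(transfer_labels(model, ref_emb[0, , drop = FALSE]), "Empty")
})

test_that("sliding-window label transfer recovers fine-scale domains", {
  sim <- small_striped_sim()
  g <- simple_grid_bin(sim$matrix, bin_spec(10))
  w <- sliding_window_bin(sim$matrix, bin_spec(10, 2))
  model <- fit_reference(g, seed = 0)
  lab <- transfer_labels(model, project_bins(model, w))
  truth <- stripe_bin_truth(w, sim$boundaries)
  ari <- adjusted_rand_index(lab$cluster, truth$domain)
  expect_gte(ari, 0.8)
})

test_that("the package ARI agrees with the established implementation", {
  set.seed(17)
  for (i in 1:5) {
    a <- sample(1:4, 100, replace = TRUE)
    b <- sample(1:3, 100, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("boundary displacement averages transition offsets per row", {
  labels <- tibble::tibble(
    center_x = rep(c(5, 15, 25, 35), 2),
    center_y = rep(c(0, 10), each = 4),
    cluster = c(1, 1, 2, 2, 1, 2, 2, 2)
  )
  # transitions at midpoints 20 (row 1) and 10 (row 2); boundary truth 12
  expect_equal(boundary_displacement(labels, 12), mean(c(8, 2)))
  expect_true(is.na(boundary_displacement(labels[labels$cluster == 1, ], 12)))
})
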