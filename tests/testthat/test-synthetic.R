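test_that("barcode generation is deterministic, unique and in bounds", {
  t1 <- generate_barcodes(100, barcode_length = 8, seed = 7)
  t2 <- generate_barcodes(100, barcode_length = 8, seed = 7)
  expect_identical(t1, t2)
  t3 <- generate_barcodes(100, barcode_length = 8, seed = 8)
  expect_false(identical(t1$barcode, t3$barcode))

  expect_equal(anyDuplicated(t1$barcode), 0L)
  layout <- synthetic_layout()
  expect_true(all(t1$x >= 0 & t1$x < 2 * layout$tile_width))
  expect_true(all(t1$y >= 0 & t1$y < 2 * layout$tile_height))
  expect_true(all(t1$x_local >= 0 & t1$x_local < 1500))

  expect_error(generate_barcodes(1000, barcode_length = 4), "barcode_length")
})

test_that("domain models validate rates and spliced fractions", {
  rates <- matrix(c(1, 0, 0, 2), 2, 2,
                  dimnames = list(c("d1", "d2"), c("g1", "g2")))
  m <- domain_model(rates, spliced_fraction = 0.5)
  expect_equal(unname(m$spliced_fraction), c(0.5, 0.5))
  expect_error(domain_model(rates, spliced_fraction = 1.5), "0, 1")
  expect_error(domain_model(-rates), ">= 0")

  dm <- default_domain_model(n_genes = 50, n_domains = 3,
                             markers_per_domain = 10)
  expect_equal(dim(dm$rates), c(3L, 50L))
  # marker blocks are disjoint across domains
  expect_true(all(colSums(dm$rates[, 1:30] > 0.2) == 1))
})

test_that("stripe assignment places boundaries in general position", {
  t1 <- generate_barcodes(500, barcode_length = 8, seed = 1)
  t1 <- assign_stripe_domains(t1, n_domains = 3, extent = c(0, 300))
  b <- attr(t1, "boundaries_x")
  expect_equal(b, c(97, 194))
  expect_true(all(t1$domain[t1$x < 97] == "domain1"))
  expect_true(all(t1$domain[t1$x >= 194] == "domain3"))
  t2 <- assign_stripe_domains(t1, n_domains = 3, extent = c(0, 300),
                              boundaries_x = c(50, 200))
  expect_equal(attr(t2, "boundaries_x"), c(50, 200))
})

test_that("simulated counts follow the domain model's Poisson rates", {
  layout <- synthetic_layout(n_row = 1, n_col = 1)
  truth <- generate_barcodes(2000, barcode_length = 10, layout = layout,
                             seed = 2)
  truth <- assign_stripe_domains(truth, n_domains = 1, extent = c(0, 150))
  rate <- 0.5
  rates <- matrix(rate, 1, 3, dimnames = list("domain1", c("g1", "g2", "g3")))
  mat <- simulate_counts(truth, domain_model(rates, spliced_fraction = 0.8),
                         seed = 3)
  n <- nrow(truth)
  total <- sum(layer(mat))
  expectation <- n * rate * 3
  expect_lt(abs(total - expectation), 5 * sqrt(expectation))
  # layers satisfy Gene = spliced + unspliced
  expect_equal(as.matrix(layer(mat)),
               as.matrix(layer(mat, "spliced") + layer(mat, "unspliced")))
})

test_that("edge cases of the count model behave", {
  truth <- generate_barcodes(50, barcode_length = 8, seed = 4)
  truth <- assign_stripe_domains(truth, n_domains = 1)
  zero <- matrix(0, 1, 2, dimnames = list("domain1", c("g1", "g2")))
  m0 <- simulate_counts(truth, domain_model(zero), seed = 1)
  expect_equal(sum(layer(m0)), 0)

  all_spliced <- domain_model(
    matrix(2, 1, 2, dimnames = list("domain1", c("g1", "g2"))),
    spliced_fraction = 1
  )
  m1 <- simulate_counts(truth, all_spliced, seed = 1)
  expect_equal(sum(layer(m1, "unspliced")), 0)
  expect_equal(layer(m1, "spliced"), layer(m1, "Gene"))
})

test_that("counts are reproducible under a fixed seed without RNG side effects", {
  truth <- generate_barcodes(100, barcode_length = 8, seed = 5)
  truth <- assign_stripe_domains(truth, n_domains = 1)
  dm <- default_domain_model(n_genes = 30, markers_per_domain = 5)
  set.seed(999)
  before <- .Random.seed
  m1 <- simulate_counts(truth, dm, seed = 6)
  expect_identical(.Random.seed, before)  # caller RNG state untouched
  m2 <- simulate_counts(truth, dm, seed = 6)
  expect_equal(layer(m1), layer(m2))
})

test_that("first-seq FASTQ identifiers re-parse to the generated coordinates", {
  layout <- synthetic_layout()
  truth <- generate_barcodes(200, barcode_length = 10, layout = layout,
                             seed = 9)
  fq <- tempfile(fileext = ".fastq")
  log <- write_first_seq_fastq(truth, fq, layout = layout)
  expect_equal(log$n_errors, rep(0L, 200))
  lines <- readLines(fq)
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  parsed <- parse_read_id(ids)
  expect_equal(parsed$tile, truth$tile)
  expect_equal(parsed$x_local, truth$x_local)
  expect_equal(parsed$y_local, truth$y_local)
})

test_that("injected substitution errors occur at the requested rate", {
  layout <- synthetic_layout()
  truth <- generate_barcodes(2000, barcode_length = 20, layout = layout,
                             seed = 10)
  fq <- tempfile(fileext = ".fastq")
  log <- write_first_seq_fastq(truth, fq, layout = layout, error_rate = 0.01,
                               seed = 11)
  n_bases <- 2000 * 20
  p_hat <- sum(log$n_errors) / n_bases
  expect_lt(abs(p_hat - 0.01), 5 * sqrt(0.01 * 0.99 / n_bases))
  # flagged reads really differ from the truth where and only where flagged
  differs <- log$barcode_written != log$barcode_true
  expect_equal(differs, log$n_errors > 0)
})

test_that("whitelist correction rescues unambiguous single-substitution reads", {
  layout <- synthetic_layout()
  truth <- generate_barcodes(1500, barcode_length = 16, layout = layout,
                             seed = 12)
  fq <- tempfile(fileext = ".fastq")
  log <- write_first_seq_fastq(truth, fq, layout = layout, error_rate = 0.01,
                               seed = 13)
  single <- log[log$n_errors == 1L, ]
  oracle <- brute_force_correct(single$barcode_written, truth$barcode)
  unambiguous <- !is.na(oracle) & oracle == single$barcode_true
  corrected <- correct_barcode(single$barcode_written, truth$barcode)
  rescued <- !is.na(corrected) & corrected == single$barcode_true
  expect_gte(sum(rescued[unambiguous]) / sum(unambiguous), 0.99)
})

test_that("the bundled experiment simulator wires truth, counts and layout", {
  sim <- simulate_seqscope(n_barcodes = 500, n_genes = 40, seed = 1)
  expect_equal(nrow(sim$truth), 500L)
  expect_equal(dim(sim$matrix), c(500L, 40L))
  expect_equal(sort(unique(sim$truth$domain)),
               c("domain1", "domain2", "domain3"))
  expect_length(attr(sim$truth, "boundaries_x"), 2L)
})
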