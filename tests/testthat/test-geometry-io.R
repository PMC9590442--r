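test_that("read identifiers parse into lane/tile/x/y", {
  out <- parse_read_id(c("M0001:42:FC1:1:1101:5000:7000",
                         "M0001:42:FC1:2:2214:0:0"))
  expect_equal(out$lane, c(1L, 2L))
  expect_equal(out$tile, c(1101L, 2214L))
  expect_equal(out$x_local, c(5000L, 0L))
  expect_equal(out$y_local, c(7000L, 0L))

  # trailing fields and read descriptions are tolerated
  out2 <- parse_read_id("M:1:F:3:1102:10:20:N:0:ACGT 1:N:0")
  expect_equal(out2$tile, 1102L)
  expect_equal(out2$y_local, 20L)
})

test_that("malformed identifiers raise errors naming the read", {
  expect_error(parse_read_id("M0001:42:FC1:1:1101:5000"), "M0001:42")
  expect_error(parse_read_id("M0001:42:FC1:1:1101:xx:70"), "Non-integer")
})

test_that("globalize applies the tile offset formula", {
  lay <- tile_layout(c(11L, 12L, 13L), n_col = 3,
                     tile_width = 100, tile_height = 100,
                     gap = 10, units_per_pixel = 0.5)
  at <- function(tile, xl, yl) {
    globalize(tibble::tibble(tile = tile, x_local = xl, y_local = yl), lay)
  }
  expect_equal(at(11L, 0L, 0L)$x, 0)
  expect_equal(at(11L, 0L, 0L)$y, 0)
  # tile in column 2: x = 2 * (100 + 10) + 1 * 0.5
  expect_equal(at(13L, 1L, 0L)$x, 220.5)

  lay2 <- tile_layout(c(1L, 2L), n_col = 1, tile_width = 100,
                      tile_height = 100, gap = 0, units_per_pixel = 1)
  expect_equal(at2 <- globalize(
    tibble::tibble(tile = 2L, x_local = 0L, y_local = 5L), lay2
  )$y, 105)
})

test_that("unknown tiles error with the list of known tiles", {
  lay <- unit_layout()
  expect_error(
    globalize(tibble::tibble(tile = 9L, x_local = 0L, y_local = 0L), lay),
    "1101"
  )
})

test_that("globalize is injective across tiles for in-bounds pixels", {
  lay <- tile_layout(1:6, n_col = 3, tile_width = 50, tile_height = 40,
                     gap = 5, units_per_pixel = 1)
  set.seed(42)
  pts <- tibble::tibble(
    tile = sample(1:6, 300, replace = TRUE),
    x_local = sample.int(50, 300, replace = TRUE) - 1L,
    y_local = sample.int(40, 300, replace = TRUE) - 1L
  )
  g <- globalize(pts, lay)
  key_in <- paste(pts$tile, pts$x_local, pts$y_local)
  key_out <- paste(g$x, g$y)
  expect_equal(anyDuplicated(key_out[!duplicated(key_in)]), 0L)
})

test_that("barcode maps dedupe identical reads and count collisions", {
  lay <- unit_layout()
  id_at <- function(x, y) sprintf("S:1:F:1:1101:%d:%d", x, y)
  fq <- write_test_fastq(
    c(id_at(10, 10), id_at(10, 10), id_at(20, 5)),
    c("ACGT", "ACGT", "TTTT")
  )
  bm <- build_barcode_map(fq, lay, barcode_length = 4)
  expect_equal(nrow(bm), 2L)
  expect_equal(attr(bm, "n_collisions"), 0L)
  expect_equal(bm$x[bm$barcode == "TTTT"], 20)

  fq2 <- write_test_fastq(c(id_at(10, 10), id_at(30, 30)), c("ACGT", "ACGT"))
  bm2 <- build_barcode_map(fq2, lay, barcode_length = 4)
  expect_equal(nrow(bm2), 0L)
  expect_equal(attr(bm2, "n_collisions"), 1L)
  bm2b <- build_barcode_map(fq2, lay, barcode_length = 4,
                            collision_policy = "first")
  expect_equal(nrow(bm2b), 1L)

  # N-containing barcodes are dropped before mapping
  fq3 <- write_test_fastq(c(id_at(1, 1), id_at(2, 2)), c("ACNT", "GGGG"))
  expect_equal(build_barcode_map(fq3, lay, barcode_length = 4)$barcode, "GGGG")
})

test_that("empty and truncated FASTQ files are rejected", {
  lay <- unit_layout()
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  expect_error(build_barcode_map(empty, lay, barcode_length = 4), "Empty")
  trunc <- tempfile(fileext = ".fastq")
  writeLines(c("@S:1:F:1:1101:1:1", "ACGT", "+", "IIII", "@S:1:F:1:1101:2:2",
               "ACGT"), trunc)
  expect_error(build_barcode_map(trunc, lay, barcode_length = 4),
               "record 2")
})

test_that("barcode map recovers generator ground truth exactly", {
  layout <- synthetic_layout()
  truth <- generate_barcodes(1000, barcode_length = 12, layout = layout,
                             seed = 7)
  fq <- tempfile(fileext = ".fastq")
  write_first_seq_fastq(truth, fq, layout = layout)
  bm <- build_barcode_map(fq, layout, barcode_length = 12)
  expect_equal(nrow(bm), 1000L)
  m <- match(truth$barcode, bm$barcode)
  expect_false(anyNA(m))
  expect_equal(bm$x[m], truth$x)
  expect_equal(bm$y[m], truth$y)
})

test_that("barcode correction matches exact, unique-distance-1 and ambiguity rules", {
  expect_equal(correct_barcode("ACGT", c("ACGT", "TTTT")), "ACGT")
  expect_equal(correct_barcode("ACGA", c("ACGT", "TTTT")), "ACGT")
  expect_true(is.na(correct_barcode("ACGA", c("ACGT", "ACGG"))))
  expect_true(is.na(correct_barcode("AAAA", c("CCGG", "TTGG"))))
  expect_error(correct_barcode("ACG", c("ACGT")), "length")
})

test_that("vectorized correction agrees with the brute-force Hamming oracle", {
  set.seed(5)
  K <- 8
  wl <- unique(replicate(60, paste(sample(c("A", "C", "G", "T"), K,
                                          replace = TRUE), collapse = "")))
  obs <- c(
    wl[1:10],  # exact
    vapply(wl[11:30], function(b) {  # one substitution
      p <- sample(K, 1)
      substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(b, p, p)), 1)
      b
    }, ""),
    replicate(20, paste(sample(c("A", "C", "G", "T"), K, replace = TRUE),
                        collapse = ""))  # random
  )
  expect_equal(correct_barcode(obs, wl), brute_force_correct(obs, wl))
})

test_that("correction is idempotent and lands in the whitelist", {
  set.seed(9)
  wl <- unique(replicate(40, paste(sample(c("A", "C", "G", "T"), 6,
                                          replace = TRUE), collapse = "")))
  obs <- replicate(200, paste(sample(c("A", "C", "G", "T"), 6,
                                     replace = TRUE), collapse = ""))
  corr <- correct_barcode(obs, wl)
  expect_true(all(is.na(corr) | corr %in% wl))
  ok <- !is.na(corr)
  expect_equal(correct_barcode(corr[ok], wl), corr[ok])
})

test_that("whitelists are lexicographic and round-trip with coordinates", {
  lay <- unit_layout()
  fq <- write_test_fastq(
    c("S:1:F:1:1101:2:2", "S:1:F:1:1101:1:1"), c("TTTT", "AAAA")
  )
  bm <- build_barcode_map(fq, lay, barcode_length = 4)
  wl_path <- tempfile()
  write_whitelist(bm, wl_path)
  expect_equal(readLines(wl_path), c("AAAA", "TTTT"))
  back <- read_barcode_coords(paste0(wl_path, ".coords.tsv"))
  expect_equal(
    dplyr::arrange(tibble::as_tibble(back), barcode),
    dplyr::arrange(tibble::as_tibble(bm), barcode)
  )

  empty <- bm[0, ]
  attr(empty, "n_collisions") <- 0L
  expect_error(write_whitelist(empty, tempfile()), "empty")
})
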