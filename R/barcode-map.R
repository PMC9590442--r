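#' Build a spatial barcode map from a first-round FASTQ file
#'
#' Extracts the spatial barcode from each read sequence and its flow-cell
#' position from the read identifier, converts positions to global
#' coordinates, and collapses reads into one entry per barcode. Barcodes
#' containing `N` are discarded before mapping. Duplicate reads of one
#' barcode at one coordinate collapse to a single entry; a barcode observed
#' at more than one distinct coordinate has no defined spatial origin and is
#' handled by `collision_policy`.
#'
#' @param fastq Path to a FASTQ file (plain or gzip).
#' @param layout A [tile_layout()] used to globalize coordinates.
#' @param barcode_length Barcode length K in bases.
#' @param barcode_start 1-based offset of the barcode within the read
#'   sequence (default 1: barcode at the 5' end).
#' @param collision_policy `"drop"` (default) discards barcodes seen at
#'   multiple coordinates; `"first"` keeps the coordinate of the first read.
#' @return A `barcode_map`: a tibble with columns `barcode`, `x`, `y`, one
#'   row per retained barcode, carrying attributes `n_collisions` (barcodes
#'   discarded or resolved for multi-coordinate ambiguity) and
#'   `n_total_reads`.
#' @seealso [write_whitelist()], [correct_barcode()]
#' @export
build_barcode_map <- function(fastq, layout, barcode_length,
                              barcode_start = 1L,
                              collision_policy = c("drop", "first")) {
  collision_policy <- match.arg(collision_policy)
  check_scalar_number(barcode_length, "barcode_length",
                      positive = TRUE, integerish = TRUE)
  check_scalar_number(barcode_start, "barcode_start",
                      positive = TRUE, integerish = TRUE)
  if (!file.exists(fastq)) abort(sprintf("FASTQ file not found: %s", fastq))

  n_lines <- length(readr::read_lines(fastq, progress = FALSE))
  if (n_lines == 0L) abort(sprintf("Empty FASTQ file: %s", fastq))
  if (n_lines %% 4L != 0L) {
    abort(sprintf("Truncated FASTQ record at record %d in %s",
                  n_lines %/% 4L + 1L, fastq))
  }

  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  if (length(reads) == 0L) abort(sprintf("Empty FASTQ file: %s", fastq))
  widths <- Biostrings::width(reads)
  if (any(widths < barcode_start + barcode_length - 1L)) {
    abort(sprintf(
      "Reads shorter than barcode_start + barcode_length - 1 = %d.",
      barcode_start + barcode_length - 1L
    ))
  }
  barcode <- unname(as.character(Biostrings::subseq(
    reads, start = barcode_start, width = barcode_length
  )))
  ids <- parse_read_id(names(reads))
  pos <- globalize(ids, layout)

  tbl <- tibble(barcode = barcode, x = pos$x, y = pos$y)
  n_total <- nrow(tbl)
  tbl <- tbl[!grepl("N", tbl$barcode, fixed = TRUE), , drop = FALSE]
  tbl <- dplyr::distinct(tbl, .data$barcode, .data$x, .data$y)

  dup <- unique(tbl$barcode[duplicated(tbl$barcode)])
  n_collisions <- length(dup)
  if (n_collisions > 0L) {
    if (collision_policy == "drop") {
      tbl <- tbl[!tbl$barcode %in% dup, , drop = FALSE]
    } else {
      tbl <- tbl[!duplicated(tbl$barcode), , drop = FALSE]
    }
  }
  new_barcode_map(tbl, n_collisions = n_collisions, n_total_reads = n_total)
}

new_barcode_map <- function(tbl, n_collisions = 0L, n_total_reads = nrow(tbl)) {
  tbl <- as_tibble(tbl)[c("barcode", "x", "y")]
  stopifnot(!anyDuplicated(tbl$barcode), all(is.finite(tbl$x)),
            all(is.finite(tbl$y)), all(tbl$x >= 0), all(tbl$y >= 0))
  structure(tbl, n_collisions = as.integer(n_collisions),
            n_total_reads = as.integer(n_total_reads),
            class = c("barcode_map", class(tbl)))
}

#' @export
print.barcode_map <- function(x, ...) {
  cat(sprintf("<barcode_map> %d barcodes (%d reads, %d collision(s) dropped)\n",
              nrow(x), attr(x, "n_total_reads"), attr(x, "n_collisions")))
  NextMethod()
}

#' @rdname build_barcode_map
#' @param x A `barcode_map`.
#' @param ... Unused.
#' @export
glance.barcode_map <- function(x, ...) {
  tibble(
    n_barcodes = nrow(x),
    n_collisions = attr(x, "n_collisions"),
    n_total_reads = attr(x, "n_total_reads")
  )
}

#' Error-correct observed barcodes against a whitelist
#'
#' An observed barcode that is an exact whitelist member is returned
#' unchanged. Otherwise, if exactly one whitelist member lies at Hamming
#' distance 1 (a single substitution), that member is returned. No match, or
#' two or more distance-1 candidates, yields `NA` — the ambiguity rule that
#' keeps correction deterministic. Indels and distance-2 corrections are
#' deliberately not attempted.
#'
#' @param observed Character vector of observed barcodes, all of the
#'   whitelist's barcode length.
#' @param whitelist Character vector of known barcodes (one length).
#' @return Character vector parallel to `observed`: the corrected whitelist
#'   member, or `NA` where correction failed or was ambiguous.
#' @examples
#' correct_barcode(c("ACGT", "ACGA"), c("ACGT", "TTTT"))
#' @export
correct_barcode <- function(observed, whitelist) {
  if (length(whitelist) == 0L) abort("`whitelist` is empty.")
  K <- unique(nchar(whitelist))
  if (length(K) != 1L) abort("`whitelist` barcodes must share one length.")
  if (any(nchar(observed) != K)) {
    abort(sprintf("Observed barcode length differs from whitelist length %d.", K))
  }
  out <- whitelist[match(observed, whitelist)]
  todo <- which(is.na(out) & !is.na(observed))
  if (length(todo) == 0L) return(out)

  obs <- observed[todo]
  m <- length(obs)
  # enumerate all single-substitution neighbours and hash-match the whitelist
  bases <- c("A", "C", "G", "T")
  cand_idx <- integer(0)
  cand_seq <- character(0)
  for (pos in seq_len(K)) {
    pre <- substr(obs, 1L, pos - 1L)
    post <- substr(obs, pos + 1L, K)
    orig <- substr(obs, pos, pos)
    for (b in bases) {
      keep <- orig != b
      if (!any(keep)) next
      cand_idx <- c(cand_idx, which(keep))
      cand_seq <- c(cand_seq, paste0(pre[keep], b, post[keep]))
    }
  }
  hit <- !is.na(match(cand_seq, whitelist))
  hit_idx <- cand_idx[hit]
  hit_seq <- cand_seq[hit]
  n_hits <- tabulate(hit_idx, nbins = m)
  uniq <- n_hits == 1L
  if (any(uniq)) {
    first <- hit_seq[match(which(uniq), hit_idx)]
    out[todo[uniq]] <- first
  }
  out
}

#' Write an aligner-compatible barcode whitelist with coordinate sidecar
#'
#' Writes one barcode per line in deterministic lexicographic order (the
#' format STARsolo-style aligners consume) plus a sidecar TSV
#' (`barcode`, `x`, `y`) holding the spatial coordinates, so the barcode map
#' round-trips through [read_barcode_coords()].
#'
#' @param map A `barcode_map` from [build_barcode_map()].
#' @param path Output path for the whitelist text file.
#' @param coords_path Output path for the coordinates TSV; defaults to
#'   `<path>.coords.tsv`.
#' @return Invisibly, a list with the two paths written.
#' @export
write_whitelist <- function(map, path, coords_path = paste0(path, ".coords.tsv")) {
  if (!inherits(map, "barcode_map")) abort("`map` must be a barcode_map.")
  if (nrow(map) == 0L) abort("Refusing to write an empty whitelist.")
  ord <- order(map$barcode, method = "radix")
  readr::write_lines(map$barcode[ord], path)
  readr::write_tsv(as_tibble(map)[ord, c("barcode", "x", "y")], coords_path,
                   progress = FALSE)
  invisible(list(whitelist = path, coords = coords_path))
}

#' Read a barcode coordinates table back into a barcode map
#'
#' @param path Path to a TSV with header `barcode`, `x`, `y` as written by
#'   [write_whitelist()].
#' @return A `barcode_map` tibble.
#' @export
read_barcode_coords <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    barcode = readr::col_character(),
    x = readr::col_double(), y = readr::col_double()
  ), progress = FALSE)
  new_barcode_map(tbl)
}
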