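#' Pipeline step registry
#'
#' The workflow is a chain of labelled steps: `A1` (extract spatial
#' barcodes and coordinates from first-round FASTQ, emit whitelist), `A2`
#' (spatial QC and tissue-boundary detection), the external alignment
#' boundary (see [external_align_handoff()]), `C1` (simple grid
#' aggregation), `C2` (sliding-window aggregation), `C3` (reference
#' clustering + fine-track label transfer) and `V1` (RGB geneset
#' rendering). Steps can run end-to-end or as any consecutive sub-chain
#' whose inputs exist — e.g. `C1:C3` straight from a user-supplied MTX
#' directory, skipping FASTQ processing entirely.
#'
#' @return Character vector of step identifiers in dependency order.
#' @export
pipeline_steps <- function() c("A1", "A2", "C1", "C2", "C3", "V1")

#' Run a set of consecutive pipeline steps from one configuration
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   * `out`: output directory (required);
#'   * `fastq`: first-round FASTQ path (for `A1`);
#'   * `mtx`: spatial MTX directory (for `A2`/`C1`/`C2` when not produced
#'     upstream);
#'   * `layout`: [tile_layout()] arguments as a named list (for `A1`);
#'   * `params`: per-step parameter overrides (`barcode_length`,
#'     `barcode_start`, `cell_size`, `grid_side`, `mssw_side`, `mssw_step`,
#'     `grid_min_umi`, `layer`, `n_hvg`, `n_pcs`, `k_neighbors`,
#'     `resolution`, `k_transfer`, `red`/`green`/`blue` gene vectors,
#'     `pixel_size`);
#'   * `seed`: seed for stochastic steps (default 0).
#' @param steps Character vector of step ids to run; must be consecutive in
#'   [pipeline_steps()] order. Default: all steps whose inputs exist.
#' @return A run-manifest tibble (one row per executed step with parameter
#'   JSON, outputs, and file checksums), also written as JSON-lines to
#'   `<out>/manifest.jsonl`.
#' @export
run_steps <- function(config, steps = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out)) abort("`config$out` (output directory) is required.")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  p <- config$params %||% list()
  seed <- config$seed %||% 0
  all_steps <- pipeline_steps()

  if (is.null(steps)) {
    steps <- if (!is.null(config$fastq)) all_steps else
      c("A2", "C1", "C2", "C3", "V1")
  }
  unknown <- setdiff(steps, all_steps)
  if (length(unknown)) {
    abort(sprintf("Unknown step id(s): %s (known: %s)",
                  paste(unknown, collapse = ", "),
                  paste(all_steps, collapse = ", ")))
  }
  idx <- sort(match(steps, all_steps))
  if (length(idx) > 1L && any(diff(idx) != 1L)) {
    abort("Requested steps must form a consecutive chain.")
  }
  steps <- all_steps[idx]

  paths <- list(
    whitelist = file.path(config$out, "whitelist.txt"),
    coords = file.path(config$out, "whitelist.txt.coords.tsv"),
    qc_metrics = file.path(config$out, "qc_metrics.tsv"),
    tissue = file.path(config$out, "tissue_mask.tsv"),
    grid = file.path(config$out, "bins_grid"),
    mssw = file.path(config$out, "bins_mssw"),
    labels_grid = file.path(config$out, "labels_grid.tsv"),
    labels_mssw = file.path(config$out, "labels_mssw.tsv"),
    rgb = file.path(config$out, "render_rgb.png")
  )

  need <- function(path, producer) {
    ok <- if (grepl("\\.(tsv|txt|png|yaml)$", path)) file.exists(path) else
      dir.exists(path)
    if (!ok) {
      abort(sprintf(
        "Missing input '%s' for a requested step; run step %s first or point the config at it.",
        path, producer
      ))
    }
    path
  }
  load_matrix <- function() {
    src <- config$mtx %||% need(paths$grid, "an MTX-producing step")
    read_mtx_dir(src)
  }
  manifest <- list()
  log_step <- function(step, params, outputs) {
    files <- unlist(lapply(outputs, function(o) {
      if (dir.exists(o)) list.files(o, recursive = TRUE, full.names = TRUE)
      else o
    }))
    sums <- tools::md5sum(files[file.exists(files)])
    manifest[[length(manifest) + 1L]] <<- list(
      step = step, time = format(Sys.time(), tz = "UTC"),
      params = params, outputs = as.list(outputs),
      checksums = as.list(sums)
    )
  }

  for (step in steps) {
    switch(step,
      A1 = {
        fq <- config$fastq %||% abort("Step A1 needs `config$fastq`.")
        layout <- do.call(tile_layout, config$layout %||%
                            abort("Step A1 needs `config$layout`."))
        bm <- build_barcode_map(
          fq, layout,
          barcode_length = p$barcode_length %||% 20,
          barcode_start = p$barcode_start %||% 1
        )
        write_whitelist(bm, paths$whitelist)
        log_step("A1", list(barcode_length = p$barcode_length %||% 20),
                 c(paths$whitelist, paths$coords))
      },
      A2 = {
        sm <- load_matrix()
        ras <- density_raster(sm, cell_size = p$cell_size %||% 10)
        tis <- detect_tissue(ras)
        qc <- per_barcode_qc(sm)
        readr::write_tsv(qc, paths$qc_metrics, progress = FALSE)
        cells <- which(tis$mask, arr.ind = TRUE)
        readr::write_tsv(
          tibble(row = cells[, 1] - 1L, col = cells[, 2] - 1L,
                 x = tis$origin[1] + (cells[, 2] - 1L) * tis$cell_size,
                 y = tis$origin[2] + (cells[, 1] - 1L) * tis$cell_size),
          paths$tissue, progress = FALSE
        )
        log_step("A2", list(cell_size = p$cell_size %||% 10,
                            bbox = as.list(tis$bbox)),
                 c(paths$qc_metrics, paths$tissue))
      },
      C1 = {
        sm <- load_matrix()
        g <- simple_grid_bin(sm, bin_spec(p$grid_side %||% 10),
                             min_umi = p$grid_min_umi %||% 0,
                             layer = p$layer)
        write_binned_mtx(g, paths$grid)
        log_step("C1", list(side = p$grid_side %||% 10,
                            min_umi = p$grid_min_umi %||% 0), paths$grid)
      },
      C2 = {
        sm <- load_matrix()
        w <- sliding_window_bin(
          sm, bin_spec(p$mssw_side %||% 10, p$mssw_step %||% 2),
          min_umi = 0, layer = p$layer
        )
        write_binned_mtx(w, paths$mssw)
        log_step("C2", list(side = p$mssw_side %||% 10,
                            step = p$mssw_step %||% 2), paths$mssw)
      },
      C3 = {
        g <- drop_zero_total_bins(read_binned_mtx(need(paths$grid, "C1")))
        w <- drop_zero_total_bins(read_binned_mtx(need(paths$mssw, "C2")))
        model <- fit_reference(
          g, n_hvg = p$n_hvg %||% 2000, n_pcs = p$n_pcs %||% 20,
          k_neighbors = p$k_neighbors %||% 20,
          resolution = p$resolution %||% 0.5, seed = seed
        )
        emb <- project_bins(model, w)
        lab <- transfer_labels(model, emb, k = p$k_transfer %||% 5)
        readr::write_tsv(tidy(model), paths$labels_grid, progress = FALSE)
        readr::write_tsv(
          dplyr::left_join(lab,
                           tidy(w)[c("bin_id", "center_x", "center_y")],
                           by = "bin_id"),
          paths$labels_mssw, progress = FALSE
        )
        log_step("C3", list(n_pcs = p$n_pcs %||% 20, seed = seed),
                 c(paths$labels_grid, paths$labels_mssw))
      },
      V1 = {
        sm <- load_matrix()
        genes <- sm$genes$name
        spec <- geneset_rgb(
          red = p$red %||% head(genes, 1),
          green = p$green %||% character(),
          blue = p$blue %||% character(),
          pixel_size = p$pixel_size %||% 1
        )
        r <- render_rgb(sm, spec)
        write_render_png(r, paths$rgb)
        log_step("V1", list(pixel_size = p$pixel_size %||% 1), paths$rgb)
      }
    )
  }

  lines <- vapply(manifest, function(m) {
    jsonlite::toJSON(m, auto_unbox = TRUE)
  }, "")
  readr::write_lines(lines, file.path(config$out, "manifest.jsonl"))
  tibble(
    step = vapply(manifest, `[[`, "", "step"),
    params = vapply(manifest, function(m) {
      as.character(jsonlite::toJSON(m$params, auto_unbox = TRUE))
    }, ""),
    n_outputs = vapply(manifest, function(m) length(m$checksums), 0L)
  )
}

# clustering requires positive bin totals; bins that contain barcodes but
# zero UMIs are rejected here, upstream of normalization
drop_zero_total_bins <- function(b) {
  keep <- b$bins$total_umi > 0
  if (!all(keep)) {
    inform(sprintf("Dropping %d zero-UMI bin(s) before clustering.",
                   sum(!keep)))
    b$bins <- b$bins[keep, , drop = FALSE]
    b$counts <- b$counts[keep, , drop = FALSE]
  }
  b
}

#' Write the external alignment hand-off
#'
#' Alignment itself (STARsolo over the second-round cDNA reads) is an
#' external tool boundary: this writes the whitelist in
#' aligner-consumable form together with a documented command template, and
#' downstream steps ingest the aligner's MTX output directory via
#' [read_mtx_dir()] with coordinates joined by barcode.
#'
#' @param whitelist Path to a whitelist written by [write_whitelist()].
#' @param coords Path to its coordinates sidecar.
#' @param out_dir Directory to write the hand-off into.
#' @return Invisibly, the instruction-file path.
#' @export
external_align_handoff <- function(whitelist, coords, out_dir) {
  if (!file.exists(whitelist)) abort(sprintf("No whitelist at %s", whitelist))
  wl <- readr::read_lines(whitelist, progress = FALSE)
  if (length(wl) == 0L) abort("Whitelist is empty.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(out_dir, "whitelist.txt")
  file.copy(whitelist, dest, overwrite = TRUE)
  file.copy(coords, file.path(out_dir, "coordinates.tsv"), overwrite = TRUE)
  instr <- file.path(out_dir, "ALIGN_COMMAND.txt")
  readr::write_lines(c(
    "# External alignment boundary — run with your reference genome:",
    "STAR --runMode alignReads --soloType CB_UMI_Simple \\",
    sprintf("  --soloCBwhitelist %s \\", dest),
    "  --soloCBstart 1 --soloCBlen <K> --soloUMIstart <K+1> --soloUMIlen <L> \\",
    "  --soloFeatures Gene GeneFull Velocyto \\",
    "  --readFilesIn second_seq.fastq.gz --genomeDir <GENOME_DIR> \\",
    "  --outSAMtype BAM Unsorted --outSAMattributes CB UB",
    "# Then ingest the Solo output with read_mtx_dir(<solo_dir>, coords = coordinates.tsv)"
  ), instr)
  invisible(instr)
}
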