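# Readers/writers for the external formats the pipeline touches. CSV is the
# canonical interchange format; FCS support is read-only. Time is hours as
# decimal; image coordinates are 0-based pixel indices (x = column,
# y = row). All file writes are atomic (temp-then-rename).

# Internal: atomic write — writer(path) runs against a temp file which is
# renamed into place only on success.
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort_comphet(sprintf("atomic_write: could not move temp file into '%s'", path))
  }
  invisible(path)
}

#' Read a single-channel TIFF image
#'
#' Reads an 8- or 16-bit single-channel TIFF into an integer matrix
#' (rows = y, cols = x), preserving raw counts losslessly. Multi-channel
#' (RGB) or floating-point TIFFs are rejected: the pipeline measures raw
#' integer fluorescence counts from one channel.
#'
#' @param path path to the TIFF file.
#' @return integer matrix with attributes `source_id` (file name) and
#'   `bits_per_sample`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort_comphet(sprintf("read_image: no such file '%s'", path))
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(img)) != 2) {
    abort_comphet(sprintf(
      "read_image: '%s' has %d channels; expected a single-channel (grayscale) TIFF",
      path, if (length(dim(img)) == 3) dim(img)[3] else length(dim(img))))
  }
  if (!is.integer(img)) {
    abort_comphet(sprintf(
      "read_image: '%s' holds floating-point samples; expected 8/16-bit integers", path))
  }
  info <- attr(img, "info")
  bits <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else 16L
  out <- matrix(img, nrow = nrow(img), ncol = ncol(img))
  attr(out, "source_id") <- basename(path)
  attr(out, "bits_per_sample") <- bits
  out
}

#' Write an integer matrix as a single-channel TIFF
#'
#' @param image integer matrix with values in `[0, 2^bits - 1]`.
#' @param path output path.
#' @param bits bits per sample (8 or 16; default 16).
#' @return the path, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  stopifnot(is.matrix(image), bits %in% c(8L, 16L))
  maxval <- 2^bits - 1
  if (min(image) < 0 || max(image) > maxval) {
    abort_comphet(sprintf("write_image: values outside the %d-bit range", bits))
  }
  atomic_write(path, function(p) {
    tiff::writeTIFF(image / maxval, p, bits.per.sample = as.integer(bits))
  })
}

# ---- FCS 3.x reading ------------------------------------------------------
# Minimal list-mode FCS 3.0/3.1 reader (no R FCS parser is available in the
# dependency set). Supports $DATATYPE F (float32) and D (float64),
# little- or big-endian, $MODE L. Read-only by design.
read_fcs3 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    abort_comphet(sprintf("read_fcs3: '%s' is not an FCS 3.x file (header '%s')",
                          path, version))
  }
  text_start <- as.integer(substr(header, 11, 18))
  text_end <- as.integer(substr(header, 19, 26))
  seek(con, text_start)
  text <- rawToChar(readBin(con, "raw", text_end - text_start + 1))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- setNames(vals, toupper(trimws(keys)))

  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  if (!dtype %in% c("F", "D")) {
    abort_comphet(sprintf("read_fcs3: unsupported $DATATYPE '%s' (only F/D)", dtype))
  }
  byteord <- kw[["$BYTEORD"]]
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  ch_names <- vapply(seq_len(n_par),
                     function(i) kw[[sprintf("$P%dN", i)]], character(1))
  data_start <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(data_start) || data_start == 0) {
    data_start <- as.integer(substr(header, 27, 34))
  }
  seek(con, data_start)
  size <- if (dtype == "F") 4L else 8L
  vals <- readBin(con, "numeric", n = n_par * n_tot, size = size,
                  endian = endian)
  mat <- matrix(vals, ncol = n_par, byrow = TRUE)
  colnames(mat) <- ch_names
  list(data = as.data.frame(mat), keywords = kw)
}

#' Read a flow-cytometry event table
#'
#' Reads an FCS 3.x file or a CSV event table and extracts one fluorescence
#' channel. A CSV table needs either a column named like the channel
#' (e.g. `"PE-A"`) or a `value` column; `strain` and `timepoint_h` columns
#' are carried into the attributes when present.
#'
#' @param path path to a `.fcs` or `.csv` file.
#' @param channel fluorescence channel to extract (default `"PE-A"`).
#' @return data.frame with column `value` (one row per event) and attributes
#'   `channel`, `n_events`, and (when available) `strain`, `timepoint_h`.
#' @export
read_fc <- function(path, channel = "PE-A") {
  if (!file.exists(path)) abort_comphet(sprintf("read_fc: no such file '%s'", path))
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    fcs <- read_fcs3(path)
    if (!channel %in% names(fcs$data)) {
      abort_comphet(sprintf(
        "read_fc: channel '%s' not in '%s'; available: %s",
        channel, path, paste(names(fcs$data), collapse = ", ")))
    }
    out <- data.frame(value = fcs$data[[channel]])
    attr(out, "keywords") <- fcs$keywords
  } else {
    tab <- read.csv(path, check.names = FALSE)
    col <- if (channel %in% names(tab)) channel
           else if ("value" %in% names(tab)) "value"
           else abort_comphet(sprintf(
             "read_fc: neither channel '%s' nor a 'value' column in '%s'; available: %s",
             channel, path, paste(names(tab), collapse = ", ")))
    out <- data.frame(value = tab[[col]])
    if ("strain" %in% names(tab)) attr(out, "strain") <- tab$strain[1]
    if ("timepoint_h" %in% names(tab)) attr(out, "timepoint_h") <- tab$timepoint_h[1]
  }
  attr(out, "channel") <- channel
  attr(out, "n_events") <- nrow(out)
  out
}

#' Write a data.frame as CSV (atomic)
#'
#' @param x data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table_csv <- function(x, path) {
  atomic_write(path, function(p) write.csv(x, p, row.names = FALSE))
}

#' Write an R object as JSON (atomic)
#'
#' @param x object serializable by jsonlite.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_json_file <- function(x, path) {
  atomic_write(path, function(p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
}

#' Build and write a run manifest
#'
#' Records everything needed for an exact rerun: the configuration (and its
#' MD5 hash), the scenario seed plus every derived per-stage seed, an
#' inventory of produced files with MD5 checksums, the package version and
#' stage timings.
#'
#' @param out_dir directory holding the run outputs.
#' @param config the configuration list used for the run.
#' @param seeds named list: scenario seed and per-stage derived seeds.
#' @param files character vector of file paths to inventory.
#' @param timings optional named numeric vector of stage durations (s).
#' @return the manifest list, invisibly; written to
#'   `file.path(out_dir, "run_manifest.json")`.
#' @export
write_run_manifest <- function(out_dir, config, seeds, files,
                               timings = NULL) {
  cfg_file <- tempfile()
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  files <- files[file.exists(files)]
  manifest <- list(
    package = "comphet",
    version = as.character(packageVersion("comphet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    config_md5 = cfg_hash,
    seeds = seeds,
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))
    }),
    timings_s = as.list(timings))
  write_json_file(manifest, file.path(out_dir, "run_manifest.json"))
  invisible(manifest)
}

#' Write pipeline outputs with a run manifest
#'
#' Writes per-cell records, shift reports and/or kinetics fits to `out_dir`
#' using the documented CSV/JSON schemas, then writes a manifest covering
#' every produced file.
#'
#' @param out_dir output directory (created if needed).
#' @param cell_records optional data.frame from [quantify_image()] rows.
#' @param shift optional `shift_report` object.
#' @param fits optional named list of `fourpl_fit` objects.
#' @param config configuration recorded in the manifest.
#' @param seeds named list of seeds recorded in the manifest.
#' @return character vector of written file paths, invisibly.
#' @export
write_outputs <- function(out_dir, cell_records = NULL, shift = NULL,
                          fits = NULL, config = list(), seeds = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(cell_records)) {
    p <- file.path(out_dir, "cell_records.csv")
    write_table_csv(cell_records, p); written <- c(written, p)
  }
  if (!is.null(shift)) {
    p1 <- file.path(out_dir, "shift_fractions.csv")
    p2 <- file.path(out_dir, "shift_deltas.csv")
    p3 <- file.path(out_dir, "shift_report.json")
    write_table_csv(shift$fractions, p1)
    write_table_csv(shift$deltas, p2)
    write_json_file(list(reference_timepoint = shift$reference_timepoint,
                         late_timepoint = shift$late_timepoint,
                         levels = shift$levels,
                         thresholds = shift$thresholds,
                         fractions = shift$fractions,
                         deltas = shift$deltas), p3)
    written <- c(written, p1, p2, p3)
  }
  if (!is.null(fits)) {
    p <- file.path(out_dir, "fourpl_fits.json")
    write_json_file(lapply(fits, function(f) {
      list(params = f$params, rss = f$rss, max_slope = f$max_slope,
           peak_time = f$peak_time, fit_window = f$fit_window, n = f$n,
           degenerate = f$degenerate)
    }), p)
    written <- c(written, p)
  }
  write_run_manifest(out_dir, config, seeds, written)
  invisible(c(written, file.path(out_dir, "run_manifest.json")))
}
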