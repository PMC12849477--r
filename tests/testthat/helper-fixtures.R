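# Fixture builders shared across the test files. Everything is generated in
# code at test time; no binary fixtures are stored.

# Paint circular cells at chosen centers/intensities on a flat background.
# Gives exact control over placement (unlike render_field's rejection
# sampling), so tests can put every cell inside the central ROI.
make_grid_field <- function(centers, intensities, radius = 6,
                            width = 256, height = 256, background = 100) {
  img <- matrix(background, nrow = height, ncol = width)
  mask <- matrix(0L, nrow = height, ncol = width)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    xs <- pmax(1, floor(cx - radius)):pmin(width, ceiling(cx + radius))
    ys <- pmax(1, floor(cy - radius)):pmin(height, ceiling(cy + radius))
    dx2 <- outer(rep(1, length(ys)), (xs - 1 - cx)^2)
    dy2 <- outer((ys - 1 - cy)^2, rep(1, length(xs)))
    inside <- dx2 + dy2 <= radius^2
    img[ys, xs][inside] <- background + intensities[i]
    mask[ys, xs][inside] <- i
  }
  list(image = img, mask = mask,
       truth = data.frame(label = seq_len(nrow(centers)),
                          centroid_x = centers[, 1], centroid_y = centers[, 2],
                          intensity = intensities))
}

# A segmentation object built straight from an objects table (for tests of
# the object filters, which only need areas/centroids/labels).
make_seg <- function(objects) {
  structure(list(label_map = matrix(0L, 1, 1), objects = objects,
                 removed = NULL),
            class = "segmentation")
}

# Minimal FCS 3.0 writer (float32, list mode, little endian) used to test
# the read-only FCS parser; built byte-by-byte at test time.
write_test_fcs <- function(path, values, channel = "PE-A") {
  n <- length(values)
  text_start <- 58L
  make_text <- function(data_start, data_end) {
    paste0("/", paste(c(
      "$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
      "$PAR", "1", "$TOT", as.character(n),
      "$P1N", channel, "$P1B", "32", "$P1E", "0,0", "$P1R", "262144",
      "$BEGINDATA", as.character(data_start),
      "$ENDDATA", as.character(data_end)), collapse = "/"), "/")
  }
  txt <- make_text(0, 0)
  for (i in 1:3) {
    data_start <- text_start + nchar(txt)
    data_end <- data_start + 4L * n - 1L
    txt <- make_text(data_start, data_end)
  }
  text_end <- text_start + nchar(txt) - 1L
  hdr <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                 text_start, text_end, data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.numeric(values), con, size = 4L, endian = "little")
  invisible(path)
}

# Small pipeline config for orchestration tests (composition semantics, not
# study-scale conditions).
small_config <- function(seed = 1L) {
  cfg <- default_config()
  cfg$scenario$seed <- seed
  cfg$fc$n_events <- 2000L
  cfg$microscopy$n_fields <- 1L
  cfg$microscopy$geometry$width <- 256L
  cfg$microscopy$geometry$height <- 256L
  cfg$microscopy$geometry$n_cells <- 60L
  cfg
}
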