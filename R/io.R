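# File formats. B-scans travel as 8-bit grayscale BMP (the clinical export
# format) or PNG; ambiguity maps as 24-bit BMP / PNG; tables as CSV;
# configs and manifests as JSON; probability volumes as gzipped little-endian
# doubles with a JSON header. The BMP codec is implemented here because no
# BMP reader ships with the R stack. Row 1 of every matrix is the shallowest
# depth (vitreous side); BMP stores rows bottom-up, which the codec hides.

# --- BMP ---------------------------------------------------------------------

bmp_headers <- function(width, height, bpp, palette_entries) {
  row_bytes <- ((width * (bpp / 8) + 3) %/% 4) * 4
  data_offset <- 14L + 40L + 4L * palette_entries
  file_size <- data_offset + row_bytes * height
  list(row_bytes = row_bytes, data_offset = data_offset, file_size = file_size)
}

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")

#' Write an image as a Windows bitmap
#'
#' Grayscale matrices (values in `[0, 1]`, rows = depth, row 1 shallowest)
#' are written as 8-bit palette BMP with a gray ramp; `H x W x 3` RGB arrays
#' as 24-bit BMP.
#'
#' @param img Matrix in `[0, 1]` or an RGB array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bmp <- function(img, path) {
  rgb <- is.array(img) && length(dim(img)) == 3L
  if (!rgb && !is.matrix(img)) stop_octamb("'img' must be a matrix or RGB array")
  h <- dim(img)[1L]; w <- dim(img)[2L]
  q <- function(v) as.integer(pmin(pmax(round(v * 255), 0), 255))
  hd <- bmp_headers(w, h, if (rgb) 24L else 8L, if (rgb) 0L else 256L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  write_u32(con, hd$file_size); write_u32(con, 0L); write_u32(con, hd$data_offset)
  write_u32(con, 40L); write_u32(con, w); write_u32(con, h)
  write_u16(con, 1L); write_u16(con, if (rgb) 24L else 8L)
  write_u32(con, 0L); write_u32(con, hd$row_bytes * h)
  write_u32(con, 2835L); write_u32(con, 2835L)
  write_u32(con, if (rgb) 0L else 256L); write_u32(con, 0L)
  if (!rgb)
    writeBin(as.raw(rbind(0:255, 0:255, 0:255, 0L)), con)  # BGRA gray ramp
  pad <- raw(hd$row_bytes - w * (if (rgb) 3L else 1L))
  for (r in h:1) {                     # bottom-up storage
    if (rgb) {
      px <- as.raw(rbind(q(img[r, , 3L]), q(img[r, , 2L]), q(img[r, , 1L])))
    } else {
      px <- as.raw(q(img[r, ]))
    }
    writeBin(c(px, pad), con)
  }
  invisible(path)
}

read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  fail <- function(msg) stop_octamb("'%s' is not a readable grayscale BMP: %s",
                                    path, msg)
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM") fail("bad magic/header")
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  data_offset <- u32(10L)
  w <- u32(18L); h <- u32(22L)
  bpp <- u16(28L); compression <- u32(30L)
  if (compression != 0L) fail("compressed BMP unsupported")
  if (!bpp %in% c(8L, 24L)) fail(sprintf("unsupported bit depth %d", bpp))
  row_bytes <- ((w * (bpp / 8) + 3) %/% 4) * 4
  if (length(raw) < data_offset + row_bytes * h) fail("truncated pixel data")
  if (bpp == 8L) {
    hdr_size <- u32(14L)
    n_pal <- u32(46L); if (n_pal == 0L) n_pal <- 256L
    pal_off <- 14L + hdr_size
    pal <- matrix(as.integer(raw[pal_off + seq_len(4L * n_pal)]), 4L)
    if (any(pal[1L, ] != pal[2L, ]) || any(pal[2L, ] != pal[3L, ]))
      fail("color-indexed palette (not grayscale)")
    ramp <- pal[1L, ] / 255
    img <- matrix(0, h, w)
    for (r in seq_len(h)) {
      off <- data_offset + (r - 1L) * row_bytes
      img[h - r + 1L, ] <- ramp[as.integer(raw[off + seq_len(w)]) + 1L]
    }
  } else {
    img <- matrix(0, h, w)
    for (r in seq_len(h)) {
      off <- data_offset + (r - 1L) * row_bytes
      px <- matrix(as.integer(raw[off + seq_len(3L * w)]), 3L)
      img[h - r + 1L, ] <- (px[1L, ] + px[2L, ] + px[3L, ]) / (3 * 255)
    }
  }
  img
}

#' Read a B-scan image from disk
#'
#' Accepts 8-bit grayscale (or 24-bit, averaged to gray) BMP, and PNG when
#' the `png` package is installed. Intensities are scaled to `[0, 1]`; row 1
#' of the returned matrix is the shallowest depth.
#'
#' @param path Path to a `.bmp` or `.png` file.
#' @return Numeric depth x width matrix in `[0, 1]`.
#' @export
read_bscan_image <- function(path) {
  if (!file.exists(path)) stop_octamb("file '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") return(read_bmp_gray(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop_octamb("reading PNG requires the 'png' package; use BMP instead")
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
    return(a)
  }
  stop_octamb("unsupported image format '.%s' (use .bmp or .png)", ext)
}

#' Write a B-scan image to disk
#'
#' @param img Depth x width matrix in `[0, 1]` (quantized to 8 bits) or an
#'   RGB array.
#' @param path Output path ending in `.bmp` or `.png`.
#' @return `path`, invisibly.
#' @export
write_bscan_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") return(write_bmp(img, path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop_octamb("writing PNG requires the 'png' package; use BMP instead")
    png::writePNG(clamp(img, 0, 1), path)
    return(invisible(path))
  }
  stop_octamb("unsupported image format '.%s' (use .bmp or .png)", ext)
}

# --- probability volumes -----------------------------------------------------

#' Save / load a probability volume
#'
#' The array is stored as gzip-compressed little-endian doubles next to a
#' JSON header (`<path>.json`) recording dimensions and boundary names in
#' their fixed anatomical order.
#'
#' @param pv A [probability_volume()].
#' @param path Output path (conventionally `.pvz`).
#' @return `path` (for `save_`), the restored `probability_volume` (for
#'   `load_`).
#' @export
save_probability_volume <- function(pv, path) {
  stopifnot(inherits(pv, "probability_volume"))
  hdr <- list(dims = dim(pv$p), boundary_names = pv$boundary_names,
              storage = "gzip-double-little-endian", order = "x,z,l")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(pv$p), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_probability_volume
#' @export
load_probability_volume <- function(path) {
  hdr_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(hdr_path))
    stop_octamb("probability volume '%s' (or its .json header) missing", path)
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  dims <- as.integer(hdr$dims)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", prod(dims), size = 8, endian = "little")
  probability_volume(array(v, dims))
}

# --- tables ------------------------------------------------------------------

#' Export an entropy profile (or several slices) as a tidy CSV
#'
#' Columns: slice, boundary, x, entropy.
#'
#' @param profiles One `entropy_profile` or a list of them (slices).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_entropy_csv <- function(profiles, path) {
  if (inherits(profiles, "entropy_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(seq_along(profiles), function(s) {
    e <- profiles[[s]]$e
    data.frame(slice = s,
               boundary = rep(colnames(e), each = nrow(e)),
               x = rep(seq_len(nrow(e)), times = ncol(e)),
               entropy = as.vector(e))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Export truth boundaries or a boundary trace as CSV
#'
#' Columns: slice, boundary_index, x, depth.
#'
#' @param depths n_boundaries x width matrix (truth or [extract_boundaries()]
#'   output), or a list of such matrices (slices).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_boundaries_csv <- function(depths, path) {
  if (is.matrix(depths)) depths <- list(depths)
  rows <- do.call(rbind, lapply(seq_along(depths), function(s) {
    m <- depths[[s]]
    data.frame(slice = s,
               boundary_index = rep(seq_len(nrow(m)), times = ncol(m)),
               x = rep(seq_len(ncol(m)), each = nrow(m)),
               depth = as.vector(m))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# --- run configuration -------------------------------------------------------

config_schema <- function() {
  list(paths = c("data", "checkpoints", "outputs"),
       seeds = c("phantom", "train", "eval"),
       phantom = names(formals(phantom_config)),
       model = names(formals(model_config)),
       train = names(formals(train_config)),
       ambiguity = c("log_base", "fovea_halfwidth"),
       map = c("sigma", "colormap"),
       eval = c("n_normal", "n_diseased"))
}

#' Read / write a nested run configuration
#'
#' JSON document with sections `paths`, `seeds`, `phantom`, `model`,
#' `train`, `ambiguity`, `map`, `eval`. Unknown sections or keys are
#' rejected (typo safety); parse -> serialize -> parse is the identity.
#'
#' @param path JSON file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_octamb("config '%s' does not exist", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- config_schema()
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad))
    stop_octamb("unknown config section(s): %s", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    unknown <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(unknown))
      stop_octamb("unknown key(s) in section '%s': %s", sec,
                  paste(unknown, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param cfg A `run_config` (or plain named list following the schema).
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- output manifest ---------------------------------------------------------

#' Write a results directory with a checksummed manifest
#'
#' Each named element of `results` is written under `out_dir` with a
#' deterministic file name derived from its name and class (data.frame ->
#' CSV, matrix/RGB array -> BMP, list -> JSON, character -> copied path).
#' `NULL` elements are recorded in the manifest as absent rather than being
#' silently dropped. The manifest records an MD5 checksum per artifact, the
#' seeds, a checksum of the configuration, and package/R versions.
#'
#' @param results Named list of artifacts (may contain `NULL`s).
#' @param out_dir Output directory (created if needed).
#' @param seeds Named list/vector of seeds to record.
#' @param config Optional configuration object to hash into the manifest.
#' @return The manifest, invisibly; written as `manifest.json`.
#' @export
write_outputs <- function(results, out_dir, seeds = list(), config = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_octamb("cannot create output directory '%s'", out_dir)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop_octamb("'results' must be a fully named list")
  artifacts <- list()
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (is.null(obj)) {
      artifacts[[nm]] <- list(absent = TRUE)
      next
    }
    fname <- if (is.data.frame(obj)) paste0(nm, ".csv")
             else if (is.matrix(obj) || (is.array(obj) && length(dim(obj)) == 3L))
               paste0(nm, ".bmp")
             else paste0(nm, ".json")
    fpath <- file.path(out_dir, fname)
    if (is.data.frame(obj)) utils::write.csv(obj, fpath, row.names = FALSE)
    else if (is.matrix(obj) || (is.array(obj) && length(dim(obj)) == 3L))
      write_bmp(obj, fpath)
    else jsonlite::write_json(obj, fpath, auto_unbox = TRUE, digits = NA)
    artifacts[[nm]] <- list(file = fname,
                            md5 = unname(tools::md5sum(fpath)))
  }
  cfg_md5 <- if (is.null(config)) NA_character_ else {
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
    on.exit(unlink(tmp), add = TRUE)
    unname(tools::md5sum(tmp))
  }
  manifest <- list(artifacts = artifacts,
                   seeds = seeds,
                   config_md5 = cfg_md5,
                   package_version =
                     as.character(utils::packageVersion("octamb")),
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# --- model checkpoints -------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A single `.rds` file holding the configuration, parameters, training
#' state flags and loss history.
#'
#' @param model An `octamb_model`.
#' @param path Checkpoint path.
#' @return `path` / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "octamb_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_octamb("checkpoint '%s' does not exist", path)
  m <- readRDS(path)
  if (!inherits(m, "octamb_model")) stop_octamb("'%s' is not a model checkpoint", path)
  m
}
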