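# Minimal baseline TIFF codec for single-channel, uncompressed stacks.
#
# The analysis environment ships no R TIFF bindings, so the package carries
# its own reader/writer for the subset of TIFF 6.0 the pipeline needs:
# grayscale, uncompressed, 8/16-bit unsigned or 32-bit float, single sample
# per pixel, one or more strips, little- or big-endian, multi-page. The
# writer emits little-endian float32 with a JSON ImageDescription carrying
# pixel size (um/px) and per-frame timestamps (s), which the reader recovers.

TAG_WIDTH <- 256L; TAG_LENGTH <- 257L; TAG_BITS <- 258L
TAG_COMPRESSION <- 259L; TAG_PHOTOMETRIC <- 262L; TAG_DESCRIPTION <- 270L
TAG_STRIP_OFFSETS <- 273L; TAG_SPP <- 277L; TAG_ROWS_PER_STRIP <- 278L
TAG_STRIP_COUNTS <- 279L; TAG_SAMPLE_FORMAT <- 339L

#' Write a multi-page TIFF stack
#'
#' Writes a `time_lapse` (or a single matrix / `image_frame`) as an
#' uncompressed little-endian 32-bit float grayscale TIFF. Pixel size and
#' frame timestamps are embedded as JSON in the ImageDescription tag so a
#' round trip through [read_tiff()] restores the full calibration.
#'
#' @param x a `time_lapse`, `image_frame`, or numeric matrix.
#' @param path output file path.
#' @param pixel_size um/px; required when `x` is a bare matrix.
#' @param times per-frame timestamps (s); defaults taken from `x`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, pixel_size = NULL, times = NULL) {
  if (is.matrix(x)) {
    if (is.null(pixel_size)) stop("`pixel_size` required for a bare matrix")
    x <- time_lapse(list(x), pixel_size, if (is.null(times)) 0 else times)
  } else if (inherits(x, "image_frame")) {
    x <- time_lapse(list(x$intensity), x$pixel_size, x$timestamp)
  }
  stopifnot(inherits(x, "time_lapse"))
  frames <- x$frames
  nr <- nrow(frames[[1L]]); nc <- ncol(frames[[1L]])
  n <- length(frames)
  desc <- jsonlite::toJSON(
    list(pixel_size_um = x$pixel_size, times_s = x$times),
    auto_unbox = TRUE, digits = NA)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  bytes_per_page <- nr * nc * 4L
  data_off <- 8L + cumsum(c(0L, rep(bytes_per_page, n - 1L)))
  desc_off <- 8L + n * bytes_per_page
  ifd0_off <- desc_off + length(desc_raw)
  # per-page IFD: page 1 carries the description tag
  ntags <- c(10L, rep(9L, max(0L, n - 1L)))
  ifd_sizes <- 2L + 12L * ntags + 4L
  ifd_off <- ifd0_off + cumsum(c(0L, ifd_sizes[-n]))

  writeBin(charToRaw("II"), con); w16(42L); w32(ifd0_off)
  for (i in seq_len(n)) {
    # column-major matrix -> row-major raster
    writeBin(as.numeric(t(frames[[i]])), con, size = 4, endian = "little")
  }
  writeBin(desc_raw, con)

  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (i in seq_len(n)) {
    w16(ntags[i])
    entry(TAG_WIDTH, 4L, 1L, nc)
    entry(TAG_LENGTH, 4L, 1L, nr)
    entry(TAG_BITS, 3L, 1L, 32L)
    entry(TAG_COMPRESSION, 3L, 1L, 1L)
    entry(TAG_PHOTOMETRIC, 3L, 1L, 1L)
    if (i == 1L) entry(TAG_DESCRIPTION, 2L, length(desc_raw), desc_off)
    entry(TAG_STRIP_OFFSETS, 4L, 1L, data_off[i])
    entry(TAG_SPP, 3L, 1L, 1L)
    entry(TAG_STRIP_COUNTS, 4L, 1L, bytes_per_page)
    entry(TAG_SAMPLE_FORMAT, 3L, 1L, 3L)
    w32(if (i < n) ifd_off[i + 1L] else 0L)
  }
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Reads uncompressed grayscale TIFF (8/16-bit unsigned or 32-bit float,
#' either endianness, multiple strips allowed) into a [time_lapse()].
#' Calibration is taken from a JSON ImageDescription written by
#' [write_tiff()] when present; otherwise `pixel_size` must be supplied and
#' timestamps default to `interval_s * (0, 1, ...)`.
#'
#' @param path TIFF file path.
#' @param pixel_size um/px fallback when the file has no embedded metadata.
#' @param interval_s frame interval fallback (default 1 s).
#' @return a `time_lapse`.
#' @export
read_tiff <- function(path, pixel_size = NULL, interval_s = 1) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path, " (not found)")
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path)
  endian <- if (raw[1L] == charToRaw("I")[1L]) "little" else "big"
  rd <- function(off, n, size, what = "integer", signed = TRUE) {
    readBin(raw[(off + 1L):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  if (rd(2L, 1L, 2L) != 42L) stop("bad TIFF magic in ", path)
  ifd_off <- rd(4L, 1L, 4L)
  frames <- list(); desc <- NULL
  while (ifd_off != 0L) {
    ntag <- rd(ifd_off, 1L, 2L)
    tags <- list()
    for (i in seq_len(ntag)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd(e, 1L, 2L, signed = FALSE)
      type <- rd(e + 2L, 1L, 2L)
      count <- rd(e + 4L, 1L, 4L)
      tsize <- c(1L, 1L, 2L, 4L, 8L)[type]
      if (is.na(tsize)) next
      inline <- tsize * count <= 4L
      voff <- if (inline) e + 8L else rd(e + 8L, 1L, 4L)
      val <- switch(as.character(type),
        "1" = rd(voff, count, 1L, signed = FALSE),
        "2" = rawToChar(raw[(voff + 1L):(voff + count)][
          seq_len(max(0L, count - 1L))]),
        "3" = rd(voff, count, 2L, signed = FALSE),
        "4" = rd(voff, count, 4L),
        "5" = rd(voff, 2L * count, 4L),
        NULL)
      tags[[as.character(tag)]] <- val
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    nc <- g(TAG_WIDTH); nr <- g(TAG_LENGTH)
    if (is.null(nc) || is.null(nr)) stop("TIFF page missing dimensions")
    if (g(TAG_COMPRESSION, 1L)[1L] != 1L) {
      stop("only uncompressed TIFF is supported")
    }
    if (g(TAG_SPP, 1L)[1L] != 1L) {
      stop("only single-sample (grayscale) TIFF is supported")
    }
    bits <- g(TAG_BITS, 1L)[1L]
    fmt <- g(TAG_SAMPLE_FORMAT, 1L)[1L]
    if (is.null(desc)) desc <- g(TAG_DESCRIPTION)
    offs <- g(TAG_STRIP_OFFSETS)
    cnts <- g(TAG_STRIP_COUNTS, nr * nc * (bits %/% 8L))
    px <- numeric(0)
    for (s in seq_along(offs)) {
      nbytes <- cnts[min(s, length(cnts))]
      nvals <- nbytes %/% (bits %/% 8L)
      px <- c(px, if (fmt == 3L) {
        rd(offs[s], nvals, bits %/% 8L, what = "numeric")
      } else if (bits == 8L) {
        rd(offs[s], nvals, 1L, signed = FALSE)
      } else if (bits == 16L) {
        rd(offs[s], nvals, 2L, signed = FALSE)
      } else {
        rd(offs[s], nvals, 4L)
      })
    }
    if (length(px) != nr * nc) stop("TIFF strip data size mismatch")
    frames[[length(frames) + 1L]] <- matrix(px, nr, nc, byrow = TRUE)
    ifd_off <- rd(ifd_off + 2L + 12L * ntag, 1L, 4L)
  }
  if (!length(frames)) stop("empty TIFF stack: ", path)
  meta <- NULL
  if (!is.null(desc) && nzchar(desc) && startsWith(trimws(desc), "{")) {
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  }
  ps <- if (!is.null(meta$pixel_size_um)) meta$pixel_size_um else pixel_size
  if (is.null(ps)) {
    stop("pixel size not found in TIFF metadata; supply `pixel_size`")
  }
  tms <- if (!is.null(meta$times_s) && length(meta$times_s) == length(frames)) {
    as.numeric(meta$times_s)
  } else {
    interval_s * (seq_along(frames) - 1)
  }
  time_lapse(frames, ps, tms)
}

#' Read point annotations from CSV
#'
#' Expects columns `frame`, `label`, `x`, `y` (0-based pixel coordinates).
#' Used for ablation sites, vertex/ray points and furrow line endpoints.
#'
#' @param path CSV path.
#' @return data.frame with those columns.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "label", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("annotation CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Write a data.frame as UTF-8 CSV with a header row
#'
#' Thin wrapper fixing the package's CSV conventions (no row names, no
#' quoting of numerics, "." decimal separator).
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
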