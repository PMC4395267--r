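#' Kymograph container
#'
#' A kymograph is an `m x n` grayscale intensity matrix in which each row is
#' one time frame and each column is a position along the nanochannel, so a
#' stretched DNA molecule appears as a set of bright/dark bands wandering
#' horizontally over time. Intensities are in arbitrary camera units; no
#' normalisation is applied anywhere in the package.
#'
#' @param intensity Numeric `m x n` matrix of finite, non-negative values.
#'   Rows are time frames, columns are channel positions.
#' @param pixel_size Pixel size along the channel, micrometres per pixel.
#' @param frame_interval Time between frames in seconds, or `NULL` if unknown.
#'
#' @return An object of class `kymograph`: a list with elements `intensity`,
#'   `pixel_size` and `frame_interval`.
#' @examples
#' k <- kymograph(matrix(runif(50), 5, 10))
#' dim(k$intensity)
#' @export
kymograph <- function(intensity, pixel_size = 0.16, frame_interval = NULL) {
  if (is.data.frame(intensity)) intensity <- as.matrix(intensity)
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("`intensity` must be a numeric matrix")
  }
  if (nrow(intensity) < 1L || ncol(intensity) < 1L) {
    stop("kymograph must have at least one row and one column")
  }
  if (!all(is.finite(intensity))) {
    stop("kymograph intensities must all be finite")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a positive number")
  }
  structure(
    list(intensity = unname(intensity),
         pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d px (%.3g um/px%s)\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size,
              if (is.null(x$frame_interval)) ""
              else sprintf(", %.3g s/frame", x$frame_interval)))
  cat(sprintf("intensity range [%.4g, %.4g]\n",
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
dim.kymograph <- function(x) dim(x$intensity)

as_kymograph <- function(x, ...) {
  if (inherits(x, "kymograph")) x else kymograph(as.matrix(x), ...)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = "tiff",
         png = "png",
         tsv = , txt = , dat = "tsv",
         stop("cannot infer kymograph format from extension '", ext, "'"))
}

#' Read a kymograph from file
#'
#' Supported formats: plain-text TSV (rows = frames, tab-separated, `.`
#' decimal), grayscale TIFF (single 2D page, or a multi-page stack in which
#' every page is a single `1 x n` line frame), and grayscale PNG. Intensities
#' are returned exactly as stored; scaled 16-bit images written by
#' [write_kymograph()] are mapped back to their original units using the
#' JSON sidecar written alongside them. RGB images, ragged text matrices and
#' multi-page stacks of genuinely 2D frames are rejected: projecting a raw
#' movie down to a kymograph is out of scope.
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"tiff"`, `"png"`, `"tsv"`.
#' @param pixel_size,frame_interval Metadata attached to the result.
#' @return A [kymograph].
#' @export
read_kymograph <- function(path, format = c("auto", "tiff", "png", "tsv"),
                           pixel_size = 0.16, frame_interval = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "auto") format <- guess_format(path)
  mat <- switch(format,
                tsv = read_kymo_tsv(path),
                tiff = read_kymo_tiff(path),
                png = read_kymo_png(path))
  kymograph(mat, pixel_size = pixel_size, frame_interval = frame_interval)
}

read_kymo_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty TSV kymograph: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged TSV matrix in %s: row %d has %d entries, expected %d",
                 path, bad, widths[bad], widths[1L]))
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  nas <- vapply(vals, anyNA, logical(1L))
  if (any(nas)) {
    stop(sprintf("non-numeric entry in %s at row %d", path, which(nas)[1L]))
  }
  do.call(rbind, vals)
}

read_kymo_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  check_gray <- function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] == 1L) return(p[, , 1L])
      stop("RGB/multi-channel TIFF is not a kymograph: ", path)
    }
    p
  }
  pages <- lapply(pages, check_gray)
  if (length(pages) == 1L) {
    mat <- pages[[1L]]
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  } else {
    line_frames <- vapply(pages, function(p) is.null(dim(p)) || nrow(p) == 1L,
                          logical(1L))
    if (!all(line_frames)) {
      stop("multi-page TIFF with 2D frames is a raw movie, not a kymograph: ",
           path)
    }
    rows <- lapply(pages, function(p) as.numeric(p))
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      stop("TIFF stack frames differ in width: ", path)
    }
    mat <- do.call(rbind, rows)
  }
  mat <- apply_scaling_sidecar(mat, path)
  mat
}

read_kymo_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] > 1L) stop("RGB PNG is not a kymograph: ", path)
    img <- img[, , 1L]
  }
  apply_scaling_sidecar(img * 255, path)
}

sidecar_path <- function(path) paste0(path, ".json")

apply_scaling_sidecar <- function(mat, path) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$scale_min) && !is.null(meta$scale_max)) {
      mat <- mat / meta$scale_levels * (meta$scale_max - meta$scale_min) +
        meta$scale_min
    }
  }
  mat
}

#' Write a kymograph to file
#'
#' TSV output is lossless: values are printed with 17 significant digits, so a
#' read/write round trip reproduces every double bit-for-bit. TIFF output is
#' 16-bit and PNG 8-bit, after min--max linear scaling (camera units are
#' arbitrary, so no fixed scale exists); the scaling is recorded in a JSON sidecar
#' `<path>.json` that [read_kymograph()] uses to restore the original units.
#'
#' @param kymo A [kymograph] (or plain matrix).
#' @param path Destination path.
#' @param format One of `"tsv"`, `"tiff"`, `"png"`.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path, format = c("tsv", "tiff", "png")) {
  format <- match.arg(format)
  kymo <- as_kymograph(kymo)
  mat <- kymo$intensity
  switch(format,
         tsv = {
           lines <- apply(mat, 1L, function(row) {
             paste(sprintf("%.17g", row), collapse = "\t")
           })
           writeLines(lines, path)
         },
         tiff = {
           sc <- scale_to_unit(mat)
           tiff::writeTIFF(sc$img, path, bits.per.sample = 16L)
           write_scaling_sidecar(sc, path, levels = 65535)
         },
         png = {
           sc <- scale_to_unit(mat)
           png::writePNG(sc$img, path)
           write_scaling_sidecar(sc, path, levels = 255)
         })
  invisible(path)
}

scale_to_unit <- function(mat) {
  lo <- min(mat); hi <- max(mat)
  img <- if (hi > lo) (mat - lo) / (hi - lo) else matrix(0, nrow(mat), ncol(mat))
  list(img = img, lo = lo, hi = hi)
}

write_scaling_sidecar <- function(sc, path, levels) {
  jsonlite::write_json(
    list(scale_min = sc$lo, scale_max = sc$hi, scale_levels = levels),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
}
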