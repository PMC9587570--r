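#' Read a grayscale image
#'
#' Reads a PNG or TIFF raster and returns it as a numeric matrix of 8-bit
#' intensities. Pixels are addressed as `img[row, col]`, row 1 at the top,
#' column 1 at the left. Multi-channel images are collapsed to luminance
#' (Rec. 709 weights); an alpha channel, if present, is dropped. Images
#' stored at higher bit depth are rescaled to the `[0, 255]` range with a
#' warning.
#'
#' @param path Path to a PNG (`.png`) or TIFF (`.tif`, `.tiff`) file.
#' @return A numeric matrix with values in `[0, 255]`.
#' @examples
#' m <- matrix(c(0, 255, 128, 64), 2, 2)
#' f <- tempfile(fileext = ".png")
#' write_gray(m, f)
#' all.equal(read_gray(f), m)
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) {
    stop_angio(sprintf("file not found: %s", path), "angiotrace_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = {
        if (!requireNamespace("tiff", quietly = TRUE)) {
          stop_angio("the 'tiff' package is required to read TIFF files",
                     "angiotrace_io_error")
        }
        tiff::readTIFF(path)
      },
      stop_angio(sprintf("unsupported image format: '%s'", ext),
                 "angiotrace_format_error")
    ),
    error = function(e) {
      if (inherits(e, "angiotrace_error")) stop(e)
      stop_angio(sprintf("cannot decode %s: %s", path, conditionMessage(e)),
                 "angiotrace_io_error")
    }
  )
  if (length(arr) == 0L) {
    stop_angio(sprintf("zero-sized image: %s", path), "angiotrace_format_error")
  }
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    arr <- if (nc >= 3L) {
      0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  img <- arr * 255
  if (max(img) > 255) {          # 16-bit source decoded on a wider scale
    warning("rescaling high bit-depth image to [0, 255]")
    img <- img / max(img) * 255
  }
  round(img)
}

#' Write a grayscale image
#'
#' Writes a `[0, 255]` intensity matrix as an 8-bit grayscale PNG.
#'
#' @param img Numeric matrix with values in `[0, 255]`.
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  assert_gray(img)
  ok <- tryCatch({
    png::writePNG(round(img) / 255, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_angio(sprintf("cannot write %s", path), "angiotrace_io_error")
  invisible(path)
}

#' Write a binary vessel mask
#'
#' Stores a vessel mask as an 8-bit grayscale PNG with vessel pixels black
#' (0) and background white (255), matching the display convention for
#' binarised angiograms. `read_mask(write_mask(m))` round-trips exactly.
#'
#' @param mask Logical matrix; `TRUE` marks vessel pixels.
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  write_gray(ifelse(mask, 0, 255), path)
}

#' Read a binary vessel mask
#'
#' Reads a two-valued raster written by [write_mask()]: pixels strictly
#' below 128 are vessel, the rest background.
#'
#' @param path Path to the mask raster.
#' @return Logical matrix; `TRUE` marks vessel pixels.
#' @export
read_mask <- function(path) {
  read_gray(path) < 128
}

#' Count vessel and background pixels
#'
#' Tallies the black (vessel) and white (background) pixel populations of a
#' mask, the per-image accounting used to compare segmentation strategies.
#'
#' @param mask Logical matrix; `TRUE` marks vessel pixels.
#' @return Named integer vector with elements `vessel` and `background`;
#'   the two always sum to `nrow(mask) * ncol(mask)`.
#' @export
count_mask_pixels <- function(mask) {
  assert_mask(mask)
  v <- sum(mask)
  c(vessel = v, background = length(mask) - v)
}
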