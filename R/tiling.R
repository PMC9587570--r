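#' Partition an image into a grid of square tiles
#'
#' Divides a grayscale image into non-overlapping `tile_size` x `tile_size`
#' subimages. A 512 x 512 angiogram at the default tile size yields the
#' 16 x 16 grid on which tile classification and regional parameter
#' expansion operate. Dimensions must divide exactly: the pipeline's pixel
#' accounting assumes no padding.
#'
#' @param img Numeric intensity matrix (`[0, 255]`).
#' @param tile_size Side length of each tile in pixels (default 32).
#' @return A `tile_grid` object: a list with elements `image`, `tile_size`,
#'   `n_rows`, `n_cols` and `labels`, an `n_rows` x `n_cols` character
#'   matrix over `"unknown"`, `"vascular"`, `"nonvascular"` (all
#'   `"unknown"` initially).
#' @seealso [classify_tiles()], [segment_rpe()]
#' @export
tile_image <- function(img, tile_size = 32L) {
  assert_gray(img)
  tile_size <- as.integer(tile_size)
  if (tile_size < 1L) {
    stop_angio("`tile_size` must be a positive integer", "angiotrace_argument_error")
  }
  h <- nrow(img); w <- ncol(img)
  if (h %% tile_size != 0L || w %% tile_size != 0L) {
    stop_angio(sprintf(
      "image dimensions %d x %d are not divisible by tile_size %d",
      h, w, tile_size), "angiotrace_dimension_error")
  }
  n_rows <- h %/% tile_size
  n_cols <- w %/% tile_size
  structure(list(
    image = img,
    tile_size = tile_size,
    n_rows = n_rows,
    n_cols = n_cols,
    labels = matrix("unknown", n_rows, n_cols)
  ), class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles of %d px (image %d x %d)\n",
              x$n_rows, x$n_cols, x$tile_size, nrow(x$image), ncol(x$image)))
  tab <- table(factor(x$labels, c("vascular", "nonvascular", "unknown")))
  cat(sprintf("  labels: %d vascular, %d nonvascular, %d unknown\n",
              tab[["vascular"]], tab[["nonvascular"]], tab[["unknown"]]))
  invisible(x)
}

# Pixel-index ranges (1-based) of tile (i, j), i/j 1-based tile coordinates.
tile_pixel_rows <- function(grid, i) ((i - 1L) * grid$tile_size + 1L):(i * grid$tile_size)
tile_pixel_cols <- function(grid, j) ((j - 1L) * grid$tile_size + 1L):(j * grid$tile_size)

#' Extract the pixels of one tile
#'
#' @param grid A `tile_grid`.
#' @param i,j Tile coordinates, 1-based.
#' @return Numeric matrix of the tile's pixels.
#' @export
tile_pixels <- function(grid, i, j) {
  check_tile_index(grid, i, j)
  grid$image[tile_pixel_rows(grid, i), tile_pixel_cols(grid, j), drop = FALSE]
}

check_tile_index <- function(grid, i, j) {
  if (length(i) != 1L || length(j) != 1L ||
      i < 1L || i > grid$n_rows || j < 1L || j > grid$n_cols) {
    stop_angio(sprintf("tile index (%s, %s) outside %d x %d grid",
                       toString(i), toString(j), grid$n_rows, grid$n_cols),
               "angiotrace_index_error")
  }
  invisible(NULL)
}

#' Tiles in the 3 x 3 neighbourhood of a tile
#'
#' Returns the tile itself plus its up-to-eight adjacent tiles, clipped at
#' the grid border. This block is the region into which a vascular tile's
#' intensity threshold is expanded.
#'
#' @param grid A `tile_grid`.
#' @param i,j Tile coordinates, 1-based.
#' @return Two-column integer matrix (`i`, `j`) of the in-bounds tiles of
#'   the 3 x 3 block centred on `(i, j)`, in row-major order.
#' @export
tile_neighborhood <- function(grid, i, j) {
  check_tile_index(grid, i, j)
  ii <- max(1L, i - 1L):min(grid$n_rows, i + 1L)
  jj <- max(1L, j - 1L):min(grid$n_cols, j + 1L)
  out <- as.matrix(expand.grid(j = jj, i = ii))[, c("i", "j"), drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

# Pixel-index ranges of the clipped 3x3 tile block centred on (i, j).
block_pixel_rows <- function(grid, i) {
  (max(1L, i - 1L) * grid$tile_size - grid$tile_size + 1L):(min(grid$n_rows, i + 1L) * grid$tile_size)
}
block_pixel_cols <- function(grid, j) {
  (max(1L, j - 1L) * grid$tile_size - grid$tile_size + 1L):(min(grid$n_cols, j + 1L) * grid$tile_size)
}
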