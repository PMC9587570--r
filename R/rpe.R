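#' Exact two-cluster intensity threshold
#'
#' Splits an intensity sample into a dark and a bright cluster by exact
#' one-dimensional two-means: in one dimension the optimal two-cluster
#' partition is a cut point in the sorted sample, so the global
#' within-cluster sum-of-squares optimum is found by scanning every cut
#' with prefix sums. The returned threshold `delta` is the midpoint of the
#' two cluster means, which in one dimension is exactly the
#' nearest-centre assignment boundary. The result is deterministic; there
#' is no seeding or initialisation as in Lloyd-style k-means.
#'
#' @param values Numeric vector of intensities (at least two distinct
#'   values).
#' @return An `rpe_threshold` object: list with `delta` (cut point),
#'   `center_dark`, `center_bright` (cluster means, `center_dark < delta <
#'   center_bright`) and `sse` (the optimal within-cluster sum of squares).
#' @examples
#' kmeans2_threshold(c(0, 0, 255, 255))$delta  # 127.5
#' @export
kmeans2_threshold <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop_angio("need at least two non-missing values", "angiotrace_argument_error")
  }
  x <- sort(values)
  n <- length(x)
  if (x[1] == x[n]) {
    stop_angio("all intensities identical: no two-cluster structure",
               "angiotrace_degeneracy_error")
  }
  cs <- cumsum(x)
  cs2 <- cumsum(x * x)
  k <- seq_len(n - 1L)                       # cut after position k
  sse_lo <- cs2[k] - cs[k]^2 / k
  sse_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  sse <- sse_lo + sse_hi
  best <- which.min(sse)                     # first optimum on ties
  mu_lo <- cs[best] / best
  mu_hi <- (cs[n] - cs[best]) / (n - best)
  structure(list(
    delta = (mu_lo + mu_hi) / 2,
    center_dark = mu_lo,
    center_bright = mu_hi,
    sse = sse[best]
  ), class = "rpe_threshold")
}

#' @export
print.rpe_threshold <- function(x, ...) {
  cat(sprintf("<rpe_threshold> delta = %.2f (dark %.2f | bright %.2f)\n",
              x$delta, x$center_dark, x$center_bright))
  invisible(x)
}

#' Segment vessels by regional parameter expansion
#'
#' Binarises the vessel regions of a tiled, classified image. For every
#' tile labelled vascular, a two-cluster threshold is computed and applied
#' over the clipped 3 x 3 block of tiles centred on it; the per-tile masks
#' are unioned. Three strategies are available:
#'
#' * `"flood_fill"` (default, the method proper): the centre tile's
#'   threshold `delta` seeds a flood fill. Seeds are the centre tile's
#'   pixels darker than `delta`; the fill grows 8-connected through any
#'   block pixel darker than `delta`. Dark structure in neighbour tiles
#'   that is not connected to the centre tile's vessel pixels is left out,
#'   which is what suppresses background noise.
#' * `"merged_block"`: the block's pixels are pooled, one threshold is
#'   computed from the pool, and the whole block is thresholded.
#' * `"single_tile"`: every tile of the block is thresholded independently
#'   with its own per-tile threshold. This forces a two-cluster split even
#'   on tiles that contain no vessel, and is the noisiest strategy.
#'
#' Ties at the threshold go to background (`intensity < delta` is vessel).
#' Tiles with constant intensity have no two-cluster structure and
#' contribute nothing; they are recorded in the `degenerate` attribute.
#'
#' @param grid A `tile_grid` with no `"unknown"` labels (see
#'   [classify_tiles()]).
#' @param strategy One of `"flood_fill"`, `"merged_block"`,
#'   `"single_tile"`.
#' @param tile_order Optional permutation of the vascular tile indices
#'   (row-major rank), mainly for testing that the union is
#'   order-independent.
#' @return Logical mask (`TRUE` = vessel) of the image's size, with
#'   attributes `deltas` (per-tile thresholds used, named `"i,j"`) and
#'   `degenerate` (tiles skipped for constant intensity).
#' @export
segment_rpe <- function(grid, strategy = c("flood_fill", "merged_block", "single_tile"),
                        tile_order = NULL) {
  strategy <- match.arg(strategy)
  if (!inherits(grid, "tile_grid")) {
    stop_angio("`grid` must be a tile_grid", "angiotrace_argument_error")
  }
  if (any(grid$labels == "unknown")) {
    stop_angio("all tiles must be labelled before segmentation; run classify_tiles()",
               "angiotrace_argument_error")
  }
  img <- grid$image
  mask <- matrix(FALSE, nrow(img), ncol(img))
  vasc <- which(t(grid$labels) == "vascular")  # row-major rank over (i, j)
  if (!is.null(tile_order)) vasc <- vasc[tile_order]
  deltas <- numeric(0)
  degen <- character(0)
  for (v in vasc) {
    i <- (v - 1L) %/% grid$n_cols + 1L
    j <- (v - 1L) %% grid$n_cols + 1L
    rows <- block_pixel_rows(grid, i)
    cols <- block_pixel_cols(grid, j)
    block <- img[rows, cols, drop = FALSE]
    key <- sprintf("%d,%d", i, j)
    if (strategy == "single_tile") {
      # each tile of the block gets its own threshold
      for (nb in seq_len(nrow(tile_neighborhood(grid, i, j)))) {
        tn <- tile_neighborhood(grid, i, j)[nb, ]
        px <- tile_pixels(grid, tn[1], tn[2])
        th <- tryCatch(kmeans2_threshold(px), angiotrace_degeneracy_error = function(e) NULL)
        if (is.null(th)) { degen <- c(degen, sprintf("%d,%d", tn[1], tn[2])); next }
        r2 <- tile_pixel_rows(grid, tn[1]); c2 <- tile_pixel_cols(grid, tn[2])
        mask[r2, c2] <- mask[r2, c2] | (img[r2, c2, drop = FALSE] < th$delta)
        if (tn[1] == i && tn[2] == j) deltas[key] <- th$delta
      }
    } else if (strategy == "merged_block") {
      th <- tryCatch(kmeans2_threshold(block), angiotrace_degeneracy_error = function(e) NULL)
      if (is.null(th)) { degen <- c(degen, key); next }
      deltas[key] <- th$delta
      mask[rows, cols] <- mask[rows, cols] | (block < th$delta)
    } else {
      th <- tryCatch(kmeans2_threshold(tile_pixels(grid, i, j)),
                     angiotrace_degeneracy_error = function(e) NULL)
      if (is.null(th)) { degen <- c(degen, key); next }
      deltas[key] <- th$delta
      cand <- block < th$delta
      if (!any(cand)) next
      seed <- matrix(FALSE, length(rows), length(cols))
      sr <- tile_pixel_rows(grid, i) - rows[1] + 1L
      sc <- tile_pixel_cols(grid, j) - cols[1] + 1L
      seed[sr, sc] <- cand[sr, sc]
      if (!any(seed)) next
      lab <- label_components(cand, connectivity = 8L)
      keep <- unique(lab[seed])
      reach <- cand & matrix(lab %in% keep, nrow(lab), ncol(lab))
      mask[rows, cols] <- mask[rows, cols] | reach
    }
  }
  attr(mask, "deltas") <- deltas
  attr(mask, "degenerate") <- unique(degen)
  mask
}

#' Whole-image two-means baseline segmentation
#'
#' Thresholds the full image with a single global two-cluster cut, the
#' naive baseline that regional parameter expansion improves on: one
#' global threshold cannot follow uneven illumination, so it either eats
#' into the background or drops low-contrast vessel segments.
#'
#' @param img Numeric intensity matrix.
#' @return Logical mask (`TRUE` = vessel).
#' @export
segment_whole_image_kmeans <- function(img) {
  assert_gray(img)
  th <- kmeans2_threshold(img)
  img < th$delta
}
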