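#' Diameter profile along the main vessel path
#'
#' Walks the longest simple path of the main cover tree and records one
#' sample per cover: the cover's midpoint as position and its Euclidean
#' chord length as the local vessel diameter, in pixels. No physical
#' calibration is applied.
#'
#' @param main A non-empty `cover_tree`.
#' @return Data frame with columns `index`, `row`, `col` (midpoint,
#'   rounded to the nearest pixel), `direction` and `diameter_px`, ordered
#'   along the path from one end to the other.
#' @export
extract_profile <- function(main) {
  if (!inherits(main, "cover_tree") || tree_size(main) == 0L) {
    stop_angio("`main` must be a non-empty cover_tree", "angiotrace_novessel_error")
  }
  path <- tree_longest_path(main)
  cov <- main$covers[path, , drop = FALSE]
  data.frame(
    index = seq_along(path),
    row = round((cov$anchor_row + cov$end_row) / 2),
    col = round((cov$anchor_col + cov$end_col) / 2),
    direction = cov$direction,
    diameter_px = cov$length,
    row.names = NULL
  )
}

#' Write a diameter profile to CSV
#'
#' @param profile Data frame from [extract_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Fixed diverging palette, thin (red) to thick (blue); interpolated to the
# requested number of bins so overlays are comparable across runs.
DIAMETER_PALETTE <- c("#B2182B", "#EF8A62", "#FDDBC7", "#D1E5F0", "#67A9CF", "#2166AC")

#' Colour-code vessel diameter on the image
#'
#' Paints every cover of the main tree over the grayscale image, coloured
#' by which quantile bin of the tree's diameter distribution the cover
#' falls in, so diameter changes — stenoses in particular — are visible at
#' a glance. Pixels under no cover keep their grayscale value.
#'
#' @param img Numeric intensity matrix the mask came from.
#' @param main A `cover_tree`.
#' @param n_bins Number of diameter bins (default 5). Bin edges are
#'   quantiles of the cover lengths, so the scale adapts per image; with
#'   a constant-width vessel all covers share one colour.
#' @return An `height x width x 3` RGB array in `[0, 1]`, writable with
#'   `png::writePNG()`.
#' @export
colorize <- function(img, main, n_bins = 5L) {
  assert_gray(img)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop_angio("`n_bins` must be >= 1", "angiotrace_argument_error")
  base <- round(img) / 255
  out <- array(rep(base, 3L), c(nrow(img), ncol(img), 3L))
  if (is.null(main) || tree_size(main) == 0L) return(out)
  lens <- main$covers$length
  edges <- unique(stats::quantile(lens, probs = seq(0, 1, length.out = n_bins + 1L),
                                  names = FALSE, type = 7))
  nb <- max(1L, length(edges) - 1L)
  bins <- if (nb == 1L) rep(1L, length(lens)) else
    pmin(findInterval(lens, edges, rightmost.closed = TRUE), nb)
  pal <- grDevices::col2rgb(grDevices::colorRampPalette(DIAMETER_PALETTE)(nb)) / 255
  npix <- nrow(img) * ncol(img)
  for (q in seq_len(tree_size(main))) {
    px <- cover_pixels(main$covers[q, , drop = FALSE])
    lin <- px[, 1] + (px[, 2] - 1L) * nrow(img)
    col <- pal[, bins[q]]
    out[lin] <- col[1]
    out[lin + npix] <- col[2]
    out[lin + 2L * npix] <- col[3]
  }
  out
}
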