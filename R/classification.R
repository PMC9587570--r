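#' Tile classifiers
#'
#' The vascular/nonvascular tile decision is a pluggable stage: any
#' per-tile labelling source can drive the downstream segmentation. Three
#' kinds are provided.
#'
#' * `heuristic_classifier()` is the built-in reference rule, a
#'   deterministic stand-in for a learned patch classifier. A tile is
#'   vascular iff (a) its intensities support a non-degenerate two-cluster
#'   split, (b) the cluster centres are at least `min_contrast` gray
#'   levels apart, and (c) the dark-cluster pixel fraction lies within
#'   `[min_fraction, max_fraction]` — excluding tiles whose dark class is
#'   a sliver (too little vessel to threshold reliably) or dominates the
#'   tile (shadow, border, device).
#' * `oracle_classifier()` labels from a ground-truth mask: a tile is
#'   vascular iff its true vessel-pixel fraction is at least
#'   `min_fraction`. Used with phantoms to isolate downstream stages from
#'   classification error.
#' * `external_classifier()` reads per-tile labels from a CSV file with
#'   columns `i`, `j`, `label` (1-based tile coordinates; label
#'   `"vascular"`/`"nonvascular"` or 1/0), so an externally trained model
#'   can be slotted in.
#'
#' @param min_contrast Minimum separation of the two cluster centres, in
#'   gray levels (default 40).
#' @param min_fraction,max_fraction Admissible dark-class pixel fraction
#'   (defaults 0.05 and 0.80).
#' @param truth_mask Logical ground-truth mask, same size as the image.
#' @param path CSV file of per-tile labels.
#' @return A `tile_classifier` object.
#' @name tile_classifier
NULL

#' @rdname tile_classifier
#' @export
heuristic_classifier <- function(min_contrast = 40, min_fraction = 0.05,
                                 max_fraction = 0.80) {
  structure(list(kind = "heuristic",
                 params = list(min_contrast = min_contrast,
                               min_fraction = min_fraction,
                               max_fraction = max_fraction)),
            class = "tile_classifier")
}

#' @rdname tile_classifier
#' @export
oracle_classifier <- function(truth_mask, min_fraction = 0.05) {
  assert_mask(truth_mask, "truth_mask")
  structure(list(kind = "oracle",
                 params = list(truth_mask = truth_mask,
                               min_fraction = min_fraction)),
            class = "tile_classifier")
}

#' @rdname tile_classifier
#' @export
external_classifier <- function(path) {
  if (missing(path) || !file.exists(path)) {
    stop_angio("external classifier needs an existing label CSV",
               "angiotrace_config_error")
  }
  structure(list(kind = "external", params = list(path = path)),
            class = "tile_classifier")
}

#' @export
print.tile_classifier <- function(x, ...) {
  cat(sprintf("<tile_classifier> kind = %s\n", x$kind))
  invisible(x)
}

#' Score one tile with the heuristic rule
#'
#' Applies the built-in vascular-tile test (see [tile_classifier]) to one
#' tile's pixels and reports the intermediate quantities.
#'
#' @param pixels Numeric vector or matrix of the tile's intensities.
#' @param min_contrast,min_fraction,max_fraction Rule parameters, as in
#'   [heuristic_classifier()].
#' @return List with `label` (`"vascular"`/`"nonvascular"`) and
#'   `diagnostics` (separation, dark fraction, delta; `NA` when the tile
#'   is degenerate).
#' @export
heuristic_score <- function(pixels, min_contrast = 40, min_fraction = 0.05,
                            max_fraction = 0.80) {
  if (length(pixels) == 0L) {
    stop_angio("empty tile", "angiotrace_argument_error")
  }
  th <- tryCatch(kmeans2_threshold(pixels),
                 angiotrace_degeneracy_error = function(e) NULL,
                 angiotrace_argument_error = function(e) NULL)
  if (is.null(th)) {
    return(list(label = "nonvascular",
                diagnostics = list(separation = NA_real_, dark_fraction = NA_real_,
                                   delta = NA_real_)))
  }
  sep <- th$center_bright - th$center_dark
  frac <- mean(pixels < th$delta)
  ok <- sep >= min_contrast && frac >= min_fraction && frac <= max_fraction
  list(label = if (ok) "vascular" else "nonvascular",
       diagnostics = list(separation = sep, dark_fraction = frac,
                          delta = th$delta))
}

#' Label every tile of a grid
#'
#' Runs a classifier over all tiles; afterwards no tile is `"unknown"`.
#' Classification is deterministic given the grid and the classifier's
#' parameters.
#'
#' @param grid A `tile_grid`.
#' @param clf A `tile_classifier` (default: the heuristic with its default
#'   parameters).
#' @return The grid with `labels` filled in.
#' @export
classify_tiles <- function(grid, clf = heuristic_classifier()) {
  if (!inherits(grid, "tile_grid")) {
    stop_angio("`grid` must be a tile_grid", "angiotrace_argument_error")
  }
  if (!inherits(clf, "tile_classifier")) {
    stop_angio("`clf` must be a tile_classifier", "angiotrace_argument_error")
  }
  labs <- grid$labels
  if (clf$kind == "external") {
    tab <- utils::read.csv(clf$params$path, stringsAsFactors = FALSE)
    need <- c("i", "j", "label")
    if (!all(need %in% names(tab))) {
      stop_angio("label CSV must have columns i, j, label", "angiotrace_config_error")
    }
    labs[] <- "nonvascular"
    lab_chr <- ifelse(tab$label %in% c("vascular", "1", 1), "vascular", "nonvascular")
    for (k in seq_len(nrow(tab))) {
      check_tile_index(grid, tab$i[k], tab$j[k])
      labs[tab$i[k], tab$j[k]] <- lab_chr[k]
    }
  } else if (clf$kind == "oracle") {
    tm <- clf$params$truth_mask
    if (!all(dim(tm) == dim(grid$image))) {
      stop_angio("truth mask dimensions differ from the image",
                 "angiotrace_argument_error")
    }
    for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
      frac <- mean(tm[tile_pixel_rows(grid, i), tile_pixel_cols(grid, j)])
      labs[i, j] <- if (frac >= clf$params$min_fraction) "vascular" else "nonvascular"
    }
  } else {
    p <- clf$params
    for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
      labs[i, j] <- heuristic_score(tile_pixels(grid, i, j),
                                    p$min_contrast, p$min_fraction,
                                    p$max_fraction)$label
    }
  }
  grid$labels <- labs
  grid
}

#' Write per-tile labels to CSV
#'
#' Emits the grid's labels in the same `i, j, label` format that
#' [external_classifier()] accepts (1-based tile coordinates).
#'
#' @param grid A labelled `tile_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tile_labels <- function(grid, path) {
  idx <- expand.grid(i = seq_len(grid$n_rows), j = seq_len(grid$n_cols))
  idx <- idx[order(idx$i, idx$j), ]
  utils::write.csv(
    data.frame(i = idx$i, j = idx$j,
               label = grid$labels[cbind(idx$i, idx$j)]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
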