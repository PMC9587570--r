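# Internal helpers shared across modules: classed error conditions and
# connected-component labelling on logical pixel masks.

stop_angio <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "angiotrace_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' @noRd
is_binary_mask <- function(x) {
  is.matrix(x) && is.logical(x) && nrow(x) >= 1L && ncol(x) >= 1L
}

assert_mask <- function(mask, arg = "mask") {
  if (!is_binary_mask(mask)) {
    stop_angio(sprintf("`%s` must be a logical matrix (TRUE = vessel)", arg),
               "angiotrace_argument_error")
  }
  invisible(mask)
}

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img) || nrow(img) < 1L || ncol(img) < 1L) {
    stop_angio(sprintf("`%s` must be a numeric matrix", arg),
               "angiotrace_argument_error")
  }
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    stop_angio(sprintf("`%s` must hold intensities in [0, 255]", arg),
               "angiotrace_argument_error")
  }
  invisible(img)
}

# Label connected components of TRUE pixels. Returns an integer matrix,
# 0 for FALSE pixels, components numbered by first appearance in
# column-major order of `which()`. Connectivity 4 or 8.
label_components <- function(mask, connectivity = 4L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  id <- integer(h * w)
  id[idx] <- seq_len(n)
  r0 <- (idx - 1L) %% h
  c0 <- (idx - 1L) %/% h
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    r2 <- r0 + o[1]; c2 <- c0 + o[2]
    ok <- r2 >= 0L & r2 < h & c2 >= 0L & c2 < w
    nidx <- r2[ok] + c2[ok] * h + 1L
    keep <- mask[nidx]
    edges[[k]] <- cbind(id[idx[ok][keep]], id[nidx[keep]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(el) && nrow(el)) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  # renumber so that component ids follow first appearance in scan order
  first <- match(unique(memb), memb)
  ord <- order(first)
  renum <- integer(max(memb))
  renum[unique(memb)[ord]] <- seq_along(ord)
  lab[idx] <- renum[memb]
  lab
}

# Row-major scan order rank of 0-based (row, col) pixels.
scan_rank <- function(row, col, width) row * width + col
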