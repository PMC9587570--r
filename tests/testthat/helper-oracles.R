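# Independent oracles and geometric fixtures used across the test files.
# These deliberately use naive loops / explicit recursions so they share no
# code path with the implementation they check.

# Exhaustive 1-D two-cluster scan: try every cut in the sorted sample and
# compute both cluster SSEs with plain mean()/sum() arithmetic.
oracle_kmeans2_scan <- function(values) {
  x <- sort(values)
  n <- length(x)
  best <- list(sse = Inf)
  for (k in 1:(n - 1)) {
    lo <- x[1:k]; hi <- x[(k + 1):n]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < best$sse) {
      best <- list(sse = sse, mu_lo = mean(lo), mu_hi = mean(hi))
    }
  }
  best
}

# Stack-based 8-connected flood fill over `open` (logical matrix) from the
# TRUE pixels of `seeds`.
oracle_flood8 <- function(open, seeds) {
  h <- nrow(open); w <- ncol(open)
  visited <- matrix(FALSE, h, w)
  stack <- which(seeds & open)
  visited[stack] <- TRUE
  while (length(stack)) {
    p <- stack[length(stack)]; stack <- stack[-length(stack)]
    r <- (p - 1) %% h + 1; c <- (p - 1) %/% h + 1
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
          open[r2, c2] && !visited[r2, c2]) {
        visited[r2, c2] <- TRUE
        stack <- c(stack, (c2 - 1) * h + r2)
      }
    }
  }
  visited
}

# Per-pixel 4-neighbour boundary test by explicit loops.
oracle_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- NULL
  for (r in 1:h) for (c in 1:w) {
    if (!mask[r, c]) next
    nb <- c(
      if (r > 1) mask[r - 1, c] else FALSE,
      if (r < h) mask[r + 1, c] else FALSE,
      if (c > 1) mask[r, c - 1] else FALSE,
      if (c < w) mask[r, c + 1] else FALSE
    )
    if (!all(nb)) out <- rbind(out, c(r, c))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Re-walk one cover's ray pixel by pixel and check maximality.
oracle_cover_valid <- function(mask, cover) {
  steps <- list(E = c(0, 1), S = c(1, 0), N = c(-1, 0), SE = c(1, 1), NE = c(-1, 1))
  d <- steps[[cover$direction]]
  r <- cover$anchor_row; c <- cover$anchor_col
  for (k in seq_len(cover$span)) {
    if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask) || !mask[r, c]) return(FALSE)
    if (k < cover$span) { r <- r + d[1]; c <- c + d[2] }
  }
  if (r != cover$end_row || c != cover$end_col) return(FALSE)
  r2 <- r + d[1]; c2 <- c + d[2]   # pixel after the end must not be vessel
  !(r2 >= 1 && r2 <= nrow(mask) && c2 >= 1 && c2 <= ncol(mask) && mask[r2, c2])
}

# Axis-aligned or 45-degree bar masks spanning the frame.
make_bar_mask <- function(size, width, orientation = c("vertical", "horizontal", "diagonal")) {
  orientation <- match.arg(orientation)
  m <- matrix(FALSE, size, size)
  mid <- size %/% 2
  half_lo <- (width - 1) %/% 2
  half_hi <- width %/% 2
  if (orientation == "vertical") {
    m[, (mid - half_lo):(mid + half_hi)] <- TRUE
  } else if (orientation == "horizontal") {
    m[(mid - half_lo):(mid + half_hi), ] <- TRUE
  } else {
    for (r in 1:size) for (c in 1:size) {
      if (abs((r - c) / sqrt(2)) <= width / 2) m[r, c] <- TRUE
    }
  }
  m
}

# Vertical bar with +/-1 jagged edge noise on both sides.
make_jagged_bar <- function(size = 60, width = 9, seed = 42) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  mid <- size %/% 2
  for (r in 1:size) {
    lo <- mid - width %/% 2 + sample(-1:1, 1)
    hi <- lo + width - 1 + sample(-1:1, 1)
    m[r, lo:hi] <- TRUE
  }
  m
}

# U-shaped vessel (two vertical arms joined by a curved bottom).
make_u_mask <- function(size = 96, width = 9) {
  m <- matrix(FALSE, size, size)
  cx <- size / 2
  r0 <- size * 0.65
  rad <- size * 0.28
  for (t in seq(0, pi, length.out = 400)) {   # lower semicircle
    y <- r0 + rad * sin(t); x <- cx + rad * cos(t)
    m <- stamp_disk(m, y, x, width)
  }
  for (y in seq(1, r0, by = 1)) {             # arms
    m <- stamp_disk(m, y, cx - rad, width)
    m <- stamp_disk(m, y, cx + rad, width)
  }
  m
}

stamp_disk <- function(m, y, x, w) {
  h <- nrow(m); wd <- ncol(m); rad <- w / 2
  rr <- max(1, floor(y - rad)):min(h, ceiling(y + rad))
  cc <- max(1, floor(x - rad)):min(wd, ceiling(x + rad))
  d2 <- outer((rr - y)^2, (cc - x)^2, "+")
  m[rr, cc] <- m[rr, cc] | (d2 <= rad^2)
  m
}

# Pixels lying under any cover of a forest/tree, as a logical matrix.
covered_pixels_mask <- function(trees, dm) {
  if (inherits(trees, "cover_tree")) trees <- list(trees)
  m <- matrix(FALSE, dm[1], dm[2])
  for (tr in trees) {
    for (q in seq_len(tree_size(tr))) {
      cv <- tr$covers[q, ]
      steps <- list(E = c(0, 1), S = c(1, 0), N = c(-1, 0), SE = c(1, 1), NE = c(-1, 1))
      d <- steps[[cv$direction]]
      s <- seq_len(cv$span) - 1
      m[cbind(cv$anchor_row + s * d[1], cv$anchor_col + s * d[2])] <- TRUE
    }
  }
  m
}

# Circular variance of undirected cover orientations (axial data, mod 180).
circular_variance_axial <- function(angles_deg) {
  a <- 2 * angles_deg * pi / 180
  1 - sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}

# A grayscale image holding a dark bar on a bright background, plus the
# tile grid with all labels set from a given matrix position.
bar_image <- function(size = 96, width = 8, vessel = 50, background = 200) {
  img <- matrix(background, size, size)
  mid <- size %/% 2
  img[, (mid - (width - 1) %/% 2):(mid + width %/% 2)] <- vessel
  img
}
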