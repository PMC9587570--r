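# Optimal cover tree: chord casting across black regions, rule-constrained
# cover selection, spanning-tree construction over adjacent covers, main-tree
# retention and noise pruning.

# Direction table. A cover is a chord, so Rule-1 angles are undirected line
# orientations: E = 0, SE = 45, S/N = 90, NE = 135 degrees. Euclidean length
# per pixel step is 1 on the axes and sqrt(2) on the diagonals. `priority`
# fixes the tie-break order among equal-length candidates.
DIRECTION_TABLE <- data.frame(
  direction = c("E", "S", "N", "SE", "NE"),
  dr = c(0L, 1L, -1L, 1L, -1L),
  dc = c(1L, 0L, 0L, 1L, 1L),
  angle = c(0, 90, 90, 45, 135),
  step = c(1, 1, 1, sqrt(2), sqrt(2)),
  priority = 1:5,
  stringsAsFactors = FALSE
)

dir_meta <- function(direction) {
  DIRECTION_TABLE[match(direction, DIRECTION_TABLE$direction), , drop = FALSE]
}

# Minimum circular distance between undirected line orientations (mod 180).
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Cover-selection configuration
#'
#' Settings for casting and selecting covers. The default direction set is
#' the five chord directions down, up, right, down-right and up-right; the
#' reduced three-direction set (`"three"`: right, down, down-right) is the
#' ablation that fails to cover the underside of curved vessels. Rule 1
#' bounds the orientation change between consecutive covers
#' (`max_angle_step`, default 45 degrees); Rule 2 bounds the length change.
#' The length tolerance is `max(length_tolerance_abs,
#' length_tolerance_rel * previous length)` (`"hybrid"`, default), or a
#' running-window band of mean +/- 2 sd over the last `window` selected
#' lengths (`"window"`).
#'
#' @param directions `"five"`, `"three"`, or a character subset of
#'   `c("E","S","N","SE","NE")`.
#' @param rules_enabled Apply Rules 1-2 when chaining covers (default
#'   `TRUE`); with `FALSE` every selection is simply the shortest chord.
#' @param max_angle_step Rule-1 bound in degrees, in `(0, 90]`.
#' @param length_tolerance_abs,length_tolerance_rel Rule-2 hybrid bound
#'   components, in pixels and as a fraction of the previous length.
#' @param tolerance_mode `"hybrid"` or `"window"`.
#' @param window Window size for `"window"` mode.
#' @return A `cover_rules` list.
#' @export
cover_rules <- function(directions = "five", rules_enabled = TRUE,
                        max_angle_step = 45, length_tolerance_abs = 2,
                        length_tolerance_rel = 0.30,
                        tolerance_mode = c("hybrid", "window"), window = 5L) {
  if (identical(directions, "five")) directions <- c("E", "S", "N", "SE", "NE")
  if (identical(directions, "three")) directions <- c("E", "S", "SE")
  if (!length(directions) || !all(directions %in% DIRECTION_TABLE$direction)) {
    stop_angio("`directions` must be a non-empty subset of E, S, N, SE, NE",
               "angiotrace_argument_error")
  }
  if (max_angle_step <= 0 || max_angle_step > 90) {
    stop_angio("`max_angle_step` must lie in (0, 90]", "angiotrace_argument_error")
  }
  structure(list(
    directions = unique(directions),
    rules_enabled = isTRUE(rules_enabled),
    max_angle_step = max_angle_step,
    length_tolerance_abs = length_tolerance_abs,
    length_tolerance_rel = length_tolerance_rel,
    tolerance_mode = match.arg(tolerance_mode),
    window = as.integer(window)
  ), class = "cover_rules")
}

#' Boundary pixels of a mask in scan order
#'
#' Vessel pixels whose 4-neighbourhood is not entirely vessel (pixels on
#' the image border count as exposed), listed top-down, left-right from
#' the top-left pixel — the order in which the tracer visits a region's
#' edge.
#'
#' @param mask Logical vessel mask.
#' @return Two-column integer matrix (`row`, `col`), row-major order;
#'   zero rows when the mask is empty.
#' @export
scan_boundary_pixels <- function(mask) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  interior <- core &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  boundary <- core & !interior
  idx <- which(t(boundary))             # row-major
  if (!length(idx)) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  cbind(row = (idx - 1L) %/% w + 1L, col = (idx - 1L) %% w + 1L)
}

#' Cast candidate covers from a boundary pixel
#'
#' From an anchor vessel pixel, walks a ray in each configured direction
#' and records the maximal run of consecutive vessel pixels (the chord
#' across the black region). Directions whose ray leaves the region at the
#' first step are dropped; if every direction does (an isolated pixel),
#' all configured directions are returned with span 1. Rays clipped by the
#' image border do not witness a full edge-to-edge chord, so they are
#' likewise kept only when no unclipped chord exists (they are flagged in
#' the `truncated` column).
#'
#' @param mask Logical vessel mask.
#' @param anchor Integer `c(row, col)` of a vessel pixel.
#' @param cfg A [cover_rules()] configuration.
#' @return Data frame of candidate covers with columns `anchor_row`,
#'   `anchor_col`, `direction`, `span`, `length`, `end_row`, `end_col`.
#'   `length` is the Euclidean chord length: `span` on the axes,
#'   `span * sqrt(2)` on the diagonals.
#' @export
cast_covers <- function(mask, anchor, cfg = cover_rules()) {
  assert_mask(mask)
  r0 <- as.integer(anchor[1]); c0 <- as.integer(anchor[2])
  h <- nrow(mask); w <- ncol(mask)
  if (r0 < 1L || r0 > h || c0 < 1L || c0 > w || !mask[r0, c0]) {
    stop_angio("`anchor` must be a vessel pixel inside the mask",
               "angiotrace_argument_error")
  }
  meta <- dir_meta(cfg$directions)
  spans <- integer(nrow(meta))
  truncated <- logical(nrow(meta))
  for (k in seq_len(nrow(meta))) {
    dr <- meta$dr[k]; dc <- meta$dc[k]
    m <- h * w  # upper bound on steps
    if (dr > 0) m <- min(m, h - r0) else if (dr < 0) m <- min(m, r0 - 1L)
    if (dc > 0) m <- min(m, w - c0) else if (dc < 0) m <- min(m, c0 - 1L)
    if (m > 0L) {
      rr <- r0 + seq_len(m) * dr
      cc <- c0 + seq_len(m) * dc
      run <- mask[cbind(rr, cc)]
      stop_at <- which(!run)[1]
      spans[k] <- if (is.na(stop_at)) m + 1L else stop_at
      truncated[k] <- is.na(stop_at)
    } else {
      spans[k] <- 1L
      truncated[k] <- TRUE
    }
  }
  keep <- spans >= 2L & !truncated
  if (!any(keep)) keep <- spans >= 2L
  if (!any(keep)) keep <- rep(TRUE, length(spans))
  meta <- meta[keep, , drop = FALSE]
  data.frame(
    anchor_row = r0, anchor_col = c0,
    direction = meta$direction,
    span = spans[keep],
    length = spans[keep] * meta$step,
    end_row = r0 + (spans[keep] - 1L) * meta$dr,
    end_col = c0 + (spans[keep] - 1L) * meta$dc,
    truncated = truncated[keep],
    stringsAsFactors = FALSE
  )
}

# Shortest candidate with the fixed direction-priority tie-break.
shortest_candidate <- function(cand) {
  pr <- dir_meta(cand$direction)$priority
  cand[order(cand$length, pr)[1], , drop = FALSE]
}

#' Select the optimal cover among candidates
#'
#' Implements the chaining rules. With no previous cover (or rules
#' disabled) the shortest chord wins, ties broken by the fixed direction
#' priority E, S, N, SE, NE. Otherwise candidates are screened by Rule 1
#' (orientation change from the previous cover at most `max_angle_step`)
#' and Rule 2 (length change within the tolerance): the shortest
#' admissible candidate is taken, with equal-length ties resolved in
#' favour of the previous cover's direction, then by the fixed priority.
#' When no candidate is admissible, the previous direction is preferred
#' if still available, else the shortest candidate overall; either way
#' the selection is flagged as a fallback.
#'
#' The relative length tolerance must admit the `1 - 1/sqrt(2)` (about
#' 29 percent) length step between an oblique axial chord and the true
#' diagonal diameter of the same vessel, or the chain could never rotate
#' onto a 45-degree segment; hence the 0.30 default.
#'
#' @param candidates Data frame from [cast_covers()] (non-empty).
#' @param previous The previously selected cover (one-row data frame) or
#'   `NULL`.
#' @param cfg A [cover_rules()] configuration.
#' @param history Numeric vector of previously selected lengths in this
#'   region, used by the `"window"` tolerance mode.
#' @return One-row data frame: the selected cover, with an extra logical
#'   column `fallback` marking selections where no candidate satisfied
#'   both rules.
#' @export
select_cover <- function(candidates, previous = NULL, cfg = cover_rules(),
                         history = NULL) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop_angio("no candidate covers to select from", "angiotrace_argument_error")
  }
  pick <- function(row, fallback) { row$fallback <- fallback; row }
  if (is.null(previous) || !cfg$rules_enabled) {
    return(pick(shortest_candidate(candidates), FALSE))
  }
  prev_meta <- dir_meta(previous$direction)
  adiff <- angle_diff(dir_meta(candidates$direction)$angle, prev_meta$angle)
  if (cfg$tolerance_mode == "window" && length(history) >= 2L) {
    tail_len <- utils::tail(history, cfg$window)
    centre <- mean(tail_len)
    tol <- max(2 * stats::sd(tail_len), cfg$length_tolerance_abs)
  } else {
    centre <- previous$length
    tol <- max(cfg$length_tolerance_abs,
               cfg$length_tolerance_rel * previous$length)
  }
  admissible <- adiff <= cfg$max_angle_step & abs(candidates$length - centre) <= tol
  if (any(admissible)) {
    pool <- candidates[admissible, , drop = FALSE]
    ties <- pool[pool$length <= min(pool$length) + 1e-9, , drop = FALSE]
    same_dir <- ties$direction == previous$direction
    if (any(same_dir)) return(pick(ties[same_dir, , drop = FALSE], FALSE))
    return(pick(shortest_candidate(ties), FALSE))
  }
  same_dir <- candidates$direction == previous$direction
  if (any(same_dir)) {
    return(pick(candidates[same_dir, , drop = FALSE][1, , drop = FALSE], TRUE))
  }
  pick(shortest_candidate(candidates), TRUE)
}

# Pixel coordinates (matrix row, col) under one cover.
cover_pixels <- function(cover) {
  meta <- dir_meta(cover$direction)
  s <- seq_len(cover$span) - 1L
  cbind(row = cover$anchor_row + s * meta$dr,
        col = cover$anchor_col + s * meta$dc)
}

new_cover_tree <- function(covers, edges, regions, dim) {
  structure(list(covers = covers, edges = edges, regions = regions, dim = dim),
            class = "cover_tree")
}

#' @export
print.cover_tree <- function(x, ...) {
  cat(sprintf("<cover_tree> %d covers, longest path %d, %d region(s)\n",
              tree_size(x), tree_path_length(x), length(x$regions)))
  invisible(x)
}

#' Cover-tree size and longest path
#'
#' `tree_size()` is the number of covers (nodes); `tree_path_length()` the
#' number of nodes on the longest simple path through the tree;
#' `tree_longest_path()` the node indices along that path, in order.
#'
#' @param tree A `cover_tree`.
#' @return An integer (or integer vector for `tree_longest_path()`).
#' @export
tree_size <- function(tree) nrow(tree$covers)

#' @rdname tree_size
#' @export
tree_path_length <- function(tree) length(tree_longest_path(tree))

#' @rdname tree_size
#' @export
tree_longest_path <- function(tree) {
  n <- tree_size(tree)
  if (n == 1L) return(1L)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(tree$edges)) g <- igraph::add_edges(g, t(tree$edges))
  d1 <- igraph::distances(g, v = 1)
  u <- which.max(d1)
  du <- igraph::distances(g, v = u)
  v <- which.max(du)
  as.integer(igraph::shortest_paths(g, from = u, to = v)$vpath[[1]])
}

# Order a region's boundary pixels by following its outer contour
# (Moore-neighbour tracing, rotating through the down-left side first so the
# walk heads downward/rightward from the top-left pixel), then any inner
# (hole) boundary pixels in scan order. `bp` holds the region's boundary
# pixels in scan order; its first row is the topmost-leftmost pixel, whose
# west neighbour is guaranteed outside the region.
region_boundary_order <- function(lab, reg, bp) {
  if (nrow(bp) == 1L) return(bp)
  h <- nrow(lab); w <- ncol(lab)
  offs <- rbind(c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L),
                c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  off_index <- function(dr, dc) which(offs[, 1] == dr & offs[, 2] == dc)
  start <- bp[1, ]
  cur <- start
  back <- 1L                       # backtrack direction: west
  # stop on returning to the start state; the iteration bound covers shapes
  # where the re-entry backtrack differs (any pixels missed in that case are
  # appended in scan order below, so only the visit order is affected)
  maxit <- 4L * nrow(bp) + 64L
  path_r <- integer(0); path_c <- integer(0)
  for (it in seq_len(maxit)) {
    if (it > 1L && cur[1] == start[1] && cur[2] == start[2] && back == 1L) break
    path_r <- c(path_r, cur[1]); path_c <- c(path_c, cur[2])
    nxt <- NULL
    for (k in 0:7) {
      idx <- (back - 1L + k) %% 8L + 1L
      r2 <- cur[1] + offs[idx, 1]; c2 <- cur[2] + offs[idx, 2]
      if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w && lab[r2, c2] == reg) {
        prev_idx <- (idx - 2L) %% 8L + 1L   # neighbour examined just before
        br <- cur[1] + offs[prev_idx, 1]; bc <- cur[2] + offs[prev_idx, 2]
        back <- off_index(br - r2, bc - c2)
        nxt <- c(r2, c2)
        break
      }
    }
    if (is.null(nxt)) break        # isolated pixel
    cur <- nxt
  }
  path <- cbind(path_r, path_c)
  key <- function(m) (m[, 2] - 1L) * h + m[, 1]
  path <- path[!duplicated(key(path)), , drop = FALSE]
  on_contour <- key(path) %in% key(bp)
  rest <- !(key(bp) %in% key(path))
  out <- rbind(path[on_contour, , drop = FALSE], bp[rest, , drop = FALSE])
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

#' Build cover trees over every black region
#'
#' Scans the mask top-down, left-right. Each 4-connected black region is
#' traversed once: starting from its first boundary pixel in scan order,
#' the walk follows the region's outer contour (heading downward, then
#' rightward, the way a region edge is naturally traced from its top-left
#' pixel), visiting inner hole boundaries afterwards in scan order. At
#' every boundary pixel not already lying under a selected cover, a cover
#' is cast and selected, each selection chained (Rules 1-2) to the
#' previous one. Covers cast from the near edge of a vessel cross the
#' region and mark the far edge as covered, so the far edge — from which
#' only oblique chords could be cast — is skipped. The region's covers
#' form one spanning tree whose edges follow the selection chain; every
#' region ends up with at least one cover. The result is deterministic.
#'
#' @param mask Logical vessel mask.
#' @param cfg A [cover_rules()] configuration.
#' @return List of `cover_tree` objects (empty list for an empty mask),
#'   ordered by first boundary pixel in scan order. Each tree's `covers`
#'   data frame keeps the per-selection `truncated` and `fallback` flags;
#'   the tree carries the label ids (`regions`) of the 4-connected
#'   components its covers touch and an attribute `fallbacks`, the number
#'   of rule-fallback selections.
#' @export
build_cover_forest <- function(mask, cfg = cover_rules()) {
  assert_mask(mask)
  lab <- label_components(mask, connectivity = 4L)
  bp <- scan_boundary_pixels(mask)
  if (!nrow(bp)) return(list())
  region_of <- lab[bp]                      # component id per boundary pixel
  region_order <- unique(region_of)         # by first appearance in scan order
  covered <- matrix(FALSE, nrow(mask), ncol(mask))
  forest <- vector("list", length(region_order))
  for (t in seq_along(region_order)) {
    reg <- region_order[t]
    pix <- region_boundary_order(lab, reg, bp[region_of == reg, , drop = FALSE])
    covers <- list()
    prev <- NULL
    history <- numeric(0)
    n_fallback <- 0L
    for (k in seq_len(nrow(pix))) {
      if (covered[pix[k, 1], pix[k, 2]]) next
      cand <- cast_covers(mask, pix[k, ], cfg)
      sel <- select_cover(cand, prev, cfg, history)
      n_fallback <- n_fallback + as.integer(sel$fallback)
      covers[[length(covers) + 1L]] <- sel
      covered[cover_pixels(sel)] <- TRUE
      prev <- sel
      history <- c(history, sel$length)
    }
    if (!length(covers)) next   # fully covered by a ray crossing from a neighbour
    covers <- do.call(rbind, covers)
    n <- nrow(covers)
    edges <- if (n > 1L) cbind(seq_len(n - 1L), 2:n) else matrix(integer(0), 0, 2)
    regions <- sort(unique(lab[do.call(rbind, lapply(seq_len(n), function(q)
      cover_pixels(covers[q, , drop = FALSE])))]))
    regions <- regions[regions > 0L]
    tr <- new_cover_tree(covers, edges, regions, dim(mask))
    attr(tr, "fallbacks") <- n_fallback
    forest[[t]] <- tr
  }
  forest[!vapply(forest, is.null, TRUE)]
}

#' Merge trees whose covers touch
#'
#' Two trees are merged when any pixel of one tree's covers is 8-adjacent
#' to (or coincides with) a pixel of the other's — regions touching only
#' diagonally are still one vessel. Merging is transitive and idempotent;
#' each group of mutually adjacent trees becomes a single tree, connected
#' by one edge per adjacency used, so the result stays acyclic.
#'
#' @param forest List of `cover_tree` objects over the same mask.
#' @return List of merged `cover_tree` objects.
#' @export
merge_adjacent_trees <- function(forest) {
  nt <- length(forest)
  if (nt <= 1L) return(forest)
  dm <- forest[[1]]$dim
  h <- dm[1]; w <- dm[2]
  tid <- matrix(0L, h, w)       # owning tree per cover pixel (last writer)
  cid <- matrix(0L, h, w)       # cover index within that tree
  contacts <- list()            # rows: treeA, treeB, coverA, coverB
  pix_by_tree <- vector("list", nt)
  for (t in seq_len(nt)) {
    cov <- forest[[t]]$covers
    px <- do.call(rbind, lapply(seq_len(nrow(cov)), function(q) {
      p <- cover_pixels(cov[q, , drop = FALSE]); cbind(p, cover = q)
    }))
    pix_by_tree[[t]] <- px
    lin <- px[, 1] + (px[, 2] - 1L) * h
    clash <- tid[lin] != 0L & tid[lin] != t
    if (any(clash)) {
      contacts[[length(contacts) + 1L]] <-
        cbind(tid[lin][clash], t, cid[lin][clash], px[clash, 3])
    }
    tid[lin] <- t
    cid[lin] <- px[, 3]
  }
  offs <- rbind(c(-1L,-1L), c(-1L,0L), c(-1L,1L), c(0L,-1L),
                c(0L,1L), c(1L,-1L), c(1L,0L), c(1L,1L))
  for (t in seq_len(nt)) {
    px <- pix_by_tree[[t]]
    for (o in seq_len(nrow(offs))) {
      r2 <- px[, 1] + offs[o, 1]; c2 <- px[, 2] + offs[o, 2]
      ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
      if (!any(ok)) next
      lin <- r2[ok] + (c2[ok] - 1L) * h
      other <- tid[lin]
      hit <- other != 0L & other != t
      if (any(hit)) {
        contacts[[length(contacts) + 1L]] <-
          cbind(t, other[hit], px[ok, 3][hit], cid[lin][hit])
      }
    }
  }
  if (!length(contacts)) return(forest)
  con <- do.call(rbind, contacts)
  # tree-level graph; keep one connecting cover pair per used adjacency
  g <- igraph::make_empty_graph(nt, directed = FALSE)
  key <- paste(pmin(con[, 1], con[, 2]), pmax(con[, 1], con[, 2]))
  first <- !duplicated(key)
  con1 <- con[first, , drop = FALSE]
  g <- igraph::add_edges(g, t(con1[, 1:2, drop = FALSE]))
  g <- igraph::simplify(g)
  memb <- igraph::components(g)$membership
  groups <- split(seq_len(nt), memb)
  groups <- groups[order(vapply(groups, min, 1L))]
  # spanning tree of each group's adjacency graph picks the connector edges
  mst <- igraph::mst(igraph::graph_from_edgelist(con1[, 1:2, drop = FALSE],
                                                 directed = FALSE))
  mst_edges <- igraph::as_edgelist(mst)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    members <- sort(groups[[gi]])
    if (length(members) == 1L) { out[[gi]] <- forest[[members]]; next }
    offset <- c(0L, cumsum(vapply(members, function(t) tree_size(forest[[t]]), 1L)))
    names(offset) <- c(as.character(members), "end")
    covers <- do.call(rbind, lapply(members, function(t) forest[[t]]$covers))
    edges <- do.call(rbind, lapply(seq_along(members), function(mi) {
      e <- forest[[members[mi]]]$edges
      if (nrow(e)) e + offset[mi] else e
    }))
    fall <- sum(vapply(members, function(t) attr(forest[[t]], "fallbacks"), 1L))
    # connector edges from the spanning tree of the adjacency graph
    for (e in seq_len(nrow(mst_edges))) {
      a <- mst_edges[e, 1]; b <- mst_edges[e, 2]
      if (!(a %in% members && b %in% members)) next
      row <- con1[(con1[, 1] == a & con1[, 2] == b) |
                  (con1[, 1] == b & con1[, 2] == a), , drop = FALSE][1, ]
      ia <- offset[as.character(row[1])] + row[3]
      ib <- offset[as.character(row[2])] + row[4]
      edges <- rbind(edges, cbind(ia, ib))
    }
    regions <- sort(unique(unlist(lapply(members, function(t) forest[[t]]$regions))))
    tr <- new_cover_tree(covers, unname(edges), regions, dm)
    attr(tr, "fallbacks") <- fall
    out[[gi]] <- tr
  }
  out
}

#' Retain the main vessel tree
#'
#' Picks the tree with the longest path (most covers on a simple path);
#' ties go to the larger tree, then to the tree whose earliest cover
#' anchor comes first in scan order. Everything else is treated as noise.
#'
#' @param forest Non-empty list of `cover_tree` objects.
#' @return The selected `cover_tree`.
#' @export
select_main_tree <- function(forest) {
  if (!length(forest)) {
    stop_angio("no cover trees: mask contains no vessel", "angiotrace_novessel_error")
  }
  pl <- vapply(forest, tree_path_length, 1L)
  sz <- vapply(forest, tree_size, 1L)
  first_anchor <- vapply(forest, function(tr) {
    min(scan_rank(tr$covers$anchor_row - 1L, tr$covers$anchor_col - 1L, tr$dim[2]))
  }, 1)
  ord <- order(-pl, -sz, first_anchor)
  forest[[ord[1]]]
}

#' Remove black regions not covered by the main tree
#'
#' Vessel pixels whose 4-connected region holds no cover of the retained
#' tree become background: disconnected blobs, guidewires and other
#' devices disappear — as does any genuine vessel that is not connected
#' to the main one, the documented cost of keeping a single tree.
#'
#' @param mask The mask the tree was built from.
#' @param main A `cover_tree` (or list of trees, when keeping more than
#'   one).
#' @return Pruned logical mask.
#' @export
prune_mask <- function(mask, main) {
  assert_mask(mask)
  trees <- if (inherits(main, "cover_tree")) list(main) else main
  if (!length(trees)) return(mask & FALSE)
  if (any(dim(mask) != trees[[1]]$dim)) {
    stop_angio("`main` was not built from this mask (dimension mismatch)",
               "angiotrace_argument_error")
  }
  lab <- label_components(mask, connectivity = 4L)
  keep <- unique(unlist(lapply(trees, function(tr) {
    unlist(lapply(seq_len(tree_size(tr)), function(q)
      lab[cover_pixels(tr$covers[q, , drop = FALSE])]))
  })))
  keep <- keep[keep > 0L]
  if (!length(keep)) {
    stop_angio("`main` covers no vessel pixel of this mask",
               "angiotrace_argument_error")
  }
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Serialise a cover forest to JSON
#'
#' Writes each tree as a list of nodes `{anchor: [row, col], direction,
#' span, length, end: [row, col]}` (1-based pixel coordinates) plus its
#' edge list, so a traced result can be reloaded or inspected without the
#' package.
#'
#' @param forest List of `cover_tree` objects (a single tree is wrapped).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cover_forest <- function(forest, path) {
  if (inherits(forest, "cover_tree")) forest <- list(forest)
  payload <- lapply(forest, function(tr) {
    list(
      nodes = lapply(seq_len(tree_size(tr)), function(q) {
        cv <- tr$covers[q, ]
        list(anchor = c(cv$anchor_row, cv$anchor_col),
             direction = cv$direction, span = cv$span, length = cv$length,
             end = c(cv$end_row, cv$end_col))
      }),
      edges = if (nrow(tr$edges)) unname(apply(tr$edges, 1, c, simplify = FALSE)) else list(),
      regions = tr$regions
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
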