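test_that("two-point and degenerate samples behave as specified", {
  th <- kmeans2_threshold(c(0, 0, 255, 255))
  expect_equal(th$center_dark, 0)
  expect_equal(th$center_bright, 255)
  expect_equal(th$delta, 127.5)
  expect_error(kmeans2_threshold(c(10, 10, 10)),
               class = "angiotrace_degeneracy_error")
  expect_error(kmeans2_threshold(numeric(0)), class = "angiotrace_argument_error")
})

test_that("threshold invariants hold on random samples", {
  set.seed(31)
  for (k in 1:25) {
    x <- sample(0:255, 200, replace = TRUE)
    if (length(unique(x)) < 2) next
    th <- kmeans2_threshold(x)
    expect_lt(th$center_dark, th$delta)
    expect_gt(th$center_bright, th$delta)
    expect_equal(th$delta, (th$center_dark + th$center_bright) / 2)
  }
})

test_that("the threshold attains the exhaustive cut-scan optimum on bimodal draws", {
  set.seed(17)
  x <- round(c(rnorm(512, 60, 12), rnorm(512, 180, 15)))
  x <- pmin(pmax(x, 0), 255)
  th <- kmeans2_threshold(x)
  ref <- oracle_kmeans2_scan(x)
  expect_equal(th$sse, ref$sse, tolerance = 1e-9)
  expect_equal(th$center_dark, ref$mu_lo, tolerance = 1e-9)
  expect_equal(th$center_bright, ref$mu_hi, tolerance = 1e-9)
})

make_labelled_grid <- function(img, vascular = NULL) {
  grid <- tile_image(img, 32)
  grid$labels[] <- "nonvascular"
  for (v in vascular) grid$labels[v[1], v[2]] <- "vascular"
  grid
}

test_that("no vascular tiles yields an all-background mask", {
  grid <- make_labelled_grid(matrix(runif(96 * 96, 0, 255), 96, 96))
  for (s in c("flood_fill", "merged_block", "single_tile")) {
    expect_equal(sum(segment_rpe(grid, s)), 0)
  }
})

test_that("flood fill reproduces an independent threshold-and-reachability oracle", {
  img <- bar_image(96, width = 8)
  grid <- make_labelled_grid(img, list(c(2, 2)))
  mask <- segment_rpe(grid, "flood_fill")
  delta <- attr(mask, "deltas")[["2,2"]]
  # oracle: threshold the full 3x3 block, flood from the centre tile's dark set
  open <- matrix(FALSE, 96, 96); open[1:96, 1:96] <- img < delta
  seeds <- matrix(FALSE, 96, 96); seeds[33:64, 33:64] <- img[33:64, 33:64] < delta
  expect_identical(mask, structure(oracle_flood8(open, seeds),
                                   deltas = attr(mask, "deltas"),
                                   degenerate = attr(mask, "degenerate")))
  # the mask is exactly the bar within the block
  expect_true(all(which(mask) == which(img < delta)))
})

test_that("flood fill excludes disconnected blobs that plain thresholding includes", {
  img <- bar_image(96, width = 8)
  img[10:16, 5:11] <- 50                   # blob in tile (1,1), off the bar
  grid_centre <- make_labelled_grid(img, list(c(2, 2)))
  flood <- segment_rpe(grid_centre, "flood_fill")
  expect_false(any(flood[10:16, 5:11]))    # unreachable from tile (2,2) seeds
  # bar pixels inside the block still captured
  expect_true(all(flood[33:64, 45:52]))

  grid_both <- make_labelled_grid(img, list(c(2, 2), c(1, 1)))
  single <- segment_rpe(grid_both, "single_tile")
  expect_true(all(single[10:16, 5:11]))    # blob's own tile thresholds it in
})

test_that("every vessel pixel lies inside the 3x3 block of some vascular tile", {
  ph <- generate_phantom(phantom_spec(image_size = 256, seed = 13))
  grid <- classify_tiles(tile_image(ph$image, 32))
  vasc <- which(grid$labels == "vascular", arr.ind = TRUE)
  allowed <- matrix(FALSE, 256, 256)
  for (k in seq_len(nrow(vasc))) {
    rows <- (max(1, vasc[k, 1] - 1) * 32 - 31):(min(8, vasc[k, 1] + 1) * 32)
    cols <- (max(1, vasc[k, 2] - 1) * 32 - 31):(min(8, vasc[k, 2] + 1) * 32)
    allowed[rows, cols] <- TRUE
  }
  for (s in c("flood_fill", "merged_block", "single_tile")) {
    mask <- segment_rpe(grid, s)
    expect_true(all(allowed[mask]), label = sprintf("locality under %s", s))
  }
})

test_that("the tile union is independent of iteration order", {
  ph <- generate_phantom(phantom_spec(image_size = 256, seed = 19))
  grid <- classify_tiles(tile_image(ph$image, 32))
  n_vasc <- sum(grid$labels == "vascular")
  base <- segment_rpe(grid, "flood_fill")
  set.seed(4)
  for (k in 1:3) {
    shuffled <- segment_rpe(grid, "flood_fill", tile_order = sample(n_vasc))
    expect_identical(as.vector(shuffled), as.vector(base))
  }
})

test_that("whole-image two-means segments a two-tone image exactly and errors on constants", {
  img <- matrix(200, 64, 64); img[20:40, 10:30] <- 60
  mask <- segment_whole_image_kmeans(img)
  expect_identical(mask, img == 60)
  expect_error(segment_whole_image_kmeans(matrix(7, 8, 8)),
               class = "angiotrace_degeneracy_error")
})

test_that("a global threshold produces more false positives than flood-fill RPE under uneven illumination", {
  ph <- generate_phantom(phantom_spec(image_size = 256, illumination_amplitude = 60,
                                      seed = 23))
  grid <- classify_tiles(tile_image(ph$image, 32))
  fp_rpe <- evaluate_segmentation(segment_rpe(grid, "flood_fill"), ph$truth)$fp
  fp_global <- evaluate_segmentation(segment_whole_image_kmeans(ph$image), ph$truth)$fp
  expect_gt(fp_global, fp_rpe)
})
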