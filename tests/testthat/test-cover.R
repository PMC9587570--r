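test_that("boundary scan finds edge pixels in row-major order", {
  m <- matrix(TRUE, 10, 10)
  bp <- scan_boundary_pixels(m)
  expect_equal(nrow(bp), 36)               # ring of a 10x10 block
  expect_true(all(bp[, 1] %in% c(1, 10) | bp[, 2] %in% c(1, 10)))
  expect_true(all(diff((bp[, 1] - 1) * 10 + bp[, 2] - 1) > 0))

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(scan_boundary_pixels(single), cbind(row = 3L, col = 3L))
  expect_equal(nrow(scan_boundary_pixels(matrix(FALSE, 4, 4))), 0)
})

test_that("boundary scan equals the brute-force 4-neighbour test on random masks", {
  set.seed(41)
  for (k in 1:10) {
    m <- matrix(runif(20 * 17) < 0.45, 20, 17)
    got <- scan_boundary_pixels(m)
    ref <- oracle_boundary(m)
    expect_equal(unname(got), unname(ref))
  }
})

test_that("cast covers follow bar geometry and handle isolated pixels", {
  m <- matrix(FALSE, 30, 40); m[5:8, 10:29] <- TRUE   # 20 wide x 4 tall bar
  cand <- cast_covers(m, c(5, 10))
  expect_setequal(cand$direction, c("E", "S", "SE"))   # N/NE leave the bar
  expect_equal(cand$span[cand$direction == "E"], 20)
  expect_equal(cand$length[cand$direction == "E"], 20)
  expect_equal(cand$span[cand$direction == "S"], 4)
  expect_equal(cand$span[cand$direction == "SE"], 4)
  expect_equal(cand$length[cand$direction == "SE"], 4 * sqrt(2))

  iso <- matrix(FALSE, 5, 5); iso[3, 3] <- TRUE
  ci <- cast_covers(iso, c(3, 3))
  expect_equal(nrow(ci), 5)
  expect_true(all(ci$span == 1))
  expect_error(cast_covers(m, c(1, 1)), class = "angiotrace_argument_error")
})

test_that("cast covers on random blobs re-validate under the ray-walk oracle", {
  set.seed(47)
  for (k in 1:8) {
    m <- matrix(runif(25 * 25) < 0.5, 25, 25)
    anchors <- which(m, arr.ind = TRUE)
    for (a in sample(nrow(anchors), min(10, nrow(anchors)))) {
      cand <- cast_covers(m, anchors[a, ])
      for (q in seq_len(nrow(cand))) {
        expect_true(oracle_cover_valid(m, cand[q, ]),
                    label = sprintf("cover %s at (%d,%d)", cand$direction[q],
                                    anchors[a, 1], anchors[a, 2]))
      }
    }
  }
})

test_that("cover selection applies the chaining rules and their fallbacks", {
  mk <- function(direction, span) {
    step <- c(E = 1, S = 1, N = 1, SE = sqrt(2), NE = sqrt(2))[[direction]]
    data.frame(anchor_row = 1, anchor_col = 1, direction = direction,
               span = span, length = span * step,
               end_row = NA, end_col = NA, stringsAsFactors = FALSE)
  }
  # same direction admissible -> kept
  sel <- select_cover(rbind(mk("E", 6), mk("S", 20), mk("SE", 8)), mk("E", 6))
  expect_equal(sel$direction, "E")
  # rule-1 violation on the only candidate -> fallback shortest
  sel <- select_cover(mk("E", 4), mk("S", 4))
  expect_equal(sel$direction, "E")
  expect_true(sel$fallback)
  # initialization: shortest Euclidean length wins
  sel <- select_cover(rbind(mk("S", 4), mk("E", 20), mk("SE", 4)), NULL)
  expect_equal(sel$direction, "S")
  # equal-length tie at init: fixed priority E before S
  sel <- select_cover(rbind(mk("S", 4), mk("E", 4)), NULL)
  expect_equal(sel$direction, "E")
  expect_error(select_cover(mk("E", 1)[0, ], NULL),
               class = "angiotrace_argument_error")
})

test_that("forest construction: one tree per region, covers validate, regions covered", {
  expect_equal(length(build_cover_forest(matrix(FALSE, 10, 10))), 0)

  m <- matrix(FALSE, 30, 30)
  m[3:8, 3:8] <- TRUE
  m[20:26, 15:24] <- TRUE
  forest <- build_cover_forest(m)
  expect_equal(length(forest), 2)

  # vertical bar: covers settle into horizontal chords of the bar width
  bar <- matrix(FALSE, 60, 30); bar[, 11:19] <- TRUE
  fb <- build_cover_forest(bar)
  expect_equal(length(fb), 1)
  cov <- fb[[1]]$covers
  expect_true(mean(cov$direction == "E" & cov$length == 9) > 0.9)
  expect_equal(stats::median(cov$length), 9)
})

test_that("random masks: every selected cover is valid and every region holds one", {
  set.seed(53)
  for (k in 1:10) {
    m <- matrix(runif(30 * 30) < 0.4, 30, 30)
    forest <- build_cover_forest(m)
    lab <- angiotrace:::label_components(m, 4L)
    covered_regions <- integer(0)
    for (tr in forest) {
      for (q in seq_len(tree_size(tr))) {
        expect_true(oracle_cover_valid(m, tr$covers[q, ]))
      }
      covered_regions <- c(covered_regions, tr$regions)
    }
    expect_setequal(unique(covered_regions[covered_regions > 0]),
                    seq_len(max(lab)))
  }
})

test_that("forest construction is deterministic", {
  set.seed(59)
  m <- matrix(runif(40 * 40) < 0.35, 40, 40)
  f1 <- build_cover_forest(m)
  f2 <- build_cover_forest(m)
  expect_identical(f1, f2)
})

test_that("rule-compliant chains change orientation by at most 45 degrees", {
  angles <- c(E = 0, S = 90, N = 90, SE = 45, NE = 135)
  ph <- generate_phantom(phantom_spec(image_size = 256, n_vessels = 1,
                                      n_blobs = 0, n_guidewires = 0, seed = 61))
  forest <- build_cover_forest(ph$truth$mask)
  expect_gt(length(forest), 0)
  for (tr in forest) {
    a <- angles[tr$covers$direction]
    d <- abs(diff(a)) %% 180
    d <- pmin(d, 180 - d)
    # pairs whose second member was selected under the rules (not a fallback)
    ruled <- !tr$covers$fallback[-1]
    expect_true(all(d[ruled] <= 45))
    expect_equal(sum(tr$covers$fallback), attr(tr, "fallbacks"))
  }
})

test_that("adjacent trees merge transitively and idempotently", {
  m <- matrix(FALSE, 20, 20)
  m[2:5, 2:5] <- TRUE
  m[6:9, 6:9] <- TRUE        # corner-to-corner with the first: 8-adjacent
  forest <- build_cover_forest(m)
  expect_equal(length(forest), 2)        # 4-connectivity keeps them apart
  merged <- merge_adjacent_trees(forest)
  expect_equal(length(merged), 1)
  expect_setequal(merged[[1]]$regions, c(1, 2))
  expect_identical(merge_adjacent_trees(merged), merged)

  far <- matrix(FALSE, 20, 20)
  far[2:5, 2:5] <- TRUE
  far[10:13, 10:13] <- TRUE
  ff <- build_cover_forest(far)
  expect_identical(merge_adjacent_trees(ff), ff)
})

test_that("merged trees stay acyclic with a consistent longest path", {
  m <- matrix(FALSE, 25, 25)
  m[2:6, 2:6] <- TRUE
  m[7:11, 7:11] <- TRUE
  m[12:16, 12:16] <- TRUE   # chain of three diagonal blocks
  merged <- merge_adjacent_trees(build_cover_forest(m))
  expect_equal(length(merged), 1)
  tr <- merged[[1]]
  expect_equal(nrow(tr$edges), tree_size(tr) - 1)   # tree: n-1 edges
  expect_lte(tree_path_length(tr), tree_size(tr))
  expect_gte(tree_path_length(tr), 1)
})

test_that("the main tree is the longest-path tree and pruning keeps exactly its regions", {
  expect_error(select_main_tree(list()), class = "angiotrace_novessel_error")

  m <- matrix(FALSE, 80, 80)
  m[5:75, 20:28] <- TRUE                  # long vessel
  m[10:14, 50:54] <- TRUE                 # blob noise
  m[60:63, 60:66] <- TRUE
  m[30:36, 5:9] <- TRUE                   # disconnected second "vessel"
  forest <- merge_adjacent_trees(build_cover_forest(m))
  main <- select_main_tree(forest)
  expect_identical(select_main_tree(list(main)), main)

  # all of the main tree's covers lie on the long vessel
  cp <- covered_pixels_mask(main, dim(m))
  vessel_only <- matrix(FALSE, 80, 80); vessel_only[5:75, 20:28] <- TRUE
  expect_true(all(vessel_only[cp]))

  pruned <- prune_mask(m, main)
  expect_identical(pruned, vessel_only)   # blobs AND the second vessel removed
  expect_identical(prune_mask(vessel_only, main), vessel_only)
})

test_that("pruned vessel set equals the components holding main-tree covers", {
  ph <- generate_phantom(phantom_spec(image_size = 256, seed = 67))
  mask <- ph$truth$mask | (matrix(runif(256^2), 256, 256) < 0)  # copy
  # add distractor blobs directly to the mask
  for (pos in list(c(30, 200), c(200, 30), c(120, 240))) {
    mask[pos[1]:(pos[1] + 4), pos[2]:(pos[2] + 4)] <- TRUE
  }
  forest <- merge_adjacent_trees(build_cover_forest(mask))
  main <- select_main_tree(forest)
  pruned <- prune_mask(mask, main)
  lab <- angiotrace:::label_components(mask, 4L)
  keep <- unique(lab[covered_pixels_mask(main, dim(mask))])
  expect_identical(pruned, mask & matrix(lab %in% keep, 256, 256))
})

test_that("five directions cover a curved vessel bottom at least as well as three", {
  u <- make_u_mask(96, 9)
  frac_covered <- function(dirs) {
    forest <- build_cover_forest(u, cover_rules(directions = dirs))
    sum(covered_pixels_mask(forest, dim(u)) & u) / sum(u)
  }
  expect_gte(frac_covered("five"), frac_covered("three"))
})

test_that("the chaining rules reduce direction scatter on a jagged bar", {
  jag <- make_jagged_bar(60, 9, seed = 42)
  angles <- c(E = 0, S = 90, N = 90, SE = 45, NE = 135)
  var_with <- circular_variance_axial(
    angles[build_cover_forest(jag, cover_rules(rules_enabled = TRUE))[[1]]$covers$direction])
  var_without <- circular_variance_axial(
    angles[build_cover_forest(jag, cover_rules(rules_enabled = FALSE))[[1]]$covers$direction])
  expect_lt(var_with, var_without)
})

test_that("a cover forest serialises to JSON and back-reads consistently", {
  m <- matrix(FALSE, 20, 20); m[5:15, 8:12] <- TRUE
  forest <- build_cover_forest(m)
  f <- withr::local_tempfile(fileext = ".json")
  write_cover_forest(forest, f)
  back <- jsonlite::read_json(f)
  expect_equal(length(back), length(forest))
  expect_equal(length(back[[1]]$nodes), tree_size(forest[[1]]))
  n1 <- back[[1]]$nodes[[1]]
  expect_equal(unlist(n1$anchor),
               c(forest[[1]]$covers$anchor_row[1], forest[[1]]$covers$anchor_col[1]))
})
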