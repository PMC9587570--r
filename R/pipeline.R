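# End-to-end orchestration: tile -> classify -> expand (RPE) -> trace (OCT)
# -> diameter profile and overlay, with every artifact written to disk and
# every parameter echoed so a run is reproducible from its log alone.

default_run_config <- function() {
  list(
    input = NULL,                 # path to a grayscale raster, or NULL
    phantom = list(),             # phantom_spec() overrides, used when input is NULL
    output_dir = ".",
    tile_size = 32L,
    classifier = list(kind = "heuristic", min_contrast = 40,
                      min_fraction = 0.05, max_fraction = 0.80,
                      labels = NULL),
    rpe = list(strategy = "flood_fill"),
    oct = list(directions = "five", rules = "on", max_angle_step = 45,
               length_tolerance_abs = 2, length_tolerance_rel = 0.30,
               tolerance_mode = "hybrid", keep_top_n = 1L),
    diameter = list(n_bins = 5L),
    verbose = TRUE
  )
}

#' Build and validate a run configuration
#'
#' Merges user settings over the defaults and rejects unknown keys, so a
#' typo cannot silently fall back to a default. Settings may come from a
#' YAML file (`path`) or a nested list (`overrides`); flags in
#' `overrides` win over the file.
#'
#' @param path Optional YAML config file.
#' @param overrides Optional nested list of settings.
#' @return A validated `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  apply_over <- function(base, over, prefix = "") {
    for (nm in names(over)) {
      key <- paste0(prefix, nm)
      if (!nm %in% names(base)) {
        stop_angio(sprintf("unknown config key: %s", key), "angiotrace_config_error")
      }
      if (is.list(base[[nm]]) && is.list(over[[nm]]) && nm != "phantom") {
        base[[nm]] <- apply_over(base[[nm]], over[[nm]], paste0(key, "."))
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop_angio(sprintf("config file not found: %s", path), "angiotrace_config_error")
    }
    cfg <- apply_over(cfg, yaml::read_yaml(path))
  }
  cfg <- apply_over(cfg, overrides)
  if (!cfg$rpe$strategy %in% c("flood_fill", "merged_block", "single_tile")) {
    stop_angio("rpe.strategy must be flood_fill, merged_block or single_tile",
               "angiotrace_config_error")
  }
  if (!cfg$classifier$kind %in% c("heuristic", "oracle", "external")) {
    stop_angio("classifier.kind must be heuristic, oracle or external",
               "angiotrace_config_error")
  }
  structure(cfg, class = "run_config")
}

config_rules <- function(cfg) {
  cover_rules(directions = cfg$oct$directions,
              rules_enabled = identical(cfg$oct$rules, "on") || isTRUE(cfg$oct$rules),
              max_angle_step = cfg$oct$max_angle_step,
              length_tolerance_abs = cfg$oct$length_tolerance_abs,
              length_tolerance_rel = cfg$oct$length_tolerance_rel,
              tolerance_mode = cfg$oct$tolerance_mode)
}

config_classifier <- function(cfg, truth = NULL) {
  cl <- cfg$classifier
  switch(cl$kind,
    heuristic = heuristic_classifier(cl$min_contrast, cl$min_fraction, cl$max_fraction),
    oracle = {
      if (is.null(truth)) {
        stop_angio("oracle classifier needs a phantom input (ground truth)",
                   "angiotrace_config_error")
      }
      oracle_classifier(truth$mask, cl$min_fraction)
    },
    external = {
      if (is.null(cl$labels)) {
        stop_angio("external classifier needs classifier.labels (CSV path)",
                   "angiotrace_config_error")
      }
      external_classifier(cl$labels)
    })
}

#' Run the full segmentation and tracing pipeline
#'
#' Executes the five pipeline stages on a raster image or a generated
#' phantom and writes the artifact bundle to `output_dir`:
#' `mask_pre.png` (segmentation before pruning), `mask_pruned.png`,
#' `labels.csv` (per-tile classification), `covers.json` (the merged
#' cover forest), `profile.csv` (diameter along the main path),
#' `overlay.png` (diameter colour-coding) and `run_log.yaml` (every
#' effective parameter, per-tile thresholds, rule-fallback count). With
#' identical configuration the bundle is bit-identical across runs.
#'
#' An image in which no vessel is found produces empty artifacts and a
#' warning, not an error.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results: `image`, `grid`,
#'   `mask_pre`, `forest`, `main`, `mask_pruned`, `profile`, `truth`
#'   (phantom runs only), and `paths`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(overrides = unclass(cfg))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  truth <- NULL
  if (!is.null(cfg$input)) {
    img <- read_gray(cfg$input)
    say("stage input: read %s (%d x %d)", cfg$input, nrow(img), ncol(img))
  } else {
    ph <- generate_phantom(do.call(phantom_spec, cfg$phantom))
    img <- ph$image
    truth <- ph$truth
    say("stage input: generated phantom (seed %d)", ph$spec$seed)
  }
  with_stage <- function(stage, expr) {
    tryCatch(expr, angiotrace_error = function(e) {
      stop_angio(sprintf("[%s] %s", stage, conditionMessage(e)), class(e)[1])
    })
  }
  grid <- with_stage("tiling", tile_image(img, cfg$tile_size))
  grid <- with_stage("classification", classify_tiles(grid, config_classifier(cfg, truth)))
  say("stage classification: %d vascular tiles", sum(grid$labels == "vascular"))
  mask_pre <- with_stage("rpe", segment_rpe(grid, cfg$rpe$strategy))
  say("stage rpe (%s): %d vessel pixels", cfg$rpe$strategy, sum(mask_pre))
  rules <- config_rules(cfg)
  forest <- with_stage("oct", merge_adjacent_trees(build_cover_forest(mask_pre, rules)))
  paths <- file.path(cfg$output_dir,
                     c(mask_pre = "mask_pre.png", mask_pruned = "mask_pruned.png",
                       labels = "labels.csv", covers = "covers.json",
                       profile = "profile.csv", overlay = "overlay.png",
                       log = "run_log.yaml"))
  names(paths) <- c("mask_pre", "mask_pruned", "labels", "covers",
                    "profile", "overlay", "log")
  write_mask(mask_pre, paths[["mask_pre"]])
  write_tile_labels(grid, paths[["labels"]])
  if (!length(forest)) {
    warning("no vessel found; writing empty artifacts")
    main <- NULL
    mask_pruned <- mask_pre
    profile <- data.frame(index = integer(0), row = numeric(0), col = numeric(0),
                          direction = character(0), diameter_px = numeric(0))
  } else {
    keep_n <- max(1L, as.integer(cfg$oct$keep_top_n %||% 1L))
    ranked <- forest[order(-vapply(forest, tree_path_length, 1L),
                           -vapply(forest, tree_size, 1L))]
    kept <- ranked[seq_len(min(keep_n, length(ranked)))]
    main <- select_main_tree(forest)
    mask_pruned <- with_stage("oct", prune_mask(mask_pre, kept))
    profile <- with_stage("diameter", extract_profile(main))
    say("stage oct: %d trees, main path %d covers, %d px after pruning",
        length(forest), tree_path_length(main), sum(mask_pruned))
  }
  write_mask(mask_pruned, paths[["mask_pruned"]])
  write_cover_forest(forest, paths[["covers"]])
  write_profile(profile, paths[["profile"]])
  overlay <- colorize(img, main, cfg$diameter$n_bins)
  png::writePNG(overlay, paths[["overlay"]])
  cfg_echo <- unclass(cfg)
  cfg_echo$output_dir <- NULL      # not a computation parameter; the log's own location
  log <- list(
    config = cfg_echo,
    tile_deltas = as.list(attr(mask_pre, "deltas")),
    degenerate_tiles = attr(mask_pre, "degenerate"),
    rule_fallbacks = if (length(forest))
      sum(vapply(forest, function(t) attr(t, "fallbacks") %||% 0L, 1L)) else 0L,
    n_trees = length(forest),
    vessel_pixels_pre = sum(mask_pre),
    vessel_pixels_pruned = sum(mask_pruned)
  )
  log$config$phantom <- lapply(cfg$phantom, unclass)
  yaml::write_yaml(log, paths[["log"]])
  invisible(list(image = img, grid = grid, mask_pre = mask_pre, forest = forest,
                 main = main, mask_pruned = mask_pruned, profile = profile,
                 truth = truth, paths = paths))
}
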