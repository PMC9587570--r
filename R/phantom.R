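# Synthetic angiogram phantoms: dark curvilinear vessels of known, slowly
# varying width on a brighter background with smooth illumination drift,
# clipped additive noise, and disconnected dark distractors (blobs and a
# guidewire-like curve). Ground truth is exact because vessels are stamped
# as hard disks along the centreline with no anti-aliasing.

#' Phantom specification
#'
#' Parameters of the synthetic angiogram generator. Defaults describe the
#' standard test condition: a 512 x 512 frame, two vessels (a main branch
#' of width 15 px and a secondary of 9 px) dropping through the frame as
#' bounded-curvature random walks, vessel gray level 70 on background 170,
#' a low-order polynomial illumination field of amplitude +/- 40 gray
#' levels, additive noise of sd 8 clipped at +/- 14 so the nominal 30-level
#' vessel/background contrast cannot be crossed by noise alone, three dark
#' distractor blobs and one thin guidewire-like curve disconnected from
#' the vessels.
#'
#' @param image_size Side of the square frame in pixels.
#' @param n_vessels Number of vessels (0 allowed).
#' @param widths Base vessel widths in pixels, recycled over vessels; all
#'   resulting widths must stay >= 3 px.
#' @param width_wobble Amplitude of the slow sinusoidal width variation.
#' @param stenosis `NULL`, or `list(vessel =, at =, severity =, extent =)`:
#'   a Gaussian narrowing of vessel `vessel` centred at arc-length
#'   fraction `at`, reducing width by the fraction `severity` at its
#'   deepest point, with sd `extent/2` pixels.
#' @param vessel_intensity,background_intensity Gray levels of vessel and
#'   nominal background.
#' @param illumination_amplitude Peak deviation of the smooth shading
#'   field, gray levels.
#' @param noise_sd Additive Gaussian noise sd (clipped at +/- 14).
#' @param curvature Per-step sd of the centreline heading change,
#'   radians; headings are kept within +/- 1 radian of straight down.
#' @param heading_jitter Half-range of the uniform initial heading offset
#'   from straight down, radians. Zero with zero `curvature` gives an
#'   exactly vertical vessel.
#' @param n_blobs,blob_radius Count and radius range of distractor disks.
#' @param n_guidewires Number of thin (2 px) distractor curves.
#' @param seed Integer seed; fully determines the phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 512L, n_vessels = 2L,
                         widths = c(15, 9), width_wobble = 1,
                         stenosis = NULL,
                         vessel_intensity = 70, background_intensity = 170,
                         illumination_amplitude = 40, noise_sd = 8,
                         curvature = 0.02, heading_jitter = 0.3,
                         n_blobs = 3L, blob_radius = c(4, 8),
                         n_guidewires = 1L, seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  min_w <- min(spec$widths) - spec$width_wobble
  if (!is.null(stenosis)) {
    sw <- spec$widths[(stenosis$vessel - 1L) %% length(spec$widths) + 1L]
    min_w <- min(min_w, (sw - spec$width_wobble) * (1 - stenosis$severity))
  }
  if (spec$n_vessels > 0L && min_w < 3) {
    stop_angio("vessel widths must stay >= 3 px (after wobble and stenosis)",
               "angiotrace_spec_error")
  }
  spec
}

# Evaluate the nominal width at arc length s (pixels from the start).
phantom_width_at <- function(spec, vessel, s) {
  w <- spec$widths[(vessel - 1L) %% length(spec$widths) + 1L] +
    spec$width_wobble * sin(2 * pi * s / 200)
  st <- spec$stenosis
  if (!is.null(st) && st$vessel == vessel) {
    total <- attr(s, "total") %||% max(s)
    s0 <- st$at * total
    sdv <- (st$extent %||% 30) / 2
    w <- w * (1 - st$severity * exp(-(s - s0)^2 / (2 * sdv^2)))
  }
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stamp disks of radius w/2 at continuous centreline points into a logical
# canvas. Hard-edged: pixel centre within radius.
stamp_disks <- function(canvas, y, x, w) {
  h <- nrow(canvas); wd <- ncol(canvas)
  for (k in seq_along(y)) {
    rad <- w[k] / 2
    r0 <- max(1L, floor(y[k] - rad)); r1 <- min(h, ceiling(y[k] + rad))
    c0 <- max(1L, floor(x[k] - rad)); c1 <- min(wd, ceiling(x[k] + rad))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - y[k])^2, (cc - x[k])^2, "+")
    canvas[rr, cc] <- canvas[rr, cc] | (d2 <= rad^2)
  }
  canvas
}

#' Generate a synthetic angiogram with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]. Vessel centrelines
#' are unit-step random walks with bounded curvature entering from the top
#' edge; the vessel body is the union of hard disks of radius width/2
#' stamped at every centreline point, which makes the perpendicular chord
#' width of the truth mask equal the nominal width to within a pixel. The
#' rendered vessel gray level is forced at least 30 levels below the local
#' illuminated background before noise. Distractors are placed so they do
#' not touch the vessels and are excluded from the truth mask. The raster
#' is integer-valued and fully determined by `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (intensity matrix), `truth` (list with
#'   `mask`, and `centerlines`: one data frame per vessel with `index`,
#'   `row`, `col`, `width_px`), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) {
    stop_angio("`spec` must come from phantom_spec()", "angiotrace_spec_error")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  n <- spec$image_size
  mask <- matrix(FALSE, n, n)
  centerlines <- list()
  for (v in seq_len(spec$n_vessels)) {
    x <- stats::runif(1, 0.15 * n, 0.85 * n)
    y <- 1
    theta <- pi / 2 +
      if (spec$heading_jitter > 0) stats::runif(1, -spec$heading_jitter, spec$heading_jitter) else 0
    ys <- xs <- numeric(0)
    while (y >= 1 && y <= n && x >= 1 && x <= n) {
      ys <- c(ys, y); xs <- c(xs, x)
      theta <- theta + stats::rnorm(1, 0, spec$curvature)
      theta <- min(max(theta, pi / 2 - 1), pi / 2 + 1)
      y <- y + sin(theta)
      x <- x + cos(theta)
    }
    s <- seq_along(ys) - 1
    attr(s, "total") <- max(s)
    wv <- phantom_width_at(spec, v, s)
    mask <- stamp_disks(mask, ys, xs, wv)
    centerlines[[v]] <- data.frame(index = seq_along(ys), row = ys, col = xs,
                                   width_px = as.numeric(wv))
  }
  # smooth illumination: low-order polynomial on [-1, 1]^2, scaled to amplitude
  u <- matrix(rep(seq(-1, 1, length.out = n), each = n), n, n)   # col coord
  vco <- matrix(rep(seq(-1, 1, length.out = n), times = n), n, n) # row coord
  cf <- stats::runif(5, -1, 1)
  field <- cf[1] * u + cf[2] * vco + cf[3] * u * vco + cf[4] * u^2 + cf[5] * vco^2
  mx <- max(abs(field))
  if (mx > 0) field <- field / mx * spec$illumination_amplitude
  bg <- spec$background_intensity + field
  img <- bg
  img[mask] <- pmin(spec$vessel_intensity, bg[mask] - 30)
  # distractors: dark blobs and a thin guidewire, never touching the vessels
  distract <- matrix(FALSE, n, n)
  forbid <- dilate3x3(mask, times = 2L)
  place <- function(stamp_fun) {
    for (try in 1:50) {
      cand <- stamp_fun(matrix(FALSE, n, n))
      if (!any(cand & forbid)) return(cand)
    }
    matrix(FALSE, n, n)
  }
  for (b in seq_len(spec$n_blobs)) {
    distract <- distract | place(function(cv) {
      r <- stats::runif(1, spec$blob_radius[1], spec$blob_radius[2])
      stamp_disks(cv, stats::runif(1, r + 1, n - r), stats::runif(1, r + 1, n - r),
                  2 * r)
    })
  }
  for (g in seq_len(spec$n_guidewires)) {
    distract <- distract | place(function(cv) {
      x <- stats::runif(1, 0.1 * n, 0.9 * n); y <- 1
      th <- pi / 2 + stats::runif(1, -0.5, 0.5)
      len <- round(stats::runif(1, 0.3 * n, 0.8 * n))
      ys <- xs <- numeric(0)
      for (k in seq_len(len)) {
        if (y < 1 || y > n || x < 1 || x > n) break
        ys <- c(ys, y); xs <- c(xs, x)
        th <- th + stats::rnorm(1, 0, 0.03)
        y <- y + sin(th); x <- x + cos(th)
      }
      stamp_disks(cv, ys, xs, rep(2, length(ys)))
    })
  }
  img[distract] <- pmin(spec$vessel_intensity, img[distract] - 30)
  noise <- pmin(pmax(stats::rnorm(n * n, 0, spec$noise_sd), -14), 14)
  img <- pmin(pmax(round(img + noise), 0), 255)
  list(image = img,
       truth = structure(list(mask = mask, centerlines = centerlines),
                         class = "phantom_truth"),
       spec = spec)
}

# 3x3 binary dilation, repeated `times`.
dilate3x3 <- function(mask, times = 1L) {
  h <- nrow(mask); w <- ncol(mask)
  for (t in seq_len(times)) {
    pad <- matrix(FALSE, h + 2L, w + 2L)
    pad[2:(h + 1L), 2:(w + 1L)] <- mask
    out <- matrix(FALSE, h, w)
    for (dr in 0:2) for (dc in 0:2) {
      out <- out | pad[(1L + dr):(h + dr), (1L + dc):(w + dc)]
    }
    mask <- out
  }
  mask
}

#' Pixel-level segmentation metrics against phantom truth
#'
#' Standard confusion-count metrics between a predicted vessel mask and
#' the ground truth: precision (vessel calls that are true vessel), recall
#' (true vessel recovered) and the raw false-positive pixel count, the
#' quantity that separates the expansion strategies.
#'
#' @param pred Predicted logical mask.
#' @param truth A `phantom_truth` or a logical truth mask.
#' @return List with `precision`, `recall`, `fp` (and `tp`, `fn`).
#'   Precision is `NA` when nothing was predicted; recall is `NA` when the
#'   truth is empty.
#' @export
evaluate_segmentation <- function(pred, truth) {
  assert_mask(pred, "pred")
  tm <- if (inherits(truth, "phantom_truth")) truth$mask else truth
  assert_mask(tm, "truth")
  if (any(dim(pred) != dim(tm))) {
    stop_angio("prediction and truth dimensions differ", "angiotrace_argument_error")
  }
  tp <- sum(pred & tm)
  fp <- sum(pred & !tm)
  fn <- sum(!pred & tm)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fp = fp, tp = tp, fn = fn)
}

#' Diameter-recovery error against phantom truth
#'
#' Matches every profile sample to the nearest ground-truth centreline
#' point (over all vessels) and summarises the estimation error
#' `estimated - true` in pixels.
#'
#' @param profile Data frame from [extract_profile()].
#' @param truth A `phantom_truth` with at least one centreline.
#' @return List with `bias` (mean error), `rmse`, and `n` samples.
#' @export
evaluate_diameter_recovery <- function(profile, truth) {
  if (!inherits(truth, "phantom_truth") || !length(truth$centerlines)) {
    stop_angio("`truth` must contain at least one centreline",
               "angiotrace_argument_error")
  }
  if (is.null(profile) || nrow(profile) == 0L) {
    stop_angio("empty diameter profile", "angiotrace_argument_error")
  }
  cl <- do.call(rbind, truth$centerlines)
  err <- vapply(seq_len(nrow(profile)), function(k) {
    d2 <- (cl$row - profile$row[k])^2 + (cl$col - profile$col[k])^2
    profile$diameter_px[k] - cl$width_px[which.min(d2)]
  }, 1.0)
  list(bias = mean(err), rmse = sqrt(mean(err^2)), n = length(err))
}
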