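#' Synthetic two-channel transfection scenes
#'
#' Describes a simulated micrograph of sparse transfected cells on a dark
#' background: elliptical cells with per-cell red (control) intensity drawn
#' from a truncated normal, green = `true_fraction` x red with independent
#' multiplicative noise per pixel on both channels, plus Gaussian
#' background, clipped to the 16-bit range.  Rendering is fully
#' deterministic given the seed.
#'
#' @param n_cells number of non-overlapping cells to paint.
#' @param true_fraction ground-truth green/red expression ratio of the
#'   construct (1.0 = un-attenuated control).
#' @param width,height image size in pixels.
#' @param red_mean,red_sd per-cell red intensity distribution (truncated to
#'   `red_range`).
#' @param red_range admissible per-cell red intensities.
#' @param noise_sd multiplicative per-pixel noise SD (fraction of signal).
#' @param background_mean,background_sd additive Gaussian background.
#' @param cell_radius range of ellipse semi-axes, pixels.
#' @param seed integer seed governing every random draw.
#' @return a `synthetic_scene`.
#' @export
synthetic_scene <- function(n_cells = 25L, true_fraction = 1.0,
                            width = 192L, height = 192L,
                            red_mean = 20000, red_sd = 6000,
                            red_range = c(8000, 50000),
                            noise_sd = 0.05,
                            background_mean = 150, background_sd = 40,
                            cell_radius = c(6, 14), seed = 1L) {
  stopifnot(n_cells >= 0L, true_fraction >= 0, noise_sd >= 0,
            background_sd >= 0, cell_radius[1] <= cell_radius[2])
  structure(list(n_cells = as.integer(n_cells),
                 true_fraction = true_fraction,
                 width = as.integer(width), height = as.integer(height),
                 red_mean = red_mean, red_sd = red_sd, red_range = red_range,
                 noise_sd = noise_sd, background_mean = background_mean,
                 background_sd = background_sd, cell_radius = cell_radius,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

# run expr under a private RNG stream, restoring global state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a synthetic scene into an image pair plus ground truth
#'
#' Cells are placed by rejection sampling with a bounded number of attempts
#' (an error is raised if the requested packing is infeasible).  The
#' returned ground truth records the painted foreground mask and per-cell
#' parameters, enabling closed-loop validation of the ratiometry pipeline.
#'
#' @param scene a `synthetic_scene`.
#' @return list with `pair` (a `channel_image_pair`), and `truth`: the
#'   scene parameters, per-cell table, logical `foreground` mask,
#'   `n_foreground_pixels` and `suggested_threshold`
#'   (background mean + 3 SD).
#' @examples
#' r <- generate_synthetic_pair(synthetic_scene(n_cells = 5, seed = 42))
#' r$truth$n_foreground_pixels
#' @export
generate_synthetic_pair <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  .with_seed(scene$seed, {
    h <- scene$height; w <- scene$width
    red <- matrix(0, h, w)
    green <- matrix(0, h, w)
    fg <- matrix(FALSE, h, w)
    cells <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                        b = numeric(0), theta = numeric(0),
                        intensity = numeric(0), pixels = integer(0))
    attempts <- 0L
    max_attempts <- 200L * max(1L, scene$n_cells)
    placed <- 0L
    while (placed < scene$n_cells) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("infeasible packing: could not place ", scene$n_cells,
             " non-overlapping cells in ", w, "x", h)
      }
      a <- stats::runif(1, scene$cell_radius[1], scene$cell_radius[2])
      b <- stats::runif(1, scene$cell_radius[1], scene$cell_radius[2])
      theta <- stats::runif(1, 0, pi)
      rmax <- max(a, b)
      cx <- stats::runif(1, rmax + 1, w - rmax - 1)
      cy <- stats::runif(1, rmax + 1, h - rmax - 1)
      # bounding-box pixel membership of the rotated ellipse
      xs <- floor(cx - rmax):ceiling(cx + rmax)
      ys <- floor(cy - rmax):ceiling(cy + rmax)
      gx <- rep(xs, each = length(ys)) - cx
      gy <- rep(ys, times = length(xs)) - cy
      u <- gx * cos(theta) + gy * sin(theta)
      v <- -gx * sin(theta) + gy * cos(theta)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      px <- rep(xs, each = length(ys))[inside]
      py <- rep(ys, times = length(xs))[inside]
      lin <- (px - 1L) * h + py
      if (any(fg[lin])) next  # overlap; retry
      intensity <- stats::rnorm(1, scene$red_mean, scene$red_sd)
      intensity <- min(max(intensity, scene$red_range[1]), scene$red_range[2])
      npx <- length(lin)
      red[lin] <- intensity * (1 + stats::rnorm(npx, 0, scene$noise_sd))
      green[lin] <- scene$true_fraction * intensity *
        (1 + stats::rnorm(npx, 0, scene$noise_sd))
      fg[lin] <- TRUE
      placed <- placed + 1L
      cells[placed, ] <- list(cx, cy, a, b, theta, intensity, npx)
    }
    red <- red + stats::rnorm(h * w, scene$background_mean,
                              scene$background_sd)
    green <- green + stats::rnorm(h * w, scene$background_mean,
                                  scene$background_sd)
    clip16 <- function(m) matrix(pmin(pmax(round(m), 0), 65535), h, w)
    pair <- channel_image_pair(clip16(green), clip16(red),
                               metadata = list(seed = scene$seed,
                                               true_fraction =
                                                 scene$true_fraction))
    list(pair = pair,
         truth = list(scene = scene, cells = cells, foreground = fg,
                      n_foreground_pixels = sum(fg),
                      suggested_threshold = scene$background_mean +
                        3 * scene$background_sd))
  })
}

#' Write a rendered scene as 16-bit TIFFs plus a JSON ground-truth sidecar
#'
#' @param render result of [generate_synthetic_pair()].
#' @param dir output directory (created if needed).
#' @param basename file stem; writes `<stem>_green.tif`, `<stem>_red.tif`,
#'   `<stem>_truth.json`.
#' @return named character vector of the three paths, invisibly.
#' @export
write_synthetic_pair <- function(render, dir, basename = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, paste0(basename, "_green.tif"))
  rp <- file.path(dir, paste0(basename, "_red.tif"))
  jp <- file.path(dir, paste0(basename, "_truth.json"))
  tiff::writeTIFF(render$pair$green / 65535, gp, bits.per.sample = 16L)
  tiff::writeTIFF(render$pair$red / 65535, rp, bits.per.sample = 16L)
  truth <- render$truth
  sidecar <- list(scene = unclass(truth$scene), cells = truth$cells,
                  n_foreground_pixels = truth$n_foreground_pixels,
                  suggested_threshold = truth$suggested_threshold)
  jsonlite::write_json(sidecar, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(green = gp, red = rp, truth = jp))
}
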