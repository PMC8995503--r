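#' Two-channel image pairs
#'
#' A `channel_image_pair` holds matched green (GFP, attenuated rescue
#' reporter) and red (RFP, IRES-driven internal control) intensity matrices
#' on the 16-bit scale, processed as floating point.
#'
#' @param green,red numeric matrices of identical dimensions, values >= 0.
#' @param pixel_size microns per pixel (metadata only).
#' @param metadata free-form list.
#' @return a `channel_image_pair`.
#' @export
channel_image_pair <- function(green, red, pixel_size = NA_real_,
                               metadata = list()) {
  green <- as.matrix(green) * 1.0
  red <- as.matrix(red) * 1.0
  if (!identical(dim(green), dim(red))) stop("channel shapes differ")
  if (any(green < 0) || any(red < 0)) stop("intensities must be >= 0")
  structure(list(green = green, red = red, pixel_size = pixel_size,
                 metadata = metadata), class = "channel_image_pair")
}

#' @export
print.channel_image_pair <- function(x, ...) {
  cat("<channel_image_pair> ", nrow(x$green), "x", ncol(x$green),
      if (!is.null(x$metadata$tile_id)) paste0(" tile ", x$metadata$tile_id),
      "\n", sep = "")
  invisible(x)
}

#' Read a two-channel pair from single-channel 16-bit TIFFs
#'
#' @param green_path,red_path TIFF files.
#' @param pixel_size microns per pixel.
#' @return a `channel_image_pair` with intensities on the integer 16-bit
#'   scale.
#' @export
read_image_pair <- function(green_path, red_path, pixel_size = NA_real_) {
  rd <- function(p) {
    img <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  }
  channel_image_pair(rd(green_path), rd(red_path), pixel_size = pixel_size,
                     metadata = list(green_path = green_path,
                                     red_path = red_path))
}

#' Subdivide a composite into an n x n grid of tiles
#'
#' Tiles are `floor(H/n) x floor(W/n)`; remainder rows and columns that do
#' not fill a tile are discarded from the bottom and right edges.
#' Concatenating the tiles reproduces the cropped composite exactly.
#'
#' @param pair a `channel_image_pair`.
#' @param n grid size per side (n x n tiles).
#' @return list of `channel_image_pair` tiles, row-major, each carrying
#'   `metadata$tile_id` of the form `"r<i>c<j>"`.
#' @export
subdivide_tiles <- function(pair, n) {
  stopifnot(inherits(pair, "channel_image_pair"), n >= 1L)
  n <- as.integer(n)
  th <- nrow(pair$green) %/% n
  tw <- ncol(pair$green) %/% n
  if (th < 1L || tw < 1L) stop("tiles would be smaller than 1 pixel")
  out <- vector("list", n * n)
  idx <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      rows <- ((i - 1L) * th + 1L):(i * th)
      cols <- ((j - 1L) * tw + 1L):(j * tw)
      md <- pair$metadata
      md$tile_id <- sprintf("r%02dc%02d", i, j)
      out[[idx]] <- channel_image_pair(pair$green[rows, cols, drop = FALSE],
                                       pair$red[rows, cols, drop = FALSE],
                                       pixel_size = pair$pixel_size,
                                       metadata = md)
      idx <- idx + 1L
    }
  }
  out
}

#' Background-threshold mask
#'
#' A pixel enters the analysis when its red (transfection/internal control)
#' intensity exceeds `threshold_red` and -- in the default `"both"` mode --
#' its green intensity also exceeds `threshold_green`; a pixel with
#' sub-background green contributes an unreliable ratio.  `"red_only"`
#' masks on the control channel alone.  Thresholds are applied uniformly;
#' no background subtraction is performed.
#'
#' @param pair a `channel_image_pair`.
#' @param threshold_red,threshold_green intensity thresholds (>= 0).
#' @param mode `"both"` (default) or `"red_only"`.
#' @return logical matrix the shape of the image.
#' @export
pixel_mask <- function(pair, threshold_red, threshold_green = threshold_red,
                       mode = c("both", "red_only")) {
  stopifnot(inherits(pair, "channel_image_pair"),
            threshold_red >= 0, threshold_green >= 0)
  mode <- match.arg(mode)
  m <- pair$red > threshold_red
  if (mode == "both") m <- m & (pair$green > threshold_green)
  m
}

#' Pixelwise green/red ratio over a mask
#'
#' The primary statistic is the mean over masked pixels of the per-pixel
#' green/red ratio (mean of ratios); `"ratio_of_sums"` instead divides the
#' summed green by the summed red intensity over the mask.  An empty mask
#' yields a no-signal measurement (`pixel_count` 0, `mean_ratio` NA), not an
#' error.
#'
#' @param pair a `channel_image_pair`.
#' @param mask logical matrix matching the image shape.
#' @param estimator `"mean_of_ratios"` (default) or `"ratio_of_sums"`.
#' @param threshold_red,threshold_green recorded on the measurement for
#'   provenance (optional).
#' @return a `ratio_measurement`: `mean_ratio`, `pixel_count`,
#'   `threshold_red`, `threshold_green`, `tile_id`, `estimator`.
#' @export
pixelwise_ratio <- function(pair, mask,
                            estimator = c("mean_of_ratios", "ratio_of_sums"),
                            threshold_red = NA_real_,
                            threshold_green = NA_real_) {
  stopifnot(inherits(pair, "channel_image_pair"),
            identical(dim(mask), dim(pair$green)))
  estimator <- match.arg(estimator)
  g <- pair$green[mask]
  r <- pair$red[mask]
  n <- length(g)
  ratio <- if (n == 0L) NA_real_ else if (estimator == "mean_of_ratios") {
    mean(g / r)
  } else {
    sum(g) / sum(r)
  }
  structure(list(mean_ratio = ratio, pixel_count = n,
                 threshold_red = threshold_red,
                 threshold_green = threshold_green,
                 tile_id = pair$metadata$tile_id %||% NA_character_,
                 estimator = estimator),
            class = "ratio_measurement")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ratio_measurement <- function(x, ...) {
  cat("<ratio_measurement> ratio ", format(x$mean_ratio, digits = 4),
      " over ", x$pixel_count, " px\n", sep = "")
  invisible(x)
}

#' Expression as percent of the un-attenuated control
#'
#' @param sample,control `ratio_measurement`s.
#' @return `100 * sample$mean_ratio / control$mean_ratio`.
#' @export
percent_of_control <- function(sample, control) {
  stopifnot(inherits(sample, "ratio_measurement"),
            inherits(control, "ratio_measurement"))
  if (is.na(control$mean_ratio) || control$mean_ratio <= 0) {
    stop("control ratio undefined or non-positive")
  }
  if (is.na(sample$mean_ratio)) stop("sample ratio undefined (empty mask)")
  100 * sample$mean_ratio / control$mean_ratio
}

#' Tile, mask and measure one composite in a single call
#'
#' @param pair a `channel_image_pair`.
#' @param threshold_red,threshold_green background thresholds.
#' @param tiles grid size per side (default 10, i.e. 100 sub-images).
#' @param mode,estimator passed to [pixel_mask()] / [pixelwise_ratio()].
#' @return list with `tiles` (data.frame of per-tile measurements) and
#'   `overall` (a `ratio_measurement` over the full cropped composite).
#' @export
quantify_pair <- function(pair, threshold_red, threshold_green = threshold_red,
                          tiles = 10L, mode = "both",
                          estimator = "mean_of_ratios") {
  tl <- subdivide_tiles(pair, tiles)
  ms <- lapply(tl, function(tp) {
    pixelwise_ratio(tp, pixel_mask(tp, threshold_red, threshold_green,
                                   mode = mode),
                    estimator = estimator, threshold_red = threshold_red,
                    threshold_green = threshold_green)
  })
  df <- data.frame(
    tile_id = vapply(ms, `[[`, character(1), "tile_id"),
    mean_ratio = vapply(ms, `[[`, numeric(1), "mean_ratio"),
    pixel_count = vapply(ms, `[[`, numeric(1), "pixel_count"))
  overall <- pixelwise_ratio(pair, pixel_mask(pair, threshold_red,
                                              threshold_green, mode = mode),
                             estimator = estimator,
                             threshold_red = threshold_red,
                             threshold_green = threshold_green)
  list(tiles = df, overall = overall, measurements = ms)
}

#' Aggregate tile measurements into per-condition replicate statistics
#'
#' Within each replicate, tile measurements are combined as a pixel-weighted
#' mean ratio (tiles with more signal carry more weight); replicate means
#' are then averaged unweighted and summarised with
#' [summarize_replicates()].
#'
#' @param groups named list (one element per condition) of lists (one per
#'   replicate) of `ratio_measurement`s; a replicate may also be a single
#'   `ratio_measurement`.
#' @param z confidence multiplier.
#' @return data.frame per condition: `condition`, `mean_ratio`, `sem`,
#'   `ci95_halfwidth`, `n_replicates`, `total_pixels`.
#' @export
aggregate_replicates <- function(groups, z = 1.96) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  one_rep <- function(rep) {
    if (inherits(rep, "ratio_measurement")) rep <- list(rep)
    w <- vapply(rep, `[[`, numeric(1), "pixel_count")
    r <- vapply(rep, `[[`, numeric(1), "mean_ratio")
    keep <- w > 0
    c(ratio = sum(r[keep] * w[keep]) / sum(w[keep]), pixels = sum(w))
  }
  rows <- lapply(names(groups), function(cond) {
    reps <- vapply(groups[[cond]], one_rep, numeric(2))
    ratios <- reps["ratio", ]
    if (length(ratios) >= 2L) {
      s <- summarize_replicates(ratios, z = z)
    } else {
      s <- list(mean = ratios[[1]], sem = NA_real_, ci95_halfwidth = NA_real_)
    }
    data.frame(condition = cond, mean_ratio = s$mean, sem = s$sem,
               ci95_halfwidth = s$ci95_halfwidth,
               n_replicates = length(ratios),
               total_pixels = sum(reps["pixels", ]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
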