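#' Define an experiment design
#'
#' A design is an evenly spaced, inclusive grid of tilt angles crossed with
#' a set of objects, presentation sides and repetitions. The total trial
#' count is `|angles| * |objects| * |sides| * repetitions`.
#'
#' @param name design name.
#' @param angle_min,angle_max,angle_step angle grid in degrees; the grid is
#'   `seq(angle_min, angle_max, angle_step)` and must reach `angle_max`
#'   exactly.
#' @param objects character vector of object ids.
#' @param sides subset of `c("left", "right")`.
#' @param repetitions repetitions per (object, angle, side) cell.
#' @return An `experiment_design` object (a list).
#' @export
experiment_design <- function(name, angle_min, angle_max, angle_step,
                              objects, sides = c("left", "right"),
                              repetitions = 2L) {
  stopifnot(is.character(name), length(objects) >= 1L)
  if (angle_step <= 0 || angle_max < angle_min) {
    stop("configuration error: empty or invalid angle grid", call. = FALSE)
  }
  angles <- seq(angle_min, angle_max, by = angle_step)
  if (abs(angles[length(angles)] - angle_max) > 1e-9) {
    stop("configuration error: angle grid does not land on angle_max",
         call. = FALSE)
  }
  if (!all(sides %in% c("left", "right")) || length(sides) < 1L) {
    stop("sides must be a non-empty subset of {left, right}", call. = FALSE)
  }
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) stop("repetitions must be >= 1", call. = FALSE)
  structure(
    list(name = name, angle_min = angle_min, angle_max = angle_max,
         angle_step = angle_step, angles = angles,
         objects = as.character(objects), sides = sides,
         repetitions = repetitions),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> %s: %d angles (%g-%g by %g), %d objects, %d side(s), %d reps = %d trials\n",
    x$name, length(x$angles), x$angle_min, x$angle_max, x$angle_step,
    length(x$objects), length(x$sides), x$repetitions, n_trials(x)))
  invisible(x)
}

#' Trial count implied by a design
#' @param design an [experiment_design()].
#' @export
n_trials <- function(design) {
  length(design$angles) * length(design$objects) * length(design$sides) *
    design$repetitions
}

#' Expand a design into an empty trial table
#'
#' One row per (object, angle, side, repetition) in a deterministic order;
#' rows are shuffled only when a seed is supplied. `response` and `label`
#' start as `NA` and are filled by observers ([simulate_responses()]) or by
#' ingesting recorded data.
#'
#' @param design an [experiment_design()].
#' @param seed optional integer; when given, the row order is shuffled
#'   reproducibly.
#' @return A trial tibble with columns `object_id`, `angle_deg`, `side`,
#'   `rep`, `response`, `label`.
#' @export
trial_grid <- function(design, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  grid <- tidyr::expand_grid(
    object_id = design$objects,
    angle_deg = design$angles,
    side = design$sides,
    rep = seq_len(design$repetitions)
  )
  grid$response <- NA_integer_
  grid$label <- NA_integer_
  if (!is.null(seed)) {
    ord <- withr::with_seed(seed, sample.int(nrow(grid)))
    grid <- grid[ord, ]
  }
  grid
}

#' Read / write experiment designs as YAML
#'
#' @param path YAML file path. The file holds a list of designs, each with
#'   fields `name`, `angle_min`, `angle_max`, `angle_step`, `objects`,
#'   `sides`, `repetitions`.
#' @return `read_designs()` returns a named list of [experiment_design()]s.
#' @export
read_designs <- function(path) {
  lst <- yaml::read_yaml(path)
  designs <- lapply(lst, function(d) {
    experiment_design(d$name, d$angle_min, d$angle_max, d$angle_step,
                      d$objects, d$sides %||% c("left", "right"),
                      d$repetitions %||% 2L)
  })
  stats::setNames(designs, vapply(designs, `[[`, "", "name"))
}

#' @rdname read_designs
#' @param designs list of [experiment_design()]s to write.
#' @export
write_designs <- function(designs, path) {
  lst <- lapply(designs, function(d) {
    list(name = d$name, angle_min = d$angle_min, angle_max = d$angle_max,
         angle_step = d$angle_step, objects = d$objects, sides = d$sides,
         repetitions = d$repetitions)
  })
  yaml::write_yaml(unname(lst), path)
  invisible(path)
}

#' Rasterize a trial scene
#'
#' Simplified orthographic stand-in for the rendered scene set: a grayscale
#' square canvas containing the tilted object silhouette (value 1) pivoted
#' at the table-edge point, plus the table edge line (value 0.5). Left and
#' right presentation sides are exact mirror images. The canvas is scaled so
#' the object fits at every tilt (fixed per object), unless `units_per_px`
#' pins the scale explicitly.
#'
#' @param spec one-row catalog tibble.
#' @param tilt_deg tilt angle in degrees.
#' @param side `"left"` or `"right"`.
#' @param size canvas side length in pixels (>= 32).
#' @param units_per_px optional fixed scale; errors if the object cannot fit.
#' @return A `scene_image` object: list with `pixels` (size x size matrix in
#'   \[0,1\], row 1 = top), `width`, `height`, `meta`.
#' @export
scene_raster <- function(spec, tilt_deg, side = c("right", "left"),
                         size = 64L, units_per_px = NULL) {
  side <- match.arg(side)
  spec <- validate_catalog(spec)
  stopifnot(nrow(spec) == 1L)
  size <- as.integer(size)
  if (size < 32L) stop("size must be >= 32 px", call. = FALSE)
  R <- spec$bottom_radius; r <- spec$top_radius; h <- spec$height
  # corners relative to the pivot (base rim at the table edge), object inboard
  corners <- rbind(
    c(-2 * R, 0), c(0, 0), c(-R + r, h), c(-R - r, h)
  )
  reach <- sqrt(max(rowSums(corners^2)))
  upp <- if (is.null(units_per_px)) 2.2 * reach / size else units_per_px
  if (2 * reach > upp * size) {
    stop("layout error: object larger than canvas at the given scale",
         call. = FALSE)
  }
  th <- tilt_deg * pi / 180
  rot <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))  # clockwise
  pc <- corners %*% t(rot)
  # pivot at the canvas centre; x to the right, y upward
  half <- upp * size / 2
  px_centers <- (seq_len(size) - 0.5) * upp - half
  X <- matrix(px_centers, size, size, byrow = TRUE)
  Y <- matrix(rev(px_centers), size, size)
  inside <- matrix(TRUE, size, size)
  n <- nrow(pc)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- pc[j, 1] - pc[i, 1]; ey <- pc[j, 2] - pc[i, 2]
    inside <- inside & (ex * (Y - pc[i, 2]) - ey * (X - pc[i, 1]) >= 0)
  }
  pix <- matrix(0, size, size)
  edge <- abs(Y) <= upp / 2 & X <= 0
  pix[edge] <- 0.5
  pix[inside] <- 1
  if (side == "left") pix <- pix[, rev(seq_len(size))]
  structure(
    list(pixels = pix, width = size, height = size,
         meta = list(object_id = spec$object_id, tilt = tilt_deg, side = side)),
    class = "scene_image"
  )
}

#' @export
print.scene_image <- function(x, ...) {
  cat(sprintf("<scene_image> %dx%d px, object %s, tilt %g, side %s\n",
              x$width, x$height, x$meta$object_id, x$meta$tilt, x$meta$side))
  invisible(x)
}

#' Toy pixel embedding of a scene image
#'
#' Downsamples the canvas into a `grid x grid` block-mean vector: a crude
#' stand-in for a pretrained-network embedding, used to exercise the
#' image-based classifier path.
#'
#' @param image a `scene_image`.
#' @param grid blocks per side (canvas size must be divisible by `grid`).
#' @return Numeric vector of length `grid^2`.
#' @export
pixel_embedding <- function(image, grid = 8L) {
  stopifnot(inherits(image, "scene_image"))
  size <- image$width
  if (size %% grid != 0) stop("canvas size must be divisible by grid", call. = FALSE)
  b <- size %/% grid
  m <- image$pixels
  idx <- (seq_len(size) - 1L) %/% b + 1L
  agg <- rowsum(t(rowsum(m, idx)), idx) / b^2
  as.numeric(t(agg))
}
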