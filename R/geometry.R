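#' Hexagonal honeycomb grid specification
#'
#' Describes the grid of pointy-top hexagonal keys used both for the
#' multidirectional point-select task and for keyboard layouts. Keys are laid
#' out in odd-r offset coordinates: odd rows are shifted right by half a key
#' width, and rows are spaced `key_width_px * sqrt(3) / 2` apart, so every
#' pair of adjacent keys (same-row neighbours and row-to-row neighbours alike)
#' is exactly one key width apart centre-to-centre.
#'
#' @param rows,cols Number of key rows and columns (default 9 x 9, the
#'   characterization grid).
#' @param key_width_px Horizontal centre-to-centre key spacing in pixels; this
#'   is the target width `W` in the index of difficulty. Default 130.
#' @param origin_x,origin_y Pixel coordinates of the top-left key centre
#'   (screen convention: x grows rightward, y grows downward).
#'
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec()
#' grid_spec(rows = 3, cols = 10)
#' @export
grid_spec <- function(rows = 9, cols = 9, key_width_px = 130,
                      origin_x = 0, origin_y = 0) {
  stopifnot(rows >= 1, cols >= 1, key_width_px > 0)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         key_width_px = as.numeric(key_width_px),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d hex keys, W = %g px, origin (%g, %g)\n",
              x$rows, x$cols, x$key_width_px, x$origin_x, x$origin_y))
  invisible(x)
}

#' Pixel centre of one key
#'
#' @param grid A [grid_spec()].
#' @param row,col 0-based key indices; row 0 is the top row.
#' @return Named numeric vector `c(x, y)` in pixels.
#' @examples
#' key_center(grid_spec(), 1, 0)  # c(65, 130 * sqrt(3) / 2)
#' @export
key_center <- function(grid, row, col) {
  if (any(row < 0L) || any(row >= grid$rows) ||
      any(col < 0L) || any(col >= grid$cols)) {
    stop("key index out of range for ", grid$rows, " x ", grid$cols, " grid",
         call. = FALSE)
  }
  w <- grid$key_width_px
  x <- grid$origin_x + col * w + ifelse(row %% 2 == 1, w / 2, 0)
  y <- grid$origin_y + row * w * sqrt(3) / 2
  if (length(x) == 1L) c(x = x, y = y) else cbind(x = x, y = y)
}

#' All key centres of a grid as a tibble
#'
#' @param grid A [grid_spec()].
#' @return A tibble with columns `row`, `col`, `x`, `y` (one row per key).
#' @export
key_centers <- function(grid) {
  keys <- tidyr::expand_grid(row = 0:(grid$rows - 1L),
                             col = 0:(grid$cols - 1L))
  ctr <- rbind(key_center(grid, keys$row, keys$col))
  dplyr::mutate(keys, x = unname(ctr[, "x"]), y = unname(ctr[, "y"]))
}

#' Central key of a grid
#'
#' The key whose centre is nearest the centroid of all key centres; used as
#' the homing position and as the origin of the hex-spiral position ordering.
#'
#' @param grid A [grid_spec()].
#' @return A one-row tibble with `row`, `col`, `x`, `y`.
#' @export
grid_center_key <- function(grid) {
  keys <- key_centers(grid)
  d2 <- (keys$x - mean(keys$x))^2 + (keys$y - mean(keys$y))^2
  keys[which.min(d2), ]
}

#' Selection angle between two pixel points
#'
#' Angle of the displacement in the user-facing convention: 0 degrees is
#' rightward and 90 degrees is upward *as seen on screen* (screen y grows
#' downward, so it is negated before the arctangent). Result in [0, 360).
#'
#' @param x_from,y_from,x_to,y_to Pixel coordinates (vectorized).
#' @return Angle(s) in degrees in [0, 360).
#' @examples
#' selection_angle(0, 0, 10, 0)   # 0
#' selection_angle(0, 0, 0, -10)  # 90: up on screen
#' @export
selection_angle <- function(x_from, y_from, x_to, y_to) {
  dx <- x_to - x_from
  dy <- y_to - y_from
  if (any(dx == 0 & dy == 0)) {
    stop("selection angle is undefined for zero displacement", call. = FALSE)
  }
  (atan2(-dy, dx) * 180 / pi) %% 360
}

#' Angular bin scheme
#'
#' Partition of [0, 360) into equal arcs of direction; bin 0 is centred on 0
#' degrees (rightward), bins are indexed counter-clockwise, and each bin is
#' the half-open arc `[c - w/2, c + w/2)` around its centre `c`. The default
#' 16 bins give the four cardinal, four intercardinal, and eight half
#' directions, each owning a symmetric 22.5-degree arc.
#'
#' @param n_bins Number of bins (default 16).
#' @return An object of class `bin_scheme` with `n_bins`, `bin_width_deg`,
#'   `centers_deg`.
#' @export
bin_scheme <- function(n_bins = 16) {
  stopifnot(n_bins >= 1)
  w <- 360 / n_bins
  structure(
    list(n_bins = as.integer(n_bins), bin_width_deg = w,
         centers_deg = w * (0:(n_bins - 1L))),
    class = "bin_scheme"
  )
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> %d bins of %g degrees, bin 0 centred on 0\n",
              x$n_bins, x$bin_width_deg))
  invisible(x)
}

#' Map angles to angular bins
#'
#' @param angle_deg Angle(s) in degrees in [0, 360).
#' @param scheme A [bin_scheme()].
#' @return Integer bin indices in `0:(n_bins - 1)`.
#' @examples
#' bin_of(c(0, 11.25, 350), bin_scheme())  # 0, 1, 0
#' @export
bin_of <- function(angle_deg, scheme = bin_scheme()) {
  w <- scheme$bin_width_deg
  as.integer(floor(((angle_deg + w / 2) %% 360) / w))
}

#' Fitts' law index of difficulty (Shannon formulation)
#'
#' `ID = log2(D / W + 1)` bits, with `D` the movement distance and `W` the
#' (constant) target width. Zero iff `D = 0`, strictly increasing in `D`.
#'
#' @param distance_px Movement distance(s) in pixels, `>= 0`.
#' @param key_width_px Target width in pixels, `> 0`.
#' @return Index of difficulty in bits.
#' @examples
#' index_of_difficulty(c(0, 130, 1040), 130)  # 0, 1, log2(9)
#' @export
index_of_difficulty <- function(distance_px, key_width_px) {
  if (any(distance_px < 0)) {
    stop("distance must be nonnegative", call. = FALSE)
  }
  stopifnot(key_width_px > 0)
  log2(distance_px / key_width_px + 1)
}
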