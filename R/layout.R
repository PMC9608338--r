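#' Candidate key positions for a keyboard footprint
#'
#' Deterministic "hex-spiral" ordering: the `m` grid keys sorted by
#' ascending Euclidean distance from the grid's central key, ties broken by
#' ascending selection angle from that centre (the central key itself comes
#' first). With the default 27 positions on the 9 x 9 grid this yields a
#' compact roughly hexagonal patch around the centre.
#'
#' @param grid A [grid_spec()].
#' @param m Number of positions (default 27, the alphabet size).
#' @return A tibble of `m` rows: `position` (0-based), `row`, `col`, `x`,
#'   `y`.
#' @export
candidate_positions <- function(grid, m = 27) {
  if (m > grid$rows * grid$cols) {
    stop("grid has only ", grid$rows * grid$cols, " keys; cannot take ", m,
         call. = FALSE)
  }
  keys <- key_centers(grid)
  ctr <- grid_center_key(grid)
  d <- sqrt((keys$x - ctr$x)^2 + (keys$y - ctr$y)^2)
  ang <- ifelse(d == 0, 0,
                selection_angle(rep(ctr$x, nrow(keys)), rep(ctr$y, nrow(keys)),
                                keys$x + (d == 0), keys$y))
  ord <- order(round(d, 9), round(ang, 9))[seq_len(m)]
  out <- keys[ord, ]
  out$position <- 0:(m - 1L)
  dplyr::relocate(out, "position")
}

#' Predicted movement-time matrix between candidate positions
#'
#' The QAP's distance matrix: for each ordered pair of positions, the
#' selection angle is computed, the user's directional constants are sampled
#' for that angle, and Fitts' law is applied to the pair's distance. The
#' diagonal holds the zero-distance re-selection time (ID = 0 with the mean
#' intercept over valid bins). The result is generally asymmetric because
#' the constants depend on movement direction. All entries are floored at
#' `mt_floor_s`.
#'
#' @param profile A [fitts_profile] with at least one valid bin.
#' @param positions A position tibble from [candidate_positions()].
#' @param key_width_px Target width `W`; defaults to the profile's grid.
#' @param mt_floor_s Lower bound on predicted movement time (s).
#' @return An `m x m` numeric matrix of seconds.
#' @export
build_mt_matrix <- function(profile, positions,
                            key_width_px = profile$grid$key_width_px,
                            mt_floor_s = 0.05) {
  res <- resolve_bin_constants(profile)
  m <- nrow(positions)
  dx <- outer(positions$x, positions$x, function(a, b) b - a)
  dy <- outer(positions$y, positions$y, function(a, b) b - a)
  dist <- sqrt(dx^2 + dy^2)
  ang <- (atan2(-dy, dx) * 180 / pi) %% 360
  k <- bin_of(ang, profile$scheme)
  a <- matrix(res$a_s[k + 1L], m, m)
  b <- matrix(res$b_s_per_bit[k + 1L], m, m)
  mt <- a + b * index_of_difficulty(dist, key_width_px)
  diag(mt) <- mean(profile$fits$a_s[profile$fits$valid])
  pmax(mt, mt_floor_s)
}

#' Isotropic generic movement model
#'
#' A [fitts_profile] with the standard cursor-movement constants used for
#' generically optimized layouts: delay `a = 0.127` s and acceleration
#' `b = 1/4.9` s/bit in every direction.
#'
#' @param scheme A [bin_scheme()].
#' @param grid A [grid_spec()].
#' @return A [fitts_profile].
#' @export
generic_profile <- function(scheme = bin_scheme(), grid = grid_spec()) {
  profile_from_constants(0.127, 1 / 4.9, scheme = scheme, grid = grid,
                         provenance = "generic isotropic constants")
}

#' Keyboard layout object
#'
#' An assignment of the alphabet's characters to grid key positions.
#'
#' @param keys Tibble with one row per character: `char`, `position`,
#'   `row`, `col`, `x`, `y`.
#' @param grid The [grid_spec()] the positions live on.
#' @param label Human-readable label ("personalized", "generic", "qwerty",
#'   ...).
#' @param energy_s Achieved QAP objective value, if produced by a solver.
#' @param seed RNG seed recorded for provenance.
#' @return An object of class `keyboard_layout`.
#' @export
new_keyboard_layout <- function(keys, grid, label = "layout",
                                energy_s = NA_real_, seed = NA) {
  stopifnot(!anyDuplicated(keys$char), !anyDuplicated(keys[, c("row", "col")]))
  structure(
    list(keys = tibble::as_tibble(keys), grid = grid, label = label,
         energy_s = as.numeric(energy_s), seed = seed),
    class = "keyboard_layout"
  )
}

#' @export
print.keyboard_layout <- function(x, ...) {
  cat(sprintf("<keyboard_layout> '%s': %d keys on %d x %d grid",
              x$label, nrow(x$keys), x$grid$rows, x$grid$cols))
  if (!is.na(x$energy_s)) cat(sprintf(", energy %.4f s", x$energy_s))
  cat("\n")
  invisible(x)
}

#' Tidy a keyboard layout
#'
#' @param x A [keyboard_layout].
#' @param ... Unused.
#' @return The per-key tibble (`char`, `position`, `row`, `col`, `x`, `y`).
#' @export
tidy.keyboard_layout <- function(x, ...) x$keys

#' Plot a keyboard layout
#'
#' Draws the hexagonal keys with their characters at the true pixel
#' positions (screen convention, y down).
#'
#' @param object A [keyboard_layout].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.keyboard_layout <- function(object, ...) {
  w <- object$grid$key_width_px
  r <- w / sqrt(3)  # circumradius of a pointy-top hexagon of width w
  hex <- purrr::pmap_dfr(object$keys[, c("char", "x", "y")],
                         function(char, x, y) {
    th <- pi / 180 * (seq(30, 330, by = 60))
    tibble::tibble(char = char, hx = x + r * cos(th), hy = y + r * sin(th))
  })
  lab <- dplyr::mutate(object$keys,
                       shown = ifelse(.data$char == " ", "\u2423",
                                      .data$char))
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = hex,
                          ggplot2::aes(.data$hx, .data$hy, group = .data$char),
                          fill = "grey95", colour = "grey30") +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(.data$x, .data$y, label = .data$shown)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$label, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' The QWERTY reference layout
#'
#' Standard typewriter rows QWERTYUIOP / ASDFGHJKL / ZXCVBNM with a
#' normal-width space key placed immediately to the right of "M" (so all 27
#' keys have the same width and the layout is comparable to the optimized
#' ones).
#'
#' @param grid A [grid_spec()] with at least 3 rows and 10 columns (default
#'   a 3 x 10 grid of 130-px keys).
#' @return A [keyboard_layout].
#' @export
qwerty_layout <- function(grid = grid_spec(rows = 3, cols = 10)) {
  rows <- c("QWERTYUIOP", "ASDFGHJKL", "ZXCVBNM ")
  if (grid$rows < 3 || grid$cols < 10) {
    stop("QWERTY needs a grid of at least 3 rows and 10 columns",
         call. = FALSE)
  }
  keys <- purrr::imap_dfr(rows, function(s, r) {
    chars <- strsplit(s, "")[[1]]
    tibble::tibble(char = chars, row = r - 1L,
                   col = 0:(length(chars) - 1L))
  })
  ctr <- key_center(grid, keys$row, keys$col)
  keys$x <- ctr[, "x"]
  keys$y <- ctr[, "y"]
  keys$position <- 0:(nrow(keys) - 1L)
  new_keyboard_layout(dplyr::relocate(keys, "char", "position"), grid,
                      label = "qwerty")
}
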