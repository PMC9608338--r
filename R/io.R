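# Canonical JSON writer: fixed key order (construction order), unboxed
# scalars, 6-decimal reals, trailing newline — so identical objects produce
# byte-identical files.
write_canonical_json <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 6, null = "null",
                           na = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

grid_to_list <- function(grid) {
  list(rows = grid$rows, cols = grid$cols,
       key_width_px = grid$key_width_px,
       origin_x = grid$origin_x, origin_y = grid$origin_y)
}

grid_from_list <- function(x) {
  grid_spec(x$rows, x$cols, x$key_width_px, x$origin_x, x$origin_y)
}

#' Write / read a directional Fitts profile as JSON
#'
#' @param profile A [fitts_profile].
#' @param path File path.
#' @return `write_profile` returns `path` invisibly; `read_profile` the
#'   reconstructed [fitts_profile].
#' @export
write_profile <- function(profile, path) {
  write_canonical_json(list(
    scheme = list(n_bins = profile$scheme$n_bins),
    grid = grid_to_list(profile$grid),
    fits = purrr::pmap(profile$fits, function(bin, a_s, b_s_per_bit, r2, n,
                                              residual_sd_s, valid) {
      list(bin = bin, a_s = a_s, b_s_per_bit = b_s_per_bit, r2 = r2, n = n,
           residual_sd_s = residual_sd_s, valid = valid)
    }),
    provenance = profile$provenance,
    seed = profile$seed
  ), path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path)
  fits <- purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(
      bin = as.integer(f$bin),
      a_s = if (is.null(f$a_s)) NA_real_ else as.numeric(f$a_s),
      b_s_per_bit = if (is.null(f$b_s_per_bit)) NA_real_
      else as.numeric(f$b_s_per_bit),
      r2 = if (is.null(f$r2)) NA_real_ else as.numeric(f$r2),
      n = as.integer(f$n),
      residual_sd_s = if (is.null(f$residual_sd_s)) NA_real_
      else as.numeric(f$residual_sd_s),
      valid = isTRUE(f$valid)
    )
  })
  new_fitts_profile(fits, bin_scheme(x$scheme$n_bins),
                    grid_from_list(x$grid),
                    provenance = x$provenance %||% "",
                    seed = x$seed %||% NA)
}

#' Write / read a keyboard layout as JSON
#'
#' @param layout A [keyboard_layout].
#' @param path File path.
#' @return `write_layout` returns `path` invisibly; `read_layout` the
#'   reconstructed [keyboard_layout].
#' @export
write_layout <- function(layout, path) {
  write_canonical_json(list(
    label = layout$label,
    energy_s = layout$energy_s,
    seed = layout$seed,
    grid = grid_to_list(layout$grid),
    keys = purrr::pmap(layout$keys[, c("char", "row", "col", "x", "y")],
                       function(char, row, col, x, y) {
      list(char = char, row = row, col = col,
           center_x = x, center_y = y)
    })
  ), path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- jsonlite::read_json(path)
  grid <- grid_from_list(x$grid)
  keys <- purrr::map_dfr(x$keys, function(k) {
    tibble::tibble(char = k$char, row = as.integer(k$row),
                   col = as.integer(k$col))
  })
  ctr <- key_center(grid, keys$row, keys$col)
  keys$x <- if (is.matrix(ctr)) ctr[, "x"] else ctr["x"]
  keys$y <- if (is.matrix(ctr)) ctr[, "y"] else ctr["y"]
  keys$position <- 0:(nrow(keys) - 1L)
  new_keyboard_layout(dplyr::relocate(keys, "char", "position"), grid,
                      label = x$label %||% "layout",
                      energy_s = x$energy_s %||% NA_real_,
                      seed = x$seed %||% NA)
}

#' Write / read a synthetic user model as JSON
#'
#' @param user A [user_model()].
#' @param path File path.
#' @return `write_user_model` returns `path` invisibly; `read_user_model`
#'   the reconstructed [user_model()].
#' @export
write_user_model <- function(user, path) {
  write_canonical_json(list(
    scheme = list(n_bins = user$scheme$n_bins),
    a_s = user$a_s, b_s_per_bit = user$b_s_per_bit,
    noise_sd_s = user$noise_sd_s, miss_prob = user$miss_prob,
    mt_floor_s = user$mt_floor_s, rng_seed = user$rng_seed
  ), path)
}

#' @rdname write_user_model
#' @export
read_user_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  user_model(a_s = x$a_s, b_s_per_bit = x$b_s_per_bit,
             noise_sd_s = x$noise_sd_s, miss_prob = x$miss_prob,
             mt_floor_s = x$mt_floor_s, rng_seed = x$rng_seed,
             scheme = bin_scheme(x$scheme$n_bins))
}

#' Write / read a characterization trial log as CSV
#'
#' One row per presented target, with click coordinates, distance, movement
#' time, angle, bin, index of difficulty, attempt count, and success flag.
#'
#' @param trials Trial tibble from [run_characterization()].
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` the
#'   trial tibble.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  spec <- readr::cols(
    trial_id = readr::col_integer(), level = readr::col_integer(),
    from_row = readr::col_integer(), from_col = readr::col_integer(),
    to_row = readr::col_integer(), to_col = readr::col_integer(),
    click_from_x = readr::col_double(), click_from_y = readr::col_double(),
    click_to_x = readr::col_double(), click_to_y = readr::col_double(),
    distance_px = readr::col_double(),
    movement_time_s = readr::col_double(),
    angle_deg = readr::col_double(), bin = readr::col_integer(),
    id_bits = readr::col_double(),
    n_click_attempts = readr::col_integer(),
    success = readr::col_logical()
  )
  out <- readr::read_csv(path, col_types = spec, progress = FALSE)
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    stop(sprintf("malformed trial log '%s': row %d, %s", path,
                 prob$row[1], prob$expected[1]), call. = FALSE)
  }
  out
}

#' Write / read a digraph flow matrix as CSV
#'
#' The first column (`from`) holds the from-characters; remaining column
#' names are the to-characters (space spelled as itself).
#'
#' @param flow Digraph count matrix with dimnames.
#' @param path File path.
#' @return `write_flow` returns `path` invisibly; `read_flow` the matrix.
#' @export
write_flow <- function(flow, path) {
  df <- tibble::as_tibble(flow, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(from = rownames(flow)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_flow
#' @export
read_flow <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    from = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE, trim_ws = FALSE)  # keep the space key's label
  m <- as.matrix(df[, -1])
  rownames(m) <- df$from
  storage.mode(m) <- "integer"
  m
}
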