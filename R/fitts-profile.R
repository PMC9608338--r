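#' Directional Fitts profile
#'
#' A `fitts_profile` holds one ordinary-least-squares Fitts' law fit per
#' angular bin — the intercept `a` (s), slope `b` (s/bit), `R^2`, trial
#' count, and residual SD — together with the bin scheme and grid it was
#' measured on. It is the movement-ability summary that drives keyboard
#' personalization.
#'
#' @param fits Tibble with one row per bin: `bin`, `a_s`, `b_s_per_bit`,
#'   `r2`, `n`, `residual_sd_s`, `valid`.
#' @param scheme The [bin_scheme()].
#' @param grid The [grid_spec()].
#' @param provenance Free-text provenance note.
#' @param seed The RNG seed recorded with the profile.
#' @return An object of class `fitts_profile`.
#' @name fitts_profile
#' @export
new_fitts_profile <- function(fits, scheme, grid, provenance = "", seed = NA) {
  stopifnot(nrow(fits) == scheme$n_bins,
            setequal(fits$bin, 0:(scheme$n_bins - 1L)))
  fits <- dplyr::arrange(fits, .data$bin)
  structure(
    list(fits = fits, scheme = scheme, grid = grid,
         provenance = provenance, seed = seed),
    class = "fitts_profile"
  )
}

#' Build a profile directly from known directional constants
#'
#' Convenience constructor for a fully valid profile with given per-bin
#' constants (for example a synthetic user's ground truth), bypassing the
#' point-select task.
#'
#' @param a_s,b_s_per_bit Per-bin constants (recycled if scalar).
#' @inheritParams new_fitts_profile
#' @return A [fitts_profile].
#' @export
profile_from_constants <- function(a_s, b_s_per_bit, scheme = bin_scheme(),
                                   grid = grid_spec(),
                                   provenance = "constants") {
  n <- scheme$n_bins
  fits <- tibble::tibble(
    bin = 0:(n - 1L),
    a_s = rep_len(as.numeric(a_s), n),
    b_s_per_bit = rep_len(as.numeric(b_s_per_bit), n),
    r2 = 1, n = n, residual_sd_s = 0, valid = TRUE
  )
  new_fitts_profile(fits, scheme, grid, provenance = provenance)
}

#' @export
print.fitts_profile <- function(x, ...) {
  nv <- sum(x$fits$valid)
  cat(sprintf("<fitts_profile> %d bins (%d valid)\n", x$scheme$n_bins, nv))
  if (nv > 0) {
    v <- x$fits[x$fits$valid, ]
    cat(sprintf("  a: %.3f-%.3f s   b: %.3f-%.3f s/bit   mean R^2 %.2f\n",
                min(v$a_s), max(v$a_s), min(v$b_s_per_bit),
                max(v$b_s_per_bit), mean(v$r2)))
  }
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a directional Fitts profile
#'
#' @param x A [fitts_profile].
#' @param ... Unused.
#' @return One row per angular bin with the bin centre angle and the fit
#'   columns.
#' @export
tidy.fitts_profile <- function(x, ...) {
  dplyr::mutate(x$fits, center_deg = x$scheme$centers_deg[.data$bin + 1L],
                .after = "bin")
}

#' One-row summary of a directional Fitts profile
#'
#' @param x A [fitts_profile].
#' @param ... Unused.
#' @return A one-row tibble: bin counts, mean constants over valid bins,
#'   mean `R^2`, total trials used.
#' @export
glance.fitts_profile <- function(x, ...) {
  v <- x$fits[x$fits$valid, ]
  tibble::tibble(
    n_bins = x$scheme$n_bins, n_valid = nrow(v),
    mean_a_s = mean(v$a_s), mean_b_s_per_bit = mean(v$b_s_per_bit),
    mean_r2 = mean(v$r2), n_trials = sum(x$fits$n)
  )
}

# Per-bin constants with invalid bins resolved to the nearest valid bin by
# circular bin distance (equidistant pair -> average of the two).
resolve_bin_constants <- function(profile) {
  fits <- profile$fits
  nb <- profile$scheme$n_bins
  if (!any(fits$valid)) {
    stop("profile has no valid bin fits", call. = FALSE)
  }
  valid_bins <- fits$bin[fits$valid]
  resolve <- function(k) {
    if (fits$valid[k + 1L]) {
      return(c(a = fits$a_s[k + 1L], b = fits$b_s_per_bit[k + 1L]))
    }
    dd <- pmin((valid_bins - k) %% nb, (k - valid_bins) %% nb)
    nearest <- valid_bins[dd == min(dd)]
    c(a = mean(fits$a_s[nearest + 1L]),
      b = mean(fits$b_s_per_bit[nearest + 1L]))
  }
  ab <- vapply(0:(nb - 1L), resolve, numeric(2))
  tibble::tibble(bin = 0:(nb - 1L), a_s = ab["a", ], b_s_per_bit = ab["b", ])
}

#' Sample directional Fitts constants for given angles
#'
#' Returns the constants of the bin containing each angle (piecewise
#' constant over bins). If that bin's fit is invalid, the nearest valid bin
#' by circular distance is used; when two valid bins are equidistant their
#' constants are averaged.
#'
#' @param profile A [fitts_profile] with at least one valid bin.
#' @param angle_deg Angle(s) in degrees.
#' @return A tibble with columns `angle_deg`, `bin`, `a_s`, `b_s_per_bit`.
#' @export
sample_constants <- function(profile, angle_deg) {
  res <- resolve_bin_constants(profile)
  k <- bin_of(angle_deg %% 360, profile$scheme)
  tibble::tibble(angle_deg = angle_deg, bin = k,
                 a_s = res$a_s[k + 1L], b_s_per_bit = res$b_s_per_bit[k + 1L])
}

#' Plot a directional Fitts profile
#'
#' Polar chart of the per-bin intercept and slope: each spoke points in the
#' movement direction of its bin; invalid bins are hollow.
#'
#' @param object A [fitts_profile].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fitts_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("a_s", "b_s_per_bit"),
                            names_to = "constant", values_to = "value")
  df$constant <- dplyr::recode(df$constant, a_s = "a (s)",
                               b_s_per_bit = "b (s/bit)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center_deg, y = .data$value,
                                   fill = .data$valid)) +
    ggplot2::geom_col(width = 360 / object$scheme$n_bins * 0.9,
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-360 / object$scheme$n_bins / 2,
                                           360 - 360 / object$scheme$n_bins / 2),
                                breaks = c(0, 90, 180, 270)) +
    ggplot2::facet_wrap(~constant) +
    ggplot2::labs(x = "movement direction (deg)", y = NULL,
                  fill = "valid fit") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
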