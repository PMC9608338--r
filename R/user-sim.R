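#' Synthetic user model
#'
#' Ground-truth generative model of a single-input user: movement time for a
#' selection follows the directional Fitts' law
#' `MT = a*(bin) + b*(bin) * ID + eps`, with `eps ~ Normal(0, noise_sd_s)`,
#' floored at `mt_floor_s`, plus an independent per-click miss probability.
#' Zero-distance re-selections use `ID = 0` and the mean of `a*` across bins
#' (there is no defined direction).
#'
#' @param a_s True intercepts in seconds, one per angular bin (recycled if
#'   scalar).
#' @param b_s_per_bit True slopes in s/bit, one per bin (recycled if scalar).
#' @param noise_sd_s SD of additive Gaussian movement-time noise (s).
#' @param miss_prob Probability that any single click misses its target.
#' @param mt_floor_s Lower bound on any movement-time draw (s); keeps draws
#'   physical.
#' @param rng_seed Seed used by default when this user transcribes a prompt.
#' @param scheme The [bin_scheme()] over which `a_s`/`b_s_per_bit` are
#'   defined.
#'
#' @return An object of class `user_model`.
#' @examples
#' user_model(a_s = 0.5, b_s_per_bit = 1.0, noise_sd_s = 0)
#' @export
user_model <- function(a_s, b_s_per_bit, noise_sd_s = 0.1, miss_prob = 0,
                       mt_floor_s = 0.05, rng_seed = 1L,
                       scheme = bin_scheme()) {
  a <- rep_len(as.numeric(a_s), scheme$n_bins)
  b <- rep_len(as.numeric(b_s_per_bit), scheme$n_bins)
  stopifnot(all(a >= 0), all(b >= 0), noise_sd_s >= 0,
            miss_prob >= 0, miss_prob < 1, mt_floor_s >= 0)
  structure(
    list(a_s = a, b_s_per_bit = b, noise_sd_s = as.numeric(noise_sd_s),
         miss_prob = as.numeric(miss_prob), mt_floor_s = as.numeric(mt_floor_s),
         rng_seed = as.integer(rng_seed), scheme = scheme),
    class = "user_model"
  )
}

#' @export
print.user_model <- function(x, ...) {
  cat(sprintf(
    "<user_model> %d bins; a* in [%.2f, %.2f] s, b* in [%.2f, %.2f] s/bit\n",
    x$scheme$n_bins, min(x$a_s), max(x$a_s), min(x$b_s_per_bit),
    max(x$b_s_per_bit)))
  cat(sprintf("  noise sd %.3g s, miss prob %.3g, seed %d\n",
              x$noise_sd_s, x$miss_prob, x$rng_seed))
  invisible(x)
}

#' Draw a random synthetic user
#'
#' Per-bin intercepts are uniform on `a_range` and slopes uniform on
#' `b_range`; the defaults span the ability range seen with head-tilt cursor
#' control (intercepts 0.3-1.3 s, slopes 0.4-1.4 s/bit, noise SD 0.1 s).
#'
#' @param seed Integer seed; also stored as the user's `rng_seed`.
#' @param a_range,b_range Ranges for the per-bin constants.
#' @inheritParams user_model
#' @return A [user_model()].
#' @export
random_user_model <- function(seed, a_range = c(0.3, 1.3),
                              b_range = c(0.4, 1.4), noise_sd_s = 0.1,
                              miss_prob = 0, scheme = bin_scheme()) {
  set.seed(seed)
  user_model(
    a_s = stats::runif(scheme$n_bins, a_range[1], a_range[2]),
    b_s_per_bit = stats::runif(scheme$n_bins, b_range[1], b_range[2]),
    noise_sd_s = noise_sd_s, miss_prob = miss_prob, rng_seed = seed,
    scheme = scheme
  )
}

# One movement-time draw for a displacement already resolved to (a, b, ID).
mt_draw <- function(user, a, b, id_bits) {
  max(user$mt_floor_s, a + b * id_bits + stats::rnorm(1, 0, user$noise_sd_s))
}

#' Simulate one target selection
#'
#' Draws the movement time for one point-select from `(x_from, y_from)` to
#' `(x_to, y_to)` under the user's directional Fitts' law. With
#' `retry = TRUE` (the characterization task, which gives unlimited chances)
#' each miss adds one attempt and an independent re-homing movement-time
#' draw until the click lands, and the selection always succeeds; with
#' `retry = FALSE` (transcription) a single attempt is made and `success`
#' may be `FALSE`.
#'
#' Uses the current RNG state; seed the stream before calling for
#' reproducibility.
#'
#' @param user A [user_model()].
#' @param x_from,y_from,x_to,y_to Pixel coordinates of the two click points.
#' @param key_width_px Target width `W` in pixels.
#' @param retry Unlimited chances (`TRUE`) or single attempt (`FALSE`).
#' @return A list with `movement_time_s`, `success`, `n_click_attempts`.
#' @export
simulate_selection <- function(user, x_from, y_from, x_to, y_to,
                               key_width_px, retry = TRUE) {
  d <- sqrt((x_to - x_from)^2 + (y_to - y_from)^2)
  if (d == 0) {
    a <- mean(user$a_s)
    b <- 0
    id <- 0
  } else {
    ang <- selection_angle(x_from, y_from, x_to, y_to)
    k <- bin_of(ang, user$scheme) + 1L
    a <- user$a_s[k]
    b <- user$b_s_per_bit[k]
    id <- index_of_difficulty(d, key_width_px)
  }
  mt <- mt_draw(user, a, b, id)
  if (!retry) {
    return(list(movement_time_s = mt,
                success = stats::runif(1) >= user$miss_prob,
                n_click_attempts = 1L))
  }
  attempts <- 1L
  while (stats::runif(1) < user$miss_prob) {
    attempts <- attempts + 1L
    mt <- mt + mt_draw(user, a, b, id)
  }
  list(movement_time_s = mt, success = TRUE, n_click_attempts = attempts)
}

#' Simulate transcription of a prompt on a keyboard layout
#'
#' Walks the prompt's character sequence over the layout's key centres. The
#' first character is reached from the layout's central key; each later
#' character is reached from the previously *selected* key. A missed click
#' selects a uniformly random key adjacent to the intended target and the
#' walk continues from there without correction (the task is uncorrected
#' transcription).
#'
#' @param user A [user_model()].
#' @param layout A [keyboard_layout] (see [solve_qap()], [qwerty_layout()]).
#' @param prompt Prompt text; uppercased and whitespace-collapsed before
#'   simulation. Every remaining character must be on the layout.
#' @param seed Seed for this session (default: the user's `rng_seed`); pass
#'   `NULL` to continue from the current RNG state.
#' @return A `session_log` tibble with one row per selection: `from_char`,
#'   `intended`, `selected`, `movement_time_s`, `success`; the prompt is kept
#'   in the `"prompt"` attribute.
#' @export
simulate_transcription <- function(user, layout, prompt,
                                   seed = user$rng_seed) {
  if (!is.null(seed)) set.seed(seed)
  keys <- layout$keys
  chars <- strsplit(normalize_text(prompt), "")[[1]]
  missing <- setdiff(chars, keys$char)
  if (length(missing) > 0) {
    stop("prompt character(s) not on layout: ",
         paste(sprintf("'%s'", missing), collapse = ", "), call. = FALSE)
  }
  w <- layout$grid$key_width_px
  start <- which.min((keys$x - mean(keys$x))^2 + (keys$y - mean(keys$y))^2)
  n <- length(chars)
  out <- vector("list", n)
  cur <- start
  for (i in seq_len(n)) {
    tgt <- match(chars[i], keys$char)
    sel <- simulate_selection(user, keys$x[cur], keys$y[cur],
                              keys$x[tgt], keys$y[tgt], w, retry = FALSE)
    if (sel$success) {
      landed <- tgt
    } else {
      d <- sqrt((keys$x - keys$x[tgt])^2 + (keys$y - keys$y[tgt])^2)
      nbr <- which(d > 0 & d <= w * 1.001)
      if (length(nbr) == 0) nbr <- which(d > 0 & d <= min(d[d > 0]) * 1.001)
      landed <- nbr[sample.int(length(nbr), 1)]
    }
    out[[i]] <- tibble::tibble(
      from_char = keys$char[cur], intended = chars[i],
      selected = keys$char[landed], movement_time_s = sel$movement_time_s,
      success = sel$success
    )
    cur <- landed
  }
  log <- if (n == 0) {
    tibble::tibble(from_char = character(), intended = character(),
                   selected = character(), movement_time_s = numeric(),
                   success = logical())
  } else {
    dplyr::bind_rows(out)
  }
  attr(log, "prompt") <- prompt
  class(log) <- c("session_log", class(log))
  log
}

#' Total duration of a transcription session
#'
#' @param session A `session_log` from [simulate_transcription()].
#' @return Total movement time in seconds.
#' @export
session_time <- function(session) sum(session$movement_time_s)
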