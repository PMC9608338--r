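#' Configuration of the multidirectional point-select task
#'
#' Defaults reproduce the published task design: nine key-separation levels
#' (0-8 key widths), 25 seeded targets per level (225 total), a hard cap of
#' 400 presented targets, at least 10 directional trials per angular bin, a
#' repeat rule for bins with `R^2 <= 0.25`, and a 3-SD outlier rule.
#'
#' @param n_levels Number of key-separation levels (level `k` targets a key
#'   about `k` key widths away; level 0 re-selects the same key).
#' @param per_level Seeded targets per level.
#' @param max_targets Hard cap on total presented targets.
#' @param min_per_bin Minimum directional trials required per angular bin.
#' @param r2_threshold A bin whose movement-time regression has
#'   `R^2 <= r2_threshold` is re-presented with more targets.
#' @param outlier_sd Trials more than `outlier_sd` residual SDs from the
#'   bin regression are flagged for repetition.
#' @param rng_seed Seed driving queue shuffling, target planning ties, and
#'   the simulated user during [run_characterization()].
#' @param include_level0 If `TRUE`, zero-distance (level-0) trials are added
#'   to every bin's regression as `(ID = 0, MT)` points. Off by default:
#'   zero-distance movement time has no direction, so sharing it across bins
#'   pulls each bin's intercept toward the all-bin mean and masks real
#'   directional differences (see the methods vignette).
#' @param repeat_levels Separation levels used to pad a deficient bin's
#'   repeat batch, spanning low/mid/high separation.
#' @return An object of class `seed_config`.
#' @export
seed_config <- function(n_levels = 9, per_level = 25, max_targets = 400,
                        min_per_bin = 10, r2_threshold = 0.25,
                        outlier_sd = 3, rng_seed = 1L,
                        include_level0 = FALSE, repeat_levels = c(2, 5, 8)) {
  stopifnot(n_levels >= 1, per_level >= 1,
            n_levels * per_level <= max_targets,
            min_per_bin >= 1, r2_threshold >= 0, r2_threshold < 1,
            outlier_sd > 0)
  repeat_levels <- repeat_levels[repeat_levels >= 1 &
                                   repeat_levels < n_levels]
  structure(
    list(n_levels = as.integer(n_levels), per_level = as.integer(per_level),
         max_targets = as.integer(max_targets),
         min_per_bin = as.integer(min_per_bin),
         r2_threshold = as.numeric(r2_threshold),
         outlier_sd = as.numeric(outlier_sd),
         rng_seed = as.integer(rng_seed),
         include_level0 = isTRUE(include_level0),
         repeat_levels = as.integer(repeat_levels)),
    class = "seed_config"
  )
}

#' Seed the characterization target queue
#'
#' @param cfg A [seed_config()].
#' @return An integer vector of separation levels: `per_level` copies of each
#'   level in `0:(n_levels - 1)`, uniformly shuffled by `cfg$rng_seed`.
#' @export
seed_queue <- function(cfg = seed_config()) {
  set.seed(cfg$rng_seed)
  sample(rep(0:(cfg$n_levels - 1L), cfg$per_level))
}

#' Plan the next target key
#'
#' Picks a key realizing the queued separation level from the previous key,
#' steering coverage toward under-sampled movement directions. Level 0 means
#' re-selecting the previous key. Otherwise candidate keys are those whose
#' centre distance from the previous key is within half a key width of
#' `level * W`; among them, keys whose selection angle falls in the least
#' covered bin are preferred (ties broken uniformly at random from the
#' current RNG stream). If the distance window contains no key it is relaxed
#' in steps of a quarter key width until one does.
#'
#' @param grid A [grid_spec()].
#' @param scheme A [bin_scheme()].
#' @param prev_row,prev_col The previous key.
#' @param level Separation level in `0:(n_levels - 1)`.
#' @param coverage Integer vector of per-bin directional trial counts.
#' @param prefer_bin Optional bin index: plan a target whose selection angle
#'   falls in this bin (used when repeating a deficient bin), falling back
#'   to the coverage rule if that direction is unreachable at this level.
#' @return A list with `row`, `col`, `x`, `y`, `angle_deg`, `bin`
#'   (angle/bin are `NA` for level 0).
#' @export
plan_next_target <- function(grid, scheme, prev_row, prev_col, level,
                             coverage = integer(scheme$n_bins),
                             prefer_bin = NULL) {
  prev <- key_center(grid, prev_row, prev_col)
  if (level == 0) {
    return(list(row = prev_row, col = prev_col,
                x = unname(prev["x"]), y = unname(prev["y"]),
                angle_deg = NA_real_, bin = NA_integer_))
  }
  keys <- key_centers(grid)
  keys <- keys[!(keys$row == prev_row & keys$col == prev_col), ]
  if (nrow(keys) == 0) stop("cannot plan a moving target on a 1-key grid",
                            call. = FALSE)
  w <- grid$key_width_px
  d <- sqrt((keys$x - prev["x"])^2 + (keys$y - prev["y"])^2)
  ang <- selection_angle(prev["x"], prev["y"], keys$x, keys$y)
  bins <- bin_of(ang, scheme)
  win <- 0.5 * w
  max_win <- max(d) + level * w
  cand <- integer(0)
  while (win <= max_win) {
    in_win <- which(abs(d - level * w) <= win)
    if (!is.null(prefer_bin)) {
      hit <- in_win[bins[in_win] == prefer_bin]
      if (length(hit) > 0) { cand <- hit; break }
    } else if (length(in_win) > 0) {
      cand <- in_win
      break
    }
    win <- win + 0.25 * w
  }
  if (length(cand) == 0) {
    # preferred direction unreachable at any window: fall back to coverage rule
    cand <- which(abs(d - level * w) <= 0.5 * w)
    win <- 0.5 * w
    while (length(cand) == 0) {
      win <- win + 0.25 * w
      cand <- which(abs(d - level * w) <= win)
    }
  }
  cov_cand <- coverage[bins[cand] + 1L]
  best <- cand[cov_cand == min(cov_cand)]
  pick <- best[sample.int(length(best), 1)]
  list(row = keys$row[pick], col = keys$col[pick],
       x = keys$x[pick], y = keys$y[pick],
       angle_deg = unname(ang[pick]), bin = bins[pick])
}

#' Ordinary least squares Fitts fit for one angular bin
#'
#' Regresses movement time on index of difficulty for the trials of one bin.
#' The fit is `valid` when the bin holds at least `min_per_bin` trials with
#' at least two distinct ID values and the coefficient of determination
#' exceeds `r2_threshold`.
#'
#' @param trials Tibble of trials sharing one bin, with columns `id_bits`
#'   and `movement_time_s`.
#' @param bin The bin index, recorded in the output.
#' @param cfg A [seed_config()] supplying `min_per_bin` and `r2_threshold`.
#' @return A one-row tibble: `bin`, `a_s`, `b_s_per_bit`, `r2`, `n`,
#'   `residual_sd_s`, `valid`.
#' @export
fit_bin <- function(trials, bin, cfg = seed_config()) {
  n <- nrow(trials)
  empty <- tibble::tibble(bin = as.integer(bin), a_s = NA_real_,
                          b_s_per_bit = NA_real_, r2 = NA_real_, n = n,
                          residual_sd_s = NA_real_, valid = FALSE)
  if (n == 0) return(empty)
  x <- trials$id_bits
  y <- trials$movement_time_s
  if (length(unique(x)) < 2) {
    empty$a_s <- mean(y)
    empty$r2 <- 0
    return(empty)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  res_sd <- if (n > 2) sqrt(ss_res / (n - 2)) else 0
  tibble::tibble(
    bin = as.integer(bin),
    a_s = unname(fit$coefficients[1]),
    b_s_per_bit = unname(fit$coefficients[2]),
    r2 = r2, n = n, residual_sd_s = res_sd,
    valid = n >= cfg$min_per_bin && r2 > cfg$r2_threshold
  )
}

#' Flag movement-time outliers against a bin regression
#'
#' A trial is an outlier when its absolute residual from the bin's fitted
#' line strictly exceeds `outlier_sd` times the residual SD. An invalid fit
#' flags nothing.
#'
#' @param fit A one-row fit from [fit_bin()].
#' @param trials The trials the fit was computed on.
#' @param outlier_sd SD multiplier (default 3).
#' @return The subset of `trials` flagged as outliers.
#' @export
detect_outliers <- function(fit, trials, outlier_sd = 3) {
  if (!isTRUE(fit$valid) || is.na(fit$residual_sd_s)) return(trials[0, ])
  # an (essentially) exact fit has no outliers; guards against flagging
  # floating-point residuals of a perfect line
  if (fit$residual_sd_s < 1e-12) return(trials[0, ])
  resid <- abs(trials$movement_time_s -
                 (fit$a_s + fit$b_s_per_bit * trials$id_bits))
  trials[resid > outlier_sd * fit$residual_sd_s, ]
}

# Rows of `trials` entering bin k's regression.
bin_trials <- function(trials, k, include_level0 = FALSE) {
  rows <- !is.na(trials$bin) & trials$bin == k
  if (include_level0) rows <- rows | trials$level == 0L
  trials[rows, ]
}

#' Fit a directional Fitts profile from a trial log
#'
#' Runs [fit_bin()] over every angular bin of a trial log (for instance one
#' replayed from disk) and assembles a [fitts_profile].
#'
#' @param trials A trial tibble as produced by [run_characterization()] (or
#'   read back with [read_trials()]).
#' @param scheme A [bin_scheme()].
#' @param grid The [grid_spec()] the trials were collected on.
#' @param cfg A [seed_config()].
#' @param provenance Free-text provenance note.
#' @return A [fitts_profile].
#' @export
fit_profile <- function(trials, scheme = bin_scheme(), grid = grid_spec(),
                        cfg = seed_config(), provenance = "fit from log") {
  fits <- purrr::map_dfr(0:(scheme$n_bins - 1L), function(k) {
    fit_bin(bin_trials(trials, k, cfg$include_level0), k, cfg)
  })
  new_fitts_profile(fits, scheme, grid,
                    provenance = provenance, seed = cfg$rng_seed)
}

# Present one planned target to the simulated user and log the trial.
present_target <- function(user, grid, scheme, trials, prev, level,
                           coverage, prefer_bin = NULL) {
  tgt <- plan_next_target(grid, scheme, prev$row, prev$col, level,
                          coverage, prefer_bin)
  d <- sqrt((tgt$x - prev$x)^2 + (tgt$y - prev$y)^2)
  sel <- simulate_selection(user, prev$x, prev$y, tgt$x, tgt$y,
                            grid$key_width_px, retry = TRUE)
  rec <- tibble::tibble(
    trial_id = nrow(trials) + 1L, level = as.integer(level),
    from_row = prev$row, from_col = prev$col,
    to_row = tgt$row, to_col = tgt$col,
    click_from_x = prev$x, click_from_y = prev$y,
    click_to_x = tgt$x, click_to_y = tgt$y,
    distance_px = d, movement_time_s = sel$movement_time_s,
    angle_deg = tgt$angle_deg, bin = tgt$bin,
    id_bits = index_of_difficulty(d, grid$key_width_px),
    n_click_attempts = sel$n_click_attempts, success = sel$success
  )
  list(trials = dplyr::bind_rows(trials, rec),
       prev = list(row = tgt$row, col = tgt$col, x = tgt$x, y = tgt$y))
}

#' Run the adaptive movement-characterization task on a simulated user
#'
#' Presents the seeded queue of 225 targets, then repeatedly fits per-bin
#' Fitts regressions and appends repeat targets for every bin that fails the
#' quality rule (at least `min_per_bin` directional trials and
#' `R^2 > r2_threshold`) or still holds an un-repeated outlier, until all
#' bins pass or the presented-target count reaches `max_targets`, at which
#' point the task stops exactly at the cap. Each deficient bin receives up
#' to three repeat targets per pass at distinct separation levels (the
#' levels of its un-repeated outliers first, padded from
#' `cfg$repeat_levels`). An outlier counts as repeated once a later trial in
#' the same bin at the same level has been presented; the outlier itself
#' stays in the data.
#'
#' @param user A [user_model()].
#' @param grid A [grid_spec()].
#' @param scheme A [bin_scheme()].
#' @param cfg A [seed_config()]; its `rng_seed` drives the queue shuffle,
#'   planner ties, and the user's noise stream.
#' @return A list with `profile` (a [fitts_profile]) and `trials` (the full
#'   trial tibble, one row per presented target).
#' @export
run_characterization <- function(user, grid = grid_spec(),
                                 scheme = bin_scheme(),
                                 cfg = seed_config()) {
  queue <- seed_queue(cfg)  # also seeds the RNG stream for everything below
  start <- grid_center_key(grid)
  prev <- list(row = start$row, col = start$col, x = start$x, y = start$y)
  trials <- NULL
  coverage <- integer(scheme$n_bins)
  for (level in queue) {
    step <- present_target(user, grid, scheme,
                           trials %||% empty_trials(), prev, level, coverage)
    trials <- step$trials
    prev <- step$prev
    b <- trials$bin[nrow(trials)]
    if (!is.na(b)) coverage[b + 1L] <- coverage[b + 1L] + 1L
  }

  outliers <- tibble::tibble(trial_id = integer(), bin = integer(),
                             level = integer(), flagged_at = integer())
  repeat {
    fits <- purrr::map_dfr(0:(scheme$n_bins - 1L), function(k) {
      fit_bin(bin_trials(trials, k, cfg$include_level0), k, cfg)
    })
    # flag new outliers bin by bin
    for (k in 0:(scheme$n_bins - 1L)) {
      btr <- bin_trials(trials, k, include_level0 = FALSE)
      out <- detect_outliers(fits[fits$bin == k, ], btr, cfg$outlier_sd)
      new <- out[!(out$trial_id %in% outliers$trial_id), ]
      if (nrow(new) > 0) {
        outliers <- dplyr::bind_rows(outliers, tibble::tibble(
          trial_id = new$trial_id, bin = as.integer(k),
          level = new$level, flagged_at = nrow(trials)))
      }
    }
    # an outlier is repeated once a later same-bin same-level trial exists
    open <- outliers[!purrr::map_lgl(seq_len(nrow(outliers)), function(i) {
      any(!is.na(trials$bin) &
            trials$bin == outliers$bin[i] &
            trials$level == outliers$level[i] &
            trials$trial_id > outliers$flagged_at[i])
    }), ]
    dir_n <- purrr::map_int(0:(scheme$n_bins - 1L), function(k) {
      nrow(bin_trials(trials, k, include_level0 = FALSE))
    })
    deficient <- which(
      dir_n < cfg$min_per_bin | !fits$valid |
        (0:(scheme$n_bins - 1L)) %in% open$bin
    ) - 1L
    if (length(deficient) == 0 || nrow(trials) >= cfg$max_targets) break
    budget <- cfg$max_targets - nrow(trials)
    for (k in deficient) {
      lv <- unique(c(open$level[open$bin == k], cfg$repeat_levels))
      lv <- utils::head(lv[lv > 0], 3)
      for (level in lv) {
        if (budget <= 0) break
        step <- present_target(user, grid, scheme, trials, prev, level,
                               coverage, prefer_bin = k)
        trials <- step$trials
        prev <- step$prev
        b <- trials$bin[nrow(trials)]
        if (!is.na(b)) coverage[b + 1L] <- coverage[b + 1L] + 1L
        budget <- budget - 1L
      }
      if (budget <= 0) break
    }
  }

  profile <- new_fitts_profile(
    fits, scheme, grid,
    provenance = sprintf("simulated characterization, %d targets",
                         nrow(trials)),
    seed = cfg$rng_seed
  )
  list(profile = profile, trials = trials)
}

empty_trials <- function() {
  tibble::tibble(
    trial_id = integer(), level = integer(),
    from_row = integer(), from_col = integer(),
    to_row = integer(), to_col = integer(),
    click_from_x = numeric(), click_from_y = numeric(),
    click_to_x = numeric(), click_to_y = numeric(),
    distance_px = numeric(), movement_time_s = numeric(),
    angle_deg = numeric(), bin = integer(), id_bits = numeric(),
    n_click_attempts = integer(), success = logical()
  )
}
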