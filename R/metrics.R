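#' Words per minute of a transcription session
#'
#' Characters selected (correct or incorrect) per minute, divided by the
#' conventional 5 characters per word.
#'
#' @param session A `session_log` from [simulate_transcription()].
#' @return Words per minute.
#' @examples
#' # 50 selections in 2 minutes -> 5 wpm
#' @export
wpm <- function(session) {
  total <- session_time(session)
  n <- nrow(session)
  if (n == 0) {
    if (total <= 0) stop("rate undefined for an empty zero-duration session",
                         call. = FALSE)
    return(0)
  }
  if (total <= 0) stop("rate undefined: session has zero duration",
                       call. = FALSE)
  (n / (total / 60)) / 5
}

#' Words per minute excluding space transitions (WPM*)
#'
#' Recomputes [wpm()] after removing every selection whose source or
#' destination character is the space key — both the character and its
#' movement time are dropped. With `drop_time_only = TRUE` only the times
#' are dropped and all characters still count (a documented alternative
#' reading of "excluding the space key").
#'
#' @param session A `session_log`.
#' @param drop_time_only Keep all characters and subtract only the
#'   space-adjacent movement times.
#' @return Words per minute over the space-free remainder.
#' @export
wpm_star <- function(session, drop_time_only = FALSE) {
  spacey <- session$from_char == " " | session$selected == " "
  kept <- session[!spacey, ]
  total <- sum(kept$movement_time_s)
  n <- if (drop_time_only) nrow(session) else nrow(kept)
  if (total <= 0) stop("rate undefined: no non-space transitions remain",
                       call. = FALSE)
  (n / (total / 60)) / 5
}

#' Target-selection accuracy of a session
#'
#' Each selection scores 100 when the intended target was selected and 0
#' otherwise.
#'
#' @param session A `session_log`.
#' @return Accuracy in percent.
#' @export
accuracy <- function(session) {
  if (nrow(session) == 0) stop("accuracy undefined for an empty session",
                               call. = FALSE)
  100 * mean(session$success)
}

#' Wolpaw information transfer rate
#'
#' Bits per selection
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`
#' (with `0 log2 0 = 0`), multiplied by the selection rate per minute. `B`
#' is floored at 0 below chance accuracy (`P < 1/N`) so rates stay
#' nonnegative.
#'
#' @param session A `session_log`.
#' @param n_targets Number of possible targets `N` (default 27 keys).
#' @return Information transfer rate in bits/min.
#' @export
wolpaw_itr <- function(session, n_targets = 27) {
  if (n_targets < 2) stop("Wolpaw ITR needs at least 2 possible targets",
                          call. = FALSE)
  p <- accuracy(session) / 100
  b <- wolpaw_bits(p, n_targets)
  rate <- nrow(session) / (session_time(session) / 60)
  b * rate
}

#' Wolpaw bits per selection
#'
#' @param p Selection accuracy as a fraction in [0, 1].
#' @param n_targets Number of possible targets.
#' @return Bits per selection, floored at 0 below chance.
#' @export
wolpaw_bits <- function(p, n_targets) {
  stopifnot(p >= 0, p <= 1, n_targets >= 2)
  xlogx <- function(z) ifelse(z > 0, z * log2(z), 0)
  b <- log2(n_targets) + xlogx(p) +
    ifelse(p < 1, (1 - p) * log2((1 - p) / (n_targets - 1)), 0)
  pmax(b, 0)
}

#' Fitts-digraph energy of a keyboard layout
#'
#' Expected movement time per character transition:
#' `E = sum_ij p_ij * MT(position(i) -> position(j))`, with `p_ij` the
#' digraph counts normalized to probabilities and `MT` predicted from the
#' supplied movement model (a directional [fitts_profile] or the isotropic
#' [generic_profile()]). Lower is better; this is the "computational
#' keyboard efficiency" of a layout for a given corpus and user.
#'
#' @param layout A [keyboard_layout] covering the flow's alphabet.
#' @param flow Digraph count matrix with dimnames; must not be all zero.
#' @param profile Movement model; defaults to the generic constants.
#' @param key_width_px Target width `W` (default: the layout grid's).
#' @return Expected seconds per character transition.
#' @export
fitts_digraph_energy <- function(layout, flow,
                                 profile = generic_profile(),
                                 key_width_px = layout$grid$key_width_px) {
  total <- sum(flow)
  if (total <= 0) stop("energy undefined for an all-zero flow matrix",
                       call. = FALSE)
  missing <- setdiff(rownames(flow), layout$keys$char)
  if (length(missing) > 0) {
    stop("layout does not cover character(s): ",
         paste(sprintf("'%s'", missing), collapse = ", "), call. = FALSE)
  }
  idx <- match(rownames(flow), layout$keys$char)
  pos <- layout$keys[idx, ]
  pos$position <- seq_len(nrow(pos)) - 1L
  mt <- build_mt_matrix(profile, pos, key_width_px = key_width_px)
  sum((flow / total) * mt)
}

#' Summarize one transcription session into a metrics report
#'
#' @param session A `session_log`.
#' @param layout The [keyboard_layout] the session was transcribed on
#'   (optional; enables `energy_s_per_char` when `flow` is also given).
#' @param flow Optional digraph count matrix for the energy covariate.
#' @param profile Movement model used for the energy covariate.
#' @param n_targets Number of possible targets for the ITR.
#' @return A one-row tibble: `n_selections`, `total_time_s`,
#'   `accuracy_pct`, `wpm`, `wpm_star`, `itr_bits_per_min`,
#'   `energy_s_per_char`.
#' @export
session_metrics <- function(session, layout = NULL, flow = NULL,
                            profile = generic_profile(), n_targets = 27) {
  energy <- if (!is.null(layout) && !is.null(flow)) {
    fitts_digraph_energy(layout, flow, profile)
  } else {
    NA_real_
  }
  ws <- tryCatch(wpm_star(session), error = function(e) NA_real_)
  tibble::tibble(
    n_selections = nrow(session),
    total_time_s = session_time(session),
    accuracy_pct = accuracy(session),
    wpm = wpm(session),
    wpm_star = ws,
    itr_bits_per_min = wolpaw_itr(session, n_targets),
    energy_s_per_char = energy
  )
}
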