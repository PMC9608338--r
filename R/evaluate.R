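#' Evaluate a keyboard layout with a simulated user over a prompt set
#'
#' Simulates the transcription of each prompt on the layout and computes
#' the communication metrics per prompt plus one aggregate row (metrics
#' pooled over all selections of all prompts). The session RNG is seeded
#' once from `seed`, so consecutive prompts see independent noise while the
#' whole evaluation is reproducible.
#'
#' @param user A [user_model()].
#' @param layout A [keyboard_layout].
#' @param prompts Character vector of prompts.
#' @param flow Optional digraph count matrix: adds the layout's
#'   Fitts-digraph energy covariate to every row.
#' @param profile Movement model for the energy covariate (default: the
#'   layout-agnostic generic constants).
#' @param n_targets Number of possible targets for the ITR (default: keys
#'   on the layout).
#' @param seed Seed for the whole evaluation (default: the user's seed).
#' @return A tibble with one row per prompt plus a final `"aggregate"` row:
#'   `prompt_id`, `prompt`, `n_selections`, `total_time_s`, `accuracy_pct`,
#'   `wpm`, `wpm_star`, `itr_bits_per_min`, `energy_s_per_char`.
#' @export
evaluate_layout <- function(user, layout, prompts, flow = NULL,
                            profile = generic_profile(),
                            n_targets = nrow(layout$keys),
                            seed = user$rng_seed) {
  stopifnot(length(prompts) > 0)
  if (!is.null(seed)) set.seed(seed)
  sessions <- purrr::map(prompts, function(p) {
    simulate_transcription(user, layout, p, seed = NULL)
  })
  per_prompt <- purrr::imap_dfr(sessions, function(s, i) {
    dplyr::bind_cols(
      tibble::tibble(prompt_id = as.character(i), prompt = prompts[i]),
      session_metrics(s, layout = layout, flow = flow, profile = profile,
                      n_targets = n_targets)
    )
  })
  pooled <- dplyr::bind_rows(sessions)
  class(pooled) <- c("session_log", class(pooled))
  aggregate <- dplyr::bind_cols(
    tibble::tibble(prompt_id = "aggregate", prompt = NA_character_),
    session_metrics(pooled, layout = layout, flow = flow, profile = profile,
                    n_targets = n_targets)
  )
  dplyr::bind_rows(per_prompt, aggregate)
}
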