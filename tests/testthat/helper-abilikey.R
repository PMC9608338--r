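# Shared fixtures, all built in code.

# Deterministic isotropic user: exact Fitts behaviour, no noise, no misses.
iso_user <- function(a = 0.5, b = 1.0, noise = 0, miss = 0, seed = 1L) {
  user_model(a_s = a, b_s_per_bit = b, noise_sd_s = noise, miss_prob = miss,
             rng_seed = seed)
}

# Strongly anisotropic user: slopes in one half-plane 3x the other.
anisotropic_user <- function(seed) {
  set.seed(seed)
  sch <- bin_scheme()
  centers <- sch$centers_deg
  axis <- stats::runif(1, 0, 360)
  slow <- cos((centers - axis) * pi / 180) > 0
  b_base <- stats::runif(1, 0.3, 0.5)
  b <- ifelse(slow, 3 * b_base, b_base)
  a <- stats::runif(sch$n_bins, 0.4, 0.9)
  user_model(a_s = a, b_s_per_bit = b, noise_sd_s = 0.1, rng_seed = seed)
}

true_profile <- function(user, grid = grid_spec()) {
  profile_from_constants(user$a_s, user$b_s_per_bit, scheme = user$scheme,
                         grid = grid, provenance = "ground truth")
}

# Hand-built transcription session log (for the metrics closed forms).
make_session <- function(from_char, intended, selected = intended,
                         movement_time_s, success = intended == selected) {
  log <- tibble::tibble(from_char = from_char, intended = intended,
                        selected = selected,
                        movement_time_s = movement_time_s,
                        success = success)
  class(log) <- c("session_log", class(log))
  log
}

# Independent OLS oracle via the normal equations (textbook closed form).
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(a = a, b = b, r2 = 1 - ss_res / ss_tot,
       residual_sd = sqrt(ss_res / (n - 2)))
}

random_qap_instance <- function(n, seed) {
  set.seed(seed)
  list(flow = matrix(stats::runif(n^2), n, n),
       dist = matrix(stats::runif(n^2, 0.1, 1), n, n))
}

tiny_flow <- function(chars = c("A", "B", "C")) {
  n <- length(chars)
  matrix(0, n, n, dimnames = list(chars, chars))
}
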