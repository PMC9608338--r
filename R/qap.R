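#' Quadratic assignment energy of an assignment
#'
#' `E(pi) = sum_ij flow[i, j] * dist[pi(i), pi(j)]` — the digraph-weighted
#' total predicted movement time of a character-to-position assignment.
#' Diagonal flow (double letters) pairs with the diagonal of `dist` (the
#' re-selection time).
#'
#' @param flow `N x N` nonnegative flow (digraph count) matrix.
#' @param dist `M x M` distance (movement time) matrix, `M >= N`.
#' @param assignment Integer vector of length `N`: `assignment[i]` is the
#'   1-based position index of item `i`.
#' @return The energy (seconds when `flow` is in counts, count-weighted).
#' @export
qap_energy <- function(flow, dist, assignment) {
  sum(flow * dist[assignment, assignment, drop = FALSE])
}

# Linear assignment: minimize sum_i cost[i, p(i)]. clue::solve_LSAP needs a
# nonnegative matrix; shifting all entries by a constant leaves the argmin
# unchanged.
lap_min <- function(cost) {
  lo <- min(cost)
  if (lo < 0) cost <- cost - lo
  as.integer(clue::solve_LSAP(cost))
}

# One Frank-Wolfe descent from a doubly stochastic start, minimizing
# <F, P D P^T>; returns the projected permutation and its energy.
faq_descent <- function(flow, dist, p0, max_iter = 30, tol = 1e-6) {
  p <- p0
  tf <- t(flow)
  td <- t(dist)
  for (iter in seq_len(max_iter)) {
    grad <- flow %*% p %*% td + tf %*% p %*% dist
    q <- diag(nrow(p))[lap_min(grad), , drop = FALSE]  # row i -> position
    r <- q - p
    c2 <- sum(flow * (r %*% dist %*% t(r)))
    c1 <- sum(flow * (r %*% dist %*% t(p))) +
      sum(flow * (p %*% dist %*% t(r)))
    alpha <- if (c2 > 0) max(0, min(1, -c1 / (2 * c2)))
    else if (c1 + c2 < 0) 1 else 0
    if (alpha < tol) break
    p <- p + alpha * r
  }
  perm <- lap_min(-p)  # nearest permutation to the relaxed solution
  list(assignment = perm, energy = qap_energy(flow, dist, perm))
}

# row i of the permutation matrix for assignment p: P[i, p[i]] = 1
perm_matrix <- function(p) {
  m <- matrix(0, length(p), length(p))
  m[cbind(seq_along(p), p)] <- 1
  m
}

#' Solve the keyboard QAP with the Fast Approximate QAP algorithm
#'
#' Minimizes `E(pi) = sum_ij flow[i, j] * dist[pi(i), pi(j)]` over
#' assignments of the `N` characters to the `M >= N` candidate positions,
#' using Frank-Wolfe descent over doubly stochastic matrices with a linear
#' assignment solve per step and projection of the final relaxed solution to
#' a permutation (the FAQ algorithm). When `M > N` the flow matrix is
#' zero-padded to `M x M`; padded items occupy positions that are left
#' blank. The descent is run from the barycenter plus `restarts - 1` seeded
#' random starts and the lowest-energy permutation is returned.
#'
#' @param flow `N x N` nonnegative flow matrix (digraph counts).
#' @param dist `M x M` movement-time matrix from [build_mt_matrix()].
#' @param restarts Number of initializations (default 32).
#' @param rng_seed Seed for the random starts.
#' @param max_iter Frank-Wolfe iteration cap per start.
#' @return A list of class `qap_solution`: `assignment` (1-based position
#'   per character, length `N`), `energy_s`, `restarts`, `rng_seed`.
#' @export
solve_qap <- function(flow, dist, restarts = 32, rng_seed = 1L,
                      max_iter = 30) {
  n <- nrow(flow)
  m <- nrow(dist)
  stopifnot(ncol(flow) == n, ncol(dist) == m)
  if (n > m) stop("more characters than candidate positions", call. = FALSE)
  f <- matrix(0, m, m)
  f[seq_len(n), seq_len(n)] <- flow
  set.seed(rng_seed)
  bary <- matrix(1 / m, m, m)
  best <- NULL
  for (s in seq_len(restarts)) {
    p0 <- if (s == 1) bary
    else 0.5 * bary + 0.5 * perm_matrix(sample.int(m))
    sol <- faq_descent(f, dist, p0, max_iter = max_iter)
    if (is.null(best) || sol$energy < best$energy) best <- sol
  }
  structure(
    list(assignment = best$assignment[seq_len(n)],
         energy_s = qap_energy(flow, dist,
                               best$assignment[seq_len(n)]),
         restarts = restarts, rng_seed = rng_seed),
    class = "qap_solution"
  )
}

#' @export
print.qap_solution <- function(x, ...) {
  cat(sprintf("<qap_solution> %d items, energy %.6f (restarts %d, seed %s)\n",
              length(x$assignment), x$energy_s, x$restarts,
              format(x$rng_seed)))
  invisible(x)
}

#' Exhaustive QAP oracle
#'
#' Enumerates every permutation (square instances, `N = M <= 8`) and
#' returns the global minimum of the QAP energy; ties are broken by
#' lexicographic permutation order. Intended as an independent check on
#' [solve_qap()] at toy sizes.
#'
#' @param flow,dist Square matrices of equal size at most 8.
#' @return A list of class `qap_solution` with the optimal `assignment` and
#'   `energy_s`.
#' @export
brute_force_qap <- function(flow, dist) {
  n <- nrow(flow)
  stopifnot(ncol(flow) == n, nrow(dist) == n, ncol(dist) == n)
  if (n > 8) stop("brute force limited to N <= 8", call. = FALSE)
  perms <- permutations_lex(n)
  best_p <- NULL
  best_e <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    e <- sum(flow * dist[p, p, drop = FALSE])
    if (e < best_e) {
      best_e <- e
      best_p <- p
    }
  }
  structure(list(assignment = best_p, energy_s = best_e,
                 restarts = NA_integer_, rng_seed = NA),
            class = "qap_solution")
}

# all permutations of 1:n in lexicographic row order
permutations_lex <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_lex(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- setdiff(seq_len(n), i)
    out[rows, 1] <- i
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# Assemble a keyboard_layout from a QAP solution over `positions`.
assignment_to_layout <- function(solution, positions, alphabet, grid,
                                 label) {
  idx <- solution$assignment
  keys <- tibble::tibble(
    char = alphabet,
    position = positions$position[idx],
    row = positions$row[idx], col = positions$col[idx],
    x = positions$x[idx], y = positions$y[idx]
  )
  new_keyboard_layout(keys, grid, label = label,
                      energy_s = solution$energy_s,
                      seed = solution$rng_seed)
}

#' Generate a personalized keyboard layout
#'
#' Builds the QAP instance — digraph flow from the corpus, movement-time
#' distance from the user's directional Fitts profile — and solves it with
#' [solve_qap()].
#'
#' @param profile A [fitts_profile] (from [run_characterization()] or
#'   [fit_profile()]).
#' @param flow Digraph count matrix from [count_digraphs()]; its dimnames
#'   define the alphabet.
#' @param grid Grid for the candidate positions (default: the profile's).
#' @param positions Candidate positions (default: hex-spiral footprint of
#'   `nrow(flow)` keys).
#' @param restarts,rng_seed,max_iter Passed to [solve_qap()].
#' @param label Layout label.
#' @return A [keyboard_layout] with the achieved energy attached.
#' @export
personalized_layout <- function(profile, flow, grid = profile$grid,
                                positions = candidate_positions(grid,
                                                                nrow(flow)),
                                restarts = 32, rng_seed = 1L, max_iter = 30,
                                label = "personalized") {
  mt <- build_mt_matrix(profile, positions,
                        key_width_px = grid$key_width_px)
  sol <- solve_qap(flow, mt, restarts = restarts, rng_seed = rng_seed,
                   max_iter = max_iter)
  assignment_to_layout(sol, positions, rownames(flow), grid, label)
}

#' Generate a generically optimized keyboard layout
#'
#' As [personalized_layout()], but the movement-time matrix uses the
#' isotropic generic constants `a = 0.127` s, `b = 1/4.9` s/bit in every
#' direction ([generic_profile()]); this is the conventional
#' Fitts-digraph-optimized keyboard that ignores the individual user.
#'
#' @inheritParams personalized_layout
#' @param grid Grid for the candidate positions.
#' @return A [keyboard_layout].
#' @export
generic_layout <- function(flow, grid = grid_spec(),
                           positions = candidate_positions(grid, nrow(flow)),
                           restarts = 32, rng_seed = 1L, max_iter = 30,
                           label = "generic") {
  personalized_layout(generic_profile(grid = grid), flow, grid = grid,
                      positions = positions, restarts = restarts,
                      rng_seed = rng_seed, max_iter = max_iter, label = label)
}
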