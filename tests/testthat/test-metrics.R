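test_that("words per minute is characters per minute over five", {
  s <- make_session(from_char = rep("A", 50), intended = rep("B", 50),
                    movement_time_s = rep(120 / 50, 50))
  expect_equal(wpm(s), 5)  # 50 chars in 2 min
  s2 <- make_session(from_char = rep("A", 41), intended = rep("B", 41),
                     movement_time_s = rep(300 / 41, 41))
  expect_equal(wpm(s2), 1.64)
  # incorrect selections still count as characters
  s3 <- make_session(from_char = rep("A", 10), intended = rep("B", 10),
                     selected = rep("C", 10),
                     movement_time_s = rep(6, 10))
  expect_equal(wpm(s3), 2)
  zero <- make_session(character(), character(), character(), numeric())
  expect_error(wpm(zero), "undefined")
})

test_that("WPM* removes space-adjacent selections, characters and times", {
  # prompt "A B": homing -> A, A -> space, space -> B
  s <- make_session(from_char = c("H", "A", " "),
                    intended = c("A", " ", "B"),
                    movement_time_s = c(2, 1, 1))
  # only the homing->A selection survives: 1 char over 2 s
  expect_equal(wpm_star(s), (1 / (2 / 60)) / 5)
  # sessions without spaces are unchanged
  s2 <- make_session(from_char = c("X", "A"), intended = c("A", "B"),
                     movement_time_s = c(1, 3))
  expect_equal(wpm_star(s2), wpm(s2))
  # time-only variant keeps all characters
  expect_equal(wpm_star(s, drop_time_only = TRUE), (3 / (2 / 60)) / 5)
  only_space <- make_session(from_char = "A", intended = " ",
                             movement_time_s = 1)
  expect_error(wpm_star(only_space), "no non-space")
})

test_that("accuracy is the percentage of successful selections", {
  s <- make_session(from_char = rep("A", 100), intended = rep("B", 100),
                    selected = c(rep("B", 99), "C"),
                    movement_time_s = rep(1, 100))
  expect_equal(accuracy(s), 99)
  all_good <- make_session("A", "B", movement_time_s = 1)
  expect_equal(accuracy(all_good), 100)
})

test_that("Wolpaw bits follow the closed form with chance clamped to zero", {
  expect_equal(wolpaw_bits(1, 27), log2(27))
  expect_equal(wolpaw_bits(1 / 27, 27), 0, tolerance = 1e-12)
  expect_equal(wolpaw_bits(0.5, 2), 0)
  # hand-evaluated intermediate point
  p <- 0.9
  expect_equal(wolpaw_bits(p, 27),
               log2(27) + p * log2(p) + (1 - p) * log2((1 - p) / 26))
  # monotone in accuracy above chance
  ps <- seq(1 / 27, 1, length.out = 50)
  expect_true(all(diff(wolpaw_bits(ps, 27)) >= -1e-12))
})

test_that("the ITR combines bits per selection with the selection rate", {
  s <- make_session(from_char = rep("A", 10), intended = rep("B", 10),
                    movement_time_s = rep(6, 10))  # 10 selections in 1 min
  expect_equal(wolpaw_itr(s, 27), 10 * log2(27))
  # doubling the rate doubles the ITR at fixed accuracy
  s2 <- make_session(from_char = rep("A", 10), intended = rep("B", 10),
                     movement_time_s = rep(3, 10))
  expect_equal(wolpaw_itr(s2, 27), 2 * wolpaw_itr(s, 27))
  expect_error(wolpaw_itr(s, 1), "at least 2")
})

test_that("Fitts-digraph energy reduces to its closed forms", {
  # constant movement model: energy equals that constant, any flow
  qw <- qwerty_layout()
  flow <- count_digraphs(default_corpus())
  const <- profile_from_constants(0.42, 0, grid = qw$grid)
  expect_equal(fitts_digraph_energy(qw, flow, const), 0.42)
  # two adjacent characters, all flow on one digraph, generic constants
  f2 <- tiny_flow(c("A", "B"))
  f2["A", "B"] <- 1
  keys <- tibble::tibble(char = c("A", "B"), position = 0:1,
                         row = c(0L, 0L), col = c(0L, 1L),
                         x = c(0, 130), y = c(0, 0))
  lay <- new_keyboard_layout(keys, grid_spec(1, 2))
  expect_equal(fitts_digraph_energy(lay, f2), 0.127 + 1 / 4.9)
  # swapping characters with no flow leaves the energy unchanged
  f3 <- tiny_flow(c("A", "B", "C"))
  f3["A", "B"] <- 7
  keys3 <- tibble::tibble(char = c("A", "B", "C"), position = 0:2,
                          row = 0L, col = 0:2,
                          x = c(0, 130, 260), y = 0)
  l1 <- new_keyboard_layout(keys3, grid_spec(1, 3))
  keys3b <- keys3
  keys3b$char <- c("A", "B", "C")  # identical; now swap C with nothing flows
  e1 <- fitts_digraph_energy(l1, f3)
  keys3c <- keys3
  keys3c$x[3] <- 1300  # moving the zero-flow character changes nothing
  keys3c$col[3] <- 9L
  l2 <- new_keyboard_layout(keys3c, grid_spec(1, 10))
  expect_equal(fitts_digraph_energy(l2, f3), e1)
  expect_error(fitts_digraph_energy(l1, tiny_flow(c("A", "B", "C"))),
               "all-zero")
  expect_error(fitts_digraph_energy(lay, f3), "does not cover")
})

test_that("session_metrics assembles one coherent row", {
  u <- iso_user()
  qw <- qwerty_layout()
  flow <- count_digraphs(default_corpus())
  log <- simulate_transcription(u, qw, "HELLO WORLD")
  m <- session_metrics(log, layout = qw, flow = flow)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_selections, 11)
  expect_equal(m$accuracy_pct, 100)
  expect_equal(m$wpm, (11 / (m$total_time_s / 60)) / 5)
  expect_gt(m$energy_s_per_char, 0)
})
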