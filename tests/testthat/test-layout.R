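test_that("the hex-spiral footprint grows outward from the central key", {
  g <- grid_spec()
  p1 <- candidate_positions(g, 1)
  ctr <- grid_center_key(g)
  expect_equal(c(p1$row, p1$col), c(ctr$row, ctr$col))
  # 7 positions: the centre plus its 6 nearest neighbours (brute force scan)
  p7 <- candidate_positions(g, 7)
  keys <- key_centers(g)
  d <- sqrt((keys$x - ctr$x)^2 + (keys$y - ctr$y)^2)
  nearest7 <- keys[order(d)[1:7], c("row", "col")]
  expect_setequal(paste(p7$row, p7$col), paste(nearest7$row, nearest7$col))
  expect_equal(max(sqrt((p7$x - ctr$x)^2 + (p7$y - ctr$y)^2)), 130,
               tolerance = 1e-9)
  # deterministic across calls
  expect_identical(candidate_positions(g, 27), candidate_positions(g, 27))
  expect_error(candidate_positions(grid_spec(2, 2), 5), "only 4")
})

test_that("the movement-time matrix applies direction-specific constants", {
  pos <- candidate_positions(grid_spec(5, 5), 7)
  iso <- profile_from_constants(0.5, 1.0, grid = grid_spec(5, 5))
  mt <- build_mt_matrix(iso, pos)
  expect_equal(mt, t(mt))  # isotropy implies symmetry
  d12 <- sqrt((pos$x[2] - pos$x[1])^2 + (pos$y[2] - pos$y[1])^2)
  expect_equal(mt[1, 2], 0.5 + log2(d12 / 130 + 1))
  expect_equal(d12, 130, tolerance = 1e-9)  # adjacent: 0.5 + 1 bit
  expect_equal(mt[1, 2], 1.5)
  expect_equal(unique(diag(mt)), 0.5)  # re-selection time = mean intercept

  # rightward slope half of leftward: moving right is predicted faster
  b <- rep(1, 16)
  b[1] <- 0.5                      # bin 0 = rightward
  b[9] <- 1.0                      # bin 8 = leftward
  aniso <- profile_from_constants(0.5, b, grid = grid_spec(5, 5))
  mta <- build_mt_matrix(aniso, pos)
  right_of <- outer(pos$x, pos$x, function(a, b) b > a) &
    outer(pos$y, pos$y, function(a, b) abs(b - a) < 1)
  idx <- which(right_of, arr.ind = TRUE)
  expect_true(all(mta[idx] < mta[idx[, 2:1, drop = FALSE]]))

  # the floor binds when the constants predict almost nothing
  lowp <- profile_from_constants(0, 0.001, grid = grid_spec(5, 5))
  expect_true(all(build_mt_matrix(lowp, pos) >= 0.05))
})

test_that("the generic movement model uses the published constants", {
  gp <- generic_profile()
  expect_equal(unique(gp$fits$a_s), 0.127)
  expect_equal(unique(gp$fits$b_s_per_bit), 1 / 4.9)
  pos <- candidate_positions(grid_spec(), 27)
  mt <- build_mt_matrix(gp, pos)
  expect_equal(mt, t(mt))
  adj <- which(abs(sqrt(outer(pos$x, pos$x, "-")^2 +
                          outer(pos$y, pos$y, "-")^2) - 130) < 1e-6,
               arr.ind = TRUE)
  expect_equal(unique(round(mt[adj], 6)), round(0.127 + 1 / 4.9, 6))
})

test_that("a vertical flip of the footprint preserves generic layout energy", {
  flow <- count_digraphs(default_corpus())
  g <- grid_spec()
  pos <- candidate_positions(g, 27)
  flipped <- pos
  flipped$y <- max(pos$y) + min(pos$y) - pos$y
  mt1 <- build_mt_matrix(generic_profile(grid = g), pos)
  mt2 <- build_mt_matrix(generic_profile(grid = g), flipped)
  s1 <- solve_qap(flow, mt1, restarts = 8, rng_seed = 5)
  expect_equal(qap_energy(flow, mt2, s1$assignment), s1$energy_s)
})

test_that("the QWERTY reference layout is laid out as on a typewriter", {
  qw <- qwerty_layout()
  expect_equal(nrow(qw$keys), 27)
  expect_setequal(qw$keys$char, keyboard_alphabet())
  expect_equal(qw$keys[qw$keys$char == "Q", c("row", "col")],
               tibble::tibble(row = 0L, col = 0L))
  expect_equal(qw$keys[qw$keys$char == "M", c("row", "col")],
               tibble::tibble(row = 2L, col = 6L))
  expect_equal(qw$keys[qw$keys$char == " ", c("row", "col")],
               tibble::tibble(row = 2L, col = 7L))
  expect_identical(tidy(qwerty_layout()), tidy(qwerty_layout()))
  expect_error(qwerty_layout(grid_spec(3, 9)), "10 columns")
})

test_that("layout objects round through tidy() and validate their keys", {
  qw <- qwerty_layout()
  td <- tidy(qw)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 27)
  bad <- td
  bad$char[2] <- bad$char[1]
  expect_error(new_keyboard_layout(bad, qw$grid))
})
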