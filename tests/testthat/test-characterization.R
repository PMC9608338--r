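test_that("the seeded queue holds 25 shuffled copies of each of 9 levels", {
  q <- seed_queue(seed_config())
  expect_length(q, 225)
  expect_equal(as.vector(table(q)), rep(25L, 9))
  expect_setequal(unique(q), 0:8)
  expect_equal(q, seed_queue(seed_config()))              # same seed
  expect_false(identical(q, seed_queue(seed_config(rng_seed = 2))))
  q2 <- seed_queue(seed_config(n_levels = 1, per_level = 3, max_targets = 3))
  expect_equal(q2, c(0L, 0L, 0L))
})

test_that("target planning realizes the queued separation level", {
  g <- grid_spec()
  sch <- bin_scheme()
  ctr <- grid_center_key(g)
  set.seed(1)
  t0 <- plan_next_target(g, sch, ctr$row, ctr$col, 0)
  expect_equal(c(t0$row, t0$col), c(ctr$row, ctr$col))
  expect_true(is.na(t0$angle_deg))
  # level 1 from the centre: one of the 6 adjacent keys, one width away
  for (i in 1:20) {
    t1 <- plan_next_target(g, sch, ctr$row, ctr$col, 1)
    d <- sqrt((t1$x - ctr$x)^2 + (t1$y - ctr$y)^2)
    expect_equal(d, 130, tolerance = 1e-9)
  }
  # level 8 from a corner: a key near the opposite edge, within the window
  keys <- key_centers(g)
  for (i in 1:10) {
    t8 <- plan_next_target(g, sch, 0, 0, 8)
    d <- sqrt((t8$x - keys$x[1])^2 + (t8$y - keys$y[1])^2)
    expect_true(abs(d - 8 * 130) <= 0.5 * 130 + 1e-9)
  }
  # preferred-bin planning lands in that bin when it is reachable
  for (k in c(0L, 4L, 8L, 12L)) {
    tp <- plan_next_target(g, sch, ctr$row, ctr$col, 3, prefer_bin = k)
    expect_equal(tp$bin, k)
  }
  expect_error(plan_next_target(grid_spec(1, 1), sch, 0, 0, 2), "1-key")
})

test_that("per-bin regression matches the closed-form OLS oracle", {
  cfg <- seed_config()
  # exact line: recovered exactly with R^2 = 1
  tr <- tibble::tibble(id_bits = rep(seq(0.5, 3, by = 0.25), 2))
  tr$movement_time_s <- 0.5 + 0.9 * tr$id_bits
  f <- fit_bin(tr, 0, cfg)
  expect_equal(f$a_s, 0.5)
  expect_equal(f$b_s_per_bit, 0.9)
  expect_equal(f$r2, 1)
  expect_true(f$valid)
  # random samples against the normal equations
  set.seed(99)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    x <- stats::runif(n, 0, 3.2)
    y <- 0.8 + 0.9 * x + stats::rnorm(n, 0, 0.1)
    f <- fit_bin(tibble::tibble(id_bits = x, movement_time_s = y), 0, cfg)
    o <- ols_oracle(x, y)
    expect_equal(f$a_s, o$a, tolerance = 1e-9)
    expect_equal(f$b_s_per_bit, o$b, tolerance = 1e-9)
    expect_equal(f$r2, o$r2, tolerance = 1e-9)
    expect_equal(f$residual_sd_s, o$residual_sd, tolerance = 1e-9)
  }
})

test_that("degenerate bins are marked invalid, not errors", {
  cfg <- seed_config()
  empty <- fit_bin(tibble::tibble(id_bits = numeric(),
                                  movement_time_s = numeric()), 3, cfg)
  expect_false(empty$valid)
  expect_true(is.na(empty$a_s))
  # constant MT over varying ID: slope 0, R^2 = 0
  flat <- fit_bin(tibble::tibble(id_bits = seq(1, 3, by = 0.2),
                                 movement_time_s = 0.7), 0, cfg)
  expect_equal(flat$b_s_per_bit, 0)
  expect_equal(flat$r2, 0)
  expect_false(flat$valid)
  # all IDs identical: no slope is identifiable
  same <- fit_bin(tibble::tibble(id_bits = rep(2, 15),
                                 movement_time_s = stats::runif(15)), 0, cfg)
  expect_false(same$valid)
  expect_equal(same$r2, 0)
})

test_that("outlier detection uses a strict 3-SD residual rule", {
  cfg <- seed_config()
  x <- rep(seq(0.5, 3, length.out = 12), 2)
  tr <- tibble::tibble(trial_id = seq_along(x), id_bits = x,
                       movement_time_s = 0.5 + 0.9 * x)
  f <- fit_bin(tr, 0, cfg)
  expect_equal(nrow(detect_outliers(f, tr)), 0)  # perfect line: none
  # one grossly inflated trial among many small-residual ones
  set.seed(7)
  tr$movement_time_s <- tr$movement_time_s + stats::rnorm(nrow(tr), 0, 0.05)
  tr$movement_time_s[5] <- tr$movement_time_s[5] + 10 * 0.05
  f <- fit_bin(tr, 0, cfg)
  out <- detect_outliers(f, tr)
  expect_equal(out$trial_id, 5L)
  # boundary convention: exactly 3 SD is not flagged
  fit <- tibble::tibble(bin = 0L, a_s = 0, b_s_per_bit = 0, r2 = 1, n = 2,
                        residual_sd_s = 1, valid = TRUE)
  probe <- tibble::tibble(trial_id = 1:2, id_bits = c(1, 1),
                          movement_time_s = c(3, 3 + 1e-9))
  expect_equal(detect_outliers(fit, probe, 3)$trial_id, 2L)
})

test_that("a noiseless user is identified exactly from the initial task", {
  u <- user_model(a_s = seq(0.3, 1.3, length.out = 16),
                  b_s_per_bit = seq(0.4, 1.4, length.out = 16),
                  noise_sd_s = 0, miss_prob = 0)
  res <- run_characterization(u)
  f <- res$profile$fits
  expect_true(all(f$valid))
  expect_equal(f$r2, rep(1, 16))
  expect_lt(max(abs(f$a_s - u$a_s)), 1e-6)
  expect_lt(max(abs(f$b_s_per_bit - u$b_s_per_bit)), 1e-6)
  expect_gte(nrow(res$trials), 225)
  expect_lte(nrow(res$trials), 400)
  # level-0 trials have no distance, no angle, zero ID
  lvl0 <- res$trials[res$trials$level == 0, ]
  expect_true(all(lvl0$distance_px == 0))
  expect_true(all(is.na(lvl0$bin)))
  expect_true(all(lvl0$id_bits == 0))
})

test_that("a pure-noise user drives the task exactly to the 400-target cap", {
  u <- user_model(a_s = 1, b_s_per_bit = 0, noise_sd_s = 0.5)
  res <- run_characterization(u, cfg = seed_config(rng_seed = 11))
  expect_equal(nrow(res$trials), 400L)
  expect_false(any(res$profile$fits$valid))
})

test_that("constants are sampled piecewise with nearest-valid fallback", {
  p <- profile_from_constants(seq(0.3, 1.8, by = 0.1), 1)
  sc <- sample_constants(p, c(0, 5, -5, 90))
  expect_equal(sc$a_s, c(0.3, 0.3, 0.3, 0.7))  # piecewise constant per bin
  # invalidate bin 4; bins 3 and 5 stay valid and are equidistant
  p$fits$valid[5] <- FALSE
  expect_equal(sample_constants(p, 90)$a_s, mean(c(0.6, 0.8)))
  # invalidate bins 4 and 5: nearest valid to angle 90 is now bin 3 only
  p$fits$valid[6] <- FALSE
  expect_equal(sample_constants(p, 90)$a_s, 0.6)
  p$fits$valid <- rep(FALSE, 16)
  expect_error(sample_constants(p, 0), "no valid bin")
})
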