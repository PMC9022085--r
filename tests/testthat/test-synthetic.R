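test_that("RBC trains hit the target hematocrit coverage and are deterministic", {
  flow <- flow_config(5, hematocrit = 0.35)
  train <- make_rbc_train(flow, axis_length = 10e-3, seed = 7)
  cov <- kymovel:::train_coverage(train, 0, 10e-3)
  expect_true(abs(cov - 0.35) < 0.02)
  # near-unity hematocrit: cells nearly abutting
  flow99 <- flow_config(5, hematocrit = 0.99)
  train99 <- make_rbc_train(flow99, axis_length = 2e-3, seed = 7)
  expect_gt(kymovel:::train_coverage(train99, 0, 2e-3), 0.95)
  # same seed, same train; different seed, different train
  expect_identical(make_rbc_train(flow, 10e-3, seed = 7), train)
  expect_false(identical(make_rbc_train(flow, 10e-3, seed = 8)$center, train$center))
  # gaps never negative (no overlapping shadows)
  expect_true(all(diff(train$center) >= train$d_rbc))
  expect_error(make_rbc_train(flow, axis_length = 1e-5),
               class = "kymovel_domain_error")
})

test_that("static scenes render as vertical stripes", {
  cfg <- cfg_jft(0.5, 200, 60)
  img <- render_clean(cfg, 0, duration = 0.05)
  expect_true(all(apply(img$data, 2, function(col) length(unique(col)) == 1)))
})

test_that("a displacement of one pixel per line renders an exact unit slope", {
  cfg <- cfg_jft(0.5, 200, 60) # T_line = 4.5e-4 s
  v <- cfg$px_size / line_period(cfg) # apparent velocity of 1 px per line
  img <- render_clean(cfg, v * 1e3, duration = 0.05)
  d <- img$data
  ok <- 0
  for (r in seq_len(nrow(d) - 1)) {
    ok <- ok + all(d[r + 1, 2:ncol(d)] == d[r, 1:(ncol(d) - 1)])
  }
  # exact shift row to row (floating boundary ties are measure-zero)
  expect_gte(ok, nrow(d) - 2)
})

test_that("apparent shadow width emerges from per-pixel time sampling", {
  # anterograde at half the scan velocity: width = D_RBC * 1.5 = 18 px
  cfg <- cfg_jft(0.5, 200, 200)
  v <- scan_velocity(cfg) / 2
  img <- render_clean(cfg, v * 1e3, duration = 0.05)
  thr <- (200 + 50) / 2
  widths <- unlist(lapply(seq_len(nrow(img$data)), function(ri) {
    runs <- rle(img$data[ri, ] < thr)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- runs$values & starts > 1 & ends < ncol(img$data) # interior runs
    runs$lengths[keep]
  }))
  expect_true(abs(stats::median(widths) - 18) <= 1)
})

test_that("flipping the scan direction mirrors the rendered vessel segment", {
  # scanning the mirrored scene in the opposite direction reproduces the
  # left-right mirrored image exactly when the underlying RBC speed matches;
  # the apparent velocities of the two renders differ by the scan geometry
  cfg_f <- cfg_jft(0.5, 200, 50)
  cfg_r <- cfg_jft(0.5, 200, 50, direction = -1L)
  vs <- scan_velocity(cfg_f)
  flow_f <- flow_config(4, noise_ratio = 0)
  vr <- kymovel:::real_velocity(cfg_f, flow_f) # true cell speed
  # retrograde apparent velocity giving the same cell speed
  flow_r <- flow_config(vr * vs / (vs + vr) * 1e3, noise_ratio = 0)
  expect_equal(kymovel:::real_velocity(cfg_r, flow_r), vr)
  seg_len <- cfg_f$n_px_vessel * cfg_f$px_size
  dur <- 0.02
  train <- make_rbc_train(flow_f, axis_length = vr * dur + seg_len + 2e-4,
                          seed = 3, origin = -vr * dur - 1e-4)
  m_train <- train
  m_train$center <- sort(seg_len - cfg_f$px_size - train$center)
  img_f <- render_linescan(train, cfg_f, flow_f, dur, intra_line_sampling = FALSE)
  img_r <- render_linescan(m_train, cfg_r, flow_r, dur, intra_line_sampling = FALSE)
  expect_identical(img_r$data, img_f$data[, ncol(img_f$data):1])
})

test_that("defocus flags the requested fraction and keeps windows in transit", {
  flow <- flow_config(5)
  train <- make_rbc_train(flow, axis_length = 4e-3, seed = 11) # ~230 cells
  expect_identical(apply_defocus(train, 0, 1.2, seed = 1), train)
  all_f <- apply_defocus(train, 1, 1.2, seed = 1)
  expect_true(all(all_f$defocused))
  expect_true(all(all_f$entry_time < all_f$exit_time))
  half <- apply_defocus(train, 0.5, 1.2, seed = 1)
  n <- length(train$center)
  frac <- mean(half$defocused)
  expect_true(abs(frac - 0.5) < 3 * sqrt(0.25 / n))
  expect_error(apply_defocus(train, 1.5, 1.2), class = "kymovel_domain_error")
})

test_that("white noise has the stated amplitude and zero mean", {
  cfg <- cfg_jft(0.5, 500, 200)
  img <- render_clean(cfg, 3, duration = 0.4) # > 1e5 pixels
  expect_identical(add_noise(img, noise_ratio = 0)$data, img$data)
  noisy <- add_noise(img, noise_ratio = 1.5, seed = 5)
  delta <- noisy$data - img$data
  expect_gte(length(delta), 1e5)
  a <- 1.5 * (200 - 50)
  expect_lte(max(delta) - min(delta), a)
  expect_gte(max(delta) - min(delta), a * 140 / 150)
  se <- stats::sd(delta) / sqrt(length(delta))
  expect_lt(abs(mean(delta)), 4 * se)
  # determinism
  expect_identical(add_noise(img, noise_ratio = 1.5, seed = 5)$data, noisy$data)
})

test_that("streak slope measured by pixel tracking equals the apparent velocity", {
  cfg <- cfg_jft(0.5, 200, 100)
  v_mms <- 4
  img <- render_clean(cfg, v_mms, duration = 0.08)
  # brute-force: track the correlogram displacement over 10 lines
  lag <- bf_lspiv_peak(img$data, 10)
  expected <- v_mms * 1e-3 * 10 * img$t_line / cfg$px_size
  expect_true(abs(lag - expected) <= 1)
})

test_that("simulation is fully deterministic for a fixed seed", {
  cfg <- cfg_jft(0.8, 400, 60, direction = -1L)
  flow <- flow_config(5.33, defocus_fraction = 0.5, noise_ratio = 1.5)
  a <- simulate_linescan(cfg, flow, duration = 0.1, seed = 123)
  b <- simulate_linescan(cfg, flow, duration = 0.1, seed = 123)
  expect_identical(a$data, b$data)
})
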