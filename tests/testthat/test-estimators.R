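test_that("angle estimator recovers an exact lattice point", {
  # v = gammaV*Px*Fp/((1+gf)*k) at k = 10: 6.67 mm/s
  cfg <- cfg_jft(0.5, 200, 50)
  v_true <- angle_velocity(cfg, 10)
  img <- render_clean(cfg, v_true * 1e3, duration = 0.12)
  est <- estimate_angle(split_sections(img, drop_edges = FALSE)[[1]])
  expect_equal(est$params$n_scan_per_rbc, 10)
  expect_equal(est$v_app, v_true)
})

test_that("angle estimator returns the zero-velocity convention on stripes", {
  img <- render_clean(cfg_jft(0.5, 200, 60), 0, duration = 0.05)
  est <- estimate_angle(img)
  expect_equal(est$v_app, 0)
  expect_false(est$ok)
})

test_that("angle and lspiv estimates lie exactly on their velocity lattices", {
  cfg <- cfg_jft(0.5, 200, 80)
  for (seed in 1:5) {
    flow <- flow_config(4 + seed, noise_ratio = 1.5)
    img <- simulate_linescan(cfg, flow, duration = 0.12, seed = seed)
    sec <- preprocess_linescan(img, section_duration = 0.05, drop_edges = FALSE)[[1]]
    w <- sec$cfg$n_px_vessel
    ea <- estimate_angle(sec)
    k_implied <- w * sec$cfg$px_size / (abs(ea$v_app) * sec$t_line)
    expect_equal(k_implied, round(k_implied), tolerance = 1e-9)
    el <- estimate_lspiv(sec, n_tline = 2, check_validity = FALSE)
    nmov_implied <- el$v_app * 2 * sec$t_line / sec$cfg$px_size
    expect_equal(nmov_implied, round(nmov_implied), tolerance = 1e-9)
  }
})

test_that("lspiv recovers an exact lattice point and the zero-velocity case", {
  cfg <- cfg_jft(0.5, 200, 50) # V_scan = 100 mm/s
  v_true <- lspiv_velocity(cfg, n_mov = 5, n_tline = 1) # 6.67 mm/s
  img <- render_clean(cfg, v_true * 1e3, duration = 0.12)
  est <- estimate_lspiv(split_sections(img, drop_edges = FALSE)[[1]],
                        n_tline = 1, check_validity = FALSE)
  expect_equal(est$params$n_mov, 5)
  expect_equal(est$v_app, v_true)

  img0 <- render_clean(cfg, 0, duration = 0.05)
  est0 <- estimate_lspiv(img0, check_validity = FALSE)
  expect_equal(est0$params$n_mov, 0)
  expect_equal(est0$v_app, 0)
})

test_that("frequency-domain lspiv equals brute-force spatial cross-correlation", {
  cfg <- cfg_jft(1, 100, 20)
  set.seed(99)
  for (rep in 1:8) {
    d <- matrix(stats::runif(20 * 20, 0, 100), 20, 20)
    # implant a coherent shifted pattern so a genuine peak exists
    shift <- sample(-6:6, 1)
    base <- stats::runif(20, 0, 100)
    for (r in 1:20) {
      idx <- ((seq_len(20) - 1 - r * shift) %% 20) + 1
      d[r, ] <- 0.7 * base[idx] + 0.3 * d[r, ]
    }
    img <- linescan_image(d, cfg, t_line = line_period(cfg))
    est <- tryCatch(estimate_lspiv(img, n_tline = 1, check_validity = FALSE),
                    kymovel_correlation_failed = function(e) NULL)
    if (!is.null(est)) {
      expect_equal(est$params$n_mov, bf_lspiv_peak(d, 1))
    }
  }
})

test_that("fourier estimator is exact on a pure plane-wave image", {
  cfg <- cfg_jft(0.5, 200, 32, gamma_flyback = 0)
  nr <- 64L; w <- 32L
  t_line <- line_period(cfg)
  a <- 3; b <- 5 # harmonic base: fx = a/(w px), fT = b/(nr T)
  v_expected <- (b / (nr * t_line)) / (a / (w * cfg$px_size))
  tt <- matrix(0:(nr - 1), nr, w)
  xx <- matrix(0:(w - 1), nr, w, byrow = TRUE)
  d <- 0
  for (h in 1:3) d <- d + cos(2 * pi * h * (a * xx / w - b * tt / nr)) / h
  img <- linescan_image(d + 2, cfg, t_line = t_line)
  est <- estimate_fourier(img, check_validity = FALSE)
  expect_equal(est$v_app, v_expected, tolerance = 1e-9)
  # opposite travelling wave flips the sign
  d2 <- 0
  for (h in 1:3) d2 <- d2 + cos(2 * pi * h * (a * xx / w + b * tt / nr)) / h
  img2 <- linescan_image(d2 + 2, cfg, t_line = t_line)
  expect_equal(estimate_fourier(img2, check_validity = FALSE)$v_app,
               -v_expected, tolerance = 1e-9)
})

test_that("fourier estimator flags sparse spectra and vertical stripes", {
  cfg <- cfg_jft(0.5, 200, 32, gamma_flyback = 0)
  nr <- 64; w <- 32
  tt <- matrix(0:(nr - 1), nr, w)
  xx <- matrix(0:(w - 1), nr, w, byrow = TRUE)
  single <- cos(2 * pi * (3 * xx / w - 5 * tt / nr)) # one spectral line
  img <- linescan_image(single, cfg, t_line = line_period(cfg))
  expect_error(estimate_fourier(img, check_validity = FALSE),
               class = "kymovel_sparse_spectrum")
  stripes <- render_clean(cfg_jft(0.5, 200, 60), 0, duration = 0.05)
  est <- estimate_fourier(stripes, check_validity = FALSE)
  expect_equal(est$v_app, 0)
  expect_false(est$ok)
})

test_that("flipping the scan direction flips the sign of every estimate", {
  for (alg in c("angle", "lspiv", "fourier")) {
    cfg_f <- cfg_jft(0.8, 400, 120)
    cfg_r <- cfg_jft(0.8, 400, 120, direction = -1L)
    flow <- flow_config(5.33)
    sec_f <- preprocess_linescan(simulate_linescan(cfg_f, flow, 0.3, seed = 4))[[1]]
    sec_r <- preprocess_linescan(simulate_linescan(cfg_r, flow, 0.3, seed = 4))[[1]]
    v_f <- suppressWarnings(estimate_velocity(sec_f, alg, n_tline = 4)$v_app)
    v_r <- suppressWarnings(estimate_velocity(sec_r, alg, n_tline = 4)$v_app)
    expect_gt(v_f, 0)
    expect_lt(v_r, 0)
  }
})

test_that("estimators stay inside the error level in their validity regions", {
  # scaled-down closed loop (5 seeds; the acceptance suite runs 20)
  conds <- closed_loop_conditions()
  rec <- run_validation(conds, seeds = 1:5)
  expect_true(all(rec$model_feasible))
  expect_true(all(rec$pass))
  # angle additionally respects its own lattice error bound
  ang <- rec[rec$algorithm == "angle", ]
  expect_true(all(ang$max_abs_rel_error <= ang$predicted_rel_error))
})
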