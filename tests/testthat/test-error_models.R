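test_that("angle model anchors reproduce hand arithmetic", {
  cfg <- cfg_jft(0.5, 200, 50)
  expect_equal(angle_velocity(cfg, 10), 6.667e-3, tolerance = 1e-3)
  expect_lt(angle_velocity(cfg, 1e9), 1e-9)
  expect_equal(angle_velocity(cfg_jft(0.5, 200, 50, n_out = 50), 10),
               3.333e-3, tolerance = 1e-3)
  expect_equal(angle_relative_error(cfg, n_scan_per_rbc = 11), 0.10)
  expect_equal(angle_relative_error(cfg, n_scan_per_rbc = 2), 1.0)
  expect_error(angle_relative_error(cfg, n_scan_per_rbc = 1),
               class = "kymovel_domain_error")
  b <- angle_bounds(cfg, 10, 2e-3)
  expect_equal(b$v_max, 6.06e-3, tolerance = 1e-3)
  expect_equal(b$min_px_size, 0.165e-6, tolerance = 1e-3)
})

test_that("lspiv model anchors reproduce hand arithmetic", {
  cfg <- cfg_jft(0.5, 200, 50) # V_scan = 100 mm/s
  expect_equal(lspiv_velocity(cfg, 5, 1), 6.667e-3, tolerance = 1e-3)
  expect_equal(lspiv_velocity(cfg, 0, 1), 0)
  expect_equal(lspiv_velocity(cfg, 1, 5), 0.267e-3, tolerance = 2e-3)
  expect_equal(lspiv_relative_error(cfg, 5e-3, 1), 0.267, tolerance = 2e-3)
  expect_equal(lspiv_relative_error(cfg, 5e-3, 2),
               lspiv_relative_error(cfg, 5e-3, 1) / 2)

  b1 <- lspiv_bounds(cfg, 10, 5e-3, n_tline = 1)
  expect_equal(b1$v_min, 13.3e-3, tolerance = 5e-3)
  expect_equal(b1$v_max, 14.9e-3, tolerance = 5e-3)
  b1r <- lspiv_bounds(cfg_jft(0.5, 200, 50, direction = -1L), 10, 5e-3, n_tline = 1)
  expect_equal(b1r$v_max, 20.6e-3, tolerance = 5e-3)
  expect_gt(b1r$v_max, b1$v_max) # retrograde scanning reaches higher velocities
  expect_equal(b1$details$n_two_shadows, 72) # Ht = 0.35, D = 6 um, v = 5 mm/s
})

test_that("fourier model anchors reproduce hand arithmetic", {
  cfg50 <- cfg_jft(0.5, 200, 50)
  expect_equal(ft_sigma_x(cfg50), 6.366e4, tolerance = 1e-3)
  # quadrupling N halves sigma_x at zero inertia
  expect_equal(ft_sigma_x(cfg_jft(0.5, 200, 200)) * 2, ft_sigma_x(cfg50))
  expect_equal(ft_relative_error(cfg50), 0.068, tolerance = 2e-3)
  expect_equal(ft_relative_error(cfg_jft(0.5, 200, 100)), 0.047, tolerance = 5e-3)
  ns <- c(30, 50, 100, 300, 1000)
  errs <- vapply(ns, function(n) ft_relative_error(cfg_jft(0.5, 200, n)), numeric(1))
  expect_true(all(diff(errs) < 0))

  b <- ft_bounds(cfg50, 10, 5e-3)
  expect_equal(b$details$n_error_level, 25) # N >= 2*((100+P)/(pi P))^2 at P=10
  expect_equal(b$v_min, 2.67e-3, tolerance = 5e-3)
  expect_lt(ft_bounds(cfg_jft(0.5, 200, 100000), 10, 5e-3)$v_min, 1e-5)
})

test_that("sigma_x matches a quadrature oracle for the squared-sinc density", {
  # independent oracle: SD of the density L*sinc^2(pi L f) truncated at the
  # spatial Nyquist band, computed by numerical quadrature
  for (n in c(50, 100, 400)) {
    cfg <- cfg_jft(0.5, 200, n)
    l <- beta_constant_fraction(cfg) * n * cfg$px_size
    f_nyq <- 1 / (2 * cfg$px_size)
    f <- seq(-f_nyq, f_nyq, length.out = 200001)
    dens <- (sinc_sq <- function(z) ifelse(z == 0, 1, (sin(z) / z)^2))(pi * l * f)
    sd_oracle <- sqrt(sum(f^2 * dens) / sum(dens))
    expect_equal(ft_sigma_x(cfg), sd_oracle, tolerance = 0.15)
  }
})

test_that("algebraic identities hold across randomized configurations", {
  set.seed(2024)
  for (rep in 1:25) {
    cfg <- cfg_jft(px_um = stats::runif(1, 0.1, 1),
                   fp_khz = stats::runif(1, 50, 1000),
                   n_px = sample(30:500, 1),
                   jft = stats::runif(1, 0, 5e-8),
                   n_out = sample(0:100, 1),
                   gamma_flyback = stats::runif(1, 0, 1))
    p <- stats::runif(1, 1, 50)
    # velocity-parameterized angle error equals the lattice form on lattice points
    for (k in c(2, 3, 10, 47, 100)) {
      expect_equal(angle_relative_error(cfg, v_app = angle_velocity(cfg, k)),
                   angle_relative_error(cfg, n_scan_per_rbc = k),
                   tolerance = 1e-10)
    }
    # the maximal velocity at error level P inverts the error model exactly
    b <- angle_bounds(cfg, p, 1e-3)
    expect_equal(angle_relative_error(cfg, v_app = b$v_max), p / 100,
                 tolerance = 1e-10)
    # lspiv error at the P% minimum velocity equals P/100 exactly
    nt <- sample(1:8, 1)
    bl <- lspiv_bounds(cfg, p, 5e-3, n_tline = nt)
    expect_equal(lspiv_relative_error(cfg, bl$v_min, nt), p / 100,
                 tolerance = 1e-10)
    # lspiv error at a lattice velocity is exactly 1/n_mov
    nmov <- sample(1:30, 1)
    expect_equal(lspiv_relative_error(cfg, lspiv_velocity(cfg, nmov, nt), nt),
                 1 / nmov, tolerance = 1e-10)
    # the two-shadow pixel bound is one formula with two call sites
    expect_identical(ft_bounds(cfg, p, 5e-3)$details$n_two_shadows,
                     lspiv_bounds(cfg, p, 5e-3, n_tline = nt)$details$n_two_shadows)
  }
})

test_that("stated monotonicities hold numerically", {
  v <- 2e-3
  # angle error increases with velocity, decreases with px, fp, gamma_vessel
  errs_v <- vapply(c(1, 2, 3, 4) * 1e-3, function(vv)
    angle_relative_error(cfg_jft(0.5, 200, 50), v_app = vv), numeric(1))
  expect_true(all(diff(errs_v) > 0))
  errs_px <- vapply(c(0.3, 0.5, 0.8, 1), function(px)
    angle_relative_error(cfg_jft(px, 200, 50), v_app = v), numeric(1))
  expect_true(all(diff(errs_px) < 0))
  errs_fp <- vapply(c(100, 200, 500, 1000), function(fp)
    angle_relative_error(cfg_jft(0.5, fp, 50), v_app = v), numeric(1))
  expect_true(all(diff(errs_fp) < 0))
  errs_gv <- vapply(c(150, 100, 50, 0), function(nout)
    angle_relative_error(cfg_jft(0.5, 200, 50, n_out = nout), v_app = v), numeric(1))
  expect_true(all(diff(errs_gv) < 0))
  # lspiv error increases with scan velocity and gamma_vessel, decreases with
  # n_tline and pixel count
  errs_vs <- vapply(c(100, 200, 500), function(fp)
    lspiv_relative_error(cfg_jft(0.5, fp, 50), v), numeric(1))
  expect_true(all(diff(errs_vs) > 0))
  errs_lgv <- vapply(c(150, 50, 0), function(nout)
    lspiv_relative_error(cfg_jft(0.5, 200, 50, n_out = nout), v), numeric(1))
  expect_true(all(diff(errs_lgv) > 0))
  errs_nt <- vapply(1:4, function(nt)
    lspiv_relative_error(cfg_jft(0.5, 200, 50), v, nt), numeric(1))
  expect_true(all(diff(errs_nt) < 0))
  errs_n <- vapply(c(50, 100, 200), function(n)
    lspiv_relative_error(cfg_jft(0.5, 200, n), v), numeric(1))
  expect_true(all(diff(errs_n) < 0))
})

test_that("the lspiv maximum velocity is bell-shaped in pixel clock when J > 0", {
  fps <- exp(seq(log(20), log(5000), length.out = 60)) # kHz
  vmax <- vapply(fps, function(fp)
    lspiv_bounds(cfg_jft(0.5, fp, 100, jft = 8e-6), 10, 5e-3)$v_max, numeric(1))
  pk <- which.max(vmax)
  expect_gt(pk, 1)
  expect_lt(pk, length(fps))
  expect_true(all(diff(vmax[seq_len(pk)]) > 0))
  tail_pos <- pk:max(which(vmax > 0))
  expect_true(all(diff(vmax[tail_pos]) < 0))
})

test_that("error budgets flag infeasible configurations structurally", {
  cfg <- cfg_jft(0.5, 200, 30)
  # too few pixels for the fourier error level and the two-shadow bound
  expect_false(ft_bounds(cfg, 5, 5e-3)$feasible)
  # velocity above the angle maximum
  expect_false(angle_bounds(cfg, 10, 50e-3)$feasible)
  # n_tline above its ceiling
  expect_false(lspiv_bounds(cfg_jft(0.5, 200, 100), 10, 10e-3, n_tline = 10)$feasible)
  expect_error(angle_bounds(cfg, 0, 1e-3), class = "kymovel_domain_error")
  expect_error(angle_bounds(cfg, 100, 1e-3), class = "kymovel_domain_error")
})
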