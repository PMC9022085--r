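# small grids keep these property sweeps fast; the acceptance suite runs the
# full default grids
px_small <- exp(seq(log(0.1), log(1), length.out = 12))
n_small <- unique(round(exp(seq(log(10), log(1000), length.out = 16))))

tmpl <- function(direction = -1L, fp = 200, gv = 0.5) {
  n_ref <- 100L
  scan_config(0.5, fp, n_ref, n_px_out_vessel = round(n_ref * (1 - gv) / gv),
              direction = direction)
}

test_that("vessel profiles expose the preset velocity ranges", {
  expect_equal(vessel_profile("arteriole")$v_low, 8e-3)
  expect_equal(vessel_profile("venule")$v_high, 4e-3)
  cap <- vessel_profile("capillary")
  expect_equal(c(cap$v_low, cap$v_high), c(0.1e-3, 1e-3))
  custom <- vessel_profile("odd", 1, 2)
  expect_equal(custom$v_high, 2e-3)
  expect_error(vessel_profile("aorta"), class = "kymovel_config_error")
  expect_error(vessel_profile("x", 3, 2), class = "kymovel_config_error")
})

test_that("retrograde scanning never shrinks the lspiv/fourier feasible sets", {
  for (p in c("arteriole", "venule", "capillary")) {
    a <- feasibility_map(vessel_profile(p), tmpl(1L), px_grid_um = px_small, n_grid = n_small)
    r <- feasibility_map(vessel_profile(p), tmpl(-1L), px_grid_um = px_small, n_grid = n_small)
    expect_true(all(r$lspiv[a$lspiv]))
    expect_true(all(r$fourier[a$fourier]))
  }
})

test_that("raising the error level never shrinks any feasible set", {
  for (p in c("venule", "capillary")) {
    m5 <- feasibility_map(vessel_profile(p), tmpl(), p_pct = 5,
                          px_grid_um = px_small, n_grid = n_small)
    m20 <- feasibility_map(vessel_profile(p), tmpl(), p_pct = 20,
                           px_grid_um = px_small, n_grid = n_small)
    for (alg in c("angle", "lspiv", "fourier")) {
      expect_true(all(m20[[alg]][m5[[alg]]]))
    }
  }
})

test_that("feasible cells survive a direct re-check of the named inequalities", {
  prof <- vessel_profile("venule")
  m <- feasibility_map(prof, tmpl(), px_grid_um = px_small, n_grid = n_small)
  cells <- which(m$angle | m$lspiv | m$fourier, arr.ind = TRUE)
  gv <- m$params$gamma_vessel
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]
    n <- m$n_grid[j]
    cfg <- scan_config(m$px_grid[i] * 1e6, m$params$pixel_clock / 1e3, n,
                       n_px_out_vessel = round(n * (1 - gv) / gv),
                       direction = m$params$direction)
    if (m$angle[i, j]) {
      expect_true(angle_bounds(cfg, 10, prof$v_high)$feasible)
    }
    if (m$lspiv[i, j]) {
      nt <- m$lspiv_n_tline[i, j]
      expect_true(lspiv_bounds(cfg, 10, prof$v_low, n_tline = nt)$feasible)
      expect_true(lspiv_bounds(cfg, 10, prof$v_high, n_tline = nt)$feasible)
    }
    if (m$fourier[i, j]) {
      expect_true(ft_bounds(cfg, 10, prof$v_low)$feasible)
    }
  }
})

test_that("recommend ranks algorithms and degrades gracefully", {
  rec_cap <- recommend(vessel_profile("capillary"), tmpl(),
                       px_grid_um = px_small, n_grid = n_small)
  expect_equal(rec_cap$ranking$algorithm[1], "angle")
  expect_true(rec_cap$suggestion$px_um >= 0.1 && rec_cap$suggestion$px_um <= 1)
  # arteriole at 200 kHz: the angle algorithm is out of reach
  rec_art <- recommend(vessel_profile("arteriole"), tmpl(),
                       px_grid_um = px_small, n_grid = n_small)
  expect_false("angle" %in% rec_art$ranking$algorithm)
  # a single infeasible cell yields the explicit no-algorithm verdict
  rec_none <- recommend(vessel_profile("arteriole"), tmpl(),
                        px_grid_um = 0.1, n_grid = 10)
  expect_null(rec_none$suggestion)
  expect_match(rec_none$verdict, "no algorithm")
})

test_that("the feasibility grid exports one row per cell", {
  m <- feasibility_map(vessel_profile("capillary"), tmpl(),
                       px_grid_um = px_small, n_grid = n_small)
  g <- feasibility_grid(m)
  expect_equal(nrow(g), length(px_small) * length(n_small))
  expect_true(all(c("px_um", "n_px_vessel", "angle", "lspiv", "fourier") %in% names(g)))
  expect_equal(sum(g$angle), sum(m$angle))
})
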