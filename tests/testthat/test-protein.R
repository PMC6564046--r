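test_that("the integrator reproduces the G1-phase closed form", {
  kin <- fucci_kinetics()
  tr <- simulate_trajectory(kin, p_c = 40, p_g = 20, t_g1 = 8,
                            t_cycle = 20, c0 = 10, g0 = 5)
  tt <- tr$time_h[tr$time_h <= 8]
  closed <- 40 / 0.08 - (40 / 0.08 - 10) * exp(-0.08 * tt)
  expect_lt(max(abs(tr$cdt1[tr$time_h <= 8] - closed) / closed), 1e-8)

  # absorbing zero: no production, nothing at birth
  tr0 <- simulate_trajectory(kin, 0, 0, 8, 20, 0, 0)
  expect_true(all(tr0$cdt1 == 0) && all(tr0$geminin == 0))
  expect_error(simulate_trajectory(kin, -1, 0, 8, 20, 0, 0), "negative")
  expect_error(simulate_trajectory(kin, 1, 1, 20, 20, 0, 0), "t_g1")
})

test_that("the two-regime solution matches an independent reference integrator", {
  kin <- fucci_kinetics()
  tr <- simulate_trajectory(kin, p_c = 40, p_g = 20, t_g1 = 8,
                            t_cycle = 20, c0 = 10, g0 = 5)
  f <- function(t, y, p) {
    list(c(40 - (0.08 + 0.088 * max(t - 8, 0)) * y[1],
           20 - 0.124 * max(8 - t, 0) * y[2]))
  }
  ref <- deSolve::ode(c(10, 5), times = seq(0, 20, 0.25), f, NULL,
                      method = "rk4", hini = 0.0025)
  expect_lt(max(abs(tr$cdt1 - ref[, 2]) / pmax(ref[, 2], 1e-9)), 1e-6)
  expect_lt(max(abs(tr$geminin - ref[, 3]) / pmax(ref[, 3], 1e-9)), 1e-6)
})

test_that("step halving shows 4th-order convergence", {
  kin <- fucci_kinetics()
  at_end <- function(h) {
    tr <- simulate_trajectory(kin, 40, 20, 8, 20, 10, 5, dt = 20,
                              dt_internal = h)
    attr(tr, "c_end")
  }
  ref <- at_end(0.0025)
  e1 <- abs(at_end(0.16) - ref)
  e2 <- abs(at_end(0.08) - ref)
  expect_gt(e1 / e2, 10)  # ~16 for an order-4 scheme
})

test_that("heuristic rates implement the peak-over-duration link", {
  kin <- fucci_kinetics()
  hr <- heuristic_rates(60, 10, 40, 10, kin)
  expect_equal(hr$p_c, 36)   # 60/10 * 6
  expect_equal(hr$p_g, 16)   # 40/10 * 4
  kin1 <- fucci_kinetics(vartheta_c = 1, vartheta_g = 1)
  hr1 <- heuristic_rates(60, 10, 40, 10, kin1)
  expect_equal(hr1$p_c, 6)
  expect_equal(hr1$p_g, 4)
  expect_error(heuristic_rates(60, 0, 40, 10, kin), "positive")
})

test_that("production-rate draws respect the regression and sibling noise", {
  reg <- production_regression(noise_sd_c = 0, noise_sd_g = 0)
  r <- draw_production_rates(c(8, 10), c(20, 30), c(11, 12), c(300, 350),
                             reg)
  expect_equal(r$p_c[1, ], reg$a_g1 + reg$r1_g1 * c(8, 10) +
                 reg$r2_g1 * c(20, 30))
  expect_equal(r$p_g[1, ], reg$a_sg2m + reg$r1_sg2m * c(11, 12) +
                 reg$r2_sg2m * c(300, 350))

  # rho = 1 with equal covariates: identical sibling rates
  reg1 <- production_regression(rho_pc = 1, rho_pg = 1)
  set.seed(401)
  r1 <- draw_production_rates(c(9, 9), c(25, 25), c(11, 11), c(320, 320),
                              reg1)
  expect_equal(r1$p_c[1, 1], r1$p_c[1, 2], tolerance = 1e-12)
  expect_equal(r1$p_g[1, 1], r1$p_g[1, 2], tolerance = 1e-12)

  # sibling correlations of the noise at the default values
  set.seed(402)
  n <- 5e4
  ones <- matrix(9, n, 2)
  rd <- draw_production_rates(ones, matrix(25, n, 2), matrix(11, n, 2),
                              matrix(320, n, 2), production_regression())
  expect_equal(cor(rd$p_c[, 1], rd$p_c[, 2]), 0.66, tolerance = 0.02)
  expect_equal(cor(rd$p_g[, 1], rd$p_g[, 2]), 0.54, tolerance = 0.02)
})

test_that("unequal division conserves protein mass exactly", {
  set.seed(403)
  law <- division_law(0.13)
  expect_equal(law$alpha_beta, (0.13^-2 - 1) / 2)  # 29.09, not 29.3
  n <- 2e5
  c_end <- runif(n, 10, 100)
  g_end <- runif(n, 100, 1000)
  sp <- divide_proteins(c_end, g_end, law)
  expect_equal(sp$c[, 1] + sp$c[, 2], c_end)  # exact, no tolerance
  expect_equal(sp$g[, 1] + sp$g[, 2], g_end)
  x <- sp$c[, 1] / c_end
  expect_equal(mean(x), 0.5, tolerance = 0.001)
  expect_equal(sd(x) / mean(x), 0.13, tolerance = 0.02)

  # cv -> 0: splits collapse to one half
  tight <- divide_proteins(rep(1, 1000), rep(1, 1000), division_law(0.01))
  expect_true(all(abs(tight$c[, 1] - 0.5) < 0.06))
})

test_that("per-cell rate fitting recovers the generating rates", {
  kin <- fucci_kinetics()
  tr <- simulate_trajectory(kin, p_c = 37, p_g = 22, t_g1 = 9,
                            t_cycle = 21, c0 = 12, g0 = 300)
  fit <- fit_cell_ode(tr, 9, 21, kin)
  expect_lt(abs(fit$p_c - 37) / 37, 0.01)
  expect_lt(abs(fit$p_g - 22) / 22, 0.01)
  expect_equal(fit$c_g1_peak, attr(tr, "c_g1"), tolerance = 0.01)
  expect_equal(fit$g_end, attr(tr, "g_end"), tolerance = 0.01)

  # all-zero trajectory fits zero rates
  z <- tr; z$cdt1 <- 0; z$geminin <- 0
  fz <- fit_cell_ode(z, 9, 21, kin)
  expect_equal(fz$p_c, 0)
  expect_equal(fz$p_g, 0)

  # 5% multiplicative noise: median recovery within 10%
  set.seed(404)
  errs <- replicate(10, {
    s <- sqrt(log(1 + 0.05^2))
    noisy <- tr
    noisy$cdt1 <- noisy$cdt1 * rlnorm(nrow(tr), -s^2 / 2, s)
    noisy$geminin <- noisy$geminin * rlnorm(nrow(tr), -s^2 / 2, s)
    f <- fit_cell_ode(noisy, 9, 21, kin)
    c(abs(f$p_c - 37) / 37, abs(f$p_g - 22) / 22)
  })
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
})

test_that("protein-split asymmetry does not feed back on cycle timing", {
  # durations are generated by the inheritance model alone, so their
  # statistics must be invariant to the division-law width
  stats_at <- function(cv, seed) {
    set.seed(seed)
    cfg <- sim_config(n_ancestors = 2L, t_end = 120,
                      division = division_law(cv),
                      population_cap = 20000L)
    ped <- simulate_population(cfg)$pedigree
    c(mean(ped$t_cycle), sd(ped$t_cycle) / mean(ped$t_cycle))
  }
  res <- sapply(c(0.05, 0.13, 0.3), stats_at, seed = 405)
  expect_lt(diff(range(res[1, ])) / mean(res[1, ]), 0.1)
  expect_lt(diff(range(res[2, ])), 0.08)
})
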