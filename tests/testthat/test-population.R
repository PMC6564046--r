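test_that("population runs are deterministic given the seed", {
  cfg <- sim_config(n_ancestors = 2L, t_end = 60, population_cap = 5000L)
  set.seed(601)
  a <- simulate_population(cfg)
  set.seed(601)
  b <- simulate_population(cfg)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$census$total, b$census$total)
})

test_that("nothing divides before the horizon when residuals exceed it", {
  set.seed(602)
  anc <- data.frame(t_g1 = c(9, 10), t_sg2m = c(11, 12), age = c(0, 0))
  cfg <- sim_config(ancestors = anc, t_end = 5, track_proteins = FALSE)
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$pedigree), 2L)
  expect_true(all(sim$census$total == 2L))
})

test_that("the population cap stops the run with an explicit flag", {
  set.seed(603)
  cfg <- sim_config(n_ancestors = 2L, t_end = 400, population_cap = 40L,
                    track_proteins = FALSE)
  sim <- simulate_population(cfg)
  expect_true(sim$truncated)
  expect_lte(nrow(sim$pedigree), 40L)
})

test_that("census growth matches the renewal-equation growth rate", {
  # oracle: the Malthusian parameter alpha solves 2 E[exp(-alpha T)] = 1
  # for the lognormal cycle-time law, evaluated by numeric quadrature
  cyc <- lognormal_cycle_params(20.4, 0.30)
  el <- function(a) {
    2 * stats::integrate(function(t) {
      exp(-a * t) * stats::dlnorm(t, cyc$meanlog, cyc$sdlog)
    }, 0, Inf)$value - 1
  }
  alpha <- stats::uniroot(el, c(0.01, 0.08), tol = 1e-10)$root
  set.seed(604)
  cfg <- uncorrelated_config(n_ancestors = 1L, t_end = 300)
  sim <- simulate_census(cfg, census_dt = 1)
  sel <- sim$census$times >= 150
  fit <- stats::lm(log(sim$census$total[sel]) ~ sim$census$times[sel])
  expect_equal(unname(coef(fit)[2]), alpha, tolerance = 0.05)
  # the slope is stable across disjoint late windows
  s1 <- sim$census$times >= 150 & sim$census$times < 225
  s2 <- sim$census$times >= 225
  sl <- function(s) unname(coef(stats::lm(
    log(sim$census$total[s]) ~ sim$census$times[s]))[2])
  expect_equal(sl(s1), sl(s2), tolerance = 0.06)
})

test_that("unsynchronized founders have uniform ages within their cycles", {
  set.seed(605)
  cfg <- uncorrelated_config(n_ancestors = 20000L)
  anc <- init_unsynchronized_ancestors(cfg)
  expect_true(all(anc$residual > 0))
  expect_true(all(anc$age >= 0 & anc$age < anc$t_cycle))
  ks <- stats::ks.test(anc$age / anc$t_cycle, "punif")
  expect_gt(ks$p.value, 0.01)
  # synchronized control: everyone starts a fresh cycle
  cfg2 <- sim_config(model_variant = "uncorrelated", n_ancestors = 50L,
                     synchronized = TRUE, track_proteins = FALSE)
  anc2 <- init_unsynchronized_ancestors(cfg2)
  expect_true(all(anc2$age == 0))
  expect_equal(anc2$residual, anc2$t_cycle)
})

test_that("single-lineage simulations lose the ancestor's imprint", {
  set.seed(606)
  cfg <- sim_config(track_proteins = FALSE)
  share <- 9.2 / 20.4
  # i.i.d. control: zero inherited fraction gives no autocorrelation
  flat <- sim_config(
    g1 = bar_params_from_targets(9.2, 4.0, 0, 0.3, 0.6),
    sg2m = bar_params_from_targets(11.2, 3.8, 0, 0.3, 0.6),
    track_proteins = FALSE)
  ln <- simulate_lineage(flat, 2000L)
  ac1 <- stats::acf(ln$t_cycle, plot = FALSE)$acf[2]
  expect_lt(abs(ac1), 0.06)

  # inherited fraction theta: lag-k autocorrelation decays like theta^k
  th <- 0.5
  inh <- sim_config(
    g1 = bar_params_from_targets(9.2, 4.0, th, 0.5, 0.8),
    sg2m = bar_params_from_targets(11.2, 3.8, th, 0.5, 0.8),
    track_proteins = FALSE)
  ln2 <- simulate_lineage(inh, 4000L)
  ac <- stats::acf(ln2$t_cycle, plot = FALSE)$acf
  expect_lt(abs(ac[2] - th), 0.05)
  expect_lt(abs(ac[3] - th^2), 0.05)

  # long-run median forgets extreme ancestors
  meds <- sapply(c(13.6, 61.3), function(tc) {
    ln <- simulate_lineage(cfg, 400L,
                           ancestor = list(t_g1 = share * tc,
                                           t_sg2m = (1 - share) * tc))
    stats::median(ln$t_cycle[101:400])
  })
  expect_lt(abs(meds[1] - meds[2]), 2.5)
})

test_that("cycle-time distributions re-equilibrate from extreme ancestors", {
  set.seed(607)
  share <- 9.2 / 20.4
  pool <- function(tc) {
    out <- c()
    for (r in 1:3) {
      cfg <- sim_config(
        ancestors = data.frame(t_g1 = share * tc,
                               t_sg2m = (1 - share) * tc),
        t_end = 200, track_proteins = FALSE, population_cap = 50000L)
      ped <- simulate_population(cfg)$pedigree
      divided <- ped$cell_id %in% ped$parent_id
      alive <- ped$birth_time <= 200 & (!divided | ped$division_time > 200)
      out <- c(out, ped$t_cycle[alive])
    }
    out
  }
  fast <- pool(13.6)
  slow <- pool(61.3)
  ks <- stats::ks.test(sample(fast, 150), sample(slow, min(150, length(slow))))
  expect_gt(ks$p.value, 0.05)
  # but the fast ancestor leaves many more descendants
  expect_gt(length(fast), 3 * length(slow))
})

test_that("population size at the horizon falls with ancestor cycle length", {
  set.seed(608)
  share <- 9.2 / 20.4
  tcs <- seq(12, 40, length.out = 10)
  sizes <- sapply(tcs, function(tc) {
    cfg <- sim_config(
      ancestors = data.frame(t_g1 = share * tc, t_sg2m = (1 - share) * tc),
      t_end = 120, track_proteins = FALSE, population_cap = 50000L)
    nrow(simulate_population(cfg)$pedigree)
  })
  expect_lt(cor(tcs, sizes, method = "spearman"), 0)
})

test_that("generation-limited pedigrees are free of window censoring", {
  set.seed(609)
  cfg <- sim_config(track_proteins = FALSE)
  ped <- simulate_pedigree_generations(cfg, 8, n_ancestors = 8L)
  expect_equal(nrow(ped), 8L * (2^9 - 1))
  m <- compute_pedigree_moments(ped, "sg2m")
  mom <- stationary_moments(cfg$sg2m)
  expect_equal(m$rho_parent_hat, mom$rho_parent, tolerance = 0.1)
  expect_equal(m$mean_t, mom$mean, tolerance = 0.02)
})
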