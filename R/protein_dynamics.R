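# FUCCI marker dynamics: linear ODEs with phase-dependent degradation,
# production-rate regressions with sibling-correlated noise, heuristic
# rate links, and beta-law unequal division.

#' FUCCI protein kinetic constants
#'
#' Degradation constants of the Cdt1 and Geminin reporters and the
#' heuristic factors linking peak levels to production rates. Defaults are
#' the fitted constants shared by all cells: background degradation
#' `d_c = 0.08` / h for Cdt1 and `d_g = 0` / h for Geminin, a Cdt1
#' degradation ramp of slope `a = 0.088` / h^2 active after the G1/S
#' transition, a Geminin degradation ramp of slope `b = 0.124` / h^2 active
#' before it, and heuristic factors `vartheta_c = 6`, `vartheta_g = 4`.
#'
#' @param d_c,d_g background degradation rates (1/hour).
#' @param a slope of the S/G2/M-phase Cdt1 degradation ramp (1/hour^2).
#' @param b slope of the G1-phase Geminin degradation ramp (1/hour^2).
#' @param vartheta_c,vartheta_g dimensionless heuristic factors.
#' @return object of class `fucci_kinetics`.
#' @export
fucci_kinetics <- function(d_c = 0.08, d_g = 0.0, a = 0.088, b = 0.124,
                           vartheta_c = 6, vartheta_g = 4) {
  vals <- c(d_c = d_c, d_g = d_g, a = a, b = b,
            vartheta_c = vartheta_c, vartheta_g = vartheta_g)
  if (any(vals < 0)) stop("kinetic constants must be non-negative")
  structure(as.list(vals), class = "fucci_kinetics")
}

#' Parameters of the production-rate regressions
#'
#' Production rates of new-born cells are drawn from linear regressions:
#' `p_C` on the cell's G1 duration and Cdt1 birth amount, `p_G` on the
#' S/G2/M duration and Geminin birth amount, with residual noise that is
#' bivariate normal *between siblings* (correlations `rho_pc = 0.66` for
#' Cdt1 and `rho_pg = 0.54` for Geminin) so protein dynamics correlate
#' strongly within sibling pairs and weakly across generations.
#'
#' Coefficient and noise-scale defaults are the synthetic generator's
#' ground truth (arbitrary fluorescence units); on real data they are
#' re-estimated by [estimate_production_regression()]. The birth-amount
#' coefficients are kept small enough that the across-generation feedback
#' loop (birth amount to production rate to division amount) has gain
#' below 1, so marker levels are stationary along lineages.
#'
#' @param a_g1,r1_g1,r2_g1 intercept and coefficients for `p_C`.
#' @param a_sg2m,r1_sg2m,r2_sg2m intercept and coefficients for `p_G`.
#' @param noise_sd_c,noise_sd_g residual standard deviations (a.u./hour).
#' @param rho_pc,rho_pg sibling noise correlations.
#' @return object of class `production_regression`.
#' @export
production_regression <- function(a_g1 = 20, r1_g1 = 2.0, r2_g1 = 0.10,
                                  a_sg2m = 15, r1_sg2m = 2.5, r2_sg2m = 0.02,
                                  noise_sd_c = 8, noise_sd_g = 6,
                                  rho_pc = 0.66, rho_pg = 0.54) {
  if (noise_sd_c < 0 || noise_sd_g < 0) stop("noise sds must be >= 0")
  if (abs(rho_pc) > 1 || abs(rho_pg) > 1) stop("correlations must be in [-1, 1]")
  structure(list(a_g1 = a_g1, r1_g1 = r1_g1, r2_g1 = r2_g1,
                 a_sg2m = a_sg2m, r1_sg2m = r1_sg2m, r2_sg2m = r2_sg2m,
                 noise_sd_c = noise_sd_c, noise_sd_g = noise_sd_g,
                 rho_pc = rho_pc, rho_pg = rho_pg),
            class = "production_regression")
}

#' Beta law of unequal protein division
#'
#' At mitosis each protein amount is split between the progeny by an
#' independent beta-distributed fraction with mean 1/2. The primitive
#' parameter is the coefficient of variation `cv` of the split fraction;
#' the symmetric beta shape follows as `alpha = beta = (cv^-2 - 1)/2`
#' (from `cv = (2*alpha + 1)^-0.5` when `alpha = beta`).
#'
#' @param cv coefficient of variation of the split fraction (default 0.13,
#'   which gives shape `alpha = beta = 29.09`).
#' @return object of class `division_law` with fields `cv`, `alpha_beta`.
#' @export
division_law <- function(cv = 0.13) {
  if (cv <= 0 || cv >= 1) stop("cv must be in (0, 1)")
  structure(list(cv = cv, alpha_beta = (cv^-2 - 1) / 2),
            class = "division_law")
}

# --- fixed-step RK4 for the scalar linear ODE y' = p - d(t) y ------------
#
# Each RK4 step is affine in the state, y_{n+1} = a_n y_n + b_n, with
# coefficients that depend only on d(.) at the stage times. Solving the
# affine recurrence with a cumulative product/sum makes the integrator a
# handful of vectorized operations; the result is bit-identical to the
# step-by-step loop.
rk4_linear_coefs <- function(p, d0, dm, d1, h) {
  b1 <- -d0
  a1 <- p
  b2 <- -dm * (1 + h / 2 * b1)
  a2 <- p - dm * h / 2 * a1
  b3 <- -dm * (1 + h / 2 * b2)
  a3 <- p - dm * h / 2 * a2
  b4 <- -d1 * (1 + h * b3)
  a4 <- p - d1 * h * a3
  list(a = 1 + h / 6 * (b1 + 2 * b2 + 2 * b3 + b4),
       b = h / 6 * (a1 + 2 * a2 + 2 * a3 + a4))
}

# integrate y' = p - dfun(t) y from t0 with n steps of size h;
# returns the full state vector y(t0 + (0:n) h)
rk4_linear <- function(p, dfun, y0, t0, h, n) {
  if (n == 0L) return(y0)
  t_left <- t0 + (seq_len(n) - 1L) * h
  cf <- rk4_linear_coefs(p, dfun(t_left), dfun(t_left + h / 2),
                         dfun(t_left + h), h)
  pr <- cumprod(cf$a)
  if (all(abs(pr) > 1e-250)) {
    y <- pr * (y0 + cumsum(cf$b / pr))
  } else {
    # very strong cumulative decay underflows the product scan (possible
    # for extreme phase durations); fall back to the plain recurrence,
    # which is unconditionally stable
    y <- numeric(n)
    cur <- y0
    for (i in seq_len(n)) {
      cur <- cf$a[i] * cur + cf$b[i]
      y[i] <- cur
    }
  }
  c(y0, y)
}

# degradation-rate closures for the two markers
cdt1_deg <- function(kin, t_g1) function(t) kin$d_c + kin$a * pmax(t - t_g1, 0)
gem_deg <- function(kin, t_g1) function(t) kin$d_g + kin$b * pmax(t_g1 - t, 0)

#' Simulate a single-cell FUCCI trajectory
#'
#' Integrates the marker ODEs
#' `dC/dt = p_C - d_C C - a (t - T_G1)^+ C` and
#' `dG/dt = p_G - d_G G - b (T_G1 - t)^+ G`
#' over one cell cycle with a fixed-step 4th-order Runge-Kutta scheme, and
#' samples the solution on a uniform output grid.
#'
#' @param kin [fucci_kinetics()].
#' @param p_c,p_g production rates (a.u./hour, `>= 0`).
#' @param t_g1 G1 duration (hours), `0 < t_g1 < t_cycle`.
#' @param t_cycle total cycle duration (hours).
#' @param c0,g0 marker amounts at birth (a.u., `>= 0`).
#' @param dt output sampling interval (hours; default 0.25 h, i.e. one
#'   frame per 15 min).
#' @param dt_internal target internal integration step (hours).
#' @return data frame of class `fucci_trajectory` with columns `time_h`,
#'   `cdt1`, `geminin`, and attributes `c_g1` (Cdt1 at the G1/S
#'   transition), `c_end`, `g_end` (amounts at division) and `t_g1`,
#'   `t_cycle`.
#' @export
simulate_trajectory <- function(kin, p_c, p_g, t_g1, t_cycle, c0, g0,
                                dt = 0.25, dt_internal = 0.01) {
  stopifnot(inherits(kin, "fucci_kinetics"))
  if (p_c < 0 || p_g < 0 || c0 < 0 || g0 < 0) stop("negative inputs")
  if (!(t_g1 > 0 && t_g1 < t_cycle)) stop("need 0 < t_g1 < t_cycle")
  if (dt <= 0 || dt_internal <= 0) stop("steps must be positive")
  m <- max(1L, ceiling(dt / dt_internal))
  h <- dt / m
  n_out <- floor(t_cycle / dt + 1e-9)
  n <- n_out * m
  dC <- cdt1_deg(kin, t_g1)
  dG <- gem_deg(kin, t_g1)
  keep <- seq(1L, n + 1L, by = m)
  cdt1 <- rk4_linear(p_c, dC, c0, 0, h, n)[keep]
  gem <- rk4_linear(p_g, dG, g0, 0, h, n)[keep]

  value_at <- function(p, dfun, y0, t_from, t_to) {
    span <- t_to - t_from
    if (span <= 1e-12) return(y0)
    k <- max(1L, ceiling(span / dt_internal))
    y <- rk4_linear(p, dfun, y0, t_from, span / k, k)
    y[length(y)]
  }
  t_last <- (n_out) * dt
  c_end <- value_at(p_c, dC, cdt1[n_out + 1L], t_last, t_cycle)
  g_end <- value_at(p_g, dG, gem[n_out + 1L], t_last, t_cycle)
  i_g1 <- floor(t_g1 / dt + 1e-9)
  c_g1 <- value_at(p_c, dC, cdt1[i_g1 + 1L], i_g1 * dt, t_g1)

  out <- data.frame(time_h = (0:n_out) * dt, cdt1 = cdt1, geminin = gem)
  attr(out, "c_g1") <- c_g1
  attr(out, "c_end") <- c_end
  attr(out, "g_end") <- g_end
  attr(out, "t_g1") <- t_g1
  attr(out, "t_cycle") <- t_cycle
  class(out) <- c("fucci_trajectory", "data.frame")
  out
}

# endpoint-only integration used by the population engine: returns the
# marker amounts at the G1/S transition and at division
protein_endpoints <- function(kin, p_c, p_g, t_g1, t_cycle, c0, g0,
                              dt_internal = 0.02) {
  dC <- cdt1_deg(kin, t_g1)
  dG <- gem_deg(kin, t_g1)
  seg <- function(p, dfun, y0, t_from, t_to) {
    span <- t_to - t_from
    k <- max(1L, ceiling(span / dt_internal))
    y <- rk4_linear(p, dfun, y0, t_from, span / k, k)
    y[length(y)]
  }
  c_g1 <- seg(p_c, dC, c0, 0, t_g1)
  c_end <- seg(p_c, dC, c_g1, t_g1, t_cycle)
  g_g1 <- seg(p_g, dG, g0, 0, t_g1)
  g_end <- seg(p_g, dG, g_g1, t_g1, t_cycle)
  list(c_g1 = c_g1, c_end = c_end, g_end = g_end)
}

#' Heuristic production rates from peak levels
#'
#' Links production rates to the ratio of the peak marker level and the
#' phase duration: `p_C = (C_G1 / T_G1) * vartheta_c` and
#' `p_G = (G_end / T_SG2M) * vartheta_g`, which amounts to linear
#' interpolation of the arcs of the exponential solutions.
#'
#' @param c_g1_peak Cdt1 amount at the end of G1 (a.u.).
#' @param t_g1 G1 duration (hours, > 0).
#' @param g_end Geminin amount at division (a.u.).
#' @param t_sg2m S/G2/M duration (hours, > 0).
#' @param kin [fucci_kinetics()].
#' @return list with `p_c`, `p_g`.
#' @export
heuristic_rates <- function(c_g1_peak, t_g1, g_end, t_sg2m, kin) {
  stopifnot(inherits(kin, "fucci_kinetics"))
  if (any(t_g1 <= 0) || any(t_sg2m <= 0)) stop("durations must be positive")
  if (any(c_g1_peak < 0) || any(g_end < 0)) stop("amounts must be >= 0")
  list(p_c = c_g1_peak / t_g1 * kin$vartheta_c,
       p_g = g_end / t_sg2m * kin$vartheta_g)
}

#' Draw production rates for sibling pairs
#'
#' Evaluates the production-rate regressions for both progeny of one (or
#' more) divisions and adds residual noise that is bivariate normal within
#' the sibling pair. Negative draws are clipped to zero (rates are
#' physical); the number of clipped values is attached as attribute
#' `n_clipped`.
#'
#' @param t_g1_pair,c0_pair n x 2 matrices (or length-2 vectors) of sibling
#'   G1 durations and Cdt1 birth amounts.
#' @param t_sg2m_pair,g0_pair same for S/G2/M durations and Geminin birth
#'   amounts.
#' @param reg [production_regression()].
#' @return list with n x 2 matrices `p_c` and `p_g` (column = sibling).
#' @export
draw_production_rates <- function(t_g1_pair, c0_pair, t_sg2m_pair, g0_pair,
                                  reg) {
  stopifnot(inherits(reg, "production_regression"))
  as_pair <- function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 2L) else as.matrix(x)
  }
  t_g1_pair <- as_pair(t_g1_pair); c0_pair <- as_pair(c0_pair)
  t_sg2m_pair <- as_pair(t_sg2m_pair); g0_pair <- as_pair(g0_pair)
  n <- nrow(t_g1_pair)
  corr_pair <- function(n, sd, rho) {
    e1 <- stats::rnorm(n)
    e2 <- stats::rnorm(n)
    sd * cbind(e1, rho * e1 + sqrt(1 - rho^2) * e2)
  }
  eps_c <- corr_pair(n, reg$noise_sd_c, reg$rho_pc)
  eps_g <- corr_pair(n, reg$noise_sd_g, reg$rho_pg)
  p_c <- reg$a_g1 + reg$r1_g1 * t_g1_pair + reg$r2_g1 * c0_pair + eps_c
  p_g <- reg$a_sg2m + reg$r1_sg2m * t_sg2m_pair + reg$r2_sg2m * g0_pair + eps_g
  n_clip <- sum(p_c < 0) + sum(p_g < 0)
  p_c[p_c < 0] <- 0
  p_g[p_g < 0] <- 0
  structure(list(p_c = unname(p_c), p_g = unname(p_g)),
            n_clipped = n_clip)
}

#' Estimate production-rate regression coefficients by least squares
#'
#' Ordinary least squares of per-cell fitted production rates on the phase
#' duration and birth amount, one regression per marker. Residual sds feed
#' the noise scales of [production_regression()].
#'
#' @param p_c,p_g per-cell production rates.
#' @param t_g1,c0,t_sg2m,g0 per-cell covariates.
#' @param rho_pc,rho_pg sibling noise correlations to carry over.
#' @return [production_regression()] with fitted coefficients.
#' @export
estimate_production_regression <- function(p_c, p_g, t_g1, c0, t_sg2m, g0,
                                           rho_pc = 0.66, rho_pg = 0.54) {
  fit_c <- stats::lm(p_c ~ t_g1 + c0)
  fit_g <- stats::lm(p_g ~ t_sg2m + g0)
  production_regression(
    a_g1 = unname(stats::coef(fit_c)[1L]),
    r1_g1 = unname(stats::coef(fit_c)[2L]),
    r2_g1 = unname(stats::coef(fit_c)[3L]),
    a_sg2m = unname(stats::coef(fit_g)[1L]),
    r1_sg2m = unname(stats::coef(fit_g)[2L]),
    r2_sg2m = unname(stats::coef(fit_g)[3L]),
    noise_sd_c = stats::sd(stats::residuals(fit_c)),
    noise_sd_g = stats::sd(stats::residuals(fit_g)),
    rho_pc = rho_pc, rho_pg = rho_pg)
}

#' Split protein amounts between progeny at division
#'
#' Independent beta-distributed fractions for the two markers; amounts are
#' conserved exactly: progeny shares sum to the parent amount.
#'
#' @param c_end,g_end parent amounts at division (vectors allowed).
#' @param law [division_law()].
#' @return list with n x 2 matrices `c` and `g` of progeny amounts.
#' @export
divide_proteins <- function(c_end, g_end, law) {
  stopifnot(inherits(law, "division_law"))
  if (any(c_end < 0) || any(g_end < 0)) stop("amounts must be >= 0")
  n <- length(c_end)
  xc <- stats::rbeta(n, law$alpha_beta, law$alpha_beta)
  xg <- stats::rbeta(n, law$alpha_beta, law$alpha_beta)
  list(c = cbind(xc * c_end, c_end - xc * c_end),
       g = cbind(xg * g_end, g_end - xg * g_end))
}

#' Fit per-cell production rates to an observed trajectory
#'
#' With the degradation constants held fixed (they are shared by all
#' cells), the ODE solution is affine in the production rate, so the
#' least-squares rates have a closed form: the trajectory is projected onto
#' the particular solution with unit production. Rates are clipped at zero.
#'
#' @param traj data frame with `time_h`, `cdt1`, `geminin` covering one
#'   full cycle starting at birth.
#' @param t_g1,t_cycle known phase boundary and cycle length (hours).
#' @param kin [fucci_kinetics()].
#' @return list with `p_c`, `p_g`, `c_g1_peak`, `g_end` (fitted-model
#'   values) and `converged`.
#' @export
fit_cell_ode <- function(traj, t_g1, t_cycle, kin = fucci_kinetics()) {
  stopifnot(all(c("time_h", "cdt1", "geminin") %in% names(traj)))
  tt <- traj$time_h - traj$time_h[1L]
  keep <- tt <= t_cycle + 1e-9
  tt <- tt[keep]
  yc <- traj$cdt1[keep]
  yg <- traj$geminin[keep]
  if (length(tt) < 3L) stop("trajectory too short to fit")
  dt <- tt[2L] - tt[1L]
  fit_one <- function(y, dfun) {
    y0 <- max(y[1L], 0)
    m <- max(1L, ceiling(dt / 0.01))
    n <- (length(y) - 1L) * m
    keep_i <- seq(1L, n + 1L, by = m)
    base <- rk4_linear(0, dfun, y0, 0, dt / m, n)[keep_i]
    part <- rk4_linear(1, dfun, 0, 0, dt / m, n)[keep_i]
    denom <- sum(part^2)
    p <- if (denom > 0) sum(part * (y - base)) / denom else 0
    max(p, 0)
  }
  dC <- cdt1_deg(kin, t_g1)
  dG <- gem_deg(kin, t_g1)
  p_c <- fit_one(yc, dC)
  p_g <- fit_one(yg, dG)
  ep <- protein_endpoints(kin, p_c, p_g, t_g1, t_cycle,
                          max(yc[1L], 0), max(yg[1L], 0), dt_internal = 0.01)
  list(p_c = p_c, p_g = p_g, c_g1_peak = ep$c_g1, g_end = ep$g_end,
       converged = TRUE)
}
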