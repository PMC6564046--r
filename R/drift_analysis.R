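# Wright-Fisher comparison of simulated populations: effective population
# size from progeny-fraction variance, harmonic-mean census size,
# multinomial moment expectations and distribution comparison.

#' Replicate set of per-ancestor progeny fractions
#'
#' @param fractions M x N matrix: row m holds the per-ancestor descendant
#'   fractions of replicate simulation m at the analysis time.
#' @param analysis_time hours at which fractions were read (metadata).
#' @return object of class `drift_replicates`.
#' @export
drift_replicates <- function(fractions, analysis_time = NA_real_) {
  fractions <- as.matrix(fractions)
  if (nrow(fractions) < 2L) stop("need at least 2 replicates")
  if (ncol(fractions) < 2L) stop("need at least 2 ancestors")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  rs <- rowSums(fractions)
  if (any(abs(rs - 1) > 1e-8)) stop("replicate rows must sum to 1")
  structure(list(fractions = unname(fractions),
                 n_ancestors = ncol(fractions),
                 n_replicates = nrow(fractions),
                 analysis_time = analysis_time),
            class = "drift_replicates")
}

#' Simulate replicate progeny-fraction samples
#'
#' Repeats independent population simulations and collects per-ancestor
#' descendant fractions at the horizon, the raw material for effective
#' population size estimation. Per-replicate harmonic-mean effective sizes
#' are recorded alongside.
#'
#' @param config [sim_config()]; `config$t_end` is the analysis time.
#' @param n_replicates number of independent simulations.
#' @param census_dt census grid spacing used for the harmonic means.
#' @return `drift_replicates` with attribute `harmonic_k` (vector of
#'   per-replicate harmonic-mean effective sizes).
#' @export
simulate_drift_replicates <- function(config, n_replicates = 500L,
                                      census_dt = 0.5) {
  fr <- matrix(NA_real_, n_replicates, config$n_ancestors)
  hk <- numeric(n_replicates)
  for (m in seq_len(n_replicates)) {
    sim <- simulate_census(config, census_dt = census_dt)
    fr[m, ] <- sim$fractions
    hk[m] <- harmonic_mean_k(sim$census)$k_integral
  }
  out <- drift_replicates(fr, analysis_time = config$t_end)
  attr(out, "harmonic_k") <- hk
  out
}

#' Effective population size from fraction variance
#'
#' Inverts the multinomial variance relation
#' `Var(Y_i) = (N - 1) N^-2 K^-1`: the effective size is
#' `K = (N - 1) / (N^2 * V)` where `V` is the across-replicate variance of
#' the per-ancestor fractions (centered on per-ancestor means, averaged
#' over ancestors). Also reports the two pooled statistics `S_r^2`
#' (centered on the exchangeable mean `1/N`) and `S_c^2` (centered on
#' per-ancestor means) and direct covariance/correlation estimates
#' averaged over ancestor pairs.
#'
#' Because the exchangeable mean is exact (`E(Y_i) = 1/N` whenever rows
#' sum to one), both pooled statistics estimate `Var(Y_i) =
#' (1 - 1/N)(KN)^-1`; under the multinomial model the pairwise
#' correlation is `-1/(N - 1)` regardless of `K`.
#'
#' @param reps [drift_replicates()], or a plain fractions matrix.
#' @return object of class `effective_size`: list with `k_hat`, `s_r2`,
#'   `s_c2`, `var_hat`, `cov_hat`, `rho_hat`, `n_ancestors`,
#'   `n_replicates`.
#' @export
effective_size <- function(reps) {
  if (!inherits(reps, "drift_replicates")) reps <- drift_replicates(reps)
  y <- reps$fractions
  n <- reps$n_ancestors
  m <- reps$n_replicates
  s_r2 <- sum((y - 1 / n)^2) / (n * m)
  ybar <- colMeans(y)
  s_c2 <- sum(sweep(y, 2L, ybar)^2) / (n * m)
  v_hat <- mean(apply(y, 2L, stats::var))
  if (v_hat <= 0) stop("degenerate: K unbounded (zero fraction variance)")
  # direct pairwise covariance, averaged over ancestor pairs
  cv <- stats::cov(y)
  cov_hat <- mean(cv[upper.tri(cv)])
  structure(list(k_hat = (n - 1) / (n^2 * v_hat),
                 s_r2 = s_r2, s_c2 = s_c2,
                 var_hat = v_hat, cov_hat = cov_hat,
                 rho_hat = cov_hat / v_hat,
                 n_ancestors = n, n_replicates = m),
            class = "effective_size")
}

#' @export
print.effective_size <- function(x, ...) {
  cat(sprintf(
    "effective_size: K_hat = %.1f (N = %d ancestors, M = %d replicates)\n",
    x$k_hat, x$n_ancestors, x$n_replicates))
  cat(sprintf("  V_hat = %.3g, S_r^2 = %.3g, S_c^2 = %.3g, rho_hat = %.3g\n",
              x$var_hat, x$s_r2, x$s_c2, x$rho_hat))
  invisible(x)
}

#' Effective size from a known fraction variance
#'
#' Direct worked-example inversion `K = (N - 1) / (N^2 * V)` for a tabulated
#' or externally computed across-replicate fraction variance.
#'
#' @param n_ancestors N.
#' @param variance across-replicate variance of per-ancestor fractions.
#' @param round_k return the nearest integer (the convention used when
#'   tabulating K).
#' @return effective population size.
#' @export
effective_size_from_variance <- function(n_ancestors, variance,
                                         round_k = TRUE) {
  if (n_ancestors < 2L) stop("need at least 2 ancestors")
  if (variance <= 0) stop("variance must be positive")
  k <- (n_ancestors - 1) / (n_ancestors^2 * variance)
  if (round_k) round(k) else k
}

#' Multinomial (Wright-Fisher) moment expectations
#'
#' Under multinomial resampling with effective size `K` and `N` ancestors,
#' the scaled fractions `Y_i = X_i / K` satisfy `E(Y_i) = 1/N`,
#' `Var(Y_i) = (N-1) N^-2 K^-1`, `Cov(Y_i, Y_j) = -N^-2 K^-1`, and hence a
#' pairwise correlation of `-1/(N-1)` independent of `K`.
#'
#' @param n_ancestors N (>= 2).
#' @param k effective population size (> 0).
#' @return list with `e_y`, `var_y`, `cov_y`, `rho`.
#' @export
multinomial_expectations <- function(n_ancestors, k) {
  if (n_ancestors < 2L) stop("need at least 2 ancestors")
  if (k <= 0) stop("K must be positive")
  n <- n_ancestors
  list(e_y = 1 / n,
       var_y = (n - 1) / (n^2 * k),
       cov_y = -1 / (n^2 * k),
       rho = -1 / (n - 1))
}

#' Harmonic-mean effective population size of a census trajectory
#'
#' The textbook effective size of a population of varying size is the
#' harmonic mean of the census sizes over the analysis window:
#' `K = { dt^-1 Int 1/N(tau) dtau }^-1`, evaluated by the trapezoid rule on
#' the census grid. Also returns the exponential-growth closed form
#' `K = N0 NT / (NT - N0) * ln(NT / N0)` (continuously extended to `N0` as
#' `NT -> N0`); the two agree closely for clean exponential growth.
#'
#' @param census a `census_series`.
#' @param window `c(from, to)` hours; defaults to the full census range.
#' @return list with `k_integral`, `k_closed_form`, `n0`, `nt`.
#' @export
harmonic_mean_k <- function(census, window = range(census$times)) {
  stopifnot(inherits(census, "census_series"))
  sel <- census$times >= window[1L] & census$times <= window[2L]
  if (sum(sel) < 2L) stop("window must contain at least 2 census points")
  tt <- census$times[sel]
  nn <- census$total[sel]
  if (any(nn < 1L)) stop("census counts must be >= 1")
  inv <- 1 / nn
  integral <- sum(diff(tt) * (inv[-1L] + inv[-length(inv)]) / 2)
  k_int <- (tt[length(tt)] - tt[1L]) / integral
  n0 <- nn[1L]
  nt <- nn[length(nn)]
  k_cf <- if (nt == n0) as.numeric(n0) else n0 * nt / (nt - n0) * log(nt / n0)
  list(k_integral = k_int, k_closed_form = k_cf, n0 = n0, nt = nt)
}

#' Compare progeny fractions with the fitted binomial model
#'
#' Scales the fractions by the estimated effective size and compares them
#' with `Binom(K, 1/N)` draws: a two-sample Wilcoxon rank test plus both
#' empirical CDFs.
#'
#' The CDFs are reported for the pooled scaled fractions (all ancestors,
#' all replicates). The rank test, however, uses one coordinate per
#' replicate: the coordinates of one replicate are exchangeable but
#' dependent (they sum to `K`), and pooling them would feed the test `N`
#' times more observations than there are independent replicates,
#' inflating its type-I error.
#'
#' @param reps [drift_replicates()].
#' @param k_hat effective size (defaults to [effective_size()] of `reps`).
#' @return list with `p_value`, `statistic` and a `cdf` data frame
#'   (`x`, `empirical`, `binomial`).
#' @export
compare_to_binomial <- function(reps, k_hat = NULL) {
  if (!inherits(reps, "drift_replicates")) reps <- drift_replicates(reps)
  if (is.null(k_hat)) k_hat <- effective_size(reps)$k_hat
  k_int <- max(1L, round(k_hat))
  # scale by the same integer size used for the reference sample so the
  # two distributions share their mean exactly
  scaled <- as.vector(reps$fractions) * k_int
  test_sample <- reps$fractions[, 1L] * k_int
  ref <- stats::rbinom(length(scaled), k_int, 1 / reps$n_ancestors)
  wt <- stats::wilcox.test(test_sample,
                           ref[seq_along(test_sample)], exact = FALSE)
  xs <- sort(unique(c(scaled, ref)))
  list(p_value = wt$p.value,
       statistic = unname(wt$statistic),
       cdf = data.frame(x = xs,
                        empirical = stats::ecdf(scaled)(xs),
                        binomial = stats::ecdf(ref)(xs)))
}

#' Re-derive phase parameters for correlation targets
#'
#' For the correlation sweep: keeps the equilibrium mean and variance of a
#' base phase model fixed and re-derives `(m, theta, mu, sigma2, rho)` so
#' the parent-progeny correlation equals `theta_target` and the sibling
#' correlation equals `sib_target`. The log-scale noise variance is held
#' at the base value and the noise correlation is solved from the rescaled
#' sibling correlation.
#'
#' @param base [bar_params()] defining the fixed marginal mean/variance.
#' @param theta_target parent-progeny correlation.
#' @param sib_target sibling correlation; must satisfy
#'   `sib_target >= theta_target^2` to be feasible.
#' @return [bar_params()], or `NULL` when the pair is infeasible.
#' @export
reparameterize_correlations <- function(base, theta_target, sib_target) {
  stopifnot(inherits(base, "bar_params"))
  mom <- stationary_moments(base)
  th <- theta_target
  if (th^2 >= 1) return(NULL)
  a <- (sib_target - th^2) / (1 - th^2)
  if (a < 0 || a >= 1) return(NULL)
  s2 <- base$sigma2
  rho <- if (a == 0) 0 else log(1 + a * (exp(s2) - 1)) / s2
  if (rho > 1 + 1e-12) return(NULL)
  rho <- min(rho, 1)
  mu <- 0.5 * log(mom$variance * (1 - th^2) / (exp(s2) * (exp(s2) - 1)))
  m <- mom$mean - exp(mu + s2 / 2) / (1 - th)
  # rho = 0 needs a degenerate-noise-correlation model; bar_params allows
  # rho in (-1, 1], so 0 is valid
  bar_params(m = m, theta = th, mu = mu, sigma2 = s2, rho = rho)
}

#' Effective-size surface over family-correlation targets
#'
#' For each pair of parent-progeny and sibling correlation targets, the
#' phase models are re-parameterized (marginal mean and variance held
#' fixed), replicate populations are simulated and the effective size is
#' estimated from the fraction variance. Infeasible pairs
#' (`sib < theta^2`) are marked, not raised.
#'
#' @param base_config [sim_config()] for the full model; its phase models
#'   provide the fixed marginals.
#' @param pp_grid,sib_grid correlation target grids.
#' @param n_replicates replicates per grid point.
#' @param census_dt census spacing for harmonic means.
#' @return data frame with `pp`, `sib`, `feasible`, `k_hat`,
#'   `harmonic_k` (replicate mean).
#' @export
correlation_sweep <- function(base_config, pp_grid, sib_grid,
                              n_replicates = 100L, census_dt = 1) {
  stopifnot(inherits(base_config, "sim_config"))
  grid <- expand.grid(pp = pp_grid, sib = sib_grid)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    th <- grid$pp[r]; sb <- grid$sib[r]
    g1 <- reparameterize_correlations(base_config$g1, th, sb)
    sg <- reparameterize_correlations(base_config$sg2m, th, sb)
    if (is.null(g1) || is.null(sg)) {
      return(data.frame(pp = th, sib = sb, feasible = FALSE,
                        k_hat = NA_real_, harmonic_k = NA_real_))
    }
    cfg <- base_config
    cfg$g1 <- g1
    cfg$sg2m <- sg
    cfg$track_proteins <- FALSE
    reps <- simulate_drift_replicates(cfg, n_replicates,
                                      census_dt = census_dt)
    data.frame(pp = th, sib = sb, feasible = TRUE,
               k_hat = effective_size(reps)$k_hat,
               harmonic_k = mean(attr(reps, "harmonic_k")))
  })
  do.call(rbind, res)
}
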