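# Method-of-moments estimation of the bifurcating autoregression from
# pedigree phase durations: moment extraction, the transcendental solve
# for sigma^2, exact inversion, and the profile search over rho.

#' Bundle of sample moments for one phase
#'
#' @param mean_t,var_t sample mean and variance of the phase duration.
#' @param rho_sib_hat,rho_parent_hat sample sibling and parent-progeny
#'   correlations.
#' @param n_cells,n_sib_pairs,n_pp_pairs sample sizes (optional, kept for
#'   reporting).
#' @return object of class `pedigree_moments`.
#' @export
pedigree_moments <- function(mean_t, var_t, rho_sib_hat, rho_parent_hat,
                             n_cells = NA_integer_, n_sib_pairs = NA_integer_,
                             n_pp_pairs = NA_integer_) {
  if (!is.finite(var_t) || var_t <= 0) {
    stop("degenerate variance: var_t must be positive")
  }
  structure(list(mean_t = mean_t, var_t = var_t,
                 rho_sib_hat = rho_sib_hat, rho_parent_hat = rho_parent_hat,
                 n_cells = n_cells, n_sib_pairs = n_sib_pairs,
                 n_pp_pairs = n_pp_pairs),
            class = "pedigree_moments")
}

# correlation of a two-column pair matrix; exchangeable pairs are
# symmetrized upstream so the estimate does not depend on pair ordering
pair_correlation <- function(pairs) {
  if (nrow(pairs) < 2L) return(NA_real_)
  stats::cor(pairs[, 1L], pairs[, 2L])
}

#' Sample moments of phase durations in a pedigree
#'
#' Computes the equilibrium-moment estimates used by the method of moments:
#' mean and variance over all cells with an observed complete phase, the
#' sibling correlation on symmetrized sibling pairs (each unordered pair
#' contributes both orderings, the standard convention for exchangeable
#' pairs), and the parent-progeny correlation over all (parent, progeny)
#' pairs.
#'
#' @param ped a [as_pedigree()] object.
#' @param phase `"g1"` or `"sg2m"` (or `"cycle"` for the total time).
#' @return [pedigree_moments()].
#' @export
compute_pedigree_moments <- function(ped, phase = c("g1", "sg2m", "cycle")) {
  stopifnot(inherits(ped, "pedigree"))
  phase <- match.arg(phase)
  field <- switch(phase, g1 = "t_g1", sg2m = "t_sg2m", cycle = "t_cycle")
  v <- ped[[field]]
  if (length(v) < 2L) stop("need at least 2 cells")
  if (stats::var(v) <= 0) stop("degenerate variance in ", field)
  sib <- extract_pairs(ped, "sibling", field, symmetrize = TRUE)
  pp <- extract_pairs(ped, "parent_progeny", field)
  if (nrow(sib) == 0L) stop("no sibling pairs in pedigree")
  if (nrow(pp) == 0L) stop("no parent-progeny pairs in pedigree")
  pedigree_moments(mean_t = mean(v), var_t = stats::var(v),
                   rho_sib_hat = pair_correlation(sib),
                   rho_parent_hat = pair_correlation(pp),
                   n_cells = length(v),
                   n_sib_pairs = nrow(sib) %/% 2L,
                   n_pp_pairs = nrow(pp))
}

#' Solve the transcendental equation for the log-scale noise variance
#'
#' Given the rescaled sibling correlation `A = (rho_sib - theta^2) /
#' (1 - theta^2)` and an assumed normal-scale noise correlation `rho`, the
#' log-scale variance satisfies `x^rho - 1 = A (x - 1)` with
#' `x = exp(sigma2) > 1`. A root `x0 > 1` exists iff `rho > A` (the
#' left-hand side leaves 1 with slope `rho`, the right-hand side with slope
#' `A`). Solved by bracketed bisection with geometric bracket growth.
#'
#' @param a_hat rescaled sibling correlation, in `(0, 1)`.
#' @param rho assumed noise correlation, must exceed `a_hat`.
#' @param tol absolute residual tolerance on the root equation.
#' @param x_cap largest bracket endpoint tried before declaring
#'   non-convergence (roots run to infinity as `rho` approaches `a_hat`).
#' @return `sigma2 = log(x0)`.
#' @export
solve_sigma2 <- function(a_hat, rho, tol = 1e-12, x_cap = 1e12) {
  if (!is.finite(a_hat) || a_hat <= 0 || a_hat >= 1) {
    stop("a_hat must lie in (0, 1)")
  }
  if (rho <= a_hat) stop("no root > 1 exists: rho must exceed a_hat")
  if (rho > 1) stop("rho must be <= 1")
  f <- function(x) x^rho - 1 - a_hat * (x - 1)
  # f > 0 just right of 1; grow the upper bracket until f < 0
  lo <- 1 + 1e-12
  hi <- 2
  while (f(hi) > 0) {
    lo <- hi
    hi <- hi * 4
    if (hi > x_cap) {
      stop("no root found below bracket cap; rho is too close to a_hat")
    }
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * hi) break
  }
  x0 <- (lo + hi) / 2
  if (abs(f(x0)) > tol * max(1, a_hat * x0)) {
    stop("bisection failed to reach tolerance")
  }
  log(x0)
}

#' Method-of-moments estimate of the autoregression parameters
#'
#' Exact inversion of the equilibrium moment relations at an assumed noise
#' correlation `rho`: `theta_hat` is the parent-progeny correlation;
#' `sigma2_hat` solves the transcendental equation for the rescaled sibling
#' correlation `A_hat`; `mu_hat` and `m_hat` follow by inverting the
#' variance and mean relations.
#'
#' @param moments [pedigree_moments()] (or values from
#'   [compute_pedigree_moments()]).
#' @param rho assumed normal-scale noise correlation.
#' @return object of class `bar_estimate`: list with `params`
#'   ([bar_params()]), `a_hat`, `x0` and the input `moments`.
#' @export
estimate_params <- function(moments, rho) {
  stopifnot(inherits(moments, "pedigree_moments"))
  th <- moments$rho_parent_hat
  if (!is.finite(th) || th^2 >= 1) stop("parent-progeny correlation must satisfy theta^2 < 1")
  a_hat <- (moments$rho_sib_hat - th^2) / (1 - th^2)
  if (!is.finite(a_hat) || a_hat <= 0) {
    stop("sibling correlation below theta^2 - model misspecified or noise")
  }
  if (a_hat >= 1) stop("sibling correlation implies A >= 1 - not estimable")
  s2 <- solve_sigma2(a_hat, rho)
  mu <- 0.5 * log(moments$var_t * (1 - th^2) / (exp(s2) * (exp(s2) - 1)))
  m <- moments$mean_t - exp(mu + s2 / 2) / (1 - th)
  structure(list(params = bar_params(m = m, theta = th, mu = mu,
                                     sigma2 = s2, rho = rho),
                 a_hat = a_hat, x0 = exp(s2), moments = moments),
            class = "bar_estimate")
}

#' @export
print.bar_estimate <- function(x, ...) {
  cat("method-of-moments estimate (rho assumed = ", x$params$rho, ")\n",
      sep = "")
  print(x$params)
  invisible(x)
}

# simulate n draws from (approximately) the equilibrium distribution of T
# by iterating a single line of descent past a burn-in
sample_equilibrium <- function(params, n, burn_in = 200L) {
  mom <- stationary_moments(params)
  t_cur <- max(mom$mean, 1e-6)
  total <- burn_in + n
  w <- draw_sibling_noise(params, total)[, 1L]
  out <- numeric(total)
  for (i in seq_len(total)) {
    t_new <- params$m + params$theta * (t_cur - params$m) + w[i]
    if (t_new <= 0) t_new <- t_cur  # vanishing-probability guard
    out[i] <- t_new
    t_cur <- t_new
  }
  out[(burn_in + 1L):total]
}

ks_distance <- function(a, b) {
  all_v <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(all_v)
  fb <- stats::ecdf(b)(all_v)
  max(abs(fa - fb))
}

#' Profile the assumed noise correlation against the data distribution
#'
#' The moment relations identify `(m, theta, mu, sigma2)` only given the
#' noise correlation `rho`. Following the estimate-then-adjust strategy,
#' each candidate `rho` on a grid is turned into a full parameter set by
#' [estimate_params()], a large equilibrium sample of the phase duration is
#' simulated at those parameters, and the candidate minimizing the
#' Kolmogorov-Smirnov distance to the observed durations is returned.
#'
#' @param ped a [as_pedigree()] object.
#' @param phase `"g1"` or `"sg2m"`.
#' @param rho_grid candidate noise correlations; infeasible points
#'   (`rho <= A_hat`) are dropped.
#' @param n_sim equilibrium sample size per candidate.
#' @return the winning `bar_estimate`, with a `diagnostics` data frame
#'   (`rho`, `ks`) attached.
#' @export
profile_rho <- function(ped, phase = c("g1", "sg2m"),
                        rho_grid = seq(0.05, 0.95, by = 0.05),
                        n_sim = 1e5) {
  phase <- match.arg(phase)
  moments <- compute_pedigree_moments(ped, phase)
  obs <- ped[[switch(phase, g1 = "t_g1", sg2m = "t_sg2m")]]
  th <- moments$rho_parent_hat
  a_hat <- (moments$rho_sib_hat - th^2) / (1 - th^2)
  feasible <- rho_grid[rho_grid > a_hat & rho_grid <= 1]
  if (length(feasible) == 0L) {
    stop("no feasible rho in grid (all <= A_hat = ", signif(a_hat, 3), ")")
  }
  ks <- vapply(feasible, function(r) {
    est <- estimate_params(moments, r)
    sim <- sample_equilibrium(est$params, n_sim)
    ks_distance(obs, sim)
  }, numeric(1L))
  best <- estimate_params(moments, feasible[which.min(ks)])
  best$diagnostics <- data.frame(rho = feasible, ks = ks)
  best
}

#' Monte Carlo cross-validation standard errors of family correlations
#'
#' Repeatedly subsamples a fraction of the relevant pairs and recomputes the
#' correlation, returning the spread across iterations as a standard-error
#' estimate for the pedigree correlation coefficients.
#'
#' @param ped a [as_pedigree()] object.
#' @param relation family relation passed to [extract_pairs()].
#' @param field duration column.
#' @param n_iter resampling iterations.
#' @param frac fraction of pairs per iteration.
#' @return list with `estimate`, `se` and the resampled values.
#' @export
correlation_se <- function(ped, relation, field = "t_cycle",
                           n_iter = 1000L, frac = 0.5) {
  pairs <- extract_pairs(ped, relation, field,
                         symmetrize = relation %in% c("sibling", "cousin"))
  if (nrow(pairs) < 4L) stop("too few pairs for resampling")
  k <- max(2L, floor(nrow(pairs) * frac))
  vals <- vapply(seq_len(n_iter), function(i) {
    pair_correlation(pairs[sample.int(nrow(pairs), k), , drop = FALSE])
  }, numeric(1L))
  list(estimate = pair_correlation(pairs),
       se = stats::sd(vals, na.rm = TRUE),
       samples = vals)
}
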