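# Bifurcating autoregression of cell-cycle phase durations with
# exchangeable bivariate lognormal noise, and its equilibrium moments.

#' Bifurcating autoregression parameters for one cell-cycle phase
#'
#' The residence time of each progeny cell in a phase is
#' `T_i = m + theta * (T_parent - m) + W_i`, where `(W_1, W_2)` is an
#' exchangeable bivariate lognormal noise pair: the exponential of a
#' bivariate normal with common mean `mu`, common variance `sigma2` and
#' correlation `rho`. G1 and S/G2/M carry independent parameter sets.
#'
#' @param m location constant (hours). Equals the equilibrium phase mean
#'   minus the corrective term `exp(mu + sigma2/2) / (1 - theta)`.
#' @param theta inherited fraction, `theta^2 < 1`.
#' @param mu log-scale mean of the noise.
#' @param sigma2 log-scale variance of the noise, `> 0`.
#' @param rho correlation of the underlying normal pair, in `(-1, 1]`.
#' @return object of class `bar_params`.
#' @seealso [bar_params_from_targets()] to construct parameters from
#'   equilibrium mean/CV and family-correlation targets.
#' @export
bar_params <- function(m, theta, mu, sigma2, rho) {
  stopifnot(is.numeric(m), is.numeric(theta), is.numeric(mu),
            is.numeric(sigma2), is.numeric(rho))
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (theta^2 >= 1) stop("theta^2 must be < 1 (no equilibrium otherwise)")
  if (rho <= -1 || rho > 1) stop("rho must be in (-1, 1]")
  structure(list(m = m, theta = theta, mu = mu, sigma2 = sigma2, rho = rho),
            class = "bar_params")
}

#' @export
print.bar_params <- function(x, ...) {
  mom <- stationary_moments(x)
  cat(sprintf(
    "bar_params: m=%.4g theta=%.3g mu=%.4g sigma2=%.4g rho=%.3g\n",
    x$m, x$theta, x$mu, x$sigma2, x$rho))
  cat(sprintf(
    "  equilibrium: mean %.3g h, sd %.3g h, rho_sib %.3g, rho_parent %.3g\n",
    mom$mean, sqrt(mom$variance), mom$rho_sib, mom$rho_parent))
  invisible(x)
}

# correlation of the exponentiated pair given normal-scale (rho, sigma2)
lognormal_pair_correlation <- function(rho, sigma2) {
  (exp(rho * sigma2) - 1) / (exp(sigma2) - 1)
}

#' Draw exchangeable bivariate lognormal noise pairs
#'
#' @param params [bar_params()].
#' @param n number of pairs.
#' @return `n x 2` matrix of positive noise values; each row is the shared
#'   draw of one sibling pair.
#' @details Marginals are lognormal(`mu`, `sigma2`); the correlation of the
#'   pair on the natural scale is
#'   `(exp(rho*sigma2) - 1) / (exp(sigma2) - 1)`.
#' @export
draw_sibling_noise <- function(params, n = 1L) {
  stopifnot(inherits(params, "bar_params"))
  s <- sqrt(params$sigma2)
  e1 <- stats::rnorm(n)
  e2 <- stats::rnorm(n)
  z1 <- params$mu + s * e1
  z2 <- params$mu + s * (params$rho * e1 + sqrt(1 - params$rho^2) * e2)
  cbind(w1 = exp(z1), w2 = exp(z2))
}

#' Progeny phase durations given the parent's duration
#'
#' Applies the bifurcating autoregression step to one or more divisions.
#' Both progeny of a division share one correlated noise pair. Draws that
#' would produce a non-positive duration are redrawn (up to `max_redraw`
#' attempts per division) so the autoregressive form is preserved without
#' truncation of the returned values.
#'
#' @param parent_t parent phase duration(s), hours, `> 0`.
#' @param params [bar_params()].
#' @param max_redraw redraw budget per division before erroring.
#' @return `length(parent_t) x 2` matrix of progeny durations.
#' @export
progeny_phase_durations <- function(parent_t, params, max_redraw = 100L) {
  stopifnot(inherits(params, "bar_params"))
  if (any(parent_t <= 0)) stop("parent duration must be positive")
  n <- length(parent_t)
  base <- params$m + params$theta * (parent_t - params$m)
  w <- draw_sibling_noise(params, n)
  out <- base + w
  bad <- which(out[, 1L] <= 0 | out[, 2L] <= 0)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > max_redraw) {
      stop("could not draw positive progeny durations after ",
           max_redraw, " attempts")
    }
    w <- draw_sibling_noise(params, length(bad))
    out[bad, ] <- base[bad] + w
    bad <- bad[out[bad, 1L] <= 0 | out[bad, 2L] <= 0]
  }
  colnames(out) <- c("t1", "t2")
  out
}

#' Equilibrium moments of the bifurcating autoregression
#'
#' Closed-form stationary mean, variance and family correlations of the
#' phase duration under the lognormal-noise bifurcating autoregression:
#' \deqn{E(T) = m + e^{\mu+\sigma^2/2}/(1-\theta)}
#' \deqn{Var(T) = e^{2\mu} e^{\sigma^2}(e^{\sigma^2}-1)/(1-\theta^2)}
#' \deqn{\rho_{sib} = \theta^2 + (1-\theta^2)\,
#'   (e^{\rho\sigma^2}-1)/(e^{\sigma^2}-1)}
#' with parent-progeny correlation `theta` and cousin correlation
#' `rho_sib * theta^2` (each cousin regresses on its own parent with
#' slope `theta`, and the two parents are a sibling pair).
#'
#' @param params [bar_params()].
#' @return list with `mean`, `variance`, `rho_sib`, `rho_parent`,
#'   `rho_cousin`.
#' @export
stationary_moments <- function(params) {
  stopifnot(inherits(params, "bar_params"))
  th <- params$theta
  s2 <- params$sigma2
  ew <- exp(params$mu + s2 / 2)
  vw <- exp(2 * params$mu) * exp(s2) * (exp(s2) - 1)
  rho_w <- lognormal_pair_correlation(params$rho, s2)
  rho_sib <- th^2 + (1 - th^2) * rho_w
  list(mean = params$m + ew / (1 - th),
       variance = vw / (1 - th^2),
       rho_sib = rho_sib,
       rho_parent = th,
       rho_cousin = rho_sib * th^2)
}

#' Construct autoregression parameters from equilibrium targets
#'
#' Inverts the equilibrium relations: given a target stationary mean and
#' standard deviation of the phase duration, the parent-progeny correlation
#' (`theta`), the sibling correlation, and a normal-scale noise correlation
#' `rho`, returns the `bar_params` whose equilibrium reproduces them
#' exactly. This is the user-facing constructor: the location constant `m`
#' is derived, never set directly.
#'
#' @param mean,sd target equilibrium mean and standard deviation (hours).
#' @param theta parent-progeny correlation target.
#' @param rho_sib sibling correlation target, must satisfy
#'   `rho_sib > theta^2`.
#' @param rho normal-scale noise correlation; must exceed
#'   `(rho_sib - theta^2) / (1 - theta^2)` for a lognormal noise model to
#'   exist.
#' @return [bar_params()].
#' @export
bar_params_from_targets <- function(mean, sd, theta, rho_sib, rho) {
  est <- estimate_params(
    pedigree_moments(mean_t = mean, var_t = sd^2,
                     rho_sib_hat = rho_sib, rho_parent_hat = theta),
    rho = rho)
  est$params
}
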