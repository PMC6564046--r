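# Ground-truth fixture generator: pedigrees and noisy FUCCI trajectory
# tables with the statistical structure the pipeline assumes.

#' Generate a synthetic time-lapse experiment with known ground truth
#'
#' Emulates the structure of a FUCCI time-lapse dataset: a set of tracked
#' lineage positions filmed for a fixed duration, each yielding a
#' fluorescence trace across several divisions, plus the underlying
#' pedigree. The generator runs the full inheritance + protein model,
#' follows one random line of descent per founder (as a tracking algorithm
#' follows one position), samples both markers on a uniform grid and
#' injects multiplicative lognormal measurement noise. First and last
#' cycles are typically incomplete, as in real films.
#'
#' @param config [sim_config()]; `config$t_end` is the film duration
#'   (default set-up mirrors 72 h films).
#' @param n_tracks number of tracked lineages (one per founder).
#' @param noise_sd relative standard deviation of the multiplicative
#'   measurement noise (default 0.05); `0` disables noise.
#' @param additive_sd optional additive noise floor (a.u.).
#' @param dt sampling interval (hours; default 0.25, one frame / 15 min).
#' @return object of class `synthetic_experiment`: list with
#'   `pedigree`, `trajectories` (long table `cell_id,time_h,cdt1,geminin`,
#'   one `cell_id` per track), `truth` (per-track division / G1-S times
#'   and per-cycle durations) and `noise` (the noise spec).
#' @export
generate_experiment <- function(config = NULL, n_tracks = 25L,
                                noise_sd = 0.05, additive_sd = 0,
                                dt = 0.25) {
  if (is.null(config)) {
    config <- sim_config(n_ancestors = as.integer(n_tracks), t_end = 72,
                         population_cap = 50000L)
  } else {
    config$n_ancestors <- as.integer(n_tracks)
  }
  sim <- simulate_population(config, census_dt = max(1, dt * 4))
  ped <- sim$pedigree
  kids <- pedigree_children(ped)
  grid <- seq(0, config$t_end, by = dt)

  traj_list <- list()
  truth <- list()
  for (r in which(is.na(ped$parent_id))) {
    # follow one random line of descent from this founder
    chain <- integer(0)
    i <- r
    repeat {
      chain <- c(chain, i)
      k <- kids[[ped$cell_id[i]]]
      if (is.null(k)) break
      i <- k[sample.int(2L, 1L)]
    }
    cdt1 <- rep(NA_real_, length(grid))
    gem <- rep(NA_real_, length(grid))
    for (i in chain) {
      tr <- simulate_trajectory(config$kinetics, ped$p_c[i], ped$p_g[i],
                                ped$t_g1[i], ped$t_cycle[i],
                                ped$c0[i], ped$g0[i], dt = 0.05)
      sel <- grid >= max(ped$birth_time[i], 0) &
        grid < min(ped$division_time[i], config$t_end + dt)
      if (!any(sel)) next
      age <- grid[sel] - ped$birth_time[i]
      cdt1[sel] <- stats::approx(tr$time_h, tr$cdt1, xout = age,
                                 rule = 2)$y
      gem[sel] <- stats::approx(tr$time_h, tr$geminin, xout = age,
                                rule = 2)$y
    }
    keep <- !is.na(cdt1)
    yc <- cdt1[keep]; yg <- gem[keep]
    n <- length(yc)
    if (noise_sd > 0) {
      s <- sqrt(log(1 + noise_sd^2))
      yc <- yc * stats::rlnorm(n, -s^2 / 2, s)
      yg <- yg * stats::rlnorm(n, -s^2 / 2, s)
    }
    if (additive_sd > 0) {
      yc <- pmax(yc + stats::rnorm(n, 0, additive_sd), 0)
      yg <- pmax(yg + stats::rnorm(n, 0, additive_sd), 0)
    }
    track_id <- sprintf("track%03d", length(traj_list) + 1L)
    traj_list[[track_id]] <- data.frame(cell_id = track_id,
                                        time_h = grid[keep],
                                        cdt1 = yc, geminin = yg,
                                        stringsAsFactors = FALSE)
    div_times <- ped$division_time[chain]
    div_times <- div_times[div_times <= config$t_end]
    g1s_times <- ped$birth_time[chain] + ped$t_g1[chain]
    truth[[track_id]] <- list(
      cells = ped$cell_id[chain],
      division_times = div_times,
      g1s_times = g1s_times[g1s_times >= 0 & g1s_times <= config$t_end],
      t_g1 = ped$t_g1[chain], t_sg2m = ped$t_sg2m[chain],
      birth_times = ped$birth_time[chain])
  }
  structure(list(pedigree = ped,
                 trajectories = do.call(rbind, c(traj_list,
                                                 make.row.names = FALSE)),
                 truth = truth,
                 noise = list(model = "multiplicative-lognormal",
                              noise_sd = noise_sd,
                              additive_sd = additive_sd, dt = dt),
                 config = config),
            class = "synthetic_experiment")
}

#' Write a synthetic experiment to disk
#'
#' Writes the pedigree and trajectory tables as CSV plus a sidecar
#' `<stem>.truth.json` holding the ground-truth annotations and full
#' parameter provenance (including the seed when supplied).
#'
#' @param exp a [generate_experiment()] result.
#' @param dir output directory (created if needed).
#' @param stem file stem.
#' @param seed seed to record in the provenance block.
#' @return invisibly, the three file paths.
#' @export
write_experiment <- function(exp, dir, stem = "synthetic", seed = NULL) {
  stopifnot(inherits(exp, "synthetic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_ped <- file.path(dir, paste0(stem, ".pedigree.csv"))
  p_trj <- file.path(dir, paste0(stem, ".trajectories.csv"))
  p_tru <- file.path(dir, paste0(stem, ".truth.json"))
  write_pedigree_table(exp$pedigree, p_ped)
  write_trajectory_table(exp$trajectories, p_trj)
  jsonlite::write_json(
    list(seed = seed, noise = exp$noise,
         truth = exp$truth,
         params = list(
           g1 = unclass(exp$config$g1), sg2m = unclass(exp$config$sg2m),
           kinetics = unclass(exp$config$kinetics),
           regression = unclass(exp$config$regression),
           division = unclass(exp$config$division))),
    p_tru, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(pedigree = p_ped, trajectories = p_trj, truth = p_tru))
}

#' Multinomial null fixture for the drift estimators
#'
#' Draws `M` replicate progeny-count vectors from the Wright-Fisher
#' multinomial `MN(1/N, ..., 1/N; K)` and rescales them to fractions, the
#' exact null under which [effective_size()] should recover `K`.
#'
#' @param n_ancestors N (>= 2).
#' @param k effective size K (>= 1).
#' @param m number of replicates (>= 2).
#' @return [drift_replicates()].
#' @export
generate_multinomial_fixture <- function(n_ancestors, k, m) {
  stopifnot(n_ancestors >= 2L, k >= 1, m >= 2L)
  x <- stats::rmultinom(m, size = k, prob = rep(1 / n_ancestors, n_ancestors))
  drift_replicates(t(x) / k)
}
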