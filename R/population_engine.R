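# Event-driven simulation of growing pedigrees under the full inheritance
# model and under the simplified i.i.d.-lognormal model, plus a fast
# vectorized census-only simulator used for drift replicates.

#' Lognormal cell-cycle law of the simplified (uncorrelated) model
#'
#' In the simplified model every cell's total cycle time is an independent
#' lognormal draw; there is no inheritance and no family correlation.
#'
#' @param mean_cc mean cycle time (hours); default 20.4 h, the observed
#'   mean under 15% serum.
#' @param cv_cc coefficient of variation; default 0.30.
#' @return object of class `lognormal_cycle` with the natural-scale and
#'   log-scale parameters.
#' @export
lognormal_cycle_params <- function(mean_cc = 20.4, cv_cc = 0.30) {
  if (mean_cc <= 0 || cv_cc <= 0) stop("mean and cv must be positive")
  sdlog2 <- log(1 + cv_cc^2)
  structure(list(mean_cc = mean_cc, cv_cc = cv_cc,
                 meanlog = log(mean_cc) - sdlog2 / 2,
                 sdlog = sqrt(sdlog2)),
            class = "lognormal_cycle")
}

#' Simulation configuration
#'
#' Bundles everything a population run needs: per-phase autoregression
#' parameters, protein kinetics/regression/division laws, the simplified
#' model's cycle law, initial population and stopping rules.
#'
#' @param g1,sg2m [bar_params()] for the two phases (full model).
#' @param kinetics [fucci_kinetics()].
#' @param regression [production_regression()].
#' @param division [division_law()].
#' @param cycle [lognormal_cycle_params()] (uncorrelated model).
#' @param n_ancestors number of founder cells.
#' @param ancestors optional data frame with columns `t_g1`, `t_sg2m` (and
#'   optionally `age`, default 0) pinning the founder states explicitly;
#'   overrides `n_ancestors` and the equilibrium draw.
#' @param t_end simulation horizon (hours).
#' @param population_cap hard cap on the number of cells ever created; a
#'   run that hits it returns a result flagged `truncated`.
#' @param model_variant `"full"` (bifurcating autoregression) or
#'   `"uncorrelated"` (i.i.d. lognormal cycle times).
#' @param track_proteins logical; protein bookkeeping can be switched off
#'   where only durations matter (it does not feed back on them).
#' @param synchronized logical; if `TRUE` ancestors all start at cycle age
#'   0, otherwise ages are uniform over the drawn cycle.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(g1 = NULL, sg2m = NULL,
                       kinetics = fucci_kinetics(),
                       regression = production_regression(),
                       division = division_law(),
                       cycle = lognormal_cycle_params(),
                       n_ancestors = 1L, ancestors = NULL, t_end = 72,
                       population_cap = 100000L,
                       model_variant = c("full", "uncorrelated"),
                       track_proteins = TRUE,
                       synchronized = FALSE) {
  model_variant <- match.arg(model_variant)
  if (!is.null(ancestors)) {
    stopifnot(all(c("t_g1", "t_sg2m") %in% names(ancestors)))
    n_ancestors <- nrow(ancestors)
  }
  if (t_end <= 0) stop("t_end must be positive")
  if (population_cap < n_ancestors) stop("cap must be >= number of ancestors")
  if (model_variant == "full" && (is.null(g1) || is.null(sg2m))) {
    defaults <- default_phase_params()
    if (is.null(g1)) g1 <- defaults$g1
    if (is.null(sg2m)) sg2m <- defaults$sg2m
  }
  structure(list(g1 = g1, sg2m = sg2m, kinetics = kinetics,
                 regression = regression, division = division,
                 cycle = cycle, n_ancestors = as.integer(n_ancestors),
                 ancestors = ancestors,
                 t_end = t_end, population_cap = as.integer(population_cap),
                 model_variant = model_variant,
                 track_proteins = isTRUE(track_proteins),
                 synchronized = isTRUE(synchronized)),
            class = "sim_config")
}

#' Default phase-inheritance parameters
#'
#' Ground-truth parameter sets of the synthetic-data generator, chosen to
#' reproduce the headline statistics of proliferating fibroblasts under
#' 15% serum: total cycle mean 20.4 h with CV 0.30, G1 taking ~45% of the
#' cycle and carrying most of the variability, parent-progeny correlations
#' of 0.25 (G1) and 0.40 (S/G2/M), and sibling correlations of 0.50 (G1)
#' and 0.65 (S/G2/M).
#'
#' @return list with `bar_params` elements `g1` and `sg2m`.
#' @export
default_phase_params <- function() {
  list(g1 = bar_params_from_targets(mean = 9.2, sd = 0.52 * 9.2,
                                    theta = 0.25, rho_sib = 0.50, rho = 0.55),
       sg2m = bar_params_from_targets(mean = 11.2, sd = 0.34 * 11.2,
                                      theta = 0.40, rho_sib = 0.65, rho = 0.65))
}

# draw n equilibrium (t_g1, t_sg2m) pairs for founder cells
draw_stationary_durations <- function(config, n) {
  if (config$model_variant == "uncorrelated") {
    t_c <- stats::rlnorm(n, config$cycle$meanlog, config$cycle$sdlog)
    share <- g1_share(config)
    cbind(t_g1 = share * t_c, t_sg2m = (1 - share) * t_c)
  } else {
    cbind(t_g1 = sample_equilibrium(config$g1, n),
          t_sg2m = sample_equilibrium(config$sg2m, n))
  }
}

# stationary fraction of the cycle spent in G1 (protein bookkeeping only
# in the uncorrelated variant, where phases are not modelled)
g1_share <- function(config) {
  if (!is.null(config$g1) && !is.null(config$sg2m)) {
    m1 <- stationary_moments(config$g1)$mean
    m2 <- stationary_moments(config$sg2m)$mean
    m1 / (m1 + m2)
  } else 0.45
}

#' Initialize unsynchronized founder cells
#'
#' Each founder receives a full equilibrium cycle (and phase split) and an
#' age drawn uniformly on `[0, T_C)`; its first division happens after the
#' residual time `T_C - age`. With `synchronized = TRUE` all ages are 0.
#'
#' @param config [sim_config()].
#' @param n number of founders (defaults to `config$n_ancestors`).
#' @return data frame with `t_g1`, `t_sg2m`, `t_cycle`, `age`, `residual`.
#' @export
init_unsynchronized_ancestors <- function(config, n = config$n_ancestors) {
  if (!is.null(config$ancestors)) {
    a <- config$ancestors
    t_c <- a$t_g1 + a$t_sg2m
    age <- if (!is.null(a$age)) a$age else rep(0, nrow(a))
    return(data.frame(t_g1 = a$t_g1, t_sg2m = a$t_sg2m, t_cycle = t_c,
                      age = age, residual = t_c - age))
  }
  durs <- draw_stationary_durations(config, n)
  t_c <- durs[, 1L] + durs[, 2L]
  age <- if (config$synchronized) rep(0, n) else stats::runif(n) * t_c
  data.frame(t_g1 = durs[, 1L], t_sg2m = durs[, 2L], t_cycle = t_c,
             age = age, residual = t_c - age)
}

# progeny durations for one phase, vectorized over divisions, with redraw
# of non-positive results
ar_progeny_vec <- function(parent_t, params, max_redraw = 100L) {
  progeny_phase_durations(parent_t, params, max_redraw = max_redraw)
}

# -- fast census-only simulator -------------------------------------------
#
# Generation-wave simulation: no global event ordering is needed when the
# run is stopped by the time horizon alone, because each division depends
# only on its parent. Returns all division events (time, ancestor index)
# with times < t_end; the census at any t is n_ancestors + #events <= t,
# and the per-ancestor count is 1 + #events of that lineage.
sim_division_events <- function(config) {
  n0 <- config$n_ancestors
  anc0 <- init_unsynchronized_ancestors(config)
  act_t <- anc0$residual
  act_g1 <- anc0$t_g1
  act_sg2m <- anc0$t_sg2m
  act_anc <- seq_len(n0)
  ev_t <- list(); ev_a <- list(); k <- 0L
  uncor <- config$model_variant == "uncorrelated"
  while (length(act_t) > 0L) {
    div <- act_t < config$t_end
    if (!any(div)) break
    tp <- act_t[div]; ap <- act_anc[div]
    k <- k + 1L
    ev_t[[k]] <- tp; ev_a[[k]] <- ap
    n <- length(tp)
    if (uncor) {
      life <- stats::rlnorm(2L * n, config$cycle$meanlog, config$cycle$sdlog)
      act_t <- rep(tp, 2L) + life
      act_anc <- rep(ap, 2L)
      act_g1 <- act_sg2m <- NULL
    } else {
      g1p <- ar_progeny_vec(act_g1[div], config$g1)
      smp <- ar_progeny_vec(act_sg2m[div], config$sg2m)
      act_g1 <- c(g1p[, 1L], g1p[, 2L])
      act_sg2m <- c(smp[, 1L], smp[, 2L])
      act_t <- rep(tp, 2L) + act_g1 + act_sg2m
      act_anc <- rep(ap, 2L)
    }
  }
  list(times = unlist(ev_t), ancestor = unlist(ev_a), n0 = n0)
}

# census series on a grid from a division-event list
census_from_events <- function(events, grid) {
  o <- order(events$times)
  tt <- events$times[o]
  aa <- events$ancestor[o]
  total <- events$n0 + findInterval(grid, tt)
  by_anc <- vapply(seq_len(events$n0), function(i) {
    1L + findInterval(grid, tt[aa == i])
  }, integer(length(grid)))
  by_anc <- matrix(by_anc, nrow = length(grid),
                   dimnames = list(NULL, as.character(seq_len(events$n0))))
  new_census(grid, as.integer(total), by_anc)
}

#' Simulate one census trajectory (durations only)
#'
#' Fast path used by the drift analyses: simulates the branching pedigree
#' without protein bookkeeping and returns the census series and the
#' per-ancestor progeny fractions at the horizon.
#'
#' @param config [sim_config()].
#' @param census_dt census grid spacing (hours).
#' @return list with `census` (a `census_series`) and `fractions` (at
#'   `config$t_end`).
#' @export
simulate_census <- function(config, census_dt = 1) {
  stopifnot(inherits(config, "sim_config"))
  ev <- sim_division_events(config)
  grid <- seq(0, config$t_end, by = census_dt)
  cs <- census_from_events(ev, grid)
  z <- 1L + tabulate(ev$ancestor, nbins = ev$n0)
  list(census = cs, fractions = z / sum(z))
}

# -- full event-driven engine ---------------------------------------------

#' Simulate a growing cell population
#'
#' Event-driven continuous-time simulation: divisions are processed in
#' chronological order (ties broken by cell index). At each division the
#' progeny phase durations are drawn by bifurcating autoregression (full
#' model) or as i.i.d. lognormal cycle times (uncorrelated model); protein
#' amounts are split by the beta division law, production rates are drawn
#' from the sibling-correlated regressions, and marker levels at the G1/S
#' transition and at division are computed from the ODE model. Cells whose
#' division falls beyond the horizon remain unfinished leaves.
#'
#' @param config [sim_config()].
#' @param census_dt census grid spacing (hours).
#' @return list with `pedigree` (a [as_pedigree()] object), `census` and
#'   the logical flag `truncated` (TRUE when the population cap stopped
#'   the run before the horizon).
#' @export
simulate_population <- function(config, census_dt = 1) {
  stopifnot(inherits(config, "sim_config"))
  n0 <- config$n_ancestors
  cap <- config$population_cap
  anc0 <- init_unsynchronized_ancestors(config)
  uncor <- config$model_variant == "uncorrelated"
  track <- config$track_proteins

  # growing columns, preallocated and doubled on demand
  cap_now <- max(64L, 2L * n0)
  col <- function(x) c(x, rep(NA_real_, cap_now - length(x)))
  parent <- c(rep(NA_integer_, n0), rep(NA_integer_, cap_now - n0))
  birth <- col(-anc0$age)
  tg1 <- col(anc0$t_g1)
  tsg <- col(anc0$t_sg2m)
  divt <- col(anc0$residual)
  c0 <- g0 <- pc <- pg <- cg1 <- cend <- gend <- rep(NA_real_, cap_now)
  if (track) {
    warm <- warmup_protein_state(config, n0)
    c0[seq_len(n0)] <- warm$c0
    g0[seq_len(n0)] <- warm$g0
    pc[seq_len(n0)] <- warm$p_c
    pg[seq_len(n0)] <- warm$p_g
    for (i in seq_len(n0)) {
      ep <- protein_endpoints(config$kinetics, pc[i], pg[i], tg1[i],
                              tg1[i] + tsg[i], c0[i], g0[i])
      cg1[i] <- ep$c_g1; cend[i] <- ep$c_end; gend[i] <- ep$g_end
    }
  }
  n_cells <- n0
  pending <- rep(TRUE, cap_now)
  pending[(n0 + 1L):cap_now] <- FALSE
  truncated <- FALSE

  grow <- function() {
    new_cap <- cap_now * 2L
    pad_d <- rep(NA_real_, new_cap - cap_now)
    parent <<- c(parent, rep(NA_integer_, new_cap - cap_now))
    birth <<- c(birth, pad_d); tg1 <<- c(tg1, pad_d); tsg <<- c(tsg, pad_d)
    divt <<- c(divt, pad_d); c0 <<- c(c0, pad_d); g0 <<- c(g0, pad_d)
    pc <<- c(pc, pad_d); pg <<- c(pg, pad_d); cg1 <<- c(cg1, pad_d)
    cend <<- c(cend, pad_d); gend <<- c(gend, pad_d)
    pending <<- c(pending, rep(FALSE, new_cap - cap_now))
    cap_now <<- new_cap
  }

  repeat {
    cand <- which(pending[seq_len(n_cells)] &
                    divt[seq_len(n_cells)] < config$t_end)
    if (length(cand) == 0L) break
    i <- cand[which.min(divt[cand])]
    pending[i] <- FALSE
    if (n_cells + 2L > cap) { truncated <- TRUE; break }
    while (n_cells + 2L > cap_now) grow()
    if (uncor) {
      life <- stats::rlnorm(2L, config$cycle$meanlog, config$cycle$sdlog)
      share <- g1_share(config)
      t_g1_new <- share * life
      t_sg_new <- (1 - share) * life
    } else {
      t_g1_new <- as.numeric(ar_progeny_vec(tg1[i], config$g1))
      t_sg_new <- as.numeric(ar_progeny_vec(tsg[i], config$sg2m))
    }
    j <- n_cells + 1:2
    parent[j] <- i
    birth[j] <- divt[i]
    tg1[j] <- t_g1_new
    tsg[j] <- t_sg_new
    divt[j] <- divt[i] + t_g1_new + t_sg_new
    if (track) {
      sp <- divide_proteins(cend[i], gend[i], config$division)
      c0[j] <- sp$c[1L, ]
      g0[j] <- sp$g[1L, ]
      rates <- draw_production_rates(t_g1_new, c0[j], t_sg_new, g0[j],
                                     config$regression)
      pc[j] <- rates$p_c[1L, ]
      pg[j] <- rates$p_g[1L, ]
      for (u in j) {
        ep <- protein_endpoints(config$kinetics, pc[u], pg[u], tg1[u],
                                tg1[u] + tsg[u], c0[u], g0[u])
        cg1[u] <- ep$c_g1; cend[u] <- ep$c_end; gend[u] <- ep$g_end
      }
    }
    pending[j] <- TRUE
    n_cells <- n_cells + 2L
  }

  sel <- seq_len(n_cells)
  ids <- sprintf("c%06d", sel)
  ped <- data.frame(cell_id = ids,
                    parent_id = ifelse(is.na(parent[sel]), NA_character_,
                                       ids[parent[sel]]),
                    birth_time = birth[sel],
                    t_g1 = tg1[sel], t_sg2m = tsg[sel],
                    c0 = c0[sel], g0 = g0[sel],
                    c_end = cend[sel], g_end = gend[sel],
                    p_c = pc[sel], p_g = pg[sel],
                    stringsAsFactors = FALSE)
  ped <- as_pedigree(ped)
  grid <- seq(0, config$t_end, by = census_dt)
  census <- census_from_pedigree(ped, grid)
  list(pedigree = ped, census = census, truncated = truncated)
}

# stationary birth-state of the protein system, obtained from a short
# warm-up run along single lineages
warmup_protein_state <- function(config, n, generations = 15L) {
  share <- g1_share(config)
  c0 <- rep(30, n); g0 <- rep(30, n)
  p_c <- p_g <- rep(NA_real_, n)
  for (gen in seq_len(generations)) {
    durs <- draw_stationary_durations(config, n)
    rates <- draw_production_rates(cbind(durs[, 1L], durs[, 1L]),
                                   cbind(c0, c0),
                                   cbind(durs[, 2L], durs[, 2L]),
                                   cbind(g0, g0), config$regression)
    p_c <- rates$p_c[, 1L]
    p_g <- rates$p_g[, 1L]
    cend <- gend <- numeric(n)
    for (i in seq_len(n)) {
      ep <- protein_endpoints(config$kinetics, p_c[i], p_g[i], durs[i, 1L],
                              durs[i, 1L] + durs[i, 2L], c0[i], g0[i])
      cend[i] <- ep$c_end; gend[i] <- ep$g_end
    }
    sp <- divide_proteins(cend, gend, config$division)
    c0 <- sp$c[, 1L]
    g0 <- sp$g[, 1L]
  }
  list(c0 = c0, g0 = g0, p_c = p_c, p_g = p_g)
}

#' Simulate a complete pedigree to a fixed number of generations
#'
#' Every lineage is followed for exactly `n_generations` divisions,
#' regardless of time, so the resulting pedigree carries no
#' observation-window censoring: sample moments and family correlations
#' are unbiased for the equilibrium values. This is the right input for
#' estimator validation; time-limited simulations (like real films)
#' under-represent slow-cycling parents and attenuate correlations.
#'
#' Durations only (no protein bookkeeping).
#'
#' @param config [sim_config()].
#' @param n_generations tree depth below the founders.
#' @param n_ancestors founders (defaults to `config$n_ancestors`).
#' @return [as_pedigree()] object with `2^(g+1) - 1` cells per founder.
#' @export
simulate_pedigree_generations <- function(config, n_generations,
                                          n_ancestors = config$n_ancestors) {
  stopifnot(inherits(config, "sim_config"), n_generations >= 1L)
  durs <- draw_stationary_durations(config, n_ancestors)
  id <- sprintf("a%03d", seq_len(n_ancestors))
  rows <- list(data.frame(cell_id = id, parent_id = NA_character_,
                          birth_time = 0, t_g1 = durs[, 1L],
                          t_sg2m = durs[, 2L], stringsAsFactors = FALSE))
  cur <- rows[[1L]]
  uncor <- config$model_variant == "uncorrelated"
  for (g in seq_len(n_generations)) {
    n <- nrow(cur)
    if (uncor) {
      life <- stats::rlnorm(2L * n, config$cycle$meanlog, config$cycle$sdlog)
      share <- g1_share(config)
      g1_new <- share * life
      sg_new <- (1 - share) * life
    } else {
      g1p <- ar_progeny_vec(cur$t_g1, config$g1)
      sgp <- ar_progeny_vec(cur$t_sg2m, config$sg2m)
      g1_new <- c(g1p[, 1L], g1p[, 2L])
      sg_new <- c(sgp[, 1L], sgp[, 2L])
    }
    cur <- data.frame(
      cell_id = paste0(rep(cur$cell_id, 2L), ".", rep(1:2, each = n)),
      parent_id = rep(cur$cell_id, 2L),
      birth_time = rep(cur$birth_time + cur$t_g1 + cur$t_sg2m, 2L),
      t_g1 = g1_new, t_sg2m = sg_new, stringsAsFactors = FALSE)
    rows[[g + 1L]] <- cur
  }
  as_pedigree(do.call(rbind, rows))
}

#' Simulate one line of descent
#'
#' Follows a single lineage for `n_generations` divisions; at each division
#' one progeny is chosen uniformly at random. Used for long-run
#' stabilization analyses: the running distribution of cycle times along
#' the lineage converges to the equilibrium regardless of the ancestor.
#'
#' @param config [sim_config()] (full model).
#' @param n_generations number of divisions to follow.
#' @param ancestor optional list with `t_g1`, `t_sg2m` to pin the founder;
#'   defaults to an equilibrium draw.
#' @return data frame with one row per generation: `generation`, `t_g1`,
#'   `t_sg2m`, `t_cycle` and, when proteins are tracked, `c0`, `g0`,
#'   `p_c`, `p_g`.
#' @export
simulate_lineage <- function(config, n_generations, ancestor = NULL) {
  stopifnot(inherits(config, "sim_config"), n_generations >= 1L)
  if (is.null(ancestor)) {
    d <- draw_stationary_durations(config, 1L)
    ancestor <- list(t_g1 = d[1L, 1L], t_sg2m = d[1L, 2L])
  }
  track <- config$track_proteins && config$model_variant == "full"
  t_g1 <- numeric(n_generations); t_sg <- numeric(n_generations)
  c0v <- g0v <- pcv <- pgv <- rep(NA_real_, n_generations)
  cur_g1 <- ancestor$t_g1; cur_sg <- ancestor$t_sg2m
  cur_c0 <- 30; cur_g0 <- 30
  pick <- function() sample.int(2L, 1L)
  for (g in seq_len(n_generations)) {
    if (config$model_variant == "uncorrelated") {
      life <- stats::rlnorm(2L, config$cycle$meanlog, config$cycle$sdlog)
      share <- g1_share(config)
      k <- pick()
      cur_g1 <- share * life[k]; cur_sg <- (1 - share) * life[k]
    } else {
      g1p <- ar_progeny_vec(cur_g1, config$g1)
      sgp <- ar_progeny_vec(cur_sg, config$sg2m)
      k <- pick()
      cur_g1 <- g1p[1L, k]; cur_sg <- sgp[1L, k]
    }
    t_g1[g] <- cur_g1; t_sg[g] <- cur_sg
    if (track) {
      rates <- draw_production_rates(c(cur_g1, cur_g1), c(cur_c0, cur_c0),
                                     c(cur_sg, cur_sg), c(cur_g0, cur_g0),
                                     config$regression)
      p_c <- rates$p_c[1L, k]; p_g <- rates$p_g[1L, k]
      ep <- protein_endpoints(config$kinetics, p_c, p_g, cur_g1,
                              cur_g1 + cur_sg, cur_c0, cur_g0)
      sp <- divide_proteins(ep$c_end, ep$g_end, config$division)
      c0v[g] <- cur_c0; g0v[g] <- cur_g0; pcv[g] <- p_c; pgv[g] <- p_g
      cur_c0 <- sp$c[1L, k]; cur_g0 <- sp$g[1L, k]
    }
  }
  out <- data.frame(generation = seq_len(n_generations),
                    t_g1 = t_g1, t_sg2m = t_sg, t_cycle = t_g1 + t_sg)
  if (track) {
    out$c0 <- c0v; out$g0 <- g0v; out$p_c <- pcv; out$p_g <- pgv
  }
  out
}
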