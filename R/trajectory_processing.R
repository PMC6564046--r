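# Recovery of division times, G1/S transitions and phase durations from
# noisy FUCCI trajectories, with quality filtering.

#' Locally quadratic smoothing of a sampled series
#'
#' Local regression with weighted linear least squares and a 2nd-degree
#' polynomial (loess, direct fit), the standard pre-step before numerical
#' differentiation of noisy fluorescence traces.
#'
#' @param time,values uniform sampling grid (hours) and series.
#' @param window_h smoothing window (hours); converted to a loess span.
#' @return smoothed values on the same grid.
#' @export
smooth_series <- function(time, values, window_h = 2) {
  n <- length(values)
  dt <- stats::median(diff(time))
  k <- max(5, ceiling(window_h / dt) + 1)
  if (n < 2 * k) stop("series too short for the smoothing window")
  span <- min(1, k / n)
  # statistics not needed (fitted values only); loess warns with NaNs when
  # computing them on exactly noise-free series
  fit <- suppressWarnings(
    stats::loess(values ~ time, degree = 2, span = span,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  stats::fitted(fit)
}

# relative noise level: median relative residual of a first-pass fit
estimate_relative_noise <- function(time, values, window_h = 2) {
  sm <- smooth_series(time, values, window_h)
  scale <- pmax(abs(sm), stats::median(abs(sm)) + 1e-12)
  stats::median(abs(values - sm) / scale)
}

# noise-adaptive smoothing window, clamped to [1, 4] h; the scale factor
# maps the default 5% relative noise to the 2 h default window
adaptive_window <- function(time, values) {
  s <- tryCatch(estimate_relative_noise(time, values),
                error = function(e) 0.05)
  min(4, max(1, 40 * s))
}

#' Smooth both channels of a FUCCI trajectory
#'
#' @param traj data frame `time_h, cdt1, geminin` (one cell/track).
#' @param window_h smoothing window (hours); `NULL` picks it from the
#'   estimated noise level (window `8 * sigma_rel`, clamped to 1-4 h).
#' @return the trajectory with smoothed `cdt1`, `geminin`; the window used
#'   is attached as attribute `window_h`.
#' @export
smooth_trajectory <- function(traj, window_h = NULL) {
  stopifnot(all(c("time_h", "cdt1", "geminin") %in% names(traj)))
  if (is.null(window_h)) {
    window_h <- max(adaptive_window(traj$time_h, traj$cdt1),
                    adaptive_window(traj$time_h, traj$geminin))
  }
  out <- traj
  out$cdt1 <- smooth_series(traj$time_h, traj$cdt1, window_h)
  out$geminin <- smooth_series(traj$time_h, traj$geminin, window_h)
  attr(out, "window_h") <- window_h
  out
}

#' Numerical derivative on a uniform grid
#'
#' Central differences at interior points, one-sided differences at the
#' ends.
#'
#' @param values series on a uniform grid.
#' @param dt grid spacing (hours).
#' @return derivative series, same length.
#' @export
numerical_derivative <- function(values, dt) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 points")
  d <- numeric(n)
  d[1L] <- (values[2L] - values[1L]) / dt
  d[n] <- (values[n] - values[n - 1L]) / dt
  d[2:(n - 1L)] <- (values[3:n] - values[1:(n - 2L)]) / (2 * dt)
  d
}

#' Detect division times from the Geminin derivative
#'
#' Division causes an abrupt drop of the Geminin signal, i.e. a deep local
#' minimum of its derivative. Minima deeper than a prominence threshold
#' (`prominence_factor` times the MAD of the derivative, a spike-robust
#' scale) are kept; when two candidates fall within `min_separation_h` the
#' deeper one wins.
#'
#' @param deriv derivative of the smoothed Geminin series.
#' @param time sampling grid (hours).
#' @param prominence_factor threshold multiplier (default 6; division
#'   spikes are an order of magnitude deeper than smooth-variation and
#'   noise excursions of the derivative).
#' @param min_separation_h minimum spacing between divisions (default 5 h,
#'   well below any plausible cycle time).
#' @return division times (possibly empty).
#' @export
detect_divisions <- function(deriv, time, prominence_factor = 6,
                             min_separation_h = 5) {
  n <- length(deriv)
  if (n < 3L) return(numeric(0))
  thr <- -prominence_factor * stats::mad(deriv)
  i <- 2:(n - 1L)
  is_min <- deriv[i] < deriv[i - 1L] & deriv[i] <= deriv[i + 1L] &
    deriv[i] < thr
  cand <- i[is_min]
  if (length(cand) == 0L) return(numeric(0))
  cand <- cand[order(deriv[cand])]  # deepest first
  kept <- numeric(0)
  for (j in cand) {
    if (all(abs(time[j] - kept) >= min_separation_h)) {
      kept <- c(kept, time[j])
    }
  }
  sort(kept)
}

#' Detect the G1/S transition within one division interval
#'
#' The Cdt1 marker accumulates through G1 and drops sharply after the
#' G1/S transition; its maximum inside the division interval estimates the
#' transition time. The detection fails (quality flag) when the signal is
#' flat or the maximum sits on the interval boundary.
#'
#' @param cdt1 smoothed Cdt1 series.
#' @param time sampling grid (hours).
#' @param interval `c(from, to)` division times bounding one cycle.
#' @param flat_tol relative amplitude below which the signal counts as
#'   flat.
#' @param boundary_margin_h maxima closer than this to either division are
#'   failed as boundary peaks (default 1 h): a maximum hugging a division
#'   is a mistracked or noise-dominated cycle, since both phases last
#'   hours.
#' @return list with `time` (`NA` on failure) and `quality`
#'   (`"pass"`, `"no peak"`, `"peak at boundary"`).
#' @export
detect_g1s_transition <- function(cdt1, time, interval, flat_tol = 0.05,
                                  boundary_margin_h = 1) {
  sel <- which(time > interval[1L] & time < interval[2L])
  if (length(sel) == 0L) stop("empty division interval")
  seg <- cdt1[sel]
  rng <- max(seg) - min(seg)
  if (!is.finite(rng) || rng <= flat_tol * max(abs(seg), 1e-12)) {
    return(list(time = NA_real_, quality = "no peak"))
  }
  j <- sel[which.max(seg)]
  if (time[j] < interval[1L] + boundary_margin_h ||
      time[j] > interval[2L] - boundary_margin_h) {
    return(list(time = NA_real_, quality = "peak at boundary"))
  }
  list(time = time[j], quality = "pass")
}

#' Annotate a FUCCI trajectory with cycle endpoints
#'
#' The full endpoint-detection procedure for one tracked cell: (i) noise
#' estimation and locally quadratic smoothing, (ii) numerical
#' differentiation of the Geminin level, (iii) local-minimum detection on
#' the derivative to find division times, (iv) Cdt1-maximum detection
#' between consecutive divisions to find the G1/S transition of each
#' complete cycle.
#'
#' @param traj data frame `time_h, cdt1, geminin` for one cell/track.
#' @param window_h smoothing window; `NULL` for noise-adaptive.
#' @param cdt1_window_min_h lower bound on the Cdt1 smoothing window
#'   (default 2 h). The division spike in the Geminin derivative is a
#'   high-frequency feature and tolerates little smoothing, but the Cdt1
#'   maximum is broad and its argmax jitters under noise unless smoothed
#'   over at least a couple of hours.
#' @param high_noise_tol relative noise level above which the whole track
#'   is flagged `high-noise`.
#' @param ... passed to [detect_divisions()].
#' @return object of class `endpoint_annotation`: list with
#'   `division_times`, `cycles` (data frame `birth`, `division`, `g1s`,
#'   `quality`), `quality_flag` (`"pass"` or reason) and `window_h`.
#' @export
annotate_trajectory <- function(traj, window_h = NULL,
                                cdt1_window_min_h = 2,
                                high_noise_tol = 0.5, ...) {
  stopifnot(all(c("time_h", "cdt1", "geminin") %in% names(traj)))
  dt <- stats::median(diff(traj$time_h))
  noise <- tryCatch(
    max(estimate_relative_noise(traj$time_h, traj$cdt1),
        estimate_relative_noise(traj$time_h, traj$geminin)),
    error = function(e) Inf)
  if (!is.finite(noise) || noise > high_noise_tol) {
    return(structure(list(division_times = numeric(0),
                          cycles = NULL, quality_flag = "high-noise",
                          window_h = NA_real_),
                     class = "endpoint_annotation"))
  }
  amp_c <- max(traj$cdt1) - min(traj$cdt1)
  amp_g <- max(traj$geminin) - min(traj$geminin)
  if (amp_c <= 1e-9 && amp_g <= 1e-9) {
    return(structure(list(division_times = numeric(0),
                          cycles = NULL, quality_flag = "flat-signal",
                          window_h = NA_real_),
                     class = "endpoint_annotation"))
  }
  sm <- smooth_trajectory(traj, window_h)
  cdt1_sm <- smooth_series(traj$time_h, traj$cdt1,
                           max(attr(sm, "window_h"), cdt1_window_min_h))
  dg <- numerical_derivative(sm$geminin, dt)
  divs <- detect_divisions(dg, sm$time_h, ...)
  cycles <- NULL
  if (length(divs) >= 2L) {
    cycles <- do.call(rbind, lapply(seq_len(length(divs) - 1L), function(j) {
      g1s <- detect_g1s_transition(cdt1_sm, sm$time_h,
                                   c(divs[j], divs[j + 1L]))
      data.frame(birth = divs[j], division = divs[j + 1L],
                 g1s = g1s$time, quality = g1s$quality,
                 stringsAsFactors = FALSE)
    }))
  }
  flag <- if (length(divs) < 2L) "missing-division" else "pass"
  structure(list(division_times = divs, cycles = cycles,
                 quality_flag = flag,
                 window_h = attr(sm, "window_h")),
            class = "endpoint_annotation")
}

#' @export
print.endpoint_annotation <- function(x, ...) {
  cat(sprintf("endpoint_annotation: %d division(s), flag '%s'\n",
              length(x$division_times), x$quality_flag))
  if (!is.null(x$cycles)) print(x$cycles)
  invisible(x)
}

#' Extract per-cycle phase durations from an annotation
#'
#' Only complete cycles (both birth and division detected, G1/S transition
#' passing quality) yield durations: `t_g1 = g1s - birth`,
#' `t_sg2m = division - g1s`.
#'
#' @param annotation [annotate_trajectory()] result.
#' @return data frame `birth, t_g1, t_sg2m, t_cycle` (0 rows when no
#'   complete cycle passed); excluded cycles are reported in attribute
#'   `n_excluded`.
#' @export
extract_phase_durations <- function(annotation) {
  stopifnot(inherits(annotation, "endpoint_annotation"))
  cyc <- annotation$cycles
  if (is.null(cyc) || nrow(cyc) == 0L) {
    out <- data.frame(birth = numeric(0), t_g1 = numeric(0),
                      t_sg2m = numeric(0), t_cycle = numeric(0))
    attr(out, "n_excluded") <- if (is.null(cyc)) 0L else nrow(cyc)
    return(out)
  }
  ok <- cyc$quality == "pass" & !is.na(cyc$g1s)
  out <- data.frame(birth = cyc$birth[ok],
                    t_g1 = cyc$g1s[ok] - cyc$birth[ok],
                    t_sg2m = cyc$division[ok] - cyc$g1s[ok])
  out$t_cycle <- out$t_g1 + out$t_sg2m
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Parent-progeny duration pairs along tracked lineages
#'
#' Consecutive complete cycles of one tracked position are parent and
#' progeny; pairing their durations yields the parent-progeny sample used
#' for inheritance estimation from trajectory data alone.
#'
#' @param durations `durations` table from [process_trajectories()].
#' @param field `"t_g1"`, `"t_sg2m"` or `"t_cycle"`.
#' @return two-column matrix (parent value, progeny value).
#' @export
consecutive_cycle_pairs <- function(durations, field = "t_g1") {
  stopifnot(field %in% names(durations))
  out <- NULL
  for (id in unique(durations$cell_id)) {
    dd <- durations[durations$cell_id == id, , drop = FALSE]
    dd <- dd[order(dd$birth), , drop = FALSE]
    # consecutive means adjacent cycles sharing a division boundary
    if (nrow(dd) >= 2L) {
      adj <- which(abs(dd$birth[-1L] -
                         (dd$birth + dd$t_cycle)[-nrow(dd)]) < 0.6)
      if (length(adj) > 0L) {
        out <- rbind(out, cbind(dd[[field]][adj], dd[[field]][adj + 1L]))
      }
    }
  }
  if (is.null(out)) {
    out <- matrix(numeric(0), ncol = 2L)
  }
  colnames(out) <- c("value_a", "value_b")
  out
}

#' Process a table of trajectories into endpoint annotations
#'
#' Applies [annotate_trajectory()] to every `cell_id` of a long trajectory
#' table and collects events and phase durations.
#'
#' @param traj_table data frame `cell_id,time_h,cdt1,geminin`.
#' @param ... passed to [annotate_trajectory()].
#' @return list with `events` (data frame
#'   `cell_id,event_type,time_h,quality`) and `durations` (data frame
#'   `cell_id,birth,t_g1,t_sg2m,t_cycle`).
#' @export
process_trajectories <- function(traj_table, ...) {
  ids <- unique(traj_table$cell_id)
  events <- list(); durs <- list()
  for (id in ids) {
    tr <- traj_table[traj_table$cell_id == id, , drop = FALSE]
    ann <- annotate_trajectory(tr, ...)
    ev <- data.frame(cell_id = character(0), event_type = character(0),
                     time_h = numeric(0), quality = character(0))
    if (length(ann$division_times) > 0L) {
      ev <- rbind(ev, data.frame(cell_id = id, event_type = "division",
                                 time_h = ann$division_times,
                                 quality = ann$quality_flag))
    }
    if (!is.null(ann$cycles)) {
      ev <- rbind(ev, data.frame(cell_id = id, event_type = "g1s",
                                 time_h = ann$cycles$g1s,
                                 quality = ann$cycles$quality))
    }
    events[[id]] <- ev
    d <- extract_phase_durations(ann)
    if (nrow(d) > 0L) durs[[id]] <- cbind(cell_id = id, d)
  }
  list(events = do.call(rbind, c(events, make.row.names = FALSE)),
       durations = if (length(durs) > 0L) {
         do.call(rbind, c(durs, make.row.names = FALSE))
       } else {
         data.frame(cell_id = character(0), birth = numeric(0),
                    t_g1 = numeric(0), t_sg2m = numeric(0),
                    t_cycle = numeric(0))
       })
}
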