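# Delimited-text readers/writers, table validation, config files and run
# manifests.

PEDIGREE_COLUMNS <- c("cell_id", "parent_id", "birth_time", "t_g1",
                      "t_sg2m", "c0", "g0", "c_end", "g_end")
TRAJECTORY_COLUMNS <- c("cell_id", "time_h", "cdt1", "geminin")

#' Read a pedigree table
#'
#' Comma-delimited text with header
#' `cell_id,parent_id,birth_time,t_g1,t_sg2m,c0,g0,c_end,g_end`
#' (protein columns optional); empty `parent_id` marks founder cells,
#' times in hours.
#'
#' @param path file path.
#' @return [as_pedigree()] object.
#' @examples
#' ped <- read_pedigree_table(
#'   system.file("extdata", "synthetic_pedigree.csv", package = "ccdrift"))
#' extract_pairs(ped, "sibling", "t_g1")[1:3, ]
#' @export
read_pedigree_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character",
                                       parent_id = "character"))
  as_pedigree(df)
}

#' Write a pedigree table
#'
#' @param ped [as_pedigree()] object.
#' @param path file path.
#' @export
write_pedigree_table <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  cols <- intersect(c(PEDIGREE_COLUMNS, "p_c", "p_g"), names(ped))
  out <- as.data.frame(ped)[, cols]
  out$parent_id[is.na(out$parent_id)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trajectory table
#'
#' Comma-delimited text `cell_id,time_h,cdt1,geminin`, one row per frame.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_trajectory_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(cell_id = "character"))
}

#' Write a trajectory table
#' @param traj data frame with `cell_id,time_h,cdt1,geminin`.
#' @param path file path.
#' @export
write_trajectory_table <- function(traj, path) {
  stopifnot(all(TRAJECTORY_COLUMNS %in% names(traj)))
  utils::write.csv(traj[, TRAJECTORY_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a census series as a wide table
#' @param census `census_series`.
#' @param path file path.
#' @export
write_census_table <- function(census, path) {
  utils::write.csv(census_table(census), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Validate a delimited table against a schema
#'
#' Checks structural requirements and lists violations with row numbers.
#' Pedigree schema: required columns, positive durations, parent links
#' forming an acyclic binary tree. Trajectory schema: required columns,
#' per-cell strictly increasing time grid, non-negative intensities.
#'
#' @param path file path.
#' @param schema `"pedigree"` or `"trajectory"`.
#' @return object of class `validation_report`: list with `ok` (logical)
#'   and `violations` (data frame `row`, `message`; `row` is `NA` for
#'   file-level problems).
#' @export
validate_tables <- function(path, schema = c("pedigree", "trajectory")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  v <- data.frame(row = integer(0), message = character(0))
  add <- function(row, msg) {
    v <<- rbind(v, data.frame(row = row, message = msg))
  }
  need <- if (schema == "pedigree") {
    c("cell_id", "parent_id", "birth_time", "t_g1", "t_sg2m")
  } else TRAJECTORY_COLUMNS
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    add(NA_integer_, paste("missing columns:", paste(miss, collapse = ", ")))
    return(structure(list(ok = FALSE, violations = v),
                     class = "validation_report"))
  }
  if (schema == "pedigree") {
    bad <- which(df$t_g1 <= 0 | df$t_sg2m <= 0)
    for (r in bad) add(r, "non-positive phase duration")
    dup <- which(duplicated(df$cell_id))
    for (r in dup) add(r, "duplicate cell id")
    if (nrow(v) == 0L) {
      ok <- tryCatch({as_pedigree(df); TRUE},
                     error = function(e) {
                       add(NA_integer_, conditionMessage(e))
                       FALSE
                     })
    }
  } else {
    neg <- which(df$cdt1 < 0 | df$geminin < 0)
    for (r in neg) add(r, "negative intensity")
    for (id in unique(df$cell_id)) {
      rows <- which(df$cell_id == id)
      tt <- df$time_h[rows]
      bad <- which(diff(tt) <= 0)
      if (length(bad) > 0L) {
        add(rows[bad[1L] + 1L], "non-monotone time grid")
      }
    }
  }
  structure(list(ok = nrow(v) == 0L, violations = v),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("validation: pass\n")
  } else {
    cat("validation: FAIL,", nrow(x$violations), "violation(s)\n")
    print(x$violations)
  }
  invisible(x)
}

# -- configuration files ---------------------------------------------------

#' Write a simulation configuration as YAML
#'
#' @param config [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lst <- list(
    model_variant = config$model_variant,
    n_ancestors = config$n_ancestors,
    t_end = config$t_end,
    population_cap = config$population_cap,
    track_proteins = config$track_proteins,
    synchronized = config$synchronized,
    phases = list(g1 = if (!is.null(config$g1)) unclass(config$g1),
                  sg2m = if (!is.null(config$sg2m)) unclass(config$sg2m)),
    cycle = list(mean_cc = config$cycle$mean_cc, cv_cc = config$cycle$cv_cc),
    kinetics = unclass(config$kinetics),
    regression = unclass(config$regression),
    division = list(cv = config$division$cv))
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path file path written by [write_sim_config()] (or hand-edited
#'   with the same structure).
#' @return [sim_config()].
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  as_bar <- function(x) {
    if (is.null(x)) return(NULL)
    bar_params(x$m, x$theta, x$mu, x$sigma2, x$rho)
  }
  sim_config(
    g1 = as_bar(lst$phases$g1),
    sg2m = as_bar(lst$phases$sg2m),
    kinetics = do.call(fucci_kinetics, lst$kinetics),
    regression = do.call(production_regression, lst$regression),
    division = division_law(lst$division$cv),
    cycle = lognormal_cycle_params(lst$cycle$mean_cc, lst$cycle$cv_cc),
    n_ancestors = lst$n_ancestors, t_end = lst$t_end,
    population_cap = lst$population_cap,
    model_variant = lst$model_variant,
    track_proteins = lst$track_proteins,
    synchronized = isTRUE(lst$synchronized))
}

#' Write a run manifest
#'
#' Records command, configuration hash, seed, package version, paths and
#' wall time for a reproducible run.
#'
#' @param path output JSON path.
#' @param command command or function name.
#' @param seed integer seed used.
#' @param inputs,outputs named character vectors of paths.
#' @param config_hash hash string of the configuration (any stable digest).
#' @param wall_time_s elapsed seconds.
#' @return invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, command, seed = NA_integer_,
                               inputs = character(0),
                               outputs = character(0),
                               config_hash = NA_character_,
                               wall_time_s = NA_real_) {
  man <- list(command = command, seed = seed,
              config_hash = config_hash,
              package_version = as.character(utils::packageVersion("ccdrift")),
              r_version = R.version.string,
              inputs = as.list(inputs), outputs = as.list(outputs),
              wall_time_s = wall_time_s,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(man)
}
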