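# Pedigree containers and family-relation extraction.

#' Construct a cell pedigree
#'
#' A pedigree is a data frame of cells observed (or simulated) across a
#' binary lineage tree. Each row is one cell with its parentage, birth time
#' and per-phase residence times; founder cells ("roots") have no parent and
#' act as ancestors of their whole lineage. Division is always binary: a cell
#' has either 0 or 2 progeny.
#'
#' @param cells data frame with at least columns `cell_id`, `parent_id`
#'   (`NA` or `""` for roots), `birth_time` (hours), `t_g1`, `t_sg2m`
#'   (hours, both > 0). Optional protein columns `c0`, `g0`, `c_end`,
#'   `g_end`, `p_c`, `p_g` are kept if present.
#' @return An object of class `pedigree`: the input data frame augmented
#'   with `t_cycle = t_g1 + t_sg2m`, `division_time = birth_time + t_cycle`
#'   and `ancestor_id` (the root id of each cell's lineage).
#' @details Validation enforces: unique ids, existing parents, acyclicity,
#'   0-or-2 progeny per parent, and birth times of progeny equal to the
#'   parent's division time (within `1e-6` h).
#' @export
as_pedigree <- function(cells) {
  stopifnot(is.data.frame(cells))
  need <- c("cell_id", "parent_id", "birth_time", "t_g1", "t_sg2m")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0L) {
    stop("pedigree table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(cells) == 0L) stop("empty pedigree")
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  cells$cell_id <- as.character(cells$cell_id)
  cells$parent_id <- as.character(cells$parent_id)
  cells$parent_id[!is.na(cells$parent_id) & cells$parent_id == ""] <- NA_character_
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell ids")
  if (any(cells$t_g1 <= 0) || any(cells$t_sg2m <= 0)) {
    stop("phase durations must be positive")
  }
  idx <- match(cells$parent_id, cells$cell_id)
  if (any(is.na(idx) & !is.na(cells$parent_id))) stop("unknown parent id")
  n_prog <- table(cells$parent_id[!is.na(cells$parent_id)])
  if (any(!n_prog %in% c(2L))) {
    stop("each dividing cell must have exactly 2 progeny")
  }

  cells$t_cycle <- cells$t_g1 + cells$t_sg2m
  cells$division_time <- cells$birth_time + cells$t_cycle

  # ancestor ids by pointer doubling up the parent links (also detects cycles)
  anc <- ifelse(is.na(idx), seq_len(nrow(cells)), idx)
  for (i in seq_len(ceiling(log2(nrow(cells) + 1)) + 2L)) {
    up <- anc[anc]
    if (identical(up, anc)) break
    anc <- up
  }
  if (!all(is.na(cells$parent_id[anc]))) stop("pedigree cycle detected")
  cells$ancestor_id <- cells$cell_id[anc]

  bt_err <- abs(cells$birth_time - cells$division_time[idx])
  if (any(bt_err[!is.na(idx)] > 1e-6)) {
    stop("progeny birth time must equal parent division time")
  }
  class(cells) <- c("pedigree", "data.frame")
  cells
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d cells, %d lineages, %d divisions\n",
              nrow(x), length(unique(x$ancestor_id)),
              sum(x$cell_id %in% x$parent_id)))
  NextMethod()
}

pedigree_children <- function(ped) {
  split(seq_len(nrow(ped))[!is.na(ped$parent_id)],
        ped$parent_id[!is.na(ped$parent_id)])
}

#' Extract related-cell value pairs from a pedigree
#'
#' Collects, for a chosen per-cell field, all pairs of values for cells in a
#' given family relation. These pairs are the raw material of the family
#' correlation estimates.
#'
#' @param ped a [as_pedigree()] object.
#' @param relation one of `"parent_progeny"`, `"sibling"`, `"cousin"`,
#'   `"grandparent"`.
#' @param field per-cell column to pair, e.g. `"t_g1"`, `"t_sg2m"`,
#'   `"t_cycle"`.
#' @param symmetrize logical; if `TRUE` (used by the correlation
#'   estimators), every pair of exchangeable relatives (sibling, cousin)
#'   contributes both orderings `(a,b)` and `(b,a)`. Directed relations
#'   (parent/progeny, grandparent/grand-progeny) are never symmetrized:
#'   the first column is always the elder cell.
#' @return two-column matrix of paired values (0 rows when no such pair
#'   exists).
#' @details Sibling pairs are the two progeny of one parent. Cousin pairs
#'   are all four cross pairs between the progeny sets of two sibling
#'   parents; the classical naming convention singles out two representative
#'   pairs, but all four cross pairs are valid exchangeable pairs and all are
#'   returned so correlation estimates use the full information.
#' @export
extract_pairs <- function(ped, relation = c("parent_progeny", "sibling",
                                            "cousin", "grandparent"),
                          field = "t_cycle", symmetrize = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  relation <- match.arg(relation)
  if (!field %in% names(ped)) stop("unknown field: ", field)
  v <- ped[[field]]
  idx_parent <- match(ped$parent_id, ped$cell_id)
  kids <- pedigree_children(ped)

  pairs <- switch(relation,
    parent_progeny = {
      i <- which(!is.na(idx_parent))
      cbind(idx_parent[i], i)
    },
    sibling = {
      do.call(rbind, lapply(kids, function(k) cbind(k[1L], k[2L])))
    },
    grandparent = {
      gp <- idx_parent[idx_parent]
      i <- which(!is.na(gp))
      cbind(gp[i], i)
    },
    cousin = {
      out <- lapply(kids, function(k) {
        a <- kids[[ped$cell_id[k[1L]]]]
        b <- kids[[ped$cell_id[k[2L]]]]
        if (is.null(a) || is.null(b)) return(NULL)
        as.matrix(expand.grid(a, b))
      })
      do.call(rbind, out)
    })
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("value_a", "value_b"))))
  }
  m <- cbind(value_a = v[pairs[, 1L]], value_b = v[pairs[, 2L]])
  if (symmetrize && relation %in% c("sibling", "cousin")) {
    m <- rbind(m, m[, 2:1, drop = FALSE])
    colnames(m) <- c("value_a", "value_b")
  }
  rownames(m) <- NULL
  m
}

#' Census time series of a pedigree
#'
#' Counts cells alive at each grid time, in total and per ancestor. A cell
#' is counted on the half-open interval `[birth_time, division_time)`, so
#' population totals are unambiguous at division instants; cells that never
#' divided within the observation horizon count from birth onwards.
#'
#' @param ped a [as_pedigree()] object.
#' @param times increasing numeric grid (hours).
#' @return Object of class `census_series`: list with `times`, `total`
#'   (integer vector) and `by_ancestor` (matrix, one column per ancestor).
#' @export
census_from_pedigree <- function(ped, times) {
  stopifnot(inherits(ped, "pedigree"))
  if (nrow(ped) == 0L) stop("empty pedigree")
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE)) {
    stop("time grid must be strictly increasing")
  }
  divided <- ped$cell_id %in% ped$parent_id
  end <- ifelse(divided, ped$division_time, Inf)
  anc <- unique(ped$ancestor_id)
  by_anc <- vapply(anc, function(a) {
    sel <- ped$ancestor_id == a
    vapply(times, function(t) {
      sum(ped$birth_time[sel] <= t & t < end[sel])
    }, integer(1L))
  }, integer(length(times)))
  by_anc <- matrix(by_anc, nrow = length(times),
                   dimnames = list(NULL, anc))
  new_census(times, as.integer(rowSums(by_anc)), by_anc)
}

new_census <- function(times, total, by_ancestor) {
  structure(list(times = times, total = total, by_ancestor = by_ancestor),
            class = "census_series")
}

#' @export
print.census_series <- function(x, ...) {
  cat(sprintf("census_series: %d time points over [%g, %g] h, %d -> %d cells, %d ancestors\n",
              length(x$times), min(x$times), max(x$times),
              x$total[1L], x$total[length(x$total)], ncol(x$by_ancestor)))
  invisible(x)
}

#' Per-ancestor progeny fractions at a census time
#'
#' @param census a [census_from_pedigree()] or simulator census.
#' @param t query time (hours); counts are taken at the latest census point
#'   `<= t`.
#' @return named numeric vector of fractions summing to 1.
#' @export
progeny_fractions <- function(census, t) {
  stopifnot(inherits(census, "census_series"))
  i <- findInterval(t, census$times)
  if (i < 1L) stop("query time precedes the census range")
  z <- census$by_ancestor[i, ]
  tot <- sum(z)
  if (tot <= 0) stop("no cells alive at query time")
  z / tot
}

#' Census as a wide data frame
#'
#' @param census a `census_series`.
#' @return data frame `time, total, <ancestor...>`.
#' @export
census_table <- function(census) {
  stopifnot(inherits(census, "census_series"))
  data.frame(time = census$times, total = census$total,
             census$by_ancestor, check.names = FALSE)
}
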