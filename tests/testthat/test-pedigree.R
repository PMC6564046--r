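test_that("family relations are extracted exactly once per qualifying pair", {
  ped <- seven_cell_pedigree()

  pp <- extract_pairs(ped, "parent_progeny", "t_g1")
  expect_equal(nrow(pp), 6L)  # 2 per divided cell, 3 divided cells

  sib <- extract_pairs(ped, "sibling", "t_g1")
  expect_equal(nrow(sib), 3L)  # one per divided cell
  # generation split: (X,Y) in generation 1, (L,M) and (N,P) in generation 2
  expect_setequal(round(sib[, 1] + sib[, 2], 3), c(20.5, 17.5, 18))

  # all four cross pairs between the two sibling progeny sets
  cz <- extract_pairs(ped, "cousin", "t_g1")
  expect_equal(nrow(cz), 4L)
  expect_setequal(round(cz[, 1] + cz[, 2], 3),
                  c(8 + 11, 8 + 7, 9.5 + 11, 9.5 + 7))

  gp <- extract_pairs(ped, "grandparent", "t_g1")
  expect_equal(nrow(gp), 4L)
  expect_true(all(gp[, 1] == 9))  # grandparent is always A

  # symmetrization doubles exchangeable relations only
  expect_equal(nrow(extract_pairs(ped, "sibling", "t_g1",
                                  symmetrize = TRUE)), 6L)
  expect_equal(nrow(extract_pairs(ped, "parent_progeny", "t_g1",
                                  symmetrize = TRUE)), 6L)
})

test_that("a pedigree with no divisions yields no pairs for any relation", {
  ped <- as_pedigree(data.frame(cell_id = "solo", parent_id = NA,
                                birth_time = 0, t_g1 = 5, t_sg2m = 6))
  for (rel in c("parent_progeny", "sibling", "cousin", "grandparent")) {
    expect_equal(nrow(extract_pairs(ped, rel, "t_g1")), 0L)
  }
})

test_that("pair counts follow the structural identities on random pedigrees", {
  set.seed(101)
  for (r in 1:3) {
    ped <- random_pedigree(n_roots = 2L, depth = 3L)
    n_divided <- sum(ped$cell_id %in% ped$parent_id)
    expect_equal(nrow(extract_pairs(ped, "parent_progeny")), 2L * n_divided)
    expect_equal(nrow(extract_pairs(ped, "sibling")), n_divided)
    # brute-force oracle: enumerate all ordered cell pairs and classify
    idx <- match(ped$parent_id, ped$cell_id)
    gp_of <- function(i) idx[idx[i]]
    n_gp <- sum(!is.na(gp_of(seq_len(nrow(ped)))))
    expect_equal(nrow(extract_pairs(ped, "grandparent")), n_gp)
    n_cousin <- 0L
    for (i in seq_len(nrow(ped))) for (j in seq_len(nrow(ped))) {
      if (i < j && !is.na(idx[i]) && !is.na(idx[j]) &&
          idx[i] != idx[j] && !is.na(idx[idx[i]]) &&
          !is.na(idx[idx[j]]) && idx[idx[i]] == idx[idx[j]]) {
        n_cousin <- n_cousin + 1L
      }
    }
    expect_equal(nrow(extract_pairs(ped, "cousin")), n_cousin)
  }
})

test_that("pedigree validation rejects malformed tables", {
  base <- data.frame(cell_id = c("a", "b", "c"),
                     parent_id = c(NA, "a", "a"),
                     birth_time = c(0, 10, 10),
                     t_g1 = c(4, 5, 5), t_sg2m = c(6, 6, 7))
  expect_s3_class(as_pedigree(base), "pedigree")
  bad <- base; bad$parent_id[2] <- "zzz"
  expect_error(as_pedigree(bad), "unknown parent")
  bad <- base[-3, ]  # one progeny only
  expect_error(as_pedigree(bad), "exactly 2 progeny")
  bad <- base; bad$t_g1[1] <- -1
  expect_error(as_pedigree(bad), "positive")
  bad <- base; bad$birth_time[2] <- 3
  expect_error(as_pedigree(bad), "division time")
  expect_error(extract_pairs(as_pedigree(base), "sibling", "nope"),
               "unknown field")
})

test_that("census counts use the half-open [birth, division) convention", {
  ped <- as_pedigree(data.frame(cell_id = "c1", parent_id = NA,
                                birth_time = 0, t_g1 = 8, t_sg2m = 12))
  cs <- census_from_pedigree(ped, c(0, 10, 50))
  expect_equal(cs$total, c(1L, 1L, 1L))  # undivided leaf counts forever

  ped2 <- as_pedigree(data.frame(
    cell_id = c("p", "d1", "d2"), parent_id = c(NA, "p", "p"),
    birth_time = c(0, 20, 20), t_g1 = c(8, 9, 7), t_sg2m = c(12, 12, 12)))
  cs2 <- census_from_pedigree(ped2, c(19.99, 20, 25))
  expect_equal(cs2$total, c(1L, 2L, 2L))  # exactly 2 at the division instant
})

test_that("census matches the brute-force interval-membership oracle", {
  set.seed(102)
  ped <- random_pedigree(n_roots = 3L, depth = 4L)
  grid <- seq(0, max(ped$division_time) + 5, length.out = 37)
  cs <- census_from_pedigree(ped, grid)
  divided <- ped$cell_id %in% ped$parent_id
  oracle <- vapply(grid, function(t) {
    sum(ped$birth_time <= t &
          (!divided | t < ped$division_time))
  }, numeric(1))
  expect_equal(as.numeric(cs$total), oracle)
  expect_equal(as.integer(rowSums(cs$by_ancestor)), cs$total)
})

test_that("progeny fractions are a probability vector at every census time", {
  ped <- as_pedigree(data.frame(cell_id = "c1", parent_id = NA,
                                birth_time = 0, t_g1 = 8, t_sg2m = 12))
  cs <- census_from_pedigree(ped, c(0, 10))
  expect_equal(unname(progeny_fractions(cs, 5)), 1.0)

  fake <- ccdrift:::new_census(c(0, 10), c(40L, 40L),
                               matrix(c(30L, 30L, 10L, 10L), 2,
                                      dimnames = list(NULL, c("a", "b"))))
  expect_equal(unname(progeny_fractions(fake, 10)), c(0.75, 0.25))
  expect_error(progeny_fractions(fake, -1), "precedes")

  set.seed(103)
  ped3 <- random_pedigree(n_roots = 3L, depth = 4L)
  grid <- seq(0, max(ped3$division_time), length.out = 11)
  cs3 <- census_from_pedigree(ped3, grid)
  for (t in grid[-1]) {
    expect_equal(sum(progeny_fractions(cs3, t)), 1, tolerance = 1e-12)
  }
  # fractions agree with a brute-force leaf count at the horizon
  t_star <- max(grid)
  divided <- ped3$cell_id %in% ped3$parent_id
  alive <- ped3$birth_time <= t_star & (!divided | ped3$division_time > t_star)
  byhand <- table(ped3$ancestor_id[alive])
  fr <- progeny_fractions(cs3, t_star)
  expect_equal(unname(fr[names(byhand)]),
               unname(as.numeric(byhand) / sum(byhand)))
})
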