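# Shared fixtures: hand-built pedigrees and small configurations.

# the classic three-generation family: A -> (X, Y), X -> (L, M), Y -> (N, P)
seven_cell_pedigree <- function() {
  as_pedigree(data.frame(
    cell_id = c("A", "X", "Y", "L", "M", "N", "P"),
    parent_id = c(NA, "A", "A", "X", "X", "Y", "Y"),
    birth_time = c(0, 20, 20, 41, 41, 42, 42),
    t_g1 = c(9, 10, 10.5, 8, 9.5, 11, 7),
    t_sg2m = c(11, 11, 11.5, 12, 10, 9, 13),
    stringsAsFactors = FALSE))
}

# random pedigree grown generation-wise, durations drawn freely (no AR),
# for structural oracles
random_pedigree <- function(n_roots = 2L, depth = 3L) {
  cfg <- sim_config(track_proteins = FALSE)
  simulate_pedigree_generations(cfg, depth, n_ancestors = n_roots)
}

test_phase_params <- function() {
  bar_params_from_targets(mean = 9.2, sd = 0.52 * 9.2, theta = 0.25,
                          rho_sib = 0.50, rho = 0.55)
}

uncorrelated_config <- function(n_ancestors, t_end = 300) {
  sim_config(model_variant = "uncorrelated", n_ancestors = n_ancestors,
             t_end = t_end, track_proteins = FALSE,
             cycle = lognormal_cycle_params(20.4, 0.30))
}
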