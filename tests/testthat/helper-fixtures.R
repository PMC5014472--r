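# Shared builders for small test objects. Everything is generated in code;
# no fixture files.

quartet_tree <- function() {
  parse_tree(text = "((a1:0.1,a2:0.2):0.15,(b1:0.12,b2:0.3):0.08);")
}

quartet_scheme <- function(tree = quartet_tree()) {
  assign_partitions(tree, c("a1", "a2"), c("b1", "b2"))
}

test_pos_freqs <- function() {
  positional_frequencies(rbind(c(0.30, 0.20, 0.25, 0.25),
                               c(0.30, 0.20, 0.20, 0.30),
                               c(0.25, 0.20, 0.20, 0.35)))
}

test_exch <- function() c(AC = 1, AG = 4, AT = 1, CG = 1, CT = 4)

quartet_params <- function() {
  model_parameters(
    exch = test_exch(), pos_freqs = test_pos_freqs(),
    groups = list(
      EGV1 = list(classes = c("w1", "w2"), omega1 = 0.3, p1 = 0.6),
      EGV2 = list(classes = c("w1", "w2", "w3"), omega1 = 0.2, p1 = 0.5,
                  omega3 = 2, p2 = 0.3),
      CONNECTING = list(classes = "w2")))
}

# Small two-clade simulation; neutral_fg gives a pure-neutral foreground
# (the null of the purifying test).
small_sim_config <- function(seed, n_a = 4, n_b = 4, n_sites = 150,
                             fg = omega_distribution(0.2, 1, p1 = 0.8, p2 = 0.2)) {
  tree <- simulate_two_clade_tree(n_a, n_b, mean_length = 0.05,
                                  connecting_length = 0.8, seed = seed)
  scheme <- assign_partitions(tree, paste0("a", seq_len(n_a)),
                              paste0("b", seq_len(n_b)))
  simulation_config(
    tree, scheme,
    partition_omegas = list(
      EGV1 = fg,
      EGV2 = omega_distribution(0.3, 1, p1 = 0.6, p2 = 0.4),
      CONNECTING = omega_distribution(0.05, 1, p1 = 0.75, p2 = 0.25)),
    exch = test_exch(), pos_freqs = test_pos_freqs(),
    n_sites = n_sites, seed = seed)
}

neutral_mix <- function() omega_distribution(0.5, 1, p1 = 0, p2 = 1)

fast_fit_control <- function(...) {
  utils::modifyList(list(restarts = 0, optimize_branch_lengths = FALSE,
                         maxit = 100), list(...))
}
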