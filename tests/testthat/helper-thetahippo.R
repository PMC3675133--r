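# Small fixtures shared across test files. Everything is generated in code,
# under fixed seeds, at sizes that keep a single theta cycle in the
# low-millisecond range.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_slots = 2, slot_size = 12, n_active = 4, vocab_n = 12,
         min_hamming = 4, units_per_ca1_slot = 24, n_ca3 = 20,
         corrupt_fraction = 0.5),
    list(...))
  do.call(hippo_config, args)
}

tiny_vocab <- function(seed = 101, n = 12) {
  withr::with_seed(seed, generate_vocabulary(n, 12, 4, 4))
}

tiny_training_set <- function(vocab = tiny_vocab(), n_patterns = 6,
                              n_slots = 2, seed = 202) {
  withr::with_seed(seed, make_training_set(vocab, n_patterns, n_slots))
}

# Mean Name Error of a network on given cues (or the training patterns).
score_net <- function(net, training_set, vocab, cues = NULL) {
  pats <- do.call(rbind, training_set$ec_vector)
  if (is.null(cues)) cues <- pats
  out <- t(apply(cues, 1, function(cue) recall(net, cue)))
  mean(vapply(seq_len(nrow(pats)), function(i) {
    name_error(out[i, ], training_set$slot_indices[[i]], vocab)
  }, integer(1)))
}

# Brute-force oracle: number of units above threshold at membrane
# equilibrium for a given uniform inhibitory conductance.
equilibrium_active_count <- function(ge, gi, params = dynamics_params()) {
  vm_eq <- (ge * params$e_rev_exc + gi * params$e_rev_inh +
              params$g_l * params$e_rev_leak) / (ge + gi + params$g_l)
  sum(vm_eq > params$threshold)
}

expect_phase_equal <- function(a, b, tol = 1e-10) {
  for (ph in names(a$phases)) {
    for (l in names(a$phases[[ph]])) {
      expect_lt(max(abs(a$phases[[ph]][[l]] - b$phases[[ph]][[l]])), tol)
    }
  }
}
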