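phase_clamps <- function(network, input, phase, msp_only = FALSE) {
  clamp <- list(ec_in = as.numeric(input))
  if (msp_only) {
    clamp$dg <- rep(0, network$layers$dg$n)
    clamp$ca3 <- rep(0, network$layers$ca3$n)
  }
  clamp
}

#' Run one theta cycle
#'
#' Presents one input pattern for a full theta cycle. Activations are reset
#' to zero at trough onset and carried over between phases. The trough (TT)
#' settles with the entorhinal drive on CA1 open and the Schaffer input
#' closed; the peak (TP) settles with the Schaffer input open and the direct
#' entorhinal drive on CA1 closed; in train mode a final plus phase opens
#' the fixed one-to-one EC_in to EC_out identity projection (the
#' superficial-to-deep entorhinal mapping), which imposes the target on
#' EC_out, and settles once more, for 90 settling steps in total. Test mode
#' stops after the peak (no plus snapshot, no weight change).
#'
#' @param network A [build_hippocampus()] network.
#' @param input Binary input vector of EC_in dimensionality (a composite
#'   pattern or a partial cue).
#' @param mode `"train"` or `"test"`.
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation; identical dynamics, used for validation).
#' @param msp_only If `TRUE`, DG and CA3 are silenced (clamped to zero), as
#'   during monosynaptic-pathway pretraining.
#' @return An object of class `theta_trace`: per-phase activation snapshots
#'   of every layer, plus the input and mode.
#' @export
run_theta_cycle <- function(network, input, mode = c("train", "test"),
                            engine = c("cpp", "R"), msp_only = FALSE) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  stopifnot(length(input) == network$layers$ec_in$n)
  phases <- if (mode == "train") c("TT", "TP", "PLUS") else c("TT", "TP")
  if (engine == "cpp") {
    snaps <- cpp_run_cycle(net_to_cpp(network), as.numeric(input),
                           mode == "train", msp_only)
    names(snaps) <- phases
    snaps <- lapply(snaps, function(s) {
      stats::setNames(s, names(network$layers))
    })
  } else {
    params <- network$config$dynamics
    state <- init_state(network$layers, params)
    snaps <- list()
    for (ph in phases) {
      state <- settle(network$layers, network$projections, state,
                      open = open_projections(network, ph),
                      clamp = phase_clamps(network, input, ph, msp_only),
                      params = params)
      snaps[[ph]] <- state$y
    }
  }
  structure(list(phases = snaps, input = as.numeric(input), mode = mode),
            class = "theta_trace")
}

#' Apply the phase-contrast learning rules to one trace
#'
#' Monosynaptic-pathway projections (EC_in to CA1, CA1 to EC_out, EC_out to
#' CA1) are updated with the contrastive rule on (plus, trough) snapshot
#' pairs; the Schaffer collaterals with the contrastive rule on (plus, peak)
#' pairs; both blended with the conditional-PCA Hebbian delta in proportion
#' to the projection's `lmix`. All remaining plastic projections carry no
#' error-driven component and use the pure Hebbian delta on plus-phase
#' activations only. The fixed EC_in to EC_out mapping never changes.
#'
#' @param network A `hippo_network`.
#' @param trace A train-mode [run_theta_cycle()] trace.
#' @param msp_only If `TRUE`, only monosynaptic-pathway projections are
#'   updated (pretraining).
#' @return The network with updated weights.
#' @export
learn_from_trace <- function(network, trace, msp_only = FALSE) {
  stopifnot(inherits(trace, "theta_trace"))
  if (is.null(trace$phases$PLUS)) {
    stop("trace has no plus-phase snapshot: learning needs a train-mode trace")
  }
  eps <- network$learn$eps
  soft <- network$learn$soft_bound
  plus <- trace$phases$PLUS
  for (nm in names(network$projections)) {
    p <- network$projections[[nm]]
    if (p$rule == "fixed") next
    if (msp_only && p$rule != "msp_error") next
    xp <- plus[[p$from]]
    yp <- plus[[p$to]]
    eps_p <- eps * p$lr
    hebb <- cpca_hebb_delta(xp, yp, p$W)
    if (p$rule == "hebbian") {
      delta <- eps_p * hebb
    } else {
      minus <- trace$phases[[if (p$rule == "msp_error") "TT" else "TP"]]
      err <- chl_delta(minus[[p$from]], minus[[p$to]], xp, yp)
      delta <- combined_delta(hebb, err,
                              learning_params(lmix = p$lmix, eps = eps_p))
    }
    if (!is.null(p$mask)) delta <- delta * p$mask
    network$projections[[nm]]$W <-
      apply_delta(p$W, delta, learning_params(lmix = p$lmix, eps = eps,
                                              soft_bound = soft))
  }
  network
}

#' Recall from a (possibly partial) cue
#'
#' Runs the trough and peak phases with no plus phase and no learning, and
#' reads out the EC_out activations at the end of the peak, when the
#' CA3-driven completed pattern has propagated through CA1 to EC_out.
#' Weights are read-only.
#'
#' @inheritParams run_theta_cycle
#' @param cue Input vector (typically a [corrupt_cue()] of a trained
#'   pattern).
#' @param readout `"TP"` (default) or `"TT"` (used to probe the
#'   monosynaptic reconstruction alone).
#' @return EC_out activation vector.
#' @export
recall <- function(network, cue, engine = c("cpp", "R"), readout = "TP") {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    drop(cpp_recall(net_to_cpp(network),
                    matrix(as.numeric(cue), nrow = 1),
                    readout == "TP"))
  } else {
    trace <- run_theta_cycle(network, cue, mode = "test", engine = "R")
    trace$phases[[readout]]$ec_out
  }
}

# Batch recall over the rows of a cue matrix (compiled path).
recall_batch <- function(network, cues, readout = "TP") {
  cpp_recall(net_to_cpp(network), cues, readout == "TP")
}

#' Train a network on a set of composite patterns
#'
#' Presents every pattern once per epoch through a full train-mode theta
#' cycle followed by the phase-contrast weight updates. Presentation order
#' is reshuffled each epoch (draw the orders under a seed for
#' reproducibility).
#'
#' @param network A `hippo_network`.
#' @param patterns A matrix with one composite EC pattern per row, or a
#'   [make_training_set()] tibble.
#' @param n_epochs Number of passes over the pattern set (default 15).
#' @param engine `"cpp"` (default) or `"R"`.
#' @param msp_only Pretraining mode: silence DG/CA3 and update only the
#'   monosynaptic pathway.
#' @param shuffle Reshuffle presentation order each epoch (default `TRUE`).
#' @return The network with trained weights.
#' @export
train_network <- function(network, patterns, n_epochs = 15,
                          engine = c("cpp", "R"), msp_only = FALSE,
                          shuffle = TRUE) {
  engine <- match.arg(engine)
  pats <- as_pattern_matrix(patterns)
  n_pat <- nrow(pats)
  orders <- t(vapply(seq_len(n_epochs), function(e) {
    if (shuffle) sample.int(n_pat) else seq_len(n_pat)
  }, integer(n_pat)))
  orders <- matrix(orders, nrow = n_epochs)  # guard n_pat == 1
  if (engine == "cpp") {
    w <- cpp_train(net_to_cpp(network), pats, orders, msp_only)
    names(w) <- names(network$projections)
    network <- set_network_weights(network, w)
  } else {
    for (e in seq_len(n_epochs)) {
      for (i in orders[e, ]) {
        trace <- run_theta_cycle(network, pats[i, ], "train", "R", msp_only)
        network <- learn_from_trace(network, trace, msp_only)
      }
    }
  }
  network
}

#' Pretrain the monosynaptic pathway alone
#'
#' Trains only the EC--CA1 monosynaptic projections for `n_epochs` on the
#' same patterns later used for integrated training, with DG and CA3
#' silenced. Trisynaptic weights are untouched.
#'
#' @inheritParams train_network
#' @return The network with pretrained monosynaptic weights.
#' @export
pretrain_msp <- function(network, patterns, n_epochs = 15,
                         engine = c("cpp", "R")) {
  train_network(network, patterns, n_epochs, match.arg(engine),
                msp_only = TRUE)
}

as_pattern_matrix <- function(patterns) {
  if (is.matrix(patterns)) return(patterns)
  if (is.data.frame(patterns) && "ec_vector" %in% names(patterns)) {
    return(do.call(rbind, patterns$ec_vector))
  }
  stop("patterns must be a matrix or a make_training_set() tibble")
}
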