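#' Theta-phase gating schedule
#'
#' Three projections change strength across the theta cycle; all others stay
#' open throughout. At the theta trough (TT) the entorhinal drive on CA1 is
#' strong and the Schaffer input is fully inhibited; at the theta peak (TP)
#' CA3 drives CA1 while the direct entorhinal drive is inhibited; in the plus
#' phase the superficial-to-deep entorhinal projection imposes the target on
#' EC_out while the Schaffer input is again inhibited.
#'
#' @return A tibble with one row per phase (`TT`, `TP`, `PLUS`) and a
#'   logical column per gated projection (`TRUE` = open).
#' @export
phase_gate_table <- function() {
  tibble::tibble(
    phase        = c("TT", "TP", "PLUS"),
    ec_in_ca1    = c(TRUE, FALSE, TRUE),
    ca3_ca1      = c(FALSE, TRUE, FALSE),
    ec_in_ec_out = c(FALSE, FALSE, TRUE))
}

# gate ids used by both engines: 0 always open, 1 = ec_in->ca1, 2 = ca3->ca1,
# 3 = ec_in->ec_out (the fixed one-to-one identity projection, open only in
# the plus phase).
open_projections <- function(network, phase) {
  gates <- phase_gate_table()
  row <- gates[gates$phase == phase, ]
  keep <- vapply(network$projections, function(p) {
    switch(p$gate, always = TRUE,
           ec_in_ca1 = row$ec_in_ca1,
           ca3_ca1 = row$ca3_ca1,
           ec_in_ec_out = row$ec_in_ec_out)
  }, logical(1))
  names(network$projections)[keep]
}

random_mask <- function(n_from, n_to, density) {
  if (density >= 1) return(NULL)
  matrix(as.integer(stats::runif(n_from * n_to) < density), n_from, n_to)
}

block_diag_mask <- function(n_from, n_to, n_slots) {
  bf <- n_from / n_slots
  bt <- n_to / n_slots
  m <- matrix(0L, n_from, n_to)
  for (s in seq_len(n_slots)) {
    m[((s - 1) * bf + 1):(s * bf), ((s - 1) * bt + 1):(s * bt)] <- 1L
  }
  m
}

init_weights <- function(n_from, n_to, mask, w_init) {
  w <- matrix(stats::runif(n_from * n_to, w_init[1], w_init[2]), n_from, n_to)
  if (!is.null(mask)) w <- w * mask
  w
}

#' Build the hippocampal network
#'
#' Constructs the five layers (EC_in, DG, CA3, CA1, EC_out) and eight
#' weighted projections of the model. The trisynaptic pathway (EC_in to DG,
#' EC_in to CA3, DG to CA3, recurrent CA3) is diffuse with seeded random
#' partial connectivity and learns with the conditional-PCA Hebbian rule.
#' The Schaffer collaterals (CA3 to CA1) are full and carry the theta-peak
#' error signal. The monosynaptic pathway (EC_in to CA1, CA1 to EC_out,
#' EC_out back to CA1) is block-diagonal by slot and carries the
#' theta-trough error signal. EC_in to EC_out is a fixed one-to-one mapping
#' (EC_out is clamped to the input during the plus phase) and is never
#' plastic. Weights are initialised uniformly on `config$w_init`.
#'
#' Each projection's drive is scaled by the reciprocal of its sender layer's
#' expected activity fraction, so sparse senders (DG especially) deliver
#' drive on the same scale as dense ones.
#'
#' @param config A [hippo_config()].
#' @param condition One of [hippo_conditions()] (default
#'   `"full_error_driven"`); fixes the per-pathway Hebbian proportion.
#' @param seed Optional integer; when supplied the builder runs under
#'   [withr::with_seed()] so identical seeds give identical weights and
#'   connectivity.
#' @return An object of class `hippo_network`.
#' @export
build_hippocampus <- function(config = hippo_config(),
                              condition = "full_error_driven",
                              seed = NULL) {
  stopifnot(inherits(config, "hippo_config"))
  lm <- condition_lmix(condition)
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      build_hippocampus(config, condition, seed = NULL)))
  }
  n_ec <- config$n_slots * config$slot_size
  n_ca1 <- config$n_slots * config$units_per_ca1_slot
  slot_pool <- function(n, n_slots) rep(seq_len(n_slots), each = n / n_slots)
  k_of <- function(pct, n) max(1L, as.integer(round(pct * n)))

  layers <- list(
    ec_in = list(n = n_ec, pool = slot_pool(n_ec, config$n_slots),
                 k = rep(config$n_active, config$n_slots)),
    dg = list(n = config$n_dg, pool = rep(1L, config$n_dg),
              k = k_of(config$dg_pct, config$n_dg)),
    ca3 = list(n = config$n_ca3, pool = rep(1L, config$n_ca3),
               k = k_of(config$ca3_pct, config$n_ca3)),
    ca1 = list(n = n_ca1, pool = slot_pool(n_ca1, config$n_slots),
               k = rep(k_of(config$ca1_slot_pct, config$units_per_ca1_slot),
                       config$n_slots)),
    ec_out = list(n = n_ec, pool = slot_pool(n_ec, config$n_slots),
                  k = rep(config$n_active, config$n_slots)))

  # expected activity fraction of each sender layer, for projection scaling
  act_frac <- c(
    ec_in = config$n_active / config$slot_size,
    dg = layers$dg$k / config$n_dg,
    ca3 = layers$ca3$k / config$n_ca3,
    ca1 = layers$ca1$k[1] / config$units_per_ca1_slot,
    ec_out = config$n_active / config$slot_size)

  proj <- function(from, to, mask, rule, gate = "always", lmix = 1,
                   rel = 1, lr = 1) {
    nf <- layers[[from]]$n
    nt <- layers[[to]]$n
    list(from = from, to = to, mask = mask,
         W = init_weights(nf, nt, mask, config$w_init),
         scale = rel * config$drive_gain / act_frac[[from]],
         rule = rule, gate = gate, lmix = lmix, lr = lr)
  }

  ca3_rec_mask <- 1L - diag(1L, config$n_ca3)  # no autapses
  projections <- list(
    ec_in_dg = proj("ec_in", "dg",
                    random_mask(n_ec, config$n_dg, config$p_ec_dg),
                    "hebbian", lr = config$tsp_lr_scale),
    ec_in_ca3 = proj("ec_in", "ca3",
                     random_mask(n_ec, config$n_ca3, config$p_ec_ca3),
                     "hebbian", lr = config$tsp_lr_scale),
    dg_ca3 = proj("dg", "ca3",
                  random_mask(config$n_dg, config$n_ca3, config$p_dg_ca3),
                  "hebbian", rel = config$dg_ca3_scale,
                  lr = config$tsp_lr_scale),
    ca3_ca3 = proj("ca3", "ca3", ca3_rec_mask, "hebbian",
                   rel = config$ca3_rec_scale, lr = config$tsp_lr_scale),
    ca3_ca1 = proj("ca3", "ca1", NULL, "tsp_error", gate = "ca3_ca1",
                   lmix = lm[["tsp"]], lr = config$tsp_lr_scale),
    ec_in_ca1 = proj("ec_in", "ca1",
                     block_diag_mask(n_ec, n_ca1, config$n_slots),
                     "msp_error", gate = "ec_in_ca1", lmix = lm[["msp"]]),
    ca1_ec_out = proj("ca1", "ec_out",
                      block_diag_mask(n_ca1, n_ec, config$n_slots),
                      "msp_error", lmix = lm[["msp"]]),
    ec_out_ca1 = proj("ec_out", "ca1",
                      block_diag_mask(n_ec, n_ca1, config$n_slots),
                      "msp_error", lmix = lm[["msp"]],
                      rel = config$ec_fb_scale),
    # fixed identity: the superficial-to-deep entorhinal mapping that imposes
    # the target on EC_out in the plus phase; its scale sets the target's
    # operating point (see ?hippo_config identity_scale).
    ec_in_ec_out = list(from = "ec_in", to = "ec_out",
                        mask = diag(1L, n_ec), W = diag(1, n_ec),
                        scale = config$identity_scale, rule = "fixed",
                        gate = "ec_in_ec_out", lmix = 1, lr = 0))

  structure(list(config = config, condition = condition,
                 layers = layers, projections = projections,
                 learn = learning_params(lmix = lm[["msp"]],
                                         eps = config$eps,
                                         soft_bound = config$soft_bound)),
            class = "hippo_network")
}

#' @export
print.hippo_network <- function(x, ...) {
  cat("<hippo_network> condition = ", x$condition, "\n", sep = "")
  cat("  layers: ",
      paste(sprintf("%s(%d)", names(x$layers),
                    vapply(x$layers, `[[`, integer(1), "n")),
            collapse = ", "), "\n", sep = "")
  cat("  projections: ", paste(names(x$projections), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Extract or replace all projection weights
#'
#' Used for checkpointing and for moving weights between the R and compiled
#' engines.
#'
#' @param network A `hippo_network`.
#' @return A named list of weight matrices.
#' @export
network_weights <- function(network) {
  lapply(network$projections, `[[`, "W")
}

#' @rdname network_weights
#' @param weights A named list of weight matrices, as from
#'   `network_weights()`.
#' @export
set_network_weights <- function(network, weights) {
  stopifnot(setequal(names(weights), names(network$projections)))
  for (nm in names(weights)) {
    stopifnot(identical(dim(weights[[nm]]), dim(network$projections[[nm]]$W)))
    network$projections[[nm]]$W <- weights[[nm]]
  }
  network
}

# Flatten the network into the plain list the compiled engine consumes.
net_to_cpp <- function(network) {
  lay_names <- names(network$layers)
  dyn <- network$config$dynamics
  list(
    layer_n = vapply(network$layers, `[[`, integer(1), "n"),
    pool = lapply(network$layers, function(l) as.integer(l$pool) - 1L),
    pool_k = lapply(network$layers, function(l) as.integer(l$k)),
    proj_from = vapply(network$projections,
                       function(p) match(p$from, lay_names) - 1L, integer(1)),
    proj_to = vapply(network$projections,
                     function(p) match(p$to, lay_names) - 1L, integer(1)),
    proj_W = lapply(network$projections, `[[`, "W"),
    proj_mask = lapply(network$projections, function(p) {
      if (is.null(p$mask)) matrix(1L, nrow(p$W), ncol(p$W)) else p$mask
    }),
    proj_scale = vapply(network$projections, `[[`, numeric(1), "scale"),
    proj_rule = vapply(network$projections, function(p) {
      switch(p$rule, hebbian = 1L, msp_error = 2L, tsp_error = 3L, 0L)
    }, integer(1)),
    proj_gate = vapply(network$projections, function(p) {
      switch(p$gate, always = 0L, ec_in_ca1 = 1L, ca3_ca1 = 2L,
             ec_in_ec_out = 3L)
    }, integer(1)),
    proj_lmix = vapply(network$projections, `[[`, numeric(1), "lmix"),
    proj_lr = vapply(network$projections, `[[`, numeric(1), "lr"),
    g_l = dyn$g_l, gain = dyn$gain, threshold = dyn$threshold,
    e_rev_exc = dyn$e_rev_exc, e_rev_inh = dyn$e_rev_inh,
    e_rev_leak = dyn$e_rev_leak, dt_vm = dyn$dt_vm,
    n_settle_steps = dyn$n_settle_steps, kwta_pt = dyn$kwta_pt,
    eps = network$learn$eps,
    soft_bound = network$learn$soft_bound)
}
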