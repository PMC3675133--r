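#' Hippocampal architecture configuration
#'
#' Collects every structural parameter of the model: the slot topology of the
#' entorhinal layers, subfield sizes (with the fixed 5:1 DG:CA3 ratio),
#' per-layer kWTA sparsity, projection connectivity densities, and the weight
#' initialisation range. All values are config-exposed; the defaults are the
#' reference configuration used throughout the package.
#'
#' @param n_slots Number of entorhinal/CA1 slots (default 8).
#' @param slot_size Units per entorhinal slot (default 50).
#' @param n_active Active units per slot pattern; also the entorhinal
#'   winners-per-slot (default 10).
#' @param vocab_n Vocabulary entries per slot (default 100).
#' @param min_hamming Minimum pairwise Hamming distance within a slot
#'   vocabulary (default 10).
#' @param units_per_ca1_slot CA1 units per slot (default 160). CA1 expands
#'   each entorhinal slot into a larger code; the expansion is what gives
#'   the monosynaptic autoencoder enough capacity to separate a full slot
#'   vocabulary, and it dilutes the weight-diffusion noise that otherwise
#'   degrades stored codes over long training runs.
#' @param n_ca3 CA3 units (default 80). DG is always `5 * n_ca3`.
#' @param n_dg DG units; must equal `5 * n_ca3` (the human DG:CA3 ratio the
#'   model preserves).
#' @param dg_pct,ca3_pct,ca1_slot_pct kWTA winner fractions for DG, CA3 and
#'   each CA1 slot (defaults 0.02, 0.15, 0.20).
#' @param p_ec_dg,p_ec_ca3,p_dg_ca3 Connection densities of the diffuse
#'   trisynaptic projections (defaults 0.25, 0.25, 0.05). The CA3 recurrent
#'   and CA3 to CA1 projections are full; the monosynaptic projections are
#'   block-diagonal by slot.
#' @param dg_ca3_scale Relative strength of the mossy-fibre DG to CA3 drive
#'   (default 0.3). Attenuating the pattern-separating DG input leaves the
#'   perforant-path and recurrent drive dominant at retrieval, which is what
#'   lets CA3 complete a partial cue to the stored code instead of
#'   separating it into a new one.
#' @param ca3_rec_scale Relative strength of the CA3 recurrent collaterals
#'   (default 2). Stronger recurrence deepens the CA3 attractor basins that
#'   perform pattern completion.
#' @param ec_fb_scale Relative strength of the EC_out to CA1 backprojection
#'   (default 0.05). The backprojection lets the imposed plus-phase target
#'   inform the CA1 code, but it must stay weak: CA1 codes then agree
#'   between the trough and plus phases, the contrastive update on the
#'   entorhinal-CA1 pathway stays near zero once recall is correct, and the
#'   slot code book remains stable instead of collapsing onto a few
#'   habitual winners as training load grows.
#' @param w_init Length-2 numeric, uniform weight initialisation range
#'   (default `c(0.25, 0.75)`).
#' @param drive_gain Multiplier on the activity-normalised projection
#'   scales (default 1.25). Each projection's drive is scaled by
#'   `drive_gain / (expected sender activity fraction)`, so a fully engaged
#'   pathway with mid-range weights delivers an excitatory conductance near
#'   1 regardless of sender sparsity, keeping layers within reach of the
#'   firing threshold even when only one of their input pathways is active.
#' @param identity_scale Drive scale of the fixed one-to-one EC_in to
#'   EC_out projection that imposes the plus-phase target (default 0.9).
#'   Chosen near the conductance a well-trained CA1 to EC_out pathway
#'   delivers, so the imposed target is an attainable activation state and
#'   the error signal vanishes as recall becomes perfect.
#' @param corrupt_fraction Fraction of a pattern deleted in test cues
#'   (default 0.25).
#' @param corrupt_mode `"slot"` or `"unit"`; see [corrupt_cue()].
#' @param dynamics A [dynamics_params()] list.
#' @param eps Base learning rate (default 0.03).
#' @param tsp_lr_scale Learning-rate multiplier for the trisynaptic
#'   projections, including the Schaffer collaterals (default 5). Each
#'   pattern is presented only `n_epochs` times, so the association from
#'   sparse CA3 codes onto CA1 must move weights quickly; the monosynaptic
#'   autoencoder, in contrast, needs the smaller base rate to keep its slot
#'   code book stable under load. Per-pathway rate constants are standard
#'   in this model family.
#' @param soft_bound Weight-bounding mode (default `TRUE`: exponential
#'   approach to the 0/1 bounds); see [learning_params()].
#' @return A list of class `hippo_config`.
#' @export
hippo_config <- function(n_slots = 8, slot_size = 50, n_active = 10,
                         vocab_n = 100, min_hamming = 10,
                         units_per_ca1_slot = 160,
                         n_ca3 = 80, n_dg = 5 * n_ca3,
                         dg_pct = 0.02, ca3_pct = 0.15, ca1_slot_pct = 0.20,
                         p_ec_dg = 0.25, p_ec_ca3 = 0.25, p_dg_ca3 = 0.05,
                         dg_ca3_scale = 0.3, ca3_rec_scale = 2,
                         ec_fb_scale = 0.05,
                         w_init = c(0.25, 0.75),
                         drive_gain = 1.25, identity_scale = 0.9,
                         corrupt_fraction = 0.25,
                         corrupt_mode = "slot",
                         dynamics = dynamics_params(),
                         eps = 0.03, tsp_lr_scale = 5,
                         soft_bound = TRUE) {
  if (n_dg != 5 * n_ca3) {
    stop("n_dg (", n_dg, ") must equal 5 * n_ca3 (", 5 * n_ca3,
         "): the model holds a fixed 5:1 DG:CA3 ratio")
  }
  stopifnot(n_slots >= 1, slot_size >= 1, n_active >= 1,
            n_active <= slot_size, units_per_ca1_slot >= 1, n_ca3 >= 1,
            length(w_init) == 2, w_init[1] <= w_init[2],
            w_init[1] >= 0, w_init[2] <= 1,
            inherits(dynamics, "dynamics_params"))
  structure(list(n_slots = as.integer(n_slots),
                 slot_size = as.integer(slot_size),
                 n_active = as.integer(n_active),
                 vocab_n = as.integer(vocab_n),
                 min_hamming = as.integer(min_hamming),
                 units_per_ca1_slot = as.integer(units_per_ca1_slot),
                 n_ca3 = as.integer(n_ca3), n_dg = as.integer(n_dg),
                 dg_pct = dg_pct, ca3_pct = ca3_pct,
                 ca1_slot_pct = ca1_slot_pct,
                 p_ec_dg = p_ec_dg, p_ec_ca3 = p_ec_ca3,
                 p_dg_ca3 = p_dg_ca3,
                 dg_ca3_scale = dg_ca3_scale,
                 ca3_rec_scale = ca3_rec_scale,
                 ec_fb_scale = ec_fb_scale,
                 w_init = w_init,
                 drive_gain = drive_gain,
                 identity_scale = identity_scale,
                 corrupt_fraction = corrupt_fraction,
                 corrupt_mode = corrupt_mode,
                 dynamics = dynamics,
                 eps = eps, tsp_lr_scale = tsp_lr_scale,
                 soft_bound = soft_bound),
            class = "hippo_config")
}

#' @export
print.hippo_config <- function(x, ...) {
  cat("<hippo_config> EC ", x$n_slots, "x", x$slot_size,
      " (", x$n_active, " active/slot), CA1 ", x$n_slots, "x",
      x$units_per_ca1_slot, ", CA3 ", x$n_ca3, ", DG ", x$n_dg, "\n",
      sep = "")
  invisible(x)
}

#' Learning conditions
#'
#' The five training regimes compared in the capacity experiments. Each
#' condition fixes the Hebbian proportion `lmix` separately for the
#' monosynaptic pathway (EC--CA1) and the Schaffer collaterals (CA3 to CA1):
#' error-driven pathways use `lmix = 0.001`, Hebbian pathways `lmix = 1`.
#' The pretrained variant is identical to `full_error_driven` except that
#' the monosynaptic pathway is trained alone for 15 epochs first.
#'
#' @return Character vector of the condition names.
#' @export
hippo_conditions <- function() {
  c("full_error_driven", "full_hebbian", "tsp_error_only",
    "msp_error_only", "pretrained_msp_variant")
}

condition_lmix <- function(condition) {
  switch(condition,
         full_error_driven      = c(msp = 0.001, tsp = 0.001),
         full_hebbian           = c(msp = 1.0,   tsp = 1.0),
         tsp_error_only         = c(msp = 1.0,   tsp = 0.001),
         msp_error_only         = c(msp = 0.001, tsp = 1.0),
         pretrained_msp_variant = c(msp = 0.001, tsp = 0.001),
         stop("unknown learning condition: \"", condition, "\" (expected one of ",
              paste(hippo_conditions(), collapse = ", "), ")"))
}

#' Read / write a flat configuration file
#'
#' Configurations are stored as flat key/value YAML. Every argument of
#' [hippo_config()] and [dynamics_params()] is a key; dynamics keys are
#' prefixed `dyn_` (e.g. `dyn_g_l`, `dyn_dt_vm`, `dyn_n_settle_steps`).
#' Unknown keys raise an error naming the offending key.
#'
#' @param path File path.
#' @return `read_hippo_config()` returns a `hippo_config`;
#'   `write_hippo_config()` returns `path` invisibly.
#' @export
read_hippo_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file is not a flat key/value mapping")
  dyn_keys <- sub("^dyn_", "", grep("^dyn_", names(raw), value = TRUE))
  bad <- setdiff(dyn_keys, names(formals(dynamics_params)))
  if (length(bad) > 0) {
    stop("unknown dynamics config key: dyn_", bad[1])
  }
  dyn <- if (length(dyn_keys) == 0) {
    dynamics_params()
  } else {
    do.call(dynamics_params,
            stats::setNames(raw[paste0("dyn_", dyn_keys)], dyn_keys))
  }
  arch <- raw[!grepl("^dyn_", names(raw))]
  bad <- setdiff(names(arch), setdiff(names(formals(hippo_config)), "dynamics"))
  if (length(bad) > 0) {
    stop("unknown config key: ", bad[1])
  }
  do.call(hippo_config, c(arch, list(dynamics = dyn)))
}

#' @rdname read_hippo_config
#' @param config A `hippo_config` object.
#' @export
write_hippo_config <- function(config, path) {
  stopifnot(inherits(config, "hippo_config"))
  dyn <- unclass(config$dynamics)
  flat <- c(unclass(config)[setdiff(names(config), "dynamics")],
            stats::setNames(dyn, paste0("dyn_", names(dyn))))
  yaml::write_yaml(flat, path)
  invisible(path)
}
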