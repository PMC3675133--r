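#' Point-neuron dynamics parameters
#'
#' Parameters of the conductance-based rate-code unit. The membrane potential
#' of each unit relaxes toward the conductance-weighted mean of three reversal
#' potentials (excitation, inhibition, leak), and the firing rate is a
#' saturating threshold function of the potential.
#'
#' @param g_l Leak conductance (dimensionless, default 0.1).
#' @param gain Gain of the rate function (default 100).
#' @param threshold Firing threshold on the membrane potential (default 0.5,
#'   within the unit's 0--1 dynamic range).
#' @param e_rev_exc,e_rev_inh,e_rev_leak Reversal potentials of the
#'   excitatory, inhibitory and leak channels (defaults 1.0, 0.15, 0.15).
#' @param dt_vm Integration step size of the explicit membrane update, in
#'   (0, 1] (default 0.45, at which 30 settling steps bring the layer
#'   states close to their phase equilibria; the phase-contrast learning
#'   signals compare equilibria, not transients).
#' @param n_settle_steps Number of integration steps per theta phase
#'   (default 30).
#' @param kwta_pt Placement of the k-winners-take-all inhibitory conductance
#'   between the threshold conductances of the k-th and (k+1)-th most excited
#'   units: 0 sits at the (k+1)-th, 1 at the k-th (default 0.1).
#'
#' @return A list of class `dynamics_params`.
#' @examples
#' p <- dynamics_params()
#' p$g_l
#' @export
dynamics_params <- function(g_l = 0.1, gain = 100, threshold = 0.5,
                            e_rev_exc = 1.0, e_rev_inh = 0.15,
                            e_rev_leak = 0.15, dt_vm = 0.45,
                            n_settle_steps = 30L, kwta_pt = 0.1) {
  stopifnot(g_l >= 0, gain > 0, dt_vm > 0, dt_vm <= 1,
            n_settle_steps >= 1, kwta_pt >= 0, kwta_pt <= 1,
            threshold > e_rev_inh, threshold < e_rev_exc)
  structure(list(g_l = g_l, gain = gain, threshold = threshold,
                 e_rev_exc = e_rev_exc, e_rev_inh = e_rev_inh,
                 e_rev_leak = e_rev_leak, dt_vm = dt_vm,
                 n_settle_steps = as.integer(n_settle_steps),
                 kwta_pt = kwta_pt),
            class = "dynamics_params")
}

#' Excitatory conductance from a weighted projection
#'
#' The excitatory input to each receiving unit is the *average* (not the sum)
#' of the weighted activities over its connected senders. Averaging keeps the
#' drive on the same 0--1 scale as single synapses regardless of fan-in. With
#' partial connectivity the mean runs over connected synapses only; `scale`
#' rescales the projection as a whole (used to compensate for sparse sender
#' layers whose mean activity is far below 1).
#'
#' @param x Sender activations, vector in \[0, 1\].
#' @param weights Weight matrix, senders in rows, receivers in columns,
#'   entries in \[0, 1\].
#' @param mask Optional 0/1 connectivity matrix of the same shape; `NULL`
#'   means full connectivity.
#' @param scale Multiplicative projection scale (default 1).
#'
#' @return Vector of excitatory conductances, one per receiver, all >= 0.
#' @examples
#' net_excitation(c(1, 0.5), matrix(c(0.4, 0.8), nrow = 2))  # 0.4
#' @export
net_excitation <- function(x, weights, mask = NULL, scale = 1) {
  if (length(x) != nrow(weights)) {
    stop("sender vector length (", length(x),
         ") does not match weight matrix rows (", nrow(weights), ")")
  }
  if (is.null(mask)) {
    ge <- drop(crossprod(weights, x)) / nrow(weights)
  } else {
    stopifnot(identical(dim(mask), dim(weights)))
    fanin <- pmax(colSums(mask), 1)
    ge <- drop(crossprod(weights * mask, x)) / fanin
  }
  scale * ge
}

#' One explicit step of the membrane-potential update
#'
#' `vm' = vm + dt * (ge (Ee - vm) + gi (Ei - vm) + gl (El - vm))`. The fixed
#' point is the conductance-weighted mean of the reversal potentials,
#' `sum(g E) / sum(g)`, and for `dt * sum(g) <= 1` every step moves `vm`
#' monotonically toward it.
#'
#' @param vm Membrane potential vector.
#' @param ge Excitatory conductance vector (>= 0).
#' @param gi Inhibitory conductance, scalar (uniform within a layer) or
#'   vector; >= 0.
#' @param params A [dynamics_params()] list.
#' @return Updated membrane potential vector.
#' @export
step_membrane <- function(vm, ge, gi, params) {
  stopifnot(all(ge >= 0), all(gi >= 0))
  vm + params$dt_vm *
    (ge * (params$e_rev_exc - vm) +
     gi * (params$e_rev_inh - vm) +
     params$g_l * (params$e_rev_leak - vm))
}

#' Saturating thresholded rate function
#'
#' Zero at or below threshold; above it, `y = g d / (g d + 1)` with
#' `d = vm - threshold`, which rises with gain `g` and saturates below 1.
#'
#' @param vm Membrane potential vector.
#' @param gain Gain factor (default taken from `params`).
#' @param threshold Firing threshold (default taken from `params`).
#' @param params Optional [dynamics_params()] supplying defaults.
#' @return Activation vector in \[0, 1).
#' @examples
#' activation_fn(c(0.5, 0.51, 1.0))  # 0, 0.5, 50/51
#' @export
activation_fn <- function(vm, gain = params$gain, threshold = params$threshold,
                          params = dynamics_params()) {
  d <- pmax(vm - threshold, 0)
  gd <- gain * d
  gd / (gd + 1)
}

# Inhibitory conductance that would hold a unit exactly at threshold at its
# membrane equilibrium, given its excitatory conductance.
threshold_conductance <- function(ge, params) {
  (ge * (params$e_rev_exc - params$threshold) +
     params$g_l * (params$e_rev_leak - params$threshold)) /
    (params$threshold - params$e_rev_inh)
}

#' k-winners-take-all inhibitory conductance
#'
#' Computes the single uniform inhibitory conductance for a layer (or
#' inhibition pool) such that, at membrane equilibrium, at most `k` units sit
#' above the firing threshold. For each unit the *threshold conductance* is
#' the inhibition that would put it exactly at threshold given its excitatory
#' drive; the returned `gi` is placed between the k-th and (k+1)-th largest
#' threshold conductances (at fraction `kwta_pt` above the (k+1)-th). If the
#' two are tied, `gi` equals the shared value and all tied units are
#' suppressed (a unit exactly at threshold has zero rate); the choice is
#' deterministic and conservative.
#'
#' @param ge Excitatory conductance vector for the pool.
#' @param k Target number of winners, `1 <= k <= length(ge)`.
#' @param params A [dynamics_params()] list.
#' @return A single non-negative inhibitory conductance.
#' @export
kwta_conductance <- function(ge, k, params = dynamics_params()) {
  n <- length(ge)
  if (k < 1 || k > n) {
    stop("kWTA k = ", k, " out of range for pool of ", n, " units")
  }
  gt <- sort(threshold_conductance(ge, params), decreasing = TRUE)
  upper <- gt[k]
  lower <- if (k < n) gt[k + 1] else min(gt[n], 0)
  gi <- lower + params$kwta_pt * (upper - lower)
  max(gi, 0)
}

#' Settle a set of layers to their end-of-phase activations
#'
#' Runs `params$n_settle_steps` synchronous update sweeps over all layers:
#' each step computes every non-clamped layer's excitatory conductance from
#' the gate-open incoming projections (averaged with equal weight across
#' projections), the pool-wise kWTA inhibitory conductance, one membrane
#' step, and the rate function. Clamped layers keep their imposed
#' activations and skip integration. This is the reference (pure R) engine;
#' [run_theta_cycle()] uses a compiled equivalent by default.
#'
#' @param layers Named list; each element has `n` (units), `pool` (integer
#'   pool id per unit) and `k` (winners per pool, vector over pools).
#' @param projections List; each element has `from`, `to` (layer names),
#'   `W` (weights), `mask` (0/1 or `NULL`) and `scale`.
#' @param state Named list with `y` and `vm` vectors per layer, as produced
#'   by `init_state()`.
#' @param open Character vector of projection names open during this phase.
#' @param clamp Named list of activation vectors imposed on clamped layers.
#' @param params A [dynamics_params()] list.
#' @return The updated `state` (list of `y` and `vm` per layer).
#' @export
settle <- function(layers, projections, state, open, clamp = list(),
                   params = dynamics_params()) {
  open_proj <- projections[names(projections) %in% open]
  for (nm in names(clamp)) {
    state$y[[nm]] <- clamp[[nm]]
  }
  free <- setdiff(names(layers), names(clamp))
  for (step in seq_len(params$n_settle_steps)) {
    ge <- stats::setNames(vector("list", length(free)), free)
    for (nm in free) {
      incoming <- open_proj[vapply(open_proj, function(p) p$to == nm,
                                   logical(1))]
      if (length(incoming) == 0L) {
        ge[[nm]] <- rep(0, layers[[nm]]$n)
      } else {
        contribs <- lapply(incoming, function(p) {
          net_excitation(state$y[[p$from]], p$W, p$mask, p$scale)
        })
        ge[[nm]] <- Reduce(`+`, contribs) / length(contribs)
      }
    }
    for (nm in free) {
      lay <- layers[[nm]]
      gi <- rep(0, lay$n)
      for (pool_id in seq_along(lay$k)) {
        idx <- which(lay$pool == pool_id)
        gi[idx] <- kwta_conductance(ge[[nm]][idx], lay$k[pool_id], params)
      }
      state$vm[[nm]] <- step_membrane(state$vm[[nm]], ge[[nm]], gi, params)
      state$y[[nm]] <- activation_fn(state$vm[[nm]], params = params)
    }
  }
  state
}

# Fresh state: activations zero, membrane at the leak reversal (rest).
init_state <- function(layers, params) {
  y <- lapply(layers, function(l) rep(0, l$n))
  vm <- lapply(layers, function(l) rep(params$e_rev_leak, l$n))
  list(y = y, vm = vm)
}
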