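#' Learning-rule parameters
#'
#' @param lmix Proportion of the Hebbian component in the blended rule,
#'   in \[0, 1\]. 1 gives pure Hebbian learning; the error-driven condition
#'   uses 0.001 (a trace of Hebbian adjustment is retained).
#' @param eps Learning rate, > 0 (default 0.04).
#' @param soft_bound If `TRUE`, weight changes are bounded softly
#'   (increases scaled by `1 - w`, decreases by `w`); if `FALSE` (default),
#'   weights are hard-clipped to \[0, 1\].
#' @return A list of class `learning_params`.
#' @export
learning_params <- function(lmix = 0.001, eps = 0.04, soft_bound = FALSE) {
  stopifnot(lmix >= 0, lmix <= 1, eps > 0, is.logical(soft_bound))
  structure(list(lmix = lmix, eps = eps, soft_bound = soft_bound),
            class = "learning_params")
}

#' Contrastive Hebbian learning delta
#'
#' The error-driven weight change between a sender and receiver layer is the
#' difference of activity coproducts between the target ("plus") phase and
#' the attempted-recall ("minus") phase:
#' `delta_ij = x+_i y+_j - x-_i y-_j`.
#'
#' @param x_minus,y_minus Sender and receiver activations from the minus
#'   phase (theta trough for the monosynaptic pathway, theta peak for the
#'   Schaffer collaterals).
#' @param x_plus,y_plus Sender and receiver activations from the plus phase.
#' @return Delta matrix, senders in rows, receivers in columns.
#' @examples
#' chl_delta(0.2, 0.4, 0.5, 0.8)  # 0.32
#' @export
chl_delta <- function(x_minus, y_minus, x_plus, y_plus) {
  if (length(x_minus) != length(x_plus) || length(y_minus) != length(y_plus)) {
    stop("phase activation vectors have mismatched lengths")
  }
  outer(x_plus, y_plus) - outer(x_minus, y_minus)
}

#' Conditional-PCA Hebbian delta
#'
#' Plus-phase-only Hebbian rule `delta_ij = y+_j (x+_i - w_ij)`. Repeated
#' application drives `w_ij` toward the expected sender activity conditional
#' on the receiver being active; with no receiver activity there is no
#' learning.
#'
#' @param x_plus Sender activations from the plus phase.
#' @param y_plus Receiver activations from the plus phase.
#' @param w Current weight matrix in \[0, 1\].
#' @return Delta matrix, same shape as `w`.
#' @export
cpca_hebb_delta <- function(x_plus, y_plus, w) {
  stopifnot(nrow(w) == length(x_plus), ncol(w) == length(y_plus))
  (outer(x_plus, y_plus) - w * rep(y_plus, each = nrow(w)))
}

#' Blend Hebbian and error-driven deltas
#'
#' `delta = eps * (lmix * hebb + (1 - lmix) * err)`.
#'
#' @param hebb_delta,err_delta Delta matrices of equal shape.
#' @param params A [learning_params()] list.
#' @return Blended delta matrix.
#' @export
combined_delta <- function(hebb_delta, err_delta, params) {
  stopifnot(identical(dim(hebb_delta), dim(err_delta)))
  params$eps * (params$lmix * hebb_delta + (1 - params$lmix) * err_delta)
}

#' Apply a weight change with bounding
#'
#' All principal weights are excitatory, so weights live in \[0, 1\]. By
#' default the update is hard-clipped into that range; with
#' `params$soft_bound` the delta is rescaled so weights approach the bounds
#' exponentially and never touch them.
#'
#' @param weights Weight matrix in \[0, 1\].
#' @param delta Delta matrix of the same shape.
#' @param params A [learning_params()] list.
#' @return Updated, bounded weight matrix.
#' @export
apply_delta <- function(weights, delta, params = learning_params()) {
  stopifnot(identical(dim(weights), dim(delta)))
  if (params$soft_bound) {
    d <- ifelse(delta > 0, delta * (1 - weights), delta * weights)
    weights + d
  } else {
    pmin(pmax(weights + delta, 0), 1)
  }
}
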