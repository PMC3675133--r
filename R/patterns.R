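#' Generate a slot vocabulary of binary patterns
#'
#' Builds the representational repertoire of one entorhinal slot: `n` binary
#' vectors of length `slot_size`, each with exactly `n_active` ones, with
#' every pairwise Hamming distance at least `min_hamming`. Entries are drawn
#' by rejection sampling: a uniformly random `n_active`-of-`slot_size`
#' pattern is accepted if it is far enough from every accepted entry.
#'
#' Because all entries carry the same number of active units, the distance
#' between two entries is `2 * (n_active - overlap)`; a `min_hamming` of 10
#' at the default geometry (50 units, 10 active) allows support overlaps up
#' to 5, which random draws satisfy with high probability.
#'
#' @param n Number of entries (default 100).
#' @param slot_size Units per slot (default 50).
#' @param n_active Active units per entry (default 10). This should match
#'   the entorhinal layer's winners-per-slot so the generator and the kWTA
#'   inhibition agree on pattern sparsity.
#' @param min_hamming Minimum pairwise Hamming distance (default 10).
#' @param max_attempts Attempt budget for rejection sampling (default
#'   `2000 * n`).
#' @return An object of class `slot_vocabulary`: a list with `entries`
#'   (an `n` x `slot_size` 0/1 integer matrix), and the generating
#'   parameters.
#' @examples
#' v <- withr::with_seed(1, generate_vocabulary(10, 20, 5, 6))
#' min(stats::dist(v$entries, method = "manhattan"))
#' @export
generate_vocabulary <- function(n = 100, slot_size = 50, n_active = 10,
                                min_hamming = 10, max_attempts = 2000 * n) {
  if (n_active > slot_size) {
    stop("infeasible vocabulary: n_active (", n_active,
         ") exceeds slot_size (", slot_size, ")")
  }
  if (min_hamming > 2 * n_active) {
    stop("infeasible vocabulary: min_hamming (", min_hamming,
         ") exceeds 2 * n_active (", 2 * n_active,
         "), the largest distance two equal-sparsity patterns can attain")
  }
  entries <- matrix(0L, nrow = n, ncol = slot_size)
  accepted <- 0L
  attempts <- 0L
  # max overlap compatible with the Hamming floor, for equal-count patterns
  max_overlap <- n_active - ceiling(min_hamming / 2)
  while (accepted < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("vocabulary generation exhausted its attempt budget (",
           max_attempts, " draws) with ", accepted, "/", n,
           " entries accepted; the min_hamming = ", min_hamming,
           " constraint is too tight for slot_size = ", slot_size,
           ", n_active = ", n_active)
    }
    cand <- integer(slot_size)
    cand[sample.int(slot_size, n_active)] <- 1L
    ok <- accepted == 0L ||
      max(entries[seq_len(accepted), , drop = FALSE] %*% cand) <= max_overlap
    if (ok) {
      accepted <- accepted + 1L
      entries[accepted, ] <- cand
    }
  }
  structure(list(entries = entries, n = n, slot_size = slot_size,
                 n_active = n_active, min_hamming = min_hamming,
                 attempts = attempts),
            class = "slot_vocabulary")
}

#' @export
print.slot_vocabulary <- function(x, ...) {
  cat("<slot_vocabulary> ", x$n, " entries, ", x$slot_size,
      " units/slot, ", x$n_active, " active, min Hamming >= ",
      x$min_hamming, "\n", sep = "")
  invisible(x)
}

#' Minimum pairwise Hamming distance of a vocabulary
#'
#' Exhaustive pairwise check of the vocabulary invariant.
#'
#' @param vocab A [generate_vocabulary()] object or a 0/1 matrix with one
#'   pattern per row.
#' @return The smallest pairwise Hamming distance.
#' @export
min_pairwise_hamming <- function(vocab) {
  m <- if (inherits(vocab, "slot_vocabulary")) vocab$entries else vocab
  as.integer(min(stats::dist(m, method = "manhattan")))
}

#' Compose a training set of slot-structured input patterns
#'
#' A complete entorhinal input is built by choosing one vocabulary entry per
#' slot; with `n` vocabulary entries and `n_slots` slots the product space
#' holds `n ^ n_slots` distinct composites. Draws are uniform and distinct
#' (no composite repeats within a training set).
#'
#' @param vocab A [generate_vocabulary()] object.
#' @param n_patterns Number of composite patterns to draw.
#' @param n_slots Number of entorhinal slots (default 8).
#' @return A tibble with one row per pattern: `pattern` (integer id),
#'   `slot_indices` (list of length-`n_slots` integer vectors) and
#'   `ec_vector` (list of binary vectors of length
#'   `n_slots * slot_size`).
#' @export
make_training_set <- function(vocab, n_patterns, n_slots = 8) {
  stopifnot(inherits(vocab, "slot_vocabulary"), n_patterns >= 1)
  if (log(n_patterns) > n_slots * log(vocab$n)) {
    stop("n_patterns (", n_patterns, ") exceeds the number of distinct ",
         "slot combinations (", vocab$n, "^", n_slots, ")")
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  draws <- vector("list", n_patterns)
  got <- 0L
  while (got < n_patterns) {
    idx <- sample.int(vocab$n, n_slots, replace = TRUE)
    key <- paste(idx, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      draws[[got]] <- idx
    }
  }
  ec <- lapply(draws, function(idx) {
    as.integer(t(vocab$entries[idx, , drop = FALSE]))
  })
  tibble::tibble(pattern = seq_len(n_patterns),
                 slot_indices = draws,
                 ec_vector = ec)
}

#' Corrupt a pattern into a partial retrieval cue
#'
#' Deletes a fraction of a trained pattern to probe pattern completion.
#' Deleted content is zeroed, never flipped, so a cue only ever removes
#' active units. The default `"slot"` mode deletes `fraction * n_slots`
#' whole slots chosen uniformly (2 of 8 at the defaults), matching the
#' slot-wise scoring of recall; `"unit"` mode instead zeroes a uniform
#' fraction of the active units across the whole pattern.
#'
#' @param pattern Binary input vector (length `n_slots * slot_size`).
#' @param fraction Fraction of the pattern to delete, in \[0, 1)
#'   (default 0.25).
#' @param n_slots Number of slots the vector divides into (default 8).
#' @param mode `"slot"` (default) or `"unit"`.
#' @return The cue vector, same length as `pattern`.
#' @export
corrupt_cue <- function(pattern, fraction = 0.25, n_slots = 8,
                        mode = c("slot", "unit")) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction < 1)
  cue <- pattern
  if (fraction == 0) return(cue)
  if (mode == "slot") {
    n_del <- fraction * n_slots
    if (abs(n_del - round(n_del)) > 1e-9) {
      stop("fraction * n_slots = ", n_del, " is not a whole number of ",
           "slots; use mode = \"unit\" for non-slot-aligned fractions")
    }
    slot_size <- length(pattern) / n_slots
    del <- sample.int(n_slots, round(n_del))
    for (s in del) {
      cue[((s - 1) * slot_size + 1):(s * slot_size)] <- 0L
    }
  } else {
    act <- which(pattern > 0)
    n_del <- round(fraction * length(act))
    cue[sample(act, n_del)] <- 0L
  }
  cue
}
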