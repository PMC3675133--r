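#' Name Error of one recalled pattern
#'
#' Slot-wise winner-take-all scoring of a recalled EC output. Each slot's
#' output vector is compared against every vocabulary entry; the pattern is
#' correct (0) only if, in *every* slot, the single closest vocabulary entry
#' is the trained one, and incorrect (1) otherwise. A similarity tie
#' involving the target counts as incorrect (deterministic and
#' conservative); an all-zero slot output therefore scores incorrect.
#' Against a sum-squared error this measure de-emphasises single-unit noise
#' in favour of whole-pattern identity, and needs no threshold parameter.
#'
#' @param ec_out EC output activation vector (graded, length
#'   `n_slots * slot_size`).
#' @param target_slot_indices Integer vector, the trained vocabulary entry
#'   per slot.
#' @param vocab The [generate_vocabulary()] used to build the patterns.
#' @param metric `"cosine"` (default; robust to graded activation scale)
#'   or `"euclidean"`.
#' @return Integer 0 (correct) or 1 (incorrect).
#' @export
name_error <- function(ec_out, target_slot_indices, vocab,
                       metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  n_slots <- length(target_slot_indices)
  slot_size <- vocab$slot_size
  stopifnot(length(ec_out) == n_slots * slot_size)
  entries <- vocab$entries
  for (s in seq_len(n_slots)) {
    out <- ec_out[((s - 1) * slot_size + 1):(s * slot_size)]
    if (metric == "cosine") {
      nrm <- sqrt(sum(out^2)) * sqrt(rowSums(entries^2))
      sim <- as.numeric(entries %*% out) / ifelse(nrm > 0, nrm, 1)
      if (sum(out^2) == 0) sim[] <- 0
    } else {
      sim <- -sqrt(rowSums(sweep(entries, 2, out)^2))
    }
    tgt <- target_slot_indices[s]
    if (!(sim[tgt] > max(sim[-tgt]))) return(1L)
  }
  0L
}

#' Train a network and test pattern completion
#'
#' Presents the training set for `n_epochs` full theta cycles with learning
#' (presentation order reshuffled per epoch), then probes recall of every
#' pattern from a partial cue and scores it with [name_error()]. Cues are
#' drawn under `cue_seed`, so two conditions tested with the same
#' `cue_seed` see identical corruptions. Scoring never changes weights.
#'
#' @param network A [build_hippocampus()] network.
#' @param training_set A [make_training_set()] tibble.
#' @param vocab The [generate_vocabulary()] behind the training set.
#' @param n_epochs Training epochs (default 15).
#' @param cue_seed Integer seed for the cue corruption draws.
#' @param engine `"cpp"` (default) or `"R"`.
#' @return A tibble with one row per pattern: `pattern`, `error` (0/1).
#'   The trained network is attached as attribute `"network"`.
#' @export
train_and_test <- function(network, training_set, vocab, n_epochs = 15,
                           cue_seed = 1L, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  network <- train_network(network, training_set, n_epochs, engine)
  res <- test_recall(network, training_set, vocab, cue_seed, engine)
  attr(res, "network") <- network
  res
}

#' Score recall of a training set from corrupted cues
#'
#' Builds a partial cue for every pattern (per the network config's
#' corruption settings, under `cue_seed`), runs [recall()] and scores each
#' output with [name_error()]. Weights are never modified.
#'
#' @inheritParams train_and_test
#' @return A tibble with one row per pattern: `pattern`, `error` (0/1).
#' @export
test_recall <- function(network, training_set, vocab, cue_seed = 1L,
                        engine = "cpp") {
  cfg <- network$config
  pats <- as_pattern_matrix(training_set)
  cues <- withr::with_seed(cue_seed, {
    t(apply(pats, 1, corrupt_cue, fraction = cfg$corrupt_fraction,
            n_slots = cfg$n_slots, mode = cfg$corrupt_mode))
  })
  outs <- if (engine == "cpp") {
    recall_batch(network, cues)
  } else {
    t(apply(cues, 1, function(cue) recall(network, cue, engine = "R")))
  }
  err <- vapply(seq_len(nrow(pats)), function(i) {
    name_error(outs[i, ], training_set$slot_indices[[i]], vocab)
  }, integer(1))
  tibble::tibble(pattern = training_set$pattern, error = err)
}

#' Capacity experiment configuration
#'
#' @param conditions Learning conditions to run; see [hippo_conditions()].
#' @param ca3_sizes CA3 sizes of the sweep (units, 10--100 for the
#'   replication range); DG is always 5x.
#' @param set_sizes Training-set sizes (patterns, 40--800 for the
#'   replication range).
#' @param n_seeds Random weight initialisations per cell (default 5).
#' @param n_epochs Training epochs (default 15).
#' @param base_seed Seed from which every cell's network, training-set and
#'   cue seeds are derived (default 42).
#' @param bootstrap_n Bootstrap resamples for comparisons (default 10000).
#' @param alpha Significance level (default 0.005).
#' @param config A [hippo_config()]; its `n_ca3`/`n_dg` are overridden per
#'   cell.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(conditions = c("full_error_driven",
                                             "full_hebbian"),
                              ca3_sizes = 80, set_sizes = c(40, 200),
                              n_seeds = 5, n_epochs = 15, base_seed = 42,
                              bootstrap_n = 10000, alpha = 0.005,
                              config = hippo_config()) {
  stopifnot(length(conditions) >= 1, length(ca3_sizes) >= 1,
            length(set_sizes) >= 1, n_seeds >= 1)
  conditions <- vapply(conditions, function(cn) {
    condition_lmix(cn); cn
  }, character(1), USE.NAMES = FALSE)
  structure(list(conditions = conditions, ca3_sizes = as.integer(ca3_sizes),
                 set_sizes = as.integer(set_sizes),
                 n_seeds = as.integer(n_seeds),
                 n_epochs = as.integer(n_epochs),
                 base_seed = as.integer(base_seed),
                 bootstrap_n = as.integer(bootstrap_n), alpha = alpha,
                 config = config),
            class = "experiment_config")
}

cell_seeds <- function(exp_config, ca3, set_size, seed_idx) {
  i_ca3 <- match(ca3, exp_config$ca3_sizes)
  i_set <- match(set_size, exp_config$set_sizes)
  base <- exp_config$base_seed
  list(net = base + 1000L * i_ca3 + 100L * i_set + seed_idx,
       set = base + 10000L * i_set + 17L * seed_idx,
       cue = base + 20000L * i_set + 29L * seed_idx + 7L * i_ca3)
}

#' Run the capacity sweep
#'
#' For every (condition, CA3 size, set size, seed) cell: build a fresh
#' network (DG = 5 x CA3), draw a fresh training set, train for
#' `n_epochs`, test recall from 25%-deleted cues and record the mean Name
#' Error. Within one cell the network seed, the training set and the test
#' cues are shared across conditions, so conditions differ only in their
#' learning rule. The vocabulary is generated once per sweep from
#' `base_seed`. With a `checkpoint` file the sweep is resumable: completed
#' cells are appended as they finish and never recomputed.
#'
#' @param exp_config An [experiment_config()].
#' @param checkpoint Optional path to a tab-separated checkpoint/result
#'   file.
#' @param engine `"cpp"` (default) or `"R"`.
#' @param verbose Print per-cell progress (default `FALSE`).
#' @return A `capacity_result` tibble with one row per cell: `condition`,
#'   `ca3_size`, `dg_size`, `set_size`, `seed`, `name_error` (mean over the
#'   set) and `errors` (list column of per-pattern 0/1 scores).
#' @export
capacity_sweep <- function(exp_config, checkpoint = NULL,
                           engine = c("cpp", "R"), verbose = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(exp_config, "experiment_config"))
  cfg <- exp_config$config
  vocab <- withr::with_seed(exp_config$base_seed,
    generate_vocabulary(cfg$vocab_n, cfg$slot_size, cfg$n_active,
                        cfg$min_hamming))
  grid <- expand.grid(seed = seq_len(exp_config$n_seeds),
                      set_size = exp_config$set_sizes,
                      ca3_size = exp_config$ca3_sizes,
                      condition = exp_config$conditions,
                      stringsAsFactors = FALSE)
  done <- if (!is.null(checkpoint) && file.exists(checkpoint)) {
    read_results(checkpoint)
  } else {
    NULL
  }
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    if (!is.null(done)) {
      hit <- done$condition == cell$condition &
        done$ca3_size == cell$ca3_size &
        done$set_size == cell$set_size & done$seed == cell$seed
      if (any(hit)) {
        rows[[g]] <- done[which(hit)[1], ]
        next
      }
    }
    seeds <- cell_seeds(exp_config, cell$ca3_size, cell$set_size, cell$seed)
    cell_cfg <- cfg
    cell_cfg$n_ca3 <- as.integer(cell$ca3_size)
    cell_cfg$n_dg <- as.integer(5L * cell$ca3_size)
    training_set <- withr::with_seed(seeds$set,
      make_training_set(vocab, cell$set_size, cfg$n_slots))
    res <- withr::with_seed(seeds$net, {
      network <- build_hippocampus(cell_cfg, cell$condition)
      if (cell$condition == "pretrained_msp_variant") {
        network <- pretrain_msp(network, training_set,
                                exp_config$n_epochs, engine)
      }
      train_and_test(network, training_set, vocab, exp_config$n_epochs,
                     cue_seed = seeds$cue, engine = engine)
    })
    row <- tibble::tibble(condition = cell$condition,
                          ca3_size = as.integer(cell$ca3_size),
                          dg_size = as.integer(5L * cell$ca3_size),
                          set_size = as.integer(cell$set_size),
                          seed = as.integer(cell$seed),
                          name_error = mean(res$error),
                          errors = list(res$error))
    rows[[g]] <- row
    if (!is.null(checkpoint)) {
      write_results(dplyr::bind_rows(rows[!vapply(rows, is.null,
                                                  logical(1))]),
                    checkpoint, exp_config)
    }
    if (verbose) {
      message(sprintf("[%d/%d] %s ca3=%d set=%d seed=%d NE=%.3f",
                      g, nrow(grid), cell$condition, cell$ca3_size,
                      cell$set_size, cell$seed, row$name_error))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "exp_config") <- exp_config
  class(out) <- c("capacity_result", class(out))
  out
}

#' Pooled bootstrap comparison of Name Error samples
#'
#' Two-sided permutation-style bootstrap: the observed statistic is the
#' difference of group means; the null distribution is built by repeatedly
#' drawing both groups, with replacement and at their original sizes, from
#' the pooled values and recording the mean difference. The p-value is the
#' fraction of null differences at least as extreme (in absolute value) as
#' the observed one, and is symmetric under swapping the groups.
#'
#' @param errors_a,errors_b Numeric vectors of Name Error values (0/1
#'   per-pattern scores or per-cell means).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param alpha Significance level (default 0.005).
#' @return A one-row tibble: `estimate` (mean a - mean b), `p.value`,
#'   `n_boot`, `alpha`, `significant`.
#' @export
bootstrap_compare <- function(errors_a, errors_b, n_boot = 10000,
                              alpha = 0.005) {
  stopifnot(length(errors_a) >= 1, length(errors_b) >= 1)
  obs <- mean(errors_a) - mean(errors_b)
  pooled <- c(errors_a, errors_b)
  na <- length(errors_a)
  nb <- length(errors_b)
  null_diff <- vapply(seq_len(n_boot), function(i) {
    mean(sample(pooled, na, replace = TRUE)) -
      mean(sample(pooled, nb, replace = TRUE))
  }, numeric(1))
  p <- mean(abs(null_diff) >= abs(obs))
  tibble::tibble(estimate = obs, p.value = p, n_boot = as.integer(n_boot),
                 alpha = alpha, significant = p < alpha)
}

#' Compare two conditions within a capacity result
#'
#' Pools the per-pattern Name Error scores of each condition (optionally
#' within one grid cell) and runs [bootstrap_compare()].
#'
#' @param result A [capacity_sweep()] tibble.
#' @param condition_a,condition_b Condition names to compare.
#' @param ca3_size,set_size Optional filters restricting the comparison to
#'   one grid cell.
#' @inheritParams bootstrap_compare
#' @return A one-row tibble as from [bootstrap_compare()], with the
#'   condition names prepended.
#' @export
compare_conditions <- function(result, condition_a, condition_b,
                               ca3_size = NULL, set_size = NULL,
                               n_boot = 10000, alpha = 0.005) {
  pick <- function(cond) {
    r <- result[result$condition == cond, ]
    if (!is.null(ca3_size)) r <- r[r$ca3_size == ca3_size, ]
    if (!is.null(set_size)) r <- r[r$set_size == set_size, ]
    if (nrow(r) == 0) stop("no rows for condition \"", cond, "\"")
    unlist(r$errors)
  }
  out <- bootstrap_compare(pick(condition_a), pick(condition_b),
                           n_boot, alpha)
  dplyr::bind_cols(tibble::tibble(condition_a = condition_a,
                                  condition_b = condition_b), out)
}
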