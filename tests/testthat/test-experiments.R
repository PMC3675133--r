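test_that("Name Error scores slot-wise winner identity", {
  v <- tiny_vocab()
  idx <- c(3, 7)
  exact <- as.numeric(c(v$entries[3, ], v$entries[7, ]))
  expect_equal(name_error(exact, idx, v), 0L)
  # one slot replaced by a different vocabulary entry: any-slot-wrong rule
  wrong <- as.numeric(c(v$entries[5, ], v$entries[7, ]))
  expect_equal(name_error(wrong, idx, v), 1L)
  # graded but target-closest output is still correct
  graded <- exact * 0.4
  expect_equal(name_error(graded, idx, v), 0L)
  # a tie involving the target counts as incorrect
  tied <- as.numeric(c(v$entries[3, ] + v$entries[5, ], v$entries[7, ]))
  sims <- (v$entries %*% tied[1:12]) / sqrt(rowSums(v$entries))
  if (abs(sims[3] - sims[5]) < 1e-12) {
    expect_equal(name_error(tied, idx, v), 1L)
  }
  # an all-zero slot can never be correct
  silent <- c(rep(0, 12), v$entries[7, ])
  expect_equal(name_error(silent, idx, v), 1L)
  expect_equal(name_error(exact, idx, v, metric = "euclidean"), 0L)
})

test_that("an untrained network recalls at chance", {
  v <- tiny_vocab()
  ts <- tiny_training_set(v, n_patterns = 6)
  net <- build_hippocampus(tiny_config(), seed = 51)
  cues <- do.call(rbind, ts$ec_vector)
  res <- test_recall(net, ts, v)
  # with 12 vocabulary entries per slot and 2 slots, chance accuracy is
  # far below 50%, so mean Name Error should be near 1
  expect_gte(mean(res$error), 0.5)
  # scoring is weight-read-only
  expect_identical(network_weights(net),
                   network_weights(build_hippocampus(tiny_config(), seed = 51)))
})

test_that("training and testing drives Name Error down on a small set", {
  v <- tiny_vocab()
  ts <- tiny_training_set(v, n_patterns = 5)
  net <- build_hippocampus(tiny_config(), seed = 51)
  res <- withr::with_seed(61, train_and_test(net, ts, v, n_epochs = 10,
                                             cue_seed = 71))
  expect_s3_class(res, "tbl_df")
  expect_named(res, c("pattern", "error"))
  expect_true(all(res$error %in% c(0L, 1L)))
  untrained <- mean(test_recall(net, ts, v)$error)
  expect_lte(mean(res$error), untrained)
})

test_that("the capacity sweep fills its grid deterministically", {
  ec <- experiment_config(conditions = c("full_error_driven", "full_hebbian"),
                          ca3_sizes = 10, set_sizes = 4, n_seeds = 2,
                          n_epochs = 2, base_seed = 7, config = tiny_config())
  r1 <- capacity_sweep(ec)
  expect_s3_class(r1, "capacity_result")
  expect_equal(nrow(r1), 4)
  expect_true(all(r1$dg_size == 5 * r1$ca3_size))
  expect_true(all(r1$name_error >= 0 & r1$name_error <= 1))
  expect_true(all(lengths(r1$errors) == 4))
  r2 <- capacity_sweep(ec)
  expect_identical(tidy(r1), tidy(r2))
  expect_error(experiment_config(conditions = "bogus"), "condition")
})

test_that("interrupted sweeps resume from their checkpoint", {
  ec <- experiment_config(conditions = "full_error_driven",
                          ca3_sizes = 10, set_sizes = 4, n_seeds = 2,
                          n_epochs = 2, base_seed = 7, config = tiny_config())
  ck <- withr::local_tempfile(fileext = ".tsv")
  full <- capacity_sweep(ec, checkpoint = ck)
  # corrupt one cell's stored value; resume must keep the stored value
  # (completed cells are never recomputed)
  done <- read_results(ck)
  done$name_error[1] <- 0.987
  write_results(done, ck)
  resumed <- capacity_sweep(ec, checkpoint = ck)
  expect_equal(resumed$name_error[1], 0.987)
  expect_equal(nrow(resumed), nrow(full))
})

test_that("pooled bootstrap behaves at its edges", {
  expect_equal(bootstrap_compare(rep(0.4, 5), rep(0.4, 5),
                                 n_boot = 200)$p.value, 1)
  withr::with_seed(5, {
    b <- bootstrap_compare(rep(0, 5), rep(1, 5), n_boot = 10000)
    expect_lt(b$p.value, 0.005)
    expect_true(b$significant)
  })
  a <- withr::with_seed(9, bootstrap_compare(c(0, 0, 1), c(1, 1, 1), 5000))
  b <- withr::with_seed(10, bootstrap_compare(c(1, 1, 1), c(0, 0, 1), 5000))
  expect_equal(a$p.value, b$p.value, tolerance = 0.05)
  expect_equal(a$estimate, -b$estimate)
})

test_that("condition comparisons pool per-pattern errors", {
  r <- tibble::tibble(
    condition = rep(c("a", "b"), each = 2),
    ca3_size = 10L, dg_size = 50L, set_size = 4L, seed = rep(1:2, 2),
    name_error = c(0, 0, 1, 1),
    errors = list(rep(0L, 4), rep(0L, 4), rep(1L, 4), rep(1L, 4)))
  class(r) <- c("capacity_result", class(r))
  cmp <- withr::with_seed(3, compare_conditions(r, "a", "b", n_boot = 5000,
                                                alpha = 0.05))
  expect_equal(cmp$estimate, -1)
  expect_true(cmp$significant)
  expect_error(compare_conditions(r, "a", "c"), "no rows")
})
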