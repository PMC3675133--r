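test_that("contrastive delta matches its algebra", {
  # identical phases cancel exactly
  x <- runif(4); y <- runif(3)
  expect_equal(chl_delta(x, y, x, y), matrix(0, 4, 3))
  expect_equal(chl_delta(0, 0, 1, 1), matrix(1, 1, 1))
  # hand evaluation: 0.5*0.8 - 0.2*0.4 = 0.32
  expect_equal(chl_delta(0.2, 0.4, 0.5, 0.8)[1, 1], 0.32)
  expect_error(chl_delta(c(1, 1), 1, 1, 1), "mismatch")
})

test_that("conditional-PCA delta has the sender-trace fixed point", {
  x <- c(1, 0, 1)
  w <- matrix(x, 3, 2)
  expect_equal(cpca_hebb_delta(x, c(1, 0.5), w), matrix(0, 3, 2))
  # no receiver activity, no learning
  expect_equal(cpca_hebb_delta(runif(3), 0, matrix(0.5, 3, 1)),
               matrix(0, 3, 1))
  expect_equal(cpca_hebb_delta(1, 0.5, matrix(0.5, 1, 1))[1, 1], 0.25)
})

test_that("blended rule reduces to its endpoints and is linear in eps", {
  h <- matrix(runif(6), 2, 3)
  e <- matrix(runif(6), 2, 3)
  expect_equal(combined_delta(h, e, learning_params(lmix = 1, eps = 0.1)),
               0.1 * h)
  d <- combined_delta(h, e, learning_params(lmix = 0.001, eps = 1))
  expect_equal(d, 0.001 * h + 0.999 * e)
  expect_equal(combined_delta(h, e, learning_params(lmix = 0.3, eps = 0.2)),
               2 * combined_delta(h, e, learning_params(lmix = 0.3, eps = 0.1)))
})

test_that("weight application is bounded and idempotent at zero delta", {
  w <- matrix(c(0.9, 0.1), 1, 2)
  expect_equal(apply_delta(w, matrix(0, 1, 2)), w)
  hard <- apply_delta(w, matrix(c(0.5, -0.5), 1, 2))
  expect_equal(hard, matrix(c(1, 0), 1, 2))
  soft <- apply_delta(w, matrix(c(0.5, -0.5), 1, 2),
                      learning_params(soft_bound = TRUE))
  expect_true(all(soft > 0 & soft < 1))
  expect_equal(soft[1, 1], 0.9 + 0.5 * 0.1)
  expect_equal(soft[1, 2], 0.1 - 0.5 * 0.1)
})

test_that("repeated contrastive updates close the phase gap on a toy net", {
  # one projection, sender clamped; the plus state is produced by a target
  # weight matrix, the model settles with learned weights; updates should
  # monotonically shrink the receiver phase gap early in training.
  withr::with_seed(11, {
    p <- dynamics_params()
    layers <- list(s = list(n = 10, pool = rep(1L, 10), k = 4L),
                   r = list(n = 6, pool = rep(1L, 6), k = 2L))
    x <- as.numeric(sample(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)))
    w_true <- matrix(runif(60, 0.1, 0.9), 10, 6)
    w <- matrix(0.5, 10, 6)
    settle_r <- function(w) {
      pr <- list(sr = list(from = "s", to = "r", W = w, mask = NULL,
                           scale = 2.5))
      st <- thetahippo:::init_state(layers, p)
      settle(layers, pr, st, open = "sr", clamp = list(s = x), params = p)$y$r
    }
    y_plus <- settle_r(w_true)
    gaps <- numeric(12)
    for (i in 1:12) {
      y_minus <- settle_r(w)
      gaps[i] <- sum((y_minus - y_plus)^2)
      d <- combined_delta(cpca_hebb_delta(x, y_plus, w),
                          chl_delta(x, y_minus, x, y_plus),
                          learning_params(lmix = 0.001, eps = 0.05))
      w <- apply_delta(w, d)
    }
    expect_true(all(diff(gaps) <= 1e-12))
    expect_lt(gaps[12], gaps[1] / 100)
  })
})

test_that("conditional-PCA converges to the conditional sender mean", {
  # deterministic sender: weights converge to the pattern itself
  x <- c(1, 0, 1, 0)
  w <- matrix(0.5, 4, 1)
  for (i in 1:400) {
    w <- apply_delta(w, 0.05 * cpca_hebb_delta(x, 1, w))
  }
  expect_equal(drop(w), x, tolerance = 1e-3)
  # stochastic sender: weights converge to P(x_i = 1 | receiver active)
  withr::with_seed(21, {
    prob <- c(0.8, 0.2, 0.5)
    w <- matrix(0.5, 3, 1)
    for (i in 1:4000) {
      xs <- as.numeric(runif(3) < prob)
      w <- apply_delta(w, 0.01 * cpca_hebb_delta(xs, 1, w))
    }
    expect_equal(drop(w), prob, tolerance = 0.05)
  })
})

test_that("perfect recall freezes error-driven learning", {
  net <- build_hippocampus(tiny_config(), "full_error_driven", seed = 41)
  pat <- tiny_training_set()$ec_vector[[1]]
  tr <- run_theta_cycle(net, pat, "train")
  # overwrite minus phases with the plus snapshots: zero phase contrast
  tr$phases$TT <- tr$phases$PLUS
  tr$phases$TP <- tr$phases$PLUS
  net2 <- learn_from_trace(net, tr)
  eps <- net$config$eps
  for (nm in names(net$projections)) {
    p <- net$projections[[nm]]
    dw <- max(abs(net2$projections[[nm]]$W - p$W))
    if (p$rule %in% c("msp_error", "tsp_error")) {
      # residual movement only through the lmix-weighted Hebbian trace
      expect_lte(dw, eps * p$lr * p$lmix + 1e-12)
    } else if (p$rule == "fixed") {
      expect_equal(dw, 0)
    }
  }
})
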