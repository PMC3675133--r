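test_that("the builder realises the architecture contracts", {
  cfg <- tiny_config(n_ca3 = 20)
  expect_equal(cfg$n_dg, 100)
  expect_error(hippo_config(n_ca3 = 20, n_dg = 80), "5")
  net <- build_hippocampus(cfg, seed = 3)
  # monosynaptic projections are block-diagonal: zero weight across slots
  W <- net$projections$ec_in_ca1$W
  expect_true(all(W[1:12, 25:48] == 0))
  expect_true(all(W[13:24, 1:24] == 0))
  # determinism of init
  net2 <- build_hippocampus(cfg, seed = 3)
  expect_identical(network_weights(net), network_weights(net2))
  # rule tags per pathway
  rules <- vapply(net$projections, `[[`, character(1), "rule")
  expect_equal(unname(rules[c("ec_in_ca1", "ca1_ec_out", "ec_out_ca1")]),
               rep("msp_error", 3))
  expect_equal(unname(rules[["ca3_ca1"]]), "tsp_error")
  expect_equal(unname(rules[["ec_in_ec_out"]]), "fixed")
  expect_true(all(rules[c("ec_in_dg", "ec_in_ca3", "dg_ca3", "ca3_ca3")] ==
                    "hebbian"))
  expect_error(build_hippocampus(cfg, "not_a_condition"), "condition")
})

test_that("the gate table matches the three-phase schedule", {
  g <- phase_gate_table()
  expect_equal(g$ec_in_ca1, c(TRUE, FALSE, TRUE))
  expect_equal(g$ca3_ca1, c(FALSE, TRUE, FALSE))
  expect_equal(g$ec_in_ec_out, c(FALSE, FALSE, TRUE))
  # 90 settling steps per full training cycle
  expect_equal(3L * dynamics_params()$n_settle_steps, 90L)
})

test_that("closed projections carry no information in their phases", {
  net <- build_hippocampus(tiny_config(), seed = 13)
  pat <- tiny_training_set()$ec_vector[[1]]
  base <- run_theta_cycle(net, pat, "train")
  # Schaffer input closed at trough and plus: zeroing it changes neither
  net_z <- net
  net_z$projections$ca3_ca1$W[] <- 0
  z <- run_theta_cycle(net_z, pat, "train")
  expect_equal(z$phases$TT, base$phases$TT)
  # direct entorhinal drive closed at peak: with the trough state held
  # fixed, the peak settle is invariant to that projection's weights
  p <- net$config$dynamics
  st <- thetahippo:::init_state(net$layers, p)
  st <- settle(net$layers, net$projections, st,
               open = thetahippo:::open_projections(net, "TT"),
               clamp = list(ec_in = pat), params = p)
  net_e <- net
  net_e$projections$ec_in_ca1$W <- net$projections$ec_in_ca1$W * 0.5
  tp_a <- settle(net$layers, net$projections, st,
                 open = thetahippo:::open_projections(net, "TP"),
                 clamp = list(ec_in = pat), params = p)
  tp_b <- settle(net_e$layers, net_e$projections, st,
                 open = thetahippo:::open_projections(net_e, "TP"),
                 clamp = list(ec_in = pat), params = p)
  expect_equal(tp_a$y, tp_b$y)
  # identity projection acts only in the plus phase
  net_i <- net
  net_i$projections$ec_in_ec_out$scale <- 0
  i <- run_theta_cycle(net_i, pat, "train")
  expect_equal(i$phases$TT, base$phases$TT)
  expect_equal(i$phases$TP, base$phases$TP)
  expect_false(isTRUE(all.equal(i$phases$PLUS$ec_out, base$phases$PLUS$ec_out)))
})

test_that("test mode has no plus phase and leaves weights untouched", {
  net <- build_hippocampus(tiny_config(), seed = 13)
  pat <- tiny_training_set()$ec_vector[[1]]
  tr <- run_theta_cycle(net, pat, "test")
  expect_null(tr$phases$PLUS)
  expect_named(tr$phases, c("TT", "TP"))
  w0 <- network_weights(net)
  invisible(recall(net, pat))
  expect_identical(network_weights(net), w0)
  expect_error(learn_from_trace(net, tr), "plus")
})

test_that("plus-phase EC output carries the presented pattern", {
  net <- build_hippocampus(tiny_config(), seed = 13)
  pat <- tiny_training_set()$ec_vector[[1]]
  tr <- run_theta_cycle(net, pat, "train")
  # the imposed target activates exactly the pattern's units per slot
  expect_equal(which(tr$phases$PLUS$ec_out > 0.1), which(pat > 0))
})

test_that("learning touches only plastic projections", {
  net <- build_hippocampus(tiny_config(), seed = 13)
  pat <- tiny_training_set()$ec_vector[[1]]
  tr <- run_theta_cycle(net, pat, "train")
  net2 <- learn_from_trace(net, tr)
  expect_identical(net2$projections$ec_in_ec_out$W,
                   net$projections$ec_in_ec_out$W)
  moved <- vapply(names(net$projections), function(nm) {
    max(abs(net2$projections[[nm]]$W - net$projections[[nm]]$W))
  }, numeric(1))
  expect_true(all(moved[c("ec_in_ca1", "ca1_ec_out", "ca3_ca1")] > 0))
  # Hebbian update uses the plus phase only: dropping the minus snapshots
  # does not change it for an lmix = 1 network
  neth <- build_hippocampus(tiny_config(), "full_hebbian", seed = 13)
  trh <- run_theta_cycle(neth, pat, "train")
  trh2 <- trh
  trh2$phases$TT <- lapply(trh$phases$TT, function(y) y * 0)
  trh2$phases$TP <- lapply(trh$phases$TP, function(y) y * 0)
  a <- learn_from_trace(neth, trh)
  b <- learn_from_trace(neth, trh2)
  expect_equal(network_weights(a), network_weights(b))
})

test_that("compiled and reference engines agree", {
  net <- build_hippocampus(tiny_config(), seed = 23)
  ts <- tiny_training_set()
  pat <- ts$ec_vector[[1]]
  r <- run_theta_cycle(net, pat, "train", engine = "R")
  c <- run_theta_cycle(net, pat, "train", engine = "cpp")
  expect_phase_equal(r, c, tol = 1e-10)
  # one full training pass, both engines, identical presentation order
  wr <- network_weights(train_network(net, ts, 2, engine = "R",
                                      shuffle = FALSE))
  wc <- network_weights(train_network(net, ts, 2, engine = "cpp",
                                      shuffle = FALSE))
  for (nm in names(wr)) expect_lt(max(abs(wr[[nm]] - wc[[nm]])), 1e-8)
  expect_equal(recall(net, pat, engine = "R"),
               recall(net, pat, engine = "cpp"), tolerance = 1e-10)
})

test_that("slot perturbations stay local when the trisynaptic path is off", {
  net <- build_hippocampus(tiny_config(), seed = 23)
  ts <- tiny_training_set()
  p1 <- ts$ec_vector[[1]]
  p2 <- p1
  # replace slot 1 content with slot content from another pattern
  p2[1:12] <- ts$ec_vector[[2]][1:12]
  a <- run_theta_cycle(net, p1, "test", msp_only = TRUE)
  b <- run_theta_cycle(net, p2, "test", msp_only = TRUE)
  # slot 2 of CA1 and EC_out are bit-identical; slot 1 differs
  expect_equal(a$phases$TT$ca1[25:48], b$phases$TT$ca1[25:48])
  expect_equal(a$phases$TT$ec_out[13:24], b$phases$TT$ec_out[13:24])
  expect_false(isTRUE(all.equal(a$phases$TT$ca1[1:24], b$phases$TT$ca1[1:24])))
})

test_that("pretraining trains the monosynaptic pathway alone", {
  net <- build_hippocampus(tiny_config(), seed = 33)
  ts <- tiny_training_set(n_patterns = 8)
  set.seed(1)
  pre <- pretrain_msp(net, ts, n_epochs = 4)
  for (nm in c("ec_in_dg", "ec_in_ca3", "dg_ca3", "ca3_ca3", "ca3_ca1")) {
    expect_identical(pre$projections[[nm]]$W, net$projections[[nm]]$W)
  }
  expect_false(identical(pre$projections$ca1_ec_out$W,
                         net$projections$ca1_ec_out$W))
  # reconstruction error at the trough shrinks with pretraining
  pats <- do.call(rbind, ts$ec_vector)
  sse <- function(n) {
    out <- t(apply(pats, 1, function(p) recall(n, p, readout = "TT")))
    mean((out - pats)^2)
  }
  set.seed(1)
  pre1 <- pretrain_msp(net, ts, n_epochs = 1)
  expect_lt(sse(pre), sse(pre1))
})
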