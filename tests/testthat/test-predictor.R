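test_that("dnn_forward outputs probabilities with the sigmoid identities", {
  cfg <- dnn_config(hidden_layers = c(8L), dropout_rate = 0, batch_norm = FALSE)
  X <- random_features(6, 10, seed = 1)
  params <- withr::with_seed(1, cdaae:::dnn_init(10L, cfg))
  # zero output layer -> p = sigmoid(0) = 0.5
  params$out$W[] <- 0; params$out$b <- 0
  p <- dnn_forward(X, cfg, params)
  expect_equal(unname(p), rep(0.5, 6), ignore_attr = TRUE)
  # increasing the output logit increases p (sigmoid monotonicity)
  params$out$b <- 1
  expect_true(all(dnn_forward(X, cfg, params) > p))
  # eval mode deterministic even with dropout and batch norm configured
  cfg2 <- dnn_config(hidden_layers = c(8L), dropout_rate = 0.5, batch_norm = TRUE)
  params2 <- withr::with_seed(2, cdaae:::dnn_init(10L, cfg2))
  p1 <- dnn_forward(X, cfg2, params2)
  p2 <- dnn_forward(X, cfg2, params2)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  # batch-composition invariance: single-row call equals batched call
  expect_equal(dnn_forward(X[2, ], cfg2, params2)[1], p1[2])
})

test_that("bce_loss matches closed forms and hand arithmetic", {
  expect_equal(bce_loss(rep(0.5, 10), rep(c(0, 1), 5)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)), -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-5) # clipped perfect prediction
  expect_error(bce_loss(c(0.5), c(1, 0)), "length")
  expect_error(bce_loss(c(0.5, 0.5), c(1, 2)), "0/1")
  # independent closed-form check on random pairs
  withr::with_seed(4, {
    p <- runif(100, 0.01, 0.99)
    y <- rbinom(100, 1, 0.5)
  })
  expect_equal(bce_loss(p, y), -mean(y * log(p) + (1 - y) * log(1 - p)),
               tolerance = 1e-10)
})

test_that("classify thresholds with ties counted positive", {
  expect_identical(classify(c(0.5, 0.4999, 1.0, 0)), c(1L, 0L, 1L, 0L))
  expect_identical(classify(0.7, threshold = 0.8), 0L)
})

tiny_train_cfg <- function(...) {
  cdaae_config(
    mscnn = mscnn_config(filters_per_scale = 4L, fc_dim = 16L),
    aae = aae_config(latent_dim = 8L, encoder_hidden = 32L, decoder_hidden = 32L,
                     disc_hidden = 16L),
    dnn = dnn_config(hidden_layers = c(16L, 8L)),
    epochs = 3L, batch_size = 32L, seed = 11L, ...
  )
}

test_that("train_model is bit-reproducible under a fixed seed", {
  fx <- tiny_sim_fixture(51L)
  m1 <- train_model(fx$sims$SC, fx$sims$SD, fx$pairs, tiny_train_cfg())
  m2 <- train_model(fx$sims$SC, fx$sims$SD, fx$pairs, tiny_train_cfg())
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$mscnn, m2$mscnn)
  expect_identical(m1$dnn$hidden, m2$dnn$hidden)
  p1 <- predict_pairs(m1, fx$sims$SC, fx$sims$SD, fx$pairs)
  p2 <- predict_pairs(m2, fx$sims$SC, fx$sims$SD, fx$pairs)
  expect_identical(p1, p2)
})

test_that("training loss decreases and all losses stay finite", {
  fx <- tiny_sim_fixture(52L)
  cfg <- tiny_train_cfg()
  cfg$epochs <- 12L
  m <- train_model(fx$sims$SC, fx$sims$SD, fx$pairs, cfg)
  expect_lt(m$trace$bce[nrow(m$trace)], m$trace$bce[1])
  expect_lt(m$trace$recon[nrow(m$trace)], m$trace$recon[1])
  expect_true(all(is.finite(unlist(m$trace[, c("bce", "recon", "disc", "gen")]))))
})

test_that("every trainable parameter block receives gradient on a batch", {
  fx <- tiny_sim_fixture(53L)
  cfg <- tiny_train_cfg()
  feats <- build_pair_features(fx$sims$SC, fx$sims$SD, fx$pairs[1:16, ])
  model <- withr::with_seed(1, {
    m <- list(config = cfg)
    m$mscnn <- cdaae:::mscnn_init(ncol(feats$C), ncol(feats$D), cfg$mscnn)
    m$aae <- list(
      enc = cdaae:::mlp_init(c(32L, 32L, 8L), c("relu", "linear")),
      dec = cdaae:::mlp_init(c(8L, 32L, 32L), c("relu", "linear")),
      disc = cdaae:::mlp_init(c(8L, 16L, 1L), c("relu", "sigmoid")),
      enc_buffers = list(rmean = rep(0, 8L), rvar = rep(1, 8L))
    )
    m$dnn <- cdaae:::dnn_init(8L, cfg$dnn)
    m
  })
  opt <- list(mscnn = NULL, enc = NULL, dec = NULL, disc = NULL, dnn = NULL)
  st <- withr::with_seed(2, cdaae:::joint_step(
    feats$C, feats$D, fx$pairs$label[1:16], model, opt
  ))
  # dead-subnetwork guard: parameters moved in every component
  num <- function(x) rapply(x, c, classes = "numeric", how = "unlist")
  moved <- function(a, b) max(abs(num(a) - num(b)))
  expect_gt(moved(st$model$mscnn$circ, model$mscnn$circ), 0)
  expect_gt(moved(st$model$mscnn$drug, model$mscnn$drug), 0)
  expect_gt(moved(st$model$aae$enc, model$aae$enc), 0)
  expect_gt(moved(st$model$aae$dec, model$aae$dec), 0)
  expect_gt(moved(st$model$dnn$hidden, model$dnn$hidden), 0)
  expect_gt(moved(st$model$dnn$out, model$dnn$out), 0)
})

test_that("predict_pairs ranks deterministically with lexicographic tie-breaks", {
  fx <- tiny_sim_fixture(54L)
  m <- train_model(fx$sims$SC, fx$sims$SD, fx$pairs, tiny_train_cfg())
  pred <- predict_pairs(m, fx$sims$SC, fx$sims$SD, fx$pairs)
  expect_equal(nrow(pred), nrow(fx$pairs))
  expect_identical(pred$rank, seq_len(nrow(pred)))
  expect_true(all(diff(pred$score) <= 0))
  # ranking invariant under input order permutation
  perm <- withr::with_seed(3, sample(nrow(fx$pairs)))
  pred_p <- predict_pairs(m, fx$sims$SC, fx$sims$SD, fx$pairs[perm, ])
  expect_equal(pred_p$circ_id, pred$circ_id)
  expect_equal(pred_p$score, pred$score)
  # top-k extraction (case-study mode)
  expect_equal(nrow(utils::head(pred, 10L)), 10L)
})

test_that("ablation variants run and respect their wiring", {
  fx <- tiny_sim_fixture(55L)
  cfg_nm <- tiny_train_cfg(no_mscnn = TRUE)
  m_nm <- train_model(fx$sims$SC, fx$sims$SD, fx$pairs, cfg_nm)
  expect_null(m_nm$mscnn)
  expect_false(is.null(m_nm$aae))
  cfg_ne <- tiny_train_cfg(no_encoder = TRUE)
  m_ne <- train_model(fx$sims$SC, fx$sims$SD, fx$pairs, cfg_ne)
  expect_null(m_ne$aae)
  expect_equal(m_ne$dnn$input_dim, 2L * cfg_ne$mscnn$fc_dim)
  cfg_nd <- tiny_train_cfg(no_discriminator = TRUE)
  m_nd <- train_model(fx$sims$SC, fx$sims$SD, fx$pairs, cfg_nd)
  expect_true(all(is.na(m_nd$trace$disc)))
  for (m in list(m_nm, m_ne, m_nd)) {
    pred <- predict_pairs(m, fx$sims$SC, fx$sims$SD, fx$pairs[1:10, ])
    expect_equal(nrow(pred), 10L)
    expect_true(all(pred$score > 0 & pred$score < 1))
  }
})

test_that("backprop gradients match finite differences through the full pipeline", {
  fx <- tiny_sim_fixture(56L, n_circ = 12L, n_drug = 10L)
  cfg <- cdaae_config(
    mscnn = mscnn_config(filters_per_scale = 2L, fc_dim = 8L),
    aae = aae_config(latent_dim = 4L, encoder_hidden = 12L, decoder_hidden = 12L,
                     disc_hidden = 8L),
    dnn = dnn_config(hidden_layers = c(8L), dropout_rate = 0, batch_norm = TRUE),
    seed = 5L
  )
  feats <- build_pair_features(fx$sims$SC, fx$sims$SD, fx$pairs[1:8, ])
  y <- fx$pairs$label[1:8]
  model <- withr::with_seed(6, {
    m <- list(config = cfg)
    m$mscnn <- cdaae:::mscnn_init(12L, 10L, cfg$mscnn)
    m$aae <- list(
      enc = cdaae:::mlp_init(c(16L, 12L, 4L), c("relu", "linear")),
      dec = cdaae:::mlp_init(c(4L, 12L, 16L), c("relu", "linear")),
      disc = cdaae:::mlp_init(c(4L, 8L, 1L), c("relu", "sigmoid")),
      enc_buffers = list(rmean = rep(0, 4L), rvar = rep(1, 4L))
    )
    m$dnn <- cdaae:::dnn_init(4L, cfg$dnn)
    m
  })
  # scalar loss = BCE + reconstruction, exactly as in the joint step, but
  # recomputed from scratch (batch-norm batch statistics; dropout off). The
  # reconstruction target is the unperturbed extractor output, matching the
  # stop-gradient semantics of the training step.
  x0 <- cdaae:::pipeline_forward(feats$C, feats$D, model, train = TRUE)$x
  loss_of <- function(model) {
    fw <- cdaae:::pipeline_forward(feats$C, feats$D, model, train = TRUE)
    df <- cdaae:::dnn_forward_cached(fw$dnn_in, model$dnn, cfg$dnn, train = TRUE)
    p <- cdaae:::clip_prob(df$p)
    bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
    bce + mean((fw$df$out - x0)^2)
  }
  # analytic gradients of the conv weights via the joint backward pass
  fw <- cdaae:::pipeline_forward(feats$C, feats$D, model, train = TRUE)
  df <- cdaae:::dnn_forward_cached(fw$dnn_in, model$dnn, cfg$dnn, train = TRUE)
  p <- cdaae:::clip_prob(df$p)
  dp <- matrix((p - y) / (p * (1 - p)) / length(y), ncol = 1)
  dnn_bk <- cdaae:::dnn_backward(dp, df, model$dnn, cfg$dnn)
  err <- fw$df$out - fw$x
  dec_bk <- cdaae:::mlp_backward(2 * err / length(err), fw$df, model$aae$dec)
  enc_bk <- cdaae:::enc_backward(dec_bk$dX + dnn_bk$dX, fw$ef, model$aae$enc)
  m_bk <- cdaae:::mscnn_backward(enc_bk$dX, fw$mcache, model$mscnn, cfg$mscnn)
  eps <- 1e-5
  # sample conv weights from both branches and scales
  picks <- list(
    list(br = "circ", sc = 1L, idx = 1L), list(br = "circ", sc = 2L, idx = 5L),
    list(br = "drug", sc = 3L, idx = 7L), list(br = "drug", sc = 1L, idx = 3L)
  )
  for (pk in picks) {
    g_ana <- m_bk$grads[[pk$br]]$conv[[pk$sc]]$W[pk$idx]
    mp <- model; mp$mscnn[[pk$br]]$conv[[pk$sc]]$W[pk$idx] <-
      mp$mscnn[[pk$br]]$conv[[pk$sc]]$W[pk$idx] + eps
    mm <- model; mm$mscnn[[pk$br]]$conv[[pk$sc]]$W[pk$idx] <-
      mm$mscnn[[pk$br]]$conv[[pk$sc]]$W[pk$idx] - eps
    g_fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
    expect_equal(g_ana, g_fd, tolerance = 1e-4)
  }
  # and a fully-connected weight of the extractor
  g_ana <- m_bk$grads$circ$fc$W[10L]
  mp <- model; mp$mscnn$circ$fc$W[10L] <- mp$mscnn$circ$fc$W[10L] + eps
  mm <- model; mm$mscnn$circ$fc$W[10L] <- mm$mscnn$circ$fc$W[10L] - eps
  expect_equal(g_ana, (loss_of(mp) - loss_of(mm)) / (2 * eps), tolerance = 1e-4)
})
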