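small_aae_cfg <- function(...) {
  args <- utils::modifyList(
    list(latent_dim = 6L, encoder_hidden = 24L, decoder_hidden = 24L,
         disc_hidden = 12L, epochs = 5L, batch_size = 16L, seed = 3L),
    list(...)
  )
  do.call(aae_config, args)
}

test_that("encode and decode respect shapes and determinism", {
  X <- random_features(8, 20, seed = 1)
  state <- aae_init(20L, small_aae_cfg())
  z1 <- encode(X, state)
  z2 <- encode(X, state)
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(8L, 6L))
  xhat <- decode(z1, state)
  expect_equal(dim(xhat), dim(X))
  expect_true(all(is.finite(xhat)))
  expect_equal(dim(decode(rep(0, 6), state)), c(1L, 20L))
  # order preserved
  expect_equal(encode(X[3, ], state)[1, ], z1[3, ])
  expect_error(encode(random_features(2, 5), state), "width")
})

test_that("reconstruction_step with zero learning rate leaves parameters unchanged", {
  X <- random_features(16, 20, seed = 2)
  state <- aae_init(20L, small_aae_cfg())
  r <- reconstruction_step(X, state, lr = 0)
  expect_equal(r$state$enc, state$enc)
  expect_equal(r$state$dec, state$dec)
  expect_gte(r$loss, 0)
  # loss equals the MSE of the untrained train-mode forward pass
  z_tr <- cdaae:::enc_forward(X, state$enc, state$enc_buffers, train = TRUE)$z
  expect_equal(r$loss, mean((decode(z_tr, state) - X)^2))
})

test_that("repeated reconstruction steps overfit a single batch", {
  X <- random_features(16, 20, seed = 3)
  state <- aae_init(20L, small_aae_cfg())
  first <- reconstruction_step(X, state)$loss
  # mechanics check at a step size suited to 200 iterations
  for (i in 1:200) {
    st <- reconstruction_step(X, state, lr = 1e-2, weight_decay = 0)
    state <- st$state
  }
  final <- reconstruction_step(X, state, lr = 0)$loss
  expect_lt(final, first / 10)
})

test_that("discriminator and generator losses have their closed forms at d = 0.5", {
  X <- random_features(32, 20, seed = 4)
  state <- aae_init(20L, small_aae_cfg())
  # force d = 0.5 everywhere: zero the discriminator output layer
  nl <- length(state$disc$layers)
  state$disc$layers[[nl]]$W[] <- 0
  state$disc$layers[[nl]]$b[] <- 0
  d <- withr::with_seed(1, discriminator_step(X, state, lr = 0))
  expect_equal(d$loss, 2 * log(2), tolerance = 1e-12)
  g <- generator_step(X, state, lr = 0)
  expect_equal(g$loss, log(2), tolerance = 1e-12)
  # lr 0 leaves the encoder untouched
  expect_equal(g$state$enc, state$enc)
})

test_that("a discriminator learns to separate disjoint latent supports", {
  # frozen encoder fixture: posterior mass at -3, prior at +3 in 1-D
  withr::with_seed(9, {
    zq <- matrix(rnorm(400, mean = -3, sd = 0.3), ncol = 1)
    zp <- matrix(rnorm(400, mean = 3, sd = 0.3), ncol = 1)
  })
  disc <- withr::with_seed(2, cdaae:::mlp_init(c(1L, 16L, 1L), c("relu", "sigmoid")))
  cache <- NULL
  for (i in 1:300) {
    fp <- cdaae:::mlp_forward(zp, disc)
    fq <- cdaae:::mlp_forward(zq, disc)
    dp <- cdaae:::clip_prob(fp$out); dq <- cdaae:::clip_prob(fq$out)
    n <- nrow(zp)
    bp <- cdaae:::mlp_backward(-1 / (dp * n), fp, disc)
    bq <- cdaae:::mlp_backward(1 / ((1 - dq) * n), fq, disc)
    grads <- list(layers = Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                               bp$grads$layers, bq$grads$layers))
    up <- cdaae:::rmsprop_step(disc, grads, cache, lr = 1e-2)
    disc <- up$p; cache <- up$c
  }
  acc <- (mean(cdaae:::mlp_forward(zp, disc)$out >= 0.5) +
          mean(cdaae:::mlp_forward(zq, disc)$out < 0.5)) / 2
  expect_gt(acc, 0.95)
})

test_that("train_aae is deterministic and its reconstruction loss decreases", {
  X <- random_features(96, 20, seed = 5)
  cfg <- small_aae_cfg(epochs = 8L)
  s1 <- train_aae(X, cfg)
  s2 <- train_aae(X, cfg)
  expect_identical(s1$enc, s2$enc)
  expect_identical(s1$trace, s2$trace)
  expect_lt(s1$trace$recon_loss[nrow(s1$trace)], s1$trace$recon_loss[1])
  expect_true(all(is.finite(unlist(s1$trace[, c("recon_loss", "disc_loss", "gen_loss")]))))
})

test_that("no_discriminator degrades training to a plain autoencoder", {
  X <- random_features(64, 20, seed = 6)
  s <- train_aae(X, small_aae_cfg(epochs = 3L), no_discriminator = TRUE)
  expect_equal(s$n_disc_steps, 0L)
  expect_equal(s$n_gen_steps, 0L)
  expect_true(all(is.na(s$trace$disc_loss)))
  expect_lt(s$trace$recon_loss[3], s$trace$recon_loss[1] + 1e-12)
})

test_that("generator step counts track the configured training ratio", {
  X <- random_features(64, 16, seed = 7)
  cfg1 <- small_aae_cfg(epochs = 10L)
  s1 <- train_aae(X, cfg1)
  expect_lte(abs(s1$n_gen_steps - s1$n_disc_steps), 1L) # 1:1 alternation
  cfg12 <- aae_config(
    latent_dim = 4L, encoder_hidden = 16L, decoder_hidden = 16L, disc_hidden = 8L,
    train_ratio = 1.2, epochs = 63L, batch_size = 4L, seed = 2L
  )
  s12 <- train_aae(X, cfg12) # 16 batches/epoch * 63 epochs > 1000 iterations
  expect_gt(s12$n_disc_steps, 1000L)
  ratio <- s12$n_gen_steps / s12$n_disc_steps
  expect_lt(abs(ratio - 1.2) / 1.2, 0.02)
  cfg08 <- aae_config(
    latent_dim = 4L, encoder_hidden = 16L, decoder_hidden = 16L, disc_hidden = 8L,
    train_ratio = 0.8, epochs = 63L, batch_size = 4L, seed = 2L
  )
  s08 <- train_aae(X, cfg08)
  expect_lt(abs(s08$n_gen_steps / s08$n_disc_steps - 0.8) / 0.8, 0.02)
})

test_that("adversarial training moves the latent distribution toward the prior", {
  X <- random_features(128, 20, seed = 8)
  cfg <- small_aae_cfg(epochs = 12L, lr = 1e-3)
  s0 <- aae_init(20L, cfg)
  s <- train_aae(X, cfg)
  withr::with_seed(4, {
    prior <- matrix(rnorm(128 * cfg$latent_dim), 128)
  })
  e0 <- cdaae:::energy_distance(encode(X, s0), prior)
  e1 <- cdaae:::energy_distance(encode(X, s), prior)
  expect_lt(e1, e0)
})
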