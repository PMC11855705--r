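#' Adversarial autoencoder configuration
#'
#' The encoder compresses integrated pair features to a `latent_dim` code;
#' the decoder reconstructs the input; a discriminator is trained to tell
#' prior samples (standard normal per dimension) from encoder outputs, while
#' the encoder is trained to fool it, pushing the latent distribution toward
#' the prior.
#'
#' @param latent_dim latent code width (must stay below the input width).
#' @param encoder_hidden,decoder_hidden,disc_hidden hidden widths of the
#'   three networks.
#' @param train_ratio encoder:discriminator training ratio `r` (per
#'   discriminator step, generator steps accumulate at rate `r`); 1 means
#'   strict alternation.
#' @param epochs,batch_size,lr,weight_decay optimization settings (RMSprop;
#'   learning rate and weight decay both default to 1e-4).
#' @param seed integer seed making training deterministic.
#' @return An object of class `aae_config`.
#' @export
aae_config <- function(latent_dim = 64L, encoder_hidden = 256L,
                       decoder_hidden = 256L, disc_hidden = 64L,
                       train_ratio = 1, epochs = 200L, batch_size = 64L,
                       lr = 1e-4, weight_decay = 1e-4, seed = 1L) {
  stopifnot(latent_dim >= 1L, train_ratio > 0, epochs >= 1L, batch_size >= 1L)
  structure(
    list(
      latent_dim = as.integer(latent_dim),
      encoder_hidden = as.integer(encoder_hidden),
      decoder_hidden = as.integer(decoder_hidden),
      disc_hidden = as.integer(disc_hidden),
      train_ratio = train_ratio,
      epochs = as.integer(epochs),
      batch_size = as.integer(batch_size),
      lr = lr,
      weight_decay = weight_decay,
      seed = as.integer(seed)
    ),
    class = "aae_config"
  )
}

#' Initialize an adversarial autoencoder state
#'
#' @param input_dim width of the feature vectors to compress.
#' @param cfg an [aae_config()].
#' @return An `aae_state`: encoder/decoder/discriminator parameters
#'   (Xavier-initialized), optimizer caches, and empty loss traces.
#' @export
aae_init <- function(input_dim, cfg = aae_config()) {
  stopifnot(cfg$latent_dim < input_dim)
  withr::with_seed(cfg$seed, {
    enc <- mlp_init(c(input_dim, cfg$encoder_hidden, cfg$latent_dim), c("relu", "linear"))
    dec <- mlp_init(c(cfg$latent_dim, cfg$decoder_hidden, input_dim), c("relu", "linear"))
    disc <- mlp_init(c(cfg$latent_dim, cfg$disc_hidden, 1L), c("relu", "sigmoid"))
  })
  structure(
    list(
      enc = enc, dec = dec, disc = disc,
      enc_buffers = list(rmean = rep(0, cfg$latent_dim), rvar = rep(1, cfg$latent_dim)),
      input_dim = as.integer(input_dim), cfg = cfg,
      opt = list(enc = NULL, dec = NULL, disc = NULL),
      epoch = 0L, n_disc_steps = 0L, n_gen_steps = 0L,
      trace = data.frame(
        epoch = integer(), recon_loss = numeric(),
        disc_loss = numeric(), gen_loss = numeric()
      )
    ),
    class = "aae_state"
  )
}

# Encoder forward: MLP followed by non-affine batch standardization of the
# latent code (running statistics at eval time). Standardizing the latent
# pins its per-dimension first moments to the prior's and prevents the
# adversarial game from chasing unbounded mean/scale drift; the
# discriminator shapes the remaining structure.
enc_forward <- function(X, enc, buffers, train = FALSE) {
  mf <- mlp_forward(X, enc)
  d <- ncol(mf$out)
  bn <- bn_forward(mf$out, gamma = rep(1, d), beta = rep(0, d), buffers, train)
  list(z = bn$Y, mf = mf, bn = bn, buffers = bn$buffers)
}

enc_backward <- function(dz, fwd, enc) {
  d <- ncol(dz)
  b <- bn_backward(dz, fwd$bn, gamma = rep(1, d))
  mlp_backward(b$dX, fwd$mf, enc)
}

#' Encode features to latent codes
#'
#' Deterministic feed-forward mapping through the encoder network.
#'
#' @param x feature vector or batch matrix (rows = samples).
#' @param state an `aae_state`.
#' @return batch x latent_dim matrix of codes, order-preserving.
#' @export
encode <- function(x, state) {
  X <- if (is.null(dim(x))) matrix(x, 1L) else as.matrix(x)
  if (ncol(X) != state$input_dim) stop("feature width does not match encoder input")
  enc_forward(X, state$enc, state$enc_buffers, train = FALSE)$z
}

#' Decode latent codes to reconstructions
#'
#' @param z latent vector or batch matrix.
#' @param state an `aae_state`.
#' @return batch x input_dim matrix of reconstructions.
#' @export
decode <- function(z, state) {
  Z <- if (is.null(dim(z))) matrix(z, 1L) else as.matrix(z)
  if (ncol(Z) != state$cfg$latent_dim) stop("latent width does not match decoder input")
  mlp_forward(Z, state$dec)$out
}

#' One reconstruction step (encoder + decoder)
#'
#' Gradient step on the mean squared reconstruction error (the
#' Gaussian-likelihood reading of the negative log-likelihood objective),
#' updating encoder and decoder with RMSprop.
#'
#' @param batch batch matrix of features.
#' @param state an `aae_state`.
#' @param lr,weight_decay optional overrides of the config optimizer values.
#' @return List `(state, loss)` with the pre-update loss.
#' @export
reconstruction_step <- function(batch, state, lr = NULL, weight_decay = NULL) {
  X <- as.matrix(batch)
  if (nrow(X) == 0L) stop("empty batch")
  lr <- if (is.null(lr)) state$cfg$lr else lr
  wd <- if (is.null(weight_decay)) state$cfg$weight_decay else weight_decay
  ef <- enc_forward(X, state$enc, state$enc_buffers, train = TRUE)
  state$enc_buffers <- ef$buffers
  df <- mlp_forward(ef$z, state$dec)
  err <- df$out - X
  loss <- mean(err^2)
  if (!is.finite(loss)) stop("non-finite reconstruction loss")
  dxhat <- 2 * err / length(err)
  dec_bk <- mlp_backward(dxhat, df, state$dec)
  enc_bk <- enc_backward(dec_bk$dX, ef, state$enc)
  up <- rmsprop_step(state$dec, dec_bk$grads, state$opt$dec, lr, weight_decay = wd)
  state$dec <- up$p; state$opt$dec <- up$c
  up <- rmsprop_step(state$enc, enc_bk$grads, state$opt$enc, lr, weight_decay = wd)
  state$enc <- up$p; state$opt$enc <- up$c
  list(state = state, loss = loss)
}

# Discriminator cross-entropy on a prior batch (label 1) and a posterior
# batch (label 0): mean over samples of -log d(z_p) - log(1 - d(z_q)).
disc_loss_value <- function(d_prior, d_post) {
  mean(-log(clip_prob(d_prior))) + mean(-log(1 - clip_prob(d_post)))
}

#' One discriminator step
#'
#' Draws a standard-normal prior batch matched to the input batch size,
#' encodes the input with the (frozen) encoder, and takes one RMSprop step
#' on the discriminator cross-entropy
#' \eqn{-\log d(z_{prior}) - \log(1 - d(z_{post}))}.
#'
#' @inheritParams reconstruction_step
#' @return List `(state, loss)`.
#' @export
discriminator_step <- function(batch, state, lr = NULL, weight_decay = NULL) {
  X <- as.matrix(batch)
  if (nrow(X) == 0L) stop("empty batch")
  lr <- if (is.null(lr)) state$cfg$lr else lr
  wd <- if (is.null(weight_decay)) state$cfg$weight_decay else weight_decay
  n <- nrow(X)
  ef <- enc_forward(X, state$enc, state$enc_buffers, train = TRUE)
  state$enc_buffers <- ef$buffers
  zq <- ef$z
  zp <- matrix(stats::rnorm(n * state$cfg$latent_dim), n, state$cfg$latent_dim)
  fp <- mlp_forward(zp, state$disc)
  fq <- mlp_forward(zq, state$disc)
  dp <- clip_prob(fp$out)
  dq <- clip_prob(fq$out)
  loss <- disc_loss_value(dp, dq)
  if (!is.finite(loss)) stop("non-finite discriminator loss")
  # d/d dp of mean(-log dp) ; d/d dq of mean(-log(1-dq))
  gp <- -1 / (dp * n)
  gq <- 1 / ((1 - dq) * n)
  bp <- mlp_backward(gp, fp, state$disc)
  bq <- mlp_backward(gq, fq, state$disc)
  grads <- list(layers = Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                             bp$grads$layers, bq$grads$layers))
  up <- rmsprop_step(state$disc, grads, state$opt$disc, lr, weight_decay = wd)
  state$disc <- up$p; state$opt$disc <- up$c
  list(state = state, loss = loss)
}

#' One generator (encoder) step
#'
#' Non-saturating adversarial update: one RMSprop step on the encoder
#' minimizing \eqn{-\log d(q(z))} with the discriminator frozen.
#'
#' @inheritParams reconstruction_step
#' @return List `(state, loss)`.
#' @export
generator_step <- function(batch, state, lr = NULL, weight_decay = NULL) {
  X <- as.matrix(batch)
  if (nrow(X) == 0L) stop("empty batch")
  lr <- if (is.null(lr)) state$cfg$lr else lr
  wd <- if (is.null(weight_decay)) state$cfg$weight_decay else weight_decay
  n <- nrow(X)
  ef <- enc_forward(X, state$enc, state$enc_buffers, train = TRUE)
  state$enc_buffers <- ef$buffers
  fd <- mlp_forward(ef$z, state$disc)
  dq <- clip_prob(fd$out)
  loss <- mean(-log(dq))
  if (!is.finite(loss)) stop("non-finite generator loss")
  gdq <- -1 / (dq * n)
  disc_bk <- mlp_backward(gdq, fd, state$disc) # discriminator frozen; only dX used
  enc_bk <- enc_backward(disc_bk$dX, ef, state$enc)
  up <- rmsprop_step(state$enc, enc_bk$grads, state$opt$enc, lr, weight_decay = wd)
  state$enc <- up$p; state$opt$enc <- up$c
  list(state = state, loss = loss)
}

#' Train an adversarial autoencoder
#'
#' Alternates a reconstruction phase and a regularization phase per
#' minibatch: one reconstruction step always; then, unless
#' `no_discriminator`, one discriminator step and an accumulator-scheduled
#' number of generator steps so that the long-run generator:discriminator
#' step ratio equals `cfg$train_ratio`.
#'
#' @param features matrix of training features (rows = samples).
#' @param cfg an [aae_config()].
#' @param no_discriminator if `TRUE` the adversarial phase is skipped and
#'   the model degrades to a plain autoencoder (ablation variant).
#' @return A trained `aae_state` with per-epoch loss traces in `$trace`.
#' @export
train_aae <- function(features, cfg = aae_config(), no_discriminator = FALSE) {
  X <- as.matrix(features)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  state <- aae_init(ncol(X), cfg)
  acc <- 0
  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(nrow(X))
      starts <- seq(1L, nrow(X), by = cfg$batch_size)
      rl <- dl <- gl <- c()
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, nrow(X))]
        if (length(idx) < 2L) next # latent standardization needs >= 2 samples
        B <- X[idx, , drop = FALSE]
        r <- reconstruction_step(B, state)
        state <- r$state
        rl <- c(rl, r$loss)
        if (!no_discriminator) {
          d <- discriminator_step(B, state)
          state <- d$state
          state$n_disc_steps <- state$n_disc_steps + 1L
          dl <- c(dl, d$loss)
          acc <- acc + cfg$train_ratio
          while (acc >= 1) {
            g <- generator_step(B, state)
            state <- g$state
            state$n_gen_steps <- state$n_gen_steps + 1L
            gl <- c(gl, g$loss)
            acc <- acc - 1
          }
        }
        if (max(r$loss, 0) > 1e6) stop("AAE training diverged (loss > 1e6)")
      }
      state$epoch <- epoch
      state$trace <- rbind(state$trace, data.frame(
        epoch = epoch,
        recon_loss = mean(rl),
        disc_loss = if (length(dl)) mean(dl) else NA_real_,
        gen_loss = if (length(gl)) mean(gl) else NA_real_
      ))
    }
  })
  # re-estimate the latent standardization statistics over the full training
  # set with the final encoder (removes the lag of the running averages)
  h <- mlp_forward(X, state$enc)$out
  state$enc_buffers <- list(
    rmean = colMeans(h),
    rvar = colMeans(sweep(h, 2L, colMeans(h))^2)
  )
  state
}

# Energy distance between two samples (rows = observations); used as a
# prior-matching diagnostic for the latent distribution.
energy_distance <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  cross <- mean(sqrt(pmax(outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y), 0)))
  within <- function(M) {
    D2 <- outer(rowSums(M^2), rowSums(M^2), `+`) - 2 * tcrossprod(M)
    mean(sqrt(pmax(D2, 0)))
  }
  2 * cross - within(X) - within(Y)
}
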