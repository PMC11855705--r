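#' Deep classifier configuration
#'
#' Fully connected layers with batch normalization and dropout after each
#' hidden layer, followed by a sigmoid output unit producing the association
#' probability.
#'
#' @param hidden_layers hidden widths.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param batch_norm apply batch normalization after each hidden layer.
#' @param threshold classification threshold; `p >= threshold` is called
#'   positive (the tie at the threshold is positive).
#' @return An object of class `dnn_config`.
#' @export
dnn_config <- function(hidden_layers = c(128L, 64L), dropout_rate = 0.3,
                       batch_norm = TRUE, threshold = 0.5) {
  stopifnot(all(hidden_layers >= 1L), dropout_rate >= 0, dropout_rate < 1,
            threshold > 0, threshold < 1)
  structure(
    list(
      hidden_layers = as.integer(hidden_layers),
      dropout_rate = dropout_rate,
      batch_norm = isTRUE(batch_norm),
      threshold = threshold
    ),
    class = "dnn_config"
  )
}

dnn_init <- function(input_dim, cfg) {
  sizes <- c(input_dim, cfg$hidden_layers)
  hidden <- vector("list", length(cfg$hidden_layers))
  for (i in seq_along(cfg$hidden_layers)) {
    hidden[[i]] <- list(
      W = xavier_matrix(sizes[i], sizes[i + 1L]),
      b = rep(0, sizes[i + 1L]),
      gamma = rep(1, sizes[i + 1L]),
      beta = rep(0, sizes[i + 1L])
    )
  }
  out <- list(W = xavier_matrix(sizes[length(sizes)], 1L), b = 0)
  buffers <- lapply(cfg$hidden_layers, function(w) list(rmean = rep(0, w), rvar = rep(1, w)))
  list(hidden = hidden, out = out, buffers = buffers, input_dim = as.integer(input_dim))
}

# Forward with caches. In training mode batch statistics and fresh dropout
# masks are used (and running stats updated); in eval mode running stats are
# used and dropout is the identity, making predictions deterministic and
# batch-composition invariant.
dnn_forward_cached <- function(X, params, cfg, train = FALSE) {
  caches <- vector("list", length(params$hidden))
  H <- X
  for (i in seq_along(params$hidden)) {
    ly <- params$hidden[[i]]
    lin <- dense_forward(H, ly$W, ly$b)
    if (cfg$batch_norm) {
      bn <- bn_forward(lin, ly$gamma, ly$beta, params$buffers[[i]], train)
      params$buffers[[i]] <- bn$buffers
      a <- act_forward(bn$Y, "relu")
      dp <- dropout_forward(a, cfg$dropout_rate, train)
      caches[[i]] <- list(X = H, lin = lin, bn = bn, act = a, mask = dp$mask)
      H <- dp$Y
    } else {
      a <- act_forward(lin, "relu")
      dp <- dropout_forward(a, cfg$dropout_rate, train)
      caches[[i]] <- list(X = H, lin = lin, bn = NULL, act = a, mask = dp$mask)
      H <- dp$Y
    }
  }
  logit <- dense_forward(H, params$out$W, params$out$b)
  p <- act_forward(logit, "sigmoid")
  list(p = as.vector(p), H = H, p_mat = p, caches = caches, buffers = params$buffers)
}

dnn_backward <- function(dp, fwd, params, cfg) {
  # dp: gradient w.r.t. the probability output (batch x 1)
  dlogit <- act_backward(dp, fwd$p_mat, "sigmoid")
  out_bk <- dense_backward(dlogit, fwd$H, params$out$W)
  grads_hidden <- vector("list", length(params$hidden))
  d <- out_bk$dX
  for (i in rev(seq_along(params$hidden))) {
    cache <- fwd$caches[[i]]
    ly <- params$hidden[[i]]
    d <- dropout_backward(d, cache$mask)
    da <- act_backward(d, cache$act, "relu")
    if (cfg$batch_norm) {
      bnb <- bn_backward(da, cache$bn, ly$gamma)
      dlin <- bnb$dX
      g_extra <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    } else {
      dlin <- da
      g_extra <- list(gamma = NULL, beta = NULL)
    }
    dn <- dense_backward(dlin, cache$X, ly$W)
    grads_hidden[[i]] <- c(list(W = dn$dW, b = dn$db), g_extra)
    d <- dn$dX
  }
  list(
    dX = d,
    grads = list(hidden = grads_hidden, out = list(W = out_bk$dW, b = out_bk$db))
  )
}

#' Deep classifier forward pass
#'
#' Maps refined pair features to association probabilities. Runs in eval
#' mode: dropout off, batch normalization on running statistics, so repeated
#' calls on the same input give identical output.
#'
#' @param feature feature vector or batch matrix.
#' @param cfg a [dnn_config()].
#' @param params classifier parameters (internal structure from training);
#'   freshly initialized when omitted.
#' @return Vector of probabilities in `(0, 1)`, with attribute `"params"`.
#' @export
dnn_forward <- function(feature, cfg = dnn_config(), params = NULL) {
  X <- if (is.null(dim(feature))) matrix(feature, 1L) else as.matrix(feature)
  if (is.null(params)) params <- dnn_init(ncol(X), cfg)
  if (ncol(X) != params$input_dim) stop("feature width does not match classifier input")
  p <- dnn_forward_cached(X, params, cfg, train = FALSE)$p
  attr(p, "params") <- params
  p
}

#' Mean binary cross-entropy
#'
#' \deqn{L = -\frac{1}{N}\sum_i [y_i \log p_i + (1-y_i) \log(1-p_i)]}
#' Probabilities are clipped to `[1e-7, 1 - 1e-7]` to avoid `log(0)`.
#'
#' @param p predicted probabilities.
#' @param y binary labels.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(p, y) {
  if (length(p) != length(y)) stop("probability and label vectors differ in length")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  p <- clip_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Threshold probabilities into hard labels
#'
#' @param p probabilities in `[0, 1]`.
#' @param threshold classification threshold; `p >= threshold` maps to 1.
#' @return Integer 0/1 vector.
#' @export
classify <- function(p, threshold = 0.5) {
  as.integer(p >= threshold)
}

#' Full pipeline configuration
#'
#' Bundles the sub-model configurations and training settings, with the
#' optimizer defaults used throughout (RMSprop, learning rate 1e-4, weight
#' decay 1e-4, Xavier initialization) and the ablation switches.
#'
#' @param mscnn an [mscnn_config()].
#' @param aae an [aae_config()].
#' @param dnn a [dnn_config()].
#' @param epochs,batch_size training schedule for the end-to-end model.
#' @param lr,weight_decay RMSprop settings.
#' @param dnn_input `"latent"` feeds the encoder output to the classifier;
#'   `"reconstruction"` feeds the decoder output.
#' @param no_mscnn,no_encoder,no_discriminator ablation switches: bypass the
#'   multi-scale extractor (raw similarity concatenation), drop the
#'   autoencoder entirely (classifier consumes extractor output), or train
#'   the autoencoder without its adversarial phase.
#' @param gip_leakage_guard recompute GIP kernels from training-fold
#'   associations only during cross-validation.
#' @param seed integer seed for all randomness in a run.
#' @return An object of class `cdaae_config`.
#' @export
cdaae_config <- function(mscnn = mscnn_config(), aae = aae_config(),
                         dnn = dnn_config(), epochs = 40L, batch_size = 64L,
                         lr = 1e-4, weight_decay = 1e-4,
                         dnn_input = c("latent", "reconstruction"),
                         no_mscnn = FALSE, no_encoder = FALSE,
                         no_discriminator = FALSE, gip_leakage_guard = TRUE,
                         seed = 1L) {
  structure(
    list(
      mscnn = mscnn, aae = aae, dnn = dnn,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      lr = lr, weight_decay = weight_decay,
      dnn_input = match.arg(dnn_input),
      no_mscnn = isTRUE(no_mscnn), no_encoder = isTRUE(no_encoder),
      no_discriminator = isTRUE(no_discriminator),
      gip_leakage_guard = isTRUE(gip_leakage_guard),
      seed = as.integer(seed)
    ),
    class = "cdaae_config"
  )
}

# Forward pass through extractor (+ autoencoder) to classifier input.
# Returns classifier input plus all caches needed for the joint backward.
pipeline_forward <- function(C, D, model, train = FALSE) {
  cfg <- model$config
  if (cfg$no_mscnn) {
    x <- mscnn_bypass(C, D)
    mcache <- NULL
  } else {
    mf <- mscnn_forward_cached(C, D, model$mscnn, cfg$mscnn)
    x <- mf$out
    mcache <- mf
  }
  if (cfg$no_encoder) {
    return(list(x = x, mcache = mcache, ef = NULL, df = NULL, dnn_in = x))
  }
  ef <- enc_forward(x, model$aae$enc, model$aae$enc_buffers, train = train)
  df <- mlp_forward(ef$z, model$aae$dec)
  dnn_in <- if (cfg$dnn_input == "latent") ef$z else df$out
  list(x = x, mcache = mcache, ef = ef, df = df, dnn_in = dnn_in,
       enc_buffers = ef$buffers)
}

#' Train the full association model end-to-end
#'
#' Joint optimization of the multi-scale extractor, the adversarial
#' autoencoder and the deep classifier. Per minibatch: one RMSprop step on
#' the combined loss (binary cross-entropy + mean squared reconstruction
#' error, unit weights) through classifier, autoencoder and extractor; then,
#' unless disabled, the adversarial phase (discriminator step + scheduled
#' generator steps on the encoder). Deterministic for a fixed seed.
#'
#' @param SC,SD fused [similarity_matrix()] objects.
#' @param train_pairs balanced pair data.frame (see [sample_negatives()]).
#' @param config a [cdaae_config()].
#' @return A `cdaae_model` checkpoint: parameters, batch-norm buffers,
#'   config, and per-epoch loss traces.
#' @export
train_model <- function(SC, SD, train_pairs, config = cdaae_config()) {
  feats <- build_pair_features(SC, SD, train_pairs)
  y <- train_pairs$label
  M <- ncol(feats$C); N <- ncol(feats$D)
  cfg <- config
  feat_dim <- if (cfg$no_mscnn) M + N else 2L * cfg$mscnn$fc_dim
  dnn_in_dim <- if (cfg$no_encoder) feat_dim
                else if (cfg$dnn_input == "latent") cfg$aae$latent_dim
                else feat_dim
  model <- withr::with_seed(cfg$seed, {
    m <- list(config = cfg)
    if (!cfg$no_mscnn) m$mscnn <- mscnn_init(M, N, cfg$mscnn)
    if (!cfg$no_encoder) {
      m$aae <- list(
        enc = mlp_init(c(feat_dim, cfg$aae$encoder_hidden, cfg$aae$latent_dim),
                       c("relu", "linear")),
        dec = mlp_init(c(cfg$aae$latent_dim, cfg$aae$decoder_hidden, feat_dim),
                       c("relu", "linear")),
        disc = mlp_init(c(cfg$aae$latent_dim, cfg$aae$disc_hidden, 1L),
                        c("relu", "sigmoid")),
        enc_buffers = list(rmean = rep(0, cfg$aae$latent_dim),
                           rvar = rep(1, cfg$aae$latent_dim))
      )
    }
    m$dnn <- dnn_init(dnn_in_dim, cfg$dnn)
    m
  })
  opt <- list(mscnn = NULL, enc = NULL, dec = NULL, disc = NULL, dnn = NULL)
  trace <- data.frame(
    epoch = integer(), bce = numeric(), recon = numeric(),
    disc = numeric(), gen = numeric()
  )
  acc <- 0
  n <- nrow(feats$C)
  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      bl <- rl <- dl <- gl <- c()
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        if (length(idx) < 2L) next # batch-norm needs >= 2 samples
        C <- feats$C[idx, , drop = FALSE]
        D <- feats$D[idx, , drop = FALSE]
        yb <- y[idx]
        st <- joint_step(C, D, yb, model, opt)
        model <- st$model; opt <- st$opt
        bl <- c(bl, st$bce); rl <- c(rl, st$recon)
        if (!is.finite(st$bce) || st$bce > 1e6) stop("training diverged")
        if (!cfg$no_encoder && !cfg$no_discriminator) {
          adv <- adversarial_phase(st$x_detached, model, opt)
          model <- adv$model; opt <- adv$opt
          dl <- c(dl, adv$disc_loss)
          acc <- acc + cfg$aae$train_ratio
          while (acc >= 1) {
            gen <- generator_phase(st$x_detached, model, opt)
            model <- gen$model; opt <- gen$opt
            gl <- c(gl, gen$gen_loss)
            acc <- acc - 1
          }
        }
      }
      trace <- rbind(trace, data.frame(
        epoch = epoch,
        bce = mean(bl),
        recon = if (length(rl)) mean(rl) else NA_real_,
        disc = if (length(dl)) mean(dl) else NA_real_,
        gen = if (length(gl)) mean(gl) else NA_real_
      ))
    }
  })
  model$trace <- trace
  model$dims <- c(M = M, N = N)
  model <- refresh_bn_stats(model, feats$C, feats$D)
  class(model) <- "cdaae_model"
  model
}

# Replace all batch-normalization running statistics with population
# statistics of the final parameters over the full training set, removing
# the lag of the momentum averages behind the last parameter updates.
refresh_bn_stats <- function(model, C, D) {
  cfg <- model$config
  x <- if (cfg$no_mscnn) {
    mscnn_bypass(C, D)
  } else {
    mscnn_forward_cached(C, D, model$mscnn, cfg$mscnn)$out
  }
  pop <- function(M) list(rmean = colMeans(M), rvar = colMeans(sweep(M, 2L, colMeans(M))^2))
  if (!cfg$no_encoder) {
    h <- mlp_forward(x, model$aae$enc)$out
    model$aae$enc_buffers <- pop(h)
    ef <- enc_forward(x, model$aae$enc, model$aae$enc_buffers, train = FALSE)
    dnn_in <- if (cfg$dnn_input == "latent") ef$z else mlp_forward(ef$z, model$aae$dec)$out
  } else {
    dnn_in <- x
  }
  if (cfg$dnn$batch_norm) {
    H <- dnn_in
    for (i in seq_along(model$dnn$hidden)) {
      ly <- model$dnn$hidden[[i]]
      lin <- dense_forward(H, ly$W, ly$b)
      model$dnn$buffers[[i]] <- pop(lin)
      bn <- bn_forward(lin, ly$gamma, ly$beta, model$dnn$buffers[[i]], train = FALSE)
      H <- act_forward(bn$Y, "relu") # dropout off: population statistics
    }
  }
  model
}

# One combined BCE + reconstruction RMSprop step over all non-discriminator
# parameters. Returns the updated model/optimizer plus the batch's extractor
# output (treated as data by the adversarial phase).
joint_step <- function(C, D, yb, model, opt) {
  cfg <- model$config
  fw <- pipeline_forward(C, D, model, train = TRUE)
  if (!cfg$no_encoder) model$aae$enc_buffers <- fw$enc_buffers
  df_dnn <- dnn_forward_cached(fw$dnn_in, model$dnn, cfg$dnn, train = TRUE)
  model$dnn$buffers <- df_dnn$buffers
  p <- clip_prob(df_dnn$p)
  bce <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
  # d BCE / d p (through the clip's identity region)
  nb <- length(yb)
  dp <- matrix((p - yb) / (p * (1 - p)) / nb, ncol = 1L)
  dnn_bk <- dnn_backward(dp, df_dnn, model$dnn, cfg$dnn)
  recon <- NA_real_
  dx <- NULL
  grads_enc <- grads_dec <- NULL
  if (cfg$no_encoder) {
    dx <- dnn_bk$dX
  } else {
    err <- fw$df$out - fw$x # reconstruction target = extractor output, detached
    recon <- mean(err^2)
    dxhat <- 2 * err / length(err)
    if (cfg$dnn_input == "reconstruction") dxhat <- dxhat + dnn_bk$dX
    dec_bk <- mlp_backward(dxhat, fw$df, model$aae$dec)
    dz <- dec_bk$dX
    if (cfg$dnn_input == "latent") dz <- dz + dnn_bk$dX
    enc_bk <- enc_backward(dz, fw$ef, model$aae$enc)
    grads_enc <- enc_bk$grads
    grads_dec <- dec_bk$grads
    dx <- enc_bk$dX
  }
  lr <- cfg$lr; wd <- cfg$weight_decay
  if (!cfg$no_mscnn) {
    m_bk <- mscnn_backward(dx, fw$mcache, model$mscnn, cfg$mscnn)
    up <- rmsprop_step(model$mscnn, m_bk$grads, opt$mscnn, lr, weight_decay = wd)
    model$mscnn <- up$p; opt$mscnn <- up$c
  }
  if (!cfg$no_encoder) {
    up <- rmsprop_step(model$aae$enc, grads_enc, opt$enc, lr, weight_decay = wd)
    model$aae$enc <- up$p; opt$enc <- up$c
    up <- rmsprop_step(model$aae$dec, grads_dec, opt$dec, lr, weight_decay = wd)
    model$aae$dec <- up$p; opt$dec <- up$c
  }
  up <- rmsprop_step(
    list(hidden = model$dnn$hidden, out = model$dnn$out),
    list(hidden = dnn_bk$grads$hidden, out = dnn_bk$grads$out),
    opt$dnn, lr, weight_decay = wd
  )
  model$dnn$hidden <- up$p$hidden; model$dnn$out <- up$p$out; opt$dnn <- up$c
  list(model = model, opt = opt, bce = bce, recon = recon, x_detached = fw$x)
}

adversarial_phase <- function(x, model, opt) {
  cfg <- model$config
  n <- nrow(x)
  ef <- enc_forward(x, model$aae$enc, model$aae$enc_buffers, train = TRUE)
  model$aae$enc_buffers <- ef$buffers
  zq <- ef$z
  zp <- matrix(stats::rnorm(n * cfg$aae$latent_dim), n, cfg$aae$latent_dim)
  fp <- mlp_forward(zp, model$aae$disc)
  fq <- mlp_forward(zq, model$aae$disc)
  dpv <- clip_prob(fp$out); dqv <- clip_prob(fq$out)
  loss <- mean(-log(dpv)) + mean(-log(1 - dqv))
  bp <- mlp_backward(-1 / (dpv * n), fp, model$aae$disc)
  bq <- mlp_backward(1 / ((1 - dqv) * n), fq, model$aae$disc)
  grads <- list(layers = Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                             bp$grads$layers, bq$grads$layers))
  up <- rmsprop_step(model$aae$disc, grads, opt$disc, cfg$lr, weight_decay = cfg$weight_decay)
  model$aae$disc <- up$p; opt$disc <- up$c
  list(model = model, opt = opt, disc_loss = loss)
}

generator_phase <- function(x, model, opt) {
  cfg <- model$config
  n <- nrow(x)
  ef <- enc_forward(x, model$aae$enc, model$aae$enc_buffers, train = TRUE)
  model$aae$enc_buffers <- ef$buffers
  fd <- mlp_forward(ef$z, model$aae$disc)
  dqv <- clip_prob(fd$out)
  loss <- mean(-log(dqv))
  disc_bk <- mlp_backward(-1 / (dqv * n), fd, model$aae$disc)
  enc_bk <- enc_backward(disc_bk$dX, ef, model$aae$enc)
  up <- rmsprop_step(model$aae$enc, enc_bk$grads, opt$enc, cfg$lr,
                     weight_decay = cfg$weight_decay)
  model$aae$enc <- up$p; opt$enc <- up$c
  list(model = model, opt = opt, gen_loss = loss)
}

#' Score circRNA-drug pairs with a trained model
#'
#' Eval-mode forward pass (deterministic; dropout off, batch normalization
#' on running statistics). Results are ranked by descending probability with
#' ties broken lexicographically by `(circ_id, drug_id)`.
#'
#' @param model a trained `cdaae_model` from [train_model()].
#' @param SC,SD the fused similarity matrices the model was trained against.
#' @param pairs pair data.frame with 0-based `circ_index`, `drug_index` (a
#'   `label` column, when present, is carried through).
#' @return data.frame `circ_id, drug_id, score, label, rank` sorted by rank.
#' @export
predict_pairs <- function(model, SC, SD, pairs) {
  stopifnot(inherits(model, "cdaae_model"))
  if (ncol(SC$S) != model$dims["M"] || ncol(SD$S) != model$dims["N"]) {
    stop("similarity matrices do not match the trained model's dimensions")
  }
  feats <- build_pair_features(SC, SD, pairs)
  fw <- pipeline_forward(feats$C, feats$D, model, train = FALSE)
  p <- dnn_forward_cached(fw$dnn_in, model$dnn, model$config$dnn, train = FALSE)$p
  out <- data.frame(
    circ_id = SC$ids[pairs$circ_index + 1L],
    drug_id = SD$ids[pairs$drug_index + 1L],
    score = p,
    label = classify(p, model$config$dnn$threshold),
    stringsAsFactors = FALSE
  )
  if (!is.null(pairs$label)) out$true_label <- pairs$label
  ord <- order(-out$score, out$circ_id, out$drug_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
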