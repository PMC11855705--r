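# Run-level configuration: YAML file + overrides -> cdaae_config and
# sub-configs, with unknown keys rejected.

.config_sections <- c("mscnn", "aae", "dnn", "simulate", "training", "evaluation")

default_run_config <- function() {
  list(
    seed = 1L,
    mscnn = unclass(mscnn_config()),
    aae = unclass(aae_config()),
    dnn = unclass(dnn_config()),
    simulate = unclass(sim_config()),
    training = list(
      epochs = 40L, batch_size = 64L, lr = 1e-4, weight_decay = 1e-4,
      dnn_input = "latent", no_mscnn = FALSE, no_encoder = FALSE,
      no_discriminator = FALSE, gip_leakage_guard = TRUE
    ),
    evaluation = list(k = 5L, blind_fraction = 0.2, blind_repeats = 5L)
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Defaults reflect the published training setup where stated (kernel sizes
#' 3/5/7, encoder:discriminator ratio 1:1, RMSprop learning rate 1e-4,
#' weight decay 1e-4, classification threshold 0.5, blind fraction 0.2 with
#' 5 repeats); a YAML file and an override list are merged on top, in that
#' order. Unknown keys are rejected.
#'
#' @param path optional YAML file.
#' @param overrides optional named list merged last (highest precedence).
#' @return Full nested configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) {
    cfg <- merge_config(cfg, overrides)
  }
  cfg
}

# Materialize the S3 config objects from a run-config list.
as_model_config <- function(rc) {
  cdaae_config(
    mscnn = do.call(mscnn_config, rc$mscnn[c("kernel_sizes", "filters_per_scale", "fc_dim", "activation")]),
    aae = do.call(aae_config, rc$aae[setdiff(names(rc$aae), character(0))]),
    dnn = do.call(dnn_config, rc$dnn[c("hidden_layers", "dropout_rate", "batch_norm", "threshold")]),
    epochs = rc$training$epochs, batch_size = rc$training$batch_size,
    lr = rc$training$lr, weight_decay = rc$training$weight_decay,
    dnn_input = rc$training$dnn_input,
    no_mscnn = rc$training$no_mscnn, no_encoder = rc$training$no_encoder,
    no_discriminator = rc$training$no_discriminator,
    gip_leakage_guard = rc$training$gip_leakage_guard,
    seed = rc$seed
  )
}

as_sim_config <- function(rc) {
  args <- rc$simulate
  args$seed <- rc$seed
  do.call(sim_config, args)
}
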