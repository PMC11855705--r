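#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return Named vector `c(TP, FP, TN, FN)`; the four counts partition the
#'   input length.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("inputs must be binary 0/1 vectors")
  }
  c(
    TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FN = sum(y_true == 1 & y_pred == 0)
  )
}

#' Threshold classification metrics from confusion counts
#'
#' Precision = TP/(TP+FP), recall (TPR) = TP/(TP+FN), specificity =
#' TN/(TN+FP), accuracy = (TP+TN)/N, F1 = 2PR/(P+R). Zero-denominator cases
#' return 0 with a warning.
#'
#' @param TP,FP,TN,FN non-negative counts.
#' @return Named list with `precision`, `recall`, `specificity`,
#'   `accuracy`, `f1`.
#' @export
binary_metrics <- function(TP, FP, TN, FN) {
  counts <- c(TP, FP, TN, FN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator), returning 0")
      0
    } else {
      num / den
    }
  }
  precision <- safe_div(TP, TP + FP, "precision")
  recall <- safe_div(TP, TP + FN, "recall")
  specificity <- safe_div(TN, TN + FP, "specificity")
  accuracy <- safe_div(TP + TN, sum(counts), "accuracy")
  f1 <- if (precision + recall == 0) {
    warning("F1 undefined (precision + recall = 0), returning 0")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, specificity = specificity,
       accuracy = accuracy, f1 = f1)
}

#' Area under the ROC curve (exact rank statistic)
#'
#' Computed as the normalized Mann-Whitney U statistic with midrank tie
#' handling: the probability that a random positive outscores a random
#' negative, ties counting one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("ROC AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-curve summation \eqn{\sum_k (R_k - R_{k-1}) P_k} over descending
#' unique score thresholds, i.e. average precision. Tied scores enter the
#' curve as a single step.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return Average precision in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("PR AUC requires at least one positive")
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  tp <- 0; pp <- 0
  for (t in thr) {
    sel <- scores == t
    tp <- tp + sum(labels[sel] == 1)
    pp <- pp + sum(sel)
    r <- tp / n_pos
    p <- tp / pp
    ap <- ap + (r - r_prev) * p
    r_prev <- r
  }
  ap
}

metric_row <- function(scores, labels, threshold = 0.5) {
  cm <- confusion_counts(labels, classify(scores, threshold))
  bm <- suppressWarnings(binary_metrics(cm["TP"], cm["FP"], cm["TN"], cm["FN"]))
  data.frame(
    auc = roc_auc(scores, labels),
    aupr = pr_auc(scores, labels),
    f1 = bm$f1, accuracy = bm$accuracy, recall = bm$recall,
    specificity = bm$specificity, precision = bm$precision
  )
}

#' Assemble a dataset bundle for the evaluation protocols
#'
#' @param assoc an [association_matrix()].
#' @param seqs a [sequence_set()] aligned with `assoc$circ_ids`.
#' @param fps a [fingerprint_set()] aligned with `assoc$drug_ids`.
#' @return A `cdaae_dataset` list; sequence and structure similarities are
#'   precomputed once (they do not depend on association labels), GIP
#'   kernels are recomputed per protocol with the leakage guard.
#' @export
cdaae_dataset <- function(assoc, seqs, fps) {
  structure(
    list(
      assoc = assoc, seqs = seqs, fps = fps,
      SSC = sequence_similarity_matrix(seqs),
      SSD = drug_similarity_matrix(fps)
    ),
    class = "cdaae_dataset"
  )
}

# Fused similarities for a training view of the associations. When `mask`
# is non-NULL its positive pairs are removed from A first (leakage guard).
fused_for_training <- function(dataset, mask = NULL) {
  assoc <- dataset$assoc
  if (!is.null(mask)) assoc <- mask_test_associations(assoc, mask)
  list(
    SC = fuse_similarity(dataset$SSC, gip_kernel(assoc, "circRNA")),
    SD = fuse_similarity(dataset$SSD, gip_kernel(assoc, "drug")),
    assoc_used = assoc
  )
}

#' k-fold cross-validation of the full pipeline
#'
#' Balanced pairs are split into stratified folds; for every fold a model is
#' trained on the remaining folds and evaluated on the held-out fold at the
#' classification threshold. With the leakage guard on (default), the GIP
#' kernels for each fold are recomputed from the association matrix with the
#' test fold's positives zeroed.
#'
#' @param dataset a [cdaae_dataset()].
#' @param k number of folds (5 and 10 are the standard protocols).
#' @param config a [cdaae_config()].
#' @param pairs optional prebuilt pair set with a `fold` column; built from
#'   `config$seed` when omitted.
#' @return A `metrics_report`: per-fold metric rows, their mean and sd, and
#'   the pooled scores.
#' @export
run_cv <- function(dataset, k = 5L, config = cdaae_config(), pairs = NULL) {
  stopifnot(inherits(dataset, "cdaae_dataset"))
  if (is.null(pairs)) {
    pairs <- sample_negatives(dataset$assoc, seed = config$seed)
    pairs <- make_cv_folds(pairs, k = k, seed = config$seed)
  }
  stopifnot("fold" %in% names(pairs))
  per_fold <- vector("list", k)
  pooled <- data.frame(score = numeric(), label = integer(), fold = integer())
  for (f in seq_len(k) - 1L) {
    test <- pairs[pairs$fold == f, , drop = FALSE]
    train <- pairs[pairs$fold != f, , drop = FALSE]
    sims <- fused_for_training(dataset, mask = if (config$gip_leakage_guard) test else NULL)
    fold_cfg <- config
    fold_cfg$seed <- config$seed + f
    model <- train_model(sims$SC, sims$SD, train, fold_cfg)
    pred <- predict_pairs(model, sims$SC, sims$SD, test)
    per_fold[[f + 1L]] <- metric_row(pred$score, pred$true_label, config$dnn$threshold)
    pooled <- rbind(pooled, data.frame(score = pred$score, label = pred$true_label, fold = f))
  }
  folds_df <- do.call(rbind, per_fold)
  folds_df <- cbind(fold = seq_len(k) - 1L, folds_df)
  structure(
    list(
      protocol = paste0(k, "cv"),
      folds = folds_df,
      mean = colMeans(folds_df[, -1L]),
      sd = apply(folds_df[, -1L], 2L, stats::sd),
      pooled = pooled
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report %s> %d folds/repeats\n", x$protocol, nrow(x$folds)))
  m <- x$mean; s <- x$sd
  for (nm in names(m)) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", nm, m[nm], s[nm]))
  }
  invisible(x)
}

#' Repeated blind-test evaluation
#'
#' Per repeat: a fresh blind split isolates `fraction` of the balanced pairs
#' before anything else; the model is trained on the remaining development
#' pairs (GIP kernels computed with the blind positives masked) and
#' evaluated once on the untouched blind set. Metrics are averaged over
#' repeats.
#'
#' @param dataset a [cdaae_dataset()].
#' @param fraction blind fraction (default 0.2).
#' @param repeats number of independent splits (default 5).
#' @param config a [cdaae_config()].
#' @return A `metrics_report` with one row per repeat.
#' @export
run_blind <- function(dataset, fraction = 0.2, repeats = 5L, config = cdaae_config()) {
  stopifnot(inherits(dataset, "cdaae_dataset"))
  rows <- vector("list", repeats)
  pooled <- data.frame(score = numeric(), label = integer(), fold = integer())
  for (r in seq_len(repeats)) {
    pairs <- sample_negatives(dataset$assoc, seed = config$seed + 1000L * r)
    sp <- make_blind_split(pairs, fraction, seed = config$seed + 1000L * r)
    sims <- fused_for_training(dataset, mask = if (config$gip_leakage_guard) sp$blind else NULL)
    rep_cfg <- config
    rep_cfg$seed <- config$seed + r
    model <- train_model(sims$SC, sims$SD, sp$dev, rep_cfg)
    pred <- predict_pairs(model, sims$SC, sims$SD, sp$blind)
    rows[[r]] <- metric_row(pred$score, pred$true_label, config$dnn$threshold)
    pooled <- rbind(pooled, data.frame(score = pred$score, label = pred$true_label, fold = r))
  }
  folds_df <- cbind(fold = seq_len(repeats), do.call(rbind, rows))
  structure(
    list(
      protocol = "blind",
      folds = folds_df,
      mean = colMeans(folds_df[, -1L]),
      sd = apply(folds_df[, -1L], 2L, stats::sd),
      pooled = pooled
    ),
    class = "metrics_report"
  )
}

#' Write a metrics report to CSV
#'
#' One row per fold/repeat with columns
#' `protocol, fold, auc, aupr, f1, accuracy, recall, specificity, precision`.
#'
#' @param report a `metrics_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  df <- cbind(protocol = report$protocol, report$folds)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
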