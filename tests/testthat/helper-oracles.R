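# Independent brute-force oracles frozen into the test suite. These stay
# deliberately naive (recursion, full enumeration) so they cannot share a
# code path with the implementation they check.

# Unit-cost Levenshtein by plain recursion (exponential; strings <= 6 only).
lev_recursive <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(
    lev_recursive(substr(a, 2, nchar(a)), b) + 1L,
    lev_recursive(a, substr(b, 2, nchar(b))) + 1L,
    lev_recursive(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost
  )
}

# AUC by all-pairs concordance counting (ties get half credit).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Average precision by explicit threshold sweep over the unique scores.
ap_bruteforce <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  for (t in thresholds) {
    pred_pos <- scores >= t
    tp <- sum(labels[pred_pos] == 1)
    precision <- tp / sum(pred_pos)
    recall <- tp / n_pos
    ap <- ap + (recall - r_prev) * precision
    r_prev <- recall
  }
  ap
}

# All strings of length 0..max_len over an alphabet.
all_strings <- function(alphabet, max_len) {
  out <- ""
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# Small deterministic fixture: dataset + fused similarities + balanced pairs.
tiny_sim_fixture <- function(seed = 42L, n_circ = 20L, n_drug = 16L) {
  cfg <- sim_config(
    n_circ = n_circ, n_drug = n_drug, n_clusters = 2L,
    seq_len_range = c(40L, 60L), fp_bits = 64L, seed = seed
  )
  sim <- simulate_dataset(cfg)
  ds <- cdaae_dataset(sim$assoc, sim$seqs, sim$fps)
  sims <- cdaae:::fused_for_training(ds)
  pairs <- sample_negatives(sim$assoc, seed = seed)
  list(cfg = cfg, sim = sim, ds = ds, sims = sims, pairs = pairs)
}

# Random feature batch in [0, 1] for network-level tests.
random_features <- function(n, d, seed = 1L) {
  withr::with_seed(seed, matrix(stats::runif(n * d), n, d))
}
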