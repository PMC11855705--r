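#' Synthetic dataset configuration
#'
#' The generator plants the statistical structure the similarity-fusion
#' pipeline assumes: entities fall into latent clusters; cluster members
#' descend from a common ancestral sequence / fingerprint by point mutation,
#' so similar circRNAs (and similar drugs) share associations, and the
#' association matrix has Bernoulli block structure with a higher
#' within-cluster rate.
#'
#' @param n_circ,n_drug numbers of circRNAs and drugs.
#' @param n_clusters number of latent clusters (entities are assigned
#'   round-robin, so every cluster is populated on both axes).
#' @param seq_len_range ancestral sequence length range (uniform draw).
#' @param fp_bits fingerprint width.
#' @param within_cluster_assoc_prob,between_cluster_assoc_prob association
#'   probabilities for co-clustered / non-co-clustered pairs.
#' @param mutation_rate per-position mutation probability for sequences and
#'   bit-flip probability for fingerprints.
#' @param seed integer seed; identical configs generate identical data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_circ = 60L, n_drug = 50L, n_clusters = 4L,
                       seq_len_range = c(200L, 400L), fp_bits = 256L,
                       within_cluster_assoc_prob = 0.35,
                       between_cluster_assoc_prob = 0.03,
                       mutation_rate = 0.05, seed = 1L) {
  stopifnot(
    n_circ >= 2L, n_drug >= 2L, n_clusters >= 1L,
    within_cluster_assoc_prob > between_cluster_assoc_prob,
    within_cluster_assoc_prob <= 1, between_cluster_assoc_prob >= 0,
    mutation_rate >= 0, mutation_rate <= 1
  )
  structure(
    list(
      n_circ = as.integer(n_circ), n_drug = as.integer(n_drug),
      n_clusters = as.integer(n_clusters),
      seq_len_range = as.integer(seq_len_range), fp_bits = as.integer(fp_bits),
      within_cluster_assoc_prob = within_cluster_assoc_prob,
      between_cluster_assoc_prob = between_cluster_assoc_prob,
      mutation_rate = mutation_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

mutate_sequence <- function(seq_chars, rate) {
  n <- length(seq_chars)
  hit <- stats::runif(n) < rate
  if (any(hit)) {
    # substitute with a uniformly drawn different base
    repl <- vapply(seq_chars[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    seq_chars[hit] <- repl
  }
  seq_chars
}

#' Generate a synthetic circRNA-drug dataset with planted structure
#'
#' Per cluster one ancestral sequence and one ancestral fingerprint are
#' drawn; members are derived by point mutations / bit flips at
#' `mutation_rate`. Associations are Bernoulli draws whose rate depends on
#' cluster co-membership. Every circRNA and every drug is guaranteed at
#' least one association (so no interaction profile is all-zero): the matrix
#' is redrawn a bounded number of times and, failing that, each empty
#' row/column receives one association drawn proportional to its generating
#' rates.
#'
#' @param cfg a [sim_config()].
#' @return List with `seqs` ([sequence_set()]), `fps` ([fingerprint_set()]),
#'   `assoc` ([association_matrix()]), and the ground-truth cluster labels
#'   `circ_cluster`, `drug_cluster`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    circ_cluster <- ((seq_len(cfg$n_circ) - 1L) %% cfg$n_clusters) + 1L
    drug_cluster <- ((seq_len(cfg$n_drug) - 1L) %% cfg$n_clusters) + 1L
    anc_seq <- lapply(seq_len(cfg$n_clusters), function(i) {
      len <- sample(seq(cfg$seq_len_range[1L], cfg$seq_len_range[2L]), 1L)
      sample(c("A", "C", "G", "T"), len, replace = TRUE)
    })
    anc_fp <- lapply(seq_len(cfg$n_clusters), function(i) {
      as.integer(stats::runif(cfg$fp_bits) < 0.3)
    })
    seqs <- vapply(seq_len(cfg$n_circ), function(i) {
      paste(mutate_sequence(anc_seq[[circ_cluster[i]]], cfg$mutation_rate), collapse = "")
    }, character(1))
    fps <- t(vapply(seq_len(cfg$n_drug), function(j) {
      fp <- anc_fp[[drug_cluster[j]]]
      flip <- stats::runif(cfg$fp_bits) < cfg$mutation_rate
      as.integer(xor(fp, flip))
    }, integer(cfg$fp_bits)))
    P <- ifelse(
      outer(circ_cluster, drug_cluster, `==`),
      cfg$within_cluster_assoc_prob, cfg$between_cluster_assoc_prob
    )
    A <- NULL
    for (try in seq_len(20L)) {
      cand <- matrix(as.integer(stats::runif(length(P)) < P), nrow(P), ncol(P))
      if (all(rowSums(cand) > 0L) && all(colSums(cand) > 0L)) {
        A <- cand
        break
      }
    }
    if (is.null(A)) {
      # small matrices rarely achieve coverage by redrawing alone: give each
      # empty row/column one association drawn proportional to its rates
      A <- cand
      for (i in which(rowSums(A) == 0L)) {
        A[i, sample.int(ncol(A), 1L, prob = P[i, ])] <- 1L
      }
      for (j in which(colSums(A) == 0L)) {
        A[sample.int(nrow(A), 1L, prob = P[, j]), j] <- 1L
      }
    }
    list(
      seqs = sequence_set(sprintf("circ%03d", seq_len(cfg$n_circ)), seqs),
      fps = fingerprint_set(sprintf("drug%03d", seq_len(cfg$n_drug)), fps),
      assoc = association_matrix(
        A,
        sprintf("circ%03d", seq_len(cfg$n_circ)),
        sprintf("drug%03d", seq_len(cfg$n_drug))
      ),
      circ_cluster = circ_cluster,
      drug_cluster = drug_cluster
    )
  })
}

#' Write a simulated dataset in the real-data file formats
#'
#' Emits exactly what the real-data path consumes: a FASTA of host-gene
#' sequences, a fingerprint TSV, and an association edge-list TSV.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    sequences = file.path(dir, "sequences.fasta"),
    fingerprints = file.path(dir, "fingerprints.tsv"),
    associations = file.path(dir, "associations.tsv")
  )
  write_sequences_fasta(sim$seqs, paths["sequences"])
  write_fingerprint_tsv(sim$fps, paths["fingerprints"])
  write_association_tsv(sim$assoc, paths["associations"], "edges")
  invisible(paths)
}

#' AUC of the cluster-membership oracle on a simulated dataset
#'
#' Scores every pair (or a supplied pair subset) by the generating
#' probability (within- vs between-cluster rate) and computes the ROC AUC
#' against the realized associations. This is the ceiling any learned
#' scorer can approach on the planted structure and calibrates acceptance
#' bands for end-to-end training.
#'
#' @param sim output of [simulate_dataset()].
#' @param cfg the [sim_config()] that generated it.
#' @param pairs optional pair data.frame with `circ_index`, `drug_index`,
#'   `label`; all matrix entries are used when omitted.
#' @return Oracle AUC.
#' @export
planted_auc_ceiling <- function(sim, cfg, pairs = NULL) {
  co <- outer(sim$circ_cluster, sim$drug_cluster, `==`)
  score_mat <- ifelse(co, cfg$within_cluster_assoc_prob, cfg$between_cluster_assoc_prob)
  if (is.null(pairs)) {
    roc_auc(as.vector(score_mat), as.vector(sim$assoc$A))
  } else {
    idx <- cbind(pairs$circ_index + 1L, pairs$drug_index + 1L)
    roc_auc(score_mat[idx], pairs$label)
  }
}
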