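#' Balanced negative sampling of unobserved pairs
#'
#' Draws `n` distinct zero entries of the association matrix uniformly
#' without replacement. Combined with all positive entries this yields the
#' balanced 1:1 training set used throughout.
#'
#' @param assoc an [association_matrix()].
#' @param n number of negatives; defaults to the number of positives.
#' @param seed integer seed; the draw is deterministic given `(assoc, n, seed)`.
#' @return A pair data.frame with columns `circ_index`, `drug_index`
#'   (0-based), `label` (1 for every known association, 0 for sampled
#'   negatives).
#' @export
sample_negatives <- function(assoc, n = NULL, seed = 1L) {
  stopifnot(inherits(assoc, "association_matrix"))
  zeros <- which(assoc$A == 0L)
  ones <- which(assoc$A == 1L)
  if (is.null(n)) n <- length(ones)
  if (n > length(zeros)) {
    stop("requested ", n, " negatives but only ", length(zeros), " zero entries exist")
  }
  picked <- withr::with_seed(seed, zeros[sample.int(length(zeros), n)])
  M <- nrow(assoc$A)
  to_df <- function(lin, label) {
    data.frame(
      circ_index = (lin - 1L) %% M,
      drug_index = (lin - 1L) %/% M,
      label = label
    )
  }
  out <- rbind(to_df(ones, 1L), to_df(picked, 0L))
  rownames(out) <- NULL
  out
}

#' Stratified k-fold assignment for a balanced pair set
#'
#' Positives and negatives are shuffled and partitioned independently into
#' `k` near-equal folds (per-class fold sizes differ by at most one), so
#' every fold preserves the 1:1 class balance.
#'
#' @param pairs pair data.frame (see [sample_negatives()]).
#' @param k number of folds.
#' @param seed integer seed.
#' @return `pairs` with an added integer `fold` column in `0:(k-1)`.
#' @export
make_cv_folds <- function(pairs, k = 5L, seed = 1L) {
  stopifnot(is.data.frame(pairs), k >= 2L)
  n_pos <- sum(pairs$label == 1L)
  n_neg <- sum(pairs$label == 0L)
  if (k > min(n_pos, n_neg)) {
    stop("k = ", k, " exceeds the size of the smaller class (", min(n_pos, n_neg), ")")
  }
  assign_folds <- function(idx) {
    perm <- sample(idx)
    # deal round-robin so fold sizes differ by <= 1
    folds <- (seq_along(perm) - 1L) %% k
    stats::setNames(folds, perm)
  }
  fold <- integer(nrow(pairs))
  withr::with_seed(seed, {
    fp <- assign_folds(which(pairs$label == 1L))
    fn <- assign_folds(which(pairs$label == 0L))
  })
  fold[as.integer(names(fp))] <- unname(fp)
  fold[as.integer(names(fn))] <- unname(fn)
  pairs$fold <- fold
  pairs
}

#' Isolate a blind test split
#'
#' Removes `round(fraction * nrow(pairs))` pairs, drawn uniformly, before
#' any training or tuning; the remainder is the development set.
#'
#' @param pairs pair data.frame.
#' @param fraction blind fraction in (0, 1); default 0.2.
#' @param seed integer seed.
#' @return List with data.frames `dev` and `blind` (disjoint, union =
#'   input), each tagged with a `split` column.
#' @export
make_blind_split <- function(pairs, fraction = 0.2, seed = 1L) {
  stopifnot(is.data.frame(pairs), fraction > 0, fraction < 1)
  if (nrow(pairs) == 0L) stop("empty pair set")
  n_blind <- round(fraction * nrow(pairs))
  take <- withr::with_seed(seed, sample(nrow(pairs), n_blind))
  blind <- pairs[take, , drop = FALSE]
  dev <- pairs[-take, , drop = FALSE]
  blind$split <- "blind"
  dev$split <- "train"
  rownames(blind) <- rownames(dev) <- NULL
  list(dev = dev, blind = blind)
}

#' Per-pair similarity feature vectors
#'
#' The feature representation of a pair is the circRNA's row of the fused
#' circRNA similarity matrix together with the drug's row of the fused drug
#' similarity matrix.
#'
#' @param SC,SD fused [similarity_matrix()] objects.
#' @param pairs pair data.frame with 0-based `circ_index`, `drug_index`.
#' @return List with matrices `C` (pairs x M) and `D` (pairs x N); row `i`
#'   holds the feature vectors of pair `i`.
#' @export
build_pair_features <- function(SC, SD, pairs) {
  stopifnot(inherits(SC, "similarity_matrix"), inherits(SD, "similarity_matrix"))
  ci <- pairs$circ_index + 1L
  di <- pairs$drug_index + 1L
  if (any(ci < 1L) || any(ci > nrow(SC$S))) stop("circRNA index out of bounds")
  if (any(di < 1L) || any(di > nrow(SD$S))) stop("drug index out of bounds")
  list(C = SC$S[ci, , drop = FALSE], D = SD$S[di, , drop = FALSE])
}

#' Mask test-fold associations out of an association matrix
#'
#' Returns a copy of `assoc` with the positive entries of the given pairs
#' zeroed. Used by the leakage guard: GIP kernels for a CV fold are computed
#' from the training associations only.
#'
#' @param assoc an [association_matrix()].
#' @param test_pairs pair data.frame whose label-1 rows are hidden.
#' @return A masked [association_matrix()].
#' @export
mask_test_associations <- function(assoc, test_pairs) {
  stopifnot(inherits(assoc, "association_matrix"))
  A <- assoc$A
  pos <- test_pairs[test_pairs$label == 1L, , drop = FALSE]
  if (nrow(pos)) {
    A[cbind(pos$circ_index + 1L, pos$drug_index + 1L)] <- 0L
  }
  association_matrix(A, assoc$circ_ids, assoc$drug_ids)
}

#' Write / read a split manifest TSV
#'
#' Manifests record `circ_id, drug_id, label, fold, split` and make a run
#' exactly reproducible.
#'
#' @param pairs pair data.frame (optionally with `fold` / `split` columns).
#' @param assoc the [association_matrix()] supplying id lookups.
#' @param path file path.
#' @return `path` (writer) or a pair data.frame (reader).
#' @export
write_split_manifest <- function(pairs, assoc, path) {
  df <- data.frame(
    circ_id = assoc$circ_ids[pairs$circ_index + 1L],
    drug_id = assoc$drug_ids[pairs$drug_index + 1L],
    label = pairs$label,
    fold = if ("fold" %in% names(pairs)) pairs$fold else NA_integer_,
    split = if ("split" %in% names(pairs)) pairs$split else NA_character_,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path, assoc) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(
    circ_index = match(df$circ_id, assoc$circ_ids) - 1L,
    drug_index = match(df$drug_id, assoc$drug_ids) - 1L,
    label = as.integer(df$label)
  )
  if (anyNA(out$circ_index) || anyNA(out$drug_index)) {
    stop("manifest refers to ids absent from the association matrix")
  }
  if (!all(is.na(df$fold))) out$fold <- as.integer(df$fold)
  if (!all(is.na(df$split))) out$split <- df$split
  out
}
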