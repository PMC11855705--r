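#' Levenshtein edit distance between two sequences
#'
#' Unit-cost edit distance (insertions, deletions and substitutions all cost
#' 1), the minimum number of single-character edits transforming one string
#' into the other. Symmetric and satisfies the triangle inequality.
#'
#' @param a,b character strings (may be empty).
#' @return Non-negative integer distance.
#' @export
#' @examples
#' edit_distance("ACGT", "ACGT") # 0
#' edit_distance("AAAA", "CCCC") # 4
edit_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  as.integer(utils::adist(a, b))
}

#' Sequence similarity matrix from normalized edit distance
#'
#' For circRNAs \eqn{c_i, c_j} with host-gene sequences of lengths
#' \eqn{len(c_i)}, \eqn{len(c_j)}:
#' \deqn{SSC_{ij} = 1 - \frac{trans(c_i, c_j)}{len(c_i) + len(c_j)}}
#' where \eqn{trans} is the Levenshtein distance. Because an edit script can
#' never exceed deleting one string and inserting the other,
#' \eqn{trans \le len(c_i)+len(c_j)} and the similarity lies in `(0, 1]` for
#' non-empty sequences.
#'
#' @param seqs a [sequence_set()].
#' @return A [similarity_matrix()] with role `"SSC"`.
#' @export
sequence_similarity_matrix <- function(seqs) {
  stopifnot(inherits(seqs, "sequence_set"))
  n <- length(seqs$ids)
  lens <- nchar(seqs$seqs)
  D <- utils::adist(seqs$seqs) # full Levenshtein distance matrix
  S <- 1 - D / outer(lens, lens, `+`)
  similarity_matrix(S, seqs$ids, "SSC")
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' \eqn{|a \cap b| / |a \cup b|} over the set bits. Two all-zero vectors are
#' defined to be maximally similar (1.0) with a warning; the ratio 0/0 is
#' otherwise undefined.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.integer(a != 0)
  b <- as.integer(b != 0)
  union <- sum(a | b)
  if (union == 0L) {
    warning("Tanimoto of two all-zero fingerprints defined as 1")
    return(1)
  }
  sum(a & b) / union
}

#' Drug structural similarity matrix (pairwise Tanimoto)
#'
#' @param fps a [fingerprint_set()].
#' @return A [similarity_matrix()] with role `"SSD"`.
#' @export
drug_similarity_matrix <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  B <- fps$bits
  n <- nrow(B)
  popcount <- rowSums(B)
  inter <- tcrossprod(B)                      # |a AND b|
  uni <- outer(popcount, popcount, `+`) - inter # |a OR b|
  if (any(popcount == 0)) {
    warning(
      "all-zero fingerprint(s), Tanimoto with another all-zero vector defined as 1: ",
      paste(fps$ids[popcount == 0], collapse = ", ")
    )
  }
  S <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  similarity_matrix(S, fps$ids, "SSD")
}

#' Topological fingerprints from SMILES
#'
#' Computes deterministic path-based (Daylight-style) topological binary
#' fingerprints with the OpenBabel FP2 fingerprinter via ChemmineR /
#' ChemmineOB. FP2 hashes all linear fragments of up to 7 atoms into 1024
#' bits; other widths are obtained by OR-folding (`n_bits` must divide 1024)
#' or zero-padding is refused.
#'
#' Callers with precomputed fingerprints can bypass this entirely and build a
#' [fingerprint_set()] directly (see [read_fingerprint_tsv()]).
#'
#' @param drug_ids character vector of unique drug identifiers.
#' @param smiles character vector of SMILES strings, same length.
#' @param n_bits fingerprint width; 1024 (native) or a divisor of 1024.
#' @return A [fingerprint_set()].
#' @export
smiles_to_fingerprints <- function(drug_ids, smiles, n_bits = 1024L) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("smiles_to_fingerprints requires the ChemmineR and ChemmineOB packages")
  }
  drug_ids <- as.character(drug_ids)
  smiles <- as.character(smiles)
  stopifnot(length(drug_ids) == length(smiles))
  if (n_bits < 1L || 1024L %% n_bits != 0L) {
    stop("`n_bits` must be 1024 or a divisor of 1024 (fingerprint folding)")
  }
  names(smiles) <- drug_ids
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || !all(ChemmineR::validSDF(sdf))) {
    # identify the offending molecules one at a time
    bad <- vapply(seq_along(smiles), function(i) {
      s <- tryCatch(
        suppressWarnings(ChemmineR::smiles2sdf(smiles[i])),
        error = function(e) NULL
      )
      is.null(s) || !all(ChemmineR::validSDF(s))
    }, logical(1))
    stop("unparsable SMILES for drug id(s): ", paste(drug_ids[bad], collapse = ", "))
  }
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  M <- as.matrix(fp@fpma)
  storage.mode(M) <- "integer"
  if (n_bits < 1024L) {
    # OR-fold: bit j of the folded vector is the OR over positions j, j+n_bits, ...
    M <- t(apply(M, 1L, function(row) {
      as.integer(colSums(matrix(row, ncol = n_bits, byrow = TRUE)) > 0)
    }))
  }
  fingerprint_set(drug_ids, M)
}

#' Gaussian interaction-profile (GIP) kernel similarity
#'
#' The interaction profile \eqn{IP(c_i)} of a circRNA is row `i` of the
#' binary association matrix; the profile of a drug is the corresponding
#' column. The kernel is
#' \deqn{GS_{ij} = \exp(-\eta \, \|IP_i - IP_j\|^2)}
#' with bandwidth normalized by the mean squared profile norm,
#' \eqn{\eta = \eta' / \left(\frac{1}{n}\sum_k \|IP_k\|^2\right)}.
#'
#' @param assoc an [association_matrix()].
#' @param axis `"circRNA"` (profiles = rows, role `GSC`) or `"drug"`
#'   (profiles = columns, role `GSD`).
#' @param eta_prime raw bandwidth \eqn{\eta'} (default 1).
#' @return A [similarity_matrix()] with role `"GSC"` or `"GSD"`.
#' @export
gip_kernel <- function(assoc, axis = c("circRNA", "drug"), eta_prime = 1) {
  stopifnot(inherits(assoc, "association_matrix"), eta_prime > 0)
  axis <- match.arg(axis)
  P <- if (axis == "circRNA") assoc$A else t(assoc$A)
  ids <- if (axis == "circRNA") assoc$circ_ids else assoc$drug_ids
  role <- if (axis == "circRNA") "GSC" else "GSD"
  sqnorm <- rowSums(P^2)
  msq <- mean(sqnorm)
  if (msq == 0) {
    stop("all interaction profiles along axis '", axis, "' are zero; GIP bandwidth undefined")
  }
  eta <- eta_prime / msq
  # squared Euclidean distances between profiles
  D2 <- outer(sqnorm, sqnorm, `+`) - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0 # numerical floor
  S <- exp(-eta * D2)
  similarity_matrix(S, ids, role)
}

#' Fuse a base similarity matrix with a GIP kernel
#'
#' Elementwise: where the base (sequence or structure) similarity is nonzero
#' the fused value is the arithmetic mean of the two matrices, otherwise the
#' GIP value is used alone:
#' \deqn{S_{ij} = \begin{cases}(SS_{ij} + GS_{ij})/2 & SS_{ij} \neq 0\\ GS_{ij} & \text{otherwise}\end{cases}}
#'
#' @param SS base [similarity_matrix()] (role `SSC` or `SSD`).
#' @param GS GIP [similarity_matrix()] (role `GSC` or `GSD`) over the same
#'   ids in the same order.
#' @return A fused [similarity_matrix()] with role `"SC"` (circRNA) or
#'   `"SD"` (drug), inferred from the inputs' roles.
#' @export
fuse_similarity <- function(SS, GS) {
  stopifnot(inherits(SS, "similarity_matrix"), inherits(GS, "similarity_matrix"))
  if (!identical(dim(SS$S), dim(GS$S)) || !identical(SS$ids, GS$ids)) {
    stop("similarity matrices to fuse must share shape and id ordering")
  }
  role <- if (SS$role %in% c("SSC", "GSC") || GS$role %in% c("GSC", "SSC")) "SC" else "SD"
  S <- ifelse(SS$S != 0, (SS$S + GS$S) / 2, GS$S)
  similarity_matrix(S, SS$ids, role)
}

#' Build both fused similarity matrices for a dataset
#'
#' Convenience wrapper: sequence similarity + circRNA GIP kernel fused into
#' `SC`; fingerprint Tanimoto + drug GIP kernel fused into `SD`. Ids in
#' `seqs` / `fps` must match the association matrix axes (same order).
#'
#' @param seqs a [sequence_set()] aligned with `assoc$circ_ids`.
#' @param fps a [fingerprint_set()] aligned with `assoc$drug_ids`.
#' @param assoc an [association_matrix()]; pass a training-fold-masked copy
#'   during cross-validation to avoid test-label leakage into the kernels.
#' @param eta_prime_circ,eta_prime_drug GIP raw bandwidths (default 1).
#' @return List with elements `SC` and `SD` ([similarity_matrix()] objects).
#' @export
build_fused_similarities <- function(seqs, fps, assoc,
                                     eta_prime_circ = 1, eta_prime_drug = 1) {
  if (!identical(seqs$ids, assoc$circ_ids)) {
    stop("sequence ids must match association matrix circRNA ids (same order)")
  }
  if (!identical(fps$ids, assoc$drug_ids)) {
    stop("fingerprint ids must match association matrix drug ids (same order)")
  }
  SSC <- sequence_similarity_matrix(seqs)
  SSD <- drug_similarity_matrix(fps)
  GSC <- gip_kernel(assoc, "circRNA", eta_prime_circ)
  GSD <- gip_kernel(assoc, "drug", eta_prime_drug)
  list(SC = fuse_similarity(SSC, GSC), SD = fuse_similarity(SSD, GSD))
}
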