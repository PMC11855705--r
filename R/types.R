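#' Construct a set of circRNA host-gene sequences
#'
#' An ordered, ID-indexed collection of nucleotide sequences. Sequences are
#' uppercased on construction; characters outside `A`, `C`, `G`, `T` (for
#' example `N`) are kept as literal symbols and flagged with a warning, since
#' the edit-distance machinery treats any mismatch with unit cost.
#'
#' @param ids character vector of unique identifiers.
#' @param seqs character vector of non-empty nucleotide strings, same length
#'   as `ids`.
#' @return An object of class `sequence_set` with elements `ids` and `seqs`.
#' @export
sequence_set <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("`ids` and `seqs` must have the same length")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for id(s): ", paste(ids[empty], collapse = ", "))
  }
  odd <- grepl("[^ACGT]", seqs)
  if (any(odd)) {
    warning(
      "sequences contain characters outside {A,C,G,T} (kept literally): ",
      paste(utils::head(ids[odd], 5L), collapse = ", ")
    )
  }
  structure(list(ids = ids, seqs = seqs), class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf(
    "<sequence_set> %d sequences, lengths %d-%d\n",
    length(x$ids), min(nchar(x$seqs)), max(nchar(x$seqs))
  ))
  invisible(x)
}

#' @export
length.sequence_set <- function(x) length(x$ids)

#' Construct a set of drug fingerprints
#'
#' Fixed-length binary structural fingerprints, one row per drug.
#'
#' @param ids character vector of unique drug identifiers.
#' @param bits 0/1 matrix with `length(ids)` rows; columns are fingerprint
#'   bits (all rows the same length by construction).
#' @return An object of class `fingerprint_set` with elements `ids` and
#'   `bits` (integer matrix, rownames set to `ids`).
#' @export
fingerprint_set <- function(ids, bits) {
  ids <- as.character(ids)
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (nrow(bits) != length(ids)) {
    stop("`bits` must have one row per id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate drug ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (ncol(bits) < 1L) stop("fingerprints must have at least one bit")
  if (!all(bits %in% c(0L, 1L))) stop("fingerprint entries must be 0 or 1")
  rownames(bits) <- ids
  structure(list(ids = ids, bits = bits), class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf(
    "<fingerprint_set> %d drugs x %d bits (density %.3f)\n",
    nrow(x$bits), ncol(x$bits), mean(x$bits)
  ))
  invisible(x)
}

#' @export
length.fingerprint_set <- function(x) length(x$ids)

#' Construct a binary circRNA-drug association matrix
#'
#' Rows are circRNAs, columns are drugs; entry `A[i, j] = 1` records a known
#' association between circRNA `i` and the sensitivity of drug `j`. Row `i`
#' is the interaction profile of circRNA `i`, column `j` that of drug `j`.
#'
#' @param A 0/1 matrix (at least 2 x 2, as required by the interaction-profile
#'   kernels).
#' @param circ_ids,drug_ids unique identifiers for the rows / columns.
#' @return An object of class `association_matrix`.
#' @export
association_matrix <- function(A, circ_ids, drug_ids) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  circ_ids <- as.character(circ_ids)
  drug_ids <- as.character(drug_ids)
  if (nrow(A) != length(circ_ids) || ncol(A) != length(drug_ids)) {
    stop("dimensions of `A` must match id lists")
  }
  if (anyDuplicated(circ_ids) || anyDuplicated(drug_ids)) {
    stop("association matrix ids must be unique")
  }
  if (nrow(A) < 2L || ncol(A) < 2L) {
    stop("association matrix must be at least 2 x 2")
  }
  if (!all(A %in% c(0L, 1L))) stop("association entries must be 0 or 1")
  dimnames(A) <- list(circ_ids, drug_ids)
  structure(
    list(A = A, circ_ids = circ_ids, drug_ids = drug_ids),
    class = "association_matrix"
  )
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf(
    "<association_matrix> %d circRNAs x %d drugs, %d associations (density %.4f)\n",
    nrow(x$A), ncol(x$A), sum(x$A), mean(x$A)
  ))
  invisible(x)
}

#' @export
dim.association_matrix <- function(x) dim(x$A)

.sim_roles <- c("SSC", "SSD", "GSC", "GSD", "SC", "SD")

#' Construct a similarity matrix
#'
#' Square symmetric matrix with entries in `[0, 1]` and unit diagonal. The
#' `role` tag records which of the six similarity matrices of the pipeline it
#' holds: sequence (`SSC`), drug structure (`SSD`), the two
#' Gaussian-interaction-profile kernels (`GSC`, `GSD`), or the fused
#' matrices (`SC`, `SD`).
#'
#' @param S numeric square matrix.
#' @param ids identifiers for the rows/columns.
#' @param role one of `"SSC"`, `"SSD"`, `"GSC"`, `"GSD"`, `"SC"`, `"SD"`.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(S, ids, role) {
  S <- as.matrix(S)
  ids <- as.character(ids)
  role <- match.arg(role, .sim_roles)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (nrow(S) != length(ids)) stop("id list must match matrix dimension")
  if (anyDuplicated(ids)) stop("similarity matrix ids must be unique")
  if (max(abs(S - t(S))) > 1e-9) stop("similarity matrix must be symmetric (tol 1e-9)")
  if (min(S) < -1e-12 || max(S) > 1 + 1e-12) {
    stop("similarity entries must lie in [0, 1]")
  }
  if (max(abs(diag(S) - 1)) > 1e-12) stop("similarity diagonal must equal 1")
  # exact symmetrization so downstream checks at 1e-9 always hold
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  structure(list(S = S, ids = ids, role = role), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$S[upper.tri(x$S)]
  cat(sprintf(
    "<similarity_matrix %s> %d x %d, off-diagonal range [%.4f, %.4f]\n",
    x$role, nrow(x$S), ncol(x$S),
    if (length(off)) min(off) else NA_real_,
    if (length(off)) max(off) else NA_real_
  ))
  invisible(x)
}

#' @export
dim.similarity_matrix <- function(x) dim(x$S)
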