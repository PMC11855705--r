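#' Read circRNA host-gene sequences from a FASTA file
#'
#' Ids are the first whitespace-delimited token of each header line.
#'
#' @param path FASTA file path.
#' @return A [sequence_set()].
#' @export
read_sequences_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    return(sequence_set(ids, as.character(ss)))
  }
  # minimal fallback parser (Biostrings is a Suggests dependency)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers found in ", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(
    split(lines[!hdr], grp[!hdr]),
    function(x) paste(x, collapse = ""), character(1)
  )
  sequence_set(ids, seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs a [sequence_set()].
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_sequences_fasta <- function(seqs, path, width = 70L) {
  stopifnot(inherits(seqs, "sequence_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs$ids)) {
    writeLines(paste0(">", seqs$ids[i]), con)
    s <- seqs$seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read drug fingerprints from TSV
#'
#' Two layouts are accepted: a `drug_id` column plus one 0/1 column per bit,
#' or a `drug_id` column plus a single `bits` column holding the fingerprint
#' as a 0/1 string.
#'
#' @param path TSV file path.
#' @return A [fingerprint_set()].
#' @export
read_fingerprint_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"drug_id" %in% names(df)) stop("fingerprint TSV must have a `drug_id` column")
  if ("bits" %in% names(df) && ncol(df) == 2L) {
    bits <- do.call(rbind, lapply(strsplit(df$bits, ""), as.integer))
  } else {
    bits <- vapply(df[setdiff(names(df), "drug_id")], as.integer,
                   integer(nrow(df)))
  }
  fingerprint_set(df$drug_id, bits)
}

#' Write drug fingerprints to TSV (bitstring layout)
#'
#' @param fps a [fingerprint_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_tsv <- function(fps, path) {
  stopifnot(inherits(fps, "fingerprint_set"))
  df <- data.frame(
    drug_id = fps$ids,
    bits = apply(fps$bits, 1L, paste, collapse = ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug id / SMILES table from TSV
#'
#' @param path TSV with columns `drug_id` and `smiles`.
#' @return data.frame with columns `drug_id`, `smiles`.
#' @export
read_smiles_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("drug_id", "smiles") %in% names(df))) {
    stop("SMILES TSV must have columns `drug_id` and `smiles`")
  }
  df[, c("drug_id", "smiles")]
}

#' Read associations from a TSV edge list or dense matrix
#'
#' An edge list has columns `circ_id` and `drug_id` (one known association
#' per row); a dense file has a header row of drug ids and a first column of
#' circRNA ids with 0/1 entries. The layout is auto-detected from the
#' header.
#'
#' @param path TSV file path.
#' @param circ_ids,drug_ids for the edge-list layout, the full axis id
#'   vectors (needed because entities without associations would otherwise
#'   be dropped). Ignored for the dense layout.
#' @return An [association_matrix()].
#' @export
read_association_tsv <- function(path, circ_ids = NULL, drug_ids = NULL) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (identical(hdr[1:2], c("circ_id", "drug_id"))) {
    edges <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    if (is.null(circ_ids)) circ_ids <- sort(unique(edges$circ_id))
    if (is.null(drug_ids)) drug_ids <- sort(unique(edges$drug_id))
    bad_c <- setdiff(edges$circ_id, circ_ids)
    bad_d <- setdiff(edges$drug_id, drug_ids)
    if (length(bad_c) || length(bad_d)) {
      stop("edge list refers to unknown ids: ", paste(c(bad_c, bad_d), collapse = ", "))
    }
    A <- matrix(0L, length(circ_ids), length(drug_ids))
    A[cbind(match(edges$circ_id, circ_ids), match(edges$drug_id, drug_ids))] <- 1L
    association_matrix(A, circ_ids, drug_ids)
  } else {
    M <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
    association_matrix(as.matrix(M), rownames(M), colnames(M))
  }
}

#' Write associations to TSV
#'
#' @param assoc an [association_matrix()].
#' @param path output path.
#' @param format `"edges"` (edge list of the 1-entries) or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_association_tsv <- function(assoc, path, format = c("edges", "dense")) {
  stopifnot(inherits(assoc, "association_matrix"))
  format <- match.arg(format)
  if (format == "edges") {
    idx <- which(assoc$A == 1L, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    df <- data.frame(
      circ_id = assoc$circ_ids[idx[, 1L]],
      drug_id = assoc$drug_ids[idx[, 2L]],
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(
      data.frame(circ_id = assoc$circ_ids, assoc$A, check.names = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' Write / read a similarity matrix as dense TSV
#'
#' Full-precision round trip: values are written with 17 significant digits
#' so read-after-write reproduces the matrix to well below 1e-12.
#'
#' @param sim a [similarity_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(paste0("#role:", sim$role), sim$ids), collapse = "\t"), con)
  for (i in seq_along(sim$ids)) {
    writeLines(
      paste(c(sim$ids[i], formatC(sim$S[i, ], format = "g", digits = 17)),
            collapse = "\t"),
      con
    )
  }
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], "\t")[[1]]
  role <- sub("^#role:", "", hdr[1L])
  ids <- hdr[-1L]
  body <- strsplit(lines[-1L], "\t")
  S <- do.call(rbind, lapply(body, function(x) as.numeric(x[-1L])))
  row_ids <- vapply(body, `[`, character(1), 1L)
  if (!identical(row_ids, ids)) stop("similarity TSV row/column ids disagree")
  similarity_matrix(S, ids, role)
}
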