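#' Construct a paired multiple sequence alignment
#'
#' A paired (concatenated) MSA holds equal-length rows over the 21-state
#' alphabet together with the boundary `n_a`: the number of leading columns
#' belonging to protein A; the remaining columns belong to protein B.
#'
#' @param sequences Character vector of aligned sequences, or an integer state
#'   matrix as produced by [encode_sequences()].
#' @param boundary Number of A-protein columns (`0 < boundary < L`).
#' @param ids Optional row labels; defaults to `seq_1..seq_B`.
#' @param q Alphabet size (21 for protein data; toys may use fewer states).
#' @return A `paired_msa` object.
#' @export
#' @examples
#' paired_msa(c("MKDE", "MRDE"), boundary = 2)
paired_msa <- function(sequences, boundary, ids = NULL, q = 21L) {
  states <- if (is.character(sequences)) encode_sequences(sequences, q) else {
    storage.mode(sequences) <- "integer"
    sequences
  }
  L <- ncol(states)
  if (nrow(states) > 0L) {
    stopifnot(all(states >= 1L), all(states <= q))
  }
  boundary <- as.integer(boundary)
  if (nrow(states) > 0L || L > 0L) {
    if (boundary <= 0L || boundary >= L) {
      stop("boundary must satisfy 0 < boundary < ", L, ", got ", boundary,
           call. = FALSE)
    }
  }
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_len(nrow(states)))
  structure(
    list(states = states, boundary = boundary, ids = as.character(ids),
         q = as.integer(q)),
    class = "paired_msa"
  )
}

#' @exportS3Method base::print
print.paired_msa <- function(x, ...) {
  cat("<paired_msa> ", nrow(x$states), " rows x ", ncol(x$states),
      " columns (boundary = ", x$boundary, ", q = ", x$q, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.paired_msa <- function(x) dim(x$states)

#' Read an aligned FASTA file as a paired MSA
#'
#' All records must have equal length; characters are restricted to the
#' 21-letter alphabet (case-insensitive, `.` and `-` both map to the gap).
#'
#' @param path Path to an aligned FASTA file.
#' @param boundary Number of A-protein columns.
#' @return A [paired_msa()].
#' @export
read_paired_msa <- function(path, boundary) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("empty alignment: no records in ", path, call. = FALSE)
  seqs <- as.character(aa)
  paired_msa(unname(seqs), boundary = boundary, ids = names(aa))
}

#' Write a paired MSA as aligned FASTA (wrapped at 80 columns)
#' @param msa A [paired_msa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_msa <- function(msa, path) {
  set <- Biostrings::BStringSet(decode_sequences(msa$states))
  names(set) <- msa$ids
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Concatenate two single-protein alignments according to a pairing list
#'
#' One concatenated row is produced per `(id_a, id_b)` pair, A columns first.
#' Only listed pairs appear: no knowledge of non-interacting pairs is needed.
#'
#' @param msa_a,msa_b Single-protein alignments, given as `paired_msa`-like
#'   objects or named character vectors of aligned sequences.
#' @param pairing Data frame (or tibble) with columns `id_a`, `id_b`.
#' @return A [paired_msa()] with `boundary` equal to the A alignment width.
#' @export
concatenate_pairs <- function(msa_a, msa_b, pairing) {
  get_seqs <- function(m) {
    if (inherits(m, "paired_msa")) {
      stats::setNames(decode_sequences(m$states), m$ids)
    } else {
      stopifnot(is.character(m), !is.null(names(m)))
      m
    }
  }
  sa <- get_seqs(msa_a)
  sb <- get_seqs(msa_b)
  if (anyDuplicated(names(sa)) || anyDuplicated(names(sb))) {
    stop("duplicated sequence ids in input alignments", call. = FALSE)
  }
  pairing <- as.data.frame(pairing)
  stopifnot(all(c("id_a", "id_b") %in% names(pairing)))
  miss_a <- setdiff(pairing$id_a, names(sa))
  miss_b <- setdiff(pairing$id_b, names(sb))
  if (length(miss_a) || length(miss_b)) {
    stop("unresolved ids in pairing: ",
         paste(c(miss_a, miss_b), collapse = ", "), call. = FALSE)
  }
  la <- unique(nchar(sa))
  lb <- unique(nchar(sb))
  stopifnot(length(la) == 1L, length(lb) == 1L)
  rows <- paste0(sa[pairing$id_a], sb[pairing$id_b])
  if (nrow(pairing) == 0L) {
    out <- paired_msa(matrix(integer(0), 0L, la + lb), boundary = la)
    return(out)
  }
  paired_msa(rows, boundary = la,
             ids = paste(pairing$id_a, pairing$id_b, sep = "/"))
}

#' Pairwise identity redundancy filter
#'
#' Greedy first-come retention scanning rows in input order: a row is kept if
#' its identity to every previously retained row is at most `max_identity`.
#' Identity is the fraction of matching columns over all columns; gap-gap
#' matches count as matches.
#'
#' @param msa A [paired_msa()].
#' @param max_identity Maximum allowed pairwise identity among retained rows.
#' @return A [paired_msa()] with the retained subset, input order preserved.
#' @export
filter_identity <- function(msa, max_identity = 0.90) {
  stopifnot(inherits(msa, "paired_msa"),
            max_identity > 0, max_identity <= 1)
  m <- msa$states
  if (nrow(m) <= 1L) return(msa)
  L <- ncol(m)
  keep <- 1L
  for (i in 2:nrow(m)) {
    ident <- rowMeans(m[keep, , drop = FALSE] ==
                        matrix(m[i, ], nrow = length(keep), ncol = L,
                               byrow = TRUE))
    if (all(ident <= max_identity)) keep <- c(keep, i)
  }
  paired_msa(m[keep, , drop = FALSE], boundary = msa$boundary,
             ids = msa$ids[keep], q = msa$q)
}

#' Hamming distance between two equal-length sequences
#' @param s1,s2 Character strings or integer state vectors of equal length.
#' @return Integer count of differing positions.
#' @export
hamming_distance <- function(s1, s2) {
  if (is.character(s1)) s1 <- as.integer(encode_sequences(s1)[1, ])
  if (is.character(s2)) s2 <- as.integer(encode_sequences(s2)[1, ])
  if (length(s1) != length(s2)) {
    stop("length mismatch: ", length(s1), " vs ", length(s2), call. = FALSE)
  }
  sum(s1 != s2)
}

#' Weighted first- and second-order empirical moments of an alignment
#'
#' Returns the per-site frequencies `f1` (L x q) and the site-pair frequency
#' matrix `f2` in the same `(Lq) x (Lq)` block layout used for Potts couplings:
#' entry `((i-1)q+a, (j-1)q+b)` is the weighted frequency of observing state
#' `a` at site `i` together with state `b` at site `j`. Diagonal blocks are
#' `diag(f1[i, ])`, so `f2[(i,a),(i,a)] = f1[i,a]`.
#'
#' @param msa A [paired_msa()] or an integer state matrix.
#' @param weights Optional non-negative per-row weights (default uniform).
#' @param q Alphabet size; taken from the msa when available.
#' @return List with elements `f1` and `f2`.
#' @export
site_marginals <- function(msa, weights = NULL, q = NULL) {
  m <- if (inherits(msa, "paired_msa")) msa$states else msa
  if (is.null(q)) q <- if (inherits(msa, "paired_msa")) msa$q else max(m)
  B <- nrow(m)
  if (B == 0L) stop("empty MSA: cannot compute moments", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, B)
  stopifnot(length(weights) == B, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  L <- ncol(m)
  # one-hot encode: B x (L*q)
  X <- matrix(0, nrow = B, ncol = L * q)
  X[cbind(rep(seq_len(B), L),
          (rep(seq_len(L), each = B) - 1L) * q + as.vector(m))] <- 1
  f2 <- crossprod(X * w, X)
  f1 <- matrix(colSums(X * w), nrow = L, ncol = q, byrow = TRUE)
  list(f1 = f1, f2 = f2)
}
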