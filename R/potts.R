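#' Construct a Potts model over a paired sequence space
#'
#' A pairwise maximum-entropy (Potts) model over `L = n_a + n_b` categorical
#' sites with `q` states each, with per-site fields `h` and pairwise couplings
#' `J`. The probability of a concatenated sequence `s` is
#' `P(s) = exp(-E(s)) / Z` with statistical energy
#' `E(s) = -sum_i h_i(s_i) - sum_{i<j} J_ij(s_i, s_j)`,
#' so negative (low) energies correspond to favourable sequences.
#'
#' Couplings are stored as a dense `(Lq) x (Lq)` matrix of `q x q` blocks:
#' `J[(i-1)q+a, (j-1)q+b] = J_ij(a, b)`. The matrix is symmetric
#' (`J_ij(a,b) = J_ji(b,a)`) and the diagonal blocks `J_ii` are zero; each
#' unordered site pair is counted once in energy sums.
#'
#' @param h `L x q` field matrix.
#' @param J `(Lq) x (Lq)` coupling matrix (symmetric, zero diagonal blocks).
#' @param boundary Number of A-protein sites (`0 < boundary < L`).
#' @param q Number of states per site.
#' @return A `potts_model` object.
#' @export
potts_model <- function(h, J, boundary, q = ncol(h)) {
  h <- as.matrix(h)
  J <- as.matrix(J)
  L <- nrow(h)
  stopifnot(ncol(h) == q, nrow(J) == L * q, ncol(J) == L * q)
  boundary <- as.integer(boundary)
  if (boundary <= 0L || boundary >= L) {
    stop("boundary must satisfy 0 < boundary < L = ", L, call. = FALSE)
  }
  if (max(abs(J - t(J))) > 1e-10) {
    stop("coupling matrix must be symmetric: J_ij(a,b) = J_ji(b,a)", call. = FALSE)
  }
  for (i in seq_len(L)) {
    idx <- block_idx(i, q)
    if (any(J[idx, idx] != 0)) {
      stop("diagonal coupling blocks J_ii must be zero", call. = FALSE)
    }
  }
  structure(list(h = h, J = J, L = L, q = as.integer(q), boundary = boundary),
            class = "potts_model")
}

block_idx <- function(i, q) ((i - 1L) * q + 1L):(i * q)

#' @exportS3Method base::print
print.potts_model <- function(x, ...) {
  cat("<potts_model> L = ", x$L, " sites (boundary = ", x$boundary,
      "), q = ", x$q, " states\n", sep = "")
  invisible(x)
}

state_offsets <- function(s, q) (seq_along(s) - 1L) * q + as.integer(s)

as_states <- function(s, q) {
  if (is.character(s)) s <- as.integer(encode_sequences(s, q)[1, ])
  as.integer(s)
}

#' Statistical energy of a sequence under a Potts model
#'
#' `E(s) = -sum_i h_i(s_i) - sum_{i<j} J_ij(s_i, s_j)`; lower energy means
#' higher model probability `P(s) = exp(-E(s))/Z`.
#'
#' @param model A [potts_model()].
#' @param s Sequence: integer state vector of length `model$L` or a character
#'   string.
#' @return Scalar energy (dimensionless statistical energy units).
#' @export
energy <- function(model, s) {
  s <- as_states(s, model$q)
  if (length(s) != model$L) {
    stop("sequence length ", length(s), " does not match model L = ", model$L,
         call. = FALSE)
  }
  idx <- state_offsets(s, model$q)
  Jsub <- model$J[idx, idx]
  -sum(model$h[cbind(seq_len(model$L), s)]) - sum(Jsub[upper.tri(Jsub)])
}

#' Intra/inter decomposition of the statistical energy
#'
#' Splits `E(s)` into `e_intra_a` (fields and couplings within the A segment),
#' `e_intra_b` (within the B segment) and `e_inter` (couplings crossing the
#' boundary). The identity `e_total = e_intra_a + e_intra_b + e_inter` holds
#' exactly.
#'
#' @inheritParams energy
#' @return A one-row tibble with columns `e_total`, `e_intra_a`, `e_intra_b`,
#'   `e_inter`.
#' @export
decompose_energy <- function(model, s) {
  s <- as_states(s, model$q)
  if (length(s) != model$L) {
    stop("sequence length ", length(s), " does not match model L = ", model$L,
         call. = FALSE)
  }
  q <- model$q
  na <- model$boundary
  L <- model$L
  idx <- state_offsets(s, q)
  Jsub <- model$J[idx, idx]
  hvals <- model$h[cbind(seq_len(L), s)]
  ia <- seq_len(na)
  ib <- (na + 1L):L
  up <- upper.tri(Jsub)
  maskA <- up & outer(seq_len(L) <= na, seq_len(L) <= na)
  maskB <- up & outer(seq_len(L) > na, seq_len(L) > na)
  maskI <- up & outer(seq_len(L) <= na, seq_len(L) > na)
  e_intra_a <- -sum(hvals[ia]) - sum(Jsub[maskA])
  e_intra_b <- -sum(hvals[ib]) - sum(Jsub[maskB])
  e_inter <- -sum(Jsub[maskI])
  tibble::tibble(
    e_total = e_intra_a + e_intra_b + e_inter,
    e_intra_a = e_intra_a, e_intra_b = e_intra_b, e_inter = e_inter
  )
}

#' Normalized mutant interaction scores (cognate and cross-talk)
#'
#' For a mutant pair `(A*, B*)` relative to the wild-type pair `(A, B)`,
#' computes the five wild-type-normalized scores
#' `dE_intra(A*)`, `dE_intra(B*)`, `dE_inter(A*,B*)` (cognate), and the
#' cross-talk chimera scores `dE_inter(A*,B)` and `dE_inter(A,B*)`, each the
#' difference between the mutant term and the corresponding wild-type term.
#' All five are exactly zero when the mutant equals the wild type.
#'
#' @param model A [potts_model()].
#' @param wildtype List or vector of two sequences `(A, B)` (character strings
#'   or state vectors of lengths `boundary` and `L - boundary`).
#' @param mutant Mutant pair `(A*, B*)`, same formats.
#' @return One-row tibble with columns `d_intra_a`, `d_intra_b`,
#'   `d_inter_cognate`, `d_inter_astar_b`, `d_inter_a_bstar`.
#' @export
delta_scores <- function(model, wildtype, mutant) {
  q <- model$q
  wt_a <- as_states(wildtype[[1]], q); wt_b <- as_states(wildtype[[2]], q)
  mu_a <- as_states(mutant[[1]], q);  mu_b <- as_states(mutant[[2]], q)
  na <- model$boundary; nb <- model$L - na
  if (length(wt_a) != na || length(mu_a) != na ||
      length(wt_b) != nb || length(mu_b) != nb) {
    stop("A sequences must have length ", na, " and B sequences length ", nb,
         call. = FALSE)
  }
  d_wt <- decompose_energy(model, c(wt_a, wt_b))
  d_mm <- decompose_energy(model, c(mu_a, mu_b))
  d_mw <- decompose_energy(model, c(mu_a, wt_b))
  d_wm <- decompose_energy(model, c(wt_a, mu_b))
  tibble::tibble(
    d_intra_a = d_mm$e_intra_a - d_wt$e_intra_a,
    d_intra_b = d_mm$e_intra_b - d_wt$e_intra_b,
    d_inter_cognate = d_mm$e_inter - d_wt$e_inter,
    d_inter_astar_b = d_mw$e_inter - d_wt$e_inter,
    d_inter_a_bstar = d_wm$e_inter - d_wt$e_inter
  )
}

#' Shift a Potts model to the zero-sum gauge
#'
#' Reparametrizes the model so that `sum_a h_i(a) = 0` for every site and
#' `sum_{a,b} J_ij(a,b) = 0` for every site pair, without changing the
#' probability distribution (all energies shift by one common constant).
#' The standard shift is used: couplings lose their per-state row and column
#' means (plus the grand mean), which are absorbed into the fields, and fields
#' are centered.
#'
#' @param model A [potts_model()].
#' @return A [potts_model()] in the zero-sum gauge.
#' @export
to_zero_sum_gauge <- function(model) {
  L <- model$L; q <- model$q
  h <- model$h
  J <- model$J
  Jnew <- J
  # per-block row means r_ij(a) accumulated into fields
  for (i in seq_len(L)) {
    ii <- block_idx(i, q)
    for (j in seq_len(L)) {
      if (i == j) next
      jj <- block_idx(j, q)
      blk <- J[ii, jj]
      rm <- rowMeans(blk)
      cm <- colMeans(blk)
      gm <- mean(blk)
      if (j > i) {
        Jnew[ii, jj] <- blk - outer(rm, rep(1, q)) - outer(rep(1, q), cm) + gm
        Jnew[jj, ii] <- t(Jnew[ii, jj])
      }
      h[i, ] <- h[i, ] + (rm - gm)
    }
  }
  h <- h - rowMeans(h)
  potts_model(h, Jnew, boundary = model$boundary, q = q)
}

#' Size of a constrained mutant sequence space
#'
#' Number of distinct mutant pairs carrying exactly `k_a` substitutions in a
#' protein of `l_a` mutable positions and `k_b` in one of `l_b` positions,
#' with `n_states` alternative residues available at each position
#' (19 for the 20-amino-acid alphabet excluding the wild-type residue and the
#' gap).
#'
#' @param l_a,l_b Numbers of mutable positions in proteins A and B.
#' @param k_a,k_b Exact mutation counts.
#' @param n_states Alternative states per mutated position.
#' @return Numeric count (may exceed integer range).
#' @export
mutant_space_size <- function(l_a, l_b, k_a, k_b, n_states = 19) {
  choose(l_a, k_a) * n_states^k_a * choose(l_b, k_b) * n_states^k_b
}
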