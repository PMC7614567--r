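#' Random toy Potts model with known ground truth
#'
#' Fields and couplings are drawn from zero-mean normal distributions at the
#' given scales; couplings are symmetric with zero diagonal blocks, and
#' cross-boundary blocks use their own scale so interaction strength can be
#' switched off independently. All scales 0 gives the uniform model.
#'
#' @param l_a,l_b Segment lengths (total `L = l_a + l_b`).
#' @param q States per site (`<= 21`).
#' @param field_scale,coupling_scale,inter_coupling_scale Standard deviations
#'   of fields, within-protein couplings and cross-boundary couplings.
#' @param seed Integer seed (same seed, same model).
#' @return A [potts_model()].
#' @export
make_toy_model <- function(l_a = 4L, l_b = 4L, q = 3L, field_scale = 0.5,
                           coupling_scale = 0.3,
                           inter_coupling_scale = coupling_scale,
                           seed = 1L) {
  stopifnot(q >= 2, q <= 21, l_a >= 1, l_b >= 1)
  L <- l_a + l_b
  with_local_seed(seed, {
    h <- matrix(stats::rnorm(L * q, sd = 1), L, q) *
      if (field_scale > 0) field_scale else 0
    J <- matrix(0, L * q, L * q)
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        sc <- if (i <= l_a && j > l_a) inter_coupling_scale else coupling_scale
        blk <- matrix(stats::rnorm(q * q, sd = 1), q, q) *
          if (sc > 0) sc else 0
        J[block_idx(i, q), block_idx(j, q)] <- blk
        J[block_idx(j, q), block_idx(i, q)] <- t(blk)
      }
    }
    potts_model(h, J, boundary = l_a, q = q)
  })
}

#' Enumerate every sequence of a small state space
#'
#' @param L Number of sites.
#' @param q States per site.
#' @return Integer matrix `q^L x L`, rows in odometer order (site 1 fastest).
#' @export
enumerate_states <- function(L, q) {
  n <- q^L
  if (n > 1e7) stop("state space too large to enumerate (", n, ")",
                    call. = FALSE)
  idx <- 0:(n - 1)
  m <- vapply(seq_len(L),
              function(j) as.integer((idx %/% q^(j - 1)) %% q) + 1L,
              integer(n))
  matrix(m, nrow = n, ncol = L)
}

# vectorized energies of a state matrix under a model
batch_energy <- function(model, states) {
  L <- model$L; q <- model$q
  e <- -rowSums(matrix(model$h[cbind(rep(seq_len(L), each = nrow(states)),
                                     as.vector(states))],
                       nrow(states), L))
  for (i in seq_len(L - 1)) {
    oi <- (i - 1L) * q + states[, i]
    for (j in (i + 1):L) {
      e <- e - model$J[cbind(oi, (j - 1L) * q + states[, j])]
    }
  }
  e
}

#' Exact Boltzmann distribution of an enumerable Potts model
#'
#' @param model A [potts_model()] with `q^L <= 1e7`.
#' @param temperature Virtual temperature dividing the energy.
#' @return List: `states` (all sequences), `energy`, `prob`
#'   (`prob = exp(-E/T)/Z`, summing to 1).
#' @export
enumerate_distribution <- function(model, temperature = 1) {
  states <- enumerate_states(model$L, model$q)
  e <- batch_energy(model, states)
  w <- exp(-(e - min(e)) / temperature)
  list(states = states, energy = e, prob = w / sum(w))
}

#' Sample a synthetic paired MSA from a known model
#'
#' Independent exact draws from the enumerated Boltzmann distribution
#' (method `"exact"`), or thinned MCMC samples (method `"mcmc"`) for models
#' too large to enumerate.
#'
#' @param model A [potts_model()].
#' @param b Number of rows.
#' @param seed Integer seed.
#' @param method `"exact"` (enumeration) or `"mcmc"`.
#' @param ... Passed to [run_chains()] for the MCMC method.
#' @return A [paired_msa()] with `b` rows.
#' @export
sample_synthetic_msa <- function(model, b, seed = 1L,
                                 method = c("exact", "mcmc"), ...) {
  method <- match.arg(method)
  if (b == 0L) {
    return(paired_msa(matrix(integer(0), 0L, model$L),
                      boundary = model$boundary, q = model$q))
  }
  states <- if (method == "exact") {
    dist <- enumerate_distribution(model)
    rows <- with_local_seed(seed,
      sample.int(nrow(dist$states), b, replace = TRUE, prob = dist$prob))
    dist$states[rows, , drop = FALSE]
  } else {
    args <- list(...)
    n_chains <- args$n_chains %||% 8L
    record_every <- args$record_every %||% 50L
    n_sweeps <- ceiling(b / n_chains) * record_every
    s <- run_chains(model, n_chains = n_chains, n_sweeps = n_sweeps,
                    record_every = record_every, temperature = 1, seed = seed)
    s[seq_len(b), , drop = FALSE]
  }
  paired_msa(states, boundary = model$boundary, q = model$q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Labeled mutant set with planted orthogonal/promiscuous structure
#'
#' Generates uniform random mutants at fixed mutation counts, scores them
#' under the model, and assigns labels by rejection on the cross-talk score
#' `dE_inter(A,B*)`: promiscuous members are drawn from the low tail and
#' orthogonal members from at least `separation` energy units higher, so the
#' labels are consistent with the model's own scores. With `separation = 0`
#' the two label groups are exchangeable draws from the same pool.
#'
#' @param model A [potts_model()].
#' @param wildtype Wild-type pair `(A, B)`.
#' @param n_orthogonal,n_promiscuous Class sizes (reference set: 16 and 25).
#' @param separation Minimum gap (statistical energy units) between the
#'   promiscuous upper bound and the orthogonal lower bound.
#' @param k_a,k_b Mutation counts per protein.
#' @param pool_size Size of the random pool to draw from.
#' @param seed Integer seed.
#' @return Tibble `mutant_a`, `mutant_b`, `label` plus the five delta scores.
#' @export
make_labeled_mutant_set <- function(model, wildtype, n_orthogonal = 16L,
                                    n_promiscuous = 25L, separation = 1,
                                    k_a = 2L, k_b = 2L, pool_size = 2000L,
                                    seed = 1L) {
  stopifnot(n_orthogonal >= 1, n_promiscuous >= 1, separation >= 0)
  pool <- random_mutants(wildtype, k_a = k_a, k_b = k_b,
                         n_samples = pool_size, q = model$q, seed = seed,
                         model = model)
  s <- pool$d_inter_a_bstar
  with_local_seed(derive_seed(seed, 1L), {
    if (separation == 0) {
      idx <- sample.int(nrow(pool), n_orthogonal + n_promiscuous)
      orth <- idx[seq_len(n_orthogonal)]
      prom <- idx[n_orthogonal + seq_len(n_promiscuous)]
    } else {
      med <- stats::median(s)
      orth_pool <- which(s >= med + separation / 2)
      prom_pool <- which(s <= med - separation / 2)
      if (length(orth_pool) < n_orthogonal ||
          length(prom_pool) < n_promiscuous) {
        stop("could not plant ", n_orthogonal, "+", n_promiscuous,
             " mutants at separation ", separation,
             "; try a smaller separation or a larger pool_size",
             call. = FALSE)
      }
      orth <- sample(orth_pool, n_orthogonal)
      prom <- sample(prom_pool, n_promiscuous)
    }
    out <- dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(pool)[orth, ], label = "orthogonal"),
      dplyr::mutate(tibble::as_tibble(pool)[prom, ], label = "promiscuous")
    )
    dplyr::select(out, "mutant_a", "mutant_b", "label",
                  dplyr::all_of(feature_cols))
  })
}
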