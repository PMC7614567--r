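#' Generate candidate mutant pairs by constrained MCMC sampling
#'
#' `direct_sample()` runs a Metropolis-Hastings chain over the space of mutant
#' pairs carrying exactly `k_a` substitutions in protein A and `k_b` in
#' protein B, with stationary distribution proportional to `exp(-E(s)/T)`
#' restricted to that space. `conditional_sample()` additionally penalizes
#' cross-talk: its stationary distribution is proportional to
#' `exp(-[E_intra(A*) + E_intra(B*) + E_inter(A*,B*)]/T
#'      + [E_inter(A*,B) + E_inter(A,B*)]/T2)`,
#' so larger `t2` down-weights the reward for unfavourable chimera energies
#' and, in the limit `t2 -> Inf`, recovers direct sampling.
#'
#' The constrained move kernel mixes two reversible proposals on a uniformly
#' chosen protein: resampling the residue at a currently mutated position
#' (mutation count preserved) and swapping (reverting one mutated position to
#' wild type while mutating a currently wild-type position). Swap acceptance
#' carries the Hastings factor for the per-position counts of legal mutant
#' states. The gap state is never introduced unless `allow_gap_mutations` is
#' set. One mutant is recorded every `record_every` sweeps (a sweep is `L`
#' proposals), with its five wild-type-normalized scores tracked incrementally.
#'
#' @param model A [potts_model()].
#' @param wildtype Wild-type pair `(A, B)`: list/vector of two sequences.
#' @param k_a,k_b Exact mutation counts per protein (`>= 0`, not both 0).
#' @param temperature Virtual sampling temperature `T > 0` (reference default
#'   2 for direct sampling).
#' @param t2 Cross-talk temperature `T2 > 0` (conditional sampling only).
#' @param n_samples Number of recorded mutants.
#' @param record_every Sweeps between recorded mutants.
#' @param allowed_positions Optional list with elements `a` and `b`:
#'   protein-local 1-based positions where mutations may be placed
#'   (default: all positions).
#' @param allow_gap_mutations Allow designed mutations to the gap state
#'   (default FALSE; only meaningful for the 21-state alphabet).
#' @param seed Master integer seed.
#' @return An `ois_repertoire` tibble: one row per recorded mutant with
#'   columns `mutant_a`, `mutant_b`, the five delta scores (`d_intra_a`,
#'   `d_intra_b`, `d_inter_cognate`, `d_inter_astar_b`, `d_inter_a_bstar`)
#'   and comma-separated 1-based protein-local `positions_a`, `positions_b`.
#'   Generation settings are attached as the `config` attribute.
#' @export
direct_sample <- function(model, wildtype, k_a = 6L, k_b = 5L,
                          temperature = 2, n_samples = 500000L,
                          record_every = 100L, allowed_positions = NULL,
                          allow_gap_mutations = FALSE, seed = 1L) {
  sample_repertoire(model, wildtype, k_a, k_b, temperature, t2 = Inf,
                    n_samples, record_every, allowed_positions,
                    allow_gap_mutations, seed, mode = "direct")
}

#' @rdname direct_sample
#' @export
conditional_sample <- function(model, wildtype, k_a = 6L, k_b = 5L,
                               temperature = 1, t2 = 1,
                               n_samples = 100000L, record_every = 100L,
                               allowed_positions = NULL,
                               allow_gap_mutations = FALSE, seed = 1L) {
  stopifnot(t2 > 0)
  sample_repertoire(model, wildtype, k_a, k_b, temperature, t2,
                    n_samples, record_every, allowed_positions,
                    allow_gap_mutations, seed, mode = "conditional")
}

sample_repertoire <- function(model, wildtype, k_a, k_b, temperature, t2,
                              n_samples, record_every, allowed_positions,
                              allow_gap_mutations, seed, mode) {
  stopifnot(temperature > 0, n_samples >= 1, record_every >= 1)
  q <- model$q
  na <- model$boundary
  nb <- model$L - na
  wt_a <- as_states(wildtype[[1]], q)
  wt_b <- as_states(wildtype[[2]], q)
  if (length(wt_a) != na || length(wt_b) != nb) {
    stop("wild-type split (", length(wt_a), ", ", length(wt_b),
         ") does not match the model boundary (", na, ", ", nb, ")",
         call. = FALSE)
  }
  wt <- c(wt_a, wt_b)
  pos_a <- if (is.null(allowed_positions)) seq_len(na) else
    as.integer(allowed_positions$a)
  pos_b <- if (is.null(allowed_positions)) seq_len(nb) else
    as.integer(allowed_positions$b)
  stopifnot(all(pos_a >= 1), all(pos_a <= na),
            all(pos_b >= 1), all(pos_b <= nb),
            !anyDuplicated(pos_a), !anyDuplicated(pos_b))
  if (k_a < 0 || k_a > length(pos_a) || k_b < 0 || k_b > length(pos_b)) {
    stop("infeasible constraints: k_a must be in [0, ", length(pos_a),
         "] and k_b in [0, ", length(pos_b), "]", call. = FALSE)
  }
  if (k_a == 0 && k_b == 0) {
    stop("at least one of k_a, k_b must be positive", call. = FALSE)
  }
  gap <- gap_state(q)
  allowed_states <- matrix(FALSE, model$L, q)
  global_pos <- c(pos_a, na + pos_b)
  for (p in global_pos) {
    ok <- rep(TRUE, q)
    ok[wt[p]] <- FALSE
    if (!allow_gap_mutations && !is.na(gap)) ok[gap] <- FALSE
    allowed_states[p, ] <- ok
  }
  if (any(rowSums(allowed_states[global_pos, , drop = FALSE]) == 0)) {
    stop("no legal mutant state at some allowed position", call. = FALSE)
  }
  res <- cpp_generate(model$h, model$J, q, na, wt - 1L, allowed_states,
                      pos_a - 1L, na + pos_b - 1L, as.integer(k_a),
                      as.integer(k_b), temperature,
                      if (is.finite(t2)) 1 / t2 else 0,
                      as.integer(n_samples), as.integer(record_every),
                      as.numeric(seed))
  seqs <- res$seqs + 1L
  sc <- res$scores
  seq_a <- decode_sequences(seqs[, seq_len(na), drop = FALSE])
  seq_b <- decode_sequences(seqs[, na + seq_len(nb), drop = FALSE])
  mut_a <- apply(seqs[, seq_len(na), drop = FALSE], 1L,
                 function(s) paste(which(s != wt_a), collapse = ","))
  mut_b <- apply(seqs[, na + seq_len(nb), drop = FALSE], 1L,
                 function(s) paste(which(s != wt_b), collapse = ","))
  rep_tbl <- tibble::tibble(
    mutant_a = seq_a, mutant_b = seq_b,
    d_intra_a = sc[, 1], d_intra_b = sc[, 2],
    d_inter_cognate = sc[, 3],
    d_inter_astar_b = sc[, 4], d_inter_a_bstar = sc[, 5],
    positions_a = mut_a, positions_b = mut_b
  )
  new_repertoire(rep_tbl,
                 config = list(mode = mode, k_a = k_a, k_b = k_b,
                               temperature = temperature, t2 = t2,
                               n_samples = n_samples,
                               record_every = record_every,
                               allow_gap_mutations = allow_gap_mutations,
                               allowed_positions = list(a = pos_a, b = pos_b),
                               wildtype_a = decode_sequences(wt_a),
                               wildtype_b = decode_sequences(wt_b),
                               seed = seed))
}

new_repertoire <- function(tbl, config = list()) {
  structure(tbl, config = config,
            class = c("ois_repertoire", class(tibble::as_tibble(tbl))))
}

#' Repertoire generation settings
#' @param repertoire An `ois_repertoire`.
#' @return The generation config list (mode, temperatures, constraints, seed).
#' @export
repertoire_config <- function(repertoire) attr(repertoire, "config")

#' Uniform random mutant pairs at fixed mutation counts
#'
#' Baseline generator: positions chosen uniformly without replacement and
#' residues uniformly among the legal mutant states, with no influence of the
#' model. Used as the null background against model-guided sampling.
#'
#' @inheritParams direct_sample
#' @param q Alphabet size.
#' @return An `ois_repertoire` tibble without scores unless `model` is given.
#' @export
random_mutants <- function(wildtype, k_a, k_b, n_samples, q = 21L,
                           allow_gap_mutations = FALSE, seed = 1L,
                           model = NULL) {
  wt_a <- as_states(wildtype[[1]], q)
  wt_b <- as_states(wildtype[[2]], q)
  gap <- gap_state(q)
  draw <- function(wt, k) {
    n <- length(wt)
    t(vapply(seq_len(n_samples), function(i) {
      s <- wt
      pos <- sample.int(n, k)
      for (p in pos) {
        states <- setdiff(seq_len(q), c(wt[p],
                                        if (!allow_gap_mutations) gap))
        s[p] <- if (length(states) == 1L) states else sample(states, 1L)
      }
      s
    }, integer(n)))
  }
  states <- with_local_seed(seed, {
    cbind(draw(wt_a, k_a), draw(wt_b, k_b))
  })
  na <- length(wt_a)
  tbl <- tibble::tibble(
    mutant_a = decode_sequences(states[, seq_len(na), drop = FALSE]),
    mutant_b = decode_sequences(states[, na + seq_len(length(wt_b)),
                                       drop = FALSE])
  )
  if (!is.null(model)) {
    sc <- score_pairs(model, wildtype, tbl)
    tbl <- dplyr::bind_cols(tbl, sc)
  }
  tbl$positions_a <- apply(states[, seq_len(na), drop = FALSE], 1L,
                           function(s) paste(which(s != wt_a), collapse = ","))
  tbl$positions_b <- apply(states[, na + seq_len(length(wt_b)), drop = FALSE],
                           1L,
                           function(s) paste(which(s != wt_b), collapse = ","))
  new_repertoire(tbl, config = list(mode = "random", k_a = k_a, k_b = k_b,
                                    seed = seed))
}

#' Score a table of mutant pairs against the wild type
#'
#' @param model A [potts_model()].
#' @param wildtype Wild-type pair `(A, B)`.
#' @param mutants Tibble/data frame with columns `mutant_a`, `mutant_b`.
#' @return Tibble of the five delta scores, one row per mutant.
#' @export
score_pairs <- function(model, wildtype, mutants) {
  purrr::pmap_dfr(
    list(mutants$mutant_a, mutants$mutant_b),
    function(a, b) delta_scores(model, wildtype, list(a, b))
  )
}
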