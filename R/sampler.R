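# internal: run code under a temporary RNG seed, restoring global state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# internal: deterministic sub-seed derivation from a master seed
# (exact in double arithmetic for seeds below 2^31; result fits set.seed)
derive_seed <- function(seed, stream) {
  (seed * 1000003 + stream * 7919) %% 2147483647
}

#' Metropolis sampling of sequences from a Potts model
#'
#' Runs `n_chains` independent Metropolis chains at virtual temperature
#' `temperature`, sampling from `P(s) \propto exp(-E(s)/T)`. A sweep is `L`
#' Monte Carlo steps; each step picks a uniformly random site and one of the
#' `q - 1` other states uniformly, accepting with probability
#' `min(1, exp(-dE/T))`. A configuration is recorded every `record_every`
#' sweeps (the first record after `record_every` sweeps, with no additional
#' burn-in).
#'
#' Chains draw their random streams from per-chain seeds derived from the
#' single master `seed` by iterating a splitmix64 mixer, so runs are exactly
#' reproducible across machines.
#'
#' @param model A [potts_model()].
#' @param n_chains Number of independent chains.
#' @param n_sweeps Sweeps per chain (must be `>= record_every`).
#' @param record_every Sweeps between recorded configurations.
#' @param temperature Virtual sampling temperature `T > 0`.
#' @param seed Master integer seed.
#' @param init Chain initialization: `NULL` for uniform-random states, a
#'   [paired_msa()] (or state matrix) to start chains from rows drawn
#'   uniformly at random, or a single state vector used for every chain.
#' @return Integer state matrix with `n_chains * floor(n_sweeps/record_every)`
#'   rows (states `1..q`).
#' @export
run_chains <- function(model, n_chains = 128L, n_sweeps = 100000L,
                       record_every = 100L, temperature = 1,
                       seed = 1L, init = NULL) {
  stopifnot(temperature > 0, n_chains >= 1)
  if (n_sweeps < record_every) {
    stop("n_sweeps (", n_sweeps, ") must be at least record_every (",
         record_every, ")", call. = FALSE)
  }
  L <- model$L
  q <- model$q
  init_mat <- with_local_seed(derive_seed(seed, 0L), {
    if (is.null(init)) {
      matrix(sample.int(q, n_chains * L, replace = TRUE), nrow = n_chains)
    } else if (inherits(init, "paired_msa") || is.matrix(init)) {
      m <- if (inherits(init, "paired_msa")) init$states else init
      m[sample.int(nrow(m), n_chains, replace = TRUE), , drop = FALSE]
    } else {
      matrix(rep(as_states(init, q), each = n_chains), nrow = n_chains)
    }
  })
  stopifnot(ncol(init_mat) == L)
  out <- cpp_run_chains(model$h, model$J, q, temperature,
                        init_mat - 1L, as.integer(n_sweeps),
                        as.integer(record_every), as.numeric(seed))
  out + 1L
}
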