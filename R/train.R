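#' Gradient of the regularized negative log-likelihood
#'
#' The loss is the per-sequence negative log-likelihood of the alignment plus
#' an L2 penalty `lambda * (sum h^2 + sum_{i<j} sum_{a,b} J^2)` (each unordered
#' site pair counted once, matching the energy convention). Its gradient with
#' respect to each parameter is
#' `(model moment - data moment) + 2 * lambda * theta`,
#' where model moments are estimated from MCMC samples of the current model.
#'
#' @param model A [potts_model()] (current parameters `theta`).
#' @param data_moments,sample_moments Moment lists as returned by
#'   [site_marginals()] (`f1` `L x q`, `f2` `(Lq) x (Lq)`).
#' @param lambda_reg Non-negative L2 weight.
#' @return List with gradient matrices `h` and `J` (same shapes as the model;
#'   `J` gradient is symmetric with zero diagonal blocks).
#' @export
nll_gradient <- function(model, data_moments, sample_moments, lambda_reg = 0) {
  stopifnot(lambda_reg >= 0)
  f1 <- data_moments$f1; f2 <- data_moments$f2
  g1 <- sample_moments$f1; g2 <- sample_moments$f2
  if (!all(dim(f1) == dim(model$h)) || !all(dim(g1) == dim(model$h)) ||
      !all(dim(f2) == dim(model$J)) || !all(dim(g2) == dim(model$J))) {
    stop("moment shapes do not match the model", call. = FALSE)
  }
  grad_h <- (g1 - f1) + 2 * lambda_reg * model$h
  grad_J <- zero_diag_blocks((g2 - f2) + 2 * lambda_reg * model$J,
                             model$L, model$q)
  list(h = grad_h, J = grad_J)
}

zero_diag_blocks <- function(mat, L, q) {
  for (i in seq_len(L)) {
    idx <- block_idx(i, q)
    mat[idx, idx] <- 0
  }
  mat
}

# mix data moments with the uniform independent model (optional pseudocount)
apply_pseudocount <- function(moments, pc, L, q) {
  if (pc <= 0) return(moments)
  u1 <- matrix(1 / q, L, q)
  u2 <- matrix(1 / q^2, L * q, L * q)
  for (i in seq_len(L)) {
    idx <- block_idx(i, q)
    u2[idx, idx] <- diag(1 / q, q)
  }
  list(f1 = (1 - pc) * moments$f1 + pc * u1,
       f2 = (1 - pc) * moments$f2 + pc * u2)
}

#' Fit a Potts model to a paired MSA by Boltzmann machine learning
#'
#' Plain gradient descent on the L2-regularized negative log-likelihood with
#' the gradient estimated at each step by Metropolis sampling of the current
#' model at `T = 1` (pooling all recorded configurations from all chains).
#' Termination is by fixed step count; after training the model is shifted to
#' the zero-sum gauge.
#'
#' The reference schedule is 2000 steps with 128 chains of 100,000 sweeps
#' recording every 100 sweeps and `eta = 0.01`; reduced schedules are adequate
#' for small synthetic problems.
#'
#' @param msa A [paired_msa()].
#' @param lambda_reg L2 regularization weight (the value is a modelling
#'   choice; 0.01 is a common default for Potts inference).
#' @param eta Gradient-descent step size.
#' @param n_steps Number of gradient steps.
#' @param n_chains,n_sweeps,record_every Sampler schedule per step.
#' @param seed Master integer seed.
#' @param weights Optional per-row data weights.
#' @param init Chain initialization policy: `"msa"` restarts chains each step
#'   from rows drawn from the alignment; `"random"` from uniform states;
#'   `"persistent"` continues chains from the previous step's last samples.
#' @param pseudocount Optional small admixture of the uniform distribution
#'   into the data moments (default 0; regularization alone is the reference
#'   behaviour).
#' @return A `potts_fit` object: list with the trained `model` (in zero-sum
#'   gauge), the training `log` tibble (step, mean sampled energy, max moment
#'   gap) and the `config`.
#' @export
train_potts <- function(msa, lambda_reg = 0.01, eta = 0.01, n_steps = 2000L,
                        n_chains = 128L, n_sweeps = 100000L,
                        record_every = 100L, seed = 1L, weights = NULL,
                        init = c("msa", "random", "persistent"),
                        pseudocount = 0) {
  init <- match.arg(init)
  stopifnot(inherits(msa, "paired_msa"), nrow(msa$states) > 0,
            eta > 0, n_steps >= 1)
  L <- ncol(msa$states)
  q <- msa$q
  data_m <- apply_pseudocount(site_marginals(msa, weights), pseudocount, L, q)

  h <- matrix(0, L, q)
  J <- matrix(0, L * q, L * q)
  model <- potts_model(h, J, boundary = msa$boundary, q = q)
  steps <- integer(n_steps)
  mean_e <- numeric(n_steps)
  gaps <- numeric(n_steps)
  carry <- NULL
  for (st in seq_len(n_steps)) {
    chain_init <- if (init == "random") NULL
      else if (init == "persistent" && !is.null(carry)) carry
      else msa$states
    samples <- run_chains(model, n_chains = n_chains, n_sweeps = n_sweeps,
                          record_every = record_every, temperature = 1,
                          seed = derive_seed(seed, st), init = chain_init)
    if (init == "persistent") {
      n_rec <- nrow(samples) / n_chains
      carry <- samples[seq(n_rec, nrow(samples), by = n_rec), , drop = FALSE]
    }
    samp_m <- site_marginals(samples, q = q)
    grad <- nll_gradient(model, data_m, samp_m, lambda_reg)
    model$h <- model$h - eta * grad$h
    model$J <- model$J - eta * grad$J
    if (!all(is.finite(model$h)) || !all(is.finite(model$J))) {
      stop("training diverged at step ", st,
           ": non-finite parameters (try smaller eta or larger lambda_reg)",
           call. = FALSE)
    }
    steps[st] <- st
    # mean sampled energy from moments (full f2 matrix double-counts pairs)
    mean_e[st] <- -sum(samp_m$f1 * model$h) - sum(samp_m$f2 * model$J) / 2
    gaps[st] <- max(abs(samp_m$f1 - data_m$f1), abs(samp_m$f2 - data_m$f2))
  }
  model <- to_zero_sum_gauge(model)
  structure(
    list(model = model,
         log = tibble::tibble(step = steps, mean_energy = mean_e,
                              max_moment_gap = gaps),
         config = list(lambda_reg = lambda_reg, eta = eta, n_steps = n_steps,
                       n_chains = n_chains, n_sweeps = n_sweeps,
                       record_every = record_every, seed = seed, init = init,
                       pseudocount = pseudocount)),
    class = "potts_fit"
  )
}

#' @exportS3Method base::print
print.potts_fit <- function(x, ...) {
  cat("<potts_fit> L = ", x$model$L, ", q = ", x$model$q,
      "; ", x$config$n_steps, " gradient steps (lambda = ",
      x$config$lambda_reg, ", eta = ", x$config$eta, ")\n",
      "final max moment gap: ",
      signif(utils::tail(x$log$max_moment_gap, 1), 3), "\n", sep = "")
  invisible(x)
}
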