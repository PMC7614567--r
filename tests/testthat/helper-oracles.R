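# Independent oracles, deliberately implemented with plain loops and no reuse
# of the package's vectorized energy kernels.

# brute-force statistical energy: E = -sum_i h_i(s_i) - sum_{i<j} J_ij(s_i,s_j)
bf_energy <- function(model, s) {
  L <- model$L
  q <- model$q
  e <- 0
  for (i in seq_len(L)) {
    e <- e - model$h[i, s[i]]
    if (i < L) {
      for (j in (i + 1):L) {
        e <- e - model$J[(i - 1) * q + s[i], (j - 1) * q + s[j]]
      }
    }
  }
  e
}

# masked brute-force decomposition into intra-A / intra-B / inter parts
bf_decompose <- function(model, s) {
  L <- model$L
  q <- model$q
  na <- model$boundary
  ea <- eb <- ei <- 0
  for (i in seq_len(L)) {
    if (i <= na) ea <- ea - model$h[i, s[i]] else eb <- eb - model$h[i, s[i]]
  }
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      v <- model$J[(i - 1) * q + s[i], (j - 1) * q + s[j]]
      if (j <= na) ea <- ea - v
      else if (i > na) eb <- eb - v
      else ei <- ei - v
    }
  }
  c(e_intra_a = ea, e_intra_b = eb, e_inter = ei)
}

# exhaustive state enumeration (independent odometer, slow and simple)
bf_all_states <- function(L, q) {
  as.matrix(do.call(expand.grid, rep(list(seq_len(q)), L)))
}

# exact Boltzmann probabilities via the brute-force energy
bf_probs <- function(model, temperature = 1) {
  states <- bf_all_states(model$L, model$q)
  e <- apply(states, 1, function(s) bf_energy(model, s))
  w <- exp(-(e - min(e)) / temperature)
  list(states = states, energy = e, prob = w / sum(w))
}

# encode a state matrix into integer keys (site 1 most significant)
state_keys <- function(states, q) {
  as.vector((states - 1) %*% q^(rev(seq_len(ncol(states))) - 1)) + 1
}

# total variation distance between an empirical sample and exact probabilities
tv_distance <- function(sample_states, exact_states, exact_prob, q) {
  keys_exact <- state_keys(exact_states, q)
  keys_emp <- state_keys(sample_states, q)
  counts <- tabulate(match(keys_emp, keys_exact), nbins = length(keys_exact))
  0.5 * sum(abs(counts / length(keys_emp) - exact_prob))
}

# marginals of an exact enumerated distribution
bf_marginals <- function(states, prob, L, q) {
  f1 <- matrix(0, L, q)
  for (i in seq_len(L)) {
    for (a in seq_len(q)) f1[i, a] <- sum(prob[states[, i] == a])
  }
  f1
}

# a reproducible wild-type pair: the most probable sequence of a toy model
toy_wildtype <- function(model) {
  d <- enumerate_distribution(model)
  s <- d$states[which.max(d$prob), ]
  list(s[seq_len(model$boundary)],
       s[(model$boundary + 1):model$L])
}

# random toy models for parameterized oracle sweeps
random_toy <- function(seed, max_l = 8L, max_q = 4L) {
  set.seed(seed)
  l_a <- sample(2:(max_l %/% 2), 1)
  l_b <- sample(2:(max_l - l_a), 1)
  q <- sample(2:max_q, 1)
  make_toy_model(l_a = l_a, l_b = l_b, q = q,
                 field_scale = stats::runif(1, 0.2, 1),
                 coupling_scale = stats::runif(1, 0.1, 0.6),
                 inter_coupling_scale = stats::runif(1, 0.1, 0.6),
                 seed = seed + 1000L)
}
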