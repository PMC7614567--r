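toy_for_generation <- function(seed = 3) {
  make_toy_model(4, 4, q = 3, field_scale = 0.5, coupling_scale = 0.3,
                 seed = seed)
}

count_mutations <- function(repertoire, wt, part) {
  wt_part <- wt[[if (part == "a") 1 else 2]]
  seqs <- encode_sequences(repertoire[[paste0("mutant_", part)]], q = 21)
  rowSums(seqs != matrix(wt_part, nrow(seqs), length(wt_part), byrow = TRUE))
}

test_that("every recorded mutant satisfies the mutation-count constraint", {
  m <- toy_for_generation()
  wt <- toy_wildtype(m)
  for (rep in list(
    direct_sample(m, wt, k_a = 2, k_b = 1, temperature = 1.5,
                  n_samples = 500, record_every = 2, seed = 1),
    conditional_sample(m, wt, k_a = 2, k_b = 1, temperature = 1, t2 = 2,
                       n_samples = 500, record_every = 2, seed = 2)
  )) {
    expect_true(all(count_mutations(rep, wt, "a") == 2))
    expect_true(all(count_mutations(rep, wt, "b") == 1))
  }
  # and with a position restriction, mutations stay inside the allowed set
  allowed <- list(a = c(1L, 3L), b = c(2L, 4L))
  rep <- direct_sample(m, wt, k_a = 1, k_b = 1, temperature = 1,
                       n_samples = 300, record_every = 2,
                       allowed_positions = allowed, seed = 3)
  pos_a <- as.integer(unlist(strsplit(rep$positions_a, ",")))
  pos_b <- as.integer(unlist(strsplit(rep$positions_b, ",")))
  expect_true(all(pos_a %in% allowed$a))
  expect_true(all(pos_b %in% allowed$b))
})

test_that("gap mutations are excluded unless explicitly allowed", {
  m <- make_toy_model(3, 3, q = 21, field_scale = 0.3, coupling_scale = 0.1,
                      seed = 9)
  wt <- list(c(1L, 5L, 7L), c(2L, 9L, 4L))
  rep <- direct_sample(m, wt, k_a = 1, k_b = 1, temperature = 2,
                       n_samples = 400, record_every = 1, seed = 4)
  expect_false(any(grepl("-", rep$mutant_a, fixed = TRUE)))
  expect_false(any(grepl("-", rep$mutant_b, fixed = TRUE)))
  rep_gap <- direct_sample(m, wt, k_a = 1, k_b = 1, temperature = 5,
                           n_samples = 2000, record_every = 1, seed = 5,
                           allow_gap_mutations = TRUE)
  expect_true(any(grepl("-", paste0(rep_gap$mutant_a, rep_gap$mutant_b),
                        fixed = TRUE)))
})

test_that("infeasible constraints and bad wild types are rejected", {
  m <- toy_for_generation()
  wt <- toy_wildtype(m)
  expect_error(direct_sample(m, wt, k_a = 5, k_b = 1), "infeasible")
  expect_error(direct_sample(m, wt, k_a = 0, k_b = 0), "positive")
  expect_error(direct_sample(m, list(wt[[1]][-1], wt[[2]]), k_a = 1,
                             k_b = 1), "boundary")
  expect_error(conditional_sample(m, wt, k_a = 1, k_b = 1, t2 = 0), "t2")
})

test_that("identical config and seed reproduce the repertoire exactly", {
  m <- toy_for_generation()
  wt <- toy_wildtype(m)
  r1 <- direct_sample(m, wt, k_a = 1, k_b = 1, temperature = 1,
                      n_samples = 200, record_every = 2, seed = 11)
  r2 <- direct_sample(m, wt, k_a = 1, k_b = 1, temperature = 1,
                      n_samples = 200, record_every = 2, seed = 11)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

restricted_exact <- function(m, wt, temperature = 1, t2 = Inf) {
  # enumerate the (k_a = 1, k_b = 1) constrained space with its exact weights
  wt_full <- c(wt[[1]], wt[[2]])
  na <- m$boundary
  rows <- list()
  for (pa in seq_len(na)) for (sa in setdiff(seq_len(m$q), wt_full[pa])) {
    for (pb in (na + 1):m$L) for (sb in setdiff(seq_len(m$q), wt_full[pb])) {
      s <- wt_full
      s[pa] <- sa
      s[pb] <- sb
      d <- bf_decompose(m, s)
      # chimera cross-talk terms against the wild-type partner
      e_mw <- bf_decompose(m, c(s[seq_len(na)], wt[[2]]))
      e_wm <- bf_decompose(m, c(wt[[1]], s[(na + 1):m$L]))
      loss <- sum(d) / temperature -
        (if (is.finite(t2)) (e_mw[["e_inter"]] + e_wm[["e_inter"]]) / t2
         else 0)
      rows[[length(rows) + 1]] <- c(s, loss)
    }
  }
  tab <- do.call(rbind, rows)
  w <- exp(-(tab[, m$L + 1] - min(tab[, m$L + 1])))
  list(states = tab[, seq_len(m$L), drop = FALSE], prob = w / sum(w))
}

test_that("direct sampling matches restricted-enumeration weights", {
  m <- toy_for_generation()
  wt <- toy_wildtype(m)
  exact <- restricted_exact(m, wt, temperature = 1)
  rep <- direct_sample(m, wt, k_a = 1, k_b = 1, temperature = 1,
                       n_samples = 50000, record_every = 2, seed = 21)
  emp <- encode_sequences(paste0(rep$mutant_a, rep$mutant_b), q = 3)
  expect_lt(tv_distance(emp, exact$states, exact$prob, q = 3), 0.02)
})

test_that("conditional sampling matches its stationary law and limits", {
  m <- toy_for_generation()
  wt <- toy_wildtype(m)
  # exact conditional weights at T = 1, T2 = 1
  exact_c <- restricted_exact(m, wt, temperature = 1, t2 = 1)
  rep_c <- conditional_sample(m, wt, k_a = 1, k_b = 1, temperature = 1,
                              t2 = 1, n_samples = 50000, record_every = 2,
                              seed = 22)
  emp_c <- encode_sequences(paste0(rep_c$mutant_a, rep_c$mutant_b), q = 3)
  expect_lt(tv_distance(emp_c, exact_c$states, exact_c$prob, q = 3), 0.02)

  # T2 -> Inf reduces the conditional law to the direct one
  exact_d <- restricted_exact(m, wt, temperature = 1)
  rep_inf <- conditional_sample(m, wt, k_a = 1, k_b = 1, temperature = 1,
                                t2 = 1e12, n_samples = 50000,
                                record_every = 2, seed = 23)
  emp_inf <- encode_sequences(paste0(rep_inf$mutant_a, rep_inf$mutant_b),
                              q = 3)
  expect_lt(tv_distance(emp_inf, exact_d$states, exact_d$prob, q = 3), 0.02)
})

test_that("the t2 cross-talk reward tilts scores above direct sampling and decays with t2", {
  # under the conditional law ~ exp(-cognate/T + cross/T2) the mean total
  # cross-talk score is monotone in the tilt 1/T2 and converges to the
  # direct-sampling mean as T2 grows
  m <- toy_for_generation(seed = 13)
  wt <- toy_wildtype(m)
  cross_mean <- function(rep) {
    mean(rep$d_inter_astar_b + rep$d_inter_a_bstar)
  }
  direct <- direct_sample(m, wt, k_a = 1, k_b = 1, temperature = 1,
                          n_samples = 8000, record_every = 2, seed = 30)
  means <- vapply(c(1, 4), function(t2) {
    cross_mean(conditional_sample(m, wt, k_a = 1, k_b = 1, temperature = 1,
                                  t2 = t2, n_samples = 8000,
                                  record_every = 2, seed = 31))
  }, numeric(1))
  expect_gt(means[1], means[2])             # stronger tilt, higher reward
  expect_gt(means[2], cross_mean(direct))   # both above the direct baseline
})

test_that("model-guided sampling beats uniform random mutants on cognate scores", {
  m <- toy_for_generation(seed = 17)
  wt <- toy_wildtype(m)
  rep <- direct_sample(m, wt, k_a = 1, k_b = 1, temperature = 1,
                       n_samples = 4000, record_every = 2, seed = 41)
  rnd <- random_mutants(wt, k_a = 1, k_b = 1, n_samples = 4000, q = 3,
                        seed = 42, model = m)
  expect_lt(mean(rep$d_inter_cognate + rep$d_intra_a + rep$d_intra_b),
            mean(rnd$d_inter_cognate + rnd$d_intra_a + rnd$d_intra_b))
})

test_that("higher sampling temperature raises the mean total energy", {
  m <- toy_for_generation(seed = 19)
  wt <- toy_wildtype(m)
  tot <- vapply(c(0.5, 1, 2), function(tt) {
    rep <- direct_sample(m, wt, k_a = 1, k_b = 1, temperature = tt,
                         n_samples = 6000, record_every = 2, seed = 51)
    mean(rep$d_intra_a + rep$d_intra_b + rep$d_inter_cognate)
  }, numeric(1))
  expect_true(all(diff(tot) > 0))
})
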