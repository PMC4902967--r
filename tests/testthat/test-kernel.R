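test_that("mutation map reproduces hand-evaluated biallelic cases", {
  p0 <- model_params(10, c = 0, mu = 0)
  nu <- c(0.3, 0.2, 0.5)
  expect_equal(mutate_freqs(nu, p0), nu) # mu = 0 is the identity
  p5 <- model_params(10, c = 0, mu = 0.5)
  expect_equal(mutate_freqs(c(0, 1, 0), p5), c(0.25, 0.5, 0.25))
  expect_equal(mutate_freqs(c(1, 0, 0), p5), c(0.25, 0.5, 0.25))
})

test_that("mutation map equals the two-slot substitution construction", {
  set.seed(11)
  for (n in 2:4) {
    for (mu in c(1e-4, 0.05, 0.3)) {
      p <- model_params(10, c = 0, mu = mu, n_alleles = n)
      for (rep in 1:5) {
        nu <- random_freq(p$g)
        expect_equal(mutate_freqs(nu, p), oracle_mutate(nu, n, mu),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("all deterministic maps conserve total frequency", {
  set.seed(12)
  for (n in 2:3) {
    p <- model_params(20, c = 0.4, mu = 0.02, n_alleles = n)
    for (rep in 1:10) {
      nu <- random_freq(p$g)
      expect_equal(sum(mutate_freqs(nu, p)), 1, tolerance = 1e-12)
      expect_equal(sum(gamete_freqs(nu, p)), 1, tolerance = 1e-12)
      expect_equal(sum(reproduce_freqs(nu, p)), 1, tolerance = 1e-12)
      expect_equal(sum(step_expected(nu, p)), 1, tolerance = 1e-12)
    }
  }
})

test_that("gamete frequencies halve the heterozygotes", {
  p <- model_params(10, c = 0, mu = 0)
  expect_equal(gamete_freqs(c(0, 1, 0), p), c(0.5, 0.5))
  expect_equal(gamete_freqs(c(1, 0, 0), p), c(1, 0))
  expect_equal(gamete_freqs(c(0.25, 0.5, 0.25), p), c(0.5, 0.5))
})

test_that("reproduction mixes clonal copy with Hardy-Weinberg proportions", {
  pc1 <- model_params(10, c = 1, mu = 0)
  nu <- c(0.1, 0.6, 0.3)
  expect_equal(reproduce_freqs(nu, pc1), nu) # fully clonal: unchanged
  pc0 <- model_params(10, c = 0, mu = 0)
  expect_equal(reproduce_freqs(c(0, 1, 0), pc0), c(0.25, 0.5, 0.25))
  pch <- model_params(10, c = 0.5, mu = 0)
  expect_equal(reproduce_freqs(c(0, 1, 0), pch), c(0.125, 0.75, 0.125))
})

test_that("random mating always lands on the HWE parabola", {
  set.seed(13)
  for (n in 2:3) {
    p <- model_params(10, c = 0, mu = 0, n_alleles = n)
    for (rep in 1:10) {
      out <- reproduce_freqs(random_freq(p$g), p)
      expect_equal(fis_of_freq(out, p), 0, tolerance = 1e-12)
    }
  }
})

test_that("mutation alone converges to isoplethy and F_IS = 0", {
  p <- model_params(10, c = 0, mu = 0.02, n_alleles = 3)
  nu <- c(1, 0, 0, 0, 0, 0)
  for (i in 1:4000) nu <- mutate_freqs(nu, p)
  expect_equal(gamete_freqs(nu, p), rep(1 / 3, 3), tolerance = 1e-8)
  expect_equal(fis_of_freq(nu, p), 0, tolerance = 1e-8)
})

test_that("one-cycle expected frequencies behave at the fixed points", {
  pd <- model_params(100, c = 1, mu = 0)
  expect_equal(step_expected(c(33, 34, 33), pd), c(33, 34, 33) / 100)
  ps <- model_params(100, c = 0, mu = 0)
  expect_equal(step_expected(c(0, 100, 0), ps), c(0.25, 0.5, 0.25))
  ph <- model_params(100, c = 0.8, mu = 1e-6)
  expect_equal(step_expected(c(25, 50, 25), ph), c(0.25, 0.5, 0.25),
               tolerance = 1e-5)
})

test_that("transition probabilities are the multinomial of the cycle", {
  p1 <- model_params(1, c = 1, mu = 0)
  expect_equal(transition_prob(c(0, 1, 0), c(0, 1, 0), p1), 1)
  p2 <- model_params(2, c = 1, mu = 0)
  expect_equal(transition_prob(c(1, 1, 0), c(2, 0, 0), p2), 0.25)
  # normalisation over all target states
  p3 <- model_params(3, c = 0.3, mu = 0.02)
  sp <- enumerate_states(p3)
  from <- c(1, 1, 1)
  tot <- sum(vapply(seq_len(nrow(sp$counts)), function(i) {
    transition_prob(from, state_counts(sp, i), p3)
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("transition matrix matches the term-by-term factorial oracle", {
  p <- model_params(3, c = 0.5, mu = 0.01)
  sp <- enumerate_states(p)
  M <- as.matrix(transition_matrix(p, space = sp))
  for (j in seq_len(ncol(M))) {
    nu <- step_expected(state_counts(sp, j), p)
    for (i in seq_len(nrow(M))) {
      expect_equal(M[i, j],
                   oracle_multinomial_pmf(state_counts(sp, i), nu),
                   tolerance = 1e-12)
    }
  }
})

test_that("transition matrices are column-stochastic; degenerate chain is identity", {
  for (pars in list(model_params(2, c = 0.2, mu = 0.1),
                    model_params(3, c = 0.9, mu = 1e-4),
                    model_params(4, c = 1, mu = 0),
                    model_params(3, c = 0.5, mu = 0.05, n_alleles = 3))) {
    M <- as.matrix(transition_matrix(pars))
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(unname(colSums(M)), rep(1, ncol(M)), tolerance = 1e-10)
  }
  Mi <- as.matrix(transition_matrix(model_params(1, c = 1, mu = 0)))
  expect_equal(Mi, diag(3), ignore_attr = TRUE)
})

test_that("positive mutation makes every transition possible", {
  M <- as.matrix(transition_matrix(model_params(3, c = 0.5, mu = 0.01)))
  expect_true(all(M > 0))
})
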