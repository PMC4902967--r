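params_small <- model_params(3, c = 0.5, mu = 0.01)

test_that("propagation conserves probability and honours t = 0", {
  M <- transition_matrix(params_small)
  x0 <- suppressWarnings(preset_start(params_small, 1))
  tr <- propagate(M, x0, 8)
  expect_equal(unname(colSums(tr$dist)), rep(1, 9), tolerance = 1e-10)
  expect_equal(distribution_at(tr, 0)$probs,
               as.numeric(seq_len(10) == state_index(M$space, x0)))
  # identity chain: point mass never moves
  Mi <- transition_matrix(model_params(1, c = 1, mu = 0))
  tri <- propagate(Mi, c(0, 1, 0), 5)
  expect_equal(tri$dist, matrix(rep(c(0, 1, 0), 6), 3))
})

test_that("exact propagation equals brute-force path enumeration", {
  sp <- enumerate_states(params_small)
  S <- nrow(sp$counts)
  # independent pairwise pmf table straight from transition_prob()
  P <- outer(seq_len(S), seq_len(S), Vectorize(function(to, from) {
    transition_prob(state_counts(sp, from), state_counts(sp, to),
                    params_small)
  }))
  start <- state_index(sp, c(1, 1, 1))
  t_max <- 4
  paths <- do.call(expand.grid, rep(list(seq_len(S)), t_max))
  x4 <- numeric(S)
  for (r in seq_len(nrow(paths))) {
    chain <- c(start, as.integer(paths[r, ]))
    pr <- 1
    for (s in seq_len(t_max)) pr <- pr * P[chain[s + 1], chain[s]]
    x4[chain[t_max + 1]] <- x4[chain[t_max + 1]] + pr
  }
  M <- transition_matrix(params_small, space = sp)
  tr <- propagate(M, c(1, 1, 1), t_max)
  expect_equal(distribution_at(tr, 4)$probs, x4, tolerance = 1e-10)
})

test_that("power iteration and direct solve agree on the steady state", {
  for (p in list(params_small,
                 model_params(4, c = 0.9, mu = 0.05),
                 model_params(3, c = 0, mu = 0.2, n_alleles = 3))) {
    M <- transition_matrix(p)
    s1 <- steady_state(M, method = "power")$probs
    s2 <- steady_state(M, method = "solve")$probs
    expect_equal(s1, s2, tolerance = 1e-8)
    expect_equal(sum(s1), 1, tolerance = 1e-10)
  }
})

test_that("symmetric mutation gives an allele-exchange-symmetric steady state", {
  M <- transition_matrix(model_params(1, c = 0.5, mu = 0.5))
  s <- steady_state(M)$probs
  # states: (1,0,0), (0,1,0), (0,0,1); relabelling alleles swaps the homozygotes
  expect_equal(s[1], s[3], tolerance = 1e-10)
})

test_that("drift-only chain must go through the absorption analysis", {
  M <- transition_matrix(model_params(3, c = 1, mu = 0))
  expect_error(steady_state(M), "absorption_profile")
})

test_that("fis_summary condenses point masses and mixtures correctly", {
  p <- model_params(100, c = 0, mu = 0)
  sp <- enumerate_states(p)
  point <- function(counts) {
    x <- numeric(nrow(sp$counts))
    x[state_index(sp, counts)] <- 1
    fisdyn:::new_state_distribution(x, 0, sp)
  }
  s <- fis_summary(point(c(25, 50, 25)))
  expect_equal(s$mean_fis, 0)
  expect_equal(s$var_fis, 0)
  expect_equal(s$p_fix, 0)
  sfix <- fis_summary(point(c(100, 0, 0)))
  expect_true(is.na(sfix$mean_fis))
  expect_equal(sfix$p_fix, 1)
  x <- numeric(nrow(sp$counts))
  x[state_index(sp, c(0, 100, 0))] <- 0.5
  x[state_index(sp, c(25, 50, 25))] <- 0.5
  smix <- fis_summary(fisdyn:::new_state_distribution(x, 0, sp))
  expect_equal(smix$mean_fis, -0.5)
})

test_that("mixing time satisfies its threshold definition", {
  M <- transition_matrix(params_small)
  eps <- 1 / (2 * params_small$N)
  tmix <- mixing_time(M, epsilon = eps)
  pi_vec <- steady_state(M)$probs
  tv_at <- function(t) {
    D <- diag(nrow(M$M))
    for (s in seq_len(t)) D <- M$M %*% D
    max(0.5 * colSums(abs(D - pi_vec)))
  }
  expect_lt(tv_at(tmix), eps)
  expect_gte(tv_at(tmix - 1), eps)
})

test_that("clonality slows mixing; TV distance decreases monotonically", {
  times <- vapply(c(0, 0.5, 0.9), function(cc) {
    as.integer(mixing_time(transition_matrix(model_params(3, c = cc,
                                                          mu = 0.01))))
  }, integer(1))
  expect_true(all(diff(times) >= 0))
  # monotone approach to the steady state
  M <- transition_matrix(params_small)
  pi_vec <- steady_state(M)$probs
  x <- as.numeric(seq_len(10) == 1)
  tv <- numeric(30)
  for (t in 1:30) {
    x <- as.vector(M$M %*% x)
    tv[t] <- 0.5 * sum(abs(x - pi_vec))
  }
  expect_true(all(diff(tv) <= 1e-12))
})

test_that("multinomial drift is a martingale in expected frequencies", {
  p <- model_params(6, c = 1, mu = 0)
  M <- transition_matrix(p)
  sp <- M$space
  for (counts in list(c(2, 2, 2), c(1, 4, 1), c(0, 5, 1))) {
    x1 <- as.vector(M$M %*% as.numeric(
      seq_len(nrow(sp$counts)) == state_index(sp, counts)))
    expect_equal(as.vector(t(sp$counts / p$N) %*% x1), counts / p$N,
                 tolerance = 1e-12)
  }
})

test_that("absorption times solve the drift first-passage system", {
  # N = 1: every state is monomorphic-genotype, nothing transient
  ap1 <- absorption_profile(model_params(1, c = 1, mu = 0))
  expect_equal(ap1$table$expected_time, rep(0, 3))
  expect_equal(ap1$t_N, 0)
  # N = 2 biallelic: from any two-genotype state the stay probability is
  # 1/2 each generation, so the expected absorption time is exactly 2
  ap2 <- absorption_profile(model_params(2, c = 1, mu = 0))
  tab <- tidy(ap2)
  expect_equal(tab$expected_time[!tab$absorbing], rep(2, 3))
  expect_equal(ap2$t_N, 2)
  # hitting probabilities from (1,1,0) split evenly between its genotypes
  h <- tab[tab$q_A1A1 == 1 & tab$q_A1A2 == 1, ]
  expect_equal(h$p_hit_q_A1A1, 0.5)
  expect_equal(h$p_hit_q_A1A2, 0.5)
  expect_error(absorption_profile(model_params(5, c = 1, mu = 1e-3)),
               "drift-only")
})
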