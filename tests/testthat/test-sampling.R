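test_that("simulation is bit-reproducible under a fixed seed", {
  p <- model_params(48, c = 0.6, mu = 1e-3)
  s1 <- simulate_loci(p, preset_start(p, 0), 10, n_loci = 200, seed = 7)
  s2 <- simulate_loci(p, preset_start(p, 0), 10, n_loci = 200, seed = 7)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_loci(p, preset_start(p, 0), 10, n_loci = 200, seed = 8)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("clonal heterozygote stock drifts as a martingale", {
  p <- model_params(10, c = 1, mu = 0)
  # pure heterozygote start cannot lose its only genotype
  s <- simulate_loci(p, c(0, 10, 0), 5, n_loci = 500, seed = 1)
  expect_true(all(s$counts[[6]][, 2] == 10))
  # mixed start: expected heterozygote frequency is conserved
  s2 <- simulate_loci(p, c(2, 6, 2), 10, n_loci = 4000, seed = 2)
  sm <- sim_summary(s2)
  se <- sqrt(0.6 * 0.4 / (10 * 4000))
  expect_lt(abs(sm$mean_Ho[11] - 0.6), 3 * se)
})

test_that("one sexual generation restores Hardy-Weinberg proportions", {
  N <- 1e4
  p <- model_params(N, c = 0, mu = 0)
  s <- simulate_loci(p, c(0, N, 0), 1, n_loci = 200, seed = 3)
  frac <- colMeans(s$counts[[2]]) / N
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / (N * 200))
  expect_true(all(abs(frac - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("Monte Carlo agrees with the exact chain on a small system", {
  p <- model_params(3, c = 0.5, mu = 0.01)
  M <- transition_matrix(p)
  tr <- propagate(M, c(1, 1, 1), 3)
  exact <- distribution_at(tr, 3)$probs
  n_loci <- 2e4
  sim <- simulate_loci(p, c(1, 1, 1), 3, n_loci = n_loci, seed = 5)
  idx <- apply(sim$counts[[4]], 1, function(q) state_index(M$space, q))
  obs <- tabulate(idx, nbins = length(exact))
  expect_gt(suppressWarnings(chisq.test(obs, p = exact))$p.value, 0.01)
})

test_that("multilocus sample means average i.i.d. locus draws", {
  p <- model_params(4, c = 0, mu = 0)
  sp <- enumerate_states(p)
  x <- numeric(nrow(sp$counts))
  x[state_index(sp, c(1, 2, 1))] <- 1 # exact HWE point mass, fis = 0
  dist <- fisdyn:::new_state_distribution(x, 0, sp)
  m <- sample_fis_means(dist, L = 5, n_samples = 100, seed = 1)
  expect_equal(as.numeric(m), rep(0, 100))
  expect_equal(attr(m, "true_mean"), 0)
})

test_that("sample-mean variance scales as 1/L", {
  p <- model_params(4, c = 0.8, mu = 0.05)
  dist <- steady_state(transition_matrix(p))
  Ls <- c(2, 4, 8, 16, 32)
  vars <- vapply(Ls, function(L) {
    stats::var(sample_fis_means(dist, L, n_samples = 2e4, seed = 11))
  }, numeric(1))
  slope <- coef(lm(log(vars) ~ log(Ls)))[2]
  expect_lt(abs(slope + 1), 0.1)
})

test_that("signed deviations split at the true mean", {
  d <- signed_deviation(c(0.2, -0.1, -0.3), true_mean = 0)
  expect_equal(d$delta_plus, 0.2)
  expect_equal(d$delta_minus, -0.2)
  expect_equal(d$z1, 1)
  expect_equal(d$z2, 2)
  dd <- signed_deviation(rep(0.5, 10), true_mean = 0.5)
  expect_equal(dd$delta_plus, 0)
  expect_equal(dd$delta_minus, 0)
  expect_equal(dd$z1 + dd$z2, 10)
})

test_that("more loci shrink the sampling deviations", {
  p <- model_params(4, c = 0.8, mu = 0.05)
  dist <- steady_state(transition_matrix(p))
  d_small <- signed_deviation(sample_fis_means(dist, 5, 2e4, seed = 21))
  d_large <- signed_deviation(sample_fis_means(dist, 50, 2e4, seed = 21))
  expect_lt(d_large$delta_plus, d_small$delta_plus)
  expect_gt(d_large$delta_minus, d_small$delta_minus)
})

test_that("near-fixed exclusion conditions the sampled distribution", {
  p <- model_params(6, c = 0.9, mu = 0.01)
  dist <- steady_state(transition_matrix(p))
  d <- fisdyn:::state_fis_table(dist$space)
  m_nf <- sample_fis_means(dist, 3, 1000, seed = 2, exclude = "near_fixed")
  true_nf <- sum(dist$probs[!d$fixed & !d$near_fixed] *
                   d$fis[!d$fixed & !d$near_fixed]) /
    sum(dist$probs[!d$fixed & !d$near_fixed])
  expect_equal(attr(m_nf, "true_mean"), true_nf)
  # simulation snapshots can be sampled too
  sim <- simulate_loci(p, c(1, 4, 1), 5, n_loci = 500, seed = 4)
  ms <- sample_fis_means(sim, 3, 500, seed = 5, t = 5)
  expect_length(as.numeric(ms), 500)
})

test_that("tidy and summary views expose per-locus records", {
  p <- model_params(10, c = 0.5, mu = 0.01)
  sim <- simulate_loci(p, suppressWarnings(preset_start(p, 0)), 3,
                       n_loci = 20, seed = 9)
  tab <- tidy(sim)
  expect_equal(nrow(tab), 20 * 4)
  expect_true(all(c("locus", "t", "q_A1A1", "fis") %in% names(tab)))
  expect_true(all(rowSums(tab[, c("q_A1A1", "q_A1A2", "q_A2A2")]) == 10))
  sm <- sim_summary(sim)
  expect_equal(sm$t, 0:3)
  # rounded HWE start is (2, 6, 2): Ho = 0.6, He = 0.5, fis = -0.2
  expect_equal(sm$mean_fis[1], -0.2)
})
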