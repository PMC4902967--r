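# Independent oracles kept free of the package's own code paths.

# all compositions of N into g parts by brute-force grid filtering
oracle_compositions <- function(N, g) {
  grid <- do.call(expand.grid, rep(list(0:N), g - 1))
  keep <- rowSums(grid) <= N
  m <- as.matrix(cbind(grid[keep, , drop = FALSE],
                       N - rowSums(grid[keep, , drop = FALSE])))
  dimnames(m) <- NULL
  m
}

# k-alleles mutation via the two-slot substitution-matrix construction:
# expand unordered genotype frequencies to ordered allele pairs, mutate
# each slot independently, re-collapse
oracle_mutate <- function(nu, n, mu) {
  a <- 1 - mu; b <- mu / (n - 1)
  S <- matrix(b, n, n); diag(S) <- a
  pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  O <- matrix(0, n, n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (i == j) O[i, i] <- nu[k] else {
      O[i, j] <- nu[k] / 2; O[j, i] <- nu[k] / 2
    }
  }
  O2 <- S %*% O %*% t(S)
  out <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    out[k] <- if (i == j) O2[i, i] else O2[i, j] + O2[j, i]
  }
  out
}

# literal factorial-formula multinomial pmf
oracle_multinomial_pmf <- function(counts, prob) {
  factorial(sum(counts)) / prod(factorial(counts)) * prod(prob^counts)
}

# random frequency vector of length g
random_freq <- function(g) {
  x <- stats::runif(g)
  x / sum(x)
}

# F_IS of a genotype frequency vector (He - Ho)/He
fis_of_freq <- function(nu, params) {
  p <- gamete_freqs(nu, params)
  he <- 1 - sum(p^2)
  idx <- which(upper.tri(diag(params$n), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  ho <- sum(nu[idx[, 1] != idx[, 2]])
  (he - ho) / he
}
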