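#' Equilibrium mean F_IS of the single-population reference model
#'
#' Closed-form mean inbreeding coefficient at mutation-drift-reproduction
#' equilibrium for one finite, isolated, partially clonal population under
#' an infinite-alleles mutation model:
#' \deqn{\bar F_{IS,\infty} = \frac{1}{(2N - 1) - 2N / (c (1-\mu)^2)}.}
#' The value is negative for all `c` in `(0, 1]` (a standing heterozygote
#' excess), approaches `-1` as `c -> 1`, `mu -> 0` at small `N`, and
#' vanishes as `N` grows. At `c = 0` the equilibrium mean is 0 (random
#' mating) and is returned as the limit with a message.
#'
#' This is the single-population specialisation of a more general
#' metapopulation identity-by-descent recursion (probability of common
#' origin within subpopulation `q_s = 1`, between subpopulations
#' `q_d = 0`, selfing at the random-mating rate `1/N`); the general form
#' is available internally as `fis_metapop()`.
#'
#' Because the reference model tracks allele identities under infinite
#' alleles, it need not agree with the finite k-alleles chain: with few
#' alleles, back mutation restores heterozygosity and the exact chain's
#' stationary mean F_IS is much closer to 0 than this closed form.
#'
#' @param c Rate of clonality in `(0, 1]`. Vectorised.
#' @param mu Mutation rate. Vectorised.
#' @param N Population size. Vectorised.
#' @return Mean equilibrium F_IS.
#' @examples
#' equilibrium_fis(0.97, 1e-6, 100) # about -0.14
#' equilibrium_fis(0.99, 1e-6, 100) # about -0.33
#' @export
equilibrium_fis <- function(c, mu, N) {
  stopifnot(all(c >= 0), all(c <= 1), all(mu >= 0), all(mu < 1),
            all(N >= 1))
  out <- ifelse(c == 0, 0,
                1 / ((2 * N - 1) - 2 * N / (c * (1 - mu)^2)))
  if (any(c == 0)) {
    message("c = 0: returning the random-mating limit 0")
  }
  out
}

# general metapopulation form; qs = 1, qd = 0 gives equilibrium_fis()
fis_metapop <- function(c, mu, N, qs = 1, qd = 0) {
  g <- (1 - mu)^2
  num <- g * (qs - c * (g * (qs - qd) - 1) - 1)
  den <- 2 * N * (1 - g * c) * (g * (qs - qd) - 1) - num
  num / den
}

#' Invert the equilibrium mean F_IS for the rate of clonality
#'
#' Algebraic inversion of [equilibrium_fis()]:
#' `c = 2N / ((1-mu)^2 * ((2N - 1) - 1/fis_bar))`. Used to read a rate of
#' clonality off an observed multilocus mean F_IS under the equilibrium
#' assumption. The result is insensitive to `mu` over the realistic range
#' (the `(1-mu)^2` factor is essentially 1 below `mu = 1e-3`).
#'
#' @param fis_bar Observed mean F_IS; must be negative (the equilibrium
#'   model only produces negative means).
#' @param mu Assumed mutation rate.
#' @param N Population size.
#' @return Inferred `c` in `(0, 1]`; values outside are clipped with a
#'   warning.
#' @examples
#' infer_clonality(-0.083, mu = 1e-6, N = 247) # about 0.98
#' @export
infer_clonality <- function(fis_bar, mu, N) {
  stopifnot(all(N >= 2), all(mu >= 0), all(mu < 1))
  if (any(fis_bar >= 0)) {
    stop("observed mean F_IS must be negative: the equilibrium model ",
         "yields negative means for every c in (0, 1]", call. = FALSE)
  }
  cc <- 2 * N / ((1 - mu)^2 * ((2 * N - 1) - 1 / fis_bar))
  if (any(cc <= 0 | !is.finite(cc))) {
    stop("observed mean F_IS is inconsistent with the equilibrium model ",
         "for this N", call. = FALSE)
  }
  if (any(cc > 1)) {
    warning("inferred c exceeds 1 (observed mean more negative than the ",
            "full-clonality equilibrium); clipping to 1", call. = FALSE)
    cc <- pmin(cc, 1)
  }
  cc
}

#' One step of the heterozygosity identity recursion
#'
#' The reference model tracks `F` (probability of allele identity within
#' an individual, `1 - Ho`) and `Theta` (identity between two alleles
#' drawn from the population, `1 - He`) through the affine recursion
#' \deqn{\binom{F_{t+1}}{\Theta_{t+1}} = (1-\mu)^2 \left( A
#'   \binom{F_t}{\Theta_t} + b \right),}
#' \deqn{A = \begin{pmatrix} c + \frac{1-c}{2N} & (1-c)(1-\frac1N) \\
#'   \frac{1}{2N} & 1 - \frac1N \end{pmatrix}, \quad
#'   b = \begin{pmatrix} \frac{1-c}{2N} \\ \frac{1}{2N} \end{pmatrix}.}
#' The intercept's first entry is `(1-c)/(2N)`: a sexual offspring selfs
#' with probability `1/N` and a selfed offspring is identical-by-state
#' with probability `(1 + F)/2`, which contributes `(1-c)/(2N)` both to
#' the `F` coefficient and to the constant term. With this intercept the
#' recursion's fixed point reproduces [equilibrium_fis()] exactly for all
#' parameters (see [balloux_fixed_point()]).
#'
#' @param pair Numeric `c(F, Theta)`.
#' @param c,mu,N Model parameters.
#' @return Updated `c(F, Theta)` with attribute-free numeric values.
#' @export
balloux_step <- function(pair, c, mu, N) {
  stopifnot(length(pair) == 2, all(pair >= 0), all(pair <= 1))
  g <- (1 - mu)^2
  A <- matrix(c(c + (1 - c) / (2 * N), 1 / (2 * N),
                (1 - c) * (1 - 1 / N), 1 - 1 / N), 2, 2)
  b <- c((1 - c) / (2 * N), 1 / (2 * N))
  unname(g * (as.vector(A %*% pair) + b))
}

#' Fixed point of the identity recursion
#'
#' Solves the 2x2 linear system `(I - gamma A) x = gamma b` directly and
#' reports the corresponding F_IS `(F - Theta)/(1 - Theta)`.
#'
#' @inheritParams balloux_step
#' @return One-row tibble `F`, `Theta`, `fis`.
#' @export
balloux_fixed_point <- function(c, mu, N) {
  g <- (1 - mu)^2
  A <- matrix(c(c + (1 - c) / (2 * N), 1 / (2 * N),
                (1 - c) * (1 - 1 / N), 1 - 1 / N), 2, 2)
  b <- c((1 - c) / (2 * N), 1 / (2 * N))
  x <- solve(diag(2) - g * A, g * b)
  tibble::tibble(F = x[1], Theta = x[2],
                 fis = (x[1] - x[2]) / (1 - x[2]))
}

#' Generations for the recursion's F_IS to reach its equilibrium
#'
#' Iterates [balloux_step()] from a start pair until
#' `|fis_t - fis_inf| < epsilon`. The default start `F = Theta = 0.5`
#' matches the biallelic isoplethic Hardy-Weinberg preset
#' (`Ho = He = 0.5`).
#'
#' @inheritParams balloux_step
#' @param epsilon Convergence threshold; default `1/(2N)`.
#' @param start Numeric `c(F0, Theta0)`.
#' @param max_iter Iteration budget.
#' @return Integer number of generations (0 if already converged).
#' @export
balloux_time <- function(c, mu, N, epsilon = NULL,
                         start = c(0.5, 0.5), max_iter = 1e7) {
  if (is.null(epsilon)) epsilon <- default_epsilon(N)
  target <- balloux_fixed_point(c, mu, N)$fis
  pair <- start
  fis_of <- function(p) (p[1] - p[2]) / (1 - p[2])
  if (abs(fis_of(pair) - target) < epsilon) return(0L)
  for (t in seq_len(max_iter)) {
    pair <- balloux_step(pair, c, mu, N)
    if (abs(fis_of(pair) - target) < epsilon) return(as.integer(t))
  }
  stop("identity recursion did not converge within ", max_iter,
       " iterations", call. = FALSE)
}
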