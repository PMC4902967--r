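#' One-generation deterministic genotype-frequency maps
#'
#' The life cycle acts on genotype frequencies in three deterministic
#' stages before drift: mutation, gamete formation and reproduction.
#'
#' *Mutation* applies the symmetric k-alleles scheme independently to both
#' allele copies: an allele stays with probability `alpha = 1 - mu` and
#' becomes one specific other allele with probability `beta = mu/(n-1)`.
#' On unordered genotype frequencies this is the linear map
#' \deqn{\nu_{ii,I} = \alpha^2 \nu_{ii} + \alpha\beta \sum_{j \ne i} \nu_{ij}
#'   + \beta^2 (\sum_{j \ne i} \nu_{jj} + \sum_{j<k \ne i} \nu_{jk})}
#' \deqn{\nu_{ij,I} = (\alpha^2 + \beta^2)\nu_{ij}
#'   + 2\alpha\beta(\nu_{ii} + \nu_{jj})
#'   + (\alpha\beta + \beta^2)(\sum_{k \ne i,j}\nu_{ik} + \sum_{l \ne i,j}\nu_{jl})
#'   + 2\beta^2(\sum_{k \ne i,j}\nu_{kk} + \sum_{k<l \ne i,j}\nu_{kl}).}
#'
#' *Gamete formation* collapses genotypes to allele frequencies
#' `p_i = nu_ii + sum_{j != i} nu_ij / 2` (pangamy, no sex differences).
#'
#' *Reproduction* mixes a clonal copy of the post-mutation frequencies with
#' Hardy-Weinberg proportions formed from the gamete pool:
#' `nu_ii,III = c nu_ii,I + (1-c) p_i^2` and
#' `nu_ij,III = c nu_ij,I + 2 (1-c) p_i p_j`.
#'
#' @param nu Genotype frequency vector in canonical order (or a matrix with
#'   one row per state for the vectorised forms).
#' @param params A [model_params()] object.
#' @return A frequency vector (or matrix) of the same shape; allele
#'   frequencies of length `n` for [gamete_freqs()].
#' @examples
#' p <- model_params(100, c = 0.5, mu = 0)
#' reproduce_freqs(mutate_freqs(c(0, 1, 0), p), p) # c(0.125, 0.75, 0.125)
#' @name kernel_maps
NULL

#' Linear operator of the k-alleles mutation step
#'
#' Returns the `g x g` matrix `U` with `nu_I = U %*% nu`, assembled from
#' the per-genotype mutation coefficients (see [kernel_maps]).
#'
#' @inheritParams kernel_maps
#' @export
mutation_operator <- function(params) {
  stopifnot(inherits(params, "clonal_params"))
  a <- params$alpha; b <- params$beta
  pr <- genotype_pairs(params$n)
  g <- params$g
  U <- matrix(0, g, g)
  for (to in seq_len(g)) {
    i <- pr[to, 1]; j <- pr[to, 2]
    for (from in seq_len(g)) {
      k <- pr[from, 1]; l <- pr[from, 2]
      U[to, from] <-
        if (i == j) {
          if (k == i && l == i) a^2
          else if (k == i || l == i) a * b        # heterozygote carrying i
          else if (k == l) b^2                    # other homozygote
          else b^2                                # heterozygote without i
        } else {
          src <- c(k, l)
          if (k == i && l == j) a^2 + b^2
          else if (k == l && (k == i || k == j)) 2 * a * b
          else if (any(src == i) || any(src == j)) {
            if (k == l) 2 * b^2 else a * b + b^2  # shares one allele
          } else if (k == l) 2 * b^2
          else 2 * b^2
        }
    }
  }
  U
}

#' @rdname kernel_maps
#' @export
mutate_freqs <- function(nu, params) {
  U <- mutation_operator(params)
  if (is.matrix(nu)) nu %*% t(U) else as.vector(U %*% nu)
}

#' @rdname kernel_maps
#' @export
gamete_freqs <- function(nu, params) {
  D <- allele_dosage(params)
  if (is.matrix(nu)) nu %*% t(D) else as.vector(D %*% nu)
}

#' @rdname kernel_maps
#' @export
reproduce_freqs <- function(nu, params) {
  one_row <- !is.matrix(nu)
  if (one_row) nu <- matrix(nu, 1)
  P <- gamete_freqs(nu, params)
  pr <- genotype_pairs(params$n)
  hwe <- sapply(seq_len(params$g), function(k) {
    i <- pr[k, 1]; j <- pr[k, 2]
    if (i == j) P[, i]^2 else 2 * P[, i] * P[, j]
  })
  if (!is.matrix(hwe)) hwe <- matrix(hwe, nrow = nrow(nu))
  out <- params$c * nu + (1 - params$c) * hwe
  if (one_row) as.vector(out) else out
}

#' Expected genotype frequencies after one full generation cycle
#'
#' Composes mutation, gamete formation and reproduction on the current
#' state's frequencies; the result is the multinomial probability vector
#' from which the next generation is drawn.
#'
#' @param state Genotype count vector (or matrix of states in rows), or a
#'   frequency vector summing to 1.
#' @inheritParams kernel_maps
#' @return Frequency vector (or matrix) `nu_III`.
#' @export
step_expected <- function(state, params) {
  one_row <- !is.matrix(state)
  if (one_row) state <- matrix(state, 1)
  tot <- rowSums(state)
  nu <- if (all(abs(tot - 1) < 1e-9)) state else state / tot
  out <- reproduce_freqs(mutate_freqs(nu, params), params)
  # floating-point guard before multinomial use
  out[out > -1e-15 & out < 0] <- 0
  if (one_row) as.vector(out) else out
}

#' Transition probability between two population states
#'
#' The multinomial probability of drawing the target state's genotype
#' counts from the expected post-reproduction frequencies of the source
#' state. Evaluated in log space (log-gamma factorials), so it is stable
#' for any `N`.
#'
#' @param from,to Genotype count vectors summing to `N`.
#' @inheritParams kernel_maps
#' @return A probability.
#' @examples
#' p <- model_params(2, c = 1, mu = 0)
#' transition_prob(c(1, 1, 0), c(2, 0, 0), p) # 0.25
#' @export
transition_prob <- function(from, to, params) {
  stopifnot(sum(from) == params$N, sum(to) == params$N,
            length(from) == params$g, length(to) == params$g)
  nu <- step_expected(from, params)
  if (any(nu == 0 & to > 0)) return(0)
  pos <- to > 0
  lp <- lgamma(params$N + 1) - sum(lgamma(to + 1)) +
    sum(to[pos] * log(nu[pos]))
  exp(lp)
}

#' Full transition matrix of the genotype-state chain
#'
#' Column `j` holds the multinomial distribution of the next state given
#' current state `j` (current state per column, columns sum to one -- note
#' this is the transpose of the row-stochastic convention common in
#' linear-algebra texts).
#'
#' @inheritParams kernel_maps
#' @param space Optional pre-built [enumerate_states()] result.
#' @param cap State-space cap passed to [enumerate_states()].
#' @return A `"transition_matrix"` object: list with the dense matrix `M`
#'   (`[to, from]`), the `space` and `params`. `as.matrix()` extracts `M`.
#' @export
transition_matrix <- function(params, space = NULL, cap = 2e6) {
  if (is.null(space)) space <- enumerate_states(params, cap = cap)
  Q <- space$counts
  S <- nrow(Q)
  NU <- step_expected(Q, params)           # S x g, nu_III per source state
  lcoef <- lgamma(params$N + 1) - rowSums(lgamma(Q + 1))
  LN <- log(NU)
  LN[NU == 0] <- 0                          # placeholder; masked below
  M <- exp(tcrossprod(Q, LN) + lcoef)       # M[to, from]
  if (any(NU == 0)) {
    impossible <- tcrossprod((Q > 0) * 1, (NU == 0) * 1) > 0
    M[impossible] <- 0
  }
  structure(list(M = M, space = space, params = params),
            class = "transition_matrix")
}

#' @export
as.matrix.transition_matrix <- function(x, ...) x$M

#' @export
dim.transition_matrix <- function(x) dim(x$M)

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix>", nrow(x$M), "x", ncol(x$M),
      " (column-stochastic)\n")
  print(x$params)
  invisible(x)
}

#' Export the nonzero transition probabilities as a tibble
#'
#' @param x A `transition_matrix` object.
#' @param ... Unused.
#' @return Tibble with `state_index_from`, `state_index_to`, `probability`
#'   for every nonzero entry.
#' @method tidy transition_matrix
#' @export
tidy.transition_matrix <- function(x, ...) {
  nz <- which(x$M > 0, arr.ind = TRUE)
  tibble::tibble(
    state_index_from = as.integer(nz[, "col"]),
    state_index_to = as.integer(nz[, "row"]),
    probability = x$M[nz]
  ) |>
    dplyr::arrange(.data$state_index_from, .data$state_index_to)
}
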