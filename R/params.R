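#' Model parameters for the partially clonal genotype-frequency chain
#'
#' Bundles the four parameters of the single-locus model -- population size
#' `N` (number of ramets), number of alleles `n_alleles`, rate of clonality
#' `c` (proportion of offspring produced clonally per generation) and the
#' per-allele, per-generation mutation rate `mu` -- together with derived
#' quantities: the genotype count `g = n(n+1)/2`, the probability `alpha =
#' 1 - mu` that an allele does not mutate, and the probability `beta =
#' mu / (n - 1)` that it mutates into one specific other allele (k-alleles
#' mutation scheme, so `alpha + (n-1) * beta = 1`).
#'
#' @param N Population size, a positive integer. Every individual is a
#'   monoecious diploid ramet; the population size is constant.
#' @param c Rate of clonality in `[0, 1]`. The sexual share `1 - c` mates
#'   randomly, including selfing at rate `1/N`.
#' @param mu Per-allele mutation rate per generation. Values up to
#'   `(n - 1)/n` are accepted (at that rate every allele is equally likely
#'   to stay or become any other allele).
#' @param n_alleles Number of alleles at the locus, an integer `>= 2`.
#'
#' @return An object of class `"clonal_params"`: a list with elements `N`,
#'   `n`, `c`, `mu`, `g`, `alpha`, `beta`.
#'
#' @examples
#' model_params(N = 100, c = 0.99, mu = 1e-6)
#' @export
model_params <- function(N, c, mu, n_alleles = 2L) {
  stopifnot(
    length(N) == 1, is.numeric(N), N >= 1, N == round(N),
    length(n_alleles) == 1, n_alleles >= 2, n_alleles == round(n_alleles),
    length(c) == 1, is.numeric(c), c >= 0, c <= 1,
    length(mu) == 1, is.numeric(mu), mu >= 0
  )
  n <- as.integer(n_alleles)
  if (mu > (n - 1) / n) {
    stop("`mu` must not exceed (n - 1)/n = ", (n - 1) / n,
         " for ", n, " alleles", call. = FALSE)
  }
  structure(
    list(
      N = as.integer(N), n = n, c = as.numeric(c), mu = as.numeric(mu),
      g = as.integer(n * (n + 1) / 2),
      alpha = 1 - mu, beta = if (n > 1) mu / (n - 1) else 0
    ),
    class = "clonal_params"
  )
}

#' @export
print.clonal_params <- function(x, ...) {
  cat("<clonal_params> N =", x$N, " alleles =", x$n,
      " c =", format(x$c), " mu =", format(x$mu), "\n")
  cat("  genotypes g =", x$g,
      " states =", format(count_states(x$N, x$n), big.mark = ","), "\n")
  invisible(x)
}

#' Genotype labels in canonical order
#'
#' Canonical genotype order is lexicographic over allele pairs (i, j) with
#' i <= j: A1A1, A1A2, ..., A1An, A2A2, ..., AnAn.
#'
#' @param params A [model_params()] object.
#' @return Character vector of length `g`.
#' @export
genotype_labels <- function(params) {
  pr <- genotype_pairs(params$n)
  paste0("q_A", pr[, 1], "A", pr[, 2])
}

# allele index pairs (i <= j) in canonical genotype order, g x 2
genotype_pairs <- function(n) {
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  cbind(i = idx[, "row"], j = idx[, "col"])
}

# acceptable error: half the minimal measurable genotype-frequency change
default_epsilon <- function(N) 1 / (2 * N)
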