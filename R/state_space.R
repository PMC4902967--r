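#' Number of genotypic population states
#'
#' A population state assigns each of the `N` individuals to one of the
#' `g = n(n+1)/2` genotypes, so the states are the compositions of `N` into
#' `g` non-negative parts and their number is the binomial coefficient
#' `choose(N + g - 1, g - 1)`.
#'
#' @param N Population size.
#' @param n_alleles Number of alleles at the locus.
#' @return The exact state count as a double (exact for any desk-scale
#'   input; the count stays below 2^53).
#' @examples
#' count_states(100, 3) # 96,560,646
#' @export
count_states <- function(N, n_alleles) {
  stopifnot(N >= 1, n_alleles >= 2)
  g <- n_alleles * (n_alleles + 1) / 2
  choose(N + g - 1, g - 1)
}

#' Enumerate the genotypic state space
#'
#' Generates every distribution of `N` individuals over the `g` genotypes,
#' in a deterministic colexicographic order (the count of the last genotype
#' class is the most significant digit, so the first state puts everyone in
#' the first homozygote class). Enumeration is refused above `cap` states;
#' larger systems are meant for [simulate_loci()].
#'
#' @param params A [model_params()] object.
#' @param cap Maximum number of states that will be materialised.
#' @return A `"state_space"` object holding the integer count matrix
#'   (states x genotypes, columns named per [genotype_labels()]) and the
#'   parameters. Use [tidy()] for a tibble, [state_index()] /
#'   [state_counts()] for index lookups.
#' @examples
#' sp <- enumerate_states(model_params(2, c = 0, mu = 0))
#' tidy(sp)
#' @export
enumerate_states <- function(params, cap = 2e6) {
  stopifnot(inherits(params, "clonal_params"))
  n_states <- count_states(params$N, params$n)
  if (n_states > cap) {
    stop("state space too large; use the Monte Carlo module: ",
         format(n_states, big.mark = ","), " states exceed the cap of ",
         format(cap, big.mark = ","), call. = FALSE)
  }
  counts <- compositions_colex(params$N, params$g)
  colnames(counts) <- genotype_labels(params)
  structure(
    list(counts = counts, params = params),
    class = "state_space"
  )
}

# all compositions of N into g parts, colexicographic: last part most
# significant, ascending
compositions_colex <- function(N, g) {
  if (g == 1L) return(matrix(as.integer(N), 1L, 1L))
  blocks <- lapply(0:N, function(v) {
    cbind(compositions_colex(N - v, g - 1L), as.integer(v))
  })
  do.call(rbind, blocks)
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space>", nrow(x$counts), "states, N =", x$params$N,
      ", alleles =", x$params$n, "\n")
  invisible(x)
}

#' @rdname enumerate_states
#' @param x A `state_space` object.
#' @param ... Unused.
#' @method tidy state_space
#' @export
tidy.state_space <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(state_index = seq_len(nrow(x$counts))),
    tibble::as_tibble(x$counts)
  )
}

#' Rank of a state in the canonical enumeration
#'
#' Computed combinatorially (no table lookup), so it agrees with
#' [enumerate_states()] for any state without materialising the space.
#'
#' @param space A `state_space` object (or a [model_params()] object).
#' @param counts Integer vector of genotype counts summing to `N`.
#' @return 1-based index of `counts` in the canonical order.
#' @export
state_index <- function(space, counts) {
  params <- if (inherits(space, "state_space")) space$params else space
  stopifnot(length(counts) == params$g, all(counts >= 0),
            sum(counts) == params$N)
  g <- params$g
  idx <- 0
  rem <- params$N
  for (k in g:2) {
    v <- counts[k]
    if (v > 0) {
      # states with a smaller count in position k, all positions > k equal
      idx <- idx + sum(choose(rem - (0:(v - 1)) + k - 2, k - 2))
    }
    rem <- rem - v
  }
  as.integer(idx + 1)
}

#' @rdname state_index
#' @param index 1-based state index.
#' @export
state_counts <- function(space, index) {
  stopifnot(inherits(space, "state_space"),
            index >= 1, index <= nrow(space$counts))
  space$counts[index, ]
}

#' Per-state genotypic descriptors
#'
#' For each population state: allele frequencies
#' `p_i = nu_ii + sum_{j != i} nu_ij / 2`, observed heterozygosity `Ho`
#' (total heterozygote frequency), expected heterozygosity
#' `He = 1 - sum p_i^2`, the inbreeding coefficient
#' `fis = (He - Ho) / He`, and two flags: `fixed` (a single allele remains,
#' `He = 0`, where `fis` is undefined and reported as `NA`) and
#' `near_fixed` (the top allele frequency exceeds `1 - sqrt(1/(2N))`, the
#' exclusion threshold used in multilocus sampling).
#'
#' @param space A `state_space` object.
#' @return A tibble with one row per state: `state_index`, the count
#'   columns, `p_A*`, `Ho`, `He`, `fis`, `fixed`, `near_fixed`.
#' @examples
#' p <- model_params(100, c = 0, mu = 0)
#' describe_state(c(40, 20, 40), p) # fis = 0.6
#' @export
describe_states <- function(space) {
  stopifnot(inherits(space, "state_space"))
  params <- space$params
  nu <- space$counts / params$N
  P <- nu %*% t(allele_dosage(params)) # states x n allele frequencies
  colnames(P) <- paste0("p_A", seq_len(params$n))
  het <- genotype_pairs(params$n)[, 1] != genotype_pairs(params$n)[, 2]
  Ho <- rowSums(nu[, het, drop = FALSE])
  He <- 1 - rowSums(P^2)
  fixed <- He <= 0
  fis <- ifelse(fixed, NA_real_, (He - Ho) / He)
  near_fixed <- apply(P, 1, max) > 1 - sqrt(1 / (2 * params$N))
  dplyr::bind_cols(
    tidy(space),
    tibble::as_tibble(P),
    tibble::tibble(Ho = Ho, He = He, fis = fis,
                   fixed = fixed, near_fixed = near_fixed)
  )
}

#' @rdname describe_states
#' @param counts Genotype count vector for a single state.
#' @param params A [model_params()] object.
#' @export
describe_state <- function(counts, params) {
  stopifnot(inherits(params, "clonal_params"),
            length(counts) == params$g, sum(counts) == params$N)
  sp <- structure(list(counts = matrix(as.integer(counts), 1,
                                       dimnames = list(NULL, genotype_labels(params))),
                       params = params),
                  class = "state_space")
  describe_states(sp)
}

# n x g matrix D with p = D %*% nu: 1 for the own homozygote, 1/2 per
# heterozygote carrying the allele
allele_dosage <- function(params) {
  pr <- genotype_pairs(params$n)
  D <- matrix(0, params$n, params$g)
  for (k in seq_len(params$g)) {
    i <- pr[k, 1]; j <- pr[k, 2]
    if (i == j) D[i, k] <- 1 else D[c(i, j), k] <- 0.5
  }
  D
}

#' Preset start states under isoplethy
#'
#' The three canonical start states with equal allele frequencies `1/n`:
#' `fis0 = -1` (complete heterozygosity: individuals spread evenly over the
#' heterozygote classes), `fis0 = 0` (Hardy-Weinberg proportions) and
#' `fis0 = 1` (complete homozygosity: `N/n` per homozygote class). When the
#' exact counts are not integers the remainder is distributed to
#' heterozygote classes first and a warning records the rounding.
#'
#' @param params A [model_params()] object.
#' @param fis0 One of `-1`, `0`, `1`.
#' @return Integer genotype count vector summing to `N`.
#' @examples
#' preset_start(model_params(100, c = 0, mu = 0), 0) # c(25, 50, 25)
#' @export
preset_start <- function(params, fis0) {
  stopifnot(inherits(params, "clonal_params"), fis0 %in% c(-1, 0, 1))
  pr <- genotype_pairs(params$n)
  het <- pr[, 1] != pr[, 2]
  n <- params$n
  target <- switch(as.character(fis0),
    "-1" = ifelse(het, 1 / sum(het), 0),
    "0"  = ifelse(het, 2 / n^2, 1 / n^2),
    "1"  = ifelse(het, 0, 1 / n)
  )
  if (fis0 == -1 && n == 2) target <- c(0, 1, 0)
  exact <- params$N * target
  counts <- floor(exact)
  short <- params$N - sum(counts)
  if (short > 0) {
    # whole remainder onto heterozygote classes (cyclically): each
    # heterozygote adds half a copy of two alleles, so isoplethy survives
    het_idx <- which(het)
    take <- rep_len(het_idx, short)
    for (k in take) counts[k] <- counts[k] + 1
    warning("exact isoplethic state impossible for N = ", params$N,
            ", n = ", n, "; remainder assigned to heterozygote classes first",
            call. = FALSE)
  }
  stats::setNames(as.integer(counts), genotype_labels(params))
}
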