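#' Monte Carlo forward simulation of independent loci
#'
#' Simulates the full generation cycle (mutation, reproduction, multinomial
#' drift) forward in time for many unlinked loci that share the same
#' parameters and start state. This path enumerates nothing, so any
#' population size is tractable. The multinomial draw is performed by the
#' conditional-binomial decomposition, vectorised across loci, from R's
#' base random number generator; results are bit-reproducible for a given
#' `seed`.
#'
#' @param params A [model_params()] object.
#' @param start Genotype count vector (e.g. [preset_start()]).
#' @param generations Number of generations to simulate.
#' @param n_loci Number of independent replicate loci.
#' @param seed Optional integer seed (recorded in the result).
#' @param keep `"all"` (every generation) or `"last"`.
#' @return A `"locus_sim"`: list of per-generation integer count matrices
#'   (`n_loci x g`). [tidy()] returns the long per-locus table;
#'   [sim_summary()] the per-generation F_IS summary.
#' @examples
#' p <- model_params(10, c = 1, mu = 0)
#' sim <- simulate_loci(p, preset_start(p, -1), 5, n_loci = 100, seed = 1)
#' sim_summary(sim)
#' @export
simulate_loci <- function(params, start, generations, n_loci,
                          seed = NULL, keep = c("all", "last")) {
  stopifnot(inherits(params, "clonal_params"),
            length(start) == params$g, sum(start) == params$N,
            generations >= 0, n_loci >= 1)
  keep <- match.arg(keep)
  if (!is.null(seed)) set.seed(seed)
  g <- params$g
  counts <- matrix(as.integer(start), n_loci, g, byrow = TRUE)
  colnames(counts) <- genotype_labels(params)
  out <- vector("list", if (keep == "all") generations + 1 else 1)
  if (keep == "all") out[[1]] <- counts
  for (t in seq_len(generations)) {
    nu <- step_expected(counts, params)
    counts <- rmultinomial_rows(params$N, nu)
    colnames(counts) <- genotype_labels(params)
    if (keep == "all") out[[t + 1]] <- counts
  }
  if (keep == "last") out[[1]] <- counts
  structure(list(counts = out,
                 generations = if (keep == "all") 0:generations
                               else generations,
                 params = params, n_loci = n_loci, seed = seed),
            class = "locus_sim")
}

# one multinomial draw of size N per row of the probability matrix,
# via sequential conditional binomials (vectorised across rows)
rmultinomial_rows <- function(N, prob) {
  n_row <- nrow(prob)
  g <- ncol(prob)
  res <- matrix(0L, n_row, g)
  remaining <- rep.int(N, n_row)
  prob_left <- rep.int(1, n_row)
  for (k in seq_len(g - 1)) {
    p <- ifelse(prob_left > 0, prob[, k] / prob_left, 0)
    p <- pmin(pmax(p, 0), 1)
    draw <- stats::rbinom(n_row, remaining, p)
    res[, k] <- draw
    remaining <- remaining - draw
    prob_left <- prob_left - prob[, k]
  }
  res[, g] <- remaining
  res
}

#' @export
print.locus_sim <- function(x, ...) {
  cat("<locus_sim>", x$n_loci, "loci x", max(x$generations),
      "generations; seed =", if (is.null(x$seed)) "none" else x$seed, "\n")
  invisible(x)
}

#' @rdname simulate_loci
#' @param x A `locus_sim` object.
#' @param ... Unused.
#' @method tidy locus_sim
#' @export
tidy.locus_sim <- function(x, ...) {
  purrr::map2_dfr(x$counts, x$generations, function(cnt, t) {
    d <- sim_fis(cnt, x$params)
    dplyr::bind_cols(
      tibble::tibble(locus = seq_len(nrow(cnt)), t = t),
      tibble::as_tibble(cnt),
      tibble::tibble(fis = d$fis, fixed = d$fixed,
                     near_fixed = d$near_fixed)
    )
  })
}

# fis and flags for a matrix of count rows
sim_fis <- function(counts, params) {
  nu <- counts / params$N
  P <- nu %*% t(allele_dosage(params))
  pr <- genotype_pairs(params$n)
  Ho <- rowSums(nu[, pr[, 1] != pr[, 2], drop = FALSE])
  He <- 1 - rowSums(P^2)
  fixed <- He <= 0
  list(fis = ifelse(fixed, NA_real_, (He - Ho) / He),
       fixed = fixed,
       near_fixed = apply(P, 1, max) > 1 - sqrt(1 / (2 * params$N)),
       Ho = Ho, He = He)
}

#' @rdname simulate_loci
#' @param sim A `locus_sim` object.
#' @export
sim_summary <- function(sim) {
  stopifnot(inherits(sim, "locus_sim"))
  purrr::map2_dfr(sim$counts, sim$generations, function(cnt, t) {
    d <- sim_fis(cnt, sim$params)
    tibble::tibble(
      t = t,
      mean_fis = mean(d$fis, na.rm = TRUE),
      var_fis = stats::var(d$fis[!d$fixed]),
      p_fix = mean(d$fixed),
      p_near_fix = mean(d$near_fixed),
      mean_Ho = mean(d$Ho)
    )
  })
}

#' Multilocus sample means of F_IS
#'
#' Draws `n_samples` batches of `L` loci i.i.d. from a single-locus F_IS
#' distribution (unlinked loci each give an independent estimate) and
#' returns the batch means. The source distribution is conditioned on not
#' being excluded first: by default all near-fixed loci (top allele
#' frequency above `1 - sqrt(1/(2N))`) are discarded, mimicking the
#' empirical practice of dropping near-monomorphic markers.
#'
#' @param x Source of the F_IS distribution: a `state_distribution` (exact
#'   probabilities), a `state_trajectory` (give `t`), or a `locus_sim`
#'   snapshot (give `t`; empirical locus values).
#' @param L Loci per sample.
#' @param n_samples Number of samples (default `1e5`).
#' @param seed Optional integer seed.
#' @param exclude `"near_fixed"` (default) or `"fixed"`.
#' @param t Generation to use when `x` is a trajectory or simulation.
#' @return Numeric vector of `n_samples` sample means, with attribute
#'   `true_mean` -- the exact (or full-replicate) conditional mean of the
#'   source.
#' @export
sample_fis_means <- function(x, L, n_samples = 1e5, seed = NULL,
                             exclude = c("near_fixed", "fixed"),
                             t = NULL) {
  exclude <- match.arg(exclude)
  if (inherits(x, "state_trajectory")) {
    stopifnot(!is.null(t))
    x <- distribution_at(x, t)
  }
  if (inherits(x, "state_distribution")) {
    d <- state_fis_table(x$space)
    keep <- if (exclude == "fixed") !d$fixed else !d$fixed & !d$near_fixed
    w <- x$probs[keep]
    if (sum(w) <= 0) {
      stop("all probability mass is on excluded states", call. = FALSE)
    }
    w <- w / sum(w)
    values <- d$fis[keep]
    true_mean <- sum(w * values)
  } else if (inherits(x, "locus_sim")) {
    stopifnot(!is.null(t), t %in% x$generations)
    cnt <- x$counts[[match(t, x$generations)]]
    d <- sim_fis(cnt, x$params)
    keep <- if (exclude == "fixed") !d$fixed else !d$fixed & !d$near_fixed
    values <- d$fis[keep]
    if (length(values) == 0) {
      stop("all simulated loci are excluded", call. = FALSE)
    }
    w <- NULL
    true_mean <- mean(values)
  } else {
    stop("unsupported source for `x`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- if (is.null(w)) {
    sample(values, L * n_samples, replace = TRUE)
  } else {
    values[sample.int(length(values), L * n_samples, replace = TRUE,
                      prob = w)]
  }
  means <- colMeans(matrix(draws, nrow = L))
  attr(means, "true_mean") <- true_mean
  means
}

#' Mean signed deviation of multilocus sample means
#'
#' Splits the sample means at the true mean and averages the deviations on
#' each side separately: `delta_plus` is the mean of
#' `sample_mean - true_mean` over samples at or above the true mean,
#' `delta_minus` over samples below it, with `z1 + z2 = n_samples`.
#'
#' @param sample_means Numeric vector, e.g. from [sample_fis_means()].
#' @param true_mean Exact mean of the source distribution; defaults to the
#'   `true_mean` attribute carried by [sample_fis_means()] output.
#' @return One-row tibble: `delta_plus`, `delta_minus`, `z1`, `z2`,
#'   `true_mean`, `n_samples`.
#' @examples
#' signed_deviation(c(0.2, -0.1, -0.3), true_mean = 0)
#' @export
signed_deviation <- function(sample_means, true_mean = NULL) {
  if (is.null(true_mean)) true_mean <- attr(sample_means, "true_mean")
  stopifnot(length(sample_means) > 0, !is.null(true_mean))
  up <- sample_means >= true_mean
  tibble::tibble(
    delta_plus = if (any(up)) mean(sample_means[up]) - true_mean else 0,
    delta_minus = if (any(!up)) mean(sample_means[!up]) - true_mean else 0,
    z1 = sum(up), z2 = sum(!up),
    true_mean = true_mean, n_samples = length(sample_means)
  )
}
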