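#' Maximal convergence times of the separate evolutionary processes
#'
#' Convergence of genotype frequencies to the steady state of a single
#' process is geometric, so the number of generations needed to come
#' within an acceptable error `epsilon` of it has a closed form. The
#' default acceptable error is `epsilon = 1/(2N)`, half the smallest
#' genotype-frequency change measurable by exhaustive sampling.
#'
#' * Reproduction only: `t_c = 1 + log(epsilon)/log(c)`; `t_c = 1` for a
#'   purely sexual population (`c = 0`, Hardy-Weinberg proportions in one
#'   generation) and `t_c = Inf` for a purely clonal one. As a function of
#'   `c` this is a hyperbola: `(t_c - 1) * |log c| = |log epsilon|`.
#' * Mutation only: `t_mu = 1 + log(epsilon)/log(1 - mu * n/(n-1))`; the
#'   geometric factor is the per-generation decay of deviations under the
#'   k-alleles scheme. At the degenerate rate `mu = (n-1)/n` the base is 0
#'   and a single generation suffices.
#'
#' Both return real-valued times; round up (`ceiling()`) to report whole
#' generations.
#'
#' @param c Rate of clonality in `[0, 1]`. Vectorised.
#' @param mu Mutation rate in `(0, (n-1)/n]`. Vectorised.
#' @param n_alleles Number of alleles.
#' @param epsilon Acceptable error in `(0, 1)`.
#' @return Generations (real-valued, possibly `Inf`).
#' @examples
#' t_c(0.5, epsilon = 1 / 494)      # about 10 generations
#' t_mu(1e-6, 2, epsilon = 0.005)   # about 2.6 million generations
#' @export
t_c <- function(c, epsilon) {
  stopifnot(all(c >= 0), all(c <= 1), epsilon > 0, epsilon < 1)
  out <- 1 + log(epsilon) / log(c)
  out[c == 0] <- 1
  out[c == 1] <- Inf
  out
}

#' @rdname t_c
#' @export
t_mu <- function(mu, n_alleles = 2, epsilon) {
  stopifnot(all(mu > 0), n_alleles >= 2, epsilon > 0, epsilon < 1)
  top <- (n_alleles - 1) / n_alleles
  stopifnot(all(mu <= top))
  base <- 1 - mu / top
  out <- 1 + log(epsilon) / log(base)
  out[base == 0] <- 1
  out
}

#' Fit the linear drift law t_N = sigma * N - tau
#'
#' The maximal expected time to genotypic uniformity under drift alone
#' grows approximately linearly in the population size, with a slope that
#' increases with the number of alleles. The law is fitted by least
#' squares through exact absorption times ([absorption_profile()])
#' computed on a grid of population sizes.
#'
#' @param n_alleles Number of alleles.
#' @param N_grid Population sizes to solve exactly (at least 3).
#' @param cap State-space cap for the exact solves.
#' @return A `"drift_fit"` with `sigma`, `tau` and the fitted points;
#'   [tidy()] returns the per-N absorption times, [glance()] the
#'   coefficients, and [predict_t_N()] evaluates the law.
#' @examples
#' \donttest{
#' fit <- fit_drift_law(2, N_grid = seq(10, 30, 10))
#' glance(fit)
#' }
#' @export
fit_drift_law <- function(n_alleles = 2, N_grid = seq(10, 50, 10),
                          cap = 2e6) {
  stopifnot(length(N_grid) >= 3)
  tn <- vapply(N_grid, function(N) {
    absorption_profile(model_params(N, c = 1, mu = 0,
                                    n_alleles = n_alleles),
                       cap = cap)$t_N
  }, numeric(1))
  fit <- stats::lm(tn ~ N_grid)
  structure(list(sigma = unname(coef(fit)[2]),
                 tau = unname(-coef(fit)[1]),
                 n_alleles = n_alleles,
                 N_grid = N_grid, t_N = tn,
                 r_squared = summary(fit)$r.squared),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat("<drift_fit> t_N =", format(x$sigma), "* N -", format(x$tau),
      " (", x$n_alleles, "alleles, fitted on N in [",
      min(x$N_grid), ",", max(x$N_grid), "])\n")
  invisible(x)
}

#' @rdname fit_drift_law
#' @param x A `drift_fit` object.
#' @param ... Unused.
#' @method tidy drift_fit
#' @export
tidy.drift_fit <- function(x, ...) {
  tibble::tibble(N = x$N_grid, t_N = x$t_N,
                 fitted = x$sigma * x$N_grid - x$tau)
}

#' @rdname fit_drift_law
#' @method glance drift_fit
#' @export
glance.drift_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, tau = x$tau,
                 n_alleles = x$n_alleles, r_squared = x$r_squared)
}

#' @rdname fit_drift_law
#' @param fit A `drift_fit` object.
#' @param N Population sizes at which to evaluate the drift law.
#' @export
predict_t_N <- function(fit, N) {
  stopifnot(inherits(fit, "drift_fit"))
  fit$sigma * N - fit$tau
}

# per-n cache of the default drift fit
.drift_fit_cache <- new.env(parent = emptyenv())

default_drift_fit <- function(n_alleles) {
  key <- as.character(n_alleles)
  if (is.null(.drift_fit_cache[[key]])) {
    grid <- if (n_alleles == 2) seq(10, 50, 10) else seq(4, 12, 2)
    .drift_fit_cache[[key]] <- fit_drift_law(n_alleles, grid)
  }
  .drift_fit_cache[[key]]
}

#' Which evolutionary process dominates the genotype dynamics?
#'
#' Computes the three maximal convergence times for a parameter set and
#' reports their argmin: the process with the shortest convergence time
#' dominates the dynamics of genotype frequencies and F_IS. Random mating
#' and mutation both converge to Hardy-Weinberg-like steady states
#' (F_IS near 0), while dominant drift erodes genotypes towards
#' genotypic uniformity.
#'
#' @param params A [model_params()] object.
#' @param fit Optional [fit_drift_law()] result; defaults to a cached fit
#'   for the matching allele number.
#' @param epsilon Acceptable error; default `1/(2N)`.
#' @return One-row tibble: parameters, `epsilon`, `t_c`, `t_mu`, `t_N`,
#'   `dominant` (`"reproduction"`, `"mutation"` or `"drift"`).
#' @export
dominant_process <- function(params, fit = NULL, epsilon = NULL) {
  stopifnot(inherits(params, "clonal_params"))
  if (is.null(epsilon)) epsilon <- default_epsilon(params$N)
  if (is.null(fit)) fit <- default_drift_fit(params$n)
  tc <- t_c(params$c, epsilon)
  tm <- if (params$mu > 0) t_mu(params$mu, params$n, epsilon) else Inf
  tn <- predict_t_N(fit, params$N)
  times <- c(reproduction = tc, mutation = tm, drift = tn)
  tibble::tibble(N = params$N, n_alleles = params$n,
                 c = params$c, mu = params$mu, epsilon = epsilon,
                 t_c = tc, t_mu = tm, t_N = tn,
                 dominant = names(times)[which.min(times)])
}

#' Boundaries between dominance regions of the parameter space
#'
#' The pairwise equalities of the three convergence times partition the
#' `(c, mu)` plane (for given `N`, `n`) into reproduction-, mutation- and
#' drift-dominated regions. `form = "derived"` uses exact equality of the
#' implemented time formulas:
#' `t_c = t_mu` at `c = 1 - mu * n/(n-1)`;
#' `t_c = t_N` at `c = epsilon^(1/(t_N - 1))`;
#' `t_mu = t_N` at `mu = (n-1)/n * (1 - epsilon^(1/(t_N - 1)))`.
#' `form = "printed"` evaluates an alternative algebraic form of the same
#' boundaries that circulates in the literature (`c = mu * n/(n-1)`;
#' Euler's `e` in place of `epsilon`), exposed for comparison only -- it
#' does not agree with the implemented time formulas.
#'
#' @param mu Mutation rate(s), for the reproduction/mutation boundary.
#' @param n_alleles Number of alleles.
#' @param t_N Drift convergence time (e.g. [predict_t_N()] or an exact
#'   [absorption_profile()] `t_N`).
#' @param epsilon Acceptable error.
#' @param form `"derived"` (default) or `"printed"`.
#' @return The boundary value(s) of `c` (or `mu`).
#' @export
phase_boundary_c_mu <- function(mu, n_alleles = 2,
                                form = c("derived", "printed")) {
  form <- match.arg(form)
  ratio <- n_alleles / (n_alleles - 1)
  if (form == "derived") 1 - mu * ratio else mu * ratio
}

#' @rdname phase_boundary_c_mu
#' @export
phase_boundary_c_N <- function(t_N, epsilon,
                               form = c("derived", "printed")) {
  form <- match.arg(form)
  base <- if (form == "derived") epsilon else exp(1)
  base^(1 / (t_N - 1))
}

#' @rdname phase_boundary_c_N
#' @export
phase_boundary_mu_N <- function(t_N, epsilon, n_alleles = 2,
                                form = c("derived", "printed")) {
  form <- match.arg(form)
  (n_alleles - 1) / n_alleles *
    (1 - phase_boundary_c_N(t_N, epsilon, form))
}

#' Dominance map over a (c, mu) grid
#'
#' Evaluates [dominant_process()] over a grid of clonality and mutation
#' rates for one population size, for plotting the parameter-space
#' partition.
#'
#' @param N Population size.
#' @param n_alleles Number of alleles.
#' @param c_grid,mu_grid Grid values.
#' @param fit Optional drift fit (cached default otherwise).
#' @param epsilon Acceptable error; default `1/(2N)`.
#' @return A tibble of class `"phase_diagram"` with one row per grid point
#'   and a `dominant` label; see [autoplot.phase_diagram()].
#' @export
phase_diagram <- function(N, n_alleles = 2,
                          c_grid = seq(0, 1, length.out = 41),
                          mu_grid = 10^seq(-9, log10(0.5), length.out = 41),
                          fit = NULL, epsilon = NULL) {
  if (is.null(epsilon)) epsilon <- default_epsilon(N)
  if (is.null(fit)) fit <- default_drift_fit(n_alleles)
  tn <- predict_t_N(fit, N)
  grid <- tidyr::expand_grid(c = c_grid, mu = mu_grid)
  tc <- t_c(grid$c, epsilon)
  tm <- t_mu(grid$mu, n_alleles, epsilon)
  lab <- c("reproduction", "mutation", "drift")
  grid$t_c <- tc; grid$t_mu <- tm; grid$t_N <- tn
  grid$dominant <- lab[apply(cbind(tc, tm, tn), 1, which.min)]
  grid$N <- N; grid$n_alleles <- n_alleles; grid$epsilon <- epsilon
  class(grid) <- c("phase_diagram", class(grid))
  grid
}
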