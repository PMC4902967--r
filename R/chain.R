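#' Exact propagation of the state distribution
#'
#' Applies the chain `t` times: `x_s = M^s x_0`, by repeated matrix-vector
#' products. The start can be a single state (counts vector or state
#' index, giving a point mass) or a full probability vector.
#'
#' @param M A [transition_matrix()] object.
#' @param x0 Start: genotype count vector, state index, or probability
#'   vector over the state space.
#' @param generations Number of generations `t >= 0`.
#' @return A `"state_trajectory"`: distributions in columns `0..t`.
#'   [tidy()] summarises the F_IS distribution per generation;
#'   [distribution_at()] extracts one generation.
#' @examples
#' p <- model_params(3, c = 0.5, mu = 0.01)
#' M <- transition_matrix(p)
#' tr <- propagate(M, preset_start(p, 0), 10)
#' tidy(tr)
#' @export
propagate <- function(M, x0, generations) {
  stopifnot(inherits(M, "transition_matrix"), generations >= 0)
  S <- nrow(M$M)
  x <- as_distribution_vector(x0, M$space)
  out <- matrix(0, S, generations + 1)
  out[, 1] <- x
  if (generations > 0) {
    for (s in seq_len(generations)) {
      x <- as.vector(M$M %*% x)
      out[, s + 1] <- x
    }
  }
  structure(list(dist = out, generations = 0:generations,
                 space = M$space, params = M$params),
            class = "state_trajectory")
}

as_distribution_vector <- function(x0, space) {
  S <- nrow(space$counts)
  if (inherits(x0, "state_distribution")) x0 <- x0$probs
  if (length(x0) == 1 && x0 >= 1) {
    x <- numeric(S); x[as.integer(x0)] <- 1
    return(x)
  }
  if (length(x0) == space$params$g && sum(x0) == space$params$N) {
    x <- numeric(S); x[state_index(space, x0)] <- 1
    return(x)
  }
  if (length(x0) == S && abs(sum(x0) - 1) < 1e-8 && all(x0 >= 0)) {
    return(x0 / sum(x0))
  }
  stop("`x0` must be a state index, a genotype count vector, ",
       "or a probability vector over the state space", call. = FALSE)
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat("<state_trajectory>", nrow(x$dist), "states x",
      length(x$generations), "generations\n")
  invisible(x)
}

#' Extract the state distribution at one generation
#'
#' @param traj A [propagate()] result.
#' @param t Generation index present in the trajectory.
#' @return A `"state_distribution"` object (`probs`, `t`, `space`).
#' @export
distribution_at <- function(traj, t) {
  stopifnot(inherits(traj, "state_trajectory"), t %in% traj$generations)
  new_state_distribution(traj$dist[, match(t, traj$generations)],
                         t, traj$space)
}

new_state_distribution <- function(probs, t, space) {
  structure(list(probs = probs, t = t, space = space,
                 params = space$params),
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("<state_distribution> t =", x$t, "over", length(x$probs), "states\n")
  invisible(x)
}

#' Stationary distribution of the chain
#'
#' The steady state is the dominant eigenvector of the column-stochastic
#' transition matrix. `method = "power"` iterates `x <- M x` until the
#' total-variation change between successive iterates falls below `tol`;
#' `method = "solve"` solves the null space of `M - I` directly with the
#' normalisation constraint. The two agree to solver tolerance on any
#' irreducible chain.
#'
#' With `c = 1` and `mu = 0` the chain is reducible (monomorphic-genotype
#' states absorb) and has no unique stationary distribution; that
#' configuration is rejected with a pointer to [absorption_profile()].
#'
#' @param M A [transition_matrix()] object.
#' @param method `"power"` (default) or `"solve"`.
#' @param tol Convergence tolerance for power iteration.
#' @param max_iter Iteration budget.
#' @return A `"state_distribution"` with `t = Inf`.
#' @export
steady_state <- function(M, method = c("power", "solve"),
                         tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(M, "transition_matrix"))
  method <- match.arg(method)
  p <- M$params
  if (p$c == 1 && p$mu == 0) {
    stop("drift-only chain (c = 1, mu = 0) is reducible and absorbs in ",
         "monomorphic-genotype states; use absorption_profile()",
         call. = FALSE)
  }
  S <- nrow(M$M)
  if (method == "solve") {
    A <- M$M - diag(S)
    A[S, ] <- 1
    x <- solve(A, c(rep(0, S - 1), 1))
    x[x < 0] <- 0
    return(new_state_distribution(x / sum(x), Inf, M$space))
  }
  x <- rep(1 / S, S)
  for (it in seq_len(max_iter)) {
    x_new <- as.vector(M$M %*% x)
    x_new <- x_new / sum(x_new)
    if (0.5 * sum(abs(x_new - x)) < tol) {
      return(new_state_distribution(x_new, Inf, M$space))
    }
    x <- x_new
  }
  stop("power iteration did not converge within ", max_iter,
       " iterations", call. = FALSE)
}

#' Summarise the F_IS distribution implied by a state distribution
#'
#' Maps each state to its F_IS and aggregates under the state
#' probabilities. Mean, variance and quantiles are computed on the
#' conditional distribution given the state is not excluded
#' (renormalised); the fixation and near-fixation probabilities are
#' reported unconditionally. `exclude = "fixed"` drops only states where
#' F_IS is undefined (single allele left); `exclude = "near_fixed"`
#' additionally drops states whose top allele frequency exceeds
#' `1 - sqrt(1/(2N))`, mirroring empirical practice of discarding
#' near-monomorphic loci.
#'
#' @param x A `state_distribution`.
#' @param exclude `"fixed"` (default) or `"near_fixed"`.
#' @return One-row tibble: `t`, `mean_fis`, `var_fis`, `q2.5`, `q50`,
#'   `q97.5`, `p_fix`, `p_near_fix`. All-NA summary columns (with the
#'   probabilities still filled) if every state is excluded.
#' @export
fis_summary <- function(x, exclude = c("fixed", "near_fixed")) {
  stopifnot(inherits(x, "state_distribution"))
  exclude <- match.arg(exclude)
  d <- state_fis_table(x$space)
  p_fix <- sum(x$probs[d$fixed])
  p_near_fix <- sum(x$probs[d$near_fixed])
  keep <- if (exclude == "fixed") !d$fixed else !d$near_fixed & !d$fixed
  w <- x$probs[keep]
  base <- tibble::tibble(t = x$t, mean_fis = NA_real_, var_fis = NA_real_,
                         q2.5 = NA_real_, q50 = NA_real_, q97.5 = NA_real_,
                         p_fix = p_fix, p_near_fix = p_near_fix)
  if (sum(w) <= 0) return(base)
  w <- w / sum(w)
  f <- d$fis[keep]
  m <- sum(w * f)
  qs <- weighted_quantiles(f, w, c(0.025, 0.5, 0.975))
  base$mean_fis <- m
  base$var_fis <- sum(w * (f - m)^2)
  base$q2.5 <- qs[1]; base$q50 <- qs[2]; base$q97.5 <- qs[3]
  base
}

# cache of per-state fis/flags keyed on the space object
state_fis_table <- function(space) {
  if (is.null(space$fis_table)) {
    desc <- describe_states(space)
    space$fis_table <- desc[, c("fis", "fixed", "near_fixed", "Ho", "He")]
  }
  space$fis_table
}

weighted_quantiles <- function(values, weights, probs) {
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o])
  sapply(probs, function(p) v[which(cw >= p - 1e-12)[1]])
}

#' F_IS histogram of a state distribution
#'
#' @param x A `state_distribution`.
#' @return Tibble `(t, fis, probability)` aggregated over states with equal
#'   F_IS; undefined F_IS (fixation) appears as an `NA` row.
#' @export
fis_distribution <- function(x) {
  stopifnot(inherits(x, "state_distribution"))
  d <- state_fis_table(x$space)
  tibble::tibble(fis = d$fis, probability = x$probs) |>
    dplyr::group_by(.data$fis) |>
    dplyr::summarise(probability = sum(.data$probability),
                     .groups = "drop") |>
    dplyr::mutate(t = x$t, .before = 1)
}

#' @rdname propagate
#' @param x A `state_trajectory` object.
#' @param exclude Passed to [fis_summary()].
#' @param ... Unused.
#' @method tidy state_trajectory
#' @export
tidy.state_trajectory <- function(x, exclude = "fixed", ...) {
  purrr::map_dfr(x$generations, function(t) {
    fis_summary(distribution_at(x, t), exclude = exclude)
  })
}

#' Markov chain mixing time
#'
#' Smallest `t` at which the total-variation distance between `M^t x_0`
#' and the stationary distribution is below `epsilon` for the worst pure
#' start state `x_0`. The default threshold is the acceptable error
#' `epsilon = 1/(2N)`, half the minimal measurable genotype-frequency
#' change in a population of size `N`.
#'
#' @param M A [transition_matrix()] object (irreducible chain).
#' @param epsilon Convergence threshold; default `1/(2N)`.
#' @param max_iter Generation budget.
#' @return Integer number of generations, with attribute `tv` holding the
#'   worst-start TV distance at that time.
#' @export
mixing_time <- function(M, epsilon = NULL, max_iter = 5000) {
  stopifnot(inherits(M, "transition_matrix"))
  if (is.null(epsilon)) epsilon <- default_epsilon(M$params$N)
  stopifnot(epsilon > 0, epsilon < 1)
  pi_vec <- steady_state(M)$probs
  D <- diag(nrow(M$M))  # column j = distribution from pure start j
  for (t in seq_len(max_iter)) {
    D <- M$M %*% D
    worst <- max(0.5 * colSums(abs(D - pi_vec)))
    if (worst < epsilon) {
      return(structure(as.integer(t), tv = worst))
    }
  }
  stop("mixing time exceeds the iteration budget of ", max_iter,
       " generations (worst-start TV distance ", format(worst), ")",
       call. = FALSE)
}

#' Absorption analysis of the drift-only chain
#'
#' With `c = 1` and `mu = 0` only multinomial drift acts, and the chain is
#' eventually trapped in a state where a single genotype remains
#' (genotypic uniformity: a homozygote, ending at fixation with F_IS
#' undefined, or a heterozygote, ending at F_IS = -1). For every transient
#' state the expected number of generations to absorption and the hitting
#' probability of each absorbing state are solved from the standard linear
#' system on the transient sub-chain.
#'
#' @param params A [model_params()] with `c = 1`, `mu = 0`.
#' @param space Optional pre-built state space.
#' @param cap State-space cap.
#' @return An `"absorption_profile"`: tibble of per-start results (via
#'   [tidy()]), absorbing state indices, and `t_N`, the maximal expected
#'   absorption time over start states. [glance()] returns the one-row
#'   summary.
#' @examples
#' ap <- absorption_profile(model_params(10, c = 1, mu = 0))
#' glance(ap)
#' @export
absorption_profile <- function(params, space = NULL, cap = 2e6) {
  stopifnot(inherits(params, "clonal_params"))
  if (params$c != 1 || params$mu != 0) {
    stop("absorption_profile() requires the drift-only configuration ",
         "c = 1, mu = 0", call. = FALSE)
  }
  if (is.null(space)) space <- enumerate_states(params, cap = cap)
  Q <- space$counts
  absorbing <- rowSums(Q > 0) == 1
  res <- tibble::tibble(state_index = seq_len(nrow(Q)),
                        expected_time = 0,
                        absorbing = absorbing)
  if (any(!absorbing)) {
    M <- transition_matrix(params, space = space)$M
    P <- t(M)                                   # row convention
    Ptt <- P[!absorbing, !absorbing, drop = FALSE]
    Pta <- P[!absorbing, absorbing, drop = FALSE]
    A <- diag(nrow(Ptt)) - Ptt
    sol <- solve(A, cbind(rep(1, nrow(Ptt)), Pta))
    res$expected_time[!absorbing] <- sol[, 1]
    hit <- matrix(0, nrow(Q), sum(absorbing))
    hit[!absorbing, ] <- sol[, -1, drop = FALSE]
    hit[absorbing, ] <- diag(sum(absorbing))
    colnames(hit) <- paste0("p_hit_", colnames(Q)[apply(
      Q[absorbing, , drop = FALSE] > 0, 1, which)])
    res <- dplyr::bind_cols(res, tibble::as_tibble(hit))
  }
  structure(list(table = res, space = space, params = params,
                 t_N = max(res$expected_time)),
            class = "absorption_profile")
}

#' @export
print.absorption_profile <- function(x, ...) {
  cat("<absorption_profile> N =", x$params$N, ", alleles =", x$params$n,
      "; t_N =", format(x$t_N), "generations\n")
  invisible(x)
}

#' @rdname absorption_profile
#' @param x An `absorption_profile` object.
#' @param ... Unused.
#' @method tidy absorption_profile
#' @export
tidy.absorption_profile <- function(x, ...) {
  dplyr::bind_cols(tidy(x$space)["state_index"],
                   tibble::as_tibble(x$space$counts)) |>
    dplyr::left_join(x$table, by = "state_index")
}

#' @rdname absorption_profile
#' @method glance absorption_profile
#' @export
glance.absorption_profile <- function(x, ...) {
  tibble::tibble(N = x$params$N, n_alleles = x$params$n,
                 n_states = nrow(x$space$counts),
                 n_absorbing = sum(x$table$absorbing),
                 t_N = x$t_N)
}
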