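#' Per-locus F_IS from observed and expected heterozygosity
#'
#' Adds `fis = (He - Ho)/He` to a table of per-locus heterozygosities, as
#' used when compiling field data where only `Ho` and `He` are reported.
#' Rows with `He = 0` (monomorphic loci) get `NA` and `fixed = TRUE`.
#' Malformed rows (missing or out-of-range values) raise an error naming
#' the offending row numbers.
#'
#' @param het A data frame with columns `Ho` and `He`, both in `[0, 1]`.
#' @return The input as a tibble with `fis` and `fixed` columns appended.
#' @examples
#' fis_from_het(data.frame(Ho = c(0.5, 0.2), He = c(0.5, 0.5)))
#' @export
fis_from_het <- function(het) {
  stopifnot(is.data.frame(het), all(c("Ho", "He") %in% names(het)))
  bad <- which(!is.finite(het$Ho) | !is.finite(het$He) |
                 het$Ho < 0 | het$Ho > 1 | het$He < 0 | het$He > 1)
  if (length(bad) > 0) {
    stop("invalid heterozygosities in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(het) |>
    dplyr::mutate(
      fis = ifelse(.data$He > 0, (.data$He - .data$Ho) / .data$He,
                   NA_real_),
      fixed = .data$He == 0
    )
}

#' de Finetti coordinates of biallelic genotype states
#'
#' Maps biallelic genotype frequencies `(nu_aa, nu_aA, nu_AA)` to planar
#' coordinates of the standard equilateral ternary plot
#' (`x = nu_AA + nu_aA / 2`, `y = nu_aA * sqrt(3)/2`), carrying each
#' state's F_IS and, for a distribution source, its probability weight.
#' The Hardy-Weinberg parabola `nu_aA = 2p(1-p)` is the F_IS = 0 iso-line.
#'
#' @param x A `state_space` or `state_distribution` (biallelic only).
#' @return A tibble of class `"definetti_df"`: `nu_aa`, `nu_aA`, `nu_AA`,
#'   `x`, `y`, `fis`, and `weight` for distributions.
#' @seealso [hwe_parabola()], [autoplot.definetti_df()]
#' @export
definetti_coords <- function(x) {
  space <- if (inherits(x, "state_distribution")) x$space else x
  stopifnot(inherits(space, "state_space"))
  if (space$params$n != 2) {
    stop("de Finetti export is biallelic-only", call. = FALSE)
  }
  nu <- space$counts / space$params$N
  d <- state_fis_table(space)
  out <- tibble::tibble(
    nu_aa = nu[, 1], nu_aA = nu[, 2], nu_AA = nu[, 3],
    x = nu[, 3] + nu[, 2] / 2,
    y = nu[, 2] * sqrt(3) / 2,
    fis = d$fis
  )
  if (inherits(x, "state_distribution")) out$weight <- x$probs
  class(out) <- c("definetti_df", class(out))
  out
}

#' Hardy-Weinberg parabola as a ternary reference curve
#'
#' @param n_points Number of points along allele frequency `p`.
#' @return Tibble with `p`, `nu_aa`, `nu_aA`, `nu_AA`, `x`, `y`.
#' @export
hwe_parabola <- function(n_points = 201) {
  p <- seq(0, 1, length.out = n_points)
  tibble::tibble(
    p = p, nu_aa = (1 - p)^2, nu_aA = 2 * p * (1 - p), nu_AA = p^2,
    x = p^2 + p * (1 - p),
    y = 2 * p * (1 - p) * sqrt(3) / 2
  )
}

#' Run a complete analysis from a configuration
#'
#' Orchestrates the exact pipeline (enumerate states, build the transition
#' matrix, propagate the preset start states, summarise) or the Monte
#' Carlo pipeline, and writes plottable CSV artifacts plus a JSON summary
#' and the resolved configuration into `out_dir`. Rerunning an identical
#' configuration reproduces the files byte for byte.
#'
#' @param config A named list (or path to a `key = value` config file, see
#'   [read_run_config()]) with entries `N`, `n_alleles`, `c`, `mu`,
#'   `mode` (`"exact"` or `"monte-carlo"`), `generations`, `starts`
#'   (subset of `-1, 0, 1`), and for Monte Carlo `n_loci` and `seed`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- list(n_alleles = 2, mode = "exact", generations = 100,
                   starts = c(-1, 0, 1), n_loci = 1e4, seed = 1,
                   cap = 2e6, exclude = "fixed")
  cfg <- utils::modifyList(defaults, config)
  for (key in c("N", "c", "mu")) {
    if (is.null(cfg[[key]])) stop("config misses `", key, "`", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- model_params(cfg$N, c = cfg$c, mu = cfg$mu,
                         n_alleles = cfg$n_alleles)
  files <- list(config = file.path(out_dir, "config_resolved.txt"))
  write_run_config(cfg, files$config)

  trajectories <- list()
  for (f0 in cfg$starts) {
    start <- preset_start(params, f0)
    label <- paste0("fis", ifelse(f0 >= 0, "+", ""), f0)
    if (cfg$mode == "exact") {
      M <- get_pipeline_matrix(params, cfg$cap)
      tr <- propagate(M, start, cfg$generations)
      tab <- tidy(tr, exclude = cfg$exclude)
    } else {
      sim <- simulate_loci(params, start, cfg$generations,
                           n_loci = cfg$n_loci, seed = cfg$seed)
      tab <- sim_summary(sim)
    }
    path <- file.path(out_dir, paste0("trajectory_", label, ".csv"))
    write_result_csv(tab, path, params, cfg)
    files[[paste0("trajectory_", label)]] <- path
    trajectories[[label]] <- tab
  }

  summary_path <- file.path(out_dir, "summary.json")
  final <- purrr::imap(trajectories, function(tab, label) {
    last <- tab[nrow(tab), ]
    list(start = label, t = last$t, mean_fis = last$mean_fis,
         p_fix = last$p_fix)
  })
  jsonlite::write_json(
    list(params = cfg[c("N", "n_alleles", "c", "mu", "mode",
                        "generations", "seed")],
         final = unname(final)),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$summary <- summary_path
  invisible(files)
}

# rebuild the (single) exact matrix once per pipeline call
get_pipeline_matrix <- local({
  cache <- NULL; key <- NULL
  function(params, cap) {
    k <- paste(params$N, params$n, params$c, params$mu)
    if (!identical(k, key)) {
      cache <<- transition_matrix(params, cap = cap); key <<- k
    }
    cache
  }
})

# CSV with a provenance header comment
write_result_csv <- function(tab, path, params, cfg) {
  hdr <- paste0("# fisdyn ", as.character(utils::packageVersion("fisdyn")),
                " | N=", params$N, " n=", params$n, " c=", params$c,
                " mu=", params$mu, " mode=", cfg$mode,
                " seed=", cfg$seed)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(tab, con, row.names = FALSE)
}

#' Read and write plain-text run configurations
#'
#' The configuration format is flat `key = value` lines (`#` comments
#' allowed); vector values are comma-separated. Round-trips losslessly
#' through [write_run_config()].
#'
#' @param path File path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    vals <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    cfg[[key]] <- if (any(is.na(num))) vals else num
  }
  cfg
}

#' @rdname read_run_config
#' @param cfg Named list of configuration values.
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    paste0(k, " = ", paste(cfg[[k]], collapse = ", "))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
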