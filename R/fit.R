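#' Options controlling maximum-likelihood fitting
#'
#' @param n_starts Number of local optimisations (first start is
#'   data-informed, the rest Latin-hypercube draws over the log10 box).
#' @param seed Integer seed making the multi-start draw reproducible.
#' @param rate_bounds,influx_bounds Natural-scale box for chain and influx
#'   rates (default `1e-5` to `1e3`).
#' @param init_expand Initial concentrations are bounded within
#'   `1/init_expand` to `init_expand` times their t = 0 replicate mean.
#' @param sigma Fixed residual SD on log10 scale, or `NULL` (default) to
#'   profile sigma analytically at every evaluation.
#' @param fix Named list of parameters to freeze at given natural-scale
#'   values (names as in the fitted parameter vector, e.g. `k_C4`,
#'   `influx_C8`, `init_C16`).
#' @param maxit,factr Passed to [stats::optim()]'s L-BFGS-B.
#' @return A list of class `fao_fit_options`.
#' @export
fit_options <- function(n_starts = 50L, seed = 1L,
                        rate_bounds = c(1e-5, 1e3),
                        influx_bounds = c(1e-5, 1e3),
                        init_expand = 100, sigma = NULL, fix = list(),
                        maxit = 500L, factr = 1e7) {
  stopifnot(n_starts >= 1L, rate_bounds[1] > 0, influx_bounds[1] > 0,
            init_expand > 1)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 rate_bounds = rate_bounds, influx_bounds = influx_bounds,
                 init_expand = init_expand, sigma = sigma, fix = fix,
                 maxit = as.integer(maxit), factr = factr),
            class = "fao_fit_options")
}

lhs_starts <- function(prob, n, seed) {
  if (n < 1L) return(NULL)
  set.seed(seed)
  u <- lhs::randomLHS(n, length(prob$free))
  lo <- log10(prob$lower[prob$free])
  hi <- log10(prob$upper[prob$free])
  # rates/influxes roam the full box; initial concentrations stay within a
  # decade of the t = 0 mean (the box edges are unphysical starting guesses)
  ini <- prob$kind[match(prob$free, prob$names)] %in% c("init", "alpha")
  lo[ini] <- log10(prob$start[prob$free][ini]) - 1
  hi[ini] <- log10(prob$start[prob$free][ini]) + 1
  t(apply(u, 1, function(row) lo + row * (hi - lo)))
}

run_multistart <- function(prob, options, extra_start = NULL) {
  fn <- function(theta) problem_rss(prob, theta)
  lo <- log10(prob$lower[prob$free])
  hi <- log10(prob$upper[prob$free])
  starts <- list(log10(pmin(pmax(prob$start[prob$free], prob$lower[prob$free]),
                            prob$upper[prob$free])))
  if (!is.null(extra_start))
    starts <- c(list(extra_start[prob$free]), starts)
  n_lhs <- options$n_starts - length(starts)
  if (n_lhs > 0L) {
    m <- lhs_starts(prob, n_lhs, options$seed)
    starts <- c(starts, lapply(seq_len(nrow(m)), function(i) {
      setNames(m[i, ], prob$free)
    }))
  }
  starts <- starts[seq_len(min(length(starts), options$n_starts))]
  fits <- lapply(starts, function(s) optimise_theta(fn, s, lo, hi, options))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  if (all(!is.finite(vals)))
    stop("all optimisation starts failed; check data scaling and bounds",
         call. = FALSE)
  best <- which.min(vals)
  list(best = fits[[best]], best_start = best,
       converged_fraction = mean(vapply(fits, `[[`, logical(1), "converged")),
       n_starts = length(starts))
}

finish_fit <- function(prob, ms, options, dataset_condition) {
  theta <- ms$best$par
  rss <- ms$best$value
  sigma <- if (is.null(options$sigma)) sqrt(rss / prob$n) else options$sigma
  v <- problem_natural(prob, theta)
  est <- natural_to_params(prob, v, max(sigma, 1e-12))
  yhat <- fao_trajectory(prob$spec, est, prob$times)$values
  resid <- prob$obs$log10 -
    log10(pmax(yhat[cbind(prob$obs$species + 1L, prob$obs$time + 1L)], 1e-300))
  structure(list(spec = prob$spec, estimates = est,
                 minus2_loglik = minus2_loglik_from_rss(rss, prob$n,
                                                        options$sigma),
                 rss = rss, n_obs = prob$n, n_starts = ms$n_starts,
                 converged_fraction = ms$converged_fraction,
                 best_start_seed = options$seed, best_start = ms$best_start,
                 residuals = setNames(resid, paste(prob$obs$rows$species,
                                                   prob$obs$rows$time_min,
                                                   prob$obs$rows$replicate,
                                                   sep = "_")),
                 theta = theta, problem = prob, options = options,
                 condition = dataset_condition),
            class = "fao_fit")
}

#' Fit the FAO cascade to one condition by maximum likelihood
#'
#' Minimises the log10-scale residual sum of squares (equivalently maximises
#' the log-normal likelihood; sigma is profiled analytically unless fixed in
#' `options`) over chain rates, active influx rates and initial
#' concentrations, all optimised as log10-transformed box-constrained
#' parameters via multi-start L-BFGS-B. The first start uses the t = 0
#' replicate means for initial concentrations; remaining starts are Latin
#' hypercube draws. Deterministic given `options$seed`.
#'
#' @param dataset An `fao_timecourse` (one condition, or use `condition`).
#' @param spec A [fao_model_spec()].
#' @param options A [fit_options()] list.
#' @param condition Optional condition id to subset.
#' @return An object of class `fao_fit` with elements `estimates`
#'   ([rate_parameter_set()]), `minus2_loglik`, `converged_fraction`,
#'   `residuals`, and bookkeeping used by [profile_ci()] and friends.
#' @export
fit_condition <- function(dataset, spec, options = fit_options(),
                          condition = NULL) {
  prob <- single_problem(dataset, spec, condition, options)
  ms <- run_multistart(prob, options)
  finish_fit(prob, ms, options,
             if (is.null(condition)) unique(prob$obs$rows$condition)
             else condition)
}

#' @export
print.fao_fit <- function(x, ...) {
  cat("FAO cascade fit (condition:", x$condition, ")\n")
  cat("  -2 log L:", format(x$minus2_loglik, digits = 8),
      " | n obs:", x$n_obs,
      " | converged starts:", sprintf("%.0f%%", 100 * x$converged_fraction),
      "\n")
  cat("  chain rates (/min):\n")
  print(signif(x$estimates$chain_rates, 4))
  if (length(x$estimates$influx_rates)) {
    cat("  influx rates (nmol/g/min):\n")
    print(signif(x$estimates$influx_rates, 4))
  }
  cat("  sigma (log10):", signif(x$estimates$sigma, 4), "\n")
  invisible(x)
}
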