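# Observation arrays for the compiled objective: canonical record order
# (species, time, value) so sums are independent of input row order.
make_obs <- function(records, spec, times) {
  lab <- species_label(spec$species)
  sp_idx <- match(records$species, lab) - 1L
  t_idx <- match(records$time_min, times) - 1L
  if (anyNA(t_idx))
    stop("record time not on the fitting time grid", call. = FALSE)
  y <- log10(records$conc_nmol_per_g)
  o <- order(sp_idx, t_idx, y)
  list(species = sp_idx[o], time = t_idx[o], log10 = y[o],
       rows = records[o, , drop = FALSE], n = length(y))
}

#' -2 log-likelihood of a parameter set on log10 scale
#'
#' The measurement model is log-normal: for each observed record,
#' `log10(y) ~ Normal(log10(yhat), sigma)` with `yhat` the model trajectory.
#' Returns `-2 log L = sum_i [ (log10 y_i - log10 yhat_i)^2 / sigma^2
#' + log(2 pi sigma^2) ]` over all observed records of all replicates
#' (natural log in the normalising term). Below-LOQ records are excluded with
#' a warning; non-positive measurements are an error.
#'
#' @param dataset An `fao_timecourse`, restricted to one condition.
#' @param spec A [fao_model_spec()].
#' @param params A [rate_parameter_set()]; its `sigma` is used as given.
#' @return The scalar -2 log-likelihood.
#' @export
fao_minus2_loglik <- function(dataset, spec, params) {
  d <- fit_records(dataset, spec)
  if (length(unique(d$condition)) > 1L)
    stop("dataset spans multiple conditions; restrict to one", call. = FALSE)
  times <- sort(unique(c(0, d$time_min)))
  obs <- make_obs(d, spec, times)
  traj <- fao_trajectory(spec, params, times)
  yhat <- traj$values[cbind(obs$species + 1L, obs$time + 1L)]
  r <- obs$log10 - log10(pmax(yhat, 1e-300))
  sum(r^2) / params$sigma^2 + obs$n * log(2 * pi * params$sigma^2)
}

minus2_loglik_from_rss <- function(rss, n, sigma = NULL) {
  if (is.null(sigma)) n * (1 + log(2 * pi) + log(rss / n))
  else rss / sigma^2 + n * log(2 * pi * sigma^2)
}

# --- parameter packing -----------------------------------------------------
#
# Fitting works on theta = log10 of the positive parameters. A "problem"
# bundles the observation arrays for one condition with the mapping from
# theta to (k, b, x0) and the bound box; `fix` holds parameters frozen on
# the natural scale (used for profiling and constrained refits).

single_problem <- function(dataset, spec, condition = NULL, options) {
  d <- fit_records(dataset, spec, condition)
  if (nrow(d) == 0L) stop("no records to fit", call. = FALSE)
  if (length(unique(d$condition)) > 1L)
    stop("dataset spans multiple conditions; pass `condition`", call. = FALSE)
  # canonical record order: estimates do not depend on input row order
  d <- d[order(d$species, d$time_min, d$conc_nmol_per_g, d$replicate), ,
         drop = FALSE]
  times <- sort(unique(c(0, d$time_min)))
  lab <- species_label(spec$species)
  dynamic <- !all(paste0("k_", lab) %in% names(options$fix))
  if (length(times) < 2L && dynamic)
    stop("need at least two time points per condition", call. = FALSE)
  obs <- make_obs(d, spec, times)

  # data-informed starting values: t = 0 replicate means per species
  t0 <- d[d$time_min == times[1], , drop = FALSE]
  t0_mean <- tapply(t0$conc_nmol_per_g, factor(t0$species, levels = lab), mean)
  overall <- tapply(d$conc_nmol_per_g, factor(d$species, levels = lab), mean)
  t0_mean[is.na(t0_mean)] <- overall[is.na(t0_mean)]
  t0_mean[is.na(t0_mean) | t0_mean <= 0] <- 1

  nm <- c(paste0("k_", lab), spec$influxes, paste0("init_", lab))
  kind <- c(rep("rate", length(lab)), rep("influx", length(spec$influxes)),
            rep("init", length(lab)))
  start <- c(rep(0.1, length(lab)), rep(1, length(spec$influxes)),
             unname(t0_mean))
  lo <- hi <- numeric(length(nm))
  lo[kind == "rate"] <- options$rate_bounds[1]
  hi[kind == "rate"] <- options$rate_bounds[2]
  lo[kind == "influx"] <- options$influx_bounds[1]
  hi[kind == "influx"] <- options$influx_bounds[2]
  lo[kind == "init"] <- unname(t0_mean) / options$init_expand
  hi[kind == "init"] <- unname(t0_mean) * options$init_expand
  names(start) <- names(lo) <- names(hi) <- nm

  prob <- list(spec = spec, times = times, obs = obs, names = nm,
               kind = kind, start = start, lower = lo, upper = hi,
               t0_mean = t0_mean, n = obs$n, lab = lab,
               influx_row = match(species_label(influx_targets()[spec$influxes]),
                                  lab))
  problem_refix(prob, options$fix)
}

# freeze `fix` into the problem: precompute the natural-scale template and
# the integer positions of the free parameters (hot path of the objective)
problem_refix <- function(prob, fix) {
  badfix <- setdiff(names(fix), prob$names)
  if (length(badfix))
    stop("unknown fixed parameter(s): ", paste(badfix, collapse = ", "),
         call. = FALSE)
  prob$fix <- fix
  prob$free <- setdiff(prob$names, names(fix))
  tmpl <- unname(prob$start)
  if (length(fix)) tmpl[match(names(fix), prob$names)] <- unlist(fix)
  prob$template <- tmpl
  prob$free_idx <- match(prob$free, prob$names)
  prob
}

# full natural-scale parameter vector (fixed values + 10^theta for free ones)
problem_natural <- function(prob, theta) {
  v <- prob$template
  v[prob$free_idx] <- 10^theta
  v
}

problem_rss <- function(prob, theta) {
  v <- problem_natural(prob, theta)
  nsp <- length(prob$lab)
  if (identical(prob$type, "joint")) {
    k <- v[prob$idx$k]
    infl <- v[prob$idx$influx]
    b <- numeric(nsp)
    if (length(prob$influx_row)) b[prob$influx_row] <- infl
    rss_a <- .cascade_rss_cpp(k, b, v[prob$idx$initA], prob$timesA,
                              prob$obsA$species, prob$obsA$time,
                              prob$obsA$log10)
    rss_b <- .cascade_rss_cpp(k * v[prob$idx$alpha], b, v[prob$idx$initB],
                              prob$timesB, prob$obsB$species, prob$obsB$time,
                              prob$obsB$log10)
    return(rss_a + rss_b)
  }
  k <- v[seq_len(nsp)]
  b <- numeric(nsp)
  if (length(prob$influx_row))
    b[prob$influx_row] <- v[nsp + seq_along(prob$influx_row)]
  x0 <- v[length(v) - nsp + seq_len(nsp)]
  .cascade_rss_cpp(k, b, x0, prob$times, prob$obs$species, prob$obs$time,
                   prob$obs$log10)
}

natural_to_params <- function(prob, v, sigma) {
  nsp <- length(prob$lab)
  rate_parameter_set(
    chain_rates = setNames(v[seq_len(nsp)], prob$lab),
    influx_rates = setNames(v[nsp + seq_along(prob$spec$influxes)],
                            prob$spec$influxes),
    init_conc = setNames(v[length(v) - nsp + seq_len(nsp)], prob$lab),
    sigma = sigma)
}

# box-constrained local optimisation in log10 space; returns list(par, value,
# converged). Degenerate zero-dimensional problems are evaluated directly.
optimise_theta <- function(fn, theta0, lower, upper, options) {
  if (length(theta0) == 0L)
    return(list(par = theta0, value = fn(theta0), converged = TRUE))
  theta0 <- pmin(pmax(theta0, lower), upper)
  res <- tryCatch(
    optim(theta0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = options$maxit, factr = options$factr)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value))
    return(list(par = theta0, value = Inf, converged = FALSE))
  list(par = res$par, value = res$value, converged = res$convergence == 0)
}
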