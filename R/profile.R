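# Re-optimise all parameters except `param`, frozen at natural value v.
# Warm-started from `warm` (a full named theta over prob$free).
profile_point <- function(prob, options, param, v, warm) {
  fix2 <- prob$fix
  fix2[[param]] <- v
  prob2 <- problem_refix(prob, fix2)
  fn <- function(theta) problem_rss(prob2, theta)
  res <- optimise_theta(fn, warm[prob2$free],
                        log10(prob2$lower[prob2$free]),
                        log10(prob2$upper[prob2$free]), options)
  list(m2ll = minus2_loglik_from_rss(res$value, prob$n, options$sigma),
       theta = res$par)
}

# One-sided profile bound in log10 space: walk outward with growing steps
# until -2 logL crosses the chi-square threshold, then bisect. Returns the
# natural-scale bound and whether the profile stayed open within the box.
profile_side <- function(prob, options, param, t_hat, warm, thr, side,
                         tol = 1e-4) {
  t_lo <- log10(prob$lower[[param]])
  t_hi <- log10(prob$upper[[param]])
  bound <- if (side < 0) t_lo else t_hi
  t_in <- t_hat
  delta <- 0.05
  for (i in 1:80) {
    t_try <- t_in + side * delta
    hit_box <- if (side < 0) t_try <= bound else t_try >= bound
    if (hit_box) t_try <- bound
    pp <- profile_point(prob, options, param, 10^t_try, warm)
    if (pp$m2ll > thr) {
      t_out <- t_try
      break
    }
    warm[setdiff(prob$free, param)] <- pp$theta
    t_in <- t_try
    if (hit_box) return(list(bound = 10^bound, open = TRUE))
    delta <- delta * 1.8
    t_out <- NA_real_
  }
  if (is.na(t_out)) return(list(bound = 10^t_in, open = TRUE))
  while (abs(t_out - t_in) > tol) {
    t_mid <- (t_out + t_in) / 2
    pp <- profile_point(prob, options, param, 10^t_mid, warm)
    if (pp$m2ll > thr) {
      t_out <- t_mid
    } else {
      t_in <- t_mid
      warm[setdiff(prob$free, param)] <- pp$theta
    }
  }
  list(bound = 10^((t_in + t_out) / 2), open = FALSE)
}

profile_ci_problem <- function(prob, options, theta_hat, m2ll_min, param,
                               level) {
  if (!param %in% prob$free)
    stop("parameter '", param, "' is not free in this fit", call. = FALSE)
  thr <- m2ll_min + qchisq(level, df = 1)
  t_hat <- unname(theta_hat[param])
  warm <- theta_hat
  lo <- profile_side(prob, options, param, t_hat, warm, thr, side = -1)
  hi <- profile_side(prob, options, param, t_hat, warm, thr, side = +1)
  structure(list(param_name = param, level = level, estimate = 10^t_hat,
                 lower = lo$bound, upper = hi$bound,
                 lower_open = lo$open, upper_open = hi$open),
            class = "fao_profile_ci")
}

#' Profile-likelihood confidence interval for a fitted parameter
#'
#' Scans one parameter while re-optimising all others, and reports the values
#' where the profile -2 log-likelihood rises by the chi-square(1) quantile
#' (3.841 at the default 0.95 level) above its minimum; each side is located
#' by monotone bisection in log10 space. If the profile never crosses the
#' threshold inside the parameter box the interval is flagged open on that
#' side (`lower_open`/`upper_open`).
#'
#' @param dataset The `fao_timecourse` the fit was computed from (accepted
#'   for interface symmetry; the fit carries its own observation arrays).
#' @param spec The [fao_model_spec()] used in the fit.
#' @param fit An `fao_fit` from [fit_condition()].
#' @param param_name Parameter name as in the fitted vector: `k_C4`,
#'   `influx_C8`, `init_C16`, ...
#' @param level Confidence level, default 0.95.
#' @return An object of class `fao_profile_ci` with `lower`, `upper`,
#'   `estimate`, and open-interval flags.
#' @export
profile_ci <- function(dataset, spec, fit, param_name, level = 0.95) {
  stopifnot(inherits(fit, "fao_fit"))
  opts <- fit$options
  opts$n_starts <- 1L
  profile_ci_problem(fit$problem, opts, fit$theta, fit$minus2_loglik,
                     param_name, level)
}

#' @export
print.fao_profile_ci <- function(x, ...) {
  cat(sprintf("%s: %.4g  [%s%.4g, %.4g%s]  (%.0f%% profile likelihood)\n",
              x$param_name, x$estimate,
              if (x$lower_open) "<" else "", x$lower, x$upper,
              if (x$upper_open) ">" else "", 100 * x$level))
  invisible(x)
}
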