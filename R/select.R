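# warm-start a reduced/extended problem from a fitted theta: shared names are
# copied, new parameters keep the problem's default start
warm_theta <- function(prob, theta_named) {
  w <- log10(pmin(pmax(prob$start[prob$free], prob$lower[prob$free]),
                  prob$upper[prob$free]))
  shared <- intersect(names(w), names(theta_named))
  w[shared] <- theta_named[shared]
  w
}

#' Backward elimination of influx reactions
#'
#' Starting from a model with all candidate influx terms, iteratively removes
#' the influx whose removal gives the largest likelihood-ratio p-value at or
#' above `alpha_level` (chi-square with 1 df), refits, and repeats until all
#' remaining influxes are significant. Chain rates are never candidates for
#' removal, so the returned specification is always nested in `full_spec`
#' and retains the complete conversion chain.
#'
#' @param dataset An `fao_timecourse` restricted to one condition.
#' @param full_spec A [fao_model_spec()] including all influx candidates.
#' @param alpha_level Retention threshold for the likelihood-ratio test.
#' @param options A [fit_options()]; reduced models are refitted with a
#'   warm start from the current model plus a small multi-start.
#' @return The selected `fao_model_spec`, with attributes `fit` (the fit of
#'   the selected model) and `trace` (a data frame of elimination steps).
#' @export
select_model <- function(dataset, full_spec, alpha_level = 0.05,
                         options = fit_options()) {
  current_spec <- full_spec
  current_fit <- fit_condition(dataset, current_spec, options)
  opts_red <- options
  opts_red$n_starts <- max(2L, options$n_starts %/% 10L)
  trace <- list()
  repeat {
    if (!length(current_spec$influxes)) break
    cand <- lapply(current_spec$influxes, function(fl) {
      spec_r <- fao_model_spec(current_spec$species,
                               setdiff(current_spec$influxes, fl),
                               current_spec$observed)
      prob_r <- single_problem(dataset, spec_r, NULL, opts_red)
      theta_named <- setNames(current_fit$theta, current_fit$problem$free)
      ms <- run_multistart(prob_r, opts_red,
                           extra_start = warm_theta(prob_r, theta_named))
      fit_r <- finish_fit(prob_r, ms, opts_red, current_fit$condition)
      d <- max(fit_r$minus2_loglik - current_fit$minus2_loglik, 0)
      list(influx = fl, fit = fit_r, delta = d,
           p = pchisq(d, df = 1, lower.tail = FALSE))
    })
    ps <- vapply(cand, `[[`, numeric(1), "p")
    drop <- which.max(ps)
    trace[[length(trace) + 1L]] <-
      data.frame(influx = cand[[drop]]$influx, lrt_p = ps[drop],
                 dropped = ps[drop] >= alpha_level)
    if (ps[drop] < alpha_level) break
    current_spec <- cand[[drop]]$fit$spec
    current_fit <- cand[[drop]]$fit
  }
  attr(current_spec, "fit") <- current_fit
  attr(current_spec, "trace") <- if (length(trace)) do.call(rbind, trace)
    else data.frame(influx = character(), lrt_p = numeric(),
                    dropped = logical())
  current_spec
}
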