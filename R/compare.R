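# Joint two-condition problem: condition A keeps its own chain rates k_n;
# condition B's rates are k_n * alpha_n. Influx rates are shared (same
# loading protocol); initial concentrations are per-condition (baselines
# differ under knockdown); sigma is shared and profiled over the pooled
# records.
joint_problem <- function(probA, probB, options, alpha_bounds) {
  lab <- probA$lab
  nsp <- length(lab)
  nin <- length(probA$spec$influxes)
  nm <- c(paste0("k_", lab), probA$spec$influxes,
          paste0("initA_", lab), paste0("initB_", lab),
          paste0("alpha_", lab))
  kind <- c(rep("rate", nsp), rep("influx", nin),
            rep("init", 2 * nsp), rep("alpha", nsp))
  start <- c(rep(0.1, nsp), rep(1, nin), unname(probA$t0_mean),
             unname(probB$t0_mean), rep(1, nsp))
  lo <- c(rep(options$rate_bounds[1], nsp), rep(options$influx_bounds[1], nin),
          unname(probA$t0_mean) / options$init_expand,
          unname(probB$t0_mean) / options$init_expand,
          rep(alpha_bounds[1], nsp))
  hi <- c(rep(options$rate_bounds[2], nsp), rep(options$influx_bounds[2], nin),
          unname(probA$t0_mean) * options$init_expand,
          unname(probB$t0_mean) * options$init_expand,
          rep(alpha_bounds[2], nsp))
  names(start) <- names(lo) <- names(hi) <- nm
  idx <- list(k = seq_len(nsp), influx = nsp + seq_len(nin),
              initA = nsp + nin + seq_len(nsp),
              initB = 2 * nsp + nin + seq_len(nsp),
              alpha = 2 * nsp + nin + nsp + seq_len(nsp))
  prob <- list(type = "joint", spec = probA$spec, lab = lab, idx = idx,
               names = nm, kind = kind, start = start, lower = lo,
               upper = hi, influx_row = probA$influx_row,
               timesA = probA$times, timesB = probB$times,
               obsA = probA$obs, obsB = probB$obs, n = probA$n + probB$n)
  problem_refix(prob, options$fix)
}

joint_warm_start <- function(prob, fitA, fitB, alpha_bounds) {
  lab <- prob$lab
  kA <- fitA$estimates$chain_rates[lab]
  kB <- fitB$estimates$chain_rates[lab]
  v <- prob$start
  v[prob$idx$k] <- kA
  if (length(prob$idx$influx))
    v[prob$idx$influx] <- (fitA$estimates$influx_rates[prob$spec$influxes] +
                           fitB$estimates$influx_rates[prob$spec$influxes]) / 2
  v[prob$idx$initA] <- fitA$estimates$init_conc[lab]
  v[prob$idx$initB] <- fitB$estimates$init_conc[lab]
  v[prob$idx$alpha] <- pmin(pmax(kB / kA, alpha_bounds[1] * 1.01),
                            alpha_bounds[2] * 0.99)
  log10(pmin(pmax(v, prob$lower), prob$upper))[prob$free]
}

#' Rate-ratio (alpha) inference between two conditions
#'
#' Fits a joint model in which condition A has chain rates `k_n` and
#' condition B has rates `alpha_n * k_n`; influx rates are shared, initial
#' concentrations are condition-specific, and the log10-scale residual SD is
#' shared and profiled. Each `alpha_n` gets a profile-likelihood confidence
#' interval and a likelihood-ratio p-value for the hypothesis
#' `alpha_n = 1` (chi-square, 1 df, unadjusted across rates); `significant`
#' is `p < 0.05`. An `alpha_n < 1` with an interval excluding 1 indicates a
#' significantly slower conversion step in condition B.
#'
#' @param dataset_A,dataset_B `fao_timecourse` data for the two conditions
#'   (e.g. control and knockdown); both must cover the observed species of
#'   `spec` on the same time grid.
#' @param spec A shared [fao_model_spec()].
#' @param options A [fit_options()] used for the per-condition fits; the
#'   joint fit is warm-started from them.
#' @param level Confidence level for the profile intervals.
#' @param ci If `FALSE`, skip the (costlier) profile intervals and report
#'   only estimates and likelihood-ratio p-values.
#' @param rates Species labels (e.g. `"C4"`) whose rate ratios get tests and
#'   intervals; default all chain rates. Estimates are always reported.
#' @param alpha_bounds Box for the rate ratios.
#' @return A data frame of class `rate_ratio_result` with one row per chain
#'   rate: `species`, `alpha`, `lower`, `upper`, `p_value`, `significant`.
#'   The joint and per-condition fits are attached as attributes.
#' @export
compare_rates <- function(dataset_A, dataset_B, spec,
                          options = fit_options(), level = 0.95, ci = TRUE,
                          rates = NULL, alpha_bounds = c(1e-4, 1e4)) {
  spA <- sort(unique(fit_records(dataset_A, spec)$species))
  spB <- sort(unique(fit_records(dataset_B, spec)$species))
  if (!identical(spA, spB))
    stop("conditions cover different species sets: A = {",
         paste(spA, collapse = ","), "}, B = {",
         paste(spB, collapse = ","), "}", call. = FALSE)

  fitA <- fit_condition(dataset_A, spec, options)
  fitB <- fit_condition(dataset_B, spec, options)
  prob <- joint_problem(fitA$problem, fitB$problem, options, alpha_bounds)

  opts_j <- options
  opts_j$n_starts <- if (options$n_starts <= 1L) 1L else 2L
  ms <- run_multistart(prob, opts_j,
                       extra_start = joint_warm_start(prob, fitA, fitB,
                                                      alpha_bounds))
  theta <- ms$best$par
  m2ll <- minus2_loglik_from_rss(ms$best$value, prob$n, options$sigma)

  opts_1 <- options
  opts_1$n_starts <- 1L
  lab <- prob$lab
  if (is.null(rates)) rates <- lab
  rows <- vector("list", length(lab))
  for (i in seq_along(lab)) {
    pn <- paste0("alpha_", lab[i])
    if (!lab[i] %in% rates) {
      rows[[i]] <- data.frame(species = NA_character_,
                              alpha = 10^unname(theta[pn]),
                              lower = NA_real_, upper = NA_real_,
                              p_value = NA_real_, significant = NA)
      next
    }
    con <- profile_point(prob, opts_1, pn, 1, theta)
    if (con$m2ll < m2ll - 1e-6) {
      # the constrained fit found a better basin; re-polish the joint fit
      w <- theta
      w[setdiff(prob$free, pn)] <- con$theta
      w[pn] <- 0
      pol <- optimise_theta(function(th) problem_rss(prob, th), w,
                            log10(prob$lower[prob$free]),
                            log10(prob$upper[prob$free]), opts_1)
      if (is.finite(pol$value)) {
        m2ll_new <- minus2_loglik_from_rss(pol$value, prob$n, options$sigma)
        if (m2ll_new < m2ll) {
          theta <- pol$par
          m2ll <- m2ll_new
        }
      }
    }
    delta <- max(con$m2ll - m2ll, 0)
    p <- pchisq(delta, df = 1, lower.tail = FALSE)
    est <- 10^unname(theta[pn])
    if (ci) {
      pci <- profile_ci_problem(prob, opts_1, theta, m2ll, pn, level)
      lo <- pci$lower
      hi <- pci$upper
    } else {
      lo <- NA_real_
      hi <- NA_real_
    }
    rows[[i]] <- data.frame(species = NA_character_,
                            alpha = est, lower = lo, upper = hi,
                            p_value = p, significant = p < 0.05)
  }
  out <- do.call(rbind, rows)
  out$species <- species_label(prob$spec$species)
  class(out) <- c("rate_ratio_result", "data.frame")
  attr(out, "fit_A") <- fitA
  attr(out, "fit_B") <- fitB
  attr(out, "joint_minus2_loglik") <- m2ll
  attr(out, "joint_theta") <- theta
  out
}

#' @export
print.rate_ratio_result <- function(x, ...) {
  cat("Rate ratios alpha = k(B) / k(A) with",
      "profile-likelihood CIs and LRT p-values\n")
  df <- as.data.frame(x)
  df$alpha <- signif(df$alpha, 4)
  df$lower <- signif(df$lower, 4)
  df$upper <- signif(df$upper, 4)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
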