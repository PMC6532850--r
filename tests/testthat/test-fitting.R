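test_that("-2 logL follows the log10-scale log-normal formula", {
  spec <- fao_model_spec(species = 16)
  p <- rate_parameter_set(chain_rates = c(C16 = 0), init_conc = c(C16 = 1),
                          sigma = 1)

  # a single record y = 10 against yhat = 1 with sigma = 1:
  # residual^2 = 1, so -2logL = 1 + ln(2*pi)
  d1 <- as_timecourse(records_from_matrix(
    matrix(10, 1, 1, dimnames = list("C16", NULL)), times = 0))
  expect_equal(fao_minus2_loglik(d1, spec, p), 1 + log(2 * pi),
               tolerance = 1e-12)

  # zero residuals: -2logL = N * ln(2*pi)
  sc <- default_scenario(1)
  ds <- exact_dataset(sc$spec, sc$base_params, n_replicates = 2)
  p0 <- sc$base_params
  p0$sigma <- 1
  n <- nrow(ds)
  expect_equal(fao_minus2_loglik(ds, sc$spec, p0), n * log(2 * pi),
               tolerance = 1e-9)

  # doubling sigma from the zero-residual state adds N * ln(4)
  p2 <- p0
  p2$sigma <- 2
  expect_equal(fao_minus2_loglik(ds, sc$spec, p2) -
                 fao_minus2_loglik(ds, sc$spec, p0), n * log(4),
               tolerance = 1e-9)

  # order invariance: likelihood is a sum over records
  perm <- ds[sample(nrow(ds)), ]
  expect_identical(fao_minus2_loglik(perm, sc$spec, p0),
                   fao_minus2_loglik(ds, sc$spec, p0))
})

test_that("non-positive measurements are rejected by name", {
  sc <- default_scenario(1)
  ds <- exact_dataset(sc$spec, sc$base_params, n_replicates = 1)
  ds$conc_nmol_per_g[5] <- 0
  expect_error(fao_minus2_loglik(ds, sc$spec, sc$base_params),
               "non-positive concentration")
})

test_that("noiseless data give near-exact rate recovery", {
  sc <- default_scenario(1)
  truth <- faoflux:::condition_params(sc, "null")
  ds <- exact_dataset(sc$spec, truth, n_replicates = 4)
  fit <- fit_condition(ds, sc$spec, quick_opts(n_starts = 2))
  rel <- abs(fit$estimates$chain_rates - truth$chain_rates) /
    truth$chain_rates
  expect_true(all(rel < 0.01))
})

test_that("noisy data at the study design size recover k4 within 25%", {
  sc <- default_scenario(1)
  ds <- generate_dataset(sc)
  truth <- faoflux:::condition_params(sc, "null")
  fit <- fit_condition(ds[ds$condition == "null", ], sc$spec,
                       quick_opts(n_starts = 3))
  rel_k4 <- abs(fit$estimates$chain_rates["C4"] - truth$chain_rates["C4"]) /
    truth$chain_rates["C4"]
  expect_lt(rel_k4, 0.25)
  expect_gt(fit$converged_fraction, 0)
  # the optimum cannot be worse than the generating truth
  theta_truth <- log10(c(truth$chain_rates, truth$influx_rates,
                         truth$init_conc))
  names(theta_truth) <- fit$problem$names
  rss_truth <- faoflux:::problem_rss(fit$problem,
                                     theta_truth[fit$problem$free])
  expect_lte(fit$minus2_loglik,
             faoflux:::minus2_loglik_from_rss(rss_truth, fit$n_obs) + 1e-6)
})

test_that("record order does not change the estimates", {
  sc <- default_scenario(2)
  ds <- generate_dataset(sc)
  nd <- ds[ds$condition == "null", ]
  set.seed(99)
  perm <- nd[sample(nrow(nd)), ]
  f1 <- fit_condition(nd, sc$spec, quick_opts())
  f2 <- fit_condition(perm, sc$spec, quick_opts())
  expect_identical(f1$estimates$chain_rates, f2$estimates$chain_rates)
  expect_identical(f1$minus2_loglik, f2$minus2_loglik)
})

test_that("pooled replicates equal the concatenated record list", {
  # the likelihood decomposes over records, so splitting/rebinding the
  # replicate rows cannot change the objective
  sc <- default_scenario(3)
  ds <- generate_dataset(sc)
  nd <- ds[ds$condition == "null", ]
  by_rep <- do.call(rbind, split(nd, nd$replicate))
  p <- sc$base_params
  expect_equal(fao_minus2_loglik(as_timecourse(by_rep), sc$spec, p),
               fao_minus2_loglik(nd, sc$spec, p))
})

test_that("replicate count tightens rate recovery", {
  errs <- sapply(c(4, 16), function(nr) {
    median(sapply(1:4, function(s) {
      sc <- default_scenario(s)
      sc$n_replicates <- nr
      ds <- generate_dataset(sc)
      truth <- faoflux:::condition_params(sc, "null")
      fit <- fit_condition(ds[ds$condition == "null", ], sc$spec,
                           quick_opts())
      median(abs(fit$estimates$chain_rates - truth$chain_rates) /
               truth$chain_rates)
    }))
  })
  expect_lt(errs[2], errs[1])
})

test_that("profile CI matches the Gaussian closed form in the toy limit", {
  # single constant species, rates fixed at zero, sigma known: profiling the
  # initial concentration is a Gaussian mean problem on log10 scale and the
  # 95% interval must be mean +/- 1.96 * sigma / sqrt(n)
  spec <- fao_model_spec(species = 16)
  set.seed(42)
  n <- 12
  sigma <- 0.1
  y <- 10^(log10(50) + rnorm(n, 0, sigma))
  ds <- as_timecourse(data.frame(
    condition = "null", dox_ng_ml = 0, replicate = paste0("R", 1:n),
    compartment = "intracellular", species = "C16", time_min = 0,
    conc_nmol_per_g = y, below_loq = FALSE))
  fit <- fit_condition(ds, spec,
                       fit_options(n_starts = 1, sigma = sigma,
                                   fix = list(k_C16 = 0)))
  ci <- profile_ci(ds, spec, fit, "init_C16")
  m <- mean(log10(y))
  half <- qnorm(0.975) * sigma / sqrt(n)
  expect_equal(log10(ci$lower), m - half, tolerance = 1e-3)
  expect_equal(log10(ci$upper), m + half, tolerance = 1e-3)
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)
})

test_that("profile CIs contain the estimate and widen with noise", {
  widths <- sapply(c(0.05, 0.15), function(sg) {
    sc <- default_scenario(5)
    sc$noise_sigma <- sg
    ds <- generate_dataset(sc)
    fit <- fit_condition(ds[ds$condition == "null", ], sc$spec, quick_opts())
    ci <- profile_ci(ds, sc$spec, fit, "k_C4")
    expect_lte(ci$lower, ci$estimate)
    expect_gte(ci$upper, ci$estimate)
    log10(ci$upper) - log10(ci$lower)
  })
  expect_lt(widths[1], widths[2])
})

test_that("profile k4 intervals cover the truth at close to nominal rate", {
  # coverage by likelihood-ratio inversion: the 95% profile CI covers the
  # truth iff the constrained fit at the true k4 stays within the
  # chi-square(1) threshold of the optimum
  hits <- sapply(1:40, function(s) {
    sc <- default_scenario(s + 300)
    ds <- generate_dataset(sc)
    truth <- faoflux:::condition_params(sc, "null")
    fit <- fit_condition(ds[ds$condition == "null", ], sc$spec, quick_opts())
    con <- faoflux:::profile_point(fit$problem,
                                   replace(fit$options, "n_starts", 1),
                                   "k_C4",
                                   unname(truth$chain_rates["C4"]),
                                   fit$theta)
    con$m2ll - fit$minus2_loglik <= qchisq(0.95, 1)
  })
  expect_gte(mean(hits), 0.85)
})

test_that("backward elimination keeps the chain and returns a nested model", {
  sc <- default_scenario(11, influx_preset = "no_C8")
  ds <- generate_dataset(sc)
  nd <- ds[ds$condition == "null", ]
  sel <- select_model(nd, sc$spec, options = quick_opts())
  expect_s3_class(sel, "fao_model_spec")
  expect_identical(sel$species, sc$spec$species)
  expect_true(all(sel$influxes %in% sc$spec$influxes))
  # nesting: the full model can never fit worse than the selected one
  full_fit <- fit_condition(nd, sc$spec, quick_opts())
  expect_lte(full_fit$minus2_loglik,
             attr(sel, "fit")$minus2_loglik + 1e-6)
})
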