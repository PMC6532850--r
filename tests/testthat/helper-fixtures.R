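# shared fixtures: built in code, no files

all_influxes <- c("input_to_C16", "influx_C14", "influx_C8", "influx_C4")

# a random full cascade (parameters spanning the realistic ranges, random
# influx subset); used for oracle-equivalence and property tests
random_cascade <- function(seed) {
  set.seed(seed)
  spec <- fao_model_spec(influxes = sample(all_influxes,
                                           sample(0:4, 1)))
  params <- rate_parameter_set(
    chain_rates = setNames(10^runif(8, -2, log10(0.5)),
                           paste0("C", seq(16, 2, -2))),
    influx_rates = setNames(runif(length(spec$influxes), 0, 10),
                            spec$influxes),
    init_conc = setNames(runif(8, 1, 100), paste0("C", seq(16, 2, -2))),
    sigma = 0.05)
  list(spec = spec, params = params)
}

# relative error with a 1e-3 nmol/g floor: agreement is only meaningful
# orders of magnitude above the integrator tolerance and far below any
# quantifiable concentration
max_rel_diff <- function(a, b, floor = 1e-3) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# long-format records for one condition from an explicit value matrix
records_from_matrix <- function(values, times, condition = "null",
                                replicate = "R1") {
  data.frame(condition = condition, dox_ng_ml = 0, replicate = replicate,
             compartment = "intracellular",
             species = rep(rownames(values), times = length(times)),
             time_min = rep(times, each = nrow(values)),
             conc_nmol_per_g = as.vector(values), below_loq = FALSE,
             stringsAsFactors = FALSE)
}

# noise-free dataset generated exactly from a parameter set
exact_dataset <- function(spec, params, times = c(0, 7, 14, 21, 28),
                          n_replicates = 2, condition = "null") {
  traj <- closed_form_trajectory(spec, params, times)
  as_timecourse(do.call(rbind, lapply(seq_len(n_replicates), function(i) {
    records_from_matrix(traj$values, times, condition, paste0("R", i))
  })))
}

quick_opts <- function(n_starts = 2, seed = 1, ...) {
  fit_options(n_starts = n_starts, seed = seed, ...)
}
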