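#' Elementwise normalisation of concentrations
#'
#' Divides measured values by a per-sample positive normaliser (protein
#' amount per well, or citrate-synthase activity), tracking the resulting
#' unit in an attribute.
#'
#' @param values Numeric vector of measurements.
#' @param normalizer Positive numeric vector of the same length.
#' @param unit Unit label for the result, e.g. `"nmol/g protein"`.
#' @return `values / normalizer` with a `unit` attribute.
#' @export
normalize_by <- function(values, normalizer, unit = "nmol/g protein") {
  stopifnot(is.numeric(values), is.numeric(normalizer))
  if (length(values) != length(normalizer))
    stop("values and normalizer lengths differ", call. = FALSE)
  if (any(!is.finite(normalizer) | normalizer <= 0))
    stop("normalizer must be strictly positive", call. = FALSE)
  structure(values / normalizer, unit = unit)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct(target) - RGI`, with the reference-gene index (RGI)
#' the arithmetic mean of the reference-gene Ct values; then
#' `ddCt = mean dCt(treated) - mean dCt(control)` and the fold change is
#' `2^(-ddCt)`.
#'
#' @param treated,control Long Ct tables (columns `sample, group, gene, ct`;
#'   see [read_ct_table()]).
#' @param target Target gene name (e.g. `"ACADS"`).
#' @param ref_genes Reference genes forming the RGI; defaults to every
#'   non-target gene present. The set must be measured in all samples.
#' @return List with `fold`, `ddct`, and per-sample `dct_treated` /
#'   `dct_control`.
#' @export
delta_delta_ct <- function(treated, control, target = "ACADS",
                           ref_genes = NULL) {
  dct <- function(tbl) {
    if (is.null(ref_genes)) ref_genes <<- setdiff(unique(tbl$gene), target)
    if (!length(ref_genes)) stop("no reference genes", call. = FALSE)
    vapply(split(tbl, tbl$sample), function(s) {
      tg <- s$ct[s$gene == target]
      if (length(tg) != 1L)
        stop("sample ", s$sample[1], ": target gene '", target,
             "' must appear exactly once", call. = FALSE)
      refs <- s$ct[match(ref_genes, s$gene)]
      if (anyNA(refs))
        stop("sample ", s$sample[1], ": missing reference gene(s) ",
             paste(ref_genes[is.na(refs)], collapse = ", "), call. = FALSE)
      tg - mean(refs)
    }, numeric(1))
  }
  dt <- dct(treated)
  dc <- dct(control)
  ddct <- mean(dt) - mean(dc)
  list(fold = 2^(-ddct), ddct = ddct, dct_treated = dt, dct_control = dc)
}

select_records <- function(dataset, species, condition, time, compartment) {
  d <- dataset[dataset$species == species & dataset$condition == condition &
                 dataset$time_min == time &
                 dataset$compartment == compartment & !dataset$below_loq, ,
               drop = FALSE]
  if (nrow(d) == 0L)
    stop("no records for ", species, " / ", condition, " / t=", time,
         " / ", compartment, call. = FALSE)
  d
}

#' Fold change of group means at a fixed time point
#'
#' Ratio of replicate-mean concentrations between two conditions
#' (numerator / denominator), by default at baseline `t = 0`. Fold changes
#' are ratios of group means, not means of ratios; per-replicate values are
#' returned for downstream nonparametric tests.
#'
#' @param dataset An `fao_timecourse`.
#' @param species Species token, e.g. `"C4"`.
#' @param condition_num,condition_den Condition ids for numerator and
#'   denominator.
#' @param time Time point in minutes (default 0, the baseline).
#' @param compartment `"intracellular"` (default) or `"extracellular"`.
#' @return List with `fold`, `mean_num`, `mean_den`, and per-replicate
#'   vectors `values_num`, `values_den`.
#' @export
baseline_fold_change <- function(dataset, species, condition_num,
                                 condition_den, time = 0,
                                 compartment = "intracellular") {
  num <- select_records(dataset, species, condition_num, time, compartment)
  den <- select_records(dataset, species, condition_den, time, compartment)
  fold <- mean(num$conc_nmol_per_g) / mean(den$conc_nmol_per_g)
  list(fold = fold, mean_num = mean(num$conc_nmol_per_g),
       mean_den = mean(den$conc_nmol_per_g),
       values_num = setNames(num$conc_nmol_per_g, num$replicate),
       values_den = setNames(den$conc_nmol_per_g, den$replicate))
}

#' Replicate-paired acylcarnitine ratio
#'
#' Computes the per-replicate ratio of two species measured in the same
#' replicates (default the C3/C4 ratio, a screening marker of short-chain
#' acyl-CoA dehydrogenase activity) for one condition and time point.
#'
#' @param dataset An `fao_timecourse`.
#' @param species_num,species_den Species tokens (default `"C3"`, `"C4"`).
#' @param condition Condition id.
#' @param time Time point in minutes (default 0).
#' @param compartment Compartment (default intracellular).
#' @return List with per-replicate `ratios`, their `mean`, and the two
#'   replicate-matched value vectors.
#' @export
acyl_ratio <- function(dataset, species_num = "C3", species_den = "C4",
                       condition, time = 0, compartment = "intracellular") {
  num <- select_records(dataset, species_num, condition, time, compartment)
  den <- select_records(dataset, species_den, condition, time, compartment)
  shared <- intersect(num$replicate, den$replicate)
  if (!length(shared))
    stop("no replicates with both ", species_num, " and ", species_den,
         call. = FALSE)
  nv <- num$conc_nmol_per_g[match(shared, num$replicate)]
  dv <- den$conc_nmol_per_g[match(shared, den$replicate)]
  if (any(dv <= 0))
    stop("non-positive denominator concentration", call. = FALSE)
  r <- setNames(nv / dv, shared)
  list(ratios = r, mean = mean(r), values_num = setNames(nv, shared),
       values_den = setNames(dv, shared))
}

#' Per-time-point two-sample t-tests between conditions
#'
#' Equal-variance two-sample t-tests (Welch by setting
#' `var_equal = FALSE`) comparing one species between two conditions at each
#' time point, with significance stars at 0.05 / 0.01.
#'
#' @param dataset An `fao_timecourse`.
#' @param species Species token.
#' @param condition_A,condition_B Condition ids.
#' @param compartment Compartment (default intracellular).
#' @param var_equal Pool variances (default `TRUE`).
#' @return Data frame with one row per time point: `time_min`, `statistic`,
#'   `p_value`, `star`. Time points with fewer than two replicates per group
#'   are flagged `NA`.
#' @export
timepoint_tests <- function(dataset, species, condition_A, condition_B,
                            compartment = "intracellular",
                            var_equal = TRUE) {
  d <- dataset[dataset$species == species &
                 dataset$compartment == compartment & !dataset$below_loq, ,
               drop = FALSE]
  times <- sort(unique(d$time_min))
  rows <- lapply(times, function(tt) {
    a <- d$conc_nmol_per_g[d$condition == condition_A & d$time_min == tt]
    b <- d$conc_nmol_per_g[d$condition == condition_B & d$time_min == tt]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(time_min = tt, statistic = NA_real_,
                        p_value = NA_real_, star = ""))
    res <- tryCatch(t.test(a, b, var.equal = var_equal),
                    error = function(e) NULL)
    if (is.null(res)) {
      # zero within-group variance; identical constant groups carry no signal
      warning("degenerate (constant) data at t=", tt, "; p set to 1")
      return(data.frame(time_min = tt, statistic = 0, p_value = 1, star = ""))
    }
    p <- res$p.value
    data.frame(time_min = tt, statistic = unname(res$statistic), p_value = p,
               star = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
  })
  do.call(rbind, rows)
}

# exact two-sided Mann-Whitney by exhaustive enumeration over all
# choose(n1+n2, n1) group assignments of the mid-ranks
mann_whitney_exact <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  assign_u <- combn(n1 + n2, n1, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  p <- mean(abs(assign_u - mu) >= abs(u_obs - mu) - 1e-9)
  list(statistic = u_obs, p_value = p)
}

mann_whitney_normal <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  s2 <- n1 * n2 / 12 * ((n + 1) - tie_corr)
  if (s2 <= 0) {
    warning("degenerate (constant) data; p set to 1")
    return(list(statistic = u, p_value = 1))
  }
  # continuity-corrected, matching the exact enumeration closely
  z <- (abs(u - n1 * n2 / 2) - 0.5) / sqrt(s2)
  list(statistic = u, p_value = min(1, 2 * pnorm(-max(z, 0))))
}

# Dunn's pairwise z-tests on the pooled mid-ranks after a Kruskal-Wallis
# omnibus, Bonferroni-adjusted
dunn_posthoc <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tcorr <- sum(ties^3 - ties) / (12 * (n - 1))
  rb <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  gl <- names(rb)
  pairs <- combn(length(gl), 2)
  out <- data.frame(group1 = gl[pairs[1, ]], group2 = gl[pairs[2, ]])
  z <- (rb[pairs[1, ]] - rb[pairs[2, ]]) /
    sqrt((n * (n + 1) / 12 - tcorr) * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  out$z <- as.numeric(z)
  out$p_value <- pmin(1, 2 * pnorm(-abs(out$z)) * ncol(pairs))
  out
}

#' Group comparison tests used in the study
#'
#' One entry point for the statistical comparisons: exact-enumeration
#' Mann-Whitney U (normal approximation for combined n > 12; ties handled by
#' mid-ranks), Kruskal-Wallis with Dunn's Bonferroni-adjusted post hoc,
#' equal-variance two-sample t, one-sample t against `mu` (for fold
#' changes, against 1), and two-way ANOVA (condition x time) with
#' Bonferroni-adjusted per-time contrasts against the first condition level.
#'
#' @param values Numeric vector of measurements.
#' @param groups Group labels (same length as `values`).
#' @param method One of `"mann_whitney"`, `"kruskal_dunn"`,
#'   `"two_sample_t"`, `"one_sample_t"`, `"two_way_anova_bonferroni"`.
#' @param mu Null value for the one-sample t-test (default 1).
#' @param time Time labels, required for the two-way ANOVA.
#' @return A list of class `fao_group_comparison` with `method`,
#'   `statistic`, `p_value`, and (where applicable) a `posthoc` data frame.
#' @export
compare_groups <- function(values, groups = NULL,
                           method = c("mann_whitney", "kruskal_dunn",
                                      "two_sample_t", "one_sample_t",
                                      "two_way_anova_bonferroni"),
                           mu = 1, time = NULL) {
  method <- match.arg(method)
  out <- switch(method,
    mann_whitney = {
      g <- unique(groups)
      if (length(g) != 2L) stop("mann_whitney needs two groups", call. = FALSE)
      x <- values[groups == g[1]]
      y <- values[groups == g[2]]
      res <- if (length(values) <= 12L) mann_whitney_exact(x, y)
             else mann_whitney_normal(x, y)
      c(res, list(groups = g))
    },
    kruskal_dunn = {
      if (length(unique(values)) == 1L) {
        warning("degenerate (constant) data; p set to 1")
        list(statistic = 0, p_value = 1,
             posthoc = dunn_posthoc(values, groups), groups = unique(groups))
      } else {
        kw <- kruskal.test(values, factor(groups))
        list(statistic = unname(kw$statistic), p_value = kw$p.value,
             posthoc = dunn_posthoc(values, groups), groups = unique(groups))
      }
    },
    two_sample_t = {
      g <- unique(groups)
      if (length(g) != 2L) stop("two_sample_t needs two groups", call. = FALSE)
      res <- t.test(values[groups == g[1]], values[groups == g[2]],
                    var.equal = TRUE)
      list(statistic = unname(res$statistic), p_value = res$p.value,
           groups = g)
    },
    one_sample_t = {
      if (isTRUE(all.equal(var(values), 0)) || length(values) < 2L) {
        warning("degenerate (constant) data; p set to 1")
        list(statistic = 0, p_value = 1, groups = "sample")
      } else {
        res <- t.test(values, mu = mu)
        list(statistic = unname(res$statistic), p_value = res$p.value,
             groups = "sample")
      }
    },
    two_way_anova_bonferroni = {
      if (is.null(time))
        stop("two_way_anova_bonferroni needs `time`", call. = FALSE)
      df <- data.frame(y = values, g = factor(groups), t = factor(time))
      fit <- aov(y ~ g * t, data = df)
      tab <- summary(fit)[[1]]
      ctrl <- levels(df$g)[1]
      cells <- expand.grid(g = setdiff(levels(df$g), ctrl),
                           t = levels(df$t), stringsAsFactors = FALSE)
      ph <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
        a <- df$y[df$g == ctrl & df$t == cells$t[i]]
        b <- df$y[df$g == cells$g[i] & df$t == cells$t[i]]
        p <- if (length(a) > 1L && length(b) > 1L &&
                 (var(a) + var(b)) > 0)
          t.test(a, b, var.equal = TRUE)$p.value else NA_real_
        data.frame(group = cells$g[i], time = cells$t[i], p_raw = p)
      }))
      ph$p_value <- pmin(1, ph$p_raw * sum(!is.na(ph$p_raw)))
      g_row <- which(trimws(rownames(tab)) == "g")
      list(statistic = tab[g_row, "F value"],
           p_value = tab[g_row, "Pr(>F)"],
           anova_table = tab, posthoc = ph, groups = levels(df$g))
    })
  structure(c(list(method = method), out), class = "fao_group_comparison")
}

#' @export
print.fao_group_comparison <- function(x, ...) {
  cat("Group comparison:", x$method, "\n")
  cat("  statistic:", signif(x$statistic, 5),
      " p:", signif(x$p_value, 4), "\n")
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
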