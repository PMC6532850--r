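test_that("normalisation is elementwise division with unit tracking", {
  expect_equal(as.numeric(normalize_by(c(10, 20), c(1, 1))), c(10, 20))
  expect_equal(as.numeric(normalize_by(c(10, 20), c(2, 4))), c(5, 5))
  v <- c(3.2, 8.7, 11)
  nz <- c(1.1, 0.8, 2.5)
  expect_equal(as.numeric(normalize_by(v, nz)) * nz, v)
  expect_error(normalize_by(c(1, 2), c(1, 0)), "positive")
  expect_error(normalize_by(c(1, 2), 1), "length")
})

make_ct <- function(group, target_ct, ref_ct, n = 2) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(sample = paste0(group, i), group = group,
               gene = c("ACADS", names(ref_ct)),
               ct = c(target_ct[i], unname(ref_ct)))
  }))
}

test_that("delta-delta-Ct reproduces hand arithmetic", {
  refs <- c(GAPDH = 20, YWHAZ = 21, PPIA = 22)
  ctrl <- make_ct("ctrl", c(25, 25), refs)
  expect_equal(delta_delta_ct(ctrl, ctrl)$fold, 1)

  # one cycle earlier amplification means twofold expression
  tr <- make_ct("tr", c(24, 24), refs)
  expect_equal(delta_delta_ct(tr, ctrl)$fold, 2)

  # asymmetric toy computed by hand: dCt(treated) = (26.3 + 25.1)/2 - 21,
  # dCt(control) = (25 + 25.4)/2 - 21, fold = 2^-(ddct)
  tr2 <- make_ct("tr", c(26.3, 25.1), refs)
  ct2 <- make_ct("ctrl", c(25.0, 25.4), refs)
  ddct_hand <- mean(c(26.3, 25.1) - 21) - mean(c(25.0, 25.4) - 21)
  expect_equal(delta_delta_ct(tr2, ct2)$ddct, ddct_hand)
  expect_equal(delta_delta_ct(tr2, ct2)$fold, 2^(-ddct_hand))

  # shifting target and all references of every sample by a constant
  # leaves the fold unchanged
  tr3 <- tr2
  tr3$ct <- tr3$ct + 1.7
  expect_equal(delta_delta_ct(tr3, ct2)$fold,
               delta_delta_ct(tr2, ct2)$fold)

  # missing reference gene is a data error
  broken <- ctrl[ctrl$gene != "PPIA", ]
  expect_error(delta_delta_ct(tr2, broken, ref_genes = names(refs)),
               "missing reference gene")
})

test_that("baseline fold changes are ratios of replicate means", {
  df <- as_timecourse(data.frame(
    condition = rep(c("a", "b"), each = 2), dox_ng_ml = 0,
    replicate = c("R1", "R2", "R1", "R2"), compartment = "intracellular",
    species = "C4", time_min = 0, conc_nmol_per_g = c(2, 4, 1, 1),
    below_loq = FALSE))
  expect_equal(baseline_fold_change(df, "C4", "a", "b")$fold, 3)
  expect_equal(baseline_fold_change(df, "C4", "a", "a")$fold, 1)
  expect_equal(baseline_fold_change(df, "C4", "a", "b")$fold *
                 baseline_fold_change(df, "C4", "b", "a")$fold, 1)
  expect_error(baseline_fold_change(df, "C4", "a", "zz"), "no records")
})

test_that("acyl ratios are replicate-paired", {
  df <- as_timecourse(data.frame(
    condition = "a", dox_ng_ml = 0,
    replicate = rep(c("R1", "R2"), 2), compartment = "intracellular",
    species = rep(c("C3", "C4"), each = 2), time_min = 0,
    conc_nmol_per_g = c(1, 1, 2, 4), below_loq = FALSE))
  r <- acyl_ratio(df, condition = "a")
  expect_equal(unname(r$ratios), c(0.5, 0.25))
  same <- df
  same$conc_nmol_per_g <- c(2, 4, 2, 4)
  expect_equal(unname(acyl_ratio(as_timecourse(same),
                                 condition = "a")$ratios), c(1, 1))
})

test_that("per-time-point t-tests match hand computation", {
  mk <- function(cond, values, tt) data.frame(
    condition = cond, dox_ng_ml = 0,
    replicate = paste0("R", seq_along(values)),
    compartment = "intracellular", species = "C4", time_min = tt,
    conc_nmol_per_g = values, below_loq = FALSE)
  df <- as_timecourse(rbind(mk("a", 1:4, 0), mk("b", 11:14, 0),
                            mk("a", 1:4, 7), mk("b", 1:4 + 0.5, 7)))
  res <- timepoint_tests(df, "C4", "a", "b")
  # pooled-variance t by hand: diff -10, s2p = 5/3, se = sqrt(2*s2p/4)
  t_hand <- -10 / sqrt(2 * (5 / 3) / 4)
  expect_equal(res$statistic[res$time_min == 0], t_hand, tolerance = 1e-10)
  expect_equal(res$p_value[res$time_min == 0],
               2 * pt(t_hand, df = 6), tolerance = 1e-12)
  expect_equal(res$star[res$time_min == 0], "**")

  # identical groups: t = 0, p = 1
  df2 <- as_timecourse(rbind(mk("a", 1:4, 0), mk("b", 1:4, 0)))
  res2 <- timepoint_tests(df2, "C4", "a", "b")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
})

test_that("exact Mann-Whitney enumeration matches known and reference p", {
  res <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                        "mann_whitney")
  # {1,2,3} vs {4,5,6}: only the two most extreme of the 20 assignments
  expect_equal(res$p_value, 0.1)

  # cross-check against the reference implementation on random data
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(5)
    y <- rnorm(6) + 0.5
    p_pkg <- compare_groups(c(x, y), rep(c("a", "b"), c(5, 6)),
                            "mann_whitney")$p_value
    p_ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }

  # two-sided symmetry under label swap
  set.seed(1)
  v <- rnorm(10)
  g <- rep(c("a", "b"), 5)
  expect_equal(compare_groups(v, g, "mann_whitney")$p_value,
               compare_groups(v, ifelse(g == "a", "b", "a"),
                              "mann_whitney")$p_value)
})

test_that("normal approximation tracks the exact Mann-Whitney p", {
  for (s in 1:15) {
    set.seed(s + 100)
    x <- rnorm(10)
    y <- rnorm(10) + runif(1, -1, 1)
    p_exact <- faoflux:::mann_whitney_exact(x, y)$p_value
    p_norm <- faoflux:::mann_whitney_normal(x, y)$p_value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("Kruskal-Wallis/Dunn handles identical and degenerate groups", {
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- compare_groups(v, g, "kruskal_dunn")
  expect_equal(res$p_value, 1)
  expect_true(all(res$posthoc$p_value == 1))

  expect_warning(res0 <- compare_groups(rep(5, 9), g, "kruskal_dunn"),
                 "degenerate")
  expect_equal(res0$p_value, 1)

  # omnibus agrees with the reference implementation on real structure
  set.seed(3)
  v2 <- c(rnorm(5), rnorm(5) + 2, rnorm(5))
  g2 <- rep(c("a", "b", "c"), each = 5)
  res2 <- compare_groups(v2, g2, "kruskal_dunn")
  expect_equal(res2$p_value, kruskal.test(v2, factor(g2))$p.value)
  expect_true(any(res2$posthoc$p_value < 0.05))
})

test_that("one-sample t against unity handles constant fold changes", {
  expect_warning(res <- compare_groups(c(1, 1, 1, 1), method = "one_sample_t"),
                 "degenerate")
  expect_equal(res$p_value, 1)
  set.seed(5)
  v <- 2^rnorm(8, 1, 0.2)
  res2 <- compare_groups(v, method = "one_sample_t", mu = 1)
  expect_equal(res2$p_value, t.test(v, mu = 1)$p.value)
})

test_that("two-way ANOVA layer reports condition effect and contrasts", {
  set.seed(7)
  df <- expand.grid(rep = 1:4, g = c("ctrl", "kd"), t = c(0, 7, 14))
  y <- ifelse(df$g == "kd" & df$t > 0, 3, 0) + rnorm(nrow(df), 0, 0.5)
  res <- compare_groups(y, df$g, "two_way_anova_bonferroni", time = df$t)
  expect_lt(res$p_value, 0.01)
  ph <- res$posthoc
  expect_true(all(ph$p_value[ph$time != "0"] < 0.05))
  expect_gt(ph$p_value[ph$time == "0"], 0.05)
})
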