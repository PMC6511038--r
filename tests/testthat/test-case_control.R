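test_that("the group model without covariates is exactly the pooled two-sample t-test", {
  set.seed(21)
  y <- rnorm(40) + rep(c(0.8, 0), each = 20)
  grp <- rep(c("case", "control"), each = 20)
  fit <- fit_group_model(y, grp)
  tt <- t.test(y[grp == "case"], y[grp == "control"], var.equal = TRUE)
  expect_equal(fit$t_stat, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-8)
  expect_equal(fit$df, unname(tt$parameter))
  # Hedge's g: direct standardized-mean-difference oracle with exact J(df)
  sp <- sqrt(((20 - 1) * var(y[grp == "case"]) +
                (20 - 1) * var(y[grp == "control"])) / 38)
  d <- (mean(y[grp == "case"]) - mean(y[grp == "control"])) / sp
  J <- gamma(19) / (sqrt(19) * gamma(18.5))
  expect_equal(fit$hedges_g, d * J, tolerance = 1e-8)
  expect_equal(sign(fit$t_stat), sign(fit$hedges_g))
})

test_that("the covariate-adjusted model matches lm() coefficient inference", {
  set.seed(22)
  n <- 60
  grp <- rep(c("case", "control"), each = n / 2)
  age <- runif(n, 20, 60)
  sex <- sample(c("M", "F"), n, TRUE)
  y <- 0.5 * (grp == "case") + 0.03 * age + 0.4 * (sex == "F") + rnorm(n)
  fit <- fit_group_model(y, grp, age, sex)
  age_c <- age - mean(age)
  ref <- summary(lm(y ~ I(grp == "case") + age_c + I(sex == "F") +
                      I(age_c * (sex == "F"))))$coefficients
  expect_equal(fit$t_stat, ref[2, "t value"], tolerance = 1e-8)
  expect_equal(fit$p_value, ref[2, "Pr(>|t|)"], tolerance = 1e-8)
})

test_that("age confounding is removed by adjustment", {
  set.seed(23)
  n <- 100
  grp <- rep(c("case", "control"), each = n / 2)
  age <- c(runif(n / 2, 40, 60), runif(n / 2, 20, 40))  # cases older
  sex <- sample(c("M", "F"), n, TRUE)
  y <- 0.1 * age + rnorm(n, sd = 0.5)  # effect only via age
  unadj <- fit_group_model(y, grp)
  adj <- fit_group_model(y, grp, age, sex)
  expect_gt(abs(unadj$t_stat), 5)
  expect_lt(abs(adj$t_stat), 2.5)
})

test_that("the group model rejects degenerate designs", {
  y <- rnorm(10)
  expect_error(fit_group_model(y, rep(c("case", "control"), c(2, 8))),
               "at least 3")
  grp <- rep(c("case", "control"), each = 5)
  expect_error(fit_group_model(y, grp, age = rep(1, 10), sex = NULL),
               "rank-deficient")
})

test_that("Fisher's method matches its chi-square closed form", {
  f <- combine_fisher(c(1, 1, 1))
  expect_equal(f$chi2, 0)
  expect_equal(f$p, 1)
  f2 <- combine_fisher(c(0.5, 0.5, 0.5))
  expect_equal(f2$chi2, 4.158883, tolerance = 1e-6)
  expect_equal(f2$p, 0.655185, tolerance = 1e-6)
  expect_equal(f2$df, 6)
  f3 <- combine_fisher(c(0.01, 0.02, 0.03))
  expect_equal(f3$chi2, 24.0475, tolerance = 1e-4)
  expect_equal(f3$p, 5.118543e-4, tolerance = 1e-6)
  expect_error(combine_fisher(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(combine_fisher(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("combining concordant evidence amplifies it", {
  # accumulation holds below the chi-square crossover (~0.3 for k = 3);
  # above it, combining several weak p-values is rightly less extreme
  for (p in c(0.2, 0.1, 0.01, 1e-4))
    expect_lt(combine_fisher(rep(p, 3))$p, p)
  expect_gt(combine_fisher(rep(0.9, 3))$p, 0.9)
})

test_that("BH flags match exhaustive step-up enumeration", {
  expect_false(any(fdr_bh(rep(1, 5))))
  expect_equal(fdr_bh(c(0.001, 0.02, 0.9), q = 0.05),
               brute_force_bh(c(0.001, 0.02, 0.9), 0.05))
  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(3:10, 1))^sample(1:3, 1)
    flags <- fdr_bh(p, q = 0.05)
    expect_identical(flags, brute_force_bh(p, 0.05))
    # monotone: no flagged p above an unflagged smaller p
    if (any(flags) && any(!flags))
      expect_lt(max(p[flags]), min(p[!flags]) + 1e-15)
  }
  expect_error(fdr_bh(c(0.5), q = 0), "\\(0, 1\\)")
})

test_that("KS comparison matches an exhaustive ECDF-gap brute force", {
  same <- rnorm(10)
  res <- compare_strength_distributions(same, same)
  expect_equal(res$D, 0)
  expect_equal(res$p, 1)
  res2 <- compare_strength_distributions(1:5, 11:15)
  expect_equal(res2$D, 1)
  x <- c(0.1, 0.4, 0.42, 0.9, 1.3)
  y <- c(0.2, 0.43, 0.8, 1.1, 2.0)
  grid <- sort(c(x, y))
  d_brute <- max(abs(vapply(grid, function(g)
    mean(x <= g) - mean(y <= g), numeric(1))))
  expect_equal(compare_strength_distributions(x, y)$D, d_brute,
               tolerance = 1e-12)
  expect_error(compare_strength_distributions(1, 1:3), "at least 2")
})

test_that("hub vulnerability recovers exact anticorrelation and calibrates under the null", {
  s <- setNames(seq(-0.2, 0.6, length.out = 30), paste0("r", 1:30))
  hv <- hub_vulnerability(s, -s, n_perm = 199, seed = 1)
  expect_equal(hv$r, -1)
  expect_equal(hv$p_perm, 1 / 200)
  expect_error(hub_vulnerability(s, setNames(s, paste0("q", 1:30))),
               "identical region sets")
  # independent maps: p should not pile up near zero
  set.seed(41)
  ps <- vapply(1:60, function(i) {
    a <- setNames(rnorm(25), paste0("r", 1:25))
    b <- setNames(rnorm(25), paste0("r", 1:25))
    hub_vulnerability(a, b, n_perm = 99, seed = i)$p_perm
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  # surrogate-map hook bypasses naive permutation
  surr <- matrix(rnorm(30 * 50), 30, 50, dimnames = list(names(s), NULL))
  hv2 <- hub_vulnerability(s, -s, surrogates = surr)
  expect_equal(hv2$p_perm, 1 / 51)
})

test_that("a hub-targeted effect produces a negative hub-vulnerability correlation", {
  # effect planted in the highest-strength regions of a compact atlas:
  # strongly connected regions should lose the most similarity in cases
  aff <- default_affected_regions(60, 10)
  sets <- lapply(1:2, function(i)
    compute_msn_set(generate_cohort(cohort_spec(
      n_cases = 30, n_controls = 30, n_regions = 60,
      affected_regions = aff, effect_size = 1.5,
      study_id = paste0("s", i), seed = 1100 + i))))
  cc <- casecontrol_msn(sets)
  hv <- hub_vulnerability(cc$control_strength,
                          setNames(cc$combined$mean_t,
                                   cc$combined$region_id),
                          n_perm = 999, seed = 12)
  expect_lt(hv$r, -0.3)
  expect_lt(hv$p_perm, 0.05)
})

test_that("multi-study combination detects a planted effect consistently", {
  aff <- default_affected_regions(30, 5)
  sets <- lapply(1:3, function(i)
    compute_msn_set(generate_cohort(cohort_spec(
      n_cases = 25, n_controls = 25, n_regions = 30,
      affected_regions = aff, effect_size = 1.5,
      study_id = paste0("s", i), seed = 700 + i))))
  cc <- casecontrol_msn(sets)
  expect_s3_class(cc, "msn_casecontrol")
  expect_equal(nrow(cc$combined), 30)
  expect_equal(nrow(cc$per_study), 90)
  # combined detection should cover most affected regions
  expect_gte(sum(cc$combined$fdr_significant[aff]), 3)
  expect_true(all(cc$combined$fisher_chi2 >= 0))
  expect_true(all(cc$combined$combined_p > 0 & cc$combined$combined_p <= 1))
  expect_output(print(cc), "Case-control MSN analysis")
  expect_output(print(summary(cc)), "FDR-significant")
})

test_that("class aggregation reduces to the global test for one all-covering class", {
  ms <- compute_msn_set(small_cohort(seed = 8, n_regions = 12,
                                     n_cases = 10, n_controls = 10))
  labels <- setNames(rep("all", 12), colnames(ms$strengths))
  res <- class_aggregation_test(ms, labels)
  ref <- fit_group_model(rowMeans(ms$strengths), ms$subjects$group,
                         ms$subjects$age, ms$subjects$sex)
  expect_equal(res$mean_t, ref$t_stat, tolerance = 1e-10)
  expect_error(class_aggregation_test(ms, labels[-1]), "unlabeled")
})

test_that("class aggregation localizes a class-restricted effect", {
  hits <- 0; others <- 0
  for (s in 1:4) {
    sp <- cohort_spec(n_cases = 30, n_controls = 30, n_regions = 40,
                      effect_size = 1.5, seed = 900 + s)
    tab <- generate_cohort(sp)
    ms <- compute_msn_set(tab)
    labels <- setNames(
      ifelse(seq_len(40) %in% sp$affected_regions, "hit", "rest")[
        match(colnames(ms$strengths), unique(tab$region_id))],
      colnames(ms$strengths))
    res <- class_aggregation_test(ms, labels)
    hits <- hits + res$fdr_significant[res$class == "hit"]
    others <- others + (res$combined_p[res$class == "rest"] < 0.05)
  }
  expect_gte(hits, 3)
})

test_that("clinical correlations recover planted associations and respect FDR", {
  set.seed(51)
  summary_vec <- setNames(rnorm(40), paste0("s", 1:40))
  clin <- data.frame(self = summary_vec,
                     anti = -summary_vec + rnorm(40, sd = 0.3),
                     noise1 = rnorm(40), noise2 = rnorm(40))
  res <- clinical_correlation(summary_vec, clin)
  expect_equal(res$r[res$measure == "self"], 1)
  expect_lt(res$r[res$measure == "anti"], -0.8)
  expect_equal(res$r[res$measure == "anti"],
               cor(summary_vec, clin$anti), tolerance = 1e-12)
  expect_true(all(res$fdr_significant[res$measure %in% c("self", "anti")]))
  clin$sparse <- c(1, 2, 3, rep(NA, 37))
  expect_error(clinical_correlation(summary_vec, clin), "fewer than 4")
  clin$sparse <- NULL
  clin$empty <- NA_real_
  expect_error(clinical_correlation(summary_vec, clin), "no complete pairs")
})
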