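# Case-control inference on MSN strength: covariate-adjusted linear models
# per study, Fisher's-method combination across studies, BH-FDR over
# regions, hub-vulnerability correlation, class aggregation, and clinical
# correlations.

# Vectorized OLS of many response columns on the shared design
# 1 + group + age + sex + age:sex. Returns per-column group t, Hedge's g,
# two-sided p, and residuals. The design matrix is identical across
# responses, so a single QR decomposition serves all of them.
.group_model_fit <- function(Y, group, age = NULL, sex = NULL) {
  Y <- as.matrix(Y)
  g <- as.numeric(group == "case")
  n1 <- sum(g == 1); n0 <- sum(g == 0)
  if (n1 < 3 || n0 < 3)
    stop("each group needs at least 3 subjects", call. = FALSE)
  X <- cbind(intercept = 1, group = g)
  if (!is.null(age)) {
    age_c <- age - mean(age)
    X <- cbind(X, age = age_c)
  }
  if (!is.null(sex)) {
    s <- as.numeric(sex == "F")
    X <- cbind(X, sex = s)
  }
  if (!is.null(age) && !is.null(sex)) X <- cbind(X, age_sex = age_c * s)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design matrix (collinear covariates)", call. = FALSE)
  coefs <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtxinv_gg <- chol2inv(qr.R(qx))[2, 2]
  se <- sqrt(sigma2 * xtxinv_gg)
  tval <- coefs["group", ] / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  # exact small-sample (Hedges) correction factor
  J <- exp(lgamma(df / 2) - log(sqrt(df / 2)) - lgamma((df - 1) / 2))
  gval <- tval * sqrt(1 / n1 + 1 / n0) * J
  list(t = tval, hedges_g = gval, p = pval, df = df,
       n_case = n1, n_control = n0, residuals = res)
}

#' Covariate-adjusted case-control model for one regional measure
#'
#' Ordinary least squares of a per-subject scalar on group, age, sex and
#' the age-by-sex interaction. The reported t statistic is for the group
#' coefficient (positive means higher values in cases); Hedge's g is
#' derived from it by the standard t-to-g conversion with the exact
#' small-sample bias correction.
#'
#' @param values per-subject numeric vector.
#' @param group character/factor with levels \code{"case"} and
#'   \code{"control"}.
#' @param age numeric, years; \code{NULL} drops the age terms.
#' @param sex character/factor with levels \code{"M"} and \code{"F"};
#'   \code{NULL} drops the sex terms. With both covariates \code{NULL} the
#'   model is the pooled-variance two-sample t-test.
#' @return list with \code{t_stat}, \code{hedges_g}, \code{p_value},
#'   \code{df}, \code{n_case}, \code{n_control}.
#' @examples
#' set.seed(1)
#' n <- 40
#' grp <- rep(c("case", "control"), each = n)
#' fit_group_model(rnorm(2 * n) + 0.5 * (grp == "case"), grp,
#'                 age = runif(2 * n, 20, 60),
#'                 sex = sample(c("M", "F"), 2 * n, TRUE))
#' @export
fit_group_model <- function(values, group, age = NULL, sex = NULL) {
  fit <- .group_model_fit(matrix(values, ncol = 1), group, age, sex)
  list(t_stat = unname(fit$t), hedges_g = unname(fit$hedges_g),
       p_value = unname(fit$p), df = fit$df,
       n_case = fit$n_case, n_control = fit$n_control)
}

#' Combine independent p-values by Fisher's method
#'
#' \eqn{\chi^2 = -2 \sum \log p_i} referred to a chi-square distribution
#' with \eqn{2k} degrees of freedom.
#'
#' @param p_values numeric vector of per-study p-values in (0, 1].
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @examples
#' combine_fisher(c(0.5, 0.5, 0.5))
#' @export
combine_fisher <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1) || anyNA(p_values))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  chi2 <- -2 * sum(log(p_values))
  k <- length(p_values)
  list(chi2 = chi2, df = 2 * k,
       p = pchisq(chi2, df = 2 * k, lower.tail = FALSE))
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false discovery rate control at level \code{q} over a family of
#' tests.
#'
#' @param p_values numeric vector in (0, 1].
#' @param q FDR level (default 0.05).
#' @return logical vector of discovery flags.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(q) != 1 || is.na(q) || q <= 0 || q >= 1)
    stop("`q` must be a single value in (0, 1)", call. = FALSE)
  if (any(p_values <= 0 | p_values > 1) || anyNA(p_values))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH") <= q
}

#' Compare case and control strength distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the per-region distributions of
#' (residualized) mean strength in cases versus controls.
#'
#' @param case_map,control_map named numeric vectors of per-region values.
#' @return list with \code{D} and \code{p}.
#' @export
compare_strength_distributions <- function(case_map, control_map) {
  if (length(case_map) < 2 || length(control_map) < 2)
    stop("each map needs at least 2 regions", call. = FALSE)
  kt <- suppressWarnings(ks.test(case_map, control_map))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Residualized group strength maps
#'
#' Regresses age, sex and age-by-sex out of each region's per-subject
#' strengths (per study), then averages the residuals within each group,
#' pooling across studies. The resulting per-region case and control maps
#' are what the distributional comparison operates on.
#'
#' @param msn_sets a single \code{msn_set} or a list of them (one per
#'   study).
#' @return list with named vectors \code{case} and \code{control}.
#' @export
residualized_strength_maps <- function(msn_sets) {
  sets <- if (inherits(msn_sets, "msn_set")) list(msn_sets) else msn_sets
  res_list <- lapply(sets, function(s) {
    sub <- s$subjects
    g <- as.numeric(sub$group == "case")
    sx <- as.numeric(sub$sex == "F")
    age_c <- sub$age - mean(sub$age)
    X <- cbind(1, age_c, sx, age_c * sx)
    r <- qr.resid(qr(X), s$strengths)
    # keep the group effect: residualize covariates only, then re-split
    list(res = r, group = sub$group)
  })
  regions <- colnames(sets[[1]]$strengths)
  case_rows <- do.call(rbind, lapply(res_list, function(x)
    x$res[x$group == "case", regions, drop = FALSE]))
  ctrl_rows <- do.call(rbind, lapply(res_list, function(x)
    x$res[x$group == "control", regions, drop = FALSE]))
  list(case = colMeans(case_rows), control = colMeans(ctrl_rows))
}

#' Multi-study case-control analysis of regional MSN strength
#'
#' For each study, fits the covariate-adjusted group model at every region
#' of the strength matrix; combines the per-region p-values across studies
#' with Fisher's method; and thresholds the combined p-values with
#' Benjamini-Hochberg FDR. Also fits the same model to each subject's
#' global mean similarity.
#'
#' @param msn_sets a single \code{\link{compute_msn_set}} result or a list
#'   of them, one per study (all on the same region set).
#' @param q FDR level over regions (default 0.05).
#' @return object of class \code{msn_casecontrol}: \code{per_study} (long
#'   data.frame: study_id, region_id, t_stat, hedges_g, p_value, df),
#'   \code{combined} (region_id, mean_t, fisher_chi2, combined_p,
#'   fdr_significant), \code{global} (per-study model of global
#'   similarity), \code{q}, \code{control_strength} (mean control map
#'   pooled over studies).
#' @export
casecontrol_msn <- function(msn_sets, q = 0.05) {
  sets <- if (inherits(msn_sets, "msn_set")) list(msn_sets) else msn_sets
  regions <- colnames(sets[[1]]$strengths)
  for (s in sets)
    if (!identical(colnames(s$strengths), regions))
      stop("all studies must share the same region set", call. = FALSE)
  per_study <- list()
  global <- list()
  tmat <- matrix(NA_real_, length(regions), length(sets),
                 dimnames = list(regions, NULL))
  pmat <- tmat
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    sub <- s$subjects
    study <- unique(sub$study_id)[1]
    fit <- .group_model_fit(s$strengths, sub$group, sub$age, sub$sex)
    per_study[[i]] <- data.frame(
      study_id = study, region_id = regions,
      t_stat = unname(fit$t), hedges_g = unname(fit$hedges_g),
      p_value = unname(fit$p), df = fit$df, stringsAsFactors = FALSE)
    tmat[, i] <- fit$t
    pmat[, i] <- fit$p
    gfit <- fit_group_model(s$global, sub$group, sub$age, sub$sex)
    global[[i]] <- data.frame(study_id = study, t_stat = gfit$t_stat,
                              hedges_g = gfit$hedges_g,
                              p_value = gfit$p_value, df = gfit$df,
                              stringsAsFactors = FALSE)
  }
  pmat <- pmax(pmat, .Machine$double.xmin)  # guard against underflow to 0
  fisher <- apply(pmat, 1, function(p) {
    f <- combine_fisher(p)
    c(f$chi2, f$p)
  })
  combined <- data.frame(
    region_id = regions,
    mean_t = rowMeans(tmat),
    fisher_chi2 = fisher[1, ],
    combined_p = fisher[2, ],
    stringsAsFactors = FALSE)
  combined$fdr_significant <- fdr_bh(combined$combined_p, q = q)
  ctrl <- Reduce(`+`, lapply(sets, mean_strength_map, group = "control")) /
    length(sets)
  structure(list(per_study = do.call(rbind, per_study),
                 combined = combined,
                 global = do.call(rbind, global),
                 q = q, control_strength = ctrl,
                 n_studies = length(sets)),
            class = "msn_casecontrol")
}

#' @export
print.msn_casecontrol <- function(x, ...) {
  cat(sprintf("Case-control MSN analysis: %d stud%s, %d regions\n",
              x$n_studies, if (x$n_studies == 1) "y" else "ies",
              nrow(x$combined)))
  cat("global similarity (case - control):\n")
  print(transform(x$global, t_stat = round(t_stat, 3),
                  hedges_g = round(hedges_g, 3),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  nsig <- sum(x$combined$fdr_significant)
  cat(sprintf("regions FDR-significant at q = %.2g (Fisher-combined): %d\n",
              x$q, nsig))
  invisible(x)
}

#' @export
summary.msn_casecontrol <- function(object, ...) {
  sig <- object$combined[object$combined$fdr_significant, ]
  sig <- sig[order(sig$combined_p), ]
  structure(list(combined_top = head(sig, 20),
                 n_significant = nrow(sig),
                 q = object$q,
                 global = object$global),
            class = "summary.msn_casecontrol")
}

#' @export
print.summary.msn_casecontrol <- function(x, ...) {
  cat(sprintf("%d FDR-significant regions at q = %.2g\n", x$n_significant, x$q))
  if (x$n_significant > 0) {
    cat("top regions by combined p:\n")
    print(transform(x$combined_top, mean_t = round(mean_t, 3),
                    fisher_chi2 = round(fisher_chi2, 2),
                    combined_p = signif(combined_p, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.msn_casecontrol <- function(x, ...) {
  ctrl <- x$control_strength[x$combined$region_id]
  plot(ctrl, x$combined$mean_t,
       xlab = "mean control strength",
       ylab = "mean case-control t",
       pch = ifelse(x$combined$fdr_significant, 19, 1),
       col = ifelse(x$combined$fdr_significant, "firebrick", "grey40"), ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Hub-vulnerability correlation
#'
#' Pearson correlation between the control-group mean strength map and the
#' mean case-control t map, with a permutation p-value obtained by
#' shuffling region labels. A negative correlation means the most strongly
#' connected regions in controls show the largest similarity loss in
#' cases. The naive label permutation ignores spatial autocorrelation; a
#' matrix of user-supplied surrogate maps (columns = surrogates of
#' \code{mean_t}) can be passed via \code{surrogates} to use a
#' spatially-informed null instead.
#'
#' @param control_strength named per-region control strength map.
#' @param mean_t named per-region mean case-control t map (same regions).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param surrogates optional matrix of null t-maps (regions x surrogates)
#'   used in place of label permutation.
#' @return list with \code{r} and \code{p_perm} (two-sided, add-one
#'   convention).
#' @export
hub_vulnerability <- function(control_strength, mean_t, n_perm = 10000,
                              seed = 1L, surrogates = NULL) {
  if (!identical(sort(names(control_strength)), sort(names(mean_t))))
    stop("maps must cover identical region sets", call. = FALSE)
  mean_t <- mean_t[names(control_strength)]
  r_obs <- cor(control_strength, mean_t)
  if (is.null(surrogates)) {
    r_null <- with_seed(seed, replicate(n_perm,
      cor(control_strength, sample(mean_t))))
  } else {
    surrogates <- surrogates[names(control_strength), , drop = FALSE]
    r_null <- as.numeric(cor(control_strength, surrogates))
    n_perm <- length(r_null)
  }
  list(r = r_obs,
       p_perm = perm_pvalue(sum(abs(r_null) >= abs(r_obs)), n_perm))
}

#' Case-control test of class-aggregated strength
#'
#' Averages each subject's regional strengths within each region class
#' (e.g., cytoarchitectonic classes or functional networks), fits the
#' covariate-adjusted group model per class and study, combines p-values
#' across studies by Fisher's method when several studies are supplied,
#' and controls FDR across classes.
#'
#' @param msn_sets a single \code{msn_set} or list of them.
#' @param class_labels named character vector mapping region_id to class
#'   label; every region in the strength matrices must be labeled.
#' @param q FDR level across classes.
#' @return data.frame: class, n_regions, mean_t, combined_p,
#'   fdr_significant, plus per-study t columns.
#' @export
class_aggregation_test <- function(msn_sets, class_labels, q = 0.05) {
  sets <- if (inherits(msn_sets, "msn_set")) list(msn_sets) else msn_sets
  regions <- colnames(sets[[1]]$strengths)
  if (!all(regions %in% names(class_labels)))
    stop("unlabeled region(s): ",
         paste(head(setdiff(regions, names(class_labels)), 3), collapse = ", "),
         call. = FALSE)
  cls <- class_labels[regions]
  classes <- sort(unique(cls))
  counts <- table(cls)
  if (any(counts < 2))
    stop("every class needs at least 2 regions", call. = FALSE)
  tmat <- matrix(NA_real_, length(classes), length(sets),
                 dimnames = list(classes, NULL))
  pmat <- tmat
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    agg <- sapply(classes, function(cl)
      rowMeans(s$strengths[, cls == cl, drop = FALSE]))
    fit <- .group_model_fit(agg, s$subjects$group, s$subjects$age,
                            s$subjects$sex)
    tmat[, i] <- fit$t
    pmat[, i] <- fit$p
  }
  combined_p <- if (length(sets) == 1) pmat[, 1] else
    apply(pmat, 1, function(p) combine_fisher(p)$p)
  out <- data.frame(class = classes,
                    n_regions = as.integer(counts[classes]),
                    mean_t = rowMeans(tmat),
                    combined_p = combined_p,
                    fdr_significant = fdr_bh(combined_p, q = q),
                    stringsAsFactors = FALSE)
  tcols <- as.data.frame(tmat)
  names(tcols) <- paste0("t_study", seq_along(sets))
  rownames(out) <- NULL
  cbind(out, tcols)
}

#' Correlate subject-level MSN summaries with clinical measures
#'
#' Pearson (or Spearman) correlation between a per-subject summary (e.g.,
#' mean strength over significant regions) and each clinical measure, with
#' pairwise deletion of missing values and BH-FDR across measures.
#'
#' @param subject_summary named per-subject numeric vector.
#' @param clinical_measures data.frame of per-subject measures (rows
#'   aligned with \code{subject_summary}; may contain NAs).
#' @param q FDR level across measures.
#' @param method correlation method, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @return data.frame: measure, n, r, p_value, fdr_significant.
#' @export
clinical_correlation <- function(subject_summary, clinical_measures,
                                 q = 0.05, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  out <- lapply(names(clinical_measures), function(m) {
    y <- clinical_measures[[m]]
    ok <- complete.cases(subject_summary, y)
    if (sum(ok) == 0)
      stop(sprintf("clinical measure '%s' has no complete pairs", m),
           call. = FALSE)
    if (sum(ok) < 4)
      stop(sprintf("clinical measure '%s' has fewer than 4 complete pairs", m),
           call. = FALSE)
    ct <- suppressWarnings(cor.test(subject_summary[ok], y[ok],
                                    method = method))
    data.frame(measure = m, n = sum(ok), r = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$fdr_significant <- fdr_bh(pmax(pmin(out$p_value, 1), .Machine$double.xmin),
                                q = q)
  out
}
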