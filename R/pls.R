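# Partial least squares linking a regional case-control t-map to regional
# gene expression: SIMPLS fit with deterministic orientation, permutation
# test of variance explained, bootstrap gene ranking, tail gene sets.

# SIMPLS (de Jong 1993) on column-standardized X and column-centered Y.
# Returns weights R (X %*% R = scores T, T orthonormal), loadings, and the
# per-component explained sum of squares of Y. Component 1 equals the
# dominant left singular vector of crossprod(X, Y), i.e., for a single
# response it is proportional to the predictor-response covariance vector.
.simpls <- function(Xs, Yc, A) {
  n <- nrow(Xs); p <- ncol(Xs); m <- ncol(Yc)
  R <- matrix(0, p, A); TT <- matrix(0, n, A)
  P <- matrix(0, p, A); Q <- matrix(0, m, A)
  V <- matrix(0, p, A)
  S <- crossprod(Xs, Yc)
  for (a in seq_len(A)) {
    sv <- svd(S, nu = 1, nv = 0)
    r <- sv$u[, 1]
    t_ <- Xs %*% r
    normt <- sqrt(sum(t_^2))
    if (normt < .Machine$double.eps^0.5)
      stop("degenerate component: X has rank below n_components", call. = FALSE)
    t_ <- t_ / normt
    r <- r / normt
    p_ <- crossprod(Xs, t_)
    q_ <- crossprod(Yc, t_)
    v <- p_
    if (a > 1) {
      v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], p_)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; TT[, a] <- t_; P[, a] <- p_; Q[, a] <- q_; V[, a] <- v
  }
  # T orthonormal => SS of Y explained by component a is sum(Q[, a]^2)
  list(R = R, T = TT, P = P, Q = Q, ss_expl = colSums(Q^2))
}

.standardize_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  if (any(sdv == 0))
    stop("zero-variance predictor column(s): ",
         paste(head(colnames(X)[sdv == 0], 3), collapse = ", "), call. = FALSE)
  list(X = sweep(sweep(X, 2, mu), 2, sdv, "/"), mu = mu, sd = sdv)
}

.align_xy <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of regions", call. = FALSE)
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    if (!setequal(rownames(X), rownames(Y)))
      stop("X and Y region sets differ", call. = FALSE)
    Y <- Y[rownames(X), , drop = FALSE]
  }
  list(X = X, Y = Y)
}

#' Fit a PLS model of a regional map on gene expression
#'
#' Partial least squares regression using gene expression (predictors,
#' z-scored per gene across regions) to predict one or more regional
#' case-control t-maps (responses, centered). The first component (PLS1)
#' is the weighted gene combination whose regional score map covaries most
#' strongly with the response maps. The sign indeterminacy of each
#' component is resolved deterministically: scores are flipped so that
#' they correlate positively with the mean response map (ties broken
#' toward a positive weight sum).
#'
#' @param X numeric matrix, regions (rows, named) by genes (columns,
#'   named).
#' @param Y numeric matrix or vector of per-region responses, rows aligned
#'   with \code{X} (a named vector or matrix with rownames is re-ordered
#'   to match).
#' @param n_components number of components to extract (default 2; only
#'   component 1 is interpreted downstream).
#' @return object of class \code{pls_map}: \code{weights} (genes x
#'   components; \code{X_std \%*\% weights = scores}), \code{scores}
#'   (regions x components, orthonormal columns), \code{y_loadings},
#'   \code{variance_explained} (per component, proportion of pooled
#'   response variance), \code{total_ss}, plus centering/scaling info.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(50 * 20), 50, 20,
#'             dimnames = list(sprintf("r%02d", 1:50), sprintf("g%02d", 1:20)))
#' y <- X[, 1] + rnorm(50, sd = 0.5)
#' fit <- fit_pls(X, y)
#' fit$variance_explained
#' @export
fit_pls <- function(X, Y, n_components = 2) {
  al <- .align_xy(X, Y)
  X <- al$X; Y <- al$Y
  if (nrow(X) < n_components + 3)
    stop("need at least n_components + 3 regions", call. = FALSE)
  std <- .standardize_cols(X)
  Ymu <- colMeans(Y)
  Yc <- sweep(Y, 2, Ymu)
  if (all(abs(Yc) < .Machine$double.eps^0.5))
    stop("response has zero variance", call. = FALSE)
  fit <- .simpls(std$X, Yc, n_components)
  ybar <- rowMeans(Yc)
  for (a in seq_len(n_components)) {
    s <- sum(fit$T[, a] * ybar)
    if (s == 0) s <- sum(fit$R[, a])
    if (s < 0) {
      fit$R[, a] <- -fit$R[, a]; fit$T[, a] <- -fit$T[, a]
      fit$P[, a] <- -fit$P[, a]; fit$Q[, a] <- -fit$Q[, a]
    }
  }
  total_ss <- sum(Yc^2)
  dimnames(fit$R) <- list(colnames(X), paste0("PLS", seq_len(n_components)))
  dimnames(fit$T) <- list(rownames(X), colnames(fit$R))
  structure(list(weights = fit$R, scores = fit$T,
                 x_loadings = fit$P, y_loadings = fit$Q,
                 variance_explained = fit$ss_expl / total_ss,
                 total_ss = total_ss,
                 x_center = std$mu, x_scale = std$sd, y_center = Ymu,
                 n_components = n_components,
                 genes = colnames(X), regions = rownames(X)),
            class = "pls_map")
}

#' @export
print.pls_map <- function(x, ...) {
  cat(sprintf("PLS model: %d regions, %d genes, %d components\n",
              length(x$regions), length(x$genes), x$n_components))
  ve <- round(100 * x$variance_explained, 1)
  cat("response variance explained (%):",
      paste(sprintf("%s=%.1f", colnames(x$weights), ve), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pls_map <- function(object, ...) {
  w1 <- object$weights[, 1]
  structure(list(variance_explained = object$variance_explained,
                 top_pos = head(sort(w1, decreasing = TRUE), 5),
                 top_neg = head(sort(w1), 5)),
            class = "summary.pls_map")
}

#' @export
print.summary.pls_map <- function(x, ...) {
  cat("variance explained per component:\n")
  print(round(x$variance_explained, 4))
  cat("strongest positive PLS1 weights:\n"); print(round(x$top_pos, 4))
  cat("strongest negative PLS1 weights:\n"); print(round(x$top_neg, 4))
  invisible(x)
}

#' @export
coef.pls_map <- function(object, component = 1, ...) {
  object$weights[, component]
}

#' @export
predict.pls_map <- function(object, newdata = NULL, ...) {
  Xs <- if (is.null(newdata)) NULL else {
    nd <- as.matrix(newdata)[, object$genes, drop = FALSE]
    sweep(sweep(nd, 2, object$x_center), 2, object$x_scale, "/")
  }
  TT <- if (is.null(Xs)) object$scores else Xs %*% object$weights
  sweep(TT %*% t(object$y_loadings), 2, object$y_center, "+")
}

#' @export
plot.pls_map <- function(x, y_map = NULL, ...) {
  s <- x$scores[, 1]
  if (is.null(y_map)) {
    plot(s, xlab = "region index", ylab = "PLS1 score", ...)
  } else {
    plot(s, y_map[x$regions], xlab = "PLS1 score",
         ylab = "regional response", ...)
    abline(lm_line <- stats::lm(y_map[x$regions] ~ s), lty = 2)
  }
  invisible(x)
}

#' Permutation test of PLS1 variance explained
#'
#' Re-fits the first component after jointly permuting the response rows
#' (all response columns move together, preserving their correlation) and
#' compares the observed variance explained to the permutation
#' distribution.
#'
#' @inheritParams fit_pls
#' @param n_perm number of permutations (default 1000, minimum 100).
#' @param seed RNG seed.
#' @return list with \code{observed} (PLS1 variance explained),
#'   \code{perm_p} (add-one convention), \code{null} (permutation values).
#' @export
permutation_test_variance <- function(X, Y, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("`n_perm` must be at least 100", call. = FALSE)
  al <- .align_xy(X, Y)
  X <- al$X; Y <- al$Y
  std <- .standardize_cols(X)
  Yc <- sweep(Y, 2, colMeans(Y))
  if (all(abs(Yc) < .Machine$double.eps^0.5))
    stop("response has zero variance", call. = FALSE)
  total_ss <- sum(Yc^2)
  obs <- .simpls(std$X, Yc, 1)$ss_expl / total_ss
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    Yp <- Yc[sample.int(nrow(Yc)), , drop = FALSE]
    .simpls(std$X, sweep(Yp, 2, colMeans(Yp)), 1)$ss_expl / sum(
      sweep(Yp, 2, colMeans(Yp))^2)
  }, numeric(1)))
  list(observed = unname(obs),
       perm_p = perm_pvalue(sum(null >= obs), n_perm),
       null = null)
}

#' Bootstrap standard errors and Z-scores for PLS1 gene weights
#'
#' Resamples the regions of the analysis matrix with replacement, refits
#' the first PLS component on each replicate (re-aligning its sign to the
#' original component so the indeterminate component orientation cannot
#' inflate the SE), and scores each gene by the ratio of its original
#' weight to its bootstrap SE. Genes are ranked by Z descending (rank 1 =
#' most positive Z).
#'
#' @inheritParams fit_pls
#' @param n_boot number of bootstrap replicates (default 1000, minimum
#'   100).
#' @param seed RNG seed.
#' @return data.frame of class \code{gene_table}: \code{gene_id},
#'   \code{pls1_weight}, \code{bootstrap_se}, \code{z_score}, \code{rank}.
#' @export
bootstrap_gene_weights <- function(X, Y, n_boot = 1000, seed = 1L) {
  if (n_boot < 100) stop("`n_boot` must be at least 100", call. = FALSE)
  al <- .align_xy(X, Y)
  X <- al$X; Y <- al$Y
  fit <- fit_pls(X, Y, n_components = 1)
  w0 <- fit$weights[, 1]
  n <- nrow(X)
  acc <- matrix(0, ncol(X), n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) > 4) break  # degenerate resample: redraw
      }
      Xb <- X[idx, , drop = FALSE]
      sdb <- apply(Xb, 2, sd)
      keep <- sdb > 0
      Yb <- Y[idx, , drop = FALSE]
      stdb <- sweep(sweep(Xb[, keep, drop = FALSE], 2,
                          colMeans(Xb[, keep, drop = FALSE])), 2,
                    sdb[keep], "/")
      Ycb <- sweep(Yb, 2, colMeans(Yb))
      wb <- numeric(ncol(X))
      wb[keep] <- .simpls(stdb, Ycb, 1)$R[, 1]
      if (sum(wb[keep] * w0[keep]) < 0) wb <- -wb  # sign-align to original
      acc[, b] <- wb
    }
  })
  se <- apply(acc, 1, sd)
  if (any(se == 0))
    stop("bootstrap SE of zero for some gene(s); increase n_boot", call. = FALSE)
  z <- w0 / se
  out <- data.frame(gene_id = colnames(X), pls1_weight = unname(w0),
                    bootstrap_se = se, z_score = unname(z),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$z_score, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Extract PLS+ / PLS- tail gene sets
#'
#' @param gene_table result of \code{\link{bootstrap_gene_weights}}.
#' @param z_threshold positive Z cutoff (default 3).
#' @return list with character vectors \code{pls_plus} (Z above threshold)
#'   and \code{pls_minus} (Z below minus threshold); always disjoint.
#' @export
select_gene_sets <- function(gene_table, z_threshold = 3) {
  if (z_threshold <= 0) stop("`z_threshold` must be positive", call. = FALSE)
  list(pls_plus = gene_table$gene_id[gene_table$z_score > z_threshold],
       pls_minus = gene_table$gene_id[gene_table$z_score < -z_threshold])
}

#' Correlate PLS1 regional scores with a regional map
#'
#' Pearson correlation between PLS1 scores and a study's regional t-map,
#' with a region-permutation p-value (two-sided, add-one convention).
#'
#' @param pls_scores named per-region PLS1 scores (e.g.
#'   \code{fit$scores[, 1]}).
#' @param t_map named per-region map on the same regions.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with \code{r} and \code{p_perm}.
#' @export
score_map_correlation <- function(pls_scores, t_map, n_perm = 10000,
                                  seed = 1L) {
  if (!setequal(names(pls_scores), names(t_map)))
    stop("score and map region sets differ", call. = FALSE)
  t_map <- t_map[names(pls_scores)]
  r_obs <- cor(pls_scores, t_map)
  r_null <- with_seed(seed,
    replicate(n_perm, cor(pls_scores, sample(t_map))))
  list(r = r_obs,
       p_perm = perm_pvalue(sum(abs(r_null) >= abs(r_obs)), n_perm))
}
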