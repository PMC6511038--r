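#' Z-score morphometric features within study
#'
#' Normalizes each (region, feature) value by the sample mean and SD of that
#' region-feature pair across the subjects of its study, so every feature
#' contributes on a comparable scale to the similarity computation. Studies
#' are normalized independently: scanner and protocol differences between
#' studies never leak across study boundaries. The alternative reading of
#' sample normalization — z-scoring each feature across regions within
#' subject — is available via \code{scope = "regions"}.
#'
#' @param table a long-format feature table (see
#'   \code{\link{generate_cohort}} for the column contract).
#' @param scope \code{"subjects"} (default): center and scale each
#'   region-feature pair across the study's subjects; \code{"regions"}:
#'   center and scale each subject-feature vector across regions.
#' @return the table with feature columns replaced by their z-scores.
#' @export
zscore_features <- function(table, scope = c("subjects", "regions")) {
  scope <- match.arg(scope)
  feats <- check_feature_table(table)
  out <- table
  if (scope == "subjects") {
    idx <- interaction(table$study_id, table$region_id, drop = TRUE)
    for (study in unique(table$study_id)) {
      n_sub <- length(unique(table$subject_id[table$study_id == study]))
      if (n_sub < 2)
        stop(sprintf("study '%s' has fewer than 2 subjects; cannot normalize",
                     study), call. = FALSE)
    }
    counts <- as.vector(table(idx))
    for (f in feats) {
      x <- table[[f]]
      m <- rowsum(x, idx) / counts
      ctr <- x - m[as.integer(idx)]
      ss <- rowsum(ctr^2, idx)
      s <- sqrt(ss / (counts - 1))
      if (any(s <= 0 | !is.finite(s))) {
        bad <- rownames(s)[which(s <= 0 | !is.finite(s))[1]]
        stop(sprintf(
          "feature '%s' is constant across subjects for study.region '%s'",
          f, bad), call. = FALSE)
      }
      out[[f]] <- ctr / s[as.integer(idx)]
    }
  } else {
    idx <- interaction(table$study_id, table$subject_id, drop = TRUE)
    counts <- as.vector(table(idx))
    for (f in feats) {
      x <- table[[f]]
      m <- rowsum(x, idx) / counts
      ctr <- x - m[as.integer(idx)]
      s <- sqrt(rowsum(ctr^2, idx) / (counts - 1))
      if (any(s <= 0 | !is.finite(s)))
        stop(sprintf("feature '%s' is constant across regions for a subject", f),
             call. = FALSE)
      out[[f]] <- ctr / s[as.integer(idx)]
    }
  }
  attr(out, "spec") <- attr(table, "spec")
  attr(out, "region_metadata") <- attr(table, "region_metadata")
  out
}

#' Build one subject's morphometric similarity matrix
#'
#' The morphometric similarity network of a subject is the matrix of
#' Pearson correlations between every pair of regions' z-scored feature
#' vectors. The diagonal (self-similarity) is uninformative and returned as
#' \code{NA}; all strength and global summaries exclude it.
#'
#' @param zscored_slice numeric matrix, regions (rows, named) by features,
#'   of one subject's z-scored values.
#' @param subject_id optional label stored as an attribute.
#' @return symmetric region-by-region matrix with \code{NA} diagonal,
#'   off-diagonal entries in [-1, 1].
#' @examples
#' m <- matrix(rnorm(28), 4, 7, dimnames = list(paste0("r", 1:4), NULL))
#' build_msn(m)
#' @export
build_msn <- function(zscored_slice, subject_id = NULL) {
  x <- as.matrix(zscored_slice)
  if (ncol(x) < 3)
    stop("at least 3 features are required to correlate regional profiles",
         call. = FALSE)
  if (anyNA(x)) stop("missing feature values", call. = FALSE)
  rsd <- apply(x, 1, sd)
  if (any(rsd == 0)) {
    bad <- rownames(x)[which(rsd == 0)[1]]
    stop(sprintf("region '%s' has a zero-variance feature vector; correlation undefined",
                 if (is.null(bad)) as.character(which(rsd == 0)[1]) else bad),
         call. = FALSE)
  }
  M <- cor(t(x))
  diag(M) <- NA_real_
  attr(M, "subject_id") <- subject_id
  M
}

#' Regional strength (weighted degree) of a similarity matrix
#'
#' The strength of region j is the mean of its similarities to all other
#' regions — the weighted degree of its node in the signed, weighted MSN.
#' When \code{region_subset} is given, both the regions reported and the
#' neighbors averaged over are restricted to the subset (e.g., left
#' intrahemispheric edges only).
#'
#' @param M similarity matrix from \code{\link{build_msn}}.
#' @param region_subset optional character vector of region ids (or integer
#'   indices) to restrict to.
#' @return named numeric vector of per-region strengths in [-1, 1].
#' @export
regional_strength <- function(M, region_subset = NULL) {
  if (!is.null(region_subset)) {
    if (length(region_subset) < 2)
      stop("`region_subset` must contain at least 2 regions", call. = FALSE)
    M <- M[region_subset, region_subset, drop = FALSE]
  }
  rowMeans(M, na.rm = TRUE)
}

#' Global mean morphometric similarity
#'
#' The mean of all off-diagonal entries of a subject's similarity matrix;
#' equals the mean of the subject's regional strengths.
#'
#' @inheritParams regional_strength
#' @return scalar.
#' @export
global_mean <- function(M, region_subset = NULL) {
  mean(regional_strength(M, region_subset))
}

#' Compute per-subject MSNs and strength maps for a study
#'
#' Runs the full similarity stage for one study: z-scores the feature
#' table, builds each subject's similarity matrix, and collects regional
#' strengths and global means together with the subject covariates needed
#' downstream.
#'
#' @param table a long-format feature table for one or more studies (each
#'   study is normalized independently; all are returned in one set).
#' @param region_subset optional region ids defining an intrahemispheric
#'   restriction (see \code{\link{regional_strength}}).
#' @param scope normalization scope, passed to \code{\link{zscore_features}}.
#' @param keep_matrices if \code{TRUE}, the per-subject matrices are kept in
#'   the result (memory-heavy for large cohorts).
#' @return an object of class \code{msn_set}: list with \code{strengths}
#'   (subjects x regions matrix), \code{global} (per-subject mean
#'   similarity), \code{subjects} (data.frame of study_id, subject_id,
#'   group, age, sex), \code{regions}, and optionally \code{matrices}.
#' @export
compute_msn_set <- function(table, region_subset = NULL,
                            scope = c("subjects", "regions"),
                            keep_matrices = FALSE) {
  scope <- match.arg(scope)
  feats <- check_feature_table(table)
  z <- zscore_features(table, scope = scope)
  subj_rows <- !duplicated(z$subject_id)
  subjects <- z[subj_rows, .meta_cols[.meta_cols != "region_id"]]
  rownames(subjects) <- NULL
  regions <- unique(z$region_id)
  use_regions <- if (is.null(region_subset)) regions else {
    if (!all(region_subset %in% regions))
      stop("`region_subset` contains unknown region ids", call. = FALSE)
    region_subset
  }
  ord <- order(match(z$subject_id, subjects$subject_id),
               match(z$region_id, regions))
  z <- z[ord, ]
  nr <- length(regions)
  ns <- nrow(subjects)
  fmat <- as.matrix(z[, feats])
  strengths <- matrix(NA_real_, ns, length(use_regions),
                      dimnames = list(subjects$subject_id, use_regions))
  globals <- numeric(ns)
  matrices <- if (keep_matrices) vector("list", ns) else NULL
  sub_idx <- match(use_regions, regions)
  for (i in seq_len(ns)) {
    slice <- fmat[((i - 1) * nr + 1):(i * nr), , drop = FALSE]
    rownames(slice) <- regions
    M <- build_msn(slice[sub_idx, , drop = FALSE],
                   subject_id = subjects$subject_id[i])
    strengths[i, ] <- regional_strength(M)
    globals[i] <- global_mean(M)
    if (keep_matrices) matrices[[i]] <- M
  }
  structure(list(strengths = strengths, global = globals,
                 subjects = subjects, regions = use_regions,
                 matrices = matrices, scope = scope),
            class = "msn_set")
}

#' @export
print.msn_set <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("MSN set: %d subjects (%s), %d regions\n",
              nrow(x$subjects),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              length(x$regions)))
  cat(sprintf("  studies: %s\n",
              paste(unique(x$subjects$study_id), collapse = ", ")))
  cat(sprintf("  global similarity: mean %.4f (range %.4f..%.4f)\n",
              mean(x$global), min(x$global), max(x$global)))
  invisible(x)
}

#' @export
summary.msn_set <- function(object, ...) {
  by_group <- split(object$global, object$subjects$group)
  out <- list(
    n_subjects = nrow(object$subjects),
    n_regions = length(object$regions),
    global_by_group = vapply(by_group, mean, numeric(1)),
    strength_range = range(object$strengths))
  class(out) <- "summary.msn_set"
  out
}

#' @export
print.summary.msn_set <- function(x, ...) {
  cat(sprintf("%d subjects, %d regions\n", x$n_subjects, x$n_regions))
  cat("mean global similarity by group:\n")
  print(round(x$global_by_group, 4))
  cat(sprintf("regional strength range: %.4f .. %.4f\n",
              x$strength_range[1], x$strength_range[2]))
  invisible(x)
}

#' Group-mean regional strength map
#'
#' @param msn_set an \code{\link{compute_msn_set}} result.
#' @param group \code{"case"}, \code{"control"} or \code{"all"}.
#' @return named numeric vector of mean strengths over the selected
#'   subjects.
#' @export
mean_strength_map <- function(msn_set, group = c("all", "case", "control")) {
  group <- match.arg(group)
  keep <- if (group == "all") rep(TRUE, nrow(msn_set$strengths)) else
    msn_set$subjects$group == group
  colMeans(msn_set$strengths[keep, , drop = FALSE])
}
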