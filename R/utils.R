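# Internal helpers shared across modules.

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards (same contract as the `seed` argument of simulate()).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

stop_if_not_scalar_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x))
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# Canonical metadata columns of a long-format feature table; everything else
# is treated as a morphometric feature.
.meta_cols <- c("study_id", "subject_id", "group", "age", "sex", "region_id")

feature_cols <- function(table) {
  setdiff(names(table), .meta_cols)
}

check_feature_table <- function(table) {
  missing <- setdiff(.meta_cols, names(table))
  if (length(missing))
    stop("feature table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(table$group %in% c("case", "control")))
    stop("`group` must be 'case' or 'control'", call. = FALSE)
  feats <- feature_cols(table)
  if (!length(feats)) stop("feature table has no feature columns", call. = FALSE)
  invisible(feats)
}

# p-value with the add-one convention: never zero, floor 1/(n+1).
perm_pvalue <- function(n_extreme, n_perm) {
  (1 + n_extreme) / (n_perm + 1)
}
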