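# Config-driven orchestration of the full analysis: simulate -> MSN ->
# case-control -> PLS -> enrichment, with seeds, stage logging and an
# output manifest (parameters + md5 checksums) for reproducibility.

#' Default pipeline configuration
#'
#' Returns the complete configuration list driving
#' \code{\link{run_pipeline}}. User configs (YAML, see
#' \code{\link{read_pipeline_config}}) are merged over these defaults, so
#' a config file only needs the values it overrides. Simulation defaults
#' emulate three case-control studies on a 308-region / 7-feature atlas
#' with a hub-targeted planted effect, a 2,000-gene expression matrix with
#' 100 signal genes tracking the planted effect map, and an interaction
#' network with a planted module.
#'
#' @return nested named list of parameters.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, msn = TRUE, case_control = TRUE,
                  pls = TRUE, enrichment = TRUE),
    simulate = list(
      n_regions = 308L, n_features = 7L, n_left = 152L,
      studies = list(
        list(study_id = "study1", n_cases = 83L, n_controls = 68L),
        list(study_id = "study2", n_cases = 33L, n_controls = 82L),
        list(study_id = "study3", n_cases = 69L, n_controls = 77L)),
      n_affected = 10L, effect_size = 1.0, noise_sd = 0.5,
      age_range = c(18, 65), sex_ratio = 0.5,
      covariate_effects = list(age = 0.01, sex = 0.2),
      expression = list(n_genes = 2000L, n_signal_genes = 100L,
                        signal_correlation = 0.6),
      network = list(n_nodes = 1200L, edge_prob = 0.01,
                     clique_size = 30L),
      n_random_sets = 20L, random_set_size = 50L),
    msn = list(scope = "subjects"),
    case_control = list(fdr_q = 0.05, n_perm_hub = 1000L),
    pls = list(n_components = 2L, n_perm = 1000L, n_boot = 1000L,
               z_threshold = 3, n_perm_map = 1000L),
    enrichment = list(n_resample = 10000L, n_perm_edges = 10000L,
                      alternative = "two.sided", fdr_q = 0.05),
    paths = list())
}

# recursive modifyList that tolerates NULL overrides
.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' Reads a YAML config and merges it over
#' \code{\link{default_pipeline_config}}.
#'
#' @param path YAML file.
#' @return full configuration list.
#' @export
read_pipeline_config <- function(path) {
  .merge_config(default_pipeline_config(), yaml::read_yaml(path))
}

#' Validate pipeline inputs
#'
#' Report-only consistency checks across the analysis inputs: region
#' alignment between feature tables, expression matrix and region
#' metadata; zero-variance features; gene sets disjoint from the
#' expression genes. Never throws; returns a table of issues (empty when
#' everything lines up).
#'
#' @param feature_tables list of feature tables (or a single one).
#' @param expression optional region-by-gene matrix.
#' @param region_metadata optional region metadata data.frame with a
#'   \code{region_id} column.
#' @param gene_sets optional named list of gene id vectors.
#' @param edges optional two-column edge list.
#' @return data.frame with columns \code{component} and \code{message};
#'   zero rows if no issues.
#' @export
validate_inputs <- function(feature_tables = NULL, expression = NULL,
                            region_metadata = NULL, gene_sets = NULL,
                            edges = NULL) {
  issues <- list()
  note <- function(component, message)
    issues[[length(issues) + 1L]] <<-
      data.frame(component = component, message = message,
                 stringsAsFactors = FALSE)
  regions_ref <- NULL
  if (!is.null(feature_tables)) {
    tabs <- if (is.data.frame(feature_tables)) list(feature_tables) else
      feature_tables
    for (i in seq_along(tabs)) {
      tab <- tabs[[i]]
      feats <- tryCatch(check_feature_table(tab), error = function(e) {
        note(sprintf("feature_table[%d]", i), conditionMessage(e)); NULL
      })
      if (is.null(feats)) next
      regs <- unique(tab$region_id)
      if (is.null(regions_ref)) regions_ref <- regs
      else if (!setequal(regions_ref, regs))
        note(sprintf("feature_table[%d]", i),
             "region set differs from the first table")
      n_per_sub <- table(tab$subject_id)
      if (length(unique(n_per_sub)) > 1)
        note(sprintf("feature_table[%d]", i),
             "subjects have unequal numbers of region rows")
      for (f in feats) {
        sds <- tapply(tab[[f]], tab$region_id, sd)
        if (any(sds == 0, na.rm = TRUE))
          note(sprintf("feature_table[%d]", i),
               sprintf("feature '%s' has zero variance in region(s): %s", f,
                       paste(head(names(sds)[which(sds == 0)], 3),
                             collapse = ", ")))
      }
    }
  }
  if (!is.null(expression)) {
    if (!is.null(regions_ref)) {
      miss <- setdiff(intersect(regions_ref, regions_ref),
                      rownames(expression))
      lh_ref <- grep("^lh_", regions_ref, value = TRUE)
      miss <- setdiff(if (length(lh_ref)) lh_ref else regions_ref,
                      rownames(expression))
      if (length(miss))
        note("expression", sprintf("missing region(s): %s",
                                   paste(head(miss, 5), collapse = ", ")))
    }
    if (anyNA(expression)) note("expression", "contains missing values")
  }
  if (!is.null(region_metadata) && !is.null(regions_ref)) {
    miss <- setdiff(regions_ref, region_metadata$region_id)
    if (length(miss))
      note("region_metadata", sprintf("unlabeled region(s): %s",
                                      paste(head(miss, 5), collapse = ", ")))
  }
  if (!is.null(gene_sets) && !is.null(expression)) {
    for (nm in names(gene_sets))
      if (!length(intersect(gene_sets[[nm]], colnames(expression))))
        note("gene_sets", sprintf("set '%s' is disjoint from expression genes",
                                  nm))
  }
  if (!is.null(edges) && !is.null(expression)) {
    e <- .normalize_edges(edges)
    out_of_universe <- mean(!(c(e$from, e$to) %in% colnames(expression)))
    if (out_of_universe == 1)
      note("edges", "no edge endpoint matches an expression gene")
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(component = character(0), message = character(0),
               stringsAsFactors = FALSE)
}

.stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[msnmap] %s", sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> MSN construction -> multi-study
#' case-control inference -> PLS transcriptomic association -> gene-set
#' enrichment, writing every stage output as self-describing TSV plus a
#' JSON manifest recording the configuration, all derived seeds, and md5
#' checksums of the outputs. Reruns with the same config and output
#' directory produce identical manifests.
#'
#' With simulation enabled, the expression matrix is planted so that half
#' of the signal genes correlate positively and half negatively with the
#' planted case-effect map, giving known "up" and "down" truth sets for
#' the sign-concordance test, and the interaction network carries a
#' planted module inside the negative signal genes.
#'
#' @param config configuration list (see
#'   \code{\link{default_pipeline_config}}) or path to a YAML config.
#' @param outdir output directory (created if missing).
#' @param verbose log stage progress via \code{message}.
#' @return (invisibly) an object of class \code{msn_pipeline} with all
#'   in-memory stage results and the manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = tempfile("msnmap_run_"), verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- .merge_config(default_pipeline_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  outputs <- character(0)
  results <- list(config = config, outdir = outdir)
  t0 <- proc.time()[["elapsed"]]

  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    outputs[[length(outputs) + 1L]] <<- path
    path
  }

  ## ---- simulate -------------------------------------------------------
  sim <- config$simulate
  if (isTRUE(config$stages$simulate)) {
    .stage_log(verbose, "simulate: %d studies, %d regions, %d genes",
               length(sim$studies), sim$n_regions,
               sim$expression$n_genes)
    affected <- default_affected_regions(sim$n_regions, sim$n_affected,
                                         n_left = sim$n_left)
    tables <- vector("list", length(sim$studies))
    for (i in seq_along(sim$studies)) {
      st <- sim$studies[[i]]
      spec <- cohort_spec(
        n_cases = st$n_cases, n_controls = st$n_controls,
        n_regions = sim$n_regions, n_features = sim$n_features,
        n_left = sim$n_left, affected_regions = affected,
        effect_size = sim$effect_size, noise_sd = sim$noise_sd,
        age_range = sim$age_range, sex_ratio = sim$sex_ratio,
        covariate_effects = sim$covariate_effects,
        study_id = st$study_id, seed = seed + i)
      tables[[i]] <- generate_cohort(spec)
      emit(sprintf("features_%s.tsv", st$study_id),
           function(p) write_feature_table(tables[[i]], p))
    }
    meta <- attr(tables[[1]], "region_metadata")
    emit("region_metadata.tsv", function(p)
      write.table(meta, p, sep = "\t", quote = FALSE, row.names = FALSE))

    # planted effect map on left-hemisphere regions: similarity loss at
    # affected regions, nothing elsewhere
    lh_regions <- meta$region_id[meta$hemisphere == "lh"]
    target <- setNames(ifelse(meta$affected[meta$hemisphere == "lh"], -1, 0),
                       lh_regions)
    espec <- expression_spec(
      n_genes = sim$expression$n_genes,
      n_signal_genes = sim$expression$n_signal_genes,
      target_map = target,
      signal_correlation = sim$expression$signal_correlation,
      seed = seed + 101L)
    expr <- generate_expression(espec)
    signal <- attr(expr, "signal_genes")
    # flip half the signal genes around their mean so both tails of the
    # PLS ranking carry planted genes (truth for sign concordance)
    half <- signal[seq_len(length(signal) %/% 2)]
    expr[, half] <- sweep(-expr[, half, drop = FALSE], 2,
                          2 * colMeans(expr[, half, drop = FALSE]), "+")
    # flipped genes are overexpressed where similarity is lost (negative
    # PLS weights); unflipped genes take positive weights
    signal_down <- half
    signal_up <- setdiff(signal, half)
    emit("expression.tsv", function(p) write_expression_matrix(expr, p))

    gene_sets <- c(
      list(planted_all = signal, planted_up = signal_up,
           planted_down = signal_down),
      with_seed(seed + 202L, setNames(
        lapply(seq_len(sim$n_random_sets), function(i)
          sample(colnames(expr), sim$random_set_size)),
        sprintf("random_set_%02d", seq_len(sim$n_random_sets)))))
    emit("gene_sets.gmt", function(p) write_gmt(gene_sets, p))

    net_nodes <- with_seed(seed + 303L, unique(c(
      signal_down, sample(colnames(expr),
                          min(sim$network$n_nodes, ncol(expr))))))
    clique <- signal_down[seq_len(min(sim$network$clique_size,
                                      length(signal_down)))]
    edges <- generate_network(edge_prob = sim$network$edge_prob,
                              planted_clique = clique,
                              seed = seed + 404L, nodes = net_nodes)
    emit("ppi_edges.tsv", function(p) write_edge_list(edges, p))
    results$simulate <- list(tables = tables, expression = expr,
                             gene_sets = gene_sets, edges = edges,
                             region_metadata = meta,
                             affected_regions = affected,
                             signal_up = signal_up,
                             signal_down = signal_down)
  } else {
    .stage_log(verbose, "simulate: skipped, reading inputs from config paths")
    tables <- lapply(config$paths$feature_tables, read_feature_table)
    expr <- read_expression_matrix(config$paths$expression)
    meta <- read.delim(config$paths$region_metadata,
                       stringsAsFactors = FALSE)
    gene_sets <- read_gmt(config$paths$gene_sets)
    edges <- read_edge_list(config$paths$edges)
    results$simulate <- list(tables = tables, expression = expr,
                             gene_sets = gene_sets, edges = edges,
                             region_metadata = meta)
  }

  ## ---- msn ------------------------------------------------------------
  if (!isTRUE(config$stages$msn)) {
    .stage_log(verbose, "msn: disabled; stopping after simulate")
    return(invisible(.finish_pipeline(results, outputs, outdir, config,
                                      verbose, t0)))
  }
  .stage_log(verbose, "msn: per-subject similarity matrices and strengths")
  lh_regions <- meta$region_id[meta$hemisphere == "lh"]
  msn_sets <- lapply(tables, compute_msn_set, scope = config$msn$scope)
  msn_sets_lh <- lapply(tables, compute_msn_set, scope = config$msn$scope,
                        region_subset = lh_regions)
  results$msn <- list(full = msn_sets, left = msn_sets_lh)
  for (i in seq_along(msn_sets)) {
    study <- unique(msn_sets[[i]]$subjects$study_id)[1]
    emit(sprintf("strengths_%s.tsv", study), function(p)
      write.table(data.frame(subject_id = rownames(msn_sets[[i]]$strengths),
                             msn_sets[[i]]$strengths, check.names = FALSE),
                  p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  ## ---- case-control ---------------------------------------------------
  if (!isTRUE(config$stages$case_control))
    return(invisible(.finish_pipeline(results, outputs, outdir, config,
                                      verbose, t0)))
  .stage_log(verbose, "case-control: per-study models, Fisher, FDR")
  cc <- casecontrol_msn(msn_sets, q = config$case_control$fdr_q)
  cc_lh <- casecontrol_msn(msn_sets_lh, q = config$case_control$fdr_q)
  maps <- residualized_strength_maps(msn_sets)
  ks <- compare_strength_distributions(maps$case, maps$control)
  hub <- hub_vulnerability(cc$control_strength,
                           setNames(cc$combined$mean_t,
                                    cc$combined$region_id),
                           n_perm = config$case_control$n_perm_hub,
                           seed = seed + 505L)
  classes <- setNames(meta$cyto_class, meta$region_id)
  class_test <- class_aggregation_test(msn_sets, classes,
                                       q = config$case_control$fdr_q)
  results$case_control <- list(full = cc, left = cc_lh, ks = ks, hub = hub,
                               class_test = class_test,
                               residualized_maps = maps)
  emit("casecontrol_per_study.tsv", function(p)
    write.table(cc$per_study, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  emit("casecontrol_combined.tsv", function(p)
    write.table(cc$combined, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  emit("global_model.tsv", function(p)
    write.table(cc$global, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("distribution_test.tsv", function(p)
    write.table(data.frame(ks_D = ks$D, ks_p = ks$p,
                           hub_r = hub$r, hub_p_perm = hub$p_perm),
                p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("class_aggregation.tsv", function(p)
    write.table(class_test, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## ---- pls ------------------------------------------------------------
  if (!isTRUE(config$stages$pls))
    return(invisible(.finish_pipeline(results, outputs, outdir, config,
                                      verbose, t0)))
  .stage_log(verbose, "pls: fit, permutation test, bootstrap gene ranking")
  per_lh <- cc_lh$per_study
  studies <- unique(per_lh$study_id)
  Y <- sapply(studies, function(s)
    setNames(per_lh$t_stat[per_lh$study_id == s],
             per_lh$region_id[per_lh$study_id == s])[lh_regions])
  rownames(Y) <- lh_regions
  X <- expr[lh_regions, , drop = FALSE]
  pls <- fit_pls(X, Y, n_components = config$pls$n_components)
  perm <- permutation_test_variance(X, Y, n_perm = config$pls$n_perm,
                                    seed = seed + 606L)
  gt <- bootstrap_gene_weights(X, Y, n_boot = config$pls$n_boot,
                               seed = seed + 707L)
  tail_sets <- select_gene_sets(gt, z_threshold = config$pls$z_threshold)
  score_cor <- lapply(seq_along(studies), function(i)
    score_map_correlation(pls$scores[, 1], Y[, i],
                          n_perm = config$pls$n_perm_map,
                          seed = seed + 808L + i))
  names(score_cor) <- studies
  results$pls <- list(model = pls, perm = perm, gene_table = gt,
                      tail_sets = tail_sets, score_cor = score_cor,
                      Y = Y)
  emit("pls_scores.tsv", function(p)
    write_regional_map(pls$scores[, 1], p, value_name = "pls1_score"))
  emit("pls_summary.tsv", function(p)
    write.table(data.frame(
      component = seq_len(config$pls$n_components),
      variance_explained = pls$variance_explained,
      perm_p = c(perm$perm_p, rep(NA, config$pls$n_components - 1))),
      p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("gene_table.tsv", function(p)
    write.table(gt, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## ---- enrichment -----------------------------------------------------
  if (!isTRUE(config$stages$enrichment))
    return(invisible(.finish_pipeline(results, outputs, outdir, config,
                                      verbose, t0)))
  .stage_log(verbose, "enrichment: median-rank, sign concordance, PPI edges")
  enr <- enrich_gene_sets(gt, gene_sets,
                          n_resample = config$enrichment$n_resample,
                          alternative = config$enrichment$alternative,
                          q = config$enrichment$fdr_q,
                          seed = seed + 909L)
  sign_test <- if (!is.null(results$simulate$signal_up))
    sign_concordance_test(gt, results$simulate$signal_up,
                          results$simulate$signal_down) else NULL
  ppi_universe <- attr(edges, "nodes")
  if (is.null(ppi_universe))
    ppi_universe <- unique(c(edges$from, edges$to, colnames(expr)))
  ppi_set <- intersect(tail_sets$pls_minus, ppi_universe)
  ppi <- if (length(ppi_set) >= 2)
    ppi_edge_enrichment(edges, ppi_set, ppi_universe,
                        n_perm = config$enrichment$n_perm_edges,
                        seed = seed + 1010L) else NULL
  results$enrichment <- list(median_rank = enr, sign_test = sign_test,
                             ppi = ppi)
  emit("enrichment.tsv", function(p)
    write.table(enr, p, sep = "\t", quote = FALSE, row.names = FALSE))
  if (!is.null(ppi) || !is.null(sign_test))
    emit("enrichment_extra.tsv", function(p)
      write.table(data.frame(
        sign_W = if (is.null(sign_test)) NA else sign_test$statistic,
        sign_p = if (is.null(sign_test)) NA else sign_test$p,
        ppi_observed = if (is.null(ppi)) NA else ppi$observed_edges,
        ppi_expected = if (is.null(ppi)) NA else ppi$expected_edges,
        ppi_p = if (is.null(ppi)) NA else ppi$p),
        p, sep = "\t", quote = FALSE, row.names = FALSE))

  invisible(.finish_pipeline(results, outputs, outdir, config, verbose, t0))
}

.finish_pipeline <- function(results, outputs, outdir, config, verbose, t0) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("msnmap")),
    config = config,
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .stage_log(verbose, "done in %.1f s; manifest at %s",
             proc.time()[["elapsed"]] - t0, manifest_path)
  results$manifest <- manifest
  class(results) <- "msn_pipeline"
  results
}

#' @export
print.msn_pipeline <- function(x, ...) {
  cat("MSN analysis pipeline run\n")
  cat("  output dir:", x$outdir, "\n")
  cat("  stages run:", paste(intersect(
    c("simulate", "msn", "case_control", "pls", "enrichment"),
    names(x)), collapse = ", "), "\n")
  if (!is.null(x$case_control))
    cat(sprintf("  FDR-significant regions: %d\n",
                sum(x$case_control$full$combined$fdr_significant)))
  if (!is.null(x$pls))
    cat(sprintf("  PLS1 variance explained: %.1f%% (perm p = %.3g)\n",
                100 * x$pls$model$variance_explained[1], x$pls$perm$perm_p))
  invisible(x)
}
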