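#' Specify a synthetic case-control cohort
#'
#' A cohort spec records everything needed to simulate one study's
#' subject-by-region-by-feature morphometric table: group sizes, atlas size,
#' which regions carry a planted case effect and how strong it is, the age
#' and sex structure, per-feature covariate slopes, and the residual noise
#' level. The defaults emulate a single psychosis case-control MRI study on
#' a 308-region cortical parcellation with seven morphometric features per
#' region.
#'
#' Control subjects share a latent regional architecture: each region sits
#' at an angle on a one-dimensional gradient and loads two orthogonal
#' feature patterns by the cosine and sine of that angle, so that nearby
#' regions have positively correlated morphometric profiles and distant
#' regions negatively correlated ones. This reproduces the mix of positive
#' and negative similarity strengths seen in real morphometric similarity
#' networks, and gives regions near the middle of the gradient the highest
#' expected strength (the "hubs"). The case effect is feature
#' decorrelation: affected regions of case subjects receive extra
#' independent noise scaled by \code{effect_size}, which attenuates their
#' correlation with every other region without shifting feature means.
#'
#' @param n_cases,n_controls number of case and control subjects.
#' @param n_regions number of cortical regions (default 308).
#' @param n_features number of morphometric features per region (default 7).
#' @param affected_regions integer indices (1..n_regions) of regions with a
#'   planted case effect. Default: the \code{10} regions with the highest
#'   expected control strength (see \code{\link{default_affected_regions}}).
#' @param effect_size non-negative decorrelation strength, in units of the
#'   latent signal amplitude; 0 means no case effect.
#' @param age_range length-2 numeric, uniform age range in years.
#' @param sex_ratio proportion of female subjects.
#' @param covariate_effects list with numeric vectors \code{age} and
#'   \code{sex} of per-feature slopes (recycled to \code{n_features}).
#' @param noise_sd residual feature noise SD relative to unit latent
#'   amplitude.
#' @param n_left number of left-hemisphere regions; the remainder are
#'   right-hemisphere. Defaults to \code{ceiling(n_regions / 2)} except for
#'   the 308-region default atlas, where 152 regions are left-hemisphere.
#' @param study_id label stamped into the output table.
#' @param seed integer RNG seed; identical specs with identical seeds
#'   generate byte-identical tables.
#' @return an object of class \code{cohort_spec}.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_cases = 83, n_controls = 68, n_regions = 308,
                        n_features = 7, affected_regions = NULL,
                        effect_size = 1, age_range = c(18, 65),
                        sex_ratio = 0.5,
                        covariate_effects = list(age = 0.01, sex = 0.2),
                        noise_sd = 0.5, n_left = NULL,
                        study_id = "study1", seed = 1L) {
  stop_if_not_scalar_count(n_cases, "n_cases")
  stop_if_not_scalar_count(n_controls, "n_controls")
  stop_if_not_scalar_count(n_regions, "n_regions")
  stop_if_not_scalar_count(n_features, "n_features")
  if (length(effect_size) != 1L || is.na(effect_size) || effect_size < 0)
    stop("`effect_size` must be a single non-negative number", call. = FALSE)
  if (is.null(n_left)) n_left <- if (n_regions == 308L) 152L else ceiling(n_regions / 2)
  if (n_left < 1 || n_left >= n_regions)
    stop("`n_left` must be in [1, n_regions)", call. = FALSE)
  if (is.null(affected_regions))
    affected_regions <- default_affected_regions(n_regions, 10L, n_left = n_left)
  affected_regions <- as.integer(affected_regions)
  if (length(affected_regions) &&
      (min(affected_regions) < 1 || max(affected_regions) > n_regions))
    stop("`affected_regions` contains region indices outside 1..n_regions",
         call. = FALSE)
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("`sex_ratio` must be a proportion", call. = FALSE)
  spec <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_regions = as.integer(n_regions), n_features = as.integer(n_features),
    affected_regions = affected_regions, effect_size = effect_size,
    age_range = as.numeric(age_range), sex_ratio = sex_ratio,
    covariate_effects = list(
      age = rep_len(covariate_effects$age, n_features),
      sex = rep_len(covariate_effects$sex, n_features)),
    noise_sd = noise_sd, n_left = as.integer(n_left),
    study_id = study_id, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$study_id, "\n")
  cat(sprintf("  %d cases / %d controls, %d regions x %d features (%d left-hemisphere)\n",
              x$n_cases, x$n_controls, x$n_regions, x$n_features, x$n_left))
  cat(sprintf("  planted effect: size %.3g in %d region(s); noise SD %.3g; seed %d\n",
              x$effect_size, length(x$affected_regions), x$noise_sd, x$seed))
  invisible(x)
}

# Latent geometry shared by the generator and by default_affected_regions.
# Regions are placed on a gradient of angles spanning 0..0.8*pi within each
# hemisphere (homologous positions across hemispheres), and load two
# orthogonal feature patterns by cos/sin of the angle.
.region_geometry <- function(n_regions, n_left) {
  hemi <- rep(c("lh", "rh"), c(n_left, n_regions - n_left))
  pos <- c(seq(0, 1, length.out = n_left),
           seq(0, 1, length.out = n_regions - n_left))
  theta <- 0.8 * pi * pos
  region_id <- sprintf("%s_reg%03d", hemi, seq_len(n_regions))
  list(region_id = region_id, hemisphere = hemi, theta = theta,
       g = cos(theta), h = sin(theta))
}

.feature_patterns <- function(n_features) {
  f <- seq_len(n_features)
  p <- cos(2 * pi * (f - 1) / n_features)
  q <- sin(2 * pi * (f - 1) / n_features)
  p <- p - mean(p)
  q <- q - mean(q)
  q <- q - p * sum(p * q) / sum(p * p)  # orthogonalize
  p <- p / sd(p)
  q <- q / sd(q)
  list(p = p, q = q)
}

# Raw measurement scales so that the seven canonical features live on
# realistically different numeric ranges before z-scoring.
.feature_scales <- function(n_features) {
  base <- c(1500, 800, 2.5, 0.15, 0.12, 0.45, 8e-4)
  rep_len(base, n_features)
}

.feature_names <- function(n_features) {
  canon <- c("gm_volume", "surface_area", "thickness", "gauss_curv",
             "mean_curv", "fa", "md")
  if (n_features <= length(canon)) canon[seq_len(n_features)]
  else c(canon, sprintf("feature_%d", seq.int(length(canon) + 1, n_features)))
}

#' Regions with the highest expected control strength
#'
#' Returns the indices of the \code{k} regions whose expected mean
#' similarity to all other regions is largest under the generator's latent
#' gradient geometry — the simulated "hubs". Planting the case effect there
#' reproduces the hub-vulnerability phenomenon (strongly connected regions
#' losing the most similarity in cases).
#'
#' @param n_regions atlas size.
#' @param k number of regions to return.
#' @param n_left number of left-hemisphere regions (see
#'   \code{\link{cohort_spec}}).
#' @return integer vector of length \code{k}.
#' @export
default_affected_regions <- function(n_regions, k = 10L, n_left = NULL) {
  if (is.null(n_left)) n_left <- if (n_regions == 308L) 152L else ceiling(n_regions / 2)
  geo <- .region_geometry(n_regions, n_left)
  expected <- outer(geo$theta, geo$theta, function(a, b) cos(a - b))
  diag(expected) <- NA
  strength <- rowMeans(expected, na.rm = TRUE)
  sort(order(strength, decreasing = TRUE)[seq_len(k)])
}

#' Generate a synthetic morphometric feature table
#'
#' Simulates one study's long-format feature table under the latent model
#' described in \code{\link{cohort_spec}}: per subject and region,
#' \code{n_features} raw feature values built from the region's gradient
#' loadings, subject-level latent factors, linear age and sex effects, and
#' independent residual noise; case subjects additionally receive
#' decorrelating noise in the affected regions. Identical spec and seed
#' give identical tables.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return a \code{data.frame} with columns \code{study_id, subject_id,
#'   group, age, sex, region_id} and one column per feature; one row per
#'   subject-region. Attributes \code{spec} and \code{region_metadata} carry
#'   the generating spec and the region table from
#'   \code{\link{region_metadata}}.
#' @examples
#' tab <- generate_cohort(cohort_spec(n_cases = 4, n_controls = 4,
#'                                    n_regions = 20, seed = 7))
#' head(tab)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n_sub <- spec$n_cases + spec$n_controls
    nr <- spec$n_regions
    nf <- spec$n_features
    geo <- .region_geometry(nr, spec$n_left)
    pat <- .feature_patterns(nf)
    scales <- .feature_scales(nf)

    group <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
    age <- runif(n_sub, spec$age_range[1], spec$age_range[2])
    sex <- ifelse(runif(n_sub) < spec$sex_ratio, "F", "M")
    sex_num <- as.numeric(sex == "F")
    age_c <- age - mean(spec$age_range)
    u <- rnorm(n_sub)
    v <- rnorm(n_sub)

    # baseline regional profile, fixed given the atlas
    base <- outer(geo$g, pat$p) * 0.5 + outer(geo$h, pat$q) * 0.5 + 10

    # values[subject, region, feature]
    values <- array(0, dim = c(n_sub, nr, nf))
    for (f in seq_len(nf)) {
      latent <- outer(u, geo$g * pat$p[f]) + outer(v, geo$h * pat$q[f])
      covar <- (age_c * spec$covariate_effects$age[f] +
                  sex_num * spec$covariate_effects$sex[f])
      eps <- matrix(rnorm(n_sub * nr, sd = spec$noise_sd), n_sub, nr)
      values[, , f] <- rep(base[, f], each = n_sub) + latent + covar + eps
    }
    if (spec$effect_size > 0 && length(spec$affected_regions)) {
      is_case <- group == "case"
      nc <- sum(is_case)
      for (j in spec$affected_regions) {
        extra <- matrix(rnorm(nc * nf, sd = spec$effect_size), nc, nf)
        values[is_case, j, ] <- values[is_case, j, ] + extra
      }
    }
    for (f in seq_len(nf)) values[, , f] <- values[, , f] * scales[f]

    subject_id <- sprintf("%s_sub%03d", spec$study_id, seq_len(n_sub))
    out <- data.frame(
      study_id = spec$study_id,
      subject_id = rep(subject_id, each = nr),
      group = rep(group, each = nr),
      age = rep(age, each = nr),
      sex = rep(sex, each = nr),
      region_id = rep(geo$region_id, times = n_sub),
      stringsAsFactors = FALSE)
    feat <- matrix(0, n_sub * nr, nf)
    for (f in seq_len(nf)) feat[, f] <- as.vector(t(values[, , f]))
    colnames(feat) <- .feature_names(nf)
    out <- cbind(out, as.data.frame(feat))
    attr(out, "spec") <- spec
    attr(out, "region_metadata") <- region_metadata(spec)
    out
  })
}

#' Region metadata table for a synthetic atlas
#'
#' Returns per-region hemisphere, a five-level cytoarchitectonic class
#' label, and a seven-level functional-network label, both assigned by
#' position along the latent gradient so that class membership is spatially
#' coherent (as in real cytoarchitectonic and resting-state partitions).
#'
#' @param spec a \code{\link{cohort_spec}} (only the atlas fields are used).
#' @return data.frame with columns \code{region_id, hemisphere,
#'   cyto_class, functional_network, affected}.
#' @export
region_metadata <- function(spec) {
  geo <- .region_geometry(spec$n_regions, spec$n_left)
  pos <- geo$theta / (0.8 * pi)
  data.frame(
    region_id = geo$region_id,
    hemisphere = geo$hemisphere,
    cyto_class = paste0("class", pmin(5L, 1L + floor(pos * 5))),
    functional_network = paste0("net", pmin(7L, 1L + floor(pos * 7))),
    affected = seq_len(spec$n_regions) %in% spec$affected_regions,
    stringsAsFactors = FALSE)
}

#' Specify a synthetic regional expression matrix
#'
#' @param n_genes total number of genes.
#' @param n_signal_genes number of genes whose regional profile tracks
#'   \code{target_map}.
#' @param target_map named numeric vector of per-region scalars (names are
#'   region ids) the signal genes should correlate with.
#' @param signal_correlation population Pearson correlation in [-1, 1]
#'   between each signal gene's profile and \code{target_map}.
#' @param seed integer RNG seed.
#' @return an object of class \code{expression_spec}.
#' @export
expression_spec <- function(n_genes = 2000, n_signal_genes = 100,
                            target_map, signal_correlation = 0.6,
                            seed = 1L) {
  stop_if_not_scalar_count(n_genes, "n_genes")
  if (n_signal_genes > n_genes)
    stop("`n_signal_genes` must not exceed `n_genes`", call. = FALSE)
  if (abs(signal_correlation) > 1)
    stop("`signal_correlation` must lie in [-1, 1]", call. = FALSE)
  if (is.null(names(target_map)))
    stop("`target_map` must be named by region id", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_signal_genes = as.integer(n_signal_genes),
                 target_map = target_map,
                 signal_correlation = signal_correlation,
                 seed = as.integer(seed)),
            class = "expression_spec")
}

#' Generate a synthetic region-by-gene expression matrix
#'
#' Signal genes are built as \code{r * scale(target_map) + sqrt(1 - r^2) *
#' noise} so their regional profile correlates with the target map at
#' \code{signal_correlation} in expectation; the remaining genes are
#' independent standard-normal noise. Gene identifiers are stable
#' (\code{gene_00001}, ...) and the planted signal genes are recorded in the
#' \code{signal_genes} attribute.
#'
#' @param spec an \code{\link{expression_spec}}.
#' @return numeric matrix, regions (rows, named as in \code{target_map}) by
#'   genes (columns); attributes \code{signal_genes} and \code{spec}.
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  with_seed(spec$seed, {
    nr <- length(spec$target_map)
    t_std <- as.numeric(scale(spec$target_map))
    genes <- sprintf("gene_%05d", seq_len(spec$n_genes))
    X <- matrix(rnorm(nr * spec$n_genes), nr, spec$n_genes,
                dimnames = list(names(spec$target_map), genes))
    if (spec$n_signal_genes > 0) {
      signal_idx <- sort(sample.int(spec$n_genes, spec$n_signal_genes))
      r <- spec$signal_correlation
      X[, signal_idx] <- r * t_std + sqrt(1 - r^2) * X[, signal_idx]
    } else signal_idx <- integer(0)
    # per-gene baseline offsets, as in log-intensity expression data
    X <- sweep(X, 2, runif(spec$n_genes, 4, 10), "+")
    attr(X, "signal_genes") <- genes[signal_idx]
    attr(X, "spec") <- spec
    X
  })
}

#' Generate a synthetic undirected interaction network
#'
#' An Erdos-Renyi graph G(n, p) with an optional planted clique, as a
#' deduplicated two-column edge list without self-loops. Used as a stand-in
#' protein-protein interaction network for edge-count enrichment testing.
#'
#' @param n_nodes number of nodes (ignored if \code{nodes} is given).
#' @param edge_prob independent edge probability in [0, 1].
#' @param planted_clique indices (or node ids) of nodes to connect
#'   completely.
#' @param seed integer RNG seed.
#' @param nodes optional character vector of node identifiers.
#' @return data.frame with character columns \code{from} and \code{to};
#'   attribute \code{nodes} lists the full vertex set.
#' @export
generate_network <- function(n_nodes, edge_prob, planted_clique = integer(0),
                             seed = 1L, nodes = NULL) {
  if (is.null(nodes)) {
    stop_if_not_scalar_count(n_nodes, "n_nodes")
    nodes <- sprintf("node_%04d", seq_len(n_nodes))
  }
  n <- length(nodes)
  if (edge_prob < 0 || edge_prob > 1)
    stop("`edge_prob` must be a probability", call. = FALSE)
  if (is.character(planted_clique)) {
    clique <- match(planted_clique, nodes)
    if (anyNA(clique)) stop("clique nodes not in the vertex set", call. = FALSE)
  } else {
    clique <- as.integer(planted_clique)
    if (length(clique) && (min(clique) < 1 || max(clique) > n))
      stop("clique nodes out of range", call. = FALSE)
  }
  with_seed(seed, {
    ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    jj <- unlist(lapply(seq_len(n - 1L), function(i) seq.int(i + 1L, n)))
    keep <- if (edge_prob > 0) runif(length(ii)) < edge_prob else
      logical(length(ii))
    from <- ii[keep]; to <- jj[keep]
    if (length(clique) > 1) {
      cc <- t(utils::combn(sort(clique), 2L))
      from <- c(from, cc[, 1]); to <- c(to, cc[, 2])
      dup <- duplicated(paste(from, to))
      from <- from[dup == FALSE]; to <- to[dup == FALSE]
    }
    out <- data.frame(from = nodes[from], to = nodes[to],
                      stringsAsFactors = FALSE)
    attr(out, "nodes") <- nodes
    out
  })
}
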