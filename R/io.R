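# Readers and writers for the pipeline's plain-text interchange formats:
# long-format feature tables, region-by-gene expression matrices, region
# metadata, strength maps, GMT gene sets, and two-column edge lists. Every
# writer emits a tab-separated file with a header row; generator outputs
# get a YAML sidecar recording the generating spec and seed.

#' Read / write a long-format feature table
#'
#' @param path TSV path.
#' @return data.frame with the feature-table column contract (see
#'   \code{\link{generate_cohort}}).
#' @export
read_feature_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_feature_table(tab)
  tab
}

#' @rdname read_feature_table
#' @param table feature table to write.
#' @param sidecar if \code{TRUE} and the table carries a generating spec
#'   attribute, write \code{<path>.spec.yaml} alongside.
#' @export
write_feature_table <- function(table, path, sidecar = TRUE) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- attr(table, "spec")
  if (sidecar && !is.null(spec)) .write_spec_sidecar(spec, path)
  invisible(path)
}

.write_spec_sidecar <- function(spec, path) {
  s <- unclass(spec)
  s <- lapply(s, function(x) if (is.numeric(x) || is.character(x)) x else
    unclass(x))
  yaml::write_yaml(s, paste0(path, ".spec.yaml"))
}

#' Read / write a region-by-gene expression matrix
#'
#' TSV layout: first column \code{region_id}, remaining columns one per
#' gene.
#'
#' @param path TSV path.
#' @return numeric matrix with region rownames and gene colnames.
#' @export
read_expression_matrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param X matrix to write.
#' @param sidecar write a spec sidecar if the matrix carries one.
#' @export
write_expression_matrix <- function(X, path, sidecar = TRUE) {
  out <- data.frame(region_id = rownames(X), X, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- attr(X, "spec")
  if (sidecar && !is.null(spec)) {
    s <- unclass(spec)
    s$target_map <- NULL  # stored in its own map file, not the sidecar
    yaml::write_yaml(s, paste0(path, ".spec.yaml"))
  }
  invisible(path)
}

#' Read / write a per-region scalar map
#'
#' Two-column TSV: \code{region_id}, \code{value}.
#'
#' @param path TSV path.
#' @return named numeric vector.
#' @export
read_regional_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab[[2]], tab[[1]])
}

#' @rdname read_regional_map
#' @param map named numeric vector.
#' @param value_name header for the value column.
#' @export
write_regional_map <- function(map, path, value_name = "value") {
  out <- data.frame(region_id = names(map), value = unname(map))
  names(out)[2] <- value_name
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member gene
#' ids.
#'
#' @param path GMT path.
#' @return named list of character vectors; descriptions in the
#'   \code{descriptions} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <-
    setNames(vapply(parts, `[`, character(1), 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional named character vector of set
#'   descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a two-column undirected edge list
#'
#' @param path TSV path with columns \code{from} and \code{to}.
#' @return data.frame with character columns \code{from}, \code{to}.
#' @export
read_edge_list <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  .normalize_edges(tab)
}

#' @rdname read_edge_list
#' @param edges two-column data.frame.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges[, c("from", "to")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
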