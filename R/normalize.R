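# Library-size log-normalization and group-mean expression summaries —
# the quantities the ligand-receptor score consumes.

#' Log-normalize a count matrix
#'
#' The standard single-cell convention: each cell's counts are scaled to a
#' common library size and log-transformed,
#' `value = log(1 + count / library * scale_factor)` (natural log by
#' default). Zeros stay exactly zero, and for every cell with a non-empty
#' library the back-transformed values `exp(value) - 1` sum to
#' `scale_factor`.
#'
#' @param counts a [count_matrix()] (normally QC-filtered).
#' @param scale_factor target library size, default 10000.
#' @param log_base base of the logarithm, default `exp(1)`.
#' @return A `normalized_matrix`: list with dense `values` (genes x cells),
#'   `gene_ids`, `cell_ids`, `scale_factor`, `log_base`.
#' @examples
#' m <- count_matrix(matrix(c(1, 1, 2), ncol = 1),
#'                   gene_ids = c("a", "b", "c"), cell_ids = "c1")
#' norm <- log_normalize(m, scale_factor = 4)
#' sum(exp(norm$values) - 1)  # 4, the scale factor
#' @export
log_normalize <- function(counts, scale_factor = 10000, log_base = exp(1)) {
  stopifnot(inherits(counts, "count_matrix"))
  if (scale_factor <= 0) stop_validation("scale_factor must be positive")
  if (log_base <= 0 || log_base == 1) stop_validation("log_base must be positive and != 1")
  lib <- Matrix::colSums(counts$values)
  if (any(lib == 0)) {
    warning(sum(lib == 0), " cell(s) with empty libraries map to all-zero columns")
  }
  sf <- ifelse(lib > 0, scale_factor / lib, 0)
  vals <- as.matrix(counts$values %*% Matrix::Diagonal(x = sf))
  vals <- log1p(vals) / log(log_base)
  dimnames(vals) <- list(counts$gene_ids, counts$cell_ids)
  structure(list(values = vals, gene_ids = counts$gene_ids,
                 cell_ids = counts$cell_ids, scale_factor = scale_factor,
                 log_base = log_base),
            class = "normalized_matrix")
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (scale factor %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

group_key <- function(cell_type, time_point) {
  paste(as.character(cell_type), as.character(time_point), sep = "|")
}

#' Mean log-normalized expression per (cell type, time point) group
#'
#' Arithmetic mean over *all* cells carrying a joint label, including cells
#' not expressing the gene — the group average of log-normalized
#' expression.
#'
#' @param norm a [log_normalize()]d matrix.
#' @param ann a `cell_annotation` covering every cell in `norm`.
#' @return A `group_means` object: `means` (genes x groups matrix with
#'   `"cell_type|time_point"` column keys), `group_sizes`, and a `groups`
#'   data frame.
#' @export
group_means <- function(norm, ann) {
  stopifnot(inherits(norm, "normalized_matrix"))
  ann <- align_annotation(ann, norm)
  key <- group_key(ann$cell_type, ann$time_point)
  f <- factor(key, levels = unique(key))
  sizes <- table(f)
  means <- t(rowsum(t(norm$values), f) / as.vector(sizes))
  groups <- data.frame(key = levels(f),
                       cell_type = sub("\\|.*$", "", levels(f)),
                       time_point = sub("^.*\\|", "", levels(f)),
                       stringsAsFactors = FALSE)
  structure(list(means = means,
                 group_sizes = stats::setNames(as.integer(sizes), levels(f)),
                 groups = groups,
                 gene_ids = norm$gene_ids),
            class = "group_means")
}

#' Look up a group mean
#'
#' @param gm a [group_means()] object.
#' @param gene gene symbol; a gene absent from the universe yields 0 with a
#'   warning.
#' @param cell_type,time_point group labels; an unknown group is an error.
#' @return The mean log-normalized expression of `gene` in that group.
#' @export
group_mean <- function(gm, gene, cell_type, time_point) {
  stopifnot(inherits(gm, "group_means"))
  key <- group_key(cell_type, time_point)
  if (!key %in% colnames(gm$means)) {
    stop_validation("no cells in group (", cell_type, ", ", time_point, ")")
  }
  if (!gene %in% rownames(gm$means)) {
    warning("gene '", gene, "' absent from the gene universe; mean taken as 0")
    return(0)
  }
  gm$means[gene, key]
}

#' Export group means as a long table
#'
#' @param gm a [group_means()] object.
#' @return Data frame with columns `cell_type`, `time_point`, `gene`,
#'   `mean`, `n_cells`.
#' @export
group_means_table <- function(gm) {
  stopifnot(inherits(gm, "group_means"))
  keys <- colnames(gm$means)
  data.frame(
    cell_type = rep(gm$groups$cell_type[match(keys, gm$groups$key)],
                    each = nrow(gm$means)),
    time_point = rep(gm$groups$time_point[match(keys, gm$groups$key)],
                     each = nrow(gm$means)),
    gene = rep(rownames(gm$means), times = length(keys)),
    mean = as.vector(gm$means),
    n_cells = rep(as.integer(gm$group_sizes[keys]), each = nrow(gm$means)),
    stringsAsFactors = FALSE)
}
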