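# Core containers: UMI count matrix, per-cell annotation, ligand-receptor
# pair table, ortholog map. All gene-symbol matching is case-sensitive
# (Apoe vs APOE is meaningful across mouse/human).

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("lrperm_validation_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("lrperm_format_error", "error")))
}

#' Construct a UMI count matrix
#'
#' A `count_matrix` holds a genes x cells matrix of non-negative integer
#' UMI counts together with ordered gene and cell identifiers. Counts are
#' stored sparsely (`Matrix::dgCMatrix`).
#'
#' @param values genes x cells matrix (base or `Matrix`) of non-negative
#'   integer counts.
#' @param gene_ids character vector of unique gene symbols, one per row.
#' @param cell_ids character vector of unique cell identifiers, one per
#'   column.
#' @return A `count_matrix` object.
#' @examples
#' m <- count_matrix(matrix(c(2, 0, 0, 0, 0, 5), nrow = 3, byrow = TRUE),
#'                   gene_ids = c("g1", "g2", "g3"), cell_ids = c("c1", "c2"))
#' library_sizes(m)
#' @export
count_matrix <- function(values,
                         gene_ids = rownames(values),
                         cell_ids = colnames(values)) {
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  x <- values@x
  if (any(x < 0)) stop_validation("count matrix contains negative entries")
  if (any(x != round(x))) stop_validation("count matrix contains non-integer entries")
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop_validation("gene_ids and cell_ids are required")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values)) {
    stop_format("number of gene_ids (", length(gene_ids),
                ") does not match matrix rows (", nrow(values), ")")
  }
  if (length(cell_ids) != ncol(values)) {
    stop_format("number of cell_ids (", length(cell_ids),
                ") does not match matrix columns (", ncol(values), ")")
  }
  if (anyDuplicated(gene_ids)) stop_validation("gene_ids are not unique")
  if (anyDuplicated(cell_ids)) stop_validation("cell_ids are not unique")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d non-zero entries\n",
              nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' Read a CellRanger-style Matrix-Market count triplet
#'
#' Reads `matrix.mtx` (coordinate *integer* Matrix-Market; `real` matrices
#' are rejected because UMI counts are integers by definition) together
#' with one-identifier-per-line `features` and `barcodes` files. For
#' multi-column feature files (e.g. id / symbol TSVs) the first column is
#' used.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param features_path path to the gene identifier file (one per matrix row).
#' @param barcodes_path path to the cell identifier file (one per matrix column).
#' @return A [count_matrix()].
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path) {
  header <- readLines(matrix_path, n = 1L)
  banner <- tolower(strsplit(trimws(header), "[[:space:]]+")[[1]])
  if (length(banner) < 4 || banner[1] != "%%matrixmarket" ||
      banner[2] != "matrix" || banner[3] != "coordinate") {
    stop_format("not a Matrix-Market coordinate file: ", matrix_path)
  }
  if (banner[4] != "integer") {
    stop_format("Matrix-Market field must be 'integer' for UMI counts, got '",
                banner[4], "'")
  }
  m <- Matrix::readMM(matrix_path)
  first_col <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    vapply(strsplit(lines, "[\t,]"), `[`, character(1), 1L)
  }
  genes <- first_col(features_path)
  cells <- first_col(barcodes_path)
  if (length(genes) != nrow(m)) {
    stop_format("features file has ", length(genes),
                " identifiers but matrix header declares ", nrow(m), " rows")
  }
  if (length(cells) != ncol(m)) {
    stop_format("barcodes file has ", length(cells),
                " identifiers but matrix header declares ", ncol(m), " columns")
  }
  count_matrix(m, gene_ids = genes, cell_ids = cells)
}

#' Write a count matrix as a Matrix-Market triplet
#'
#' Writes the coordinate *integer* Matrix-Market format (plus features and
#' barcodes files) so that [read_counts_mtx()] round-trips values and
#' identifier order exactly.
#'
#' @param counts a [count_matrix()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default `""` giving `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return Invisibly, the three paths written.
#' @export
write_counts_mtx <- function(counts, dir, prefix = "") {
  stopifnot(inherits(counts, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "features.tsv", "barcodes.tsv")))
  trip <- Matrix::summary(counts$values)
  con <- file(paths[1], "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(counts$values), ncol(counts$values), nrow(trip))), con)
  if (nrow(trip) > 0) {
    writeLines(paste(trip$i, trip$j, as.integer(trip$x)), con)
  }
  writeLines(counts$gene_ids, paths[2])
  writeLines(counts$cell_ids, paths[3])
  invisible(paths)
}

#' Read a dense delimited count table
#'
#' Alternative input format: genes in rows, cells in columns, header row of
#' cell identifiers, first column of gene symbols. Delimiter inferred from
#' the file extension (`.csv` vs tab).
#'
#' @param path path to the delimited file.
#' @return A [count_matrix()].
#' @export
read_counts_dense <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  count_matrix(as.matrix(df), gene_ids = rownames(df), cell_ids = colnames(df))
}

#' Default label vocabularies
#'
#' The study design the package emulates: two sorted populations (microglia,
#' NSPCs) across three time points (uninjured, and day 1 / day 7 after
#' photothrombotic cortical injury).
#'
#' @return A list with `cell_type` and `time_point` character vectors; the
#'   `time_point` vector is ordered.
#' @export
default_vocab <- function() {
  list(cell_type = c("microglia", "NSPC"),
       time_point = c("uninjured", "PT_D1", "PT_D7"))
}

#' Construct a per-cell annotation table
#'
#' @param df data frame with columns `cell_id`, `cell_type`, `time_point`.
#' @param vocab list with `cell_type` and `time_point` label vocabularies;
#'   every label in `df` must be drawn from them. `time_point` order defines
#'   the factor level order.
#' @return A `cell_annotation` data frame with factor labels.
#' @export
cell_annotation <- function(df, vocab = default_vocab()) {
  need <- c("cell_id", "cell_type", "time_point")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_format("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id)) {
    stop_validation("duplicate cell_id in annotation: ",
                    paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  }
  for (col in c("cell_type", "time_point")) {
    vals <- as.character(df[[col]])
    if (any(is.na(vals)) || any(!nzchar(vals))) {
      stop_validation("empty ", col, " label in annotation")
    }
    bad <- setdiff(unique(vals), vocab[[col]])
    if (length(bad)) {
      stop_validation(col, " label(s) outside vocabulary {",
                      paste(vocab[[col]], collapse = ", "), "}: ",
                      paste(bad, collapse = ", "))
    }
    df[[col]] <- factor(vals, levels = vocab[[col]])
  }
  structure(df, class = c("cell_annotation", "data.frame"), vocab = vocab)
}

#' Read a per-cell annotation table
#'
#' Delimited text with header columns `cell_id`, `cell_type`, `time_point`;
#' labels are validated against `vocab`.
#'
#' @inheritParams cell_annotation
#' @param path path to the delimited file (`.csv` or tab-separated).
#' @return A `cell_annotation` data frame.
#' @export
read_annotation <- function(path, vocab = default_vocab()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  cell_annotation(df, vocab = vocab)
}

#' Align an annotation with a count matrix
#'
#' Every analyzed cell needs a label: a matrix cell absent from the
#' annotation is an error. Annotated cells absent from the matrix are
#' dropped with a warning (they may have been removed by QC).
#'
#' @param ann a `cell_annotation`.
#' @param counts a [count_matrix()] or an object with `cell_ids`.
#' @return The annotation reordered to the matrix's cell order.
#' @export
align_annotation <- function(ann, counts) {
  cell_ids <- if (is.character(counts)) counts else counts$cell_ids
  missing_cells <- setdiff(cell_ids, ann$cell_id)
  if (length(missing_cells)) {
    stop_validation("cells in matrix but not in annotation: ",
                    paste(utils::head(missing_cells, 5), collapse = ", "),
                    if (length(missing_cells) > 5) ", ..." else "")
  }
  extra <- setdiff(ann$cell_id, cell_ids)
  if (length(extra)) {
    warning(length(extra), " annotated cell(s) absent from the matrix were ignored")
  }
  out <- ann[match(cell_ids, ann$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(ann), vocab = attr(ann, "vocab"))
}

#' Construct a ligand-receptor pair table
#'
#' @param df data frame with columns `ligand`, `receptor` and optionally
#'   `pathway`.
#' @return An `lr_pairs` data frame with unique (ligand, receptor) rows.
#' @export
lr_pairs <- function(df) {
  need <- c("ligand", "receptor")
  if (!all(need %in% names(df))) {
    stop_format("ligand-receptor table needs columns: ligand, receptor")
  }
  df <- as.data.frame(df)
  df$ligand <- as.character(df$ligand)
  df$receptor <- as.character(df$receptor)
  if (!"pathway" %in% names(df)) df$pathway <- rep(NA_character_, nrow(df))
  df <- df[, c("ligand", "receptor", "pathway")]
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor)) ||
      any(is.na(df$ligand)) || any(is.na(df$receptor))) {
    stop_validation("empty gene symbol in ligand-receptor table")
  }
  df <- df[!duplicated(df[, c("ligand", "receptor")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("lr_pairs", "data.frame"))
}

#' Read a ligand-receptor pair table
#'
#' CSV/TSV with header `ligand,receptor[,pathway]`.
#'
#' @param path path to the delimited file.
#' @return An `lr_pairs` data frame.
#' @export
read_lr_pairs <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lr_pairs(utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE))
}

#' Read an ortholog mapping table
#'
#' Two-column delimited text with header `source,target` (e.g. human symbol
#' to mouse symbol). One source symbol may map to several targets.
#'
#' @param path path to the delimited file.
#' @return A data frame with columns `source`, `target`.
#' @export
read_ortholog_map <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  ortholog_map(df)
}

#' Construct an ortholog map
#'
#' @param df data frame with columns `source`, `target`.
#' @return An `ortholog_map` data frame.
#' @export
ortholog_map <- function(df) {
  if (!all(c("source", "target") %in% names(df))) {
    stop_format("ortholog map needs columns: source, target")
  }
  df <- as.data.frame(df)[, c("source", "target")]
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  if (any(!nzchar(df$source)) || any(!nzchar(df$target)) ||
      any(is.na(df$source)) || any(is.na(df$target))) {
    stop_validation("empty symbol in ortholog map")
  }
  if (nrow(df) == 0) stop_validation("ortholog map is empty")
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ortholog_map", "data.frame"))
}

#' Map a ligand-receptor table through an ortholog table
#'
#' A pair is emitted only when both its ligand and receptor map; unmapped
#' pairs are dropped and counted. Under `policy = "expand"` a one-to-many
#' ortholog relation emits the Cartesian product of mapped symbols
#' (de-duplicated); under `policy = "drop"` pairs touching a one-to-many
#' symbol are dropped and counted separately. Matching is case-sensitive.
#'
#' @param pairs an [lr_pairs()] table (e.g. human symbols).
#' @param omap an [ortholog_map()].
#' @param policy how to resolve one-to-many orthologs: `"expand"` (default)
#'   or `"drop"`.
#' @return An `lr_pairs` table of mapped pairs, with a `"mapping_report"`
#'   attribute: a list with `n_input`, `n_output`, `n_dropped_unmapped`,
#'   `n_dropped_multi` and `policy`.
#' @examples
#' p <- lr_pairs(data.frame(ligand = "APOE", receptor = "LRP8"))
#' m <- ortholog_map(data.frame(source = c("APOE", "LRP8"),
#'                              target = c("Apoe", "Lrp8")))
#' map_orthologs(p, m)
#' @export
map_orthologs <- function(pairs, omap, policy = c("expand", "drop")) {
  policy <- match.arg(policy)
  stopifnot(inherits(pairs, "lr_pairs"))
  targets <- split(omap$target, omap$source)
  n_unmapped <- 0L
  n_multi <- 0L
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    lt <- targets[[pairs$ligand[i]]]
    rt <- targets[[pairs$receptor[i]]]
    if (is.null(lt) || is.null(rt)) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    if (policy == "drop" && (length(lt) > 1 || length(rt) > 1)) {
      n_multi <- n_multi + 1L
      next
    }
    grid <- expand.grid(ligand = lt, receptor = rt,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$pathway <- pairs$pathway[i]
    out[[i]] <- grid
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(ligand = character(), receptor = character(),
                      pathway = character())
  }
  res <- res[!duplicated(res[, c("ligand", "receptor")]), , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            class = c("lr_pairs", "data.frame"),
            mapping_report = list(n_input = nrow(pairs),
                                  n_output = nrow(res),
                                  n_dropped_unmapped = n_unmapped,
                                  n_dropped_multi = n_multi,
                                  policy = policy))
}
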