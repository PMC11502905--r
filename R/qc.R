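# Three-rule cell quality control for plate-based UMI data:
# (1) MAD-based doublet exclusion on library size, (2) UMI floor,
# (3) mitochondrial-fraction ceiling. Rules are applied in that order and
# each removed cell is attributed to the first rule that caught it.

#' QC parameter set
#'
#' @param mad_k doublets are cells whose library size exceeds
#'   `median + mad_k * MAD` of the pre-filter library-size distribution.
#'   Default 3.
#' @param min_umi library-size floor in UMIs; cells with fewer are
#'   discarded. Default 1000. Inclusive by default (a cell with exactly
#'   `min_umi` UMIs is retained); see `umi_strict`.
#' @param max_mito_pct ceiling on the percentage of the library mapping to
#'   mitochondrial genes; cells strictly above are discarded. Default 25.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#'   Default `"mt-"`, matched case-insensitively unless
#'   `mito_ignore_case = FALSE`.
#' @param mad_constant multiplier applied to the raw MAD (median of
#'   absolute deviations from the median). Default 1 (unscaled); set to
#'   1.4826 for the normal-consistency convention.
#' @param umi_strict if `TRUE`, the UMI floor is exclusive (strictly more
#'   than `min_umi` required). Default `FALSE`.
#' @param mito_ignore_case whether prefix matching ignores symbol case.
#' @return A `qc_params` list.
#' @export
qc_params <- function(mad_k = 3, min_umi = 1000, max_mito_pct = 25,
                      mito_prefix = "mt-", mad_constant = 1,
                      umi_strict = FALSE, mito_ignore_case = TRUE) {
  if (mad_k <= 0 || min_umi <= 0 || max_mito_pct <= 0 || mad_constant <= 0) {
    stop_validation("QC thresholds must be strictly positive")
  }
  if (max_mito_pct > 100) stop_validation("max_mito_pct cannot exceed 100")
  structure(list(mad_k = mad_k, min_umi = min_umi,
                 max_mito_pct = max_mito_pct, mito_prefix = mito_prefix,
                 mad_constant = mad_constant, umi_strict = umi_strict,
                 mito_ignore_case = mito_ignore_case),
            class = "qc_params")
}

#' Per-cell library sizes
#'
#' @param counts a [count_matrix()].
#' @return Named numeric vector of total UMIs per cell (column sums).
#' @export
library_sizes <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  stats::setNames(Matrix::colSums(counts$values), counts$cell_ids)
}

#' Flag putative doublets by library size
#'
#' A cell is flagged when its total UMI count exceeds
#' `median + k * constant * MAD`, where MAD is the median of absolute
#' deviations from the median (unscaled by default). The rule is one-sided:
#' doublets carry roughly twice a singlet's library, so only the upper tail
#' is flagged. When MAD is 0 the threshold degenerates to "above the
#' median".
#'
#' @param totals per-cell library sizes.
#' @param k number of MADs above the median. Default 3.
#' @param constant MAD scaling constant, default 1 (unscaled).
#' @return Logical vector, `TRUE` for putative doublets.
#' @examples
#' mad_doublet_mask(c(100, 110, 120, 130, 5000))  # flags only the 5000 cell
#' @export
mad_doublet_mask <- function(totals, k = 3, constant = 1) {
  if (length(totals) == 0) stop_validation("totals must be non-empty")
  med <- stats::median(totals)
  mad_raw <- stats::median(abs(totals - med))
  totals > med + k * constant * mad_raw
}

#' Per-cell mitochondrial UMI percentages
#'
#' 100 times the fraction of each cell's library mapping to genes whose
#' symbol starts with `prefix`. Cells with an empty library get 0. If no
#' gene matches the prefix a warning is emitted and all percentages are 0.
#'
#' @param counts a [count_matrix()].
#' @param prefix mitochondrial symbol prefix, default `"mt-"`.
#' @param ignore_case match the prefix case-insensitively (default `TRUE`).
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @export
mito_percentages <- function(counts, prefix = "mt-", ignore_case = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  genes <- if (ignore_case) tolower(counts$gene_ids) else counts$gene_ids
  pref <- if (ignore_case) tolower(prefix) else prefix
  is_mito <- startsWith(genes, pref)
  totals <- Matrix::colSums(counts$values)
  if (!any(is_mito)) {
    warning("no gene symbol starts with '", prefix, "'; mitochondrial ",
            "percentages are all zero")
    mito <- numeric(length(totals))
  } else {
    mito <- Matrix::colSums(counts$values[is_mito, , drop = FALSE])
  }
  pct <- ifelse(totals > 0, 100 * mito / totals, 0)
  stats::setNames(pct, counts$cell_ids)
}

#' Apply the three-rule cell QC
#'
#' Rules in order: (1) the doublet mask is computed on *all* input cells
#' and doublets removed; (2) cells below the UMI floor are removed;
#' (3) cells above the mitochondrial ceiling are removed. Each removed cell
#' is attributed to the first rule that removed it. Surviving cells keep
#' their original order.
#'
#' @param counts a [count_matrix()].
#' @param params a [qc_params()] set.
#' @return A list with `counts` (the filtered [count_matrix()]) and
#'   `report` (a `qc_report`: counts per fate plus a per-cell ledger of
#'   `cell_id`, `library_size`, `mito_pct`, `fate`).
#' @export
apply_qc <- function(counts, params = qc_params()) {
  stopifnot(inherits(counts, "count_matrix"), inherits(params, "qc_params"))
  totals <- library_sizes(counts)
  mito <- mito_percentages(counts, prefix = params$mito_prefix,
                           ignore_case = params$mito_ignore_case)
  doublet <- mad_doublet_mask(totals, k = params$mad_k,
                              constant = params$mad_constant)
  low_umi <- if (params$umi_strict) totals <= params$min_umi else totals < params$min_umi
  high_mito <- mito > params$max_mito_pct

  fate <- rep("retained", length(totals))
  fate[high_mito] <- "high_mito"
  fate[low_umi] <- "low_umi"
  fate[doublet] <- "doublet"

  keep <- fate == "retained"
  if (!any(keep)) {
    stop_validation("empty after QC: no cell survived the three filters")
  }
  ledger <- data.frame(cell_id = counts$cell_ids,
                       library_size = as.numeric(totals),
                       mito_pct = as.numeric(mito),
                       fate = fate,
                       stringsAsFactors = FALSE)
  report <- structure(list(n_input = length(totals),
                           n_doublet_removed = sum(fate == "doublet"),
                           n_low_umi_removed = sum(fate == "low_umi"),
                           n_high_mito_removed = sum(fate == "high_mito"),
                           n_retained = sum(keep),
                           params = unclass(params),
                           ledger = ledger),
                      class = "qc_report")
  filtered <- count_matrix(counts$values[, keep, drop = FALSE],
                           gene_ids = counts$gene_ids,
                           cell_ids = counts$cell_ids[keep])
  list(counts = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("cell QC: %d cells in -> %d retained ",
                     "(%d doublet, %d low-UMI, %d high-mito removed)\n"),
              x$n_input, x$n_retained, x$n_doublet_removed,
              x$n_low_umi_removed, x$n_high_mito_removed))
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}
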