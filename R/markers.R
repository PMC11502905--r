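# Marker-gene detection: per-gene Wilcoxon rank-sum tests with Bonferroni
# correction over the full gene universe, log2 fold changes on
# back-transformed group means, and hypergeometric signature-overlap
# tabulation for cross-study gene-set comparisons.

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum statistic of the first sample with midranks for ties. The
#' p-value is exact — computed by enumerating every assignment of the
#' combined ranks to the two groups — whenever `choose(n, |a|)` does not
#' exceed `exact_limit`; otherwise a normal approximation with tie
#' correction and continuity correction is used. The two-sided p is the
#' probability of a rank sum at least as far from its null mean as the
#' observed one.
#'
#' @param a,b numeric samples (both non-empty).
#' @param method `"auto"` (default), `"exact"`, or `"normal"`.
#' @param exact_limit largest number of enumerated assignments for the
#'   exact path under `method = "auto"`. Default 10000.
#' @return A list with `statistic` (rank sum of `a`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 2/20 = 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, method = c("auto", "exact", "normal"),
                              exact_limit = 10000) {
  method <- match.arg(method)
  if (length(a) == 0 || length(b) == 0) {
    stop_validation("both samples must be non-empty")
  }
  m <- length(a)
  n <- m + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(m)])
  e_w <- m * (n + 1) / 2
  use_exact <- method == "exact" ||
    (method == "auto" && choose(n, m) <= exact_limit)
  if (use_exact) {
    sets <- utils::combn(n, m)
    ws <- colSums(matrix(r[sets], nrow = m))
    p <- mean(abs(ws - e_w) >= abs(w - e_w) - 1e-9)
    list(statistic = w, p_value = p, method = "exact")
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- m * length(b) / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w - e_w) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    list(statistic = w, p_value = p, method = "normal")
  }
}

#' Log2 fold change between two group means
#'
#' Computed on back-transformed group means of log-normalized expression
#' (`exp(mean) - 1`), stabilized with a pseudocount.
#'
#' @param mean_in,mean_out non-negative back-transformed group means.
#' @param pseudo pseudocount, default 1e-9.
#' @return `log2((mean_in + pseudo) / (mean_out + pseudo))`.
#' @export
log2_fold_change <- function(mean_in, mean_out, pseudo = 1e-9) {
  log2((mean_in + pseudo) / (mean_out + pseudo))
}

#' Marker genes of one group by Wilcoxon rank-sum
#'
#' Tests every gene in the universe (target group versus all other cells),
#' applies a Bonferroni correction over the number of genes tested, and
#' flags genes passing the retention rule
#' `log2fc >= fc_threshold AND p_adj < p_threshold`.
#'
#' @param norm a [log_normalize()]d matrix.
#' @param labels per-cell group labels, aligned with `norm`'s cells.
#' @param target the group to find markers for; its complement is the
#'   reference.
#' @param fc_threshold log2 fold-change threshold, default 0.25.
#' @param p_threshold adjusted-p threshold, default 0.001.
#' @param pseudo pseudocount for the fold change, default 1e-9.
#' @param only_positive if `TRUE` (default) the retention rule uses the
#'   signed fold change, so only up-regulated genes are retained.
#' @return A data frame with one row per gene: `gene`, `group`, `log2fc`,
#'   `p_raw`, `p_adj`, `mean_in`, `mean_out`, `retained`.
#' @export
find_markers <- function(norm, labels, target, fc_threshold = 0.25,
                         p_threshold = 0.001, pseudo = 1e-9,
                         only_positive = TRUE) {
  stopifnot(inherits(norm, "normalized_matrix"))
  labels <- as.character(labels)
  if (length(labels) != ncol(norm$values)) {
    stop_validation("labels length does not match number of cells")
  }
  in_grp <- labels == target
  if (!any(in_grp)) stop_validation("target group '", target, "' has no cells")
  if (all(in_grp)) stop_validation("target group is all cells; no complement to test against")
  n_genes <- nrow(norm$values)
  p_raw <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    p_raw[g] <- wilcoxon_rank_sum(norm$values[g, in_grp],
                                  norm$values[g, !in_grp])$p_value
  }
  mean_in <- expm1(rowMeans(norm$values[, in_grp, drop = FALSE]))
  mean_out <- expm1(rowMeans(norm$values[, !in_grp, drop = FALSE]))
  l2fc <- log2_fold_change(mean_in, mean_out, pseudo = pseudo)
  p_adj <- pmin(1, p_raw * n_genes)
  fc_ok <- if (only_positive) l2fc >= fc_threshold else abs(l2fc) >= fc_threshold
  data.frame(gene = norm$gene_ids, group = target,
             log2fc = l2fc, p_raw = p_raw, p_adj = p_adj,
             mean_in = mean_in, mean_out = mean_out,
             retained = fc_ok & p_adj < p_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap between two gene signatures
#'
#' Tabulates shared and unique genes between two sets drawn from a common
#' universe, with a one-sided hypergeometric enrichment p-value
#' (probability of at least the observed intersection when drawing
#' `|set_b|` genes from the universe with `|set_a|` successes).
#'
#' @param set_a,set_b character vectors of gene symbols, subsets of
#'   `universe`.
#' @param universe character vector of all candidate symbols.
#' @return A `signature_overlap` list: `set_a_size`, `set_b_size`,
#'   `intersection_size`, `union_size`, `universe_size`, `enrichment_p`,
#'   `shared_genes`.
#' @examples
#' signature_overlap(letters[1:5], letters[c(1:3, 6)], letters[1:10])
#' @export
signature_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    stop_validation("both gene sets must be contained in the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), length(universe) - length(set_a),
                     length(set_b), lower.tail = FALSE)
  structure(list(set_a_size = length(set_a),
                 set_b_size = length(set_b),
                 intersection_size = k,
                 union_size = length(union(set_a, set_b)),
                 universe_size = length(universe),
                 enrichment_p = p,
                 shared_genes = sort(intersect(set_a, set_b))),
            class = "signature_overlap")
}

#' @export
print.signature_overlap <- function(x, ...) {
  cat(sprintf(paste0("signature overlap: |A|=%d, |B|=%d, shared=%d, ",
                     "union=%d of %d; hypergeometric p = %.3g\n"),
              x$set_a_size, x$set_b_size, x$intersection_size,
              x$union_size, x$universe_size, x$enrichment_p))
  invisible(x)
}
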