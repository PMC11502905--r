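# Independent oracles used across the suite. These are written directly
# from the textual rules and never call the implementation paths they
# check.

# Brute-force three-rule QC: recompute everything from a base matrix.
brute_qc_retained <- function(mat, mad_k = 3, min_umi = 1000,
                              max_mito_pct = 25, mito_prefix = "mt-") {
  totals <- colSums(mat)
  med <- median(sort(totals))
  mad_raw <- median(sort(abs(totals - med)))
  doublet <- totals > med + mad_k * mad_raw
  mito_rows <- startsWith(tolower(rownames(mat)), tolower(mito_prefix))
  mito_pct <- ifelse(totals > 0,
                     100 * colSums(mat[mito_rows, , drop = FALSE]) / totals, 0)
  keep <- !doublet & totals >= min_umi & mito_pct <= max_mito_pct
  colnames(mat)[keep]
}

# A small random count matrix with gene/cell names and a mito block.
random_count_mat <- function(n_genes, n_cells, lambda = 3, n_mito = 2) {
  mat <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes)
  mito <- if (n_mito > 0) paste0("mt-", seq_len(n_mito)) else character()
  rownames(mat) <- c(mito, sprintf("gene%03d", seq_len(n_genes - n_mito)))
  colnames(mat) <- sprintf("cell%03d", seq_len(n_cells))
  mat
}

# All distinct permutations of a vector (multiset-aware).
all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (x in unique(v)) {
    rest <- v[-match(x, v)]
    for (p in all_permutations(rest)) out[[length(out) + 1]] <- c(x, p)
  }
  out
}

# Exhaustive permutation p-value for one ligand-receptor condition on a
# tiny instance: recompute group means under every distinct joint-label
# assignment, straight from the score definition.
exhaustive_perm_p <- function(values, labels, ligand, receptor,
                              sender_key, receiver_key) {
  score_under <- function(lab) {
    ml <- mean(values[ligand, lab == sender_key])
    mr <- mean(values[receptor, lab == receiver_key])
    (ml + mr) / 2
  }
  observed <- score_under(labels)
  perms <- all_permutations(labels)
  nulls <- vapply(perms, score_under, numeric(1))
  list(observed = observed,
       p = mean(nulls >= observed - 1e-12),
       nulls = nulls)
}

# Two-sided exact Wilcoxon p by enumerating every rank assignment.
enum_wilcox_p <- function(a, b) {
  m <- length(a)
  n <- m + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(m)])
  e_w <- m * (n + 1) / 2
  sets <- combn(n, m)
  ws <- colSums(matrix(r[sets], nrow = m))
  mean(abs(ws - e_w) >= abs(w - e_w) - 1e-9)
}
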