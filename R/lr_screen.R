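# Ligand-receptor cross-talk screen between two cell populations.
#
# The interaction score of a pair at a time point is the mean of (i) the
# average log-normalized ligand expression in the sender population and
# (ii) the average log-normalized receptor expression in the receiver
# population. Significance comes from an empirical permutation null: the
# joint (cell_type, time_point) label vector is shuffled across all cells,
# group means are recomputed under the shuffled labels, and every pair is
# re-scored. One label shuffle serves every pair, and the empirical p-value
# is the proportion of null scores greater than or equal to the observed
# score (ties count as "at least as large"; p = 0 is attainable).

#' Screen configuration
#'
#' @param sender_type,receiver_type the two cell-type labels screened
#'   against each other.
#' @param time_points time points to screen; default `NULL` means every
#'   time point present in the annotation.
#' @param n_perm number of label shuffles, default 1000.
#' @param seed integer seed for the permutation stream.
#' @param direction_mode `"both-directions"` (default) scores each pair
#'   with the ligand in either population; `"ligand-in-sender"` scores only
#'   ligand-in-`sender_type`.
#' @param shuffle_mode `"joint"` (default) permutes the joint
#'   (cell_type, time_point) label across cells in one shuffle;
#'   `"independent"` permutes the two label columns independently.
#' @param smooth_p if `TRUE`, use the (count + 1) / (n_perm + 1) estimator
#'   instead of the plain proportion. Default `FALSE`.
#' @return A `screen_config` list.
#' @export
screen_config <- function(sender_type, receiver_type, time_points = NULL,
                          n_perm = 1000, seed = 1,
                          direction_mode = c("both-directions", "ligand-in-sender"),
                          shuffle_mode = c("joint", "independent"),
                          smooth_p = FALSE) {
  if (n_perm < 1) stop_validation("n_perm must be at least 1")
  structure(list(sender_type = sender_type, receiver_type = receiver_type,
                 time_points = time_points, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 direction_mode = match.arg(direction_mode),
                 shuffle_mode = match.arg(shuffle_mode),
                 smooth_p = smooth_p),
            class = "screen_config")
}

#' Interaction score of one ligand-receptor pair
#'
#' The mean of the sender group's average ligand expression and the
#' receiver group's average receptor expression at one time point.
#'
#' @param gm a [group_means()] object.
#' @param ligand,receptor gene symbols (a symbol absent from the universe
#'   contributes mean 0 with a warning).
#' @param sender,receiver cell-type labels.
#' @param time_point time-point label.
#' @return A non-negative scalar score.
#' @export
interaction_score <- function(gm, ligand, receptor, sender, receiver,
                              time_point) {
  (group_mean(gm, ligand, sender, time_point) +
     group_mean(gm, receptor, receiver, time_point)) / 2
}

#' Empirical permutation p-value
#'
#' The proportion of null scores greater than or equal to the observed
#' score. Ties count towards the numerator, and 0 is attainable. A small
#' relative tolerance (1e-9) guards the tie comparison against round-off
#' when the null recomputes the observed grouping exactly.
#'
#' @param observed observed score.
#' @param null_scores numeric vector of null scores (non-empty; `NA`s are
#'   dropped).
#' @param smooth if `TRUE`, return `(count + 1) / (n + 1)`.
#' @return p-value in `[0, 1]`.
#' @examples
#' empirical_pvalue(5, 1:10)  # 6/10
#' @export
empirical_pvalue <- function(observed, null_scores, smooth = FALSE) {
  null_scores <- null_scores[!is.na(null_scores)]
  n <- length(null_scores)
  if (n == 0) stop_validation("null_scores must be non-empty")
  tol <- 1e-9 * max(1, abs(observed))
  count <- sum(null_scores >= observed - tol)
  if (smooth) (count + 1) / (n + 1) else count / n
}

# Build the condition table (pair x time point x direction) for a screen.
# Pairs with either gene absent from the universe are dropped with a
# warning; an empty table is the "no testable pairs" error.
screen_conditions <- function(gene_ids, pairs, cfg, time_points) {
  testable <- pairs$ligand %in% gene_ids & pairs$receptor %in% gene_ids
  if (!all(testable)) {
    warning(sum(!testable), " pair(s) dropped: ligand or receptor absent ",
            "from the gene universe")
  }
  pairs <- pairs[testable, , drop = FALSE]
  if (nrow(pairs) == 0) stop_validation("no testable pairs: no ligand-receptor ",
                                        "pair has both genes in the gene universe")
  dirs <- data.frame(sender = cfg$sender_type, receiver = cfg$receiver_type,
                     stringsAsFactors = FALSE)
  if (cfg$direction_mode == "both-directions") {
    dirs <- rbind(dirs, data.frame(sender = cfg$receiver_type,
                                   receiver = cfg$sender_type))
  }
  conds <- expand.grid(pair = seq_len(nrow(pairs)),
                       time_point = time_points,
                       dir = seq_len(nrow(dirs)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(ligand = pairs$ligand[conds$pair],
             receptor = pairs$receptor[conds$pair],
             pathway = pairs$pathway[conds$pair],
             sender = dirs$sender[conds$dir],
             receiver = dirs$receiver[conds$dir],
             time_point = conds$time_point,
             stringsAsFactors = FALSE)
}

# Genes x groups mean matrix for an arbitrary key assignment; groups absent
# from `levels` come back as NA columns.
mean_by_key <- function(x_t, key, levels) {
  f <- factor(key, levels = levels)
  counts <- tabulate(f, nbins = length(levels))
  sums <- matrix(0, nrow = length(levels), ncol = ncol(x_t),
                 dimnames = list(levels, colnames(x_t)))
  present <- rowsum(x_t, f)
  sums[rownames(present), ] <- present
  means <- sums / counts
  t(means)
}

#' Permutation null for a ligand-receptor screen
#'
#' For each of `n_perm` iterations the (cell_type, time_point) labels are
#' shuffled across all cells (jointly by default, preserving the label
#' multiset), group means are recomputed under the shuffled labels, and
#' every configured condition is re-scored. Deterministic given
#' `cfg$seed`.
#'
#' @param norm a [log_normalize()]d matrix.
#' @param ann a `cell_annotation` covering every cell in `norm`.
#' @param pairs an [lr_pairs()] table.
#' @param cfg a [screen_config()].
#' @return A list with `conditions` (data frame), `observed` (scores under
#'   the true labels) and `null_scores` (conditions x n_perm matrix).
#' @export
permutation_null <- function(norm, ann, pairs, cfg) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(cfg, "screen_config"))
  ann <- align_annotation(ann, norm)
  types <- as.character(ann$cell_type)
  times <- as.character(ann$time_point)
  for (ct in c(cfg$sender_type, cfg$receiver_type)) {
    if (!ct %in% types) stop_validation("cell type '", ct, "' absent from annotation")
  }
  time_points <- cfg$time_points
  if (is.null(time_points)) {
    time_points <- levels(ann$time_point)[levels(ann$time_point) %in% times]
  } else if (!all(time_points %in% times)) {
    stop_validation("time point(s) absent from annotation: ",
                    paste(setdiff(time_points, times), collapse = ", "))
  }
  conds <- screen_conditions(norm$gene_ids, pairs, cfg, time_points)
  genes <- unique(c(conds$ligand, conds$receptor))
  x_t <- t(norm$values[genes, , drop = FALSE])  # cells x genes

  key <- group_key(types, times)
  lev <- sort(unique(c(key, group_key(conds$sender, conds$time_point),
                       group_key(conds$receiver, conds$time_point))))
  missing_grp <- setdiff(lev, key)
  if (length(missing_grp)) {
    stop_validation("no cells in group(s): ", paste(missing_grp, collapse = ", "))
  }
  lig_idx <- cbind(match(conds$ligand, genes),
                   match(group_key(conds$sender, conds$time_point), lev))
  rec_idx <- cbind(match(conds$receptor, genes),
                   match(group_key(conds$receiver, conds$time_point), lev))
  score_of <- function(means) (means[lig_idx] + means[rec_idx]) / 2

  observed <- score_of(mean_by_key(x_t, key, lev))
  n_cells <- length(key)
  null_scores <- withr::with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_perm), function(i) {
      k <- if (cfg$shuffle_mode == "joint") {
        key[sample.int(n_cells)]
      } else {
        group_key(types[sample.int(n_cells)], times[sample.int(n_cells)])
      }
      score_of(mean_by_key(x_t, k, lev))
    }, numeric(nrow(conds)))
  })
  null_scores <- matrix(null_scores, nrow = nrow(conds))
  list(conditions = conds, observed = observed, null_scores = null_scores)
}

#' Run a ligand-receptor cross-talk screen
#'
#' Scores every testable pair in both directions (by default) at every
#' requested time point, builds the shared permutation null, and reports
#' empirical p-values. Identical inputs and seed give identical output.
#'
#' @inheritParams permutation_null
#' @return A data frame with one row per (pair, sender, receiver,
#'   time point): `ligand`, `receptor`, `pathway`, `sender`, `receiver`,
#'   `time_point`, `score`, `p_value`, `n_perm`, `null_mean`, `null_max`,
#'   `count_ge`.
#' @export
lr_screen <- function(norm, ann, pairs, cfg) {
  pn <- permutation_null(norm, ann, pairs, cfg)
  tol <- 1e-9 * pmax(1, abs(pn$observed))
  count_ge <- rowSums(pn$null_scores >= pn$observed - tol, na.rm = TRUE)
  n_eff <- rowSums(!is.na(pn$null_scores))
  p <- if (cfg$smooth_p) (count_ge + 1) / (n_eff + 1) else count_ge / n_eff
  out <- pn$conditions
  out$score <- pn$observed
  out$p_value <- p
  out$n_perm <- cfg$n_perm
  out$null_mean <- rowMeans(pn$null_scores, na.rm = TRUE)
  out$null_max <- apply(pn$null_scores, 1, max, na.rm = TRUE)
  out$count_ge <- as.integer(count_ge)
  class(out) <- c("lr_screen_result", "data.frame")
  out
}

#' Chord-plot adjacency of significant interactions
#'
#' Summarizes screen results as a square sender x receiver matrix of the
#' interactions passing a p-value cutoff — the machine-readable twin of a
#' chord diagram.
#'
#' @param results an [lr_screen()] result (or compatible data frame).
#' @param p_max p-value cutoff, default 0.05.
#' @param value `"count"` (default) counts passing interactions;
#'   `"score"` sums their scores.
#' @return A square numeric matrix, senders in rows, receivers in columns.
#' @export
chord_adjacency <- function(results, p_max = 0.05, value = c("count", "score")) {
  value <- match.arg(value)
  if (nrow(results) == 0) stop_validation("results must be non-empty")
  groups <- sort(unique(c(results$sender, results$receiver)))
  adj <- matrix(0, length(groups), length(groups),
                dimnames = list(sender = groups, receiver = groups))
  pass <- results[results$p_value <= p_max, , drop = FALSE]
  for (i in seq_len(nrow(pass))) {
    inc <- if (value == "count") 1 else pass$score[i]
    adj[pass$sender[i], pass$receiver[i]] <- adj[pass$sender[i], pass$receiver[i]] + inc
  }
  adj
}
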