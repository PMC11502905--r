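# Seeded generator emulating a sorted-plate single-cell experiment: two
# cell populations across three time points on 384-well plates, gene-wise
# negative-binomial UMI counts, a reserved block of mitochondrial ("mt-")
# genes, and optional planted ligand-receptor interactions, cluster
# markers, doublets and high-mitochondrial dying cells. Ground truth is
# returned alongside the data so recovery and calibration tests are
# self-contained.

# The 13 protein-coding genes of the mouse mitochondrial genome; used to
# name the reserved mito block so prefix-based QC is exercised on
# realistic symbols.
MOUSE_MT_GENES <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Co3",
                    "mt-Atp6", "mt-Atp8", "mt-Nd3", "mt-Nd4", "mt-Nd4l",
                    "mt-Nd5", "mt-Nd6", "mt-Cytb")

#' Simulation configuration
#'
#' Defaults emulate the emulated study design: three 384-well plates
#' (1152 cells) of two sorted populations (microglia, NSPCs) across three
#' time points (uninjured, day 1 and day 7 after photothrombosis).
#' Gene-level negative-binomial means are drawn log-normally with a shared
#' dispersion, giving libraries of a few thousand UMIs — typical of
#' plate-based UMI protocols.
#'
#' @param n_plates number of plates, default 3.
#' @param wells_per_plate wells (cells) per plate, default 384.
#' @param cell_types named numeric vector of cell-type proportions
#'   (must sum to 1).
#' @param time_points named numeric vector of time-point proportions in
#'   vocabulary order (must sum to 1).
#' @param n_genes gene universe size (including the mito block).
#' @param gene_mean_log_mean,gene_mean_log_sd log-normal parameters of the
#'   per-gene negative-binomial mean.
#' @param dispersion negative-binomial size (shape) parameter shared by all
#'   genes; smaller is more overdispersed.
#' @param n_mito_genes number of reserved `mt-` genes, default 13.
#' @param mito_frac_healthy expected mitochondrial library fraction of a
#'   healthy cell, default 0.05.
#' @param mito_frac_dying mitochondrial library fraction that dying cells
#'   are re-allocated to, default 0.40 (above the 25 percent QC ceiling).
#' @param doublet_rate fraction of wells receiving two cells, default 0.03.
#' @param dying_rate fraction of cells that are dying, default 0.05.
#' @param planted_pairs `NULL` or a data frame with columns `ligand`,
#'   `receptor`, `sender`, `receiver`, `time_point`, `fold`: the ligand's
#'   mean is multiplied by `fold` in (sender, time_point) and the
#'   receptor's in (receiver, time_point).
#' @param planted_markers `NULL` or a data frame with columns `gene`,
#'   `cell_type`, `fold`: the gene's mean is multiplied by `fold` in that
#'   cell type at every time point.
#' @param gene_ids optional character vector of `n_genes` symbols
#'   overriding the generated names (the first `n_mito_genes` must keep the
#'   `mt-` prefix).
#' @param seed integer seed; the generator is deterministic given the
#'   config and seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_plates = 3, wells_per_plate = 384,
                       cell_types = c(microglia = 0.5, NSPC = 0.5),
                       time_points = c(uninjured = 1/3, PT_D1 = 1/3, PT_D7 = 1/3),
                       n_genes = 500,
                       gene_mean_log_mean = log(4), gene_mean_log_sd = 1,
                       dispersion = 2,
                       n_mito_genes = 13,
                       mito_frac_healthy = 0.05, mito_frac_dying = 0.40,
                       doublet_rate = 0.03, dying_rate = 0.05,
                       planted_pairs = NULL, planted_markers = NULL,
                       gene_ids = NULL, seed = 1) {
  if (n_plates < 1 || wells_per_plate < 1 || n_genes < 1 || n_mito_genes < 0 ||
      dispersion <= 0) {
    stop_validation("plate, well, gene and dispersion settings must be positive")
  }
  for (props in list(cell_types, time_points)) {
    if (is.null(names(props)) || abs(sum(props) - 1) > 1e-8 || any(props < 0)) {
      stop_validation("cell_types and time_points must be named proportions summing to 1")
    }
  }
  if (doublet_rate < 0 || doublet_rate >= 1 || dying_rate < 0 || dying_rate >= 1) {
    stop_validation("doublet_rate and dying_rate must lie in [0, 1)")
  }
  if (mito_frac_dying <= 0 || mito_frac_dying >= 1 ||
      mito_frac_healthy <= 0 || mito_frac_healthy >= 1) {
    stop_validation("mito fractions must lie in (0, 1)")
  }
  if (n_mito_genes >= n_genes) stop_validation("n_mito_genes must be below n_genes")
  if (is.null(gene_ids)) {
    mito_names <- if (n_mito_genes <= length(MOUSE_MT_GENES)) {
      MOUSE_MT_GENES[seq_len(n_mito_genes)]
    } else {
      c(MOUSE_MT_GENES, sprintf("mt-x%d", seq_len(n_mito_genes - length(MOUSE_MT_GENES))))
    }
    gene_ids <- c(mito_names,
                  sprintf("g%04d", seq_len(n_genes - n_mito_genes)))
  }
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids)) {
    stop_validation("gene_ids must be ", n_genes, " unique symbols")
  }
  cfg <- structure(list(n_plates = n_plates, wells_per_plate = wells_per_plate,
                        cell_types = cell_types, time_points = time_points,
                        n_genes = n_genes,
                        gene_mean_log_mean = gene_mean_log_mean,
                        gene_mean_log_sd = gene_mean_log_sd,
                        dispersion = dispersion, n_mito_genes = n_mito_genes,
                        mito_frac_healthy = mito_frac_healthy,
                        mito_frac_dying = mito_frac_dying,
                        doublet_rate = doublet_rate, dying_rate = dying_rate,
                        planted_pairs = planted_pairs,
                        planted_markers = planted_markers,
                        gene_ids = gene_ids, seed = as.integer(seed)),
                   class = "sim_config")
  check_planted(cfg)
  cfg
}

check_planted <- function(cfg) {
  check_tbl <- function(tbl, gene_cols, what) {
    if (is.null(tbl)) return(invisible())
    for (col in gene_cols) {
      bad <- setdiff(tbl[[col]], cfg$gene_ids)
      if (length(bad)) {
        stop_validation("planted ", what, " gene(s) not in the universe: ",
                        paste(bad, collapse = ", "))
      }
    }
    if (any(tbl$fold <= 1)) stop_validation("planted folds must exceed 1")
  }
  check_tbl(cfg$planted_pairs, c("ligand", "receptor"), "pair")
  check_tbl(cfg$planted_markers, "gene", "marker")
  if (!is.null(cfg$planted_pairs)) {
    stopifnot(all(cfg$planted_pairs$sender %in% names(cfg$cell_types)),
              all(cfg$planted_pairs$receiver %in% names(cfg$cell_types)),
              all(cfg$planted_pairs$time_point %in% names(cfg$time_points)))
  }
  if (!is.null(cfg$planted_markers)) {
    stopifnot(all(cfg$planted_markers$cell_type %in% names(cfg$cell_types)))
  }
  invisible()
}

#' Generate a synthetic sorted-plate dataset
#'
#' Draws `n_plates * wells_per_plate` single-cell libraries gene-wise from
#' negative-binomial distributions. Cell types and time points are sampled
#' per the configured proportions; planted markers and ligand-receptor
#' pairs multiply the relevant group means; doublet wells receive the sum
#' of two independently drawn cells; dying cells have their library
#' re-allocated so the mitochondrial share reaches `mito_frac_dying`.
#' Deterministic given the config (which includes the seed).
#'
#' @param cfg a [sim_config()].
#' @return A list with `counts` (a [count_matrix()]), `annotation` (a
#'   `cell_annotation`), and `truth` (per-cell labels, `doublet_ids`,
#'   `dying_ids`, the planted tables, and the seed).
#' @examples
#' sim <- generate_dataset(sim_config(n_plates = 1, wells_per_plate = 48,
#'                                    n_genes = 60, seed = 7))
#' dim(sim$counts)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  n_cells <- cfg$n_plates * cfg$wells_per_plate
  n_mito <- cfg$n_mito_genes
  is_mito <- seq_len(cfg$n_genes) <= n_mito

  # Per-gene baseline NB means: log-normal body, mito block scaled so its
  # expected library share is mito_frac_healthy.
  base <- stats::rlnorm(cfg$n_genes, cfg$gene_mean_log_mean, cfg$gene_mean_log_sd)
  if (n_mito > 0) {
    target_mito <- cfg$mito_frac_healthy / (1 - cfg$mito_frac_healthy) *
      sum(base[!is_mito])
    base[is_mito] <- base[is_mito] / sum(base[is_mito]) * target_mito
  }

  plate <- rep(seq_len(cfg$n_plates), each = cfg$wells_per_plate)
  well <- rep(seq_len(cfg$wells_per_plate), times = cfg$n_plates)
  cell_ids <- sprintf("P%d_W%03d", plate, well)
  types <- sample(names(cfg$cell_types), n_cells, replace = TRUE,
                  prob = cfg$cell_types)
  times <- sample(names(cfg$time_points), n_cells, replace = TRUE,
                  prob = cfg$time_points)

  # Group-specific mean vectors with planted effects multiplied in.
  group_mu <- function(ct, tp) {
    mu <- base
    pm <- cfg$planted_markers
    if (!is.null(pm)) {
      for (i in which(pm$cell_type == ct)) {
        mu[match(pm$gene[i], cfg$gene_ids)] <-
          mu[match(pm$gene[i], cfg$gene_ids)] * pm$fold[i]
      }
    }
    pp <- cfg$planted_pairs
    if (!is.null(pp)) {
      for (i in seq_len(NROW(pp))) {
        if (pp$time_point[i] != tp) next
        if (pp$sender[i] == ct) {
          j <- match(pp$ligand[i], cfg$gene_ids)
          mu[j] <- mu[j] * pp$fold[i]
        }
        if (pp$receiver[i] == ct) {
          j <- match(pp$receptor[i], cfg$gene_ids)
          mu[j] <- mu[j] * pp$fold[i]
        }
      }
    }
    mu
  }
  grid <- expand.grid(ct = names(cfg$cell_types), tp = names(cfg$time_points),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mus <- lapply(seq_len(nrow(grid)),
                function(i) group_mu(grid$ct[i], grid$tp[i]))
  names(mus) <- group_key(grid$ct, grid$tp)

  draw_cell <- function(mu) {
    stats::rnbinom(cfg$n_genes, mu = mu, size = cfg$dispersion)
  }
  counts <- matrix(0L, nrow = cfg$n_genes, ncol = n_cells)
  key <- group_key(types, times)
  for (k in unique(key)) {
    idx <- which(key == k)
    counts[, idx] <- stats::rnbinom(cfg$n_genes * length(idx),
                                    mu = mus[[k]], size = cfg$dispersion)
  }

  # Doublet wells: add a second, independently drawn cell (its population
  # sampled from the same proportions); the well keeps the host's label.
  n_doublet <- round(cfg$doublet_rate * n_cells)
  doublet_idx <- if (n_doublet > 0) sample.int(n_cells, n_doublet) else integer()
  for (i in doublet_idx) {
    partner <- group_key(sample(names(cfg$cell_types), 1, prob = cfg$cell_types),
                         sample(names(cfg$time_points), 1, prob = cfg$time_points))
    counts[, i] <- counts[, i] + draw_cell(mus[[partner]])
  }

  # Dying cells: keep the library size, re-allocate it so the mito share
  # is mito_frac_dying (multinomial over the group's gene means).
  n_dying <- round(cfg$dying_rate * n_cells)
  dying_pool <- setdiff(seq_len(n_cells), doublet_idx)
  dying_idx <- if (n_dying > 0 && length(dying_pool) > 0) {
    sample(dying_pool, min(n_dying, length(dying_pool)))
  } else integer()
  if (n_mito > 0) {
    for (i in dying_idx) {
      lib <- sum(counts[, i])
      if (lib == 0) next
      mu <- mus[[key[i]]]
      t_mito <- round(cfg$mito_frac_dying * lib)
      counts[is_mito, i] <- as.vector(stats::rmultinom(1, t_mito, mu[is_mito]))
      counts[!is_mito, i] <- as.vector(stats::rmultinom(1, lib - t_mito, mu[!is_mito]))
    }
  }

  vocab <- list(cell_type = names(cfg$cell_types),
                time_point = names(cfg$time_points))
  ann <- cell_annotation(data.frame(cell_id = cell_ids, cell_type = types,
                                    time_point = times,
                                    stringsAsFactors = FALSE),
                         vocab = vocab)
  truth <- list(cells = data.frame(cell_id = cell_ids, cell_type = types,
                                   time_point = times, plate = plate,
                                   stringsAsFactors = FALSE),
                doublet_ids = cell_ids[sort(doublet_idx)],
                dying_ids = cell_ids[sort(dying_idx)],
                planted_pairs = cfg$planted_pairs,
                planted_markers = cfg$planted_markers,
                seed = cfg$seed)
  list(counts = count_matrix(counts, gene_ids = cfg$gene_ids,
                             cell_ids = cell_ids),
       annotation = ann,
       truth = truth)
}

#' Generate a null dataset
#'
#' The same generator with every planted effect and artifact disabled —
#' no planted pairs or markers, no doublets, no dying cells — so the
#' (cell_type, time_point) labels are exchangeable. Used for type-I-error
#' calibration.
#'
#' @param cfg a [sim_config()]; its planted tables and artifact rates are
#'   overridden to zero.
#' @return As [generate_dataset()], with empty truth lists.
#' @export
null_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$planted_pairs <- NULL
  cfg$planted_markers <- NULL
  cfg$doublet_rate <- 0
  cfg$dying_rate <- 0
  generate_dataset(cfg)
}

#' Random ligand-receptor pairs over a gene universe
#'
#' Convenience builder for calibration studies: samples `2 * n_pairs`
#' distinct non-mitochondrial genes and pairs them off.
#'
#' @param gene_ids gene universe.
#' @param n_pairs number of pairs.
#' @param seed integer seed.
#' @return An [lr_pairs()] table.
#' @export
random_lr_pairs <- function(gene_ids, n_pairs, seed = 1) {
  pool <- gene_ids[!startsWith(tolower(gene_ids), "mt-")]
  if (length(pool) < 2 * n_pairs) {
    stop_validation("gene universe too small for ", n_pairs, " disjoint pairs")
  }
  withr::with_seed(seed, {
    genes <- sample(pool, 2 * n_pairs)
    lr_pairs(data.frame(ligand = genes[seq_len(n_pairs)],
                        receptor = genes[n_pairs + seq_len(n_pairs)],
                        stringsAsFactors = FALSE))
  })
}
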