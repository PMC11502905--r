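make_screen_fixture <- function(n_cells = 12, n_genes = 8, seed = 3) {
  set.seed(seed)
  mat <- random_count_mat(n_genes, n_cells, lambda = 6, n_mito = 0)
  norm <- log_normalize(count_matrix(mat))
  ann <- cell_annotation(data.frame(
    cell_id = colnames(mat),
    cell_type = rep(c("microglia", "NSPC"), length.out = n_cells),
    time_point = rep(c("uninjured", "PT_D1"), each = n_cells / 2)))
  list(norm = norm, ann = ann)
}

test_that("interaction score is the mean of the two group averages", {
  fx <- make_screen_fixture()
  gm <- group_means(fx$norm, fx$ann)
  g <- rownames(gm$means)
  s <- interaction_score(gm, g[1], g[2], "microglia", "NSPC", "PT_D1")
  expect_equal(s, (group_mean(gm, g[1], "microglia", "PT_D1") +
                     group_mean(gm, g[2], "NSPC", "PT_D1")) / 2)
  # simple arithmetic cases through a hand-built means object
  gm$means[g[1], "microglia|PT_D1"] <- 2
  gm$means[g[2], "NSPC|PT_D1"] <- 4
  expect_equal(interaction_score(gm, g[1], g[2], "microglia", "NSPC", "PT_D1"), 3)
  gm$means[g[1], "microglia|PT_D1"] <- 0
  gm$means[g[2], "NSPC|PT_D1"] <- 0
  expect_equal(interaction_score(gm, g[1], g[2], "microglia", "NSPC", "PT_D1"), 0)
  expect_error(interaction_score(gm, g[1], g[2], "astro", "NSPC", "PT_D1"),
               "no cells")
})

test_that("a single expressing cell propagates through score composition", {
  # one cell, library 4, count 1 -> ln(2501); paired with an all-zero gene
  mat <- matrix(c(1L, 3L, 0L), ncol = 1,
                dimnames = list(c("lig", "other", "rec"), "c1"))
  norm <- log_normalize(count_matrix(mat))
  ann <- cell_annotation(data.frame(cell_id = "c1", cell_type = "microglia",
                                    time_point = "PT_D1"))
  gm <- group_means(norm, ann)
  s <- interaction_score(gm, "lig", "rec", "microglia", "microglia", "PT_D1")
  expect_equal(s, log(2501) / 2)
})

test_that("empirical p-values implement the greater-or-equal proportion", {
  expect_equal(empirical_pvalue(5, 1:10), 0.6)
  expect_equal(empirical_pvalue(99, 1:10), 0)
  expect_equal(empirical_pvalue(7, rep(7, 8)), 1)
  expect_equal(empirical_pvalue(5, 1:10, smooth = TRUE), 7 / 11)
  expect_error(empirical_pvalue(1, numeric()), "non-empty")
})

test_that("screen output has one row per pair x time point x direction", {
  fx <- make_screen_fixture()
  g <- fx$norm$gene_ids
  pairs3 <- lr_pairs(data.frame(ligand = g[1:3], receptor = g[4:6]))
  cfg <- screen_config("microglia", "NSPC", n_perm = 20, seed = 1)
  res <- lr_screen(fx$norm, fx$ann, pairs3, cfg)
  expect_equal(nrow(res), 3 * 2 * 2)

  cfg1 <- screen_config("microglia", "NSPC", time_points = "PT_D1",
                        n_perm = 20, seed = 1,
                        direction_mode = "ligand-in-sender")
  res1 <- lr_screen(fx$norm, fx$ann, lr_pairs(data.frame(ligand = g[1],
                                                         receptor = g[2])), cfg1)
  expect_equal(nrow(res1), 1)
  expect_equal(res1$sender, "microglia")

  # scores recompute from group means
  gm <- group_means(fx$norm, fx$ann)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$score[i],
                 interaction_score(gm, res$ligand[i], res$receptor[i],
                                   res$sender[i], res$receiver[i],
                                   res$time_point[i]))
  }
  # p * n_perm is the integer tie-inclusive count
  expect_equal(res$p_value * res$n_perm, res$count_ge)
})

test_that("screen errors when no pair has both genes in the universe", {
  fx <- make_screen_fixture()
  pairs <- lr_pairs(data.frame(ligand = "nope1", receptor = "nope2"))
  cfg <- screen_config("microglia", "NSPC", n_perm = 5, seed = 1)
  expect_error(suppressWarnings(lr_screen(fx$norm, fx$ann, pairs, cfg)),
               "no testable pairs")
  expect_error(screen_config("a", "b", n_perm = 0), "at least 1")
})

test_that("screen is deterministic given the seed", {
  fx <- make_screen_fixture(n_cells = 20)
  g <- fx$norm$gene_ids
  pairs <- lr_pairs(data.frame(ligand = g[1:2], receptor = g[3:4]))
  cfg <- screen_config("microglia", "NSPC", n_perm = 50, seed = 99)
  r1 <- lr_screen(fx$norm, fx$ann, pairs, cfg)
  r2 <- lr_screen(fx$norm, fx$ann, pairs, cfg)
  expect_identical(r1, r2)
  cfg2 <- screen_config("microglia", "NSPC", n_perm = 50, seed = 100)
  r3 <- lr_screen(fx$norm, fx$ann, pairs, cfg2)
  expect_false(identical(r1$count_ge, r3$count_ge))
})

test_that("a single joint label makes every null score equal the observed", {
  set.seed(2)
  mat <- random_count_mat(6, 8, lambda = 5, n_mito = 0)
  norm <- log_normalize(count_matrix(mat))
  ann <- cell_annotation(data.frame(cell_id = colnames(mat),
                                    cell_type = "microglia",
                                    time_point = "PT_D1"))
  pairs <- lr_pairs(data.frame(ligand = rownames(mat)[1],
                               receptor = rownames(mat)[2]))
  cfg <- screen_config("microglia", "microglia", n_perm = 30, seed = 4)
  pn <- permutation_null(norm, ann, pairs, cfg)
  expect_equal(as.vector(pn$null_scores),
               rep(pn$observed, each = 30), tolerance = 1e-12)
  res <- lr_screen(norm, ann, pairs, cfg)
  expect_equal(res$p_value, rep(1, nrow(res)))
})

test_that("two cells with two labels yield exactly the two enumerable nulls", {
  mat <- matrix(c(4L, 0L, 1L, 2L, 3L, 1L), nrow = 3,
                dimnames = list(c("lig", "rec", "g3"), c("c1", "c2")))
  norm <- log_normalize(count_matrix(mat))
  ann <- cell_annotation(data.frame(cell_id = c("c1", "c2"),
                                    cell_type = c("microglia", "NSPC"),
                                    time_point = "PT_D1"))
  pairs <- lr_pairs(data.frame(ligand = "lig", receptor = "rec"))
  cfg <- screen_config("microglia", "NSPC", time_points = "PT_D1",
                       n_perm = 400, seed = 8,
                       direction_mode = "ligand-in-sender")
  pn <- permutation_null(norm, ann, pairs, cfg)
  s_identity <- (norm$values["lig", "c1"] + norm$values["rec", "c2"]) / 2
  s_swapped <- (norm$values["lig", "c2"] + norm$values["rec", "c1"]) / 2
  expect_equal(pn$observed, s_identity)
  expect_setequal(round(unique(as.vector(pn$null_scores)), 12),
                  round(c(s_identity, s_swapped), 12))
})

test_that("sampled p-values agree with exhaustive label permutations", {
  # <= 6 cells: compare against the p computed over every distinct
  # joint-label assignment
  set.seed(31)
  for (rep in 1:5) {
    mat <- random_count_mat(5, 6, lambda = 5, n_mito = 0)
    rownames(mat)[1:2] <- c("lig", "rec")
    norm <- log_normalize(count_matrix(mat))
    labels <- c("microglia|PT_D1", "microglia|PT_D1", "microglia|PT_D1",
                "NSPC|PT_D1", "NSPC|PT_D1", "NSPC|PT_D1")
    ex <- exhaustive_perm_p(norm$values, labels, "lig", "rec",
                            "microglia|PT_D1", "NSPC|PT_D1")
    ann <- cell_annotation(data.frame(cell_id = colnames(mat),
                                      cell_type = sub("\\|.*", "", labels),
                                      time_point = "PT_D1"))
    cfg <- screen_config("microglia", "NSPC", n_perm = 500, seed = rep,
                         direction_mode = "ligand-in-sender")
    res <- lr_screen(norm, ann, lr_pairs(data.frame(ligand = "lig",
                                                    receptor = "rec")), cfg)
    # 99% level for joint coverage over the five repetitions
    ci <- binom.test(res$count_ge[1], 500, conf.level = 0.99)$conf.int
    expect_gte(ex$p, ci[1])
    expect_lte(ex$p, ci[2])
  }
})

test_that("chord adjacency counts or sums passing interactions", {
  res <- data.frame(ligand = c("l1", "l2", "l3"), receptor = c("r1", "r2", "r3"),
                    sender = c("A", "B", "A"), receiver = c("B", "A", "B"),
                    time_point = "PT_D1", score = c(2, 3, 4),
                    p_value = c(0.01, 0.04, 0.5))
  adj <- chord_adjacency(res, p_max = 0.05)
  expect_equal(adj["A", "B"], 1)
  expect_equal(adj["B", "A"], 1)
  expect_equal(sum(adj), 2)
  adj_s <- chord_adjacency(res, p_max = 0.05, value = "score")
  expect_equal(adj_s["A", "B"], 2)
  # nothing passes -> zero matrix
  expect_true(all(chord_adjacency(res, p_max = 1e-4) == 0))
  expect_error(chord_adjacency(res[0, ]), "non-empty")
})
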