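test_that("count_matrix validates integer counts and identifiers", {
  m <- count_matrix(matrix(c(2, 0, 0, 0, 0, 5), nrow = 3, byrow = TRUE),
                    gene_ids = c("g1", "g2", "g3"), cell_ids = c("c1", "c2"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(as.matrix(m$values)["g3", "c2"], 5)
  expect_error(count_matrix(matrix(-1, 1, 1), "g", "c"), "negative")
  expect_error(count_matrix(matrix(1.5, 1, 1), "g", "c"), "non-integer")
  expect_error(count_matrix(matrix(1, 2, 1), c("g", "g"), "c"), "unique")
  expect_error(count_matrix(matrix(1, 1, 2), "g", c("c", "c")), "unique")
})

test_that("mtx reader transcribes coordinates, zero-fills, checks dims", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 2", "3 2 5"), file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  m <- read_counts_mtx(file.path(dir, "matrix.mtx"),
                       file.path(dir, "features.tsv"),
                       file.path(dir, "barcodes.tsv"))
  expect_equal(unname(as.matrix(m$values)),
               matrix(c(2, 0, 0, 0, 0, 5), nrow = 3, byrow = TRUE))
  expect_equal(m$gene_ids, c("g1", "g2", "g3"))

  # empty coordinate list -> all-zero matrix of the declared shape
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(dir, "empty.mtx"))
  z <- read_counts_mtx(file.path(dir, "empty.mtx"),
                       file.path(dir, "features.tsv"),
                       file.path(dir, "barcodes.tsv"))
  expect_true(all(as.matrix(z$values) == 0))
  expect_equal(dim(z), c(3L, 2L))

  # identifier/header dimension mismatch is a format error
  writeLines(c("g1", "g2", "g3", "g4"), file.path(dir, "features4.tsv"))
  expect_error(read_counts_mtx(file.path(dir, "matrix.mtx"),
                               file.path(dir, "features4.tsv"),
                               file.path(dir, "barcodes.tsv")),
               class = "lrperm_format_error")

  # real-valued matrices are rejected: counts are UMIs
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "3 2 1", "1 1 2.0"), file.path(dir, "real.mtx"))
  expect_error(read_counts_mtx(file.path(dir, "real.mtx"),
                               file.path(dir, "features.tsv"),
                               file.path(dir, "barcodes.tsv")),
               "integer")
})

test_that("Matrix-Market write/read round-trips values and order", {
  set.seed(41)
  for (i in 1:5) {
    mat <- random_count_mat(8, 6, lambda = 1)
    m <- count_matrix(mat)
    dir <- withr::local_tempdir()
    paths <- write_counts_mtx(m, dir)
    back <- read_counts_mtx(paths[1], paths[2], paths[3])
    expect_equal(as.matrix(back$values), as.matrix(m$values))
    expect_identical(back$gene_ids, m$gene_ids)
    expect_identical(back$cell_ids, m$cell_ids)
  }
})

test_that("annotation reader validates vocabulary and uniqueness", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.tsv")
  write.table(data.frame(cell_id = c("c1", "c2"),
                         cell_type = c("microglia", "NSPC"),
                         time_point = c("PT_D1", "uninjured")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_annotation(path)
  expect_s3_class(ann, "cell_annotation")
  expect_equal(nrow(ann), 2)
  expect_equal(as.character(ann$cell_type), c("microglia", "NSPC"))

  bad <- data.frame(cell_id = "c1", cell_type = "microglia", time_point = "PT_D3")
  expect_error(cell_annotation(bad), "PT_D3")
  dup <- data.frame(cell_id = c("c1", "c1"), cell_type = "NSPC",
                    time_point = "uninjured")
  expect_error(cell_annotation(dup), "duplicate")
})

test_that("annotation/matrix alignment warns on extra cells, errors on missing", {
  ann <- cell_annotation(data.frame(cell_id = c("c1", "c2", "c3"),
                                    cell_type = "NSPC", time_point = "uninjured"))
  expect_warning(out <- align_annotation(ann, c("c2", "c1")), "ignored")
  expect_equal(out$cell_id, c("c2", "c1"))
  expect_error(suppressWarnings(align_annotation(ann, c("c1", "c9"))),
               class = "lrperm_validation_error")
})

test_that("ortholog mapping drops unmapped pairs and expands one-to-many", {
  omap <- ortholog_map(data.frame(source = c("APOE", "LRP8", "A", "A", "B"),
                                  target = c("Apoe", "Lrp8", "a1", "a2", "b")))
  p1 <- lr_pairs(data.frame(ligand = "APOE", receptor = "LRP8"))
  out <- map_orthologs(p1, omap)
  expect_equal(out$ligand, "Apoe")
  expect_equal(out$receptor, "Lrp8")

  p2 <- lr_pairs(data.frame(ligand = c("IGF2", "A"), receptor = c("X", "B")))
  out2 <- map_orthologs(p2, omap)
  rep2 <- attr(out2, "mapping_report")
  expect_equal(rep2$n_dropped_unmapped, 1)
  expect_equal(sort(out2$ligand), c("a1", "a2"))
  expect_equal(out2$receptor, c("b", "b"))

  out3 <- map_orthologs(p2, omap, policy = "drop")
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "mapping_report")$n_dropped_multi, 1)
})

test_that("ortholog mapping is identity under an identity map and bounded", {
  genes <- c("Apoe", "Lrp8", "Igf2", "Kitl")
  pairs <- lr_pairs(data.frame(ligand = genes[c(1, 3)], receptor = genes[c(2, 4)]))
  idmap <- ortholog_map(data.frame(source = genes, target = genes))
  out <- map_orthologs(pairs, idmap)
  expect_equal(out$ligand, pairs$ligand)
  expect_equal(out$receptor, pairs$receptor)

  fan <- ortholog_map(data.frame(source = rep(genes, each = 3),
                                 target = paste0(rep(genes, each = 3), 1:3)))
  out2 <- map_orthologs(pairs, fan)
  expect_lte(nrow(out2), nrow(pairs) * 3^2)
})

test_that("symbol matching is case-sensitive", {
  omap <- ortholog_map(data.frame(source = "APOE", target = "Apoe"))
  pairs <- lr_pairs(data.frame(ligand = "Apoe", receptor = "APOE"))
  out <- map_orthologs(pairs, omap)
  expect_equal(nrow(out), 0)  # ligand "Apoe" is not the source symbol "APOE"
  expect_equal(attr(out, "mapping_report")$n_dropped_unmapped, 1)
})
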