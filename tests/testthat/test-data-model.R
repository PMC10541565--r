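test_that("reading a toy expression file yields a validated tensor", {
  dir <- withr::local_tempdir()
  vals <- matrix(seq(0.5, 12, by = 0.5), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  meta <- data.frame(sample = paste0("s", 1:6),
                     cultivar = rep(c("CS", "PN"), each = 3),
                     vintage = 2012, timepoint = 1, replicate = rep(1:3, 2))
  write.table(data.frame(gene_id = rownames(vals), vals), file.path(dir, "x.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, file.path(dir, "m.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tn <- read_expression(file.path(dir, "x.tsv"), file.path(dir, "m.tsv"))
  expect_equal(nrow(tn$conditions), 2)
  expect_equal(tn$n_replicates, 3L)
  expect_equal(length(tn$gene_ids), 4)

  # round trip preserves values exactly and normalization is a permutation
  write_expression(tn, file.path(dir, "x2.tsv"), file.path(dir, "m2.tsv"))
  tn2 <- read_expression(file.path(dir, "x2.tsv"), file.path(dir, "m2.tsv"))
  expect_identical(tn2$values, tn$values)
  orig <- sort(paste(colnames(vals), as.vector(vals[1, ])))
  norm <- sort(paste(colnames(tn$values), as.vector(tn$values[1, ])))
  expect_identical(norm, orig)
})

test_that("tensor construction rejects contract violations", {
  vals <- matrix(1:12, nrow = 2,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  meta <- data.frame(sample = paste0("s", 1:6), cultivar = "CS",
                     vintage = 2012, timepoint = rep(1:2, each = 3),
                     replicate = rep(1:3, 2))
  expect_s3_class(expression_tensor(vals, meta), "expr_tensor")

  neg <- vals; neg[1, 1] <- -1.0
  expect_error(expression_tensor(neg, meta), "negative expression")

  m2 <- meta; m2$timepoint <- rep(c(1, 3), each = 3)
  expect_error(expression_tensor(vals, m2), "non-contiguous timepoints")

  dup <- vals; rownames(dup) <- c("g1", "g1")
  expect_error(expression_tensor(dup, meta), "duplicate gene ids")

  expect_error(expression_tensor(vals, meta[-1, ]), "absent from metadata")

  m3 <- meta; m3$timepoint <- c(1, 1, 1, 2, 2, 1)
  expect_error(expression_tensor(vals, m3), "replicate counts|non-contiguous")
})

test_that("scale artifacts round-trip bit-for-bit through JSON", {
  art <- fx$scale
  path <- withr::local_tempfile(fileext = ".json")
  write_scale(art, path)
  back <- read_scale(path)
  expect_identical(back$core_gene_ids, art$core_gene_ids)
  expect_identical(back$column_means, art$column_means)
  expect_identical(back$column_sds, art$column_sds)
  expect_identical(unname(back$eigenvectors), unname(art$eigenvectors))
  expect_identical(back$control_points, art$control_points)
  expect_identical(unname(back$marks), unname(art$marks[, ]))
  expect_identical(back$pc_indices, art$pc_indices)
  expect_identical(back$n_marks, art$n_marks)
  expect_identical(back$training_stages, art$training_stages)

  # the default graduation is serialized as 30 marks
  expect_match(paste(readLines(path), collapse = ""), '"n_marks":30')
})

test_that("scale artifact reader rejects corrupt or mismatched files", {
  path <- withr::local_tempfile(fileext = ".json")
  write_scale(fx$scale, path)

  txt <- readLines(path)
  writeLines(substr(txt, 1, nchar(txt) %/% 2), path)
  expect_error(read_scale(path), "corrupt scale artifact")

  path2 <- withr::local_tempfile(fileext = ".json")
  writeLines(sub("molstage-scale/1", "molstage-scale/99",
                 readLines({write_scale(fx$scale, path2); path2})), path2)
  expect_error(read_scale(path2), "version mismatch")

  # checksum failure on a tampered gene list
  path3 <- withr::local_tempfile(fileext = ".json")
  write_scale(fx$scale, path3)
  writeLines(sub(fx$scale$core_gene_ids[1], "geneXXXX", readLines(path3)),
             path3)
  expect_error(read_scale(path3), "checksum")
})

test_that("gene panels round-trip through JSON", {
  genes <- fx$scale$core_gene_ids[1:6]
  signs <- matrix(rep(c(1, -1), 9), nrow = 6, dimnames = list(genes, NULL))
  p <- gene_panel(genes, signs, provenance = "test")
  path <- withr::local_tempfile(fileext = ".json")
  write_panel(p, path)
  q <- read_panel(path)
  expect_identical(q$gene_ids, p$gene_ids)
  expect_identical(unname(q$loading_signs), unname(p$loading_signs))
  expect_error(gene_panel(genes, signs * 2), "signs")
  expect_error(gene_panel(c(genes[1], genes[1]),
                          signs[1:2, , drop = FALSE]), "duplicate")
})
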