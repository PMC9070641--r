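test_that("expression tables round-trip through TSV at full precision", {
  em <- rand_em(7, 12, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  meta_path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(em, path, meta_path)
  back <- read_expression_table(path, meta_path)
  expect_identical(rownames(back$values), rownames(em$values))
  expect_identical(colnames(back$values), colnames(em$values))
  expect_lt(max(abs(back$values - em$values)), 1e-12)
  expect_identical(back$sample_meta, em$sample_meta)
})

test_that("expression reader preserves shape and enforces invariants", {
  dir <- withr::local_tempdir()
  expr <- file.path(dir, "e.tsv")
  meta <- file.path(dir, "m.tsv")
  writeLines(c(
    "gene_id\tS1\tS2\tS3\tS4",
    "# a comment line",
    "G1\t1\t2\t3\t4",
    "G2\t0.5\t0.25\t0.125\t0.0625",
    "G3\t-1\t0\t1\t2"
  ), expr)
  writeLines(c(
    "sample_id\ttime_point\treplicate",
    "S1\tT1\t1", "S2\tT1\t2", "S3\tT2\t1", "S4\tT2\t2"
  ), meta)
  em <- read_expression_table(expr, meta)
  expect_identical(dim(em$values), c(3L, 4L))
  expect_identical(em$values["G2", "S4"], 0.0625)

  writeLines(c(
    "gene_id\tS1\tS2\tS3\tS4",
    "G1\t1\t2\t3\t4",
    "G1\t5\t6\t7\t8"
  ), expr)
  expect_error(read_expression_table(expr, meta), "G1")

  writeLines(c(
    "gene_id\tS1\tS2\tS3\tS4",
    "G1\t1\ttwo\t3\t4"
  ), expr)
  err <- expect_error(read_expression_table(expr, meta))
  expect_match(conditionMessage(err), "two")
  expect_match(conditionMessage(err), "S2")

  writeLines(c(
    "gene_id\tS1\tS2\tS3\tS4",
    "G1\t1\t2\t3\t4",
    "G2\t1\t2\t3\t5"
  ), expr)
  writeLines(c(
    "sample_id\ttime_point\treplicate",
    "S1\tT1\t1", "S2\tT1\t2", "S3\tT2\t1"
  ), meta)
  expect_error(read_expression_table(expr, meta), "S4")
})

test_that("gene catalogs parse roles, honor aliases, reject conflicts", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "catalog.tsv")
  writeLines(c(
    "gene_id\trole\tfamily",
    "G1\tTF\tERF",
    "G2\tregulator\tNAC",
    "G3\tstructural\tNA",
    "G4\tstructure\tNA"
  ), path)
  cat <- read_gene_catalog(path)
  expect_s3_class(cat, "GeneCatalog")
  expect_identical(regulator_genes(cat), c("G1", "G2"))
  expect_identical(structural_genes(cat), c("G3", "G4"))
  expect_identical(cat$family[cat$gene_id == "G1"], "ERF")

  expect_error(gene_catalog("G1", "enzyme"), "accepted")
  expect_error(gene_catalog(c("G1", "G1"), c("TF", "structural")),
               "conflicting roles")
  expect_error(gene_catalog(c("G1", "G2"), c("structural", "TF"),
                            family = c("ERF", NA)), "family")

  path2 <- file.path(dir, "rt.tsv")
  write_gene_catalog(cat, path2)
  expect_identical(as.data.frame(read_gene_catalog(path2)),
                   as.data.frame(cat))
})

test_that("GMT process maps read, deduplicate and round-trip", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  writeLines(c(
    "jasmonic acid biosynthetic process\tna\tG1\tG2\tG2\tG3",
    "response to water deprivation\tna\tG2\tG4"
  ), path)
  pm <- read_process_map(path)
  expect_length(pm, 2L)
  expect_identical(pm[["jasmonic acid biosynthetic process"]],
                   c("G1", "G2", "G3"))  # duplicate member collapsed

  path2 <- file.path(dir, "rt.gmt")
  write_process_map(pm, path2)
  expect_identical(unclass(read_process_map(path2)), unclass(pm))

  writeLines("empty process\tna", path)
  expect_error(read_process_map(path), "empty process")
})
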