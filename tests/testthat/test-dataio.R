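test_that("expression TSV round-trips bit-for-bit at printed precision", {
  x <- make_expr(4, 6, seed = 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, f)
  y <- read_expression(f)
  expect_identical(dim(y), dim(x))
  expect_identical(dimnames(y), dimnames(x))
  expect_equal(y, x, tolerance = 1e-14)
  # a second round-trip is byte-stable
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(y, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed expression inputs are rejected with informative errors", {
  x <- make_expr(3, 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(probeset_id = c("gA", "gB", "gA"), x, check.names = FALSE)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(f), "gA")
  # fewer than 3 arrays
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, f2)
  two <- read.table(f2, header = TRUE, sep = "\t", check.names = FALSE)[, 1:3]
  utils::write.table(two, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(f2), "3 arrays")
})

test_that("missing-value policy drops the probeset or errors with coordinates", {
  x <- make_expr(5, 4, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, f)
  ln <- readLines(f)
  ln[3] <- sub("\t[-0-9.]+$", "\tNA", ln[3])  # poison last cell of 2nd probeset
  writeLines(ln, f)
  y <- read_expression(f, missing_policy = "drop_probeset")
  expect_identical(rownames(y), rownames(x)[-2])
  expect_error(read_expression(f, missing_policy = "error"), rownames(x)[2])
})

test_that("exclusion list and id normalization are applied before analysis", {
  x <- make_expr(4, 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, f)
  y <- read_expression(f, exclude = rownames(x)[c(1, 3)])
  expect_identical(rownames(y), rownames(x)[c(2, 4)])
  z <- read_expression(f, normalize_ids = TRUE)
  expect_identical(rownames(z), toupper(rownames(x)))
})

test_that("condition subsetting filters columns and guards degenerate selections", {
  x <- make_expr(6, 10)
  md <- data.frame(array_id = colnames(x),
                   subspecies = "sweet_orange",
                   organ = rep(c("fruit", "leaf"), c(6, 4)),
                   experiment_type = rep(c("stress", "dev"), 5),
                   stringsAsFactors = FALSE)
  fr <- subset_by_condition(x, md, organ = "fruit")
  expect_identical(colnames(fr), md$array_id[md$organ == "fruit"])
  expect_identical(rownames(fr), rownames(x))
  # selector matching all arrays is the identity
  expect_identical(subset_by_condition(x, md, subspecies = "sweet_orange"), x)
  expect_identical(subset_by_condition(x, md), x)
  # complementary selectors recover the full column set
  lf <- subset_by_condition(x, md, organ = "leaf")
  expect_setequal(c(colnames(fr), colnames(lf)), colnames(x))
  # conjunction of terms
  both <- subset_by_condition(x, md, organ = "fruit", experiment_type = "stress")
  expect_true(all(md$organ[match(colnames(both), md$array_id)] == "fruit"))
  expect_error(subset_by_condition(x, md, organ = "root"), "0 arrays")
  md2 <- md; md2$organ[1:4] <- "root"
  expect_error(subset_by_condition(x, md2, organ = "fruit"), "2 arrays")
})

obo_fixture <- function() {
  f <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid process",
    "namespace: biological_process", "is_a: GO:0000001 ! root process", "",
    "[Term]", "id: GO:0000003", "name: leaf process",
    "namespace: biological_process", "is_a: GO:0000002 ! mid process", "",
    "[Term]", "id: GO:0000009", "name: gone", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"), f)
  f
}

ann_fixture <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("annotation loading and true-path propagation follow the DAG", {
  obo <- obo_fixture()
  f <- ann_fixture(data.frame(probeset_id = c("g1", "g2"),
                              term_id = c("GO:0000003", "GO:0000001"),
                              namespace = "BP",
                              description = c("leaf process", "root process")))
  plain <- read_annotations(f)
  expect_s3_class(plain, "annotation_set")
  expect_identical(nrow(plain$associations), 2L)
  prop <- read_annotations(f, obo = obo, propagate = TRUE)
  g1 <- sort(prop$associations$term_id[prop$associations$probeset_id == "g1"])
  expect_identical(g1, c("GO:0000001", "GO:0000002", "GO:0000003"))
  # idempotent
  again <- propagate_annotations(prop)
  expect_identical(again$associations, prop$associations)
  # obsolete terms dropped from the ontology
  ont <- read_obo(obo)
  expect_false("GO:0000009" %in% names(ont$parents))
  # term absent from the ontology: warn, keep unpropagated
  f2 <- ann_fixture(data.frame(probeset_id = "g3", term_id = "GO:0000099",
                               namespace = "MF"))
  expect_warning(out <- read_annotations(f2, obo = obo, propagate = TRUE),
                 "GO:0000099")
  expect_identical(out$associations$term_id, "GO:0000099")
})

test_that("degenerate and invalid annotation inputs are handled", {
  f <- ann_fixture(data.frame(probeset_id = character(0),
                              term_id = character(0), namespace = character(0)))
  empty <- read_annotations(f)
  expect_identical(nrow(empty$associations), 0L)
  enr <- hypergeom_enrich(list(c1 = c("g1", "g2", "g3")), empty,
                          background = paste0("g", 1:10))
  expect_identical(nrow(enr), 0L)
  f2 <- ann_fixture(data.frame(probeset_id = "g1", term_id = "GO:1",
                               namespace = "XX"))
  expect_error(read_annotations(f2), "XX")
  # cyclic DAG is rejected
  ann <- annotation_set(data.frame(probeset_id = "g1", term_id = "GO:1",
                                   namespace = "BP"),
                        dag = list(`GO:1` = "GO:2", `GO:2` = "GO:1"))
  expect_error(propagate_annotations(ann), "cycle")
})

test_that("metadata reader enforces schema and unique array ids", {
  md <- default_metadata(8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_array_metadata(md, f)
  back <- read_array_metadata(f)
  expect_identical(back$array_id, md$array_id)
  md2 <- md; md2$array_id[2] <- md2$array_id[1]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_array_metadata(md2, f2)
  expect_error(read_array_metadata(f2), "duplicate")
  expect_error(read_array_metadata({
    f3 <- withr::local_tempfile(fileext = ".tsv")
    utils::write.table(md[, 1:2], f3, sep = "\t", row.names = FALSE, quote = FALSE)
    f3
  }), "organ")
})
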