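test_that("expression matrix round-trips through TSV and CSV", {
  m <- random_matrix(7, 4, seed = 11)
  for (dialect in c("tsv", "csv")) {
    path <- tempfile()
    write_expression_matrix(m, path, dialect = dialect,
                            params = list(unit = "tpm"))
    m2 <- read_expression_matrix(path, dialect = dialect)
    expect_identical(dim(m2), dim(m))
    expect_identical(rownames(m2), rownames(m))
    expect_identical(colnames(m2), colnames(m))
    expect_lt(max(abs(m2 - m) / pmax(abs(m), 1)), 1e-12)
  }
})

test_that("gene symbols are canonicalized and duplicate rows collapsed by mean", {
  path <- write_tmp(c("gene\ts1\ts2",
                      "ar\t1\t2",
                      "AR\t3\t4",
                      " foxa1 \t5\t6"))
  expect_warning(m <- read_expression_matrix(path), "1 duplicate")
  expect_identical(rownames(m), c("AR", "FOXA1"))
  expect_equal(unname(m["AR", ]), c(2, 3))  # arithmetic mean of the two rows
  expect_equal(attr(m, "read_report")$n_duplicates_collapsed, 1L)
})

test_that("malformed expression input raises named errors", {
  bad_cell <- write_tmp(c("gene\ts1\ts2", "AR\t1\toops"))
  expect_error(read_expression_matrix(bad_cell), "oops.*AR.*s2")
  dup_sample <- write_tmp(c("gene\ts1\ts1", "AR\t1\t2"))
  expect_error(read_expression_matrix(dup_sample), "duplicate sample")
  empty <- write_tmp("gene\ts1")
  expect_error(read_expression_matrix(empty), "empty")
})

test_that("transpose flag handles samples-in-rows input", {
  m <- random_matrix(3, 5, seed = 2)
  path <- tempfile()
  write_expression_matrix(t(m), path)  # stores samples in rows
  m2 <- read_expression_matrix(path, transpose = TRUE)
  expect_equal(m2[rownames(m), colnames(m)], m, tolerance = 1e-12)
})

test_that("catalog reader keeps order, drops comments/blanks, warns on duplicates", {
  path <- write_tmp(c("# TF catalog", "AR", "", "ASCL1", "foxa1 # trailing",
                      "AR"))
  expect_warning(cat_v <- read_catalog(path), "duplicate")
  expect_identical(as.character(cat_v), c("AR", "ASCL1", "FOXA1"))
  expect_error(read_catalog(write_tmp(c("# only comments", ""))), "empty")
})

test_that("GMT round-trips and agrees with an independent parser", {
  sets <- list(AD_TFS = list(name = "AD_TFS", description = "na",
                             members = c("AR", "NKX3-1")),
               NE_TFS = list(name = "NE_TFS", description = "x",
                             members = c("ASCL1", "FOXA2", "INSM1")))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back, sets)
  skip_if_not_installed("fgsea")
  ref <- fgsea::gmtPathways(path)
  expect_identical(lapply(back, `[[`, "members"), ref)
})

test_that("GMT lines with fewer than 3 fields error with the line number", {
  path <- write_tmp(c("OK\tna\tAR", "BAD\tna"), ext = ".gmt")
  expect_error(read_gmt(path), "line 2")
})

test_that("CLS labels parse and count mismatches error", {
  cls <- write_tmp(c("4 2 1", "# ADENO NEPC", "ADENO ADENO NEPC NEPC"),
                   ext = ".cls")
  lab <- read_labels(cls, sample_ids = paste0("P", 1:4))
  expect_equal(unname(lab), c("ADENO", "ADENO", "NEPC", "NEPC"),
               ignore_attr = TRUE)
  expect_identical(attr(lab, "groups"), c("ADENO", "NEPC"))
  # numeric label body indexes the class-name line
  cls_num <- write_tmp(c("4 2 1", "# A B", "0 0 1 1"), ext = ".cls")
  expect_equal(unname(read_labels(cls_num)), c("A", "A", "B", "B"),
               ignore_attr = TRUE)
  short <- write_tmp(c("5 2 1", "# A B", "A A B B"), ext = ".cls")
  expect_error(read_labels(short), "declares 5")
})

test_that("two-column labels parse and cover exactly the listed samples", {
  path <- write_tmp(c("s1\tADENO", "s2\tNEPC", "s3\tADENO"))
  lab <- read_labels(path)
  expect_identical(lab[c("s1", "s2", "s3")],
                   c(s1 = "ADENO", s2 = "NEPC", s3 = "ADENO"))
  expect_error(read_labels(write_tmp(c("s1\tA", "s1\tB"))), "duplicate")
})

test_that("subset_by_catalog keeps catalog order and accounts for every symbol", {
  m <- random_matrix(3, 2)
  rownames(m) <- c("A", "B", "C")
  res <- subset_by_catalog(m, c("B", "C", "D"))
  expect_identical(rownames(res$matrix), c("B", "C"))
  expect_identical(res$missing, "D")
  expect_identical(subset_by_catalog(m, c("A", "B"))$missing, character(0))
  expect_error(subset_by_catalog(m, c("X", "Y")), "disjoint")
  # row count + missing = catalog size, randomized
  set.seed(4)
  for (i in 1:20) {
    cat_v <- sample(c(LETTERS[1:3], paste0("Z", 1:5)), 4)
    r <- tryCatch(subset_by_catalog(m, cat_v), error = function(e) NULL)
    if (!is.null(r))
      expect_identical(nrow(r$matrix) + length(r$missing), length(cat_v))
  }
})
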