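test_that("delimited loader parses, orients and maps labels", {
  path <- write_temp_csv(c("id,f1,f2,class",
                           "a,1,2,A", "b,3,4,B", "c,5,6,A"))
  ds <- read_delimited(path, label_column = "class")
  expect_s3_class(ds, "lbm_dataset")
  expect_equal(dim(ds), c(3L, 2L))
  expect_equal(rownames(ds$x), c("a", "b", "c"))
  # default mapping: lexicographically smaller raw label -> GroupLow
  expect_equal(as.character(ds$labels), c("GroupLow", "GroupHi", "GroupLow"))
  expect_equal(ds$raw_labels, c("A", "B", "A"))
  expect_equal(unname(ds$x[2, ]), c(3, 4))

  # explicit reversed mapping
  ds2 <- read_delimited(path, mapping = c(GroupLow = "B", GroupHi = "A"))
  expect_equal(as.character(ds2$labels), c("GroupHi", "GroupLow", "GroupHi"))
})

test_that("delimited loader rejects bad input with named errors", {
  path <- write_temp_csv(c("f1,f2,class", "1,2,A", "3,oops,B"))
  expect_error(read_delimited(path), "row 2.*f2.*oops")
  expect_error(read_delimited(path, label_column = "label"),
               "label column 'label' not found")
  path2 <- write_temp_csv(c("f1,f2,class", "1,,A", "3,4,B"))
  expect_error(read_delimited(path2), "missing values")
  expect_error(read_delimited(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("write/read round-trip preserves values, ids and labels exactly", {
  ds <- make_random(n = 11, p = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_delimited(ds, path)
  back <- read_delimited(path)
  expect_identical(rownames(back$x), rownames(ds$x))
  expect_identical(colnames(back$x), colnames(ds$x))
  expect_identical(as.character(back$labels), as.character(ds$labels))
  expect_identical(back$x, ds$x)  # bit-for-bit via full-precision writer
})

test_that("ARFF loader reads dense files and rejects sparse/invalid ones", {
  path <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation tiny",
               "@attribute f1 numeric",
               "@attribute f2 numeric",
               "@attribute class {pos,neg}",
               "@data",
               "1.5,2.0,pos",
               "3.0,4.5,neg"), path)
  ds <- read_arff(path, label_attribute = "class")
  expect_equal(dim(ds), c(2L, 2L))
  expect_equal(ds$raw_labels, c("pos", "neg"))
  expect_equal(as.character(ds$labels), c("GroupHi", "GroupLow"))  # neg < pos
  expect_error(read_arff(path, label_attribute = "target"),
               "label attribute 'target' not found")

  sparse <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation sp", "@attribute f1 numeric",
               "@attribute class {a,b}", "@data", "{0 1.0, 1 a}"), sparse)
  expect_error(read_arff(sparse), "sparse ARFF")
})

test_that("binarize_by_target maps target to GroupLow and keeps raw labels", {
  x <- matrix(seq_len(10), 5, 2)
  ds <- lbm_dataset(x, rep("GroupHi", 5), raw_labels = c("1", "2", "4", "4", "7"))
  out <- binarize_by_target(ds, 4)
  expect_equal(as.character(out$labels),
               c("GroupHi", "GroupHi", "GroupLow", "GroupLow", "GroupHi"))
  expect_equal(out$raw_labels, c("1", "2", "4", "4", "7"))
  expect_error(binarize_by_target(ds, 9), "not present")
})

test_that("normalize_total hits the target constant for every row", {
  ds <- make_points(list(c(2, 3, 5), c(1, 1, 2)), c("GroupLow", "GroupHi"))
  pct <- normalize_total(ds, "percent100")
  expect_equal(unname(pct$x[1, ]), c(20, 30, 50))
  expect_equal(unname(normalize_total(ds, "unit1")$x[1, ]), c(0.2, 0.3, 0.5))
  # identity: all row sums equal the target for arbitrary positive matrices
  rnd <- make_random(n = 15, p = 6, seed = 9)
  rnd$x <- abs(rnd$x) + 0.1
  expect_equal(unname(rowSums(normalize_total(rnd, "percent100")$x)),
               rep(100, 15))
  expect_equal(unname(rowSums(normalize_total(rnd, "unit1")$x)), rep(1, 15))
  # zero-sum row names the offending sample
  bad <- make_points(list(c(0, 0), c(1, 2)), c("GroupLow", "GroupHi"),
                     ids = c("empty", "ok"))
  expect_error(normalize_total(bad, "unit1"), "empty")
})

test_that("scale_columns standardizes with the n-1 denominator", {
  ds <- make_points(list(c(1, 5), c(2, 6), c(3, 7)),
                    c("GroupLow", "GroupLow", "GroupHi"))
  sc <- scale_columns(ds)
  expect_equal(unname(sc$x[, 1]), c(-1, 0, 1))
  rnd <- make_random(n = 30, p = 8, seed = 11)
  scr <- scale_columns(rnd)
  expect_lt(max(abs(colMeans(scr$x))), 1e-10)
  expect_lt(max(abs(apply(scr$x, 2, sd) - 1)), 1e-10)
  # re-scaling scaled data is the identity within tolerance
  expect_lt(max(abs(scale_columns(scr)$x - scr$x)), 1e-10)
})

test_that("constant columns are dropped with a warning when scaling", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 8))
  ds <- lbm_dataset(x, c("GroupLow", "GroupLow", "GroupHi"))
  expect_warning(sc <- scale_columns(ds), "constant column")
  expect_equal(colnames(sc$x), c("a", "c"))
})

test_that("training-only scaling statistics can be requested", {
  ds <- make_random(n = 10, p = 3, seed = 5)
  sc <- scale_columns(ds, stats_from = rownames(ds$x)[1:6])
  expect_lt(max(abs(colMeans(sc$x[1:6, ]))), 1e-10)
  expect_gt(max(abs(colMeans(sc$x))), 1e-10)  # full-matrix means shifted
})

test_that("drop_zero_features removes only all-zero columns and is idempotent", {
  x <- cbind(a = c(1, 0, 2), b = c(0, 0, 0), c = c(0, 3, 0))
  ds <- lbm_dataset(x, c("GroupLow", "GroupLow", "GroupHi"))
  out <- drop_zero_features(ds)
  expect_equal(colnames(out$x), c("a", "c"))
  expect_identical(drop_zero_features(out)$x, out$x)
  clean <- make_random(n = 4, p = 3, seed = 1)
  expect_identical(drop_zero_features(clean)$x, clean$x)
})
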