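test_that("metabolite table parses non-detects and round-trips through TSV", {
  vals <- matrix(c(1.5, 2, 3, 4, NA, 6, 7, 8, 9), 3,
                 dimnames = list(paste0("S", 1:3), paste0("M", 1:3)))
  t <- tiny_table(vals)
  expect_equal(sum(!t$detected), 1L)
  expect_identical(t$seasons, c("rainy", "rainy", "dry"))

  d <- withr::local_tempdir()
  f1 <- file.path(d, "m.tsv"); f2 <- file.path(d, "meta.tsv")
  write_metabolite_table(t, f1, f2)
  t2 <- read_metabolite_table(f1, f2)
  expect_equal(t2$values, t$values)
  expect_identical(t2$detected, t$detected)
  expect_identical(t2$months, t$months)
  expect_identical(t2$seasons, t$seasons)

  # contract violations
  bad <- readLines(f1)
  bad[2] <- sub("1.5", "-1", bad[2], fixed = TRUE)
  writeLines(bad, f1)
  expect_error(read_metabolite_table(f1, f2), "negative")
  expect_error(metabolite_table(vals, months = c(5, 6, 11),
                                seasons = c("rainy", "monsoon", "dry")),
               "season")
  dup <- vals; rownames(dup) <- c("S1", "S1", "S3")
  expect_error(metabolite_table(dup, months = c(5, 6, 11)), "duplicate")
})

test_that("property and annotation tables round-trip and validate groups", {
  vals <- matrix(rnorm(9 * 4), 9,
                 dimnames = list(paste0("S", 1:9), paste0("P", 1:4)))
  vals[3, 2] <- NA
  p <- property_table(vals, setNames(c("vulcanization", "tensile",
                                       "heat_aging", "tensile"),
                                     paste0("P", 1:4)))
  d <- withr::local_tempdir()
  write_property_table(p, file.path(d, "p.tsv"), file.path(d, "g.tsv"))
  p2 <- read_property_table(file.path(d, "p.tsv"), file.path(d, "g.tsv"))
  expect_equal(p2$values, p$values)
  expect_identical(p2$groups, p$groups)
  expect_error(property_table(vals, setNames(rep("rheology", 4),
                                             paste0("P", 1:4))),
               "unknown property group")

  a <- data.frame(metabolite_id = c("m1", "m2"), smiles = c("CCO", NA),
                  compound_id = c("C1", NA), chem_class = c("acid", NA),
                  pathway = c(NA, "tca"), stringsAsFactors = FALSE)
  write_annotation_table(a, file.path(d, "a.tsv"))
  expect_identical(read_annotation_table(file.path(d, "a.tsv")), a)
})

test_that("drop_empty_items removes exactly the all-blank items", {
  n_items <- 36
  vals <- matrix(rnorm(9 * n_items), 9,
                 dimnames = list(paste0("S", 1:9), paste0("H", 1:n_items)))
  vals[, c(7, 19)] <- NA                 # two items blank in all samples
  vals[2, 4] <- NA                       # partial blank must survive
  p <- property_table(vals, setNames(rep("heat_aging", n_items),
                                     colnames(vals)))
  de <- drop_empty_items(p)
  expect_equal(length(de$table$item_ids), 34)
  expect_identical(de$dropped, c("H7", "H19"))
  expect_identical(de$table$values, vals[, -c(7, 19)])   # values untouched

  expect_identical(drop_empty_items(de$table)$dropped, character(0))
  all_blank <- property_table(matrix(NA_real_, 9, 2,
                                     dimnames = list(paste0("S", 1:9),
                                                     c("a", "b"))),
                              c(a = "tensile", b = "tensile"))
  de2 <- drop_empty_items(all_blank)
  expect_length(de2$table$item_ids, 0)
  expect_identical(de2$dropped, c("a", "b"))
})

test_that("standardize uses population SD, is idempotent and affine-invariant", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  z <- standardize(c(1, 2, 3))
  expect_equal(standardize(z), z, tolerance = 1e-12)

  set.seed(42)
  for (rep in 1:20) {
    x <- rnorm(9)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    expect_equal(standardize(a * x + b), standardize(x), tolerance = 1e-10)
  }
  # missing entries stay missing, non-missing standardized over themselves
  m <- matrix(c(1, 2, 3, NA, 5, 7), 3, dimnames = list(NULL, c("u", "v")))
  s <- standardize(m)
  expect_true(is.na(s[1, 2]))
  expect_equal(mean(s[, 2], na.rm = TRUE), 0)
  expect_error(standardize(matrix(c(1, 1, 1, 1, 2, 3), 3,
                                  dimnames = list(NULL, c("flat", "ok")))),
               "flat")
})

test_that("non-detect policies behave as defined", {
  vals <- matrix(c(NA, 4, 8,  1, 2, 3,  NA, NA, 5), 3,
                 dimnames = list(paste0("S", 1:3), c("a", "b", "c")))
  t <- tiny_table(vals)
  hm <- apply_nondetect_policy(t, "half_min")
  expect_equal(unname(hm$values[, "a"]), c(2, 4, 8))
  expect_equal(unname(hm$values[, "c"]), c(2.5, 2.5, 5))
  z <- apply_nondetect_policy(t, "zero")
  expect_equal(unname(z$values[, "a"]), c(0, 4, 8))
  dm <- apply_nondetect_policy(t, "drop_metabolite")
  expect_identical(dm$metabolite_ids, "b")

  full <- tiny_table(matrix(1:9, 3))
  expect_equal(apply_nondetect_policy(full, "zero")$values, full$values)
})
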