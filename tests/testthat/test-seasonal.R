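test_that("detection accounting matches hand enumeration", {
  # A detected everywhere; B rainy-only; C in a single dry sample
  det <- cbind(A = c(TRUE, TRUE, TRUE, TRUE),
               B = c(TRUE, TRUE, FALSE, FALSE),
               C = c(FALSE, FALSE, TRUE, FALSE))
  vals <- matrix(1, 4, 3, dimnames = list(paste0("S", 1:4), colnames(det)))
  t <- metabolite_table(vals, months = c(5, 6, 11, 12), detected = det)
  dc <- detection_counts(t)
  expect_equal(unname(dc$per_sample), c(2, 2, 2, 1))
  expect_equal(dc$summary[["union"]], 3)
  expect_equal(dc$summary[["all_samples"]], 1)
  expect_equal(dc$summary[["only_rainy"]], 1)
  expect_equal(dc$summary[["only_dry"]], 1)
  expect_equal(dc$summary[["throughout_rainy"]], 2)
  expect_equal(dc$summary[["throughout_dry"]], 1)

  all_det <- metabolite_table(vals, months = c(5, 6, 11, 12))
  dc2 <- detection_counts(all_det)
  expect_equal(dc2$summary[["union"]], 3)
  expect_equal(dc2$summary[["all_samples"]], 3)
})

test_that("concordance is Jaccard: symmetric, bounded, exact on fixtures", {
  det <- cbind(a = c(TRUE, TRUE, FALSE), b = c(TRUE, TRUE, TRUE),
               c = c(TRUE, TRUE, FALSE), d = c(FALSE, TRUE, TRUE))
  vals <- matrix(1, 3, 4, dimnames = list(paste0("S", 1:3), colnames(det)))
  t <- metabolite_table(vals, months = c(5, 6, 11), detected = det)
  # D1 = {a,b,c}, D2 = {a,b,c,d} -> 3/4; D1 vs D3 = {b,d} -> 1/4
  expect_equal(concordance_rate(t, 1, 2), 0.75)
  expect_equal(concordance_rate(t, 1, 3), 0.25)
  expect_equal(concordance_rate(t, 1, 2), concordance_rate(t, 2, 1))

  det2 <- cbind(a = c(TRUE, FALSE), b = c(TRUE, FALSE), c = c(TRUE, TRUE),
                d = c(FALSE, TRUE))
  vals2 <- matrix(1, 2, 4, dimnames = list(c("S1", "S2"), colnames(det2)))
  t2 <- metabolite_table(vals2, months = c(5, 11), detected = det2)
  # {a,b,c} vs {c,d} -> 1/4; overlap coefficient -> 1/2
  expect_equal(concordance_rate(t2, 1, 2), 0.25)
  expect_equal(concordance_rate(t2, 1, 2, method = "overlap"), 0.5)

  cm <- concordance_matrix(t)
  expect_true(isSymmetric(cm))
  expect_true(all(cm >= 0 & cm <= 1))
  expect_error(concordance_rate(t, 1, 1), "distinct")
})

test_that("one-tailed Mann-Whitney is exact by enumeration at small n", {
  # the most extreme 6-vs-3 arrangement: only 1 of C(9,3)=84 assignments
  # gives a rank sum at least as large
  res <- mann_whitney_one_tailed(1:6, c(7, 8, 9), "greater")
  expect_equal(res$p, 1 / 84, tolerance = 1e-12)
  expect_equal(res$U, 18)

  expect_equal(mann_whitney_one_tailed(2, 2, "greater")$p, 1)
  expect_equal(mann_whitney_one_tailed(2, 2, "less")$p, 1)

  # exact enumeration oracle on seeded no-tie and tied inputs
  set.seed(101)
  for (case in 1:25) {
    x <- rnorm(6); y <- rnorm(3, mean = runif(1, -1, 1))
    expect_equal(mann_whitney_one_tailed(x, y, "greater")$p,
                 mw_enumeration_p(x, y), tolerance = 1e-12)
  }
  for (case in 1:10) {
    x <- sample(1:4, 6, replace = TRUE)   # heavy ties
    y <- sample(1:4, 3, replace = TRUE)
    expect_equal(mann_whitney_one_tailed(x, y, "greater")$p,
                 mw_enumeration_p(x, y), tolerance = 1e-12)
  }
})

test_that("large-sample approximation tracks the permutation oracle", {
  set.seed(202)
  for (case in 1:6) {
    x <- round(rnorm(12), 1)              # rounding induces occasional ties
    y <- round(rnorm(10, 0.5), 1)
    p_impl <- mann_whitney_one_tailed(x, y, "greater")$p
    p_perm <- mw_permutation_p(x, y, 10000)
    mc_sd <- sqrt(p_perm * (1 - p_perm) / 10000)
    expect_lt(abs(p_impl - p_perm), max(3 * mc_sd, 0.02))
  }
})

test_that("seasonal screen direction counts are monotone in the threshold", {
  sc <- synthetic_scenario(n_metabolites = 120, rng_seed = 21)
  t <- generate_metabolite_matrix(sc)
  thresholds <- c(1.2, 1.5, 2, 3, 5, 1e6)
  ups <- downs <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    s <- seasonal_screen(t, thresholds[i])
    ups[i] <- s$n_up; downs[i] <- s$n_down
  }
  expect_true(all(diff(ups) <= 0))
  expect_true(all(diff(downs) <= 0))
  expect_identical(ups[length(ups)], 0L)
  expect_identical(downs[length(downs)], 0L)

  # one-season-absent metabolites are flagged, not counted as fold changes
  det <- cbind(x = c(TRUE, TRUE, FALSE, FALSE), y = rep(TRUE, 4))
  vals <- matrix(c(5, 6, 2, 3, 1, 1, 9, 9), 4, 2,
                 dimnames = list(paste0("S", 1:4), colnames(det)))
  tt <- metabolite_table(vals, months = c(5, 6, 11, 12), detected = det)
  scr <- suppressWarnings(seasonal_screen(tt, 2))
  expect_true(scr$table$presence_only[1])
  expect_identical(scr$table$direction[1], "none")
})

test_that("annotation tallies count labels and report the unlabelled", {
  a <- data.frame(metabolite_id = paste0("m", 1:5),
                  smiles = NA_character_, compound_id = NA_character_,
                  chem_class = c("acid", "acid", "amine", "amine", "sugar"),
                  pathway = c("tca", "tca", NA, "urea", "cancer"),
                  stringsAsFactors = FALSE)
  s <- summarize_annotations(a)
  expect_equal(as.integer(s$class_counts), c(2, 2, 1))
  expect_equal(s$n_unclassified, 0)
  s2 <- summarize_annotations(a, exclude_pathways = "cancer")
  expect_false("cancer" %in% names(s2$pathway_counts))
  expect_equal(s2$n_no_pathway, 1)

  a$chem_class <- NA_character_
  s3 <- summarize_annotations(a)
  expect_length(s3$class_counts, 0)
  expect_equal(s3$n_unclassified, 5)
})
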