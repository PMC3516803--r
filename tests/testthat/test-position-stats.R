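test_that("mutual information matches hand-computed values", {
  expect_equal(mutual_information(c(1, 1, 2, 2), c("U", "U", "A", "A")), 1.0)
  expect_equal(mutual_information(c(1, 1, 2, 2), c("U", "A", "U", "A")), 0.0)
  # 1/3*log2(2) + 1/3*log2(3) + 1/6*log2(3)
  expect_equal(mutual_information(c(1, 1, 1, 2, 2, 5),
                                  c("U", "U", "C", "A", "A", "C")),
               1 / 3 + log2(3) / 2, tolerance = 1e-12)
  expect_error(mutual_information(1:3, c("A", "C")), "length mismatch")
  expect_error(mutual_information(integer(0), character(0)), "empty")
})

test_that("MI is symmetric, non-negative and bounded by marginal entropies", {
  set.seed(5)
  H <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  for (i in 1:50) {
    n <- sample(4:40, 1)
    lab <- sample(c("AGO1", "AGO2", "AGO5"), n, replace = TRUE)
    bas <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    mi <- mutual_information(lab, bas)
    expect_gte(mi, -1e-12)
    expect_lte(mi, min(H(lab), H(bas)) + 1e-12)
    expect_equal(mi, mutual_information(bas, lab))
  }
})

test_that("permutation p-values behave at the extremes and are seeded", {
  # constant column: all shuffles tie the observed MI of 0 -> p = 1
  p0 <- permutation_pvalue(c(1, 1, 2, 2), rep("U", 4), n_perm = 99, seed = 1)
  expect_equal(p0$mi, 0)
  expect_equal(p0$p_emp, 1)
  # perfectly separating column: exceedance is (near) measure zero
  lab <- rep(c("AGO1", "AGO2"), each = 20)
  bas <- rep(c("U", "A"), each = 20)
  p1 <- permutation_pvalue(lab, bas, n_perm = 999, seed = 2)
  expect_lte(p1$p_emp, 0.01)
  expect_gt(p1$p_emp, 0)      # add-one convention: never exactly 0
  # determinism
  p2 <- permutation_pvalue(lab, bas, n_perm = 999, seed = 2)
  expect_identical(p1, p2)
})

test_that("fixed-margin table sampling agrees with literal label shuffling", {
  set.seed(31)
  lab <- rep(c("AGO1", "AGO2", "AGO5"), c(12, 9, 7))
  bas <- sample(c("A", "C", "G", "U"), 28, replace = TRUE, prob = c(.4, .3, .2, .1))
  a <- permutation_pvalue(lab, bas, n_perm = 2000, seed = 7, method = "margins")
  b <- permutation_pvalue(lab, bas, n_perm = 2000, seed = 7, method = "shuffle")
  # identical null distribution family: p and null moments agree within MC error
  expect_lt(abs(a$p_emp - b$p_emp), 0.05)
  expect_lt(abs(a$null_mean - b$null_mean), 0.02)
})

test_that("BH adjustment matches the step-up computation and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # monotone in the order statistics
  set.seed(8)
  p <- runif(21)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("MI profiles recover a planted signal position and handle subsets", {
  spec <- table1_signal_spec(position = 6, n_per_class = c(30L, 20L, 15L))
  seqs <- generate_sequences(spec, seed = 13)
  prof <- mi_profile(data.frame(seq = seqs$seq, ago = seqs$class),
                     n_perm = 999, seed = 14)
  expect_s3_class(prof, "mi_profile")
  expect_equal(nrow(prof), 21)
  expect_equal(which.max(prof$mi_bits), 6)
  expect_lt(prof$p_fdr[6], 0.05)
  expect_true(all(prof$p_fdr >= prof$p_emp))
  # pairwise subset: a column constant within the subset has zero MI
  df <- data.frame(seq = c(paste0("U", substr(random_mature(4, 20), 1, 20))),
                   ago = c("AGO1", "AGO1", "AGO5", "AGO5"))
  pr2 <- mi_profile(df, class_subset = c("AGO1", "AGO5"), n_perm = 0)
  expect_equal(pr2$mi_bits[1], 0)
  expect_error(mi_profile(df, class_subset = c("AGO1", "AGO2"), n_perm = 0),
               "0 members")
})

test_that("5'-base enrichment ratios are class frequency over background", {
  counts <- matrix(c(10, 0, 0, 10), 2, 2,
                   dimnames = list(c("X", "Y"), c("A", "U")))
  counts <- cbind(counts, C = 0, G = 0)[, c("A", "C", "G", "U")]
  comp <- base_composition(counts, c(A = 50, C = 0, G = 0, U = 50))
  # class frequency equal to background -> would be 1; here class is pure
  expect_equal(comp$enrichment[comp$class == "X" & comp$base == "A"], 2)
  expect_equal(comp$enrichment[comp$class == "X" & comp$base == "U"], 0)
  # zero background with nonzero class count flags infinite
  counts2 <- matrix(c(5L, 5L, 0L, 0L), 1, 4,
                    dimnames = list("Z", c("A", "C", "G", "U")))
  comp2 <- base_composition(counts2, c(A = 10, C = 0, G = 5, U = 5))
  expect_true(is.infinite(comp2$enrichment[comp2$base == "C"]))
})

test_that("logo information content follows R = 2 - H with optional correction", {
  allU <- rep(paste0("U", paste(rep("A", 20), collapse = "")), 4)
  lg <- logo_information(allU)
  expect_equal(lg$information[1], 2)
  expect_equal(lg$U[1], 2)     # single base carries the full stack
  uniform <- c("AAAA", "CCCC", "GGGG", "UUUU")
  expect_equal(logo_information(uniform)$information[1], 0)
  half <- c("AU", "AU", "UA", "UA")
  lg2 <- logo_information(half)
  expect_equal(lg2$information[1], 1)
  expect_equal(lg2$A[1], 0.5)
  expect_equal(lg2$U[1], 0.5)
  # small-sample correction subtracts 3 / (2 ln2 n), floored at zero
  lgc <- logo_information(allU, correction = TRUE)
  expect_equal(lgc$information[1], 2 - 3 / (2 * log(2) * 4))
  expect_equal(logo_information(uniform, correction = TRUE)$information[1], 0)
})

test_that("profile correlations match hand-computed Pearson and Spearman", {
  r <- correlate_profiles(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(r$pearson_r, 1)
  r2 <- correlate_profiles(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r2$pearson_r, 0.8)
  expect_equal(r2$spearman_rho, 0.8)
  r3 <- correlate_profiles(1:5, 5:1)
  expect_equal(r3$pearson_r, -1)
  expect_error(correlate_profiles(1:4, rep(2, 4)), "zero-variance")
  expect_error(correlate_profiles(1:2, 1:2), "length")
})
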