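test_that("feature encoding pads sequences with N and patterns with unbound", {
  cs <- data.frame(full_seq = c(paste(rep("A", 21), collapse = ""),
                                paste(rep("C", 24), collapse = "")),
                   ago = c("AGO1", "AGO2"))
  f <- encode_features(cs, "sequence")
  expect_equal(ncol(f), 24)
  expect_equal(as.character(f$pos22[1]), "N")
  expect_equal(as.character(f$pos24[1]), "N")
  expect_equal(as.character(f$pos24[2]), "C")
  expect_true(all(vapply(f, function(col)
    all(levels(col) == c("A", "C", "G", "U", "N")), logical(1))))
  # pairing mode: a 21-position pattern leaves 22-24 unbound
  pat <- structure(list(states = c(rep("WC", 19), "unpaired", "wobble"),
                        n_mismatches = 0L, max_bulge = 0L, score = 0),
                   class = "duplex_pattern")
  fp <- encode_features(cs, "pairing", patterns = list(pat, pat))
  expect_equal(as.character(fp$pos1[1]), "bound")
  expect_equal(as.character(fp$pos21[1]), "wobble")
  expect_equal(as.character(fp$pos22[1]), "unbound")
  # dropping the first position leaves 23 columns
  expect_equal(ncol(encode_features(cs, "sequence", include_first = FALSE)), 23)
  expect_error(encode_features(cs, "pairing"), "requires")
})

test_that("a perfectly informative feature yields near-perfect OOB accuracy", {
  set.seed(100)
  labels <- rep(c("AGO1", "AGO2", "AGO5"), each = 20)
  feats <- data.frame(
    pos1 = factor(c("U", "A", "C")[as.integer(factor(labels))],
                  levels = c("A", "C", "G", "U", "N")),
    pos2 = factor(sample(c("A", "C", "G", "U"), 60, replace = TRUE),
                  levels = c("A", "C", "G", "U", "N")))
  fr <- train_forest(feats, labels, seed = 101)
  expect_gte(fr$oob_accuracy, 0.95)
  # vote fractions sum to 1 per sample, margins within [-1, 1]
  expect_true(all(abs(rowSums(fr$votes) - 1) < 1e-9))
  expect_true(all(margins(fr) >= -1 & margins(fr) <= 1))
  # margin arithmetic: true-class vote minus best alternative
  i <- 1
  true_col <- as.integer(fr$labels[i])
  expect_equal(fr$margins[i],
               fr$votes[i, true_col] - max(fr$votes[i, -true_col]))
})

test_that("forests are deterministic under a fixed seed", {
  seqs <- table1_cohort(seed = 55, n_per_class = c(15L, 12L, 10L))
  f <- encode_features(seqs, "sequence")
  a <- train_forest(f, seqs$class, n_trees = 101, seed = 42)
  b <- train_forest(f, seqs$class, n_trees = 101, seed = 42)
  expect_identical(a$votes, b$votes)
  expect_identical(a$importance, b$importance)
  expect_error(train_forest(f[1:16, ], c(rep("A", 15), "B")), "at least 2")
})

test_that("variable importance is zero for constants and peaks at planted signal", {
  set.seed(200)
  labels <- rep(c("AGO1", "AGO2", "AGO5"), each = 25)
  feats <- data.frame(
    pos1 = factor(sample(c("A", "C", "G", "U"), 75, replace = TRUE),
                  levels = c("A", "C", "G", "U", "N")),
    pos2 = factor(c("U", "A", "C")[as.integer(factor(labels))],
                  levels = c("A", "C", "G", "U", "N")),
    pos3 = factor(rep("G", 75), levels = c("A", "C", "G", "U", "N")))
  fr <- train_forest(feats, labels, seed = 201)
  imp <- variable_importance(fr)
  expect_equal(unname(which.max(imp)), 2L)
  expect_equal(unname(imp["pos3"]), 0)   # constant feature: nothing to permute
})

test_that("an all-constant encoding gives the analytic chance-level forest", {
  feats <- data.frame(pos1 = factor(rep("C", 40), levels = c("A", "C", "G", "U", "N")))
  labels <- rep(c("AGO1", "AGO5"), c(25, 15))
  fr <- train_forest(feats, labels, seed = 1)
  expect_equal(fr$oob_accuracy, 25 / 40)   # tie broken by class order
  expect_true(all(margins(fr) == 0))
  expect_equal(unname(variable_importance(fr)), 0)
})

test_that("Wilcoxon rank-sum matches the exact enumeration and symmetries", {
  # C(6,3) = 20 arrangements, U = 0 -> two-sided p = 2/20
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1.0)
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(2.0, 4.4, 6.1)
  expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(y, x))
})

test_that("single-feature forest agrees with a balanced-bootstrap leaf oracle", {
  # one categorical feature, two classes: each tree reduces to the in-bag
  # majority within each feature level; simulate that rule directly
  set.seed(300)
  n <- 40
  labels <- factor(rep(c("AGO1", "AGO2"), each = n / 2))
  lvl <- c("U", "U", "U", "A")  # feature correlates imperfectly with class
  feat <- factor(ifelse(labels == "AGO1", sample(lvl, n, TRUE),
                        sample(rev(lvl), n, TRUE)), levels = c("A", "U"))
  fr <- train_forest(data.frame(pos1 = feat), labels,
                     n_trees = 1000, sampsize = 10, seed = 301)
  oracle_votes <- matrix(0, n, 2)
  for (t in 1:2000) {
    inbag <- c(sample(which(labels == "AGO1"), 10, TRUE),
               sample(which(labels == "AGO2"), 10, TRUE))
    oob <- setdiff(1:n, unique(inbag))
    for (lv in c("A", "U")) {
      members <- inbag[feat[inbag] == lv]
      if (!length(members)) next
      tab <- table(labels[members])
      win <- names(tab)[which.max(tab)]
      hit <- oob[feat[oob] == lv]
      oracle_votes[cbind(hit, ifelse(win == "AGO1", 1, 2))] <-
        oracle_votes[cbind(hit, ifelse(win == "AGO1", 1, 2))] + 1
    }
  }
  oracle_pred <- ifelse(oracle_votes[, 1] >= oracle_votes[, 2], "AGO1", "AGO2")
  oracle_acc <- mean(oracle_pred == labels)
  expect_lt(abs(fr$oob_accuracy - oracle_acc), 0.1)
})

test_that("identical conditions compare to a median p of 1", {
  seqs <- table1_cohort(seed = 77, n_per_class = c(12L, 10L, 8L))
  f <- encode_features(seqs, "sequence")
  cmp <- compare_conditions(f, f, seqs$class, n_runs = 3, n_trees = 101,
                            seed = 5)
  expect_equal(cmp$median_p, 1.0)
  expect_equal(cmp$mean_accuracy_a, cmp$mean_accuracy_b)
})

test_that("a planted signal separates from the class-shuffled baseline", {
  seqs <- table1_cohort(seed = 78, n_per_class = c(25L, 20L, 18L))
  f <- encode_features(seqs, "sequence")
  cmp <- compare_conditions(f, f, seqs$class, n_runs = 15, n_trees = 200,
                            seed = 6, shuffle_b = TRUE)
  expect_lt(cmp$median_p, 0.05)
  expect_gt(cmp$mean_accuracy_a, cmp$mean_accuracy_b)
})

test_that("mean margin tracks OOB accuracy across runs", {
  seqs <- table1_cohort(seed = 79, n_per_class = c(15L, 12L, 10L))
  f <- encode_features(seqs, "sequence")
  set.seed(9)
  acc <- numeric(20); mar <- numeric(20)
  for (r in 1:20) {
    lab <- if (r %% 2 == 0) seqs$class else sample(seqs$class)
    fr <- train_forest(f, lab, n_trees = 101, importance = FALSE)
    acc[r] <- fr$oob_accuracy
    mar[r] <- mean(margins(fr))
  }
  expect_gt(cor(acc, mar, method = "spearman"), 0)
})
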