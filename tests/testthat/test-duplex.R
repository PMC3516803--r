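test_that("a perfect duplex is all Watson-Crick with no mismatches or bulges", {
  hp <- generate_hairpin(FIX_MATURE, seed = 1)
  d <- infer_duplex(hp)
  expect_true(all(d$states[1:19] == "WC"))
  expect_equal(d$states[20:21], c("unpaired", "unpaired"))  # 3' overhang
  expect_equal(d$n_mismatches, 0)
  expect_equal(d$max_bulge, 0)
  expect_equal(d$score, 2 * 19)
})

test_that("planted wobbles, mismatches and bulges are recovered", {
  hpw <- generate_hairpin("ACGUGCGUACGGCAUUGACGC", wobble_positions = 5, seed = 2)
  dw <- infer_duplex(hpw)
  expect_equal(dw$states[5], "wobble")
  expect_equal(dw$n_mismatches, 0)   # wobble is paired, not a mismatch
  hpm <- generate_hairpin(FIX_MATURE, mismatch_positions = c(3, 7, 11), seed = 2)
  dm <- infer_duplex(hpm)
  expect_equal(dm$n_mismatches, 3)
  expect_equal(which(dm$states[1:19] == "unpaired"), c(3, 7, 11))
  for (sd in 1:5) {
    hp2 <- generate_hairpin(FIX_MATURE, seed = sd,
                            bulge = list(strand = "star", position = 10, length = 2))
    d2 <- infer_duplex(hp2)
    expect_equal(d2$max_bulge, 2)
    expect_true(all(d2$states[1:19] == "WC"))
    hp4 <- generate_hairpin(FIX_MATURE, seed = sd,
                            bulge = list(strand = "star", position = 10, length = 4))
    expect_equal(infer_duplex(hp4)$max_bulge, 4)
  }
  hpb <- generate_hairpin(FIX_MATURE, seed = 3,
                          bulge = list(strand = "mature", position = 8, length = 2))
  db <- infer_duplex(hpb)
  expect_equal(db$max_bulge, 2)
  expect_equal(which(db$states[1:19] == "unpaired"), c(8, 9))
})

test_that("star arm can be derived from precursor coordinates", {
  hp <- generate_hairpin(FIX_MATURE, seed = 4)
  rec <- hp
  rec$star_seq <- NA_character_
  expect_equal(infer_duplex(rec)$states, infer_duplex(hp)$states)
  rec$star_start <- NA_integer_; rec$star_end <- NA_integer_
  expect_error(infer_duplex(rec), "star sequence absent")
})

test_that("aligner agrees with per-position complementarity on perfect duplexes", {
  set.seed(77)
  for (i in 1:100) {
    m <- random_mature(1)
    hp <- generate_hairpin(m, seed = NULL)
    d <- infer_duplex(hp)
    mb <- strsplit(m, "")[[1]]
    sb <- strsplit(hp$star_seq, "")[[1]]
    # brute-force oracle: mature i pairs star core position (19 - i + 1)
    oracle <- vapply(1:19, function(i) {
      pair <- c(A = "U", U = "A", G = "C", C = "G")[[mb[i]]] == sb[19 - i + 1]
      if (pair) "WC" else "other"
    }, character(1))
    expect_equal(d$states[1:19], unname(oracle))
    expect_equal(d$score, 38)
  }
})

test_that("alignment score is invariant under strand exchange", {
  # exchanging the strands (mature <-> star read 3'->5') presents the same
  # pair columns, so the optimal score is unchanged
  set.seed(88)
  for (i in 1:20) {
    m <- random_mature(1)
    hp <- generate_hairpin(m, mismatch_positions = sample(3:17, 2), seed = NULL)
    a <- infer_duplex(hp$mature_seq, star = hp$star_seq)
    # exchange: the star core becomes the mature strand and vice versa
    # (fresh 2-nt 3' overhangs appended, which the aligner trims off)
    m2 <- paste0(substr(hp$star_seq, 1, 19), "AA")
    s2 <- paste0(substr(m, 1, 19), "AA")
    b <- infer_duplex(m2, star = s2)
    expect_equal(a$score, b$score)
  }
})

test_that("precursor filter uses strict thresholds and is monotone", {
  mk <- function(mis, bulge) {
    structure(list(states = rep("WC", 21), n_mismatches = mis,
                   max_bulge = bulge, score = 0), class = "duplex_pattern")
  }
  expect_false(filter_precursor(mk(7, 0))$pass)
  expect_equal(filter_precursor(mk(7, 0))$reason, "mismatches")
  expect_true(filter_precursor(mk(6, 3))$pass)    # boundary passes
  expect_false(filter_precursor(mk(0, 4))$pass)
  expect_equal(filter_precursor(mk(0, 4))$reason, "bulge")
  # monotone: adding a mismatch never converts fail -> pass
  for (m in 0:9) {
    if (!filter_precursor(mk(m, 0))$pass) {
      expect_false(filter_precursor(mk(m + 1, 0))$pass)
    }
  }
})

test_that("external dot-bracket duplex structures import as patterns", {
  p <- parse_duplex_structure("(((:...((-((((((((((.")
  expect_equal(length(p$states), 21)
  expect_equal(p$states[4], "wobble")
  expect_equal(p$states[5], "unpaired")
  expect_equal(p$max_bulge, 1)
  expect_error(parse_duplex_structure("((x"), "only")
})

test_that("pairing frequencies divide paired duplexes by class size", {
  mkpat <- function(unpaired_at) {
    st <- rep("WC", 21); st[unpaired_at] <- "unpaired"
    structure(list(states = st, n_mismatches = length(unpaired_at),
                   max_bulge = 0, score = 0), class = "duplex_pattern")
  }
  # 7 of 25 unpaired at position 12 -> 72% paired
  pats <- c(lapply(1:7, function(i) mkpat(12)), lapply(1:18, function(i) mkpat(NULL)))
  classes <- rep("AGO2", 25)
  prof <- pairing_frequency_profile(pats, classes)
  expect_equal(prof$pct_paired[prof$class == "AGO2" & prof$position == 12], 72)
  expect_equal(prof$pct_paired[prof$class == "AGO2" & prof$position == 3], 100)
  expect_equal(max(prof$position), 19)
  # Total is the pooled union, not the mean of class profiles
  pats2 <- c(pats, lapply(1:5, function(i) mkpat(12)))
  classes2 <- c(classes, rep("AGO1", 5))
  prof2 <- pairing_frequency_profile(pats2, classes2)
  tot12 <- prof2$pct_paired[prof2$class == "Total" & prof2$position == 12]
  expect_equal(tot12, (30 - 12) / 30 * 100)           # pooled: 18/30
  expect_false(isTRUE(all.equal(tot12, mean(c(72, 0)))))  # not mean of classes
})
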