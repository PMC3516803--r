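# Shared fixtures, built in code.

# a 21-nt aperiodic mature sequence used throughout the duplex tests
FIX_MATURE <- "ACCGGUUACGGCAUUGACGCA"

random_mature <- function(n = 1, length = 21) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE), collapse = ""),
    character(1))
}

# small labeled cohort with the observed 5'-base profile
table1_cohort <- function(seed = 1, n_per_class = c(70L, 25L, 22L)) {
  generate_sequences(table1_signal_spec(n_per_class = n_per_class), seed = seed)
}

# write a tiny mature/precursor FASTA pair + coordinate table to dir
write_mirna_fixture <- function(dir) {
  pre <- c(pre1 = "ACGUACGUACGUACGUACGUAGGGAAACCCUACGUACGUACG",
           pre2 = "GGGCCCAAAUUUGGGCCCAAAUUUGGGCCC")
  mat <- c(mir1 = substr(pre[["pre1"]], 1, 21),
           mir2 = substr(pre[["pre2"]], 4, 24))
  fa <- function(x, path) {
    writeLines(paste0(">", names(x), "\n", unname(x)), path)
    path
  }
  list(
    mature = fa(mat, file.path(dir, "mature.fa")),
    precursor = fa(pre, file.path(dir, "precursor.fa")),
    coords = data.frame(
      mirna_id = c("mir1", "mir2"),
      precursor_id = c("pre1", "pre2"),
      start = c(1L, 4L), end = c(21L, 24L),
      arm = "mature"))
}
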