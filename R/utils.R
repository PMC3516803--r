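## Shared helpers: RNA string handling, validation, small conveniences.

RNA_BASES <- c("A", "C", "G", "U")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Convert sequences to the internal RNA alphabet
#'
#' Uppercases and transliterates T to U. The package stores all sequences
#' as RNA (A/C/G/U, plus N for padding/ambiguity).
#'
#' @param x character vector of sequences (DNA or RNA).
#' @return character vector in the RNA alphabet.
#' @export
as_rna <- function(x) {
  x <- toupper(as.character(x))
  chartr("T", "U", x)
}

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("U", "T", toupper(as.character(x)))

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of RNA sequences.
#' @return character vector of reverse complements.
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", as_rna(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

rna_complement_base <- function(b) chartr("ACGU", "UGCA", b)

## split sequences into a character matrix (rows = sequences), padding with
## `pad` on the right up to `width`
seq_matrix <- function(seqs, width = max(nchar(seqs)), pad = "N") {
  n <- length(seqs)
  m <- matrix(pad, nrow = n, ncol = width)
  sp <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_len(n)) {
    w <- min(length(sp[[i]]), width)
    if (w > 0) m[i, seq_len(w)] <- sp[[i]][seq_len(w)]
  }
  m
}

check_rna_alphabet <- function(seqs, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGUN]*$" else "^[ACGU]*$"
  bad <- !grepl(pat, seqs)
  if (any(bad)) {
    stop(sprintf("%s contains non-RNA characters (first offender: '%s')",
                 what, seqs[which(bad)[1]]), call. = FALSE)
  }
  invisible(seqs)
}

check_prob <- function(p, what = "distribution", tol = 1e-9) {
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    stop(sprintf("%s must be non-negative and sum to 1", what), call. = FALSE)
  }
  invisible(p)
}

## deterministic TSV writer: fixed column order, no quoting surprises
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
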