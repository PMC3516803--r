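## From raw reads / count tables to the labeled Confidence Set:
## adapter trimming, exact-match counting, RPM normalization, the
## 10-RPM / 70%-share preference rule, deduplication and 21-nt trimming.

#' Trim adapter suffixes and cap read length
#'
#' Removes everything from the first exact occurrence of the adapter
#' onward, then truncates reads to `max_len` nucleotides. Reads that are
#' empty after trimming are dropped (count in `attr(, "n_dropped")`).
#'
#' @param reads character vector of reads (DNA or RNA alphabet).
#' @param adapter adapter sequence (same alphabet as given); `NULL` skips
#'   adapter removal.
#' @param max_len maximum retained read length (default 30).
#' @return trimmed reads, in the RNA alphabet.
#' @export
trim_reads <- function(reads, adapter = NULL, max_len = 30) {
  reads <- as_rna(reads)
  if (!is.null(adapter) && nzchar(adapter)) {
    adapter <- as_rna(adapter)
    pos <- regexpr(adapter, reads, fixed = TRUE)
    hit <- pos > 0
    reads[hit] <- substr(reads[hit], 1, pos[hit] - 1)
  }
  reads <- substr(reads, 1, max_len)
  empty <- !nzchar(reads)
  if (any(empty)) {
    message(sum(empty), " read(s) empty after trimming, dropped")
  }
  out <- reads[!empty]
  attr(out, "n_dropped") <- sum(empty)
  out
}

#' Count miRNA-matching reads per library
#'
#' For each mature miRNA sequence, counts the reads in each library that
#' contain it as an exact substring. A read matching several distinct
#' miRNA sequences increments each of them (miRNAs are matched to reads
#' independently). Identical mature sequences share one row (first id
#' kept).
#'
#' @param reads_by_library named list of read vectors (one per library).
#' @param mirnas data.frame with `id` and a mature-sequence column
#'   (`mature_seq` or `seq`), or a named character vector of sequences.
#' @return a [count_table()] with derived library totals.
#' @export
count_reads <- function(reads_by_library, mirnas) {
  if (length(mirnas) == 0 || (is.data.frame(mirnas) && nrow(mirnas) == 0)) {
    stop("empty miRNA list")
  }
  if (is.character(mirnas)) {
    mirnas <- data.frame(id = names(mirnas) %||% paste0("mir", seq_along(mirnas)),
                         mature_seq = unname(mirnas), stringsAsFactors = FALSE)
  }
  seqcol <- intersect(c("mature_seq", "seq"), names(mirnas))[1]
  if (is.na(seqcol)) stop("mirnas must have a 'mature_seq' or 'seq' column")
  if (nrow(mirnas) == 0) stop("empty miRNA list")
  seqs <- as_rna(mirnas[[seqcol]])
  check_rna_alphabet(seqs, what = "mature sequence")
  keep <- !duplicated(seqs)
  ids <- mirnas$id[keep]
  useqs <- seqs[keep]

  libs <- names(reads_by_library)
  counts <- matrix(0L, nrow = length(useqs), ncol = length(libs),
                   dimnames = list(ids, libs))
  for (j in seq_along(libs)) {
    subj <- Biostrings::BStringSet(as_rna(reads_by_library[[j]]))
    for (i in seq_along(useqs)) {
      counts[i, j] <- sum(Biostrings::vcountPattern(useqs[i], subj) > 0)
    }
  }
  ct <- count_table(counts)
  attr(ct, "sequences") <- stats::setNames(useqs, ids)
  ct
}

#' Reads-per-million normalization
#'
#' `rpm[i, j] = counts[i, j] / library_totals[j] * 1e6`.
#'
#' @param table a [count_table()].
#' @return an `rpm_table`: list with `rpm` matrix and the originating
#'   totals/provenance.
#' @export
normalize_rpm <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (any(table$library_totals <= 0)) stop("library totals must be positive")
  rpm <- sweep(table$counts, 2, table$library_totals, "/") * 1e6
  structure(list(rpm = rpm, counts = table$counts,
                 library_totals = table$library_totals,
                 totals_provenance = table$totals_provenance,
                 sequences = attr(table, "sequences")),
            class = "rpm_table")
}

#' Assign each miRNA an AGO preference label
#'
#' A miRNA whose summed RPM over all libraries falls below `min_rpm` is
#' `excluded`. Otherwise, if one library holds strictly more than
#' `threshold` of the miRNA's summed reads it receives that library's
#' label; otherwise it is `ambiguous`. Shares are computed on RPM by
#' default (`share_basis = "count"` uses raw counts instead).
#'
#' @param rpm an `rpm_table` from [normalize_rpm()].
#' @param min_rpm summed-RPM floor (default 10).
#' @param threshold preference share (default 0.70, strict inequality).
#' @param share_basis `"rpm"` or `"count"`.
#' @return data.frame with `id`, `status` (`labeled`/`excluded`/
#'   `ambiguous`), `ago`, `preference_fraction`, `rpm_total`.
#' @export
assign_preference <- function(rpm, min_rpm = 10, threshold = 0.70,
                              share_basis = c("rpm", "count")) {
  stopifnot(inherits(rpm, "rpm_table"))
  share_basis <- match.arg(share_basis)
  m <- rpm$rpm
  basis <- if (share_basis == "rpm") m else rpm$counts
  tot_rpm <- rowSums(m)
  tot_basis <- rowSums(basis)
  out <- data.frame(id = rownames(m), status = "ambiguous",
                    ago = NA_character_, preference_fraction = NA_real_,
                    rpm_total = tot_rpm, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in seq_len(nrow(m))) {
    if (tot_rpm[i] < min_rpm) {
      out$status[i] <- "excluded"
      next
    }
    shares <- basis[i, ] / tot_basis[i]
    b <- which.max(shares)
    out$preference_fraction[i] <- shares[b]
    if (shares[b] > threshold) {
      out$status[i] <- "labeled"
      out$ago[i] <- colnames(m)[b]
    }
  }
  out
}

#' Build the Confidence Set of AGO-preferring miRNAs
#'
#' Keeps labeled, precursor-filter-passing miRNAs; deduplicates identical
#' mature sequences (first id kept, duplicates logged); trims each
#' sequence to its 5'-anchored 21-mer (`seq21`). Sequences shorter than
#' 21 nt keep `seq21 = NA`: they are excluded from the 21-mer (MI-bound)
#' view but retained with their full sequence for the 24-padded
#' random-forest encoding. Two identical sequences carrying different
#' labels are an error (the preference rule makes labels exclusive).
#'
#' @param preferences output of [assign_preference()].
#' @param mirnas data.frame mapping `id` to `mature_seq`/`seq`; may be
#'   omitted when the preference table ids are themselves sequences.
#' @param filter_results optional data.frame with `id` and logical `pass`
#'   (from [filter_precursor()] applied per record).
#' @return a `confidence_set`: data.frame `id`, `seq21`, `full_seq`,
#'   `ago`, `preference_fraction`, `rpm_total`, with per-class counts in
#'   `attr(, "class_counts")` and an exclusion log in
#'   `attr(, "exclusions")`.
#' @export
build_confidence_set <- function(preferences, mirnas = NULL,
                                 filter_results = NULL) {
  lab <- preferences[preferences$status == "labeled", , drop = FALSE]
  excl <- data.frame(id = character(0), reason = character(0))
  log_excl <- function(ids, why) {
    if (length(ids)) rbind(excl, data.frame(id = ids, reason = why)) else excl
  }
  excl <- log_excl(preferences$id[preferences$status == "excluded"],
                   "below RPM floor")
  excl <- log_excl(preferences$id[preferences$status == "ambiguous"],
                   "no library share above threshold")
  if (!is.null(filter_results)) {
    bad <- filter_results$id[!filter_results$pass]
    excl <- log_excl(intersect(lab$id, bad), "failed precursor filter")
    lab <- lab[!lab$id %in% bad, , drop = FALSE]
  }
  if (is.null(mirnas)) {
    seqs <- stats::setNames(as_rna(lab$id), lab$id)
  } else {
    seqcol <- intersect(c("mature_seq", "seq"), names(mirnas))[1]
    seqs <- stats::setNames(as_rna(mirnas[[seqcol]]), mirnas$id)[lab$id]
  }
  if (any(is.na(seqs))) stop("missing mature sequence for a labeled miRNA")

  ## identical sequences: same label -> collapse; different labels -> error
  dup <- duplicated(seqs)
  if (any(dup)) {
    for (s in unique(seqs[dup])) {
      labs <- unique(lab$ago[seqs == s])
      if (length(labs) > 1) {
        stop("identical mature sequence labeled with different AGOs: ", s)
      }
    }
    excl <- log_excl(lab$id[dup], "duplicate mature sequence")
  }
  keep <- !dup
  out <- data.frame(
    id = lab$id[keep],
    seq21 = ifelse(nchar(seqs[keep]) >= 21, substr(seqs[keep], 1, 21),
                   NA_character_),
    full_seq = unname(seqs[keep]),
    ago = lab$ago[keep],
    preference_fraction = lab$preference_fraction[keep],
    rpm_total = lab$rpm_total[keep],
    stringsAsFactors = FALSE, row.names = NULL)
  short <- out$id[is.na(out$seq21)]
  if (length(short)) {
    message(length(short), " sequence(s) shorter than 21 nt: kept for the ",
            "padded encoding, excluded from 21-mer analyses")
  }
  attr(out, "class_counts") <- table(out$ago)
  attr(out, "exclusions") <- excl
  class(out) <- c("confidence_set", "data.frame")
  out
}

#' @export
print.confidence_set <- function(x, ...) {
  cc <- attr(x, "class_counts")
  cat(sprintf("confidence_set: %d miRNAs (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(cc), cc), collapse = ", ")))
  invisible(x)
}
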