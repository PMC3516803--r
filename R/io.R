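## I/O: miRNA sets (FASTA + coordinate table), count tables, reports.

#' Load a miRNA set from FASTA files and a coordinate table
#'
#' Reads mature (and optionally star) and precursor sequences and a
#' miRBase-style coordinate table, and assembles one record per mature
#' miRNA with 1-based inclusive coordinates on its precursor. Sequences
#' are stored in the RNA alphabet (T transliterated to U on load).
#'
#' Records whose coordinates fall outside the precursor, or whose mature
#' sequence does not equal the annotated precursor substring, are rejected
#' (with the reason retained in `attr(x, "rejected")`). Duplicate mature
#' ids are an error.
#'
#' @param mature_fasta path to the mature-sequence FASTA.
#' @param precursor_fasta path to the precursor FASTA.
#' @param coordinates a data.frame (or TSV path) with columns
#'   `mirna_id`, `precursor_id`, `start`, `end`, `arm` (`"mature"` or
#'   `"star"`), 1-based inclusive.
#' @param star_fasta optional FASTA of star (passenger) sequences.
#' @return a `mirna_set`: data.frame with columns `id`, `mature_seq`,
#'   `star_seq`, `precursor_seq`, `mature_start`, `mature_end`,
#'   `star_start`, `star_end`; rejected records in `attr(, "rejected")`.
#' @export
load_mirna_set <- function(mature_fasta, precursor_fasta, coordinates,
                           star_fasta = NULL) {
  mats <- read_fasta(mature_fasta)
  pres <- read_fasta(precursor_fasta)
  stars <- if (!is.null(star_fasta)) read_fasta(star_fasta) else character(0)
  if (is.character(coordinates) && length(coordinates) == 1) {
    coordinates <- read_tsv(coordinates)
  }
  need <- c("mirna_id", "precursor_id", "start", "end", "arm")
  if (!all(need %in% names(coordinates))) {
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  }
  mc <- coordinates[coordinates$arm == "mature", , drop = FALSE]
  sc <- coordinates[coordinates$arm == "star", , drop = FALSE]
  if (anyDuplicated(mc$mirna_id)) {
    stop("duplicate mature id in coordinate table: ",
         mc$mirna_id[duplicated(mc$mirna_id)][1])
  }
  if (anyDuplicated(names(mats))) {
    stop("duplicate id in mature FASTA: ",
         names(mats)[duplicated(names(mats))][1])
  }

  recs <- list()
  rejected <- data.frame(id = character(0), reason = character(0))
  for (i in seq_len(nrow(mc))) {
    id <- mc$mirna_id[i]
    pid <- mc$precursor_id[i]
    reason <- NULL
    if (!id %in% names(mats)) {
      reason <- "mature sequence missing from FASTA"
    } else if (!pid %in% names(pres)) {
      reason <- "precursor sequence missing from FASTA"
    } else {
      pre <- pres[[pid]]
      s <- mc$start[i]; e <- mc$end[i]
      if (!(s >= 1 && s <= e && e <= nchar(pre))) {
        reason <- sprintf("mature span %d..%d outside precursor (length %d)",
                          s, e, nchar(pre))
      } else if (substr(pre, s, e) != mats[[id]]) {
        reason <- "mature sequence does not match precursor substring"
      }
    }
    if (!is.null(reason)) {
      rejected <- rbind(rejected, data.frame(id = id, reason = reason))
      next
    }
    ## star arm: explicit FASTA beats coordinate-derived substring
    ss <- se <- NA_integer_
    star <- NA_character_
    j <- which(sc$precursor_id == pid)
    if (length(j)) {
      j <- j[1]
      if (sc$start[j] >= 1 && sc$start[j] <= sc$end[j] &&
          sc$end[j] <= nchar(pres[[pid]])) {
        ss <- sc$start[j]; se <- sc$end[j]
        star <- substr(pres[[pid]], ss, se)
      }
      if (sc$mirna_id[j] %in% names(stars)) star <- stars[[sc$mirna_id[j]]]
    }
    recs[[length(recs) + 1]] <- data.frame(
      id = id, mature_seq = mats[[id]], star_seq = star,
      precursor_seq = pres[[pid]],
      mature_start = mc$start[i], mature_end = mc$end[i],
      star_start = ss, star_end = se,
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(id = character(0), mature_seq = character(0),
               star_seq = character(0), precursor_seq = character(0),
               mature_start = integer(0), mature_end = integer(0),
               star_start = integer(0), star_end = integer(0))
  if (nrow(rejected)) {
    message(nrow(rejected), " record(s) rejected during load")
  }
  attr(out, "rejected") <- rejected
  class(out) <- c("mirna_set", "data.frame")
  out
}

## FASTA reader returning a named character vector in the RNA alphabet
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as_rna(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a small-RNA count table
#'
#' Reads a TSV with a first column of miRNA ids, one column per library
#' (e.g. AGO1, AGO2, AGO4, AGO5), and non-negative integer cells. Library
#' totals are taken from `totals` when supplied (totals may exceed column
#' sums, e.g. when the sequencing totals include reads not mapping to any
#' miRNA); otherwise they default to column sums and the table is flagged
#' `totals_provenance = "derived"`.
#'
#' @param x TSV path, or a matrix/data.frame of counts with row names.
#' @param totals optional named numeric vector of per-library totals.
#' @return a `count_table` object.
#' @export
read_count_table <- function(x, totals = NULL) {
  if (is.character(x) && length(x) == 1) {
    df <- read_tsv(x)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
  } else {
    m <- as.matrix(x)
  }
  count_table(m, totals)
}

#' Construct a count table
#'
#' @param counts integer matrix, rows = miRNAs (rownames = ids),
#'   columns = libraries.
#' @param library_totals optional per-library totals; defaults to column
#'   sums (provenance flagged `"derived"` vs `"supplied"`).
#' @return a `count_table`: list with `counts`, `library_totals`,
#'   `totals_provenance`.
#' @export
count_table <- function(counts, library_totals = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) stop("counts must have miRNA ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have library ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate miRNA ids in count table")
  if (anyDuplicated(colnames(counts))) stop("duplicate library ids in count table")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at row '%s', column '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  if (is.null(library_totals)) {
    library_totals <- colSums(counts)
    prov <- "derived"
  } else {
    library_totals <- library_totals[colnames(counts)]
    if (any(is.na(library_totals)) || any(library_totals <= 0)) {
      stop("library_totals must be positive and named for every library")
    }
    if (any(colSums(counts) > library_totals)) {
      stop("library total smaller than its column sum")
    }
    prov <- "supplied"
  }
  structure(list(counts = counts,
                 library_totals = library_totals,
                 totals_provenance = prov),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d miRNAs x %d libraries (totals %s)\n",
              nrow(x$counts), ncol(x$counts), x$totals_provenance))
  print(utils::head(x$counts))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.count_table <- function(x, ...) {
  data.frame(mirna_id = rownames(x$counts), x$counts,
             check.names = FALSE, row.names = NULL)
}

write_count_table <- function(ct, path) {
  write_tsv(as.data.frame(ct), path)
}

#' Write analysis results to a directory
#'
#' Writes each data.frame in `results` as a TSV (deterministic column
#' order, name taken from the list name) plus a JSON run manifest holding
#' the configuration, seed and the file list.
#'
#' @param results named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @param config run configuration list recorded in the manifest.
#' @param seed RNG seed recorded in the manifest.
#' @return invisibly, the manifest list.
#' @export
write_report <- function(results, out_dir, config = list(), seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    if (!is.data.frame(df)) df <- as.data.frame(df)
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(df, f)
    files[nm] <- f
  }
  manifest <- list(package = "agosort",
                   version = as.character(utils::packageVersion("agosort")),
                   seed = seed, config = config,
                   outputs = as.list(vapply(files, basename, character(1))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run configuration
#'
#' Collects the tunable thresholds and parameters of the pipeline with the
#' defaults used throughout: RPM floor 10, preference fraction 0.70,
#' precursor filter at 6 mismatches / 3-nt bulge, 500-tree forests with
#' per-class sample size 20, 10,000 permutations for MI nulls.
#'
#' @param min_rpm minimum summed RPM for a miRNA to be considered.
#' @param preference_fraction read-share a library must exceed for a label.
#' @param max_mismatches,max_bulge precursor duplex filter thresholds.
#' @param n_trees,sampsize,n_runs random-forest parameters.
#' @param n_perm permutations for the MI null.
#' @param seed RNG seed recorded in every output.
#' @return a named list of validated settings.
#' @export
run_config <- function(min_rpm = 10, preference_fraction = 0.70,
                       max_mismatches = 6, max_bulge = 3,
                       n_trees = 500, sampsize = 20, n_runs = 1000,
                       n_perm = 10000, seed = 1) {
  stopifnot(min_rpm >= 0, preference_fraction > 0.5, preference_fraction <= 1,
            max_mismatches >= 0, max_bulge >= 0,
            n_trees >= 1, sampsize >= 2, n_runs >= 1, n_perm >= 1)
  list(min_rpm = min_rpm, preference_fraction = preference_fraction,
       max_mismatches = max_mismatches, max_bulge = max_bulge,
       n_trees = n_trees, sampsize = sampsize, n_runs = n_runs,
       n_perm = n_perm, seed = as.integer(seed))
}
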