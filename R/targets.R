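## Target-set overlap expectations and GO-slim enrichment of AGO-specific
## target sets.

#' Expected random overlap of two target sets
#'
#' Under uniform random draws of `n1` and `n2` genes from a genome of `N`
#' genes, the expected number of shared genes is `n1 * n2 / N`.
#'
#' @param n1,n2 target-set sizes.
#' @param N genome size (default 30000).
#' @return expected number of shared targets.
#' @export
expected_overlap <- function(n1, n2, N = 30000) {
  if (N <= 0) stop("genome size must be positive")
  if (n1 > N || n2 > N) stop("set size exceeds genome size")
  n1 * n2 / N
}

#' Deduplicate sequences as 20-mers
#'
#' Truncates sequences to their 5'-anchored 20-mer and discards duplicate
#' 20-mers (first kept) — reducing the bias from miRNA families with
#' near-identical sequences before target profiling.
#'
#' @param cset a `confidence_set` or character vector of sequences.
#' @return the input restricted to rows with distinct 20-mers (sequences
#'   truncated to 20 nt when a character vector is given).
#' @export
dedup_20mers <- function(cset) {
  if (is.character(cset)) {
    x <- substr(cset, 1, 20)
    return(x[!duplicated(x)])
  }
  seqcol <- intersect(c("seq21", "full_seq", "seq"), names(cset))[1]
  x <- substr(cset[[seqcol]], 1, 20)
  cset[!duplicated(x), , drop = FALSE]
}

#' GO-term enrichment of a focal target set by Fisher's exact test
#'
#' Compares term membership between a focal and a background target set
#' (shared targets removed first, so the sets are disjoint; universe =
#' union of the two sets). Two-sided Fisher's exact p per term
#' (`alternative = "greater"` available for enrichment-only tests),
#' BH-FDR across terms; `significant` flags `p_fdr < 0.05`.
#'
#' @param focal_targets,background_targets character vectors of gene ids.
#' @param annotation data.frame with columns `gene`, `term`.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return data.frame: `term`, `a`, `b`, `c`, `d` (2x2 cells: focal/with
#'   term, background/with term, focal/without, background/without), `p`,
#'   `p_fdr`, `significant`.
#' @export
fisher_enrichment <- function(focal_targets, background_targets, annotation,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  shared <- intersect(focal_targets, background_targets)
  focal <- setdiff(unique(focal_targets), shared)
  bg <- setdiff(unique(background_targets), shared)
  if (!length(focal)) stop("empty focal set after shared-target removal")
  terms <- unique(annotation$term[annotation$gene %in% c(focal, bg)])
  if (!length(terms)) {
    out <- data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p = numeric(0),
                      p_fdr = numeric(0), significant = logical(0))
    return(out)
  }
  rows <- lapply(terms, function(tm) {
    genes <- annotation$gene[annotation$term == tm]
    a <- sum(focal %in% genes); b <- sum(bg %in% genes)
    cc <- length(focal) - a;   d <- length(bg) - b
    p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE),
                            alternative = alternative)$p.value
    data.frame(term = tm, a = a, b = b, c = cc, d = d, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(pmin(out$p, 1))
  out$significant <- out$p_fdr < 0.05
  out[order(out$p), , drop = FALSE]
}
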