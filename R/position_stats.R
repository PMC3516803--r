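## Univariate positional statistics: mutual information between a sequence
## column and the AGO label vector (in bits), permutation nulls with
## empirical p-values, BH-FDR over the 21 alignment positions, 5'-base
## enrichment, sequence-logo information content, and profile correlation.

#' Mutual information between AGO labels and a base column
#'
#' \deqn{MI = \sum_{ago,base} P(ago,base) \log_2
#'   \frac{P(ago,base)}{P(ago)P(base)}}
#' with probabilities taken as empirical frequencies; cells with zero
#' joint probability contribute 0.
#'
#' @param labels class labels (any discrete vector).
#' @param bases same-length vector of bases.
#' @return MI in bits.
#' @export
mutual_information <- function(labels, bases) {
  if (length(labels) != length(bases)) stop("length mismatch")
  if (length(labels) == 0) stop("empty input")
  mi_from_table(table(labels, bases))
}

## MI in bits from a joint contingency table
mi_from_table <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  e <- outer(rowSums(p), colSums(p))
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

#' Permutation p-value for a positional MI value
#'
#' The null hypothesis shuffles the label vector against the (fixed) base
#' column, preserving both margins — so each position's base composition
#' defines its own background. The default sampler (`method = "margins"`,
#' [stats::r2dtable()]) draws joint tables directly from the fixed-margin
#' (multivariate hypergeometric) distribution that label shuffling
#' induces; `method = "shuffle"` permutes the labels literally and is
#' kept as a cross-check. The empirical p uses the add-one convention
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, so p is never 0.
#'
#' @param labels,bases as in [mutual_information()].
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed; `NULL` continues the current RNG stream.
#' @param method `"margins"` (fixed-margin table sampling) or
#'   `"shuffle"` (literal label permutation).
#' @return list with `mi`, `p_emp`, and `null_q05`/`null_mean`/`null_q95`.
#' @export
permutation_pvalue <- function(labels, bases, n_perm = 10000, seed = NULL,
                               method = c("margins", "shuffle")) {
  method <- match.arg(method)
  stopifnot(n_perm >= 1)
  tab <- table(labels, bases)
  obs <- mi_from_table(tab)
  if (!is.null(seed)) set.seed(seed)
  if (method == "margins") {
    null <- null_mi_margins(tab, n_perm)
  } else {
    lab <- as.character(labels); bas <- as.character(bases)
    null <- vapply(seq_len(n_perm), function(k)
      mi_from_table(table(sample(lab), bas)), numeric(1))
  }
  p_emp <- (1 + sum(null >= obs - 1e-12)) / (n_perm + 1)
  list(mi = obs, p_emp = p_emp,
       null_q05 = unname(stats::quantile(null, 0.05)),
       null_mean = mean(null),
       null_q95 = unname(stats::quantile(null, 0.95)))
}

## vectorized MI over n_perm fixed-margin tables
null_mi_margins <- function(tab, n_perm) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  ## a single label or base category makes MI identically 0 under any
  ## relabeling
  if (length(rs) < 2 || length(cs) < 2) return(numeric(n_perm))
  tabs <- stats::r2dtable(n_perm, rs, cs)
  m <- vapply(tabs, as.numeric, numeric(length(tab)))  # cells x n_perm
  p <- m / n
  e <- as.numeric(outer(rs / n, cs / n))
  contrib <- p * log2(p / e)
  contrib[p == 0] <- 0
  colSums(contrib)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (via [stats::p.adjust()]) with input
#' validation: p-values must lie in (0, 1].
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted p-values, monotone and capped at 1.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Positional MI profile with permutation significance
#'
#' Computes MI, empirical p and BH-FDR-adjusted p for every column of the
#' 5'-anchored, ungapped 21-mer alignment of a confidence set (or of any
#' supplied labeled sequence set, e.g. star strands). FDR adjustment runs
#' across the `n_positions` tests of one profile.
#'
#' @param cset a `confidence_set`, or a data.frame with `seq`/`seq21` and
#'   `ago`/`class` columns (e.g. star-strand input).
#' @param class_subset optional subset of AGO classes (e.g.
#'   `c("AGO1","AGO5")`); default all classes present.
#' @param n_perm permutations per position; `0` skips p-values.
#' @param seed RNG seed for the permutation stream.
#' @param n_positions number of alignment columns tested (default 21).
#' @param method null sampler, see [permutation_pvalue()].
#' @return an `mi_profile` data.frame: `position`, `mi_bits`, `null_q05`,
#'   `null_mean`, `null_q95`, `p_emp`, `p_fdr`.
#' @export
mi_profile <- function(cset, class_subset = NULL, n_perm = 10000, seed = NULL,
                       n_positions = 21, method = c("margins", "shuffle")) {
  method <- match.arg(method)
  seqcol <- intersect(c("seq21", "seq"), names(cset))[1]
  labcol <- intersect(c("ago", "class"), names(cset))[1]
  if (is.na(seqcol) || is.na(labcol)) {
    stop("input needs a sequence (seq21/seq) and a label (ago/class) column")
  }
  df <- cset[!is.na(cset[[seqcol]]), , drop = FALSE]
  if (!is.null(class_subset)) {
    missing_cls <- setdiff(class_subset, unique(df[[labcol]]))
    if (length(missing_cls)) stop("class with 0 members: ",
                                  paste(missing_cls, collapse = ", "))
    df <- df[df[[labcol]] %in% class_subset, , drop = FALSE]
  }
  if (length(unique(df[[labcol]])) < 2) stop("need at least 2 classes")
  m <- seq_matrix(df[[seqcol]], width = n_positions)
  labels <- df[[labcol]]
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n_positions), function(pos) {
    col <- m[, pos]
    if (n_perm > 0) {
      pv <- permutation_pvalue(labels, col, n_perm = n_perm, seed = NULL,
                               method = method)
      data.frame(position = pos, mi_bits = pv$mi, null_q05 = pv$null_q05,
                 null_mean = pv$null_mean, null_q95 = pv$null_q95,
                 p_emp = pv$p_emp)
    } else {
      data.frame(position = pos, mi_bits = mutual_information(labels, col),
                 null_q05 = NA_real_, null_mean = NA_real_,
                 null_q95 = NA_real_, p_emp = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- if (n_perm > 0) bh_fdr(out$p_emp) else NA_real_
  class(out) <- c("mi_profile", "data.frame")
  out
}

#' 5'-base composition and enrichment ratios
#'
#' Per class and base: count of sequences carrying that base at the
#' profiled position, and the relative enrichment
#' `(class base frequency) / (background base frequency)`. A zero class
#' count yields ratio 0; a zero background frequency against a nonzero
#' class count is flagged infinite.
#'
#' @param x a `confidence_set` (or data.frame with sequences and labels),
#'   or a classes-by-bases count matrix when composition is precomputed.
#' @param background_counts named counts of each base over the reference
#'   miRNA population (A, C, G, U).
#' @param position profiled position (default 1, the 5' base).
#' @return a `composition_table` data.frame: `class`, `base`, `count`,
#'   `class_total`, `enrichment`.
#' @export
base_composition <- function(x, background_counts, position = 1) {
  check_prob(background_counts / sum(background_counts), "background frequencies",
             tol = 1e-6)
  if (is.matrix(x)) {
    counts <- x[, RNA_BASES, drop = FALSE]
  } else {
    seqcol <- intersect(c("seq21", "full_seq", "seq"), names(x))[1]
    labcol <- intersect(c("ago", "class"), names(x))[1]
    b <- substr(x[[seqcol]], position, position)
    counts <- as.matrix(table(factor(x[[labcol]]),
                              factor(b, levels = RNA_BASES)))
  }
  bg <- background_counts[RNA_BASES] / sum(background_counts)
  out <- list()
  for (cls in rownames(counts)) {
    tot <- sum(counts[cls, ])
    for (base in RNA_BASES) {
      cnt <- counts[cls, base]
      ratio <- if (cnt == 0) 0 else {
        if (bg[[base]] == 0) Inf else (cnt / tot) / bg[[base]]
      }
      out[[length(out) + 1]] <- data.frame(
        class = cls, base = base, count = as.integer(cnt),
        class_total = as.integer(tot), enrichment = ratio)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("composition_table", "data.frame")
  res
}

#' Sequence-logo information content
#'
#' Per position: information content `R = 2 - H` bits, where `H` is the
#' base-frequency entropy, optionally minus the small-sample correction
#' `e_n = 3 / (2 ln(2) n)` (floored at 0); per-base letter heights are
#' `frequency * R`.
#'
#' @param seqs character vector of aligned sequences (or a
#'   `confidence_set`, whose `seq21` column is used).
#' @param correction apply the small-sample correction (default FALSE).
#' @return data.frame: `position`, `information`, plus height columns
#'   `A`, `C`, `G`, `U`.
#' @export
logo_information <- function(seqs, correction = FALSE) {
  if (is.data.frame(seqs)) seqs <- seqs$seq21[!is.na(seqs$seq21)]
  if (!length(seqs)) stop("no sequences")
  m <- seq_matrix(seqs, width = max(nchar(seqs)))
  n <- length(seqs)
  out <- list()
  for (pos in seq_len(ncol(m))) {
    col <- m[, pos]
    col <- col[col %in% RNA_BASES]
    if (!length(col)) stop("empty column at position ", pos)
    f <- table(factor(col, levels = RNA_BASES)) / length(col)
    H <- -sum(ifelse(f > 0, f * log2(f), 0))
    R <- 2 - H
    if (correction) R <- max(0, R - 3 / (2 * log(2) * n))
    heights <- as.numeric(f) * R
    out[[pos]] <- data.frame(position = pos, information = R,
                             A = heights[1], C = heights[2],
                             G = heights[3], U = heights[4])
  }
  do.call(rbind, out)
}

#' Correlate two positional profiles
#'
#' Pearson product-moment and Spearman rank correlation with two-sided
#' p-values, e.g. for comparing an MI profile with a per-position
#' hydrogen-bond-count profile from a crystal structure.
#'
#' @param x,y equal-length numeric profiles (length >= 3).
#' @return list with `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`.
#' @export
correlate_profiles <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("profiles must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance profile")
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}
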