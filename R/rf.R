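## Random-forest evaluation of higher-order sorting signals.
##
## Forests are grown with the classical randomForest implementation (the
## standard choice for categorical sequence features), class-balanced by
## stratified bootstrap samples of `sampsize` draws per class. The module
## adds the evaluation protocol: OOB accuracy with deterministic
## tie-breaking, per-sample margins, unscaled mean-decrease-accuracy
## importance, and the median-Wilcoxon-p comparison over repeated runs.

SEQ_LEVELS <- c("A", "C", "G", "U", "N")
PAIR_LEVELS <- c("bound", "unbound", "wobble")

#' Encode a confidence set as a feature matrix
#'
#' `mode = "sequence"`: the 5'-aligned 24-nt sequence, shorter sequences
#' 3'-padded with `N` (levels A/C/G/U/N). `mode = "pairing"`: the duplex
#' state per position (`bound` = Watson-Crick, `wobble`, `unbound`), with
#' the 3' end past the pattern assumed unbound. `include_first = FALSE`
#' drops position 1 (to mask the known 5' signal).
#'
#' @param cset a `confidence_set` or data.frame with `full_seq`/`seq` and
#'   labels.
#' @param mode `"sequence"` or `"pairing"`.
#' @param include_first keep position 1 (default TRUE).
#' @param patterns list of `duplex_pattern` objects (pairing mode),
#'   aligned with the rows of `cset`.
#' @param width encoded width (default 24).
#' @return data.frame of factor columns `pos1`..`pos24`.
#' @export
encode_features <- function(cset, mode = c("sequence", "pairing"),
                            include_first = TRUE, patterns = NULL,
                            width = 24) {
  mode <- match.arg(mode)
  if (mode == "sequence") {
    seqcol <- intersect(c("full_seq", "seq21", "seq"), names(cset))[1]
    if (is.na(seqcol)) stop("no sequence column found")
    m <- seq_matrix(substr(cset[[seqcol]], 1, width), width = width, pad = "N")
    feat <- as.data.frame(lapply(seq_len(width), function(j)
      factor(m[, j], levels = SEQ_LEVELS)))
  } else {
    if (is.null(patterns)) stop("pairing mode requires `patterns`")
    stopifnot(length(patterns) == nrow(cset))
    states <- t(vapply(patterns, function(p) {
      s <- c(WC = "bound", wobble = "wobble", unpaired = "unbound")[p$states]
      length(s) <- width
      s[is.na(s)] <- "unbound"
      unname(s)
    }, character(width)))
    feat <- as.data.frame(lapply(seq_len(width), function(j)
      factor(states[, j], levels = PAIR_LEVELS)))
  }
  names(feat) <- paste0("pos", seq_len(width))
  if (!include_first) feat <- feat[, -1, drop = FALSE]
  feat
}

#' Train a class-balanced random forest
#'
#' Grows `n_trees` trees, each on a stratified bootstrap of `sampsize`
#' draws with replacement per class, with the package defaults for
#' `mtry` (`floor(sqrt(p))`) and tree depth (grown to purity). OOB votes
#' are aggregated per sample; the OOB prediction takes the majority vote
#' with ties broken by the fixed (sorted) class order. Samples never out
#' of bag are excluded from accuracy and margins.
#'
#' @param features factor data.frame from [encode_features()].
#' @param labels class labels (coerced to factor; every class needs >= 2
#'   members).
#' @param n_trees number of trees (default 500).
#' @param sampsize per-class bootstrap draw (default 20).
#' @param seed RNG seed; `NULL` continues the current stream.
#' @param importance compute permutation importance (default TRUE).
#' @return a `forest_result`: list with `votes` (OOB vote fractions),
#'   `predicted`, `oob_accuracy`, `margins`, `importance`, `params`.
#' @export
train_forest <- function(features, labels, n_trees = 500, sampsize = 20,
                         seed = NULL, importance = TRUE) {
  labels <- factor(labels)
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs at least 2 members")
  if (!is.null(seed)) set.seed(seed)
  k <- nlevels(labels)
  ## a feature matrix with no variation cannot be split on: return the
  ## analytic degenerate forest (uniform balanced votes, tie broken by
  ## class order) instead of handing the tree grower an impossible task
  if (all(vapply(features, function(col) length(unique(col)) == 1, logical(1)))) {
    votes <- matrix(1 / k, nrow(features), k,
                    dimnames = list(rownames(features), levels(labels)))
    pred <- factor(rep(levels(labels)[1], nrow(features)),
                   levels = levels(labels))
    return(structure(list(
      votes = votes, predicted = pred, labels = labels,
      oob_accuracy = mean(pred == labels),
      margins = rep(0, nrow(features)),
      importance = if (importance)
        stats::setNames(rep(0, ncol(features)), names(features)) else NULL,
      params = list(n_trees = n_trees, sampsize = sampsize, mtry = 1)),
      class = "forest_result"))
  }
  rf <- randomForest::randomForest(
    x = features, y = labels, ntree = n_trees,
    sampsize = rep(min(sampsize, min(tab)), k), strata = labels,
    replace = TRUE, importance = importance)
  votes <- rf$votes  # OOB vote fractions, rows sum to 1 (NaN if never OOB)
  ok <- stats::complete.cases(votes) & rowSums(votes) > 0
  if (any(!ok)) {
    message(sum(!ok), " sample(s) never out of bag, excluded")
  }
  pred <- factor(levels(labels)[max.col(votes, ties.method = "first")],
                 levels = levels(labels))
  oob_accuracy <- mean(pred[ok] == labels[ok])
  idx <- cbind(seq_along(labels), as.integer(labels))
  true_frac <- votes[idx]
  other_max <- vapply(seq_along(labels), function(i)
    max(votes[i, -as.integer(labels)[i]]), numeric(1))
  marg <- unname(ifelse(ok, true_frac - other_max, NA_real_))
  imp <- if (importance) {
    randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  } else NULL
  structure(list(votes = votes, predicted = pred, labels = labels,
                 oob_accuracy = oob_accuracy, margins = marg,
                 importance = imp,
                 params = list(n_trees = n_trees, sampsize = sampsize,
                               mtry = rf$mtry)),
            class = "forest_result")
}

#' @export
print.forest_result <- function(x, ...) {
  cat(sprintf("forest_result: OOB accuracy %.3f (%d trees, sampsize %d, mtry %d)\n",
              x$oob_accuracy, x$params$n_trees, x$params$sampsize, x$params$mtry))
  invisible(x)
}

#' Per-sample OOB margins
#'
#' Margin = OOB vote fraction for the true class minus the maximum vote
#' fraction for any other class; in \[-1, 1\]. Samples never out of bag
#' are dropped.
#'
#' @param result a `forest_result`.
#' @return numeric vector of margins.
#' @export
margins <- function(result) {
  stopifnot(inherits(result, "forest_result"))
  result$margins[!is.na(result$margins)]
}

#' Per-position permutation variable importance
#'
#' Unscaled mean decrease in OOB accuracy when each feature's values are
#' permuted within each tree's out-of-bag set.
#'
#' @param result a `forest_result` trained with `importance = TRUE`.
#' @return named numeric vector (one entry per feature).
#' @export
variable_importance <- function(result) {
  stopifnot(inherits(result, "forest_result"))
  if (is.null(result$importance)) stop("forest trained without importance")
  result$importance
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided p-value with midranks for ties: exact for small samples
#' without ties, normal approximation with tie correction otherwise
#' (the [stats::wilcox.test()] conventions).
#'
#' @param x,y numeric samples.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))$p.value
}

#' Compare two forest conditions by the median-Wilcoxon-p protocol
#'
#' Repeatedly (n_runs times) trains a forest under each condition on the
#' same samples, computes the OOB margin vectors, and applies the
#' two-sided Wilcoxon rank-sum test to the pair of margin vectors. The
#' reported p is the median over runs — a bootstrap-style estimate at the
#' original dataset size — together with each condition's mean OOB
#' accuracy. A condition may be class-shuffled (fresh label shuffle every
#' run) to serve as the random baseline.
#'
#' @param features_a,features_b feature encodings of the same samples.
#' @param labels true class labels.
#' @param n_runs repeated runs (default 1000).
#' @param n_trees,sampsize forest parameters.
#' @param seed RNG seed for the whole protocol.
#' @param shuffle_a,shuffle_b train that condition on freshly shuffled
#'   labels each run.
#' @return list with `median_p`, `mean_accuracy_a`, `mean_accuracy_b`,
#'   and the per-run data.frame `runs`.
#' @export
compare_conditions <- function(features_a, features_b, labels,
                               n_runs = 1000, n_trees = 500, sampsize = 20,
                               seed = NULL, shuffle_a = FALSE,
                               shuffle_b = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    la <- if (shuffle_a) sample(labels) else labels
    lb <- if (shuffle_b) sample(labels) else labels
    ## same per-run seed for both conditions: identical conditions yield
    ## identical forests, so the comparison isolates the feature encoding
    sr <- if (!is.null(seed)) (seed + 104729 * r) %% .Machine$integer.max else NULL
    fa <- train_forest(features_a, la, n_trees = n_trees, sampsize = sampsize,
                       seed = sr, importance = FALSE)
    fb <- train_forest(features_b, lb, n_trees = n_trees, sampsize = sampsize,
                       seed = sr, importance = FALSE)
    runs[[r]] <- data.frame(
      run = r,
      accuracy_a = fa$oob_accuracy, accuracy_b = fb$oob_accuracy,
      p = wilcoxon_rank_sum(margins(fa), margins(fb)))
  }
  runs <- do.call(rbind, runs)
  list(median_p = stats::median(runs$p),
       mean_accuracy_a = mean(runs$accuracy_a),
       mean_accuracy_b = mean(runs$accuracy_b),
       runs = runs)
}
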