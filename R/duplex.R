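## miRNA:miRNA* duplex inference, the precursor quality filter, and
## per-position pairing-frequency profiles.
##
## The duplex is recovered by a global (Needleman-Wunsch) alignment of the
## mature strand against the reversed star strand after removing the 2-nt
## 3' overhang from each strand. Pair scores: Watson-Crick +2, G:U wobble
## +1, other aligned pair -1, gap -2 (linear); traceback prefers paired
## columns over gaps, so ties resolve toward fewer, leftmost gaps.

PAIR_WC <- c(A = "U", U = "A", G = "C", C = "G")

pair_class <- function(a, b) {
  if (PAIR_WC[[a]] == b) "WC"
  else if ((a == "G" && b == "U") || (a == "U" && b == "G")) "wobble"
  else "mismatch"
}

pair_score <- function(a, b) {
  switch(pair_class(a, b), WC = 2, wobble = 1, mismatch = -1)
}

## Global alignment of two base vectors; returns aligned index pairs
## (0 = gap) and the optimal score. Linear gap cost -2; an infinitesimal
## gap-opening surcharge implements the tie-break "prefer fewer gap runs",
## so a planted contiguous bulge is not split when an inserted base could
## coincidentally pair at equal score. Traceback prefers paired columns,
## then gaps in y, giving leftmost gap placement among remaining ties.
align_duplex_core <- function(x, y, gap = -2, open_eps = 1e-6) {
  n <- length(x); m <- length(y)
  open <- gap - open_eps
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1), 1] <- open + gap * (0:(n - 1))
  if (m > 0) Y[1, 2:(m + 1)] <- open + gap * (0:(m - 1))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- pair_score(x[i], y[j])
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + open, X[i, j + 1] + gap,
                             Y[i, j + 1] + open)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + open, X[i + 1, j] + open,
                             Y[i + 1, j] + gap)
    }
  }
  tol <- 1e-9
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  best <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])[state]
  ai <- integer(0); aj <- integer(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (state == 1) {        # paired column
      s <- pair_score(x[i], y[j])
      cur <- M[i + 1, j + 1]
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which(abs(prev + s - cur) < tol)[1]
      ai <- c(i, ai); aj <- c(j, aj); i <- i - 1; j <- j - 1
    } else if (state == 2) { # gap in y: x[i] unpaired
      cur <- X[i + 1, j + 1]
      cand <- c(M[i, j + 1] + open, X[i, j + 1] + gap, Y[i, j + 1] + open)
      state <- if (i == 1 && j == 0) 2 else which(abs(cand - cur) < tol)[1]
      ai <- c(i, ai); aj <- c(0L, aj); i <- i - 1
    } else {                 # gap in x: y[j] unpaired
      cur <- Y[i + 1, j + 1]
      cand <- c(M[i + 1, j] + open, X[i + 1, j] + open, Y[i + 1, j] + gap)
      state <- if (j == 1 && i == 0) 3 else which(abs(cand - cur) < tol)[1]
      ai <- c(0L, ai); aj <- c(j, aj); j <- j - 1
    }
  }
  list(i = ai, j = aj, score = round(best))
}

longest_run <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Infer the miRNA:miRNA* pairing pattern
#'
#' Classifies every mature position as Watson-Crick paired (`WC`), G:U
#' `wobble`, or `unpaired` (aligned mismatch, gapped, or 3'-overhang),
#' and reports the number of aligned mismatch columns, the longest bulge
#' (gap run on either strand) and the alignment score. The star strand is
#' taken from the record, or derived from precursor coordinates when the
#' star sequence is absent.
#'
#' @param record a one-row `mirna_set` record, or a mature sequence when
#'   `star` is given.
#' @param star optional star sequence overriding the record.
#' @return a `duplex_pattern`: list with `states` (length = mature
#'   length), `n_mismatches`, `max_bulge`, `score`.
#' @export
infer_duplex <- function(record, star = NULL) {
  if (is.null(star)) {
    stopifnot(is.data.frame(record), nrow(record) == 1)
    mature <- record$mature_seq
    star <- record$star_seq
    if (is.na(star) || is.null(star)) {
      if (!is.na(record$star_start) && !is.na(record$star_end)) {
        star <- substr(record$precursor_seq, record$star_start, record$star_end)
      } else {
        stop("star sequence absent and no star coordinates to derive it")
      }
    }
  } else {
    mature <- if (is.data.frame(record)) record$mature_seq else record
  }
  mature <- as_rna(mature); star <- as_rna(star)
  L <- nchar(mature)
  mb <- strsplit(mature, "", fixed = TRUE)[[1]]
  sb <- strsplit(star, "", fixed = TRUE)[[1]]
  ## drop the 2-nt 3' overhang of each strand, reverse the star so that
  ## mature position i faces its antiparallel partner
  mcore <- mb[seq_len(max(L - 2L, 1L))]
  rstar <- rev(sb[seq_len(max(length(sb) - 2L, 1L))])
  al <- align_duplex_core(mcore, rstar)

  states <- rep("unpaired", L)
  for (k in seq_along(al$i)) {
    if (al$i[k] > 0 && al$j[k] > 0) {
      cls <- pair_class(mcore[al$i[k]], rstar[al$j[k]])
      states[al$i[k]] <- if (cls == "mismatch") "unpaired" else cls
    }
  }
  aligned <- al$i > 0 & al$j > 0
  n_mis <- sum(vapply(which(aligned), function(k)
    pair_class(mcore[al$i[k]], rstar[al$j[k]]) == "mismatch", logical(1)))
  max_bulge <- max(longest_run(al$i == 0), longest_run(al$j == 0))
  structure(list(states = states, n_mismatches = as.integer(n_mis),
                 max_bulge = as.integer(max_bulge), score = al$score),
            class = "duplex_pattern")
}

#' @export
print.duplex_pattern <- function(x, ...) {
  cat(sprintf("duplex_pattern: %s (mismatches %d, max bulge %d, score %g)\n",
              duplex_state_string(x), x$n_mismatches, x$max_bulge, x$score))
  invisible(x)
}

#' Compact state string (W = WC, w = wobble, U = unpaired)
#' @param pattern a `duplex_pattern`.
#' @export
duplex_state_string <- function(pattern) {
  paste(c(WC = "W", wobble = "w", unpaired = "U")[pattern$states], collapse = "")
}

#' Import an externally computed duplex structure
#'
#' Accepts a dot-bracket-with-gaps string over the mature strand:
#' `(` = Watson-Crick pair, `:` = wobble, `.` = unpaired, `-` = gap in the
#' mature strand (unpaired). Lets an external hybridization tool's
#' structures stand in for the built-in aligner.
#'
#' @param structure dot-bracket string.
#' @param n_mismatches,max_bulge structure statistics as reported by the
#'   external tool.
#' @return a `duplex_pattern`.
#' @export
parse_duplex_structure <- function(structure, n_mismatches = NA_integer_,
                                   max_bulge = NA_integer_) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("(", ":", ".", "-"))) {
    stop("structure may contain only '(', ':', '.', '-'")
  }
  states <- c("(" = "WC", ":" = "wobble", "." = "unpaired",
              "-" = "unpaired")[ch]
  if (is.na(n_mismatches)) n_mismatches <- sum(ch == ".")
  structure(list(states = unname(states),
                 n_mismatches = as.integer(n_mismatches),
                 max_bulge = as.integer(ifelse(is.na(max_bulge),
                                               longest_run(ch == "-"), max_bulge)),
                 score = NA_real_),
            class = "duplex_pattern")
}

#' Precursor quality filter
#'
#' Fails a record when its duplex holds more than `max_mismatches`
#' mismatches or a bulge longer than `max_bulge` nucleotides (both strict
#' inequalities: 6 mismatches and a 3-nt bulge still pass).
#'
#' @param pattern a `duplex_pattern`.
#' @param max_mismatches,max_bulge thresholds (defaults 6 and 3).
#' @return list with `pass` (logical) and `reason` (`NA`, `"mismatches"`
#'   or `"bulge"`).
#' @export
filter_precursor <- function(pattern, max_mismatches = 6, max_bulge = 3) {
  if (pattern$n_mismatches > max_mismatches) {
    list(pass = FALSE, reason = "mismatches")
  } else if (pattern$max_bulge > max_bulge) {
    list(pass = FALSE, reason = "bulge")
  } else {
    list(pass = TRUE, reason = NA_character_)
  }
}

#' Per-position pairing frequencies by AGO class
#'
#' Fraction (in percent) of duplexes paired (WC or wobble) at each mature
#' position 1..`max_position`, per class and for the pooled `Total` set.
#' Positions past 19 sit in the 3'-overhang region where duplex formation
#' is undefined, hence the default cap.
#'
#' @param patterns list of `duplex_pattern` objects.
#' @param classes AGO class per pattern.
#' @param max_position last position profiled (default 19).
#' @return data.frame with `class`, `position`, `pct_paired`, `n`.
#' @export
pairing_frequency_profile <- function(patterns, classes, max_position = 19) {
  stopifnot(length(patterns) == length(classes))
  paired <- function(p, pos) {
    if (pos > length(p$states)) FALSE else p$states[pos] %in% c("WC", "wobble")
  }
  groups <- c(stats::setNames(as.list(unique(classes)), unique(classes)),
              list(Total = unique(classes)))
  out <- list()
  for (g in names(groups)) {
    idx <- which(classes %in% groups[[g]])
    if (!length(idx)) stop("empty class: ", g)
    for (pos in seq_len(max_position)) {
      f <- mean(vapply(patterns[idx], paired, logical(1), pos = pos)) * 100
      out[[length(out) + 1]] <- data.frame(class = g, position = pos,
                                           pct_paired = f, n = length(idx))
    }
  }
  do.call(rbind, out)
}
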