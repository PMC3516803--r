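## Synthetic co-IP data with planted sorting signals.
##
## The generator emulates the statistical structure of AGO
## co-immunoprecipitation small-RNA libraries: per-miRNA AGO preference
## mixtures (Dirichlet-multinomial over libraries), class-conditional
## positional base distributions (including the observed 5'-base profile),
## optional nested conditional rules, and hairpin precursors with
## controlled mismatches, G:U wobbles and bulges.

#' Specify planted positional sorting signals
#'
#' @param class_names AGO classes to simulate (subset of AGO1/2/4/5).
#' @param n_per_class integer vector (recycled) of sequences per class.
#' @param position_signals named list: names are positions ("1", "6", ...),
#'   each element a per-class list of base distributions over A/C/G/U.
#' @param nested_rule optional [nested_rule()] making labels a conditional
#'   function of two positions.
#' @param background base distribution used at unconstrained positions.
#' @return a `signal_spec` list.
#' @export
signal_spec <- function(class_names, n_per_class,
                        position_signals = list(),
                        nested_rule = NULL,
                        background = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  stopifnot(length(class_names) >= 1, all(n_per_class >= 1))
  n_per_class <- rep_len(as.integer(n_per_class), length(class_names))
  names(n_per_class) <- class_names
  check_prob(background, "background distribution")
  for (pos in names(position_signals)) {
    p <- as.integer(pos)
    if (is.na(p) || p < 1 || p > 24) stop("signal positions must be in 1..24")
    for (cls in names(position_signals[[pos]])) {
      check_prob(position_signals[[pos]][[cls]],
                 sprintf("signal distribution at position %s, class %s", pos, cls))
    }
  }
  if (!is.null(nested_rule)) {
    rp <- c(nested_rule$condition_position, nested_rule$decision_position)
    if (any(as.character(rp) %in% names(position_signals))) {
      stop("nested rule conflicts with a position signal at the same position")
    }
    if (!all(nested_rule$classes %in% class_names)) {
      stop("nested rule classes must be among class_names")
    }
  }
  structure(list(class_names = class_names, n_per_class = n_per_class,
                 position_signals = position_signals,
                 nested_rule = nested_rule, background = background),
            class = "signal_spec")
}

#' A conditional (nested) two-position sorting rule
#'
#' Encodes rules of the form "given base(s) at the condition position, the
#' base at the decision position determines the class": e.g. 5'-C
#' sequences go to AGO1 when position 9 holds G or U, else to AGO5.
#'
#' @param condition_position,condition_bases position and base set all
#'   generated sequences satisfy.
#' @param decision_position,decision_bases position and base set that
#'   selects `class_if`; other bases select `class_else`.
#' @param class_if,class_else the two class labels.
#' @export
nested_rule <- function(condition_position, condition_bases,
                        decision_position, decision_bases,
                        class_if, class_else) {
  stopifnot(all(condition_bases %in% RNA_BASES),
            all(decision_bases %in% RNA_BASES),
            length(setdiff(RNA_BASES, decision_bases)) >= 1,
            condition_position != decision_position)
  list(condition_position = as.integer(condition_position),
       condition_bases = condition_bases,
       decision_position = as.integer(decision_position),
       decision_bases = decision_bases,
       classes = c(class_if, class_else))
}

#' The observed 5'-base sorting profile as a signal specification
#'
#' Class-conditional first-base distributions matching the published
#' co-IP confidence set (AGO1: 0/70 A, 6/70 C, 1/70 G, 63/70 U; AGO2:
#' 21/25, 0, 1/25, 3/25; AGO5: 0, 6/22, 0, 16/22) with the matching class
#' sizes 70/25/22; all other positions uniform background.
#'
#' @param position position at which to plant the profile (default 1).
#' @param n_per_class class sizes (default 70/25/22).
#' @return a `signal_spec`.
#' @export
table1_signal_spec <- function(position = 1, n_per_class = c(70L, 25L, 22L)) {
  sig <- list(
    AGO1 = c(A = 0, C = 6, G = 1, U = 63) / 70,
    AGO2 = c(A = 21, C = 0, G = 1, U = 3) / 25,
    AGO5 = c(A = 0, C = 6, G = 0, U = 16) / 22)
  ps <- stats::setNames(list(sig), as.character(position))
  signal_spec(class_names = c("AGO1", "AGO2", "AGO5"),
              n_per_class = n_per_class, position_signals = ps)
}

#' Generate labeled mature miRNA sequences with planted signals
#'
#' Without a nested rule, each class draws bases independently per
#' position: from the class's planted distribution at signal positions,
#' from the background elsewhere. With a nested rule, the condition base
#' is forced, the decision base is drawn inside/outside the decision set
#' to hit the requested class sizes, and labels are assigned by the rule
#' (so generated labels satisfy the rule exactly).
#'
#' @param spec a [signal_spec()].
#' @param length sequence length (default 21, the trimmed mature length).
#' @param seed RNG seed.
#' @return data.frame with `id`, `seq`, `class`.
#' @export
generate_sequences <- function(spec, length = 21, seed = NULL) {
  stopifnot(inherits(spec, "signal_spec"))
  sig_pos <- as.integer(names(spec$position_signals))
  if (base::length(sig_pos) && max(sig_pos) > length) {
    stop("sequence length shorter than a signal position")
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n, p) sample(RNA_BASES, n, replace = TRUE, prob = p)
  out <- list()
  rule <- spec$nested_rule
  for (cls in spec$class_names) {
    n <- spec$n_per_class[[cls]]
    m <- matrix("", nrow = n, ncol = length)
    for (j in seq_len(length)) {
      sig <- spec$position_signals[[as.character(j)]]
      p <- if (!is.null(sig) && !is.null(sig[[cls]])) sig[[cls]] else spec$background
      m[, j] <- draw(n, p)
    }
    if (!is.null(rule) && cls %in% rule$classes) {
      m[, rule$condition_position] <-
        sample(rule$condition_bases, n, replace = TRUE)
      dec <- if (cls == rule$classes[1]) rule$decision_bases else
        setdiff(RNA_BASES, rule$decision_bases)
      m[, rule$decision_position] <- sample(dec, n, replace = TRUE)
    }
    out[[cls]] <- data.frame(
      class = cls,
      seq = apply(m, 1, paste, collapse = ""),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- data.frame(id = sprintf("synth-mir-%03d", seq_len(nrow(res))),
                    seq = res$seq, class = res$class,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(rule)) {
    cond <- substr(res$seq, rule$condition_position, rule$condition_position) %in%
      rule$condition_bases
    hit <- substr(res$seq, rule$decision_position, rule$decision_position) %in%
      rule$decision_bases
    res$class[cond] <- ifelse(hit[cond], rule$classes[1], rule$classes[2])
  }
  res
}

#' Build a hairpin precursor around a mature sequence
#'
#' Constructs `precursor = mature + loop + star`, where the star arm is
#' the reverse complement of the mature duplex region (positions
#' 1..L-2; the last two mature bases form the 3' overhang) modified at the
#' requested positions, plus a 2-nt star 3' overhang. Wobbles replace the
#' star partner of a mature G (or U) with U (or G); mismatches replace it
#' with a base that neither Watson-Crick- nor wobble-pairs; bulges insert
#' unpaired star nucleotides (strand "star") or delete star partners of a
#' run of mature positions (strand "mature").
#'
#' @param mature mature RNA sequence (length >= 16).
#' @param mismatch_positions,wobble_positions disjoint mature positions in
#'   the duplex region; wobble positions must hold G or U.
#' @param bulge optional `list(strand, position, length)`.
#' @param loop_length loop size between the arms.
#' @param seed RNG seed (loop, overhang and mismatch base draws).
#' @param id record id.
#' @return a one-row `mirna_set` record.
#' @export
generate_hairpin <- function(mature, mismatch_positions = integer(0),
                             wobble_positions = integer(0), bulge = NULL,
                             loop_length = 12, seed = NULL,
                             id = "synth-hairpin") {
  mature <- as_rna(mature)
  check_rna_alphabet(mature, allow_n = FALSE, what = "mature")
  L <- nchar(mature)
  if (L < 16) stop("mature sequence too short for a hairpin")
  core_len <- L - 2L
  if (length(intersect(mismatch_positions, wobble_positions))) {
    stop("mismatch and wobble position sets must be disjoint")
  }
  if (any(c(mismatch_positions, wobble_positions) > core_len)) {
    stop("modified positions must lie in the duplex region (1..L-2)")
  }
  if (!is.null(seed)) set.seed(seed)
  mb <- strsplit(mature, "", fixed = TRUE)[[1]]
  ## star arm 5'->3'; star index j pairs mature index core_len - j + 1
  star <- rev(rna_complement_base(mb[seq_len(core_len)]))
  jof <- function(i) core_len - i + 1L
  for (i in wobble_positions) {
    b <- mb[i]
    if (b == "G") star[jof(i)] <- "U"
    else if (b == "U") star[jof(i)] <- "G"
    else stop(sprintf("wobble requested at position %d but mature base is %s", i, b))
  }
  for (i in mismatch_positions) {
    forbidden <- c(rna_complement_base(mb[i]),
                   switch(mb[i], G = "U", U = "G", character(0)))
    star[jof(i)] <- sample(setdiff(RNA_BASES, forbidden), 1)
  }
  if (!is.null(bulge)) {
    stopifnot(all(c("strand", "position", "length") %in% names(bulge)))
    p <- as.integer(bulge$position); k <- as.integer(bulge$length)
    if (bulge$strand == "star") {
      if (p %in% c(mismatch_positions, wobble_positions)) {
        stop("bulge overlaps a mismatch/wobble position")
      }
      if (p < 1 || p >= core_len) stop("star bulge position out of range")
      at <- jof(p + 1L)  # insert between partners of p and p+1
      star <- append(star, sample(RNA_BASES, k, replace = TRUE), after = at)
    } else if (bulge$strand == "mature") {
      hit <- p:(p + k - 1L)
      if (length(intersect(hit, c(mismatch_positions, wobble_positions)))) {
        stop("bulge overlaps a mismatch/wobble position")
      }
      if (max(hit) > core_len) stop("mature bulge extends past the duplex region")
      star <- star[-vapply(hit, jof, integer(1))]
    } else stop("bulge strand must be 'star' or 'mature'")
  }
  loop <- paste(sample(RNA_BASES, loop_length, replace = TRUE), collapse = "")
  star <- paste(c(star, sample(RNA_BASES, 2, replace = TRUE)), collapse = "")
  precursor <- paste0(mature, loop, star)
  out <- data.frame(
    id = id, mature_seq = mature, star_seq = star, precursor_seq = precursor,
    mature_start = 1L, mature_end = L,
    star_start = L + loop_length + 1L,
    star_end = L + loop_length + nchar(star),
    stringsAsFactors = FALSE)
  class(out) <- c("mirna_set", "data.frame")
  out
}

#' Specify simulated co-IP libraries
#'
#' @param library_ids library names (one per AGO class simulated).
#' @param library_sizes target read counts per library.
#' @param preference_strength Dirichlet concentration put on the true
#'   class when drawing each miRNA's per-library read fractions; larger
#'   values give sharper sorting preference (`Inf` = all reads in the true
#'   library). Default 20.
#' @param noise_fraction fraction of extra unassignable (random-sequence)
#'   reads added per library.
#' @export
library_spec <- function(library_ids, library_sizes,
                         preference_strength = 20, noise_fraction = 0) {
  stopifnot(length(library_ids) >= 1, all(library_sizes > 0),
            preference_strength > 0, noise_fraction >= 0, noise_fraction < 1)
  library_sizes <- rep_len(library_sizes, length(library_ids))
  names(library_sizes) <- library_ids
  list(library_ids = library_ids, library_sizes = library_sizes,
       preference_strength = preference_strength,
       noise_fraction = noise_fraction)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate co-IP reads for labeled miRNA sequences
#'
#' Each miRNA receives a total read count (lognormal abundance scaled so
#' library sizes are met in expectation) split multinomially over the
#' libraries with probabilities drawn once per miRNA from a Dirichlet
#' whose concentration `preference_strength` sits on the library matching
#' the miRNA's true class (base concentration 1 elsewhere). Reads are the
#' mature sequence, optionally 3'-extended by an adapter suffix up to 30
#' nt. The returned `truth` count table is the realized draw.
#'
#' @param sequences data.frame with `id`, `seq`, `class` (from
#'   [generate_sequences()]).
#' @param lib a [library_spec()]; `library_ids` must cover every class.
#' @param seed RNG seed.
#' @param adapter adapter suffix appended to reads (then reads truncated
#'   to 30 nt); `NULL` for none.
#' @return list with `reads` (named list of character vectors per
#'   library, DNA alphabet as sequenced), `truth` (a [count_table()] of
#'   realized per-miRNA counts) and `preferences` (per-miRNA true library
#'   fractions).
#' @export
generate_reads <- function(sequences, lib, seed = NULL,
                           adapter = "UCGUAUGCCGUCUUCUGCUUG") {
  stopifnot(all(c("id", "seq", "class") %in% names(sequences)))
  if (!all(sequences$class %in% lib$library_ids)) {
    stop("library_ids must include every class in `sequences`")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sequences)
  k <- length(lib$library_ids)
  ## lognormal relative abundances, scaled to the target total depth
  ab <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  tot <- round(ab / sum(ab) * sum(lib$library_sizes))
  prefs <- matrix(0, n, k, dimnames = list(sequences$id, lib$library_ids))
  counts <- prefs
  for (i in seq_len(n)) {
    alpha <- rep(1, k)
    names(alpha) <- lib$library_ids
    if (is.infinite(lib$preference_strength)) {
      p <- as.numeric(lib$library_ids == sequences$class[i])
    } else {
      alpha[sequences$class[i]] <- lib$preference_strength
      p <- rdirichlet1(alpha)
    }
    prefs[i, ] <- p
    if (tot[i] > 0) counts[i, ] <- stats::rmultinom(1, tot[i], p)
  }
  reads <- vector("list", k)
  names(reads) <- lib$library_ids
  for (j in seq_len(k)) {
    rj <- rep(sequences$seq, counts[, j])
    if (!is.null(adapter)) rj <- substr(paste0(rj, adapter), 1, 30)
    if (lib$noise_fraction > 0) {
      nn <- round(lib$noise_fraction * length(rj))
      if (nn > 0) {
        noise <- vapply(seq_len(nn), function(i)
          paste(sample(RNA_BASES, 30, replace = TRUE), collapse = ""),
          character(1))
        rj <- c(rj, noise)
      }
    }
    reads[[j]] <- as_dna(rj)
  }
  list(reads = reads, truth = count_table(counts), preferences = prefs)
}

#' Write simulated reads as FASTQ
#'
#' Standard 4-line FASTQ with constant Phred quality "I".
#'
#' @param reads named list of read vectors (DNA alphabet).
#' @param dir output directory; one `<library>.fastq` per library.
#' @return invisibly, the file paths.
#' @export
write_fastq <- function(reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(reads)) {
    x <- Biostrings::DNAStringSet(reads[[nm]])
    names(x) <- sprintf("%s_read_%d", nm, seq_along(x))
    q <- Biostrings::PhredQuality(vapply(Biostrings::width(x),
                                         function(w) strrep("I", w), character(1)))
    p <- file.path(dir, paste0(nm, ".fastq"))
    Biostrings::writeXStringSet(x, p, format = "fastq", qualities = q)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read a FASTQ file into a read vector
#'
#' @param path FASTQ file.
#' @return character vector of read sequences (DNA alphabet as stored).
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Ground-truth manifest for a synthetic run
#'
#' @param sequences generated sequences (id, seq, class).
#' @param spec the [signal_spec()] used.
#' @return data.frame with one row per generated sequence plus the planted
#'   signal positions and rule definition serialized as strings.
#' @export
truth_manifest <- function(sequences, spec) {
  rule <- spec$nested_rule
  data.frame(
    id = sequences$id, seq = sequences$seq, true_class = sequences$class,
    signal_positions = paste(names(spec$position_signals), collapse = ","),
    nested_rule = if (is.null(rule)) "" else
      sprintf("pos%d in {%s} -> (pos%d in {%s} ? %s : %s)",
              rule$condition_position, paste(rule$condition_bases, collapse = ""),
              rule$decision_position, paste(rule$decision_bases, collapse = ""),
              rule$classes[1], rule$classes[2]),
    stringsAsFactors = FALSE)
}
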