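## End-to-end orchestration: synthetic generation (or user inputs) ->
## counting -> RPM -> preference -> precursor filter -> confidence set ->
## MI profiles -> composition/logos -> pairing profile -> random-forest
## conditions and comparisons -> optional target overlap/enrichment.

#' Default pipeline configuration
#'
#' Simulates the study conditions: three AGO classes with the observed
#' class sizes (70/25/22) and 5'-base profile, Dirichlet preference
#' concentration 20, one co-IP library per class. Library depths and the
#' run counts are sized for an interactive run (raise `n_perm` to 10000
#' and `n_runs` to 1000 to match the full protocol).
#'
#' @param seed RNG seed.
#' @return nested configuration list (YAML-serializable).
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    synthetic = list(
      n_per_class = c(AGO1 = 70L, AGO2 = 25L, AGO5 = 22L),
      signal_position = 1L,
      library_sizes = 20000L,
      preference_strength = 20,
      noise_fraction = 0.02,
      wobble_rate = 0.10,
      mismatch_rate = 0.05),
    thresholds = list(min_rpm = 10, preference_fraction = 0.70,
                      max_mismatches = 6, max_bulge = 3),
    background_counts = c(A = 66, C = 27, G = 21, U = 214),
    n_perm = 1000L,
    rf = list(n_trees = 500L, sampsize = 20L, n_runs = 20L),
    write_fastq = FALSE)
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified keys fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' Run the full sorting-signal analysis
#'
#' Executes every stage on synthetic data generated from the
#' configuration (or on a user-supplied count table plus miRNA set, the
#' "real data" path), writes all stage outputs as TSVs plus a JSON run
#' manifest into `out_dir`, and returns the manifest with the key
#' objects attached. A stage failure aborts with the stage name.
#'
#' @param config configuration list (see [default_config()]); a YAML path
#'   is accepted.
#' @param out_dir output directory.
#' @param counts optional user [count_table()] replacing the synthetic
#'   read generation and counting.
#' @param mirnas optional `mirna_set` providing sequences (and hairpins)
#'   for the user count table.
#' @return invisibly, a list with the manifest and the computed objects
#'   (`confidence_set`, `mi_profiles`, `rf`, ...).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("agosort-"),
                         counts = NULL, mirnas = NULL) {
  if (is.character(config)) config <- load_config(config)
  seed <- config$seed %||% 1L
  set.seed(seed)
  stage <- "setup"
  results <- list()
  objects <- list()
  on_fail <- function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    synthetic <- is.null(counts)
    patterns <- NULL
    truth <- NULL
    if (synthetic) {
      stage <- "synthetic generation"
      sy <- config$synthetic
      spec <- table1_signal_spec(position = sy$signal_position,
                                 n_per_class = sy$n_per_class)
      seqs <- generate_sequences(spec, length = 21, seed = NULL)
      hairpins <- do.call(rbind, lapply(seq_len(nrow(seqs)), function(i) {
        L <- 19L
        wob <- which(stats::runif(L) < (sy$wobble_rate %||% 0) &
                       substr_vec(seqs$seq[i], L) %in% c("G", "U"))
        mis <- setdiff(which(stats::runif(L) < (sy$mismatch_rate %||% 0)), wob)
        generate_hairpin(seqs$seq[i], mismatch_positions = mis,
                         wobble_positions = wob, id = seqs$id[i])
      }))
      lib <- library_spec(library_ids = names(sy$n_per_class),
                          library_sizes = sy$library_sizes,
                          preference_strength = sy$preference_strength,
                          noise_fraction = sy$noise_fraction %||% 0)
      gen <- generate_reads(seqs, lib, seed = NULL)
      truth <- truth_manifest(seqs, spec)
      results$truth_manifest <- truth
      if (isTRUE(config$write_fastq)) {
        write_fastq(gen$reads, file.path(out_dir, "fastq"))
      }

      stage <- "read trimming and counting"
      trimmed <- lapply(gen$reads, trim_reads, adapter = NULL, max_len = 30)
      ct <- count_reads(trimmed, data.frame(id = seqs$id, seq = seqs$seq))
      mir_tab <- data.frame(id = seqs$id, mature_seq = seqs$seq)
      mirnas <- hairpins
    } else {
      stage <- "user count table"
      ct <- counts
      if (is.null(mirnas)) stop("user counts need a `mirnas` table")
      mir_tab <- data.frame(id = mirnas$id, mature_seq = mirnas$mature_seq)
    }
    results$counts <- as.data.frame(ct)

    stage <- "RPM normalization"
    th <- config$thresholds
    rpm <- normalize_rpm(ct)
    results$rpm <- data.frame(mirna_id = rownames(rpm$rpm), rpm$rpm,
                              check.names = FALSE, row.names = NULL)

    stage <- "preference assignment"
    pref <- assign_preference(rpm, min_rpm = th$min_rpm,
                              threshold = th$preference_fraction)
    results$preferences <- pref

    stage <- "duplex inference and precursor filter"
    filt <- NULL
    if (!is.null(mirnas) && "precursor_seq" %in% names(mirnas)) {
      patterns <- lapply(seq_len(nrow(mirnas)), function(i)
        infer_duplex(mirnas[i, , drop = FALSE]))
      names(patterns) <- mirnas$id
      verdicts <- lapply(patterns, filter_precursor,
                         max_mismatches = th$max_mismatches,
                         max_bulge = th$max_bulge)
      filt <- data.frame(id = mirnas$id,
                         pass = vapply(verdicts, `[[`, logical(1), "pass"),
                         reason = vapply(verdicts, `[[`, character(1), "reason"))
      results$duplex_patterns <- data.frame(
        id = mirnas$id,
        states = vapply(patterns, duplex_state_string, character(1)),
        n_mismatches = vapply(patterns, `[[`, integer(1), "n_mismatches"),
        max_bulge = vapply(patterns, `[[`, integer(1), "max_bulge"),
        pass = filt$pass, row.names = NULL)
    }

    stage <- "confidence set"
    cset <- build_confidence_set(pref, mirnas = mir_tab, filter_results = filt)
    results$confidence_set <- as.data.frame(cset)
    results$exclusions <- attr(cset, "exclusions")
    objects$confidence_set <- cset

    stage <- "mutual information profiles"
    n_perm <- config$n_perm %||% 1000L
    classes <- names(sort(attr(cset, "class_counts"), decreasing = TRUE))
    classes <- intersect(c("AGO1", "AGO2", "AGO5"), classes)
    profs <- list()
    if (length(classes) >= 2) {
      profs$three_class <- mi_profile(cset, class_subset = classes,
                                      n_perm = n_perm, seed = NULL)
      results$mi_profile <- profs$three_class
      if (all(c("AGO1", "AGO5") %in% classes)) {
        profs$ago1_ago5 <- mi_profile(cset, class_subset = c("AGO1", "AGO5"),
                                      n_perm = n_perm, seed = NULL)
        results$mi_profile_ago1_ago5 <- profs$ago1_ago5
      }
      if (!is.null(mirnas) && "star_seq" %in% names(mirnas)) {
        stars <- stats::setNames(mirnas$star_seq, mirnas$id)[cset$id]
        star_df <- data.frame(seq = substr(stars, 1, 21), ago = cset$ago)
        star_df <- star_df[!is.na(star_df$seq) & nchar(star_df$seq) == 21, ]
        if (nrow(star_df) && length(unique(star_df$ago)) >= 2) {
          profs$star <- mi_profile(star_df, n_perm = n_perm, seed = NULL)
          results$mi_profile_star <- profs$star
        }
      }
    }
    objects$mi_profiles <- profs

    stage <- "composition and logos"
    comp <- base_composition(cset, config$background_counts)
    results$composition <- comp
    for (cls in classes) {
      results[[paste0("logo_", tolower(cls))]] <-
        logo_information(cset[cset$ago == cls, ])
    }

    stage <- "pairing frequency profile"
    if (!is.null(patterns)) {
      pp <- patterns[cset$id]
      keep <- !vapply(pp, is.null, logical(1))
      if (sum(keep) && length(unique(cset$ago[keep])) >= 1) {
        results$pairing_profile <-
          pairing_frequency_profile(pp[keep], cset$ago[keep])
      }
    }

    stage <- "random forest conditions"
    rfp <- config$rf
    rf_out <- list()
    three <- cset[cset$ago %in% c("AGO1", "AGO2", "AGO5"), , drop = FALSE]
    if (length(unique(three$ago)) == 3 && all(table(three$ago) >= 2)) {
      fD <- encode_features(three, "sequence")
      fB <- encode_features(three, "sequence", include_first = FALSE)
      fC <- fD[, "pos1", drop = FALSE]
      conds <- list(D_all_positions = fD, B_all_but_first = fB,
                    C_first_only = fC)
      if (!is.null(patterns)) {
        pp <- patterns[three$id]
        if (!any(vapply(pp, is.null, logical(1)))) {
          conds$E_pairing <- encode_features(three, "pairing", patterns = pp)
        }
      }
      report <- list()
      for (nm in names(conds)) {
        fr <- train_forest(conds[[nm]], three$ago, n_trees = rfp$n_trees,
                           sampsize = rfp$sampsize, seed = NULL)
        rf_out[[nm]] <- fr
        report[[nm]] <- data.frame(condition = nm,
                                   oob_accuracy = fr$oob_accuracy,
                                   mean_margin = mean(margins(fr)))
      }
      frA <- train_forest(fD, sample(three$ago), n_trees = rfp$n_trees,
                          sampsize = rfp$sampsize, seed = NULL)
      report$A_class_shuffled <- data.frame(condition = "A_class_shuffled",
                                            oob_accuracy = frA$oob_accuracy,
                                            mean_margin = mean(margins(frA)))
      results$rf_report <- do.call(rbind, unname(report))
      results$importance <- data.frame(
        feature = names(variable_importance(rf_out$D_all_positions)),
        mean_decrease_accuracy = unname(variable_importance(rf_out$D_all_positions)),
        row.names = NULL)

      stage <- "random forest comparisons"
      cmp <- list(
        B_vs_A = compare_conditions(fB, fD, three$ago, n_runs = rfp$n_runs,
                                    n_trees = rfp$n_trees, sampsize = rfp$sampsize,
                                    seed = NULL, shuffle_b = TRUE),
        D_vs_C = compare_conditions(fD, fC, three$ago, n_runs = rfp$n_runs,
                                    n_trees = rfp$n_trees,
                                    sampsize = rfp$sampsize, seed = NULL))
      if (!is.null(conds$E_pairing)) {
        cmp$E_vs_E_shuffled <- compare_conditions(
          conds$E_pairing, conds$E_pairing, three$ago, n_runs = rfp$n_runs,
          n_trees = rfp$n_trees, sampsize = rfp$sampsize, seed = NULL,
          shuffle_b = TRUE)
      }
      results$comparisons <- do.call(rbind, lapply(names(cmp), function(nm)
        data.frame(comparison = nm, median_p = cmp[[nm]]$median_p,
                   mean_accuracy_a = cmp[[nm]]$mean_accuracy_a,
                   mean_accuracy_b = cmp[[nm]]$mean_accuracy_b,
                   n_runs = rfp$n_runs)))
      objects$rf <- rf_out
      objects$comparisons <- cmp
    }

    stage <- "synthetic truth check"
    if (synthetic && !is.null(truth)) {
      m <- match(cset$id, truth$id)
      objects$label_recovery <- mean(cset$ago == truth$true_class[m])
    }

    stage <- "report"
    manifest <- write_report(results, out_dir, config = config, seed = seed)
    objects$manifest <- manifest
    objects$results <- results
  }, error = on_fail)
  invisible(objects)
}

## character vector of the first L bases of a single sequence
substr_vec <- function(seq, L) {
  strsplit(substr(seq, 1, L), "", fixed = TRUE)[[1]]
}
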