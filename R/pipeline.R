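#' Pipeline run configuration
#'
#' Bundles every knob of the three-step analysis into one object: the
#' generator configuration (or paths to cohort files), the hyperparameter
#' grid, inner-CV settings, analysis flags and the replicate counts. Every
#' stochastic step derives its seed from `seed`, so a run is fully
#' reproducible from its config.
#'
#' @param seed Master seed.
#' @param generator A `generator_config` (see [default_generator_config()]);
#'   ignored when cohort paths are given.
#' @param cohort_path,blind_path,sib_path Optional TSV paths overriding the
#'   generated cohorts.
#' @param n_blind,n_sib_pairs Sizes of the generated blind/sibling samples.
#' @param grid Hyperparameter grid.
#' @param inner,inner_k Inner cross-validation mode.
#' @param with_iq Also run the IQ covariate re-analysis.
#' @param asd_subset_only Restrict step 1 to subjects classified ASD.
#' @param pairwise Also compute the one-by-one accuracy table.
#' @param n_rep Label-permutation null replicates.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(seed = 1,
                            generator = default_generator_config(seed = seed),
                            cohort_path = NULL, blind_path = NULL,
                            sib_path = NULL,
                            n_blind = 300, n_sib_pairs = 200,
                            grid = signature_grid(reduced = TRUE),
                            inner = "kfold", inner_k = 10,
                            with_iq = FALSE, asd_subset_only = FALSE,
                            pairwise = TRUE, n_rep = 50) {
  cfg <- list(seed = seed, generator = generator, cohort_path = cohort_path,
              blind_path = blind_path, sib_path = sib_path,
              n_blind = n_blind, n_sib_pairs = n_sib_pairs, grid = grid,
              inner = inner, inner_k = inner_k, with_iq = with_iq,
              asd_subset_only = asd_subset_only, pairwise = pairwise,
              n_rep = n_rep)
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

#' Run the three-step signature analysis pipeline
#'
#' Step 1 — supervised signatures: nested LOOCV of the classifier on the
#' labeled cohort (optionally restricted to the ASD-classified subset, and
#' optionally re-run with IQ), pairwise accuracies, item importance, and the
#' probability-correctness association. Step 2 — blind allocation: train on
#' the full labeled cohort, allocate the blind cohort, compare assigned-class
#' probabilities against the item-permuted copy, and run the
#' label-permutation null. Step 3 — sibling familiality suite. All report
#' tables are written as TSV to `out_dir` together with a manifest recording
#' the seeds, package version and output checksums.
#'
#' @param config A `run_config`, see [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) written <<- c(written, write_tsv(df, file.path(out_dir, name)))
  gen <- config$generator
  seeds <- list(cohort = gen$seed, blind = gen$seed + 1000L,
                sib = gen$seed + 2000L, null = gen$seed + 3000L)

  stage <- "step1_cohort"
  res <- list()
  tryCatch({
    cohort <- if (!is.null(config$cohort_path)) read_cohort(config$cohort_path)
    else generate_cohort(gen)
    if (config$asd_subset_only) {
      ds <- domain_scores(cohort)
      keep <- classify_asd(ds, cohort$onset)
      cohort <- cohort[keep, , drop = FALSE]
      sizes <- table(cohort$group)
      small <- names(sizes)[sizes < 2]
      if (length(small) > 0) {
        warning("group(s) with < 2 ASD-classified subjects dropped: ",
                paste(small, collapse = ", "))
        cohort <- cohort[!cohort$group %in% small, , drop = FALSE]
      }
    }
    emit(cohort, "cohort.tsv")
    emit(summarize_cohort(cohort), "table1_summary.tsv")

    stage <- "step1_loocv"
    loocv <- nested_loocv(cohort, config$grid, with_iq = FALSE,
                          inner = config$inner, inner_k = config$inner_k)
    res$loocv <- loocv
    emit(loocv$predictions, "loocv_predictions.tsv")
    conf <- as.data.frame.matrix(loocv$confusion)
    conf <- cbind(predicted = rownames(conf), conf)
    emit(conf, "table4_confusion.tsv")
    mp <- as.data.frame(loocv$mean_probability)
    mp <- cbind(predicted = rownames(mp), mp)
    emit(mp, "table4_probability.tsv")
    assoc <- probability_correctness_assoc(loocv)
    emit(data.frame(slope = assoc$slope, p_value = assoc$p_value,
                    r_pointbiserial = assoc$r_pointbiserial,
                    degenerate = assoc$degenerate),
         "probability_correctness.tsv")
    if (config$pairwise) {
      stage <- "step1_pairwise"
      pw <- pairwise_accuracy_table(cohort, config$grid,
                                    inner = config$inner,
                                    inner_k = config$inner_k)
      res$pairwise <- pw
      pwdf <- as.data.frame(pw); pwdf <- cbind(group = rownames(pwdf), pwdf)
      emit(pwdf, "table3_pairwise.tsv")
    }
    if (config$with_iq) {
      stage <- "step1_iq"
      iq <- covariate_reanalysis(cohort, config$grid, inner = config$inner,
                                 inner_k = config$inner_k)
      res$iq <- iq
      emit(data.frame(accuracy_without = iq$accuracy_without,
                      accuracy_with_iq = iq$accuracy_with_iq,
                      n_used = iq$n_used, n_dropped = iq$n_dropped),
           "iq_reanalysis.tsv")
    }

    stage <- "step2_train"
    model <- signature_svm(cohort, grid = config$grid,
                           inner = config$inner, inner_k = config$inner_k)
    res$model <- model
    imp <- item_importance(model)
    emit(imp, "table5_importance.tsv")

    stage <- "step2_allocate"
    gen_blind <- gen; gen_blind$seed <- seeds$blind
    blind <- if (!is.null(config$blind_path)) read_cohort(config$blind_path)
    else generate_blind_cohort(gen_blind, config$n_blind)
    al <- allocate(model, blind)
    res$allocation <- al
    emit(al$summary, "table6_allocation.tsv")
    emit(al$assignments, "blind_assignments.tsv")
    permd <- permute_items(blind, seed = seeds$blind)
    al_perm <- allocate(model, permd)
    cmp <- compare_probability_distributions(al$assignments$p_assigned,
                                             al_perm$assignments$p_assigned)
    emit(data.frame(mann_whitney_p = cmp$mann_whitney_p,
                    welch_p = cmp$welch_p,
                    median_structured = cmp$median_a,
                    median_permuted = cmp$median_b),
         "probability_null_items.tsv")

    stage <- "step2_null"
    nul <- permuted_label_null(cohort, blind, grid = config$grid,
                               n_rep = config$n_rep, seed = seeds$null,
                               reselect = FALSE, gamma = model$gamma,
                               cost = model$cost)
    res$null <- nul
    emit(cbind(replicate = seq_len(nrow(nul$counts)),
               as.data.frame(nul$counts)), "null_label_counts.tsv")

    stage <- "step3_siblings"
    gen_sib <- gen; gen_sib$seed <- seeds$sib
    sibs <- if (!is.null(config$sib_path)) read_cohort(config$sib_path)
    else generate_sib_pairs(gen_sib, config$n_sib_pairs)
    pairs <- sib_pair_table(sibs, model)
    res$pairs <- pairs
    emit(as.data.frame(pairs), "sib_pairs.tsv")
    suite <- suppressWarnings(sibling_suite(pairs, classes = model$classes))
    res$sibling_suite <- suite
    emit(suite, "sibling_report.tsv")
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- c(
    sprintf("package_version: %s", as.character(utils::packageVersion("adirsig"))),
    sprintf("seed: %d", config$seed),
    vapply(names(seeds), function(s) sprintf("seed_%s: %d", s, seeds[[s]]),
           character(1)),
    sprintf("inner: %s (k = %d)", config$inner, config$inner_k),
    sprintf("grid_points: %d", nrow(config$grid)),
    sprintf("n_rep_null: %d", config$n_rep),
    vapply(sort(written), function(f)
      sprintf("md5 %s: %s", basename(f), unname(tools::md5sum(f))),
      character(1)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  res$manifest <- manifest
  invisible(res)
}
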