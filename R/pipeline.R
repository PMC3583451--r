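#' Configure a full imputation / genomic-selection experiment
#'
#' Describes the factorial design: missingness levels x replicates x
#' imputation methods x genomic-selection models, run on either a synthetic
#' population (generated by [simulate_population()] /
#' [simulate_phenotypes()]) or a user-supplied complete truth panel with
#' phenotypes. Every per-cell seed derives deterministically from
#' `base_seed`, so identical configurations reproduce identical results and
#' any single cell can be recomputed independently.
#'
#' @param levels subset of `"NA20"`, `"NA50"`, `"NA70"` (and `"NA0"` for the
#'   no-simulated-missingness baseline).
#' @param n_replicates missing-data simulations per level (default 10).
#' @param methods subset of `"MNI"`, `"kNNI"`, `"SVDI"`, `"EMI"`, `"RFI"`.
#' @param gs_models subset of `"RR"`, `"BL"`; empty vector skips the GS
#'   stage.
#' @param base_seed integer master seed.
#' @param sim_params list of arguments for [simulate_population()] (ignored
#'   when `truth`/`phenotypes` are supplied).
#' @param pheno_params list of arguments for [simulate_phenotypes()].
#' @param truth optional complete `geno_matrix` to use instead of a
#'   simulated panel.
#' @param phenotypes optional named phenotype vector aligned with `truth`.
#' @param knni_k,svdi_k,rfi_trees,bl_iter,bl_burn_in method hyperparameters;
#'   `knni_k = NULL` / `svdi_k = NULL` (the defaults) select k per
#'   missingness level by cross-validation ([select_k_cv()] on the first
#'   replicate's observed matrix, grids `knni_grid` / `svdi_grid`).
#' @param knni_grid,svdi_grid candidate k grids for the per-level selection.
#' @param k_folds folds used for the per-level k selection.
#' @param rfi_max_iter sweep cap for RFI inside the study pipeline (default
#'   2: on panels of this design the RFI change statistic plateaus after
#'   the second sweep and the completed matrices stop moving, so later
#'   sweeps only add runtime; [impute_rfi()] itself defaults to 10).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(levels = c("NA20", "NA50", "NA70"),
                              n_replicates = 10,
                              methods = c("MNI", "kNNI", "SVDI", "EMI", "RFI"),
                              gs_models = "RR",
                              base_seed = 1,
                              sim_params = list(),
                              pheno_params = list(),
                              truth = NULL, phenotypes = NULL,
                              knni_k = NULL, svdi_k = NULL, rfi_trees = 100,
                              rfi_max_iter = 2,
                              knni_grid = c(1, 2, 5, 10, 20),
                              svdi_grid = c(5, 10, 20, 40),
                              k_folds = 3,
                              bl_iter = 2000, bl_burn_in = 500) {
  levels <- match.arg(levels, c("NA0", "NA20", "NA50", "NA70"),
                      several.ok = TRUE)
  methods <- match.arg(methods, c("MNI", "kNNI", "SVDI", "EMI", "RFI"),
                       several.ok = TRUE)
  if (length(gs_models))
    gs_models <- match.arg(gs_models, c("RR", "BL"), several.ok = TRUE)
  stopifnot(n_replicates >= 1)
  if (!is.null(truth) && anyNA(truth$values))
    stop("supplied truth matrix must be complete")
  structure(list(levels = levels, n_replicates = n_replicates,
                 methods = methods, gs_models = gs_models,
                 base_seed = base_seed, sim_params = sim_params,
                 pheno_params = pheno_params, truth = truth,
                 phenotypes = phenotypes,
                 knni_k = knni_k, svdi_k = svdi_k, rfi_trees = rfi_trees,
                 rfi_max_iter = rfi_max_iter,
                 knni_grid = knni_grid, svdi_grid = svdi_grid,
                 k_folds = k_folds,
                 bl_iter = bl_iter, bl_burn_in = bl_burn_in),
            class = "experiment_config")
}

impute_cell <- function(observed, method, cfg, cell_seed, ks) {
  switch(method,
         MNI = impute_mni(observed),
         kNNI = impute_knni(observed, k = ks$knni),
         SVDI = impute_svdi(observed, k = ks$svdi),
         EMI = impute_emi(observed),
         RFI = impute_rfi(observed, n_trees = cfg$rfi_trees,
                          max_iter = cfg$rfi_max_iter, seed = cell_seed))
}

#' Run the full experiment described by a configuration
#'
#' For every (level, replicate) cell the truth panel is masked with the
#' built-in missingness distribution for that level, every configured
#' imputation method completes the masked matrix, per-marker and
#' per-individual accuracies are recorded, and (optionally) every configured
#' genomic-selection model is cross-validated on the completed matrix.
#' Failures in one cell are recorded and do not abort sibling cells.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print per-cell progress.
#' @return object of class `experiment_result`: list with
#'   \describe{
#'     \item{accuracy_table}{data.frame: level, method, median
#'       replicate-averaged Rm2 and Ri2, equivalent percent correct.}
#'     \item{gs_table}{data.frame: level, method, model, mean CV accuracy
#'       and its standard error across replicates (plus the NA0 baseline if
#'       requested).}
#'     \item{rm2bar,ri2bar}{per level x method: replicate-averaged accuracy
#'       vectors.}
#'     \item{ld_summary}{LD classification of the truth panel.}
#'     \item{truth,phenotypes,population}{the inputs used.}
#'     \item{failures}{data.frame of failed cells, if any.}
#'     \item{config}{the resolved configuration.}
#'   }
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  population <- NULL
  if (is.null(cfg$truth)) {
    population <- do.call(simulate_population,
                          c(cfg$sim_params,
                            list(seed = derive_seed(cfg$base_seed, "pop"))))
    population <- do.call(simulate_phenotypes,
                          c(list(pop = population),
                            cfg$pheno_params,
                            list(seed = derive_seed(cfg$base_seed, "pheno"))))
    truth <- population$genotypes
    phenotypes <- population$phenotypes
  } else {
    truth <- cfg$truth
    phenotypes <- cfg$phenotypes
  }
  maf <- minor_allele_frequency(truth)
  rm2bar <- list(); ri2bar <- list(); k_used <- list()
  gs_rows <- list(); acc_rows <- list(); fail_rows <- list()
  for (level in setdiff(cfg$levels, "NA0")) {
    spec <- default_missingness_distribution(level)
    reports_m <- list(); reports_i <- list(); cv_acc <- list()
    ks <- list(knni = cfg$knni_k, svdi = cfg$svdi_k)
    md1 <- mask_missing(truth, spec, seed = derive_seed(cfg$base_seed, level, 1))
    if ("kNNI" %in% cfg$methods && is.null(ks$knni))
      ks$knni <- select_k_cv(md1$observed, "kNNI", cfg$knni_grid,
                             n_folds = cfg$k_folds,
                             seed = derive_seed(cfg$base_seed, level, "kcv"))$chosen_k
    if ("SVDI" %in% cfg$methods && is.null(ks$svdi))
      ks$svdi <- select_k_cv(md1$observed, "SVDI",
                             pmin(cfg$svdi_grid, min(dim(truth)) - 1),
                             n_folds = cfg$k_folds,
                             seed = derive_seed(cfg$base_seed, level, "scv"))$chosen_k
    k_used[[level]] <- ks
    for (rep_i in seq_len(cfg$n_replicates)) {
      md <- if (rep_i == 1) md1 else
        mask_missing(truth, spec,
                     seed = derive_seed(cfg$base_seed, level, rep_i))
      for (method in cfg$methods) {
        cell_seed <- derive_seed(cfg$base_seed, level, rep_i, method)
        res <- tryCatch(impute_cell(md$observed, method, cfg, cell_seed, ks),
                        error = function(e) e)
        if (inherits(res, "error")) {
          fail_rows[[length(fail_rows) + 1]] <-
            data.frame(level = level, replicate = rep_i, method = method,
                       stage = "impute", message = conditionMessage(res))
          next
        }
        reports_m[[method]][[rep_i]] <-
          per_marker_accuracy(md, res, method, level, rep_i)
        reports_i[[method]][[rep_i]] <-
          per_individual_accuracy(md, res, method, level, rep_i)
        for (model in cfg$gs_models) {
          # fold partition shared across methods: the method comparison is
          # paired within each (level, replicate) cell
          cv_args <- list(res$completed, phenotypes, model = model,
                          seed = derive_seed(cfg$base_seed, level, rep_i,
                                             model))
          if (model == "BL")
            cv_args <- c(cv_args, list(n_iter = cfg$bl_iter,
                                       burn_in = cfg$bl_burn_in))
          cv <- tryCatch(do.call(cross_validate, cv_args),
                         error = function(e) e)
          if (inherits(cv, "error")) {
            fail_rows[[length(fail_rows) + 1]] <-
              data.frame(level = level, replicate = rep_i, method = method,
                         stage = paste0("gs_", model),
                         message = conditionMessage(cv))
          } else {
            cv_acc[[model]][[method]] <- c(cv_acc[[model]][[method]],
                                           cv$mean_accuracy)
          }
        }
        if (verbose)
          message(sprintf("[%s rep %d] %s done", level, rep_i, method))
      }
    }
    for (method in names(reports_m)) {
      reps <- Filter(Negate(is.null), reports_m[[method]])
      repsi <- Filter(Negate(is.null), reports_i[[method]])
      if (length(reps) == 0) next
      rb <- aggregate_accuracy(reps, "rm2")
      ib <- aggregate_accuracy(repsi, "ri2")
      rm2bar[[level]][[method]] <- rb
      ri2bar[[level]][[method]] <- ib
      med <- median_accuracy(rb)
      pc <- equivalent_percent_correct(stats::median(maf), max(min(med, 1), -1),
                                       n_sims = 20000,
                                       seed = derive_seed(cfg$base_seed, level,
                                                          method, "pc"))
      acc_rows[[length(acc_rows) + 1]] <-
        data.frame(level = level, method = method,
                   median_rm2bar = med, median_ri2bar = median_accuracy(ib),
                   percent_correct = pc)
    }
    for (model in names(cv_acc)) for (method in names(cv_acc[[model]])) {
      a <- cv_acc[[model]][[method]]
      gs_rows[[length(gs_rows) + 1]] <-
        data.frame(level = level, method = method, model = model,
                   mean_accuracy = mean(a),
                   se = stats::sd(a) / sqrt(length(a)), n_replicates = length(a))
    }
  }
  if ("NA0" %in% cfg$levels) {
    for (model in cfg$gs_models) {
      cv_args <- list(truth, phenotypes, model = model,
                      seed = derive_seed(cfg$base_seed, "NA0", 1, "none", model))
      if (model == "BL")
        cv_args <- c(cv_args, list(n_iter = cfg$bl_iter,
                                   burn_in = cfg$bl_burn_in))
      cv <- do.call(cross_validate, cv_args)
      gs_rows[[length(gs_rows) + 1]] <-
        data.frame(level = "NA0", method = "none", model = model,
                   mean_accuracy = cv$mean_accuracy, se = NA_real_,
                   n_replicates = 1L)
    }
  }
  ld <- if (n_markers(truth) >= 2) ld_classify(truth) else NULL
  structure(list(
    accuracy_table = if (length(acc_rows)) do.call(rbind, acc_rows) else NULL,
    gs_table = if (length(gs_rows)) do.call(rbind, gs_rows) else NULL,
    rm2bar = rm2bar, ri2bar = ri2bar, k_used = k_used, ld_summary = ld,
    truth = truth, phenotypes = phenotypes, population = population,
    maf = maf,
    failures = if (length(fail_rows)) do.call(rbind, fail_rows) else NULL,
    config = cfg), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result\n")
  if (!is.null(x$accuracy_table)) {
    cat("\nImputation accuracy (median replicate-averaged Rm2):\n")
    print(x$accuracy_table, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$gs_table)) {
    cat("\nGenomic selection accuracy (10-fold CV):\n")
    print(x$gs_table, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$failures)) {
    cat("\nFAILED cells:\n"); print(x$failures, row.names = FALSE)
  }
  invisible(x)
}

#' Across-level accuracy average for the factor analyses
#'
#' Averages the replicate-averaged per-marker (or per-individual) accuracy
#' vectors of one method across the missingness levels present in an
#' experiment result, producing the overall per-marker accuracy used when
#' accuracy is related to MAF, LD class, relatedness or PEV.
#'
#' @param result an `experiment_result`.
#' @param method method name.
#' @param which `"rm2"` or `"ri2"`.
#' @return named numeric vector.
#' @export
across_level_accuracy <- function(result, method, which = c("rm2", "ri2")) {
  which <- match.arg(which)
  store <- if (which == "rm2") result$rm2bar else result$ri2bar
  vecs <- lapply(store, function(lv) lv[[method]])
  vecs <- Filter(Negate(is.null), vecs)
  if (length(vecs) == 0) stop("method not present in result: ", method)
  M <- do.call(rbind, vecs)
  out <- colMeans(M, na.rm = TRUE)
  out[colSums(!is.na(M)) == 0] <- NA_real_
  out
}

#' Write the experiment report bundle as TSV files
#'
#' @param result an `experiment_result`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_experiment_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(result$accuracy_table)) wr(result$accuracy_table, "accuracy.tsv")
  if (!is.null(result$gs_table)) wr(result$gs_table, "gs_accuracy.tsv")
  if (!is.null(result$ld_summary))
    wr(data.frame(marker = names(result$ld_summary$max_r2_per_marker),
                  max_r2 = result$ld_summary$max_r2_per_marker,
                  class = result$ld_summary$class_per_marker),
       "ld_classes.tsv")
  if (!is.null(result$failures)) wr(result$failures, "failures.tsv")
  invisible(paths)
}
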