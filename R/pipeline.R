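#' Full-run configuration
#'
#' Bundles every stage configuration for the end-to-end analysis. Two scale
#' presets are provided: `"paper"` (50,000 simulations per scenario, 25
#' epochs, 10^6 parameter-estimation simulations at the full 1661-site width)
#' and `"desk"`, a workstation-scale run (2,000 per scenario, 10 epochs,
#' 20,000 estimation simulations at 400 sites) with the same structure.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed Global seed; all stage seeds are derived from it.
#' @param ... Named overrides of any config element (`priors`, `shape`,
#'   `encoder`, `net`, `synth`, `n_per_model`, `train_n`, `test_n`,
#'   `estimation_n`, `estimation_test_n`, `n_bootstrap`, `epochs`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(preset = c("desk", "paper"), seed = 1, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "desk") {
    list(n_per_model = 2000L, train_n = 7000L, test_n = 1000L,
         estimation_n = 20000L, estimation_test_n = 2000L,
         n_bootstrap = 100L, epochs = 10L, n_sites = 400L)
  } else {
    list(n_per_model = 50000L, train_n = 192000L, test_n = 8000L,
         estimation_n = 1000000L, estimation_test_n = 2000L,
         n_bootstrap = 100L, epochs = 25L, n_sites = 1661L)
  }
  cfg <- list(
    preset = preset, seed = as.integer(seed),
    priors = prior_config(),
    shape = dataset_shape(n_sites = base$n_sites),
    synth = synth_config(n_loci = base$n_sites),
    n_per_model = base$n_per_model,
    train_n = base$train_n, test_n = base$test_n,
    estimation_n = base$estimation_n,
    estimation_test_n = base$estimation_test_n,
    n_bootstrap = base$n_bootstrap, epochs = base$epochs)
  dots <- list(...)
  if ("n_sites" %in% names(dots)) {
    cfg$shape <- dataset_shape(n_sites = dots$n_sites)
    cfg$synth <- synth_config(n_loci = dots$n_sites)
    dots$n_sites <- NULL
  }
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}

# stage seeds derived deterministically from the global seed (kept < 2^31)
stage_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}

#' Run the full demographic-inference pipeline
#'
#' Orchestrates simulate, encode, train, select and estimate, plus the
#' diversity/differentiation statistics of the input data: (1) coalescent
#' training sets are simulated under the four scenarios and encoded as
#' collapsed-diploid images (matching the unphased empirical genotypes);
#' (2) the classifier is trained and evaluated on a stratified held-out set;
#' (3) the empirical dataset is encoded the same way and its class posteriors
#' computed; (4) a new training set is simulated under the selected scenario
#' (when it has free parameters, i.e. is not panmixia) for regression, scored
#' by RMSE and Spearman's rho on held-out simulations; (5) parameters are
#' estimated for the empirical data with bootstrap intervals.
#'
#' @param config A [run_config()].
#' @param empirical A `genotype_matrix`, or `NULL` to substitute a synthetic
#'   stand-in generated from `config$synth` (flagged in the report).
#' @param verbose Print stage progress.
#' @return An object of class `inference_report`.
#' @export
run_pipeline <- function(config = run_config(), empirical = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  empirical_source <- "user"
  if (is.null(empirical)) {
    empirical_source <- "synthetic stand-in (Balding-Nichols generator)"
    empirical <- generate_dataset(config$synth,
                                  rng_seed = stage_seed(config$seed, 1))
  }
  stopifnot(inherits(empirical, "genotype_matrix"))
  n_ind <- nrow(empirical$genotypes)
  if (n_ind != config$shape$n_dip_deme1 + config$shape$n_dip_deme2) {
    stop("`empirical` individual count does not match `config$shape`",
         call. = FALSE)
  }
  encoder <- encoder_config(rows_fixed = n_ind,
                            cols_fixed = config$shape$n_sites,
                            ploidy_mode = "diploid_collapsed")

  say("[1/5] simulating %d datasets per scenario", config$n_per_model)
  tensors <- simulate_tensors(config$priors, config$shape,
                              n_per_model = config$n_per_model,
                              models = 1:4,
                              rng_seed = stage_seed(config$seed, 2),
                              encoder = encoder)
  split <- split_tensors(tensors, config$train_n, config$test_n,
                         rng_seed = stage_seed(config$seed, 3))
  rm(tensors)

  say("[2/5] training the classifier (%d epochs)", config$epochs)
  clf <- train_classifier(split$train,
                          net_config(epochs = config$epochs, dropout = 0.5,
                                     lr_decay = 0.8,
                                     rng_seed = stage_seed(config$seed, 4)))
  selection <- evaluate_classifier(clf, split$test)

  say("[3/5] classifying the empirical data")
  emp_img <- matrix_to_image(empirical, encoder,
                             rng_seed = stage_seed(config$seed, 5))
  posteriors <- select_model(clf, emp_img)
  selection$empirical_posteriors <- posteriors
  selected <- posteriors$model_id[which.max(posteriors$posterior)]

  regression_score <- NULL
  estimates <- NULL
  if (selected != 1L) {
    say("[4/5] regression training under model %d (%d simulations)",
        selected, config$estimation_n)
    reg_tensors <- simulate_tensors(config$priors, config$shape,
                                    n_per_model = config$estimation_n,
                                    models = selected,
                                    rng_seed = stage_seed(config$seed, 6),
                                    encoder = encoder)
    reg_split <- split_tensors(reg_tensors,
                               config$estimation_n -
                                 config$estimation_test_n,
                               config$estimation_test_n,
                               rng_seed = stage_seed(config$seed, 7))
    rm(reg_tensors)
    reg <- train_regressor(reg_split$train,
                           net_config(epochs = config$epochs,
                                      task = "regress", dropout = 0,
                                      lr_decay = 0.9,
                                      rng_seed = stage_seed(config$seed, 8)),
                           norm = param_normalization(config$priors))
    pred <- predict(reg, reg_split$test)
    truth <- normalize_params(reg_split$test$params, reg$norm)
    regression_score <- score_regression(pred, truth)
    say("[5/5] estimating parameters (%d bootstrap replicates)",
        config$n_bootstrap)
    estimates <- estimate_params(reg, empirical, config$n_bootstrap,
                                 rng_seed = stage_seed(config$seed, 9))
  } else {
    say("[4/5] panmixia selected: no free demographic parameters to estimate")
  }

  stats <- list(summary = summarize_dataset(empirical),
                diversity = diversity(empirical),
                fst = tryCatch(pairwise_fst(empirical), error = function(e) NULL))
  structure(list(
    selection = selection,
    posteriors = posteriors,
    selected_model = selected,
    regression_score = regression_score,
    estimates = estimates,
    data_stats = stats,
    provenance = list(
      package_version = as.character(utils::packageVersion("arowana")),
      seed = config$seed, preset = config$preset,
      config_hash = rlang::hash(unclass(config)),
      empirical_source = empirical_source)),
    class = "inference_report")
}

#' @export
print.inference_report <- function(x, ...) {
  cat("== demographic inference report ==\n")
  cat(sprintf("empirical data: %s\n", x$provenance$empirical_source))
  cat(sprintf("held-out classification accuracy: %.3f\n",
              x$selection$overall_test_accuracy))
  cat(sprintf("selected scenario: model %d (posterior %.3f)\n",
              x$selected_model,
              max(x$posteriors$posterior)))
  if (!is.null(x$regression_score)) {
    cat("parameter recovery (held-out simulations):\n")
    print(as.data.frame(x$regression_score), row.names = FALSE)
  }
  if (!is.null(x$estimates)) {
    cat("parameter estimates (median and 95% bootstrap interval):\n")
    print(as.data.frame(x$estimates), row.names = FALSE)
  }
  invisible(x)
}

#' Diversity, differentiation and ordination for a genotype file
#'
#' Reads a genotype file in any supported format and computes the diversity
#' table, pairwise Weir--Cockerham FST and a PCoA; optionally writes the three
#' tables as CSV.
#'
#' @param path Genotype file.
#' @param popmap Population map (data frame or TSV path).
#' @param format Input format (see [read_genotypes()]).
#' @param out_dir Optional directory for `diversity.csv`, `fst.csv`,
#'   `pcoa.csv`.
#' @param n_axes PCoA axes to keep.
#' @return A list with `summary`, `diversity`, `fst`, `pcoa`.
#' @export
run_stats <- function(path, popmap, format = c("vcf", "dart2row", "matrix"),
                      out_dir = NULL, n_axes = 2) {
  gm <- read_genotypes(path, format, popmap)
  res <- list(summary = summarize_dataset(gm),
              diversity = diversity(gm),
              fst = if (length(unique(gm$popmap$pop)) > 1)
                pairwise_fst(gm) else NULL,
              pcoa = pcoa(gm, n_axes = n_axes))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(res$diversity, file.path(out_dir, "diversity.csv"),
                     row.names = FALSE)
    if (!is.null(res$fst)) {
      utils::write.csv(as.data.frame(unclass(res$fst)),
                       file.path(out_dir, "fst.csv"))
    }
    utils::write.csv(res$pcoa$coordinates, file.path(out_dir, "pcoa.csv"),
                     row.names = FALSE)
  }
  res
}

#' Write an inference report to disk
#'
#' Emits the report as `report.json` (selection accuracies, posteriors,
#' selected scenario, regression scores, parameter estimates, data statistics
#' and provenance) plus `confusion.csv` with the held-out confusion matrix.
#'
#' @param report An `inference_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "inference_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(unclass(report$selection$confusion)),
                   file.path(dir, "confusion.csv"))
  out <- list(
    overall_test_accuracy = report$selection$overall_test_accuracy,
    overall_train_accuracy = report$selection$overall_train_accuracy,
    per_class_accuracy = as.list(report$selection$per_class_accuracy),
    posteriors = report$posteriors,
    selected_model = report$selected_model,
    regression_score = report$regression_score,
    estimates = report$estimates,
    data_summary = report$data_stats$summary,
    diversity = report$data_stats$diversity,
    fst = if (!is.null(report$data_stats$fst))
      as.data.frame(unclass(report$data_stats$fst)),
    provenance = report$provenance)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
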