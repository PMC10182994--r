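# End-to-end orchestration: generate (or load) a cohort, filter, split,
# train, evaluate, and export importance and comparison tables with a
# reproducibility manifest.

#' Configure a full analysis run
#'
#' A run is reproducible from its configuration alone: all randomness flows
#' from the single `seed` through derived sub-streams.
#'
#' @param spec A [cohort_spec()] describing the synthetic cohort, or `NULL`
#'   when `cohort_csv` is given.
#' @param cohort_csv Optional path to an external cohort CSV (see
#'   [read_cohort()]); overrides `spec`.
#' @param fractions Split fractions, default `c(4, 1, 1) / 6`.
#' @param seed Master seed for split, model fitting and permutations.
#' @param configs Named list of three [model_config()] objects, or
#'   `"select"` to run [select_hyperparameters()] over [default_grid()] for
#'   each algorithm.
#' @param R Permutation repeats per feature, default 10000.
#' @param alpha Family-wise significance level, default 0.05.
#' @param m_convention Correction family: `"all_pairs"` (`choose(15, 2)` =
#'   105 comparisons) or `"used_pairs"` (all pairs among the variables the
#'   model actually consulted, as in a sparse decision tree).
#' @param out_dir Output directory for CSV/JSON artifacts; created if
#'   needed.
#' @return List of class `run_config`.
#' @export
run_config <- function(spec = cohort_spec(), cohort_csv = NULL,
                       fractions = c(4, 1, 1) / 6, seed = 20230513L,
                       configs = default_model_configs(),
                       R = 10000L, alpha = 0.05,
                       m_convention = c("all_pairs", "used_pairs"),
                       out_dir = tempfile("tfiperm_run_")) {
  m_convention <- match.arg(m_convention)
  structure(
    list(spec = spec, cohort_csv = cohort_csv, fractions = fractions,
         seed = as.integer(seed), configs = configs, R = as.integer(R),
         alpha = alpha, m_convention = m_convention, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full importance-analysis pipeline
#'
#' Stages: load or generate the cohort, drop incomplete records, split
#' 4/6-1/6-1/6, train (or select and train) the three classifiers, compute
#' TPR/TNR on the test subset, compute permutation-importance tables on the
#' validation and test subsets, build Bonferroni-corrected comparison
#' matrices for the test subset, and write every table plus a JSON manifest
#' (config echo, seeds, file checksums) to `config$out_dir`.  Any stage
#' error aborts with the stage name.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the cohort, split, fitted models, rate
#'   table, importance tables, comparison matrices, selection heatmaps (if
#'   any) and the manifest.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[tfiperm] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  say("stage: cohort")
  cohort <- stage("load_cohort", {
    if (!is.null(config$cohort_csv)) read_cohort(config$cohort_csv)
    else generate_cohort(config$spec)
  })
  write_cohort(cohort, out("cohort.csv"))

  say("stage: complete cases + split")
  complete <- stage("drop_incomplete", drop_incomplete(cohort))
  split <- stage("split", split_dataset(complete, config$fractions,
                                        seed = sub_seed(config$seed, 10L)))
  write_split(split, out("split.json"))
  train <- complete[split$train, ]
  validation <- complete[split$validation, ]
  test <- complete[split$test, ]

  say("stage: exploratory profile + summary")
  profile <- stage("profile", positive_response_profile(complete))
  utils::write.csv(profile, out("positive_response_profile.csv"),
                   row.names = FALSE)
  summ <- stage("summary", summarize_cohort(cohort))
  utils::write.csv(summ$counts, out("sample_characteristics.csv"),
                   row.names = FALSE)

  algorithms <- c("decision_tree", "random_forest", "adaboost")
  selections <- NULL
  if (identical(config$configs, "select")) {
    say("stage: hyperparameter selection")
    selections <- lapply(algorithms, function(a) {
      stage(paste0("select_", a),
            select_hyperparameters(a, default_grid(a), train, validation,
                                   seed = sub_seed(config$seed, 20L)))
    })
    names(selections) <- algorithms
    configs <- lapply(selections, `[[`, "config")
    heat <- do.call(rbind, lapply(selections, `[[`, "heatmap"))
    utils::write.csv(heat, out("selection_heatmap.csv"), row.names = FALSE)
  } else {
    configs <- config$configs
    stopifnot(setequal(names(configs), algorithms))
  }

  say("stage: training + test rates")
  models <- lapply(algorithms, function(a) {
    stage(paste0("train_", a), train_model(configs[[a]], train))
  })
  names(models) <- algorithms
  rates <- do.call(rbind, lapply(algorithms, function(a) {
    r <- stage(paste0("rates_", a), evaluate_rates(models[[a]], test))
    data.frame(model = a,
               tpr_pct = sprintf("%.2f", 100 * as.numeric(r$tpr)),
               tnr_pct = sprintf("%.2f", 100 * as.numeric(r$tnr)))
  }))
  utils::write.csv(rates, out("test_rates.csv"), row.names = FALSE)

  say("stage: permutation importance (validation + test)")
  importance <- list()
  comparisons <- list()
  for (a in algorithms) {
    for (sub in c("validation", "test")) {
      dat <- if (sub == "validation") validation else test
      tab <- stage(paste0("importance_", a, "_", sub),
                   importance_table(models[[a]], dat, R = config$R,
                                    seed = sub_seed(config$seed, 30L),
                                    subset = sub))
      importance[[paste(a, sub, sep = "_")]] <- tab
      utils::write.csv(as.data.frame(tab),
                       out(sprintf("importance_%s_%s.csv", a, sub)),
                       row.names = FALSE)
    }
    tab <- importance[[paste(a, "test", sep = "_")]]
    m <- if (config$m_convention == "used_pairs") {
      used <- sum(!tab$zero_importance)
      max(1L, choose(used, 2))
    } else {
      choose(15L, 2)
    }
    cm <- stage(paste0("comparison_", a),
                comparison_matrix(tab, alpha = config$alpha, m = m))
    comparisons[[a]] <- cm
    utils::write.csv(cbind(model = a, cm$pairs),
                     out(sprintf("comparison_%s_test.csv", a)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cm$delta),
                     out(sprintf("comparison_%s_test_delta.csv", a)))
  }

  say("stage: manifest")
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  checksums <- as.character(tools::md5sum(file.path(config$out_dir, files)))
  manifest <- list(
    package = "tfiperm",
    seed = config$seed,
    R = config$R,
    alpha = config$alpha,
    m_convention = config$m_convention,
    fractions = config$fractions,
    config_hash = config_hash(config),
    models = lapply(configs, unclass),
    n_records = nrow(cohort),
    n_complete = nrow(complete),
    split_sizes = lengths(split[c("train", "validation", "test")]),
    files = stats::setNames(as.list(checksums), files)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, complete = complete, split = split,
                 models = models, rates = rates, importance = importance,
                 comparisons = comparisons, selections = selections,
                 manifest = manifest))
}

# Stable hash of the run configuration (minus the output path).
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(
    rapply(x, function(v) if (is.function(v)) "fn" else v, how = "replace"),
    tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  as.character(tools::md5sum(tmp))
}
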