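# The three classifier families and the validation-based selection protocol.
#
# Decision trees use rpart, random forests use ranger (which exposes both a
# maximum depth and a minimum terminal-node size, matching the
# "data fraction per leaf" + depth parameterisation), and two-class discrete
# AdaBoost (SAMME) is implemented here over weighted rpart base learners.
# The positive class is frail (coded 1) throughout.

#' Construct a classifier configuration
#'
#' @param algorithm One of `"decision_tree"`, `"random_forest"`,
#'   `"adaboost"`.
#' @param max_depth Positive integer tree depth limit.  Defaults: 3 (decision
#'   tree), 4 (random forest), 1 (AdaBoost stumps).
#' @param min_leaf_fraction Minimum fraction of the training data per leaf,
#'   in (0, 0.5].  Defaults: 0.1 (decision tree), 0.03 (random forest), 0.01
#'   (AdaBoost base learners).
#' @param n_estimators Number of trees: forced to 1 for the decision tree;
#'   defaults 100 (random forest) and 200 (AdaBoost).
#' @param seed Integer seed controlling any randomness in fitting.
#' @return An object of class `model_config`.
#' @export
#' @examples
#' model_config("decision_tree")             # the depth-3, 0.1-leaf default
#' model_config("adaboost", n_estimators = 200, max_depth = 1)
model_config <- function(algorithm = c("decision_tree", "random_forest",
                                       "adaboost"),
                         max_depth = NULL, min_leaf_fraction = NULL,
                         n_estimators = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    decision_tree = list(max_depth = 3L, min_leaf_fraction = 0.1,
                         n_estimators = 1L),
    random_forest = list(max_depth = 4L, min_leaf_fraction = 0.03,
                         n_estimators = 100L),
    adaboost = list(max_depth = 1L, min_leaf_fraction = 0.01,
                    n_estimators = 200L)
  )
  max_depth <- as.integer(max_depth %||% defaults$max_depth)
  min_leaf_fraction <- min_leaf_fraction %||% defaults$min_leaf_fraction
  n_estimators <- as.integer(n_estimators %||% defaults$n_estimators)
  if (max_depth < 1) stop("`max_depth` must be >= 1", call. = FALSE)
  if (!is.numeric(min_leaf_fraction) || min_leaf_fraction <= 0 ||
      min_leaf_fraction > 0.5) {
    stop("`min_leaf_fraction` must lie in (0, 0.5]", call. = FALSE)
  }
  if (algorithm == "decision_tree" && n_estimators != 1L) {
    stop("a decision tree has exactly one estimator", call. = FALSE)
  }
  if (n_estimators < 1) stop("`n_estimators` must be >= 1", call. = FALSE)
  structure(
    list(algorithm = algorithm, max_depth = max_depth,
         min_leaf_fraction = min_leaf_fraction,
         n_estimators = n_estimators, seed = as.integer(seed)),
    class = "model_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The three selected configurations of the motivating study
#'
#' Decision tree: depth 3, leaf fraction 0.1.  Random forest: depth 4, leaf
#' fraction 0.03, 100 trees.  AdaBoost: 200 stumps (depth 1).
#'
#' @param seed Seed stored in each configuration.
#' @return Named list of three `model_config` objects.
#' @export
default_model_configs <- function(seed = 1L) {
  list(
    decision_tree = model_config("decision_tree", seed = seed),
    random_forest = model_config("random_forest", seed = seed),
    adaboost = model_config("adaboost", seed = seed)
  )
}

# Extract the 15-item feature frame + 0/1 labels from a cohort or data frame,
# enforcing the training-data contract.
model_frame <- function(data, require_labels = TRUE) {
  if (inherits(data, "tfi_cohort")) validate_cohort(data)
  missing_cols <- setdiff(tfi_items(), names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing item column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.data.frame(data[, tfi_items()])
  if (nrow(X) == 0) stop("data is empty", call. = FALSE)
  if (anyNA(X) || !all(as.matrix(X) %in% c(0L, 1L))) {
    stop("item columns must be complete and binary (0/1)", call. = FALSE)
  }
  y <- NULL
  if (require_labels) {
    if (!"frail" %in% names(data)) stop("data lacks `frail` labels",
                                        call. = FALSE)
    y <- as.integer(data$frail)
    if (anyNA(y) || !all(y %in% c(0L, 1L))) {
      stop("`frail` labels must be complete and binary", call. = FALSE)
    }
  }
  list(X = X, y = y)
}

#' Train a classifier on TFI items
#'
#' Fits the configured model to the 15 binary item columns with the frailty
#' label as target.  Fitting is fully reproducible from `config$seed`, and
#' prediction is deterministic after fitting.
#'
#' @param config A [model_config()].
#' @param data Training data: a `tfi_cohort` or data frame with complete
#'   binary `TFI11`..`TFI25` columns and a binary `frail` column containing
#'   both classes.
#' @return An object of class `tfi_model`.
#' @export
train_model <- function(config, data) {
  if (!inherits(config, "model_config")) {
    stop("`config` must be a model_config", call. = FALSE)
  }
  mf <- model_frame(data)
  if (length(unique(mf$y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  n <- nrow(mf$X)
  minbucket <- max(1L, ceiling(config$min_leaf_fraction * n))
  d <- cbind(mf$X, .frail = factor(mf$y, levels = c(0L, 1L)))

  fit <- switch(config$algorithm,
    decision_tree = rpart::rpart(
      .frail ~ ., data = d, method = "class",
      control = rpart::rpart.control(
        maxdepth = config$max_depth, minbucket = minbucket,
        minsplit = 2L * minbucket, cp = 0, xval = 0
      )
    ),
    random_forest = with_seed(config$seed, ranger::ranger(
      dependent.variable.name = ".frail", data = d,
      num.trees = config$n_estimators, max.depth = config$max_depth,
      min.bucket = minbucket, seed = config$seed, num.threads = 1L,
      verbose = FALSE
    )),
    adaboost = adaboost_fit(mf$X, mf$y, n_rounds = config$n_estimators,
                            max_depth = config$max_depth,
                            minbucket = minbucket)
  )
  structure(
    list(config = config, fit = fit, n_train = n,
         feature_names = tfi_items(),
         cache = new.env(parent = emptyenv())),
    class = c(paste0("tfi_model_", config$algorithm), "tfi_model")
  )
}

# Discrete two-class AdaBoost (SAMME) over weighted rpart trees.
adaboost_fit <- function(X, y, n_rounds, max_depth, minbucket) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  yy <- factor(y, levels = c(0L, 1L))
  d <- cbind(X, .frail = yy)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, minbucket = minbucket,
                               minsplit = 2L * minbucket, cp = 0, xval = 0)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    tr <- rpart::rpart(.frail ~ ., data = d, method = "class",
                       weights = w, control = ctrl)
    h <- as.integer(as.character(predict(tr, X, type = "class")))
    miss <- h != y
    err <- sum(w[miss])
    if (err >= 0.5) {
      if (length(trees) == 0) {
        stop("AdaBoost base learner is no better than chance", call. = FALSE)
      }
      break
    }
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    trees[[length(trees) + 1L]] <- tr
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break # perfect learner: nothing left to reweight
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  list(trees = trees, alphas = alphas)
}

adaboost_predict <- function(fit, X) {
  score <- rep(0, nrow(X))
  for (m in seq_along(fit$trees)) {
    h <- as.integer(as.character(predict(fit$trees[[m]], X, type = "class")))
    score <- score + fit$alphas[m] * (2 * h - 1)
  }
  as.integer(score >= 0) # tie goes to the positive (frail) class
}

#' Predict frailty labels
#'
#' @param object A `tfi_model`.
#' @param newdata Data frame with complete binary `TFI11`..`TFI25` columns.
#' @param ... Unused.
#' @return Integer vector of 0/1 labels (1 = frail).
#' @export
predict.tfi_model <- function(object, newdata, ...) {
  mf <- model_frame(newdata, require_labels = FALSE)
  raw_predict(object, mf$X)
}

# Direct (non-cached) prediction on a validated feature frame.
raw_predict <- function(model, X) {
  switch(model$config$algorithm,
    decision_tree = as.integer(as.character(
      predict(model$fit, X, type = "class"))),
    random_forest = as.integer(as.character(
      # fixed predict-time seed: ranger breaks exact vote ties randomly
      predict(model$fit, data = X, num.threads = 1L,
              seed = model$config$seed)$predictions)),
    adaboost = adaboost_predict(model$fit, X)
  )
}

# --- exact lookup-table fast path ------------------------------------------
#
# All 15 features are binary, so a fitted model is equivalent to a length-
# 2^15 lookup table over item patterns.  The table is built lazily (one bulk
# predict call) and memoised on the model; afterwards any prediction --- in
# particular the thousands needed for permutation importance --- is O(n)
# integer indexing.  This is exact, not an approximation.

all_item_patterns <- function() {
  G <- as.data.frame(as.matrix(expand.grid(rep(list(0:1), 15L),
                                           KEEP.OUT.ATTRS = FALSE)))
  names(G) <- tfi_items()
  G
}

prediction_table <- function(model) {
  stopifnot(inherits(model, "tfi_model"))
  if (is.null(model$cache$table)) {
    model$cache$table <- raw_predict(model, all_item_patterns())
  }
  model$cache$table
}

# Encode item rows as pattern indices (0..2^15-1).
pattern_bits <- function(X) {
  as.integer(as.matrix(X) %*% 2^(0:14))
}

table_predict <- function(model, bits) {
  prediction_table(model)[bits + 1L]
}

# --- evaluation -------------------------------------------------------------

#' Confusion rates for binary frailty predictions
#'
#' @param truth Integer vector of true 0/1 labels (1 = frail).
#' @param predicted Integer vector of predicted labels.
#' @return An object of class `tfi_rates`: list with `tpr`, `tnr` and
#'   `counts = c(tp, fn, tn, fp)`.  A rate whose class is absent from `truth`
#'   is `NA` with an explanatory `reason` attribute rather than 0.
#' @export
#' @examples
#' classification_rates(c(1, 1, 0, 0), c(1, 0, 0, 1)) # tpr 0.5, tnr 0.5
classification_rates <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) == 0) {
    stop("`truth` and `predicted` must be nonempty and equal length",
         call. = FALSE)
  }
  tp <- sum(truth == 1L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  tn <- sum(truth == 0L & predicted == 0L)
  fp <- sum(truth == 0L & predicted == 1L)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (is.na(tpr)) attr(tpr, "reason") <- "no positive cases in data"
  if (is.na(tnr)) attr(tnr, "reason") <- "no negative cases in data"
  structure(
    list(tpr = tpr, tnr = tnr,
         counts = c(tp = tp, fn = fn, tn = tn, fp = fp)),
    class = "tfi_rates"
  )
}

#' Evaluate a fitted model's TPR/TNR on labelled data
#'
#' @param model A `tfi_model`.
#' @param data Labelled data with complete binary item columns.
#' @return A `tfi_rates` object (see [classification_rates()]).
#' @export
evaluate_rates <- function(model, data) {
  mf <- model_frame(data)
  classification_rates(mf$y, raw_predict(model, mf$X))
}

# --- hyperparameter selection ----------------------------------------------

#' Default hyperparameter grid per algorithm
#'
#' Depth 1..6 crossed with leaf fractions {0.01, 0.03, 0.05, 0.1, 0.2};
#' the number of estimators is held at the study's values (1 tree, 100
#' forest trees, 200 boosting rounds).
#'
#' @param algorithm Algorithm name as in [model_config()].
#' @return Data frame with columns `max_depth`, `min_leaf_fraction`,
#'   `n_estimators`.
#' @export
default_grid <- function(algorithm = c("decision_tree", "random_forest",
                                       "adaboost")) {
  algorithm <- match.arg(algorithm)
  n_est <- switch(algorithm, decision_tree = 1L, random_forest = 100L,
                  adaboost = 200L)
  expand.grid(max_depth = 1:6,
              min_leaf_fraction = c(0.01, 0.03, 0.05, 0.1, 0.2),
              n_estimators = n_est, KEEP.OUT.ATTRS = FALSE)
}

#' Select hyperparameters by balanced validation rates, then lowest complexity
#'
#' Fits every grid point on the training data and scores it on the validation
#' data.  Configurations are ranked by the balance objective
#' `min(TPR, TNR)` --- so neither rate is favoured --- with ties broken by
#' higher `TPR + TNR` and then by lowest complexity (smaller depth, fewer
#' estimators, larger leaf fraction).
#'
#' @param algorithm Algorithm name.
#' @param grid Data frame of grid points as in [default_grid()].
#' @param train,validation Labelled complete-case data.
#' @param seed Seed stored into each candidate configuration.
#' @return List of class `tfi_selection` with the winning `config` and the
#'   full `heatmap` table (`algorithm`, `max_depth`, `min_leaf_fraction`,
#'   `n_estimators`, `tpr_val`, `tnr_val`, `objective`).
#' @export
select_hyperparameters <- function(algorithm, grid = default_grid(algorithm),
                                   train, validation, seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0) {
    stop("hyperparameter grid is empty", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- model_config(algorithm, max_depth = grid$max_depth[i],
                        min_leaf_fraction = grid$min_leaf_fraction[i],
                        n_estimators = grid$n_estimators[i], seed = seed)
    rates <- evaluate_rates(train_model(cfg, train), validation)
    data.frame(algorithm = algorithm, max_depth = cfg$max_depth,
               min_leaf_fraction = cfg$min_leaf_fraction,
               n_estimators = cfg$n_estimators,
               tpr_val = as.numeric(rates$tpr),
               tnr_val = as.numeric(rates$tnr),
               objective = suppressWarnings(
                 min(as.numeric(rates$tpr), as.numeric(rates$tnr))))
  })
  heatmap <- do.call(rbind, rows)
  ord <- rank_configs(heatmap)
  best <- heatmap[ord[1], ]
  config <- model_config(algorithm, max_depth = best$max_depth,
                         min_leaf_fraction = best$min_leaf_fraction,
                         n_estimators = best$n_estimators, seed = seed)
  structure(list(config = config, heatmap = heatmap),
            class = "tfi_selection")
}

# Ranking order used by the selection protocol (first = winner).  NA
# objectives (a validation class absent) sort last.
rank_configs <- function(heatmap) {
  obj <- ifelse(is.na(heatmap$objective), -Inf, heatmap$objective)
  balance <- ifelse(is.na(heatmap$tpr_val) | is.na(heatmap$tnr_val), -Inf,
                    heatmap$tpr_val + heatmap$tnr_val)
  order(-obj, -balance, heatmap$max_depth, heatmap$n_estimators,
        -heatmap$min_leaf_fraction)
}
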