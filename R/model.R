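#' The four merged IntClust pairs
#'
#' The pairs of subtypes with near-identical copy-number profiles that are
#' merged for the initial six-class model and resolved by pair-specific
#' binary models: 1/5, 3/8, 4/7 and 9/10.
#'
#' @return A named list mapping merged level to the integer pair.
#' @export
intclust_pairs <- function() {
  list("1/5" = c(1L, 5L), "3/8" = c(3L, 8L), "4/7" = c(4L, 7L),
       "9/10" = c(9L, 10L))
}

merged_levels <- function() c("1/5", "2", "3/8", "4/7", "6", "9/10")

#' Merge IntClust labels into the six-class scheme
#'
#' 1,5 -> "1/5"; 3,8 -> "3/8"; 4,7 -> "4/7"; 9,10 -> "9/10"; 2 and 6 stay
#' singletons.
#'
#' @param labels Integer vector of IntClust labels in 1..10.
#' @return A factor with the six merged levels.
#' @export
merge_labels <- function(labels) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% 1:10)) {
    abort("IntClust labels must be integers in 1..10")
  }
  map <- c("1/5", "2", "3/8", "4/7", "1/5", "6", "4/7", "3/8", "9/10", "9/10")
  factor(map[labels], levels = merged_levels())
}

#' Stratified fold assignment
#'
#' Within each class, samples are shuffled (seeded) and dealt round-robin
#' into `k` folds, so every sample appears in exactly one fold and per-class
#' fold sizes differ by at most one.
#'
#' @param labels Vector of class labels (any type).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold indices (1..k), one per sample.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      if (length(idx) < k) {
        abort(sprintf("class %s has %d samples, fewer than k = %d folds",
                      as.character(cls), length(idx), k))
      }
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified train/validation split
#'
#' @param labels Vector of class labels.
#' @param test_fraction Fraction held out per class (default 0.2).
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` for held-out (validation) samples.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  held <- logical(length(labels))
  withr::with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      n_test <- max(1L, round(length(idx) * test_fraction))
      held[sample(idx, n_test)] <- TRUE
    }
  })
  held
}

#' Default boosted-tree configuration
#'
#' A conventional mid-range configuration used when no hyperparameter search
#' is run.
#'
#' @return A named list of xgboost parameters plus `nrounds`.
#' @export
default_config <- function() {
  list(max_depth = 4L, eta = 0.1, nrounds = 150L, subsample = 0.9,
       colsample_bytree = 0.9, lambda = 1)
}

#' Default random-search space
#'
#' Conventional bounds: tree depth 2..10, learning rate 0.01..0.3
#' (log-uniform), 50..500 boosting rounds, row and column subsampling
#' 0.5..1, L2 regularisation 0..5.
#'
#' @return A named list of `c(lower, upper)` ranges.
#' @export
default_search_space <- function() {
  list(max_depth = c(2L, 10L), eta = c(0.01, 0.3), nrounds = c(50L, 500L),
       subsample = c(0.5, 1), colsample_bytree = c(0.5, 1), lambda = c(0, 5))
}

# One config sampled from the space using the current RNG state.
sample_config <- function(space) {
  list(
    max_depth = sample(space$max_depth[1]:space$max_depth[2], 1),
    eta = exp(runif(1, log(space$eta[1]), log(space$eta[2]))),
    nrounds = sample(space$nrounds[1]:space$nrounds[2], 1),
    subsample = runif(1, space$subsample[1], space$subsample[2]),
    colsample_bytree = runif(1, space$colsample_bytree[1],
                             space$colsample_bytree[2]),
    lambda = runif(1, space$lambda[1], space$lambda[2])
  )
}

# Train one booster. type: "multiclass" (softmax probabilities over
# num_class) or "binary" (logistic, output in [0,1]). y is 0-based integer
# for multiclass, 0/1 for binary. Missing feature values route natively.
train_booster <- function(x, y, type, config, num_class = NULL, seed = 1L) {
  params <- list(
    max_depth = config$max_depth, eta = config$eta,
    subsample = config$subsample, colsample_bytree = config$colsample_bytree,
    lambda = config$lambda,
    min_child_weight = config$min_child_weight %||% 1,
    nthread = 1, seed = as.integer(seed)
  )
  if (type == "multiclass") {
    params$objective <- "multi:softprob"
    params$num_class <- num_class
  } else {
    params$objective <- "binary:logistic"
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y, missing = NA)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = config$nrounds, verbose = 0)
}

predict_booster <- function(booster, x) {
  predict(booster, xgboost::xgb.DMatrix(x, missing = NA))
}

# Multiclass log-loss of a probability matrix against 0-based labels.
mlogloss <- function(prob, y0) {
  p <- prob[cbind(seq_along(y0), y0 + 1L)]
  -mean(log(pmax(p, 1e-15)))
}

rmse <- function(pred, y) sqrt(mean((pred - y)^2))

#' Random hyperparameter search with stratified cross-validation
#'
#' Samples `n_trials` configurations from `space`; for each, trains on k-1
#' folds and evaluates the objective on the held-out fold, iterating over
#' all folds, and returns the configuration with the lowest mean objective.
#' Objectives follow the model type: multiclass log-loss for multiclass
#' models, root-mean-square error against the 0/1 label for binary models.
#' Fully deterministic given `seed`.
#'
#' @param x Numeric feature matrix (missing allowed).
#' @param y Labels: a factor (multiclass) or 0/1 numeric (binary).
#' @param type `"multiclass"` or `"binary"`.
#' @param k_folds Number of CV folds (default 5).
#' @param n_trials Number of sampled configurations (default 50).
#' @param space Search space (see [default_search_space()]).
#' @param seed Integer seed driving both the fold shuffle and the sampled
#'   configurations.
#' @param folds Optional pre-computed fold vector.
#' @return A list: `best` (config), `best_objective`, and `trials`, a tibble
#'   of all sampled configs with their mean CV objective.
#' @export
random_search <- function(x, y, type = c("multiclass", "binary"),
                          k_folds = 5L, n_trials = 50L,
                          space = default_search_space(), seed = 1L,
                          folds = NULL) {
  type <- match.arg(type)
  if (n_trials < 1) abort("n_trials must be >= 1")
  if (type == "multiclass") {
    y <- as.factor(y)
    y0 <- as.integer(y) - 1L
    num_class <- nlevels(y)
    strat <- as.integer(y)
  } else {
    y0 <- as.numeric(y)
    if (!all(y0 %in% c(0, 1))) abort("binary labels must be 0/1")
    num_class <- NULL
    strat <- y0
  }
  if (is.null(folds)) folds <- stratified_folds(strat, k = k_folds, seed = seed)
  configs <- withr::with_seed(seed + 1L, {
    lapply(seq_len(n_trials), function(i) sample_config(space))
  })
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cfg <- configs[[i]]
    objs <- numeric(max(folds))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      booster <- train_booster(x[tr, , drop = FALSE], y0[tr], type, cfg,
                               num_class = num_class, seed = seed)
      pred <- predict_booster(booster, x[!tr, , drop = FALSE])
      objs[f] <- if (type == "multiclass") {
        mlogloss(matrix(pred, ncol = num_class), y0[!tr])
      } else {
        rmse(pred, y0[!tr])
      }
    }
    mean_obj <- mean(objs)
    if (!is.finite(mean_obj)) {
      warn(sprintf("trial %d produced a non-finite objective; discarded", i))
      mean_obj <- NA_real_
    }
    rows[[i]] <- tibble(trial = i, !!!cfg, mean_objective = mean_obj)
  }
  trials <- bind_rows(rows)
  usable <- which(is.finite(trials$mean_objective))
  if (length(usable) == 0) abort("every search trial failed")
  best_i <- usable[which.min(trials$mean_objective[usable])]
  list(best = configs[[best_i]],
       best_objective = trials$mean_objective[best_i],
       trials = trials)
}

#' Train a flat 10-class boosted-tree model
#'
#' Single multiclass softmax model over all ten IntClusts with the log-loss
#' training objective; missing feature values route natively.
#'
#' @param features A scaled `cn_features` tibble.
#' @param labels Label tibble covering all samples; all 10 classes required.
#' @param config Boosted-tree configuration (see [default_config()]).
#' @param seed Integer seed.
#' @return A `cn_flat10` model object.
#' @export
train_flat10 <- function(features, labels, config = default_config(),
                         seed = 1L) {
  labels <- validate_labels(labels)
  y <- labels$intclust[match(features$sample_id, labels$sample_id)]
  if (!all(1:10 %in% y)) {
    abort(paste0("all 10 classes must be present; missing: ",
                 paste(setdiff(1:10, y), collapse = ", ")))
  }
  booster <- train_booster(features_matrix(features), y - 1L, "multiclass",
                           config, num_class = 10L, seed = seed)
  structure(list(booster = booster, config = config, seed = seed,
                 regions = attr(features, "regions"),
                 region_ids = attr(features, "region_ids")),
            class = "cn_flat10")
}

#' @export
predict.cn_flat10 <- function(object, features, ...) {
  m <- check_prediction_features(features, object$region_ids)
  prob <- matrix(predict_booster(object$booster, m), ncol = 10)
  colnames(prob) <- paste0("prob_", 1:10)
  out <- tibble(sample_id = features$sample_id,
                intclust = as.integer(apply(prob, 1, which.max)))
  dplyr::bind_cols(out, as_tibble(prob))
}

check_prediction_features <- function(features, region_ids) {
  if (!isTRUE(attr(features, "scaled"))) {
    abort("feature matrix must be scaled (fit_scaler/apply_scaler or cohort_features(scale = TRUE))")
  }
  if (!identical(attr(features, "region_ids"), region_ids)) {
    abort("feature matrix regions do not match the model's regions")
  }
  features_matrix(features)
}

#' Train the six-class + binary-reclassification cascade
#'
#' Trains a six-class softmax model on the merged labels (log-loss
#' objective) and, for each merged pair, a binary logistic model on only
#' that pair's samples with the lower-numbered class encoded 0 and the
#' higher 1. Binary hyperparameter selection, when run, uses held-out RMSE.
#'
#' @param features A scaled `cn_features` tibble of the training cohort.
#' @param labels Label tibble; all 10 classes must be present.
#' @param multiclass_config Configuration for the six-class model.
#' @param binary_configs Either one configuration used for every pair or a
#'   named list keyed by pair (`"1/5"`, ...); default [default_config()].
#' @param seed Integer seed.
#' @return A `cn_bundle`: six-class booster, four binary boosters, region
#'   set, scaler, label scheme and metadata.
#' @export
train_cascade <- function(features, labels,
                          multiclass_config = default_config(),
                          binary_configs = default_config(), seed = 1L) {
  labels <- validate_labels(labels)
  y <- labels$intclust[match(features$sample_id, labels$sample_id)]
  if (!all(1:10 %in% y)) {
    abort(paste0("all 10 classes must be present; missing: ",
                 paste(setdiff(1:10, y), collapse = ", ")))
  }
  m <- features_matrix(features)
  merged <- merge_labels(y)
  multiclass <- train_booster(m, as.integer(merged) - 1L, "multiclass",
                              multiclass_config, num_class = 6L, seed = seed)
  pairs <- intclust_pairs()
  if (!is.null(names(binary_configs)) &&
      all(names(pairs) %in% names(binary_configs))) {
    cfg_for <- function(p) binary_configs[[p]]
  } else {
    cfg_for <- function(p) binary_configs
  }
  binaries <- list()
  for (p in names(pairs)) {
    pair <- pairs[[p]]
    idx <- which(y %in% pair)
    if (!all(pair %in% y[idx])) {
      abort(sprintf("pair %s has an empty side in the training labels", p))
    }
    yb <- as.numeric(y[idx] == pair[2])
    binaries[[p]] <- train_booster(m[idx, , drop = FALSE], yb, "binary",
                                   cfg_for(p), seed = seed)
  }
  structure(list(
    multiclass = multiclass,
    binaries = binaries,
    regions = attr(features, "regions"),
    scaler = attr(features, "scaler"),
    label_scheme = pairs,
    metadata = list(
      package_version = as.character(utils::packageVersion("cncascade")),
      seed = as.integer(seed),
      multiclass_config = multiclass_config,
      binary_config = if (is.list(binary_configs) &&
                          !is.null(binary_configs$max_depth))
        binary_configs else binary_configs,
      multiclass_objective = "softmax log-loss",
      binary_objective = "logistic (selection metric: RMSE)",
      n_train = nrow(features)
    )
  ), class = "cn_bundle")
}

#' Predict IntClust labels with the cascade
#'
#' Takes the six-class argmax; singleton classes (2, 6) become the final
#' label directly, merged classes are resolved by that pair's binary model
#' with a 0.5 threshold (exact ties go to the higher-numbered class).
#' Composed 10-class probabilities distribute each merged probability over
#' its pair by `(1 - p, p)` from the binary model and copy singleton
#' probabilities, so they sum to 1.
#'
#' @param object A `cn_bundle`.
#' @param features A scaled `cn_features` tibble (scaled with its own
#'   cohort's parameters).
#' @param ... Unused.
#' @return A tibble: `sample_id`, `merged_label`, `merged_prob`,
#'   `binary_pair`, `binary_prob` (`NA` for singleton argmax), `intclust`
#'   (final label), and composed `prob_1` .. `prob_10`.
#' @export
predict.cn_bundle <- function(object, features, ...) {
  m <- check_prediction_features(features, object$regions$region_id)
  n <- nrow(m)
  prob6 <- matrix(predict_booster(object$multiclass, m), ncol = 6)
  colnames(prob6) <- merged_levels()
  pairs <- object$label_scheme
  q <- sapply(names(pairs), function(p) {
    pmin(pmax(predict_booster(object$binaries[[p]], m), 0), 1)
  })
  q <- matrix(q, nrow = n, dimnames = list(NULL, names(pairs)))
  comp <- matrix(0, n, 10, dimnames = list(NULL, paste0("prob_", 1:10)))
  comp[, "prob_2"] <- prob6[, "2"]
  comp[, "prob_6"] <- prob6[, "6"]
  for (p in names(pairs)) {
    pair <- pairs[[p]]
    comp[, pair[1]] <- prob6[, p] * (1 - q[, p])
    comp[, pair[2]] <- prob6[, p] * q[, p]
  }
  # the backend's float32 softmax sums to 1 only within ~1e-7; renormalise
  comp <- comp / rowSums(comp)
  arg6 <- merged_levels()[apply(prob6, 1, which.max)]
  final <- integer(n)
  binary_prob <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lvl <- arg6[i]
    if (lvl %in% names(pairs)) {
      binary_prob[i] <- q[i, lvl]
      pair <- pairs[[lvl]]
      final[i] <- if (q[i, lvl] >= 0.5) pair[2] else pair[1]
    } else {
      final[i] <- as.integer(lvl)
    }
  }
  out <- tibble(sample_id = features$sample_id,
                merged_label = factor(arg6, levels = merged_levels()),
                merged_prob = prob6[cbind(seq_len(n), apply(prob6, 1, which.max))],
                binary_pair = ifelse(arg6 %in% names(pairs), arg6, NA_character_),
                binary_prob = binary_prob,
                intclust = final)
  dplyr::bind_cols(out, as_tibble(comp))
}

#' @export
print.cn_bundle <- function(x, ...) {
  cat("<cn_bundle> six-class + binary reclassification cascade\n")
  cat("  regions:", nrow(x$regions), "\n")
  cat("  pairs:", paste(names(x$label_scheme), collapse = ", "), "\n")
  cat("  trained on", x$metadata$n_train, "samples, seed",
      x$metadata$seed, "\n")
  invisible(x)
}

#' @export
glance.cn_bundle <- function(x, ...) {
  tibble(n_regions = nrow(x$regions),
         n_binary_models = length(x$binaries),
         n_train = x$metadata$n_train %||% NA_integer_,
         seed = x$metadata$seed %||% NA_integer_)
}

#' @importFrom rlang %||%
NULL
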