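#' Hyper-parameter search space for the balanced random forest
#'
#' The candidate lists for the random search. Defaults are the full printed
#' space: number of features retained by recursive feature elimination,
#' number of trees, fraction of features tried per split, maximum tree
#' depth (`Inf` = unlimited), minimum samples to split / per leaf,
#' under-sampling strategy of the balanced bootstrap, and the bootstrap
#' fraction (`Inf` = the full class-balanced sample).
#'
#' @param n_features_to_select,n_estimators,max_features,max_depth,
#'   min_samples_split,min_samples_leaf,sampling_strategy,max_samples
#'   Candidate vectors; all must be non-empty.
#' @return A list of class `hyperparam_space`.
#' @export
hyperparam_space <- function(
    n_features_to_select = c(28, 30, 34, 36, 38, 40, 42, 44, 46, 48, 50, 52, 54),
    n_estimators = seq(100, 1000, by = 100),
    max_features = c(0.2, 0.4, 0.6, 0.8, 1),
    max_depth = c(5, 10, 15, 20, Inf),
    min_samples_split = c(2, 5, 10),
    min_samples_leaf = c(1, 2, 4),
    sampling_strategy = c("auto", "all", "not majority", "majority"),
    max_samples = c(0.25, 0.5, 0.75, Inf)) {
  space <- list(
    n_features_to_select = n_features_to_select,
    n_estimators = n_estimators, max_features = max_features,
    max_depth = max_depth, min_samples_split = min_samples_split,
    min_samples_leaf = min_samples_leaf,
    sampling_strategy = sampling_strategy, max_samples = max_samples
  )
  if (any(lengths(space) == 0)) stop("candidate lists must be non-empty")
  structure(space, class = "hyperparam_space")
}

#' Per-class sample sizes of the balanced bootstrap
#'
#' Under-sampling targets per class for one bootstrap: classes selected by
#' the strategy are drawn down to the minority-class count.
#' `"auto"` (= not minority) and `"all"` equalise every class at the
#' minority count; `"not majority"` reduces every class except the largest;
#' `"majority"` reduces only the largest.
#'
#' @param labels Factor (or character) of class labels, >= 2 classes, no
#'   empty classes.
#' @param strategy One of `"auto"`, `"all"`, `"not majority"`,
#'   `"majority"`.
#' @return Named integer vector of per-class sample sizes (factor-level
#'   order).
#' @export
balanced_sample_sizes <- function(labels, strategy = "auto") {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 classes")
  if (any(counts == 0)) {
    stop("class with zero members: ", names(counts)[counts == 0][1])
  }
  n_min <- min(counts)
  maj <- names(counts)[which.max(counts)]
  mino <- names(counts)[which.min(counts)]
  target <- as.integer(counts)
  names(target) <- names(counts)
  sel <- switch(strategy,
    auto = names(counts) != mino,
    all = rep(TRUE, length(counts)),
    `not majority` = names(counts) != maj,
    majority = names(counts) == maj,
    stop("unknown sampling strategy: ", strategy)
  )
  target[sel] <- n_min
  target
}

#' Draw one balanced bootstrap sample
#'
#' Samples, with replacement within each class, the per-class sizes given
#' by [balanced_sample_sizes()].
#'
#' @inheritParams balanced_sample_sizes
#' @param seed Optional seed for reproducibility.
#' @return Integer vector of row indices.
#' @export
balanced_bootstrap <- function(labels, strategy = "auto", seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  labels <- as.factor(labels)
  sizes <- balanced_sample_sizes(labels, strategy)
  idx <- unlist(lapply(names(sizes), function(cl) {
    pool <- which(labels == cl)
    pool[sample.int(length(pool), sizes[[cl]], replace = TRUE)]
  }))
  unname(idx)
}

# Fit a balanced random forest (probability forest with class-wise
# under-sampled bootstraps) via ranger. x: numeric matrix/data.frame
# already standardised; y: factor.
fit_brf <- function(x, y, config, seed = 1L, num_trees = NULL) {
  y <- droplevels(as.factor(y))
  sizes <- balanced_sample_sizes(y, config$sampling_strategy)
  frac <- if (is.finite(config$max_samples)) config$max_samples else 1
  sf <- pmax(1L, round(sizes[levels(y)] * frac)) / length(y)
  counts <- table(y)
  cw <- as.numeric(length(y) / (length(counts) * counts[levels(y)]))
  ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = if (is.null(num_trees)) config$n_estimators else num_trees,
    mtry = max(1L, round(config$max_features * ncol(x))),
    max.depth = if (is.finite(config$max_depth)) config$max_depth else 0,
    min.node.size = config$min_samples_split,
    min.bucket = config$min_samples_leaf,
    sample.fraction = as.numeric(sf),
    replace = TRUE,
    class.weights = cw,
    probability = TRUE,
    importance = "impurity",
    seed = seed,
    num.threads = 1
  )
}

# Recursive feature elimination with the balanced forest: drop the 2 least
# important features (impurity importance) per iteration until n_select
# remain. Forest size is capped during elimination to keep the ranking
# step cheap; the ranking is what matters, not the forest itself.
rfe_select <- function(x, y, n_select, config, seed = 1L, step = 2L,
                       rfe_trees = 300L) {
  feats <- colnames(x)
  while (length(feats) > n_select) {
    fit <- fit_brf(x[, feats, drop = FALSE], y, config, seed = seed,
                   num_trees = min(rfe_trees, config$n_estimators))
    imp <- sort(fit$variable.importance)
    drop_n <- min(step, length(feats) - n_select)
    feats <- setdiff(feats, names(imp)[seq_len(drop_n)])
  }
  feats
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  list(center = mu, scale = sd_)
}

standardize_apply <- function(x, std) {
  scale(as.matrix(x), center = std$center[colnames(x)],
        scale = std$scale[colnames(x)])
}

#' Precision-recall curve and its step-rule area (average precision)
#'
#' Precision and recall are computed at every distinct score threshold in
#' descending order; the area is the average-precision step rule
#' `sum((R_i - R_{i-1}) * P_i)`.
#'
#' @param scores Numeric class scores.
#' @param labels Logical or 0/1 vector of one-vs-rest positives; both
#'   classes must be present.
#' @return List: `precision`, `recall`, `thresholds` (descending distinct
#'   scores), `auc`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  distinct <- which(diff(s) != 0)
  cut <- c(distinct, length(s))
  precision <- tp[cut] / (tp[cut] + fp[cut])
  recall <- tp[cut] / sum(y)
  auc <- sum(diff(c(0, recall)) * precision)
  list(precision = precision, recall = recall, thresholds = s[cut], auc = auc)
}

#' @rdname pr_curve
#' @export
pr_auc <- function(scores, labels) pr_curve(scores, labels)$auc

# Mean one-vs-rest PR-AUC over the classes present in `truth`.
mean_pr_auc <- function(score_matrix, truth) {
  cls <- colnames(score_matrix)
  cls <- cls[cls %in% unique(as.character(truth))]
  mean(vapply(cls, function(cl) {
    pr_auc(score_matrix[, cl], as.character(truth) == cl)
  }, numeric(1)))
}

# Stratified k-fold assignment (per-class round robin after shuffling).
stratified_folds <- function(labels, k, seed = 1L) {
  withr::local_seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    if (length(idx) < k) {
      stop("class ", cl, " has fewer than k = ", k, " members")
    }
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Random-search hyper-parameter tuning with nested RFE
#'
#' For each sampled candidate configuration and each stratified
#' cross-validation fold: standardisation is fitted on the training split
#' only, recursive feature elimination reduces to the candidate's feature
#' count, the balanced forest is fitted, and the held-out fold is scored by
#' mean one-vs-rest PR-AUC. The candidate with the highest mean PR-AUC is
#' returned (first sampled maximiser on ties).
#'
#' @param x Data frame / matrix of features (named columns).
#' @param y Class labels (factor or character).
#' @param space A [hyperparam_space()].
#' @param n_candidates Number of candidates to sample (without
#'   replacement from the Cartesian space, >= 1).
#' @param k Number of stratified folds (default 10).
#' @param seed Seed controlling candidate sampling, folds, and forests.
#' @return List of class `tune_result`: `best_config`, `results` tibble
#'   (one row per candidate: config, `mean_pr_auc`, `sd_pr_auc`),
#'   `fold_scores` matrix.
#' @export
tune_classifier <- function(x, y, space = hyperparam_space(),
                            n_candidates = 10, k = 10, seed = 1L) {
  if (n_candidates < 1) stop("n_candidates must be >= 1")
  y <- droplevels(as.factor(y))
  x <- as.data.frame(x)
  withr::local_seed(seed)
  cands <- sample_candidates(space, n_candidates)
  folds <- stratified_folds(y, k, seed = seed + 1L)
  scores <- matrix(NA_real_, nrow = length(cands), ncol = k)
  for (ci in seq_along(cands)) {
    cfg <- cands[[ci]]
    for (f in seq_len(k)) {
      tr <- folds != f
      std <- standardize_fit(as.matrix(x[tr, , drop = FALSE]))
      xtr <- standardize_apply(x[tr, , drop = FALSE], std)
      feats <- rfe_select(xtr, y[tr], cfg$n_features_to_select, cfg,
                          seed = seed + 100L * ci + f)
      fit <- fit_brf(xtr[, feats, drop = FALSE], y[tr], cfg,
                     seed = seed + 100L * ci + f)
      xte <- standardize_apply(x[!tr, , drop = FALSE], std)
      pred <- stats::predict(fit, as.data.frame(xte[, feats, drop = FALSE]))$predictions
      scores[ci, f] <- mean_pr_auc(pred, y[!tr])
    }
  }
  mean_scores <- rowMeans(scores)
  best <- which.max(mean_scores)  # first maximiser in sampling order
  results <- dplyr::bind_cols(
    dplyr::bind_rows(lapply(cands, tibble::as_tibble)),
    tibble::tibble(mean_pr_auc = mean_scores,
                   sd_pr_auc = apply(scores, 1, stats::sd))
  )
  structure(list(best_config = cands[[best]], results = results,
                 fold_scores = scores, seed = seed, k = k),
            class = "tune_result")
}

sample_candidates <- function(space, n) {
  total <- prod(lengths(space))
  n <- min(n, total)
  seen <- character(0)
  cands <- list()
  while (length(cands) < n) {
    cfg <- lapply(space, function(v) v[sample.int(length(v), 1)])
    key <- paste(unlist(cfg), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    cands[[length(cands) + 1L]] <- cfg
  }
  cands
}

#' Tune per-class decision thresholds on the precision-recall curve
#'
#' For each class one-vs-rest, returns the threshold on that class's score
#' that maximises the F1-score, evaluated on the grid of observed scores
#' (prediction rule: `score >= threshold`). Ties are broken toward the
#' smallest threshold, which maximises recall at equal F1. A class that
#' never receives a positive score falls back to threshold 0.5 with a
#' warning.
#'
#' @param scores Matrix of class scores (rows = objects, named columns =
#'   classes, rows sum to 1).
#' @param labels True class labels.
#' @return Tibble: `class`, `threshold`, `f1`.
#' @export
tune_thresholds <- function(scores, labels) {
  labels <- as.character(labels)
  cls <- colnames(scores)
  out <- lapply(cls, function(cl) {
    s <- scores[, cl]
    pos <- labels == cl
    if (all(s <= 0) || sum(pos) == 0) {
      warning("class ", cl, " never scored positive; threshold defaults to 0.5")
      return(tibble::tibble(class = cl, threshold = 0.5, f1 = NA_real_))
    }
    grid <- sort(unique(s))
    f1s <- vapply(grid, function(t) {
      pred <- s >= t
      tp <- sum(pred & pos)
      if (tp == 0) return(0)
      prec <- tp / sum(pred)
      rec <- tp / sum(pos)
      2 * prec * rec / (prec + rec)
    }, numeric(1))
    best <- max(f1s)
    thr <- min(grid[f1s >= best - 1e-12])
    tibble::tibble(class = cl, threshold = thr, f1 = best)
  })
  dplyr::bind_rows(out)
}

#' Apply class-specific thresholds with the ambiguity rule
#'
#' An object is assigned the unique class whose score passes its
#' class-specific threshold (`score >= threshold`). If no class or more
#' than one class passes, the object is labelled `"Ambiguous"`, to be
#' discarded from downstream quantification.
#'
#' @param scores Score matrix (named columns = classes).
#' @param thresholds Named numeric vector or the tibble returned by
#'   [tune_thresholds()]; must cover exactly the score columns.
#' @return Character vector of labels (class names or `"Ambiguous"`).
#' @export
apply_thresholds <- function(scores, thresholds) {
  if (is.data.frame(thresholds)) {
    thresholds <- stats::setNames(thresholds$threshold, thresholds$class)
  }
  if (!setequal(names(thresholds), colnames(scores))) {
    stop("threshold classes do not match score columns")
  }
  thr <- thresholds[colnames(scores)]
  pass <- sweep(scores, 2, thr, ">=")
  npass <- rowSums(pass)
  lab <- rep("Ambiguous", nrow(scores))
  one <- npass == 1
  lab[one] <- colnames(scores)[apply(pass[one, , drop = FALSE], 1, which)]
  lab
}

#' Argmax labels from a score matrix
#'
#' Plain majority-vote decision: the class with the maximum score. Ties
#' resolve to the earlier column, with the screening convention that
#' `tau` wins ties when present (screening favours keeping candidates).
#'
#' @param scores Score matrix with named columns.
#' @return Character vector of labels.
#' @export
argmax_labels <- function(scores) {
  cols <- colnames(scores)
  if ("tau" %in% cols) {
    ord <- c("tau", setdiff(cols, "tau"))
    scores <- scores[, ord, drop = FALSE]
    cols <- ord
  }
  cols[apply(scores, 1, which.max)]
}

#' Evaluate predicted against true labels
#'
#' `"Ambiguous"` predictions are excluded from the metrics but counted in
#' the ambiguous fraction. The confusion matrix has truth in rows and
#' predictions in columns.
#'
#' @param predicted,truth Equal-length label vectors (non-empty).
#' @return List of class `evaluation_report`: `per_class` tibble
#'   (precision, recall, f1, support), `macro_f1`, `kappa` (Cohen),
#'   `confusion` (counts), `confusion_pct` (row percentages),
#'   `ambiguous_fraction`, `n`.
#' @export
evaluate_classification <- function(predicted, truth) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  amb <- predicted == "Ambiguous"
  p <- predicted[!amb]; t_ <- truth[!amb]
  cls <- sort(unique(c(p, t_)))
  conf <- table(factor(t_, cls), factor(p, cls))
  per_class <- lapply(cls, function(cl) {
    tp <- sum(p == cl & t_ == cl)
    prec <- if (sum(p == cl) > 0) tp / sum(p == cl) else 0
    rec <- if (sum(t_ == cl) > 0) tp / sum(t_ == cl) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = cl, precision = prec, recall = rec, f1 = f1,
                   support = sum(t_ == cl))
  })
  per_class <- dplyr::bind_rows(per_class)
  po <- mean(p == t_)
  pe <- sum(rowSums(conf) * colSums(conf)) / length(p)^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  pct <- sweep(conf, 1, pmax(rowSums(conf), 1), "/") * 100
  structure(list(
    per_class = per_class,
    macro_f1 = mean(per_class$f1[per_class$support > 0]),
    kappa = kappa,
    confusion = conf,
    confusion_pct = pct,
    ambiguous_fraction = mean(amb),
    n = length(predicted)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, macro F1 = %.3f, kappa = %.3f, ambiguous = %.1f%%\n",
              x$n, x$macro_f1, x$kappa, 100 * x$ambiguous_fraction))
  print(x$per_class)
  invisible(x)
}

#' Train a tau (or screening) classifier
#'
#' Optionally tunes hyper-parameters by random search with nested
#' recursive feature elimination, then fits the final balanced random
#' forest on the full training set (standardisation fitted on the full
#' set after tuning) and, for threshold-moving models, tunes the per-class
#' thresholds on the forest's out-of-bag class scores.
#'
#' @param features Data frame with the 54 feature columns (extra columns
#'   are ignored).
#' @param labels Class labels. Screening models use `tau` / `non_tau`;
#'   regional models use the tau types available in that region group.
#' @param config A configuration list (as produced by tuning), or `NULL`
#'   to tune first.
#' @param space,n_candidates,k Passed to [tune_classifier()] when
#'   `config` is `NULL`.
#' @param decision `"threshold"` (threshold-moving with the ambiguity
#'   rule) or `"argmax"` (plain majority vote; used by the screening
#'   model).
#' @param seed Seed for tuning and the final fit.
#' @return Object of class `tau_classifier`: the fitted forest, selected
#'   feature names, standardisation parameters, class list, per-class
#'   thresholds (threshold mode only), decision mode and training
#'   metadata.
#' @export
train_tau_classifier <- function(features, labels, config = NULL,
                                 space = hyperparam_space(),
                                 n_candidates = 10, k = 10,
                                 decision = c("threshold", "argmax"),
                                 seed = 1L) {
  decision <- match.arg(decision)
  y <- droplevels(as.factor(labels))
  x <- as.data.frame(features)[, intersect(feature_names(), names(features)),
                               drop = FALSE]
  tune_res <- NULL
  if (is.null(config)) {
    tune_res <- tune_classifier(x, y, space, n_candidates, k, seed)
    config <- tune_res$best_config
  }
  std <- standardize_fit(as.matrix(x))
  xs <- standardize_apply(x, std)
  feats <- rfe_select(xs, y, config$n_features_to_select, config, seed = seed)
  fit <- fit_brf(xs[, feats, drop = FALSE], y, config, seed = seed)
  thresholds <- NULL
  if (decision == "threshold") {
    oob <- fit$predictions
    ok <- stats::complete.cases(oob)
    thresholds <- tune_thresholds(oob[ok, , drop = FALSE], y[ok])
  }
  structure(list(
    forest = fit, features = feats,
    center = std$center[feats], scale = std$scale[feats],
    classes = levels(y), thresholds = thresholds, decision = decision,
    config = config, tune = tune_res, seed = seed
  ), class = "tau_classifier")
}

#' @export
print.tau_classifier <- function(x, ...) {
  cat(sprintf("<tau_classifier> classes: %s | %d features | decision: %s\n",
              paste(x$classes, collapse = ", "), length(x$features),
              x$decision))
  invisible(x)
}

#' Class scores for new objects
#'
#' Standardises the selected features with the training parameters and
#' returns the forest's class-membership scores (vote fractions summing
#' to 1 per object).
#'
#' @param model A [train_tau_classifier()] model.
#' @param features Data frame containing at least the model's features.
#' @return Numeric matrix, one column per class.
#' @export
predict_scores <- function(model, features) {
  x <- as.data.frame(features)[, model$features, drop = FALSE]
  xs <- scale(as.matrix(x), center = model$center, scale = model$scale)
  p <- stats::predict(model$forest, as.data.frame(xs))$predictions
  p[, model$classes, drop = FALSE]
}

#' Predict labels with the model's decision rule
#'
#' @inheritParams predict_scores
#' @param decision Override the model's decision mode.
#' @return Character vector of labels (may include `"Ambiguous"` in
#'   threshold mode).
#' @export
predict_labels <- function(model, features, decision = model$decision) {
  scores <- predict_scores(model, features)
  if (decision == "threshold") {
    if (is.null(model$thresholds)) stop("model has no tuned thresholds")
    apply_thresholds(scores, model$thresholds)
  } else {
    argmax_labels(scores)
  }
}

#' Two-stage classification: screening then regional typing
#'
#' Objects are first screened into tau vs non-tau by the universal
#' screening classifier (argmax decision); surviving tau objects are typed
#' by the classifier of their region group using threshold-moving, so the
#' final label is one of the region's tau types or `"Ambiguous"`.
#'
#' @param features Data frame with a `region_group` column and the 54
#'   feature columns.
#' @param screening_model The tau vs non-tau `tau_classifier`.
#' @param regional_models Named list of `tau_classifier`s keyed by region
#'   group.
#' @return The input tibble plus `screen_label` and `label` columns
#'   (`label` is `NA` for objects screened out as non-tau).
#' @export
classify_pipeline <- function(features, screening_model, regional_models) {
  features <- tibble::as_tibble(features)
  if (!"region_group" %in% names(features)) stop("region_group column required")
  bad <- setdiff(unique(features$region_group), names(regional_models))
  if (length(bad)) stop("no regional model for: ", paste(bad, collapse = ", "))
  features$screen_label <- predict_labels(screening_model, features,
                                          decision = "argmax")
  features$label <- NA_character_
  for (rg in unique(features$region_group)) {
    sel <- features$region_group == rg & features$screen_label == "tau"
    if (!any(sel)) next
    features$label[sel] <- predict_labels(regional_models[[rg]],
                                          features[sel, , drop = FALSE])
  }
  features
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tau classifier: feature importances
#'
#' @param x A `tau_classifier`.
#' @param ... Unused.
#' @return Tibble of selected features with mean-decrease-in-impurity
#'   importance, descending.
#' @export
tidy.tau_classifier <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row summary of a tau classifier
#'
#' @param x A `tau_classifier`.
#' @param ... Unused.
#' @return One-row tibble: classes, feature count, decision mode, chosen
#'   hyper-parameters and out-of-bag prediction error.
#' @export
glance.tau_classifier <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_features = length(x$features),
    decision = x$decision,
    n_estimators = x$config$n_estimators,
    sampling_strategy = x$config$sampling_strategy,
    oob_error = x$forest$prediction.error
  )
}
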