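test_that("balanced under-sampling targets follow the strategy", {
  lab <- rep(c("A", "B"), c(50, 5))
  expect_equal(balanced_sample_sizes(lab, "all"), c(A = 5L, B = 5L))
  expect_equal(balanced_sample_sizes(lab, "auto"), c(A = 5L, B = 5L))
  lab3 <- rep(c("A", "B", "C"), c(30, 10, 10))
  expect_equal(balanced_sample_sizes(lab3, "majority"),
               c(A = 10L, B = 10L, C = 10L))
  lab4 <- rep(c("A", "B", "C"), c(30, 20, 10))
  expect_equal(balanced_sample_sizes(lab4, "majority"),
               c(A = 10L, B = 20L, C = 10L))
  expect_equal(balanced_sample_sizes(lab4, "not majority"),
               c(A = 30L, B = 10L, C = 10L))
  expect_error(balanced_sample_sizes(factor(rep("A", 3), c("A", "B"))),
               "zero members|2 classes")
  expect_error(balanced_sample_sizes(rep("A", 5)), "2 classes")
})

test_that("balanced bootstraps equalise class counts under 'all'", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(20:60, 3)
    lab <- rep(c("A", "B", "C"), n)
    idx <- balanced_bootstrap(lab, "all", seed = rep)
    expect_equal(as.integer(table(lab[idx])), rep(min(n), 3))
    expect_true(all(idx >= 1 & idx <= length(lab)))
  }
  # sampled balanced bootstrap stays inside each class
  lab <- rep(c("A", "B"), c(50, 5))
  idx <- balanced_bootstrap(lab, "all", seed = 1)
  expect_true(all(lab[idx[1:5]] == "A"))
})

test_that("PR curve area follows the average-precision step rule", {
  # perfect ranking
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # inverted ranking vs brute force
  s <- c(0.1, 0.2, 0.8, 0.9); y <- c(1, 1, 0, 0)
  expect_equal(pr_auc(s, y), oracle_pr_auc(s, y))
  # 4-point toy
  s <- c(0.9, 0.8, 0.4, 0.2); y <- c(1, 0, 1, 0)
  expect_equal(pr_auc(s, y), oracle_pr_auc(s, y))
  expect_error(pr_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  # random small sets (with score ties) match exhaustive enumeration
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    s <- sample(seq(0.1, 0.9, by = 0.1), n, replace = TRUE)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(pr_auc(s, y), oracle_pr_auc(s, y))
  }
})

test_that("threshold tuning maximises F1 with the smallest maximiser", {
  scores <- cbind(A = c(0.9, 0.8, 0.1, 0.2), B = c(0.1, 0.2, 0.9, 0.8))
  th <- tune_thresholds(scores, c("A", "A", "B", "B"))
  expect_equal(th$threshold[th$class == "A"], 0.8)
  expect_equal(th$f1[th$class == "A"], 1)
  # random scores: returned F1 equals a dense sweep maximum
  set.seed(6)
  s <- matrix(runif(200), ncol = 2, dimnames = list(NULL, c("A", "B")))
  s <- s / rowSums(s)
  lab <- sample(c("A", "B"), 100, replace = TRUE)
  th <- tune_thresholds(s, lab)
  dense <- seq(0, 1, by = 1e-4)
  for (cl in c("A", "B")) {
    f1_at <- function(t) {
      pred <- s[, cl] >= t
      tp <- sum(pred & lab == cl)
      if (tp == 0) return(0)
      p <- tp / sum(pred); r <- tp / sum(lab == cl)
      2 * p * r / (p + r)
    }
    best_dense <- max(vapply(dense, f1_at, numeric(1)))
    expect_equal(th$f1[th$class == cl], best_dense, tolerance = 1e-12)
  }
  # degenerate: identical scores, warning path (one warning per dead class)
  s0 <- cbind(A = rep(0, 4), B = rep(1, 4))
  w <- capture_warnings(th0 <- tune_thresholds(s0, rep("A", 4)))
  expect_true(any(grepl("0.5", w)))
  expect_equal(th0$threshold[th0$class == "A"], 0.5)
})

test_that("threshold-moving applies the ambiguity rule", {
  thr <- c(CB = 0.20, NFT = 0.68, TA = 0.51, TF = 0.76)
  sc <- rbind(c(0.90, 0.05, 0.02, 0.03),
              c(0.25, 0.01, 0.02, 0.72),
              c(0.24, 0.00, 0.00, 0.76),
              c(0.10, 0.10, 0.10, 0.70))
  colnames(sc) <- names(thr)
  expect_equal(apply_thresholds(sc, thr),
               c("CB", "CB", "Ambiguous", "Ambiguous"))
  expect_error(apply_thresholds(sc[, 1:3], thr), "match")
})

test_that("argmax screening favours tau on ties", {
  sc <- rbind(c(tau = 0.9, non_tau = 0.1), c(tau = 0.5, non_tau = 0.5))
  expect_equal(argmax_labels(sc), c("tau", "tau"))
  # brute-force comparison oracle on random two-class scores
  set.seed(10)
  s <- matrix(runif(100), ncol = 2, dimnames = list(NULL, c("tau", "non_tau")))
  got <- argmax_labels(s)
  want <- ifelse(s[, "tau"] >= s[, "non_tau"], "tau", "non_tau")
  expect_equal(got, want)
})

test_that("thresholding at 0.5 on tie-free binary scores equals argmax", {
  set.seed(11)
  s <- runif(200, 0.01, 0.99)
  s <- s[abs(s - 0.5) > 1e-6]
  sc <- cbind(A = s, B = 1 - s)
  lab_thr <- apply_thresholds(sc, c(A = 0.5, B = 0.5))
  lab_arg <- colnames(sc)[apply(sc, 1, which.max)]
  # scores summing to 1 with threshold 0.5: exactly one class passes,
  # so threshold-moving reduces to plain argmax classification
  expect_false(any(lab_thr == "Ambiguous"))
  expect_equal(lab_thr, lab_arg)
})

test_that("evaluation metrics match hand computation", {
  # identity
  ev <- evaluate_classification(c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(ev$macro_f1, 1)
  expect_equal(ev$kappa, 1)
  expect_true(all(ev$confusion == diag(diag(ev$confusion))))
  # 2x2 toy: TP=3, FP=1, FN=1, TN=5
  pred <- c(rep("pos", 3), "pos", rep("neg", 1), rep("neg", 5))
  truth <- c(rep("pos", 3), "neg", rep("pos", 1), rep("neg", 5))
  ev <- evaluate_classification(pred, truth)
  pc <- ev$per_class[ev$per_class$class == "pos", ]
  expect_equal(pc$precision, 0.75)
  expect_equal(pc$recall, 0.75)
  expect_equal(pc$f1, 0.75)
  # kappa: po = 0.8, pe = (4*4 + 6*6)/100 = 0.52
  expect_equal(ev$kappa, (0.8 - 0.52) / (1 - 0.52))
  # independent predictions -> kappa near 0
  set.seed(13)
  t2 <- sample(c("A", "B"), 4000, replace = TRUE)
  p2 <- sample(c("A", "B"), 4000, replace = TRUE)
  expect_lt(abs(evaluate_classification(p2, t2)$kappa), 0.05)
  # ambiguous handling
  ev3 <- evaluate_classification(c("A", "Ambiguous", "B", "B"),
                                 c("A", "A", "B", "B"))
  expect_equal(ev3$ambiguous_fraction, 0.25)
  expect_equal(ev3$macro_f1, 1)
  expect_error(evaluate_classification(character(0), character(0)), "empty")
})

test_that("tuning separable classes reaches PR-AUC 1 and is deterministic", {
  set.seed(20)
  n <- 120
  x <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(x) <- paste0("f", 1:6)
  y <- rep(c("A", "B"), each = n / 2)
  x$f1[y == "B"] <- x$f1[y == "B"] + 8
  space <- hyperparam_space(n_features_to_select = c(4, 6),
                            n_estimators = c(100, 200))
  t1 <- tune_classifier(x, y, space, n_candidates = 2, k = 5, seed = 7)
  expect_equal(max(t1$results$mean_pr_auc), 1)
  t2 <- tune_classifier(x, y, space, n_candidates = 2, k = 5, seed = 7)
  expect_identical(t1$best_config, t2$best_config)
  expect_equal(t1$fold_scores, t2$fold_scores)
  expect_error(tune_classifier(x, y, space, n_candidates = 0), "n_candidates")
  expect_error(tune_classifier(x[1:8, ], y[1:8], space, n_candidates = 1,
                               k = 10), "fewer than k")
})

test_that("pure-noise features score near the prevalence baseline", {
  set.seed(30)
  n <- 300
  x <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(x) <- paste0("f", 1:8)
  y <- rep(c("A", "B"), each = n / 2)
  space <- hyperparam_space(n_features_to_select = 8,
                            n_estimators = 200, max_features = 0.6,
                            max_depth = Inf, min_samples_split = 2,
                            min_samples_leaf = 1, sampling_strategy = "auto",
                            max_samples = Inf)
  tr <- tune_classifier(x, y, space, n_candidates = 1, k = 5, seed = 8)
  expect_lt(abs(mean(tr$results$mean_pr_auc) - 0.5), 0.1)
})

test_that("a trained classifier separates the synthetic tau types", {
  h <- train_features()
  m <- train_tau_classifier(h, h$class, config = fast_config(),
                            decision = "threshold", seed = 5)
  expect_s3_class(m, "tau_classifier")
  expect_true(all(m$thresholds$threshold >= 0 & m$thresholds$threshold <= 1))
  expect_length(m$features, 40)
  sc <- predict_scores(m, heldout_features())
  expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)), tolerance = 1e-9)
  lab <- predict_labels(m, heldout_features())
  ev <- evaluate_classification(lab, heldout_features()$class)
  expect_gt(ev$macro_f1, 0.85)
  # tidy/glance interfaces
  td <- tidy(m)
  expect_true(all(td$feature %in% feature_names()))
  expect_equal(glance(m)$n_features, 40)
})

test_that("the two-stage pipeline screens then types by region", {
  h <- train_features()
  screen <- train_tau_classifier(h, h$screen, config = fast_config(),
                                 decision = "argmax", seed = 3)
  regional <- lapply(region_groups(), function(rg) {
    d <- h[h$region_group == rg & h$class != "non_tau", ]
    train_tau_classifier(d, d$class, config = fast_config(),
                         decision = "threshold", seed = 4)
  })
  names(regional) <- region_groups()
  # TA-free class lists in STN_GP and dentate
  expect_false("TA" %in% regional$STN_GP$classes)
  expect_false("TA" %in% regional$dentate$classes)
  out <- classify_pipeline(heldout_features(), screen, regional)
  expect_true(all(is.na(out$label[out$screen_label == "non_tau"])))
  typed <- out[!is.na(out$label), ]
  expect_true(all(typed$label %in% c(tau_types(), "Ambiguous")))
  expect_lte(mean(typed$label == "Ambiguous"), 0.1)
  keep <- typed$class != "non_tau"
  ev <- evaluate_classification(typed$label[keep], typed$class[keep])
  expect_gt(ev$macro_f1, 0.8)
})
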