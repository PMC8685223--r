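test_that("metrics follow their definitions at threshold zero", {
  m <- evaluate_metrics(c(1, 2, -1, -2), c(1, 1, 0, 0))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$auc, 1)
  expect_equal(evaluate_metrics(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  # {+: 0.9, 0.4; -: 0.6, 0.1} -> AUC 3/4
  expect_equal(evaluate_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc,
               0.75)
  expect_true(is.na(evaluate_metrics(c(1, 2), c(1, 1))$auc))
})

test_that("rank AUC equals exhaustive pair counting with ties", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(round(rnorm(n), 1)) # coarse values force ties
    expect_equal(evaluate_metrics(s, y)$auc, auc_pairs_oracle(s, y),
                 tolerance = 1e-12)
  }
})

test_that("sensitivity and specificity are invariant under duplication", {
  set.seed(2)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  m1 <- evaluate_metrics(s, y)
  m2 <- evaluate_metrics(rep(s, 2), rep(y, 2))
  expect_equal(m1$sensitivity, m2$sensitivity)
  expect_equal(m1$specificity, m2$specificity)
  expect_equal(m1$auc, m2$auc)
})

test_that("OR/AND labeling uses the half-open episode convention", {
  phases <- data.frame(t_end = c(2.0, 2.5, 4.0))
  eps <- data.frame(start = c(1.5, 3.0), end = c(2.5, 3.5),
                    subtype = c("shuffling", "trembling"),
                    rater = c("expert1", "expert2"))
  expect_equal(label_motion_phases(phases, eps, "OR"), c(1L, 0L, 0L))
  # AND with a non-overlapping second rater: nothing survives
  expect_equal(label_motion_phases(phases, eps, "AND"), c(0L, 0L, 0L))
  # phase ending exactly at the episode end is normal
  expect_equal(label_motion_phases(data.frame(t_end = 2.5), eps[1, ], "OR"),
               0L)
  expect_equal(label_motion_phases(phases, eps[0, ], "OR"), c(0L, 0L, 0L))
})

test_that("rater agreement is the AND/OR ratio", {
  expect_equal(rater_agreement(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(rater_agreement(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # e1 marks {1,2,3}, e2 marks {2,3,4} -> 2/4
  expect_equal(rater_agreement(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 0)), 0.5)
  expect_equal(rater_agreement(c(0, 0), c(0, 0)), 1)
})

test_that("both classifier families separate Gaussian blobs", {
  set.seed(0)
  X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 4), 100, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c(0, 1), each = 100)
  m_svm <- train_classifier(X, y, classifier_spec("C210", "SVM_10"), seed = 0)
  expect_gte(mean((predict(m_svm, X) > 0) == y), 0.99)
  m_ada <- train_classifier(X, y, classifier_spec("C0", "AdaBoost"), seed = 0)
  expect_gte(mean((predict(m_ada, X) > 0) == y), 0.99)
  expect_error(train_classifier(X, rep(1, 200),
                                classifier_spec("C0", "SVM_10")),
               "both classes")
})

test_that("published hyperparameter defaults are wired to each variant", {
  expect_equal(classifier_spec("C0", "SVM_10")$hyperparams,
               list(C = 5.9, gamma = 0.005))
  expect_equal(classifier_spec("C210", "SVM_5")$hyperparams,
               list(C = 10, gamma = 0.006))
  expect_equal(classifier_spec("C21", "SVM_5")$hyperparams,
               list(C = 10, gamma = 0.081))
  hp <- classifier_spec("C210", "AdaBoost")$hyperparams
  expect_equal(hp, list(criterion = "gini", max_depth = 2L,
                        n_estimators = 20L, learning_rate = 0.447))
  expect_error(classifier_spec("C0", "SVM_10", hyperparams = list(C = -1)))
})

test_that("model JSON persistence round-trips predictions", {
  set.seed(3)
  X <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.numeric(X[, 1] + X[, 2] > 0)
  for (mdl in c("SVM_10", "AdaBoost")) {
    m <- train_classifier(X, y, classifier_spec("C0", mdl), seed = 3)
    f <- withr::local_tempfile(fileext = ".json")
    save_model_json(m, f)
    m2 <- load_model_json(f)
    expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-9)
  }
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  a <- c(0.9, 0.8, 0.85, 0.95)
  expect_equal(as.numeric(compare_models_ttest(a, a)), 1)
  p0 <- compare_models_ttest(a + 0.1, a)
  expect_equal(as.numeric(p0), 0)
  expect_true(attr(p0, "zero_variance"))
  set.seed(5)
  b <- a + rnorm(4, 0.05, 0.02)
  d <- b - a
  tstat <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(as.numeric(compare_models_ttest(b, a)),
               2 * pt(-abs(tstat), 3), tolerance = 1e-9)
  expect_error(compare_models_ttest(a, a[1:2]), "equal length")
})

test_that("best-foot selection is an argmax with left-tie rule", {
  df <- data.frame(subject = c("S1", "S1", "S2", "S2"),
                   foot = c("left", "right", "left", "right"),
                   auc = c(0.9, 0.8, 0.7, 0.7))
  bf <- select_best_foot(df)
  expect_equal(bf$foot[bf$subject == "S1"], "left")
  expect_equal(bf$foot[bf$subject == "S2"], "left")
  expect_true(bf$tie[bf$subject == "S2"])
  # best-foot mean never falls below either single-side mean
  expect_gte(mean(bf$auc),
             max(mean(df$auc[df$foot == "left"]),
                 mean(df$auc[df$foot == "right"])))
})

test_that("pre-akinesia fraction enumerates qualifying phases", {
  phases <- data.frame(t_end = c(7.2, 7.8, 8.5, 9.5, 11.0))
  eps <- data.frame(start = c(5, 10), end = c(8.6, 12),
                    subtype = c("shuffling", "akinesia"),
                    rater = "expert1")
  # qualifying (within [7, 10)): 7.2, 7.8, 8.5, 9.5; first three shuffling
  expect_equal(preakinesia_fraction(phases, eps, horizon_s = 3), 0.75)
  expect_true(is.na(preakinesia_fraction(phases, eps[1, ], 3)))
  eps2 <- eps; eps2$end[1] <- 9.6
  expect_equal(preakinesia_fraction(phases, eps2, 3), 1.0)
})

test_that("LOPO folds count correctly and never leak the held-out subject", {
  rows <- simulate_cohort(4, 0.5, effect_size = 1.5, seed = 21,
                          phases_per_foot = 25)
  spec <- classifier_spec("C0", "SVM_10")
  res <- lopo_cross_validate(rows, spec, seed = 1)
  expect_equal(nrow(res$per_foot), 8L) # 4 subjects x 2 feet
  expect_equal(sort(unique(res$per_foot$subject)), sort(unique(rows$subject)))

  # corrupting the held-out subject's labels cannot change its scores
  s1 <- unique(rows$subject)[1]
  rows2 <- rows
  rows2$label[rows2$subject == s1] <- 1 - rows2$label[rows2$subject == s1]
  train_rows <- function(r) r[r$subject != s1, ]
  m1 <- train_classifier(
    build_design_matrix(train_rows(rows), "C0")$X,
    build_design_matrix(train_rows(rows), "C0")$y, spec, seed = 1)
  d_test <- build_design_matrix(rows[rows$subject == s1, ], "C0")
  d_test2 <- build_design_matrix(rows2[rows2$subject == s1, ], "C0")
  expect_identical(predict(m1, d_test$X), predict(m1, d_test2$X))
})

test_that("a 2-subject cohort yields 2 folds and 4 results", {
  rows <- simulate_cohort(2, 0.5, effect_size = 1, seed = 22,
                          phases_per_foot = 20)
  res <- lopo_cross_validate(rows, classifier_spec("C0", "SVM_10"), seed = 1)
  expect_equal(nrow(res$per_foot), 4L)
  expect_equal(length(unique(res$per_foot$subject)), 2L)
})

test_that("SVM_5 selects five base features per training fold", {
  rows <- simulate_cohort(3, 0.5, effect_size = 2, seed = 23,
                          phases_per_foot = 30)
  res <- lopo_cross_validate(rows, classifier_spec("C0", "SVM_5"), seed = 1)
  expect_equal(nrow(res$per_foot), 6L)
  expect_gte(mean(res$per_foot$auc), 0.8)
  # fixed-subset mode bypasses the per-fold ranking
  fixed <- classifier_spec("C0", "SVM_5",
                           feature_subset = c("max_velocity", "step_duration",
                                              "stride_length", "max_pitch",
                                              "min_pitch"))
  res2 <- lopo_cross_validate(rows, fixed, seed = 1)
  expect_equal(nrow(res2$per_foot), 6L)
})

test_that("random-search tuning is seeded and respects its budget", {
  set.seed(1)
  X <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 3), 50, 2))
  y <- rep(c(0, 1), each = 50)
  spec <- classifier_spec("C0", "SVM_10")
  h1 <- tune_hyperparameters(X, y, spec, budget = 5, seed = 11)
  h2 <- tune_hyperparameters(X, y, spec, budget = 5, seed = 11)
  expect_identical(h1, h2)
  expect_gte(attr(h1, "auc"),
             0.9) # separable data: tuned model close to perfect
  h3 <- tune_hyperparameters(X, y, spec, budget = 1, seed = 2)
  expect_true(is.numeric(h3$C) && is.numeric(h3$gamma))
  expect_error(tune_hyperparameters(X, y, spec, budget = 0), "budget")
})
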