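# Motion-phase FoG classification: labeling, SVM/AdaBoost training,
# metrics, and leave-one-patient-out evaluation.

.svm_defaults <- list(
  C0   = list(SVM_10 = list(C = 5.9,  gamma = 0.005),
              SVM_5  = list(C = 0.032, gamma = 0.33)),
  C210 = list(SVM_10 = list(C = 2.37, gamma = 0.026),
              SVM_5  = list(C = 10,   gamma = 0.006)),
  C21  = list(SVM_10 = list(C = 10,   gamma = 0.006),
              SVM_5  = list(C = 10,   gamma = 0.081)))

.ada_defaults <- list(
  C0   = list(criterion = "entropy", max_depth = 3L, n_estimators = 20L,
              learning_rate = 0.318),
  C210 = list(criterion = "gini",    max_depth = 2L, n_estimators = 20L,
              learning_rate = 0.447),
  C21  = list(criterion = "entropy", max_depth = 5L, n_estimators = 20L,
              learning_rate = 0.01))

#' Classifier specification
#'
#' Bundles a design-matrix variant (`C0`: current phase, `C210`: current
#' plus two preceding phases, `C21`: two preceding phases only, i.e. a
#' predictor) with a model family and its published default
#' hyperparameters. `SVM_5` restricts each lag block to the five most
#' important features (chi-square ranking fitted on training data
#' inside each fold, or a fixed subset via `feature_subset`).
#'
#' @param variant `"C0"`, `"C210"`, or `"C21"`.
#' @param model `"SVM_10"`, `"SVM_5"`, or `"AdaBoost"`.
#' @param hyperparams optional list overriding the defaults
#'   (`C`/`gamma` for SVM; `criterion`/`max_depth`/`n_estimators`/
#'   `learning_rate` for AdaBoost).
#' @param feature_subset optional fixed character vector of base feature
#'   names for `SVM_5` (bypasses per-fold ranking).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(variant = c("C0", "C210", "C21"),
                            model = c("SVM_10", "SVM_5", "AdaBoost"),
                            hyperparams = NULL, feature_subset = NULL) {
  variant <- match.arg(variant)
  model <- match.arg(model)
  hp <- if (model == "AdaBoost") .ada_defaults[[variant]]
  else .svm_defaults[[variant]][[model]]
  if (!is.null(hyperparams)) hp[names(hyperparams)] <- hyperparams
  if (model != "AdaBoost") {
    if (hp$C <= 0 || hp$gamma <= 0) stop("C and gamma must be > 0", call. = FALSE)
  } else {
    if (hp$n_estimators < 1) stop("n_estimators must be >= 1", call. = FALSE)
  }
  structure(list(variant = variant, model = model, hyperparams = hp,
                 feature_subset = feature_subset),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("classifier_spec: %s %s | %s\n", x$variant, x$model,
              paste(names(x$hyperparams), unlist(x$hyperparams),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Train a FoG classifier
#'
#' Fits either a soft-margin RBF-kernel SVM (in-package SMO solver) or
#' AdaBoost over depth-limited decision trees. Features are z-score
#' standardised internally with the training mean/SD (stored in the
#' model and applied at prediction time). The positive class is FoG
#' (label 1).
#'
#' @param X numeric matrix of features (rows = motion phases).
#' @param y binary labels, coerced to 0/1 (1 = FoG).
#' @param spec a [classifier_spec()].
#' @param seed integer seed (tree and SMO fits are deterministic; the
#'   seed is stored for provenance).
#' @return object of class `fog_model` with a [predict.fog_model()]
#'   method returning continuous decision scores.
#' @export
train_classifier <- function(X, y, spec, seed = 1L) {
  X <- as.matrix(X)
  y01 <- as.numeric(y != 0)
  if (length(unique(y01)) < 2L)
    stop("y must contain both classes", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  set.seed(seed)
  fit <- if (spec$model == "AdaBoost") {
    hp <- spec$hyperparams
    .adaboost_fit(Xs, y01, n_estimators = hp$n_estimators,
                  max_depth = hp$max_depth, criterion = hp$criterion,
                  learning_rate = hp$learning_rate)
  } else {
    hp <- spec$hyperparams
    ypm <- 2 * y01 - 1
    sol <- .svm_smo_fit(Xs, ypm, C = hp$C, gamma = hp$gamma)
    sv <- which(sol$alpha > 1e-12)
    list(Xsv = Xs[sv, , drop = FALSE], coef = sol$alpha[sv] * ypm[sv],
         b = sol$b, gamma = hp$gamma, converged = sol$converged)
  }
  structure(list(spec = spec, fit = fit, center = ctr, scale = scl,
                 features = colnames(X), seed = seed),
            class = "fog_model")
}

#' Predict decision scores for motion phases
#'
#' @param object a `fog_model`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return numeric decision scores; positive scores classify as FoG.
#' @export
predict.fog_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X)))
    X <- X[, object$features, drop = FALSE]
  Xs <- scale(X, center = object$center, scale = object$scale)
  if (object$spec$model == "AdaBoost") {
    .adaboost_score(object$fit, Xs)
  } else {
    .svm_decision(object$fit$Xsv, object$fit$coef, object$fit$b,
                  object$fit$gamma, Xs)
  }
}

#' Random-search hyperparameter tuning
#'
#' Seeded log-uniform random search over `(C, gamma)` for SVMs or over
#' the AdaBoost grid, scored by inner k-fold cross-validated AUC. The
#' published defaults remain the shipped operating point; this is an
#' optional re-tuning utility.
#'
#' @param X,y training data (see [train_classifier()]).
#' @param spec a [classifier_spec()].
#' @param budget number of hyperparameter evaluations (>= 1).
#' @param seed integer seed; results are deterministic given the seed.
#' @param k inner CV folds.
#' @return list of tuned hyperparameters (same shape as
#'   `spec$hyperparams`) with attribute `"auc"`.
#' @export
tune_hyperparameters <- function(X, y, spec, budget = 20L, seed = 1L, k = 3L) {
  if (budget < 1L) stop("budget must be >= 1", call. = FALSE)
  X <- as.matrix(X); y01 <- as.numeric(y != 0)
  set.seed(seed)
  cand <- lapply(seq_len(budget), function(i) {
    if (spec$model == "AdaBoost") {
      list(criterion = sample(c("gini", "entropy"), 1L),
           max_depth = sample(1:5, 1L),
           n_estimators = 20L,
           learning_rate = 10^stats::runif(1, -2, 0))
    } else {
      list(C = 10^stats::runif(1, -2, 2), gamma = 10^stats::runif(1, -3, 0.5))
    }
  })
  fold <- sample(rep_len(seq_len(k), length(y01)))
  score_one <- function(hp) {
    sp <- classifier_spec(spec$variant, spec$model, hyperparams = hp)
    aucs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (length(unique(y01[tr])) < 2L || length(unique(y01[!tr])) < 2L)
        return(NA_real_)
      m <- train_classifier(X[tr, , drop = FALSE], y01[tr], sp, seed = seed)
      s <- predict(m, X[!tr, , drop = FALSE])
      evaluate_metrics(s, y01[!tr])$auc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  scores <- vapply(cand, score_one, numeric(1))
  best <- cand[[which.max(scores)]]
  attr(best, "auc") <- max(scores)
  best
}

#' Classification metrics at the natural decision threshold
#'
#' Sensitivity, specificity and accuracy at score threshold 0 (FoG is
#' the positive class), and the AUC computed as the Mann-Whitney
#' statistic over all positive-negative score pairs with ties counting
#' one half (rank-based implementation).
#'
#' @param scores continuous decision scores.
#' @param labels binary labels (1/TRUE = FoG).
#' @return list with `sensitivity`, `specificity`, `accuracy`, `auc`,
#'   and counts `n_fog`, `n_normal`. `auc` is `NA` when one class is
#'   absent.
#' @export
evaluate_metrics <- function(scores, labels) {
  y <- as.numeric(labels != 0)
  pred <- as.numeric(scores > 0)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- if (n1 == 0L || n0 == 0L) NA_real_ else {
    r <- rank(scores, ties.method = "average")
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(sensitivity = if (n1 > 0) tp / (tp + fn) else NA_real_,
       specificity = if (n0 > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(y),
       auc = auc, n_fog = n1, n_normal = n0)
}

#' Label motion phases from expert episode annotations
#'
#' A phase is FoG when its end time lies inside an annotated episode
#' (`[start, end)`, closed-open): under `"OR"` an episode of any rater
#' suffices, under `"AND"` every rater must cover the end time.
#'
#' @param phases data.frame with a `t_end` column (e.g. the `motion`
#'   table of a `phase_sequence`).
#' @param episodes data.frame of episodes (`start`, `end`, `subtype`,
#'   `rater`).
#' @param combination `"OR"` or `"AND"`.
#' @param raters raters required for `"AND"`; defaults to those present
#'   in `episodes`.
#' @return integer vector of labels (1 = FoG).
#' @export
label_motion_phases <- function(phases, episodes, combination = c("OR", "AND"),
                                raters = NULL) {
  combination <- match.arg(combination)
  te <- phases$t_end
  if (is.null(te)) stop("phases must have a t_end column", call. = FALSE)
  if (nrow(episodes) == 0L) return(integer(length(te)))
  if (is.null(raters)) raters <- unique(episodes$rater)
  covered_by <- function(eps, t)
    vapply(t, function(ti) any(eps$start <= ti & ti < eps$end), logical(1))
  per_rater <- lapply(raters, function(r)
    covered_by(episodes[episodes$rater == r, , drop = FALSE], te))
  m <- do.call(cbind, per_rater)
  lab <- if (combination == "OR") apply(m, 1L, any) else apply(m, 1L, all)
  as.integer(lab)
}

#' Inter-rater agreement on motion-phase labels
#'
#' Ratio of AND-combined to OR-combined FoG motion phases; 1 when the
#' OR set is empty.
#'
#' @param labels_e1,labels_e2 binary label vectors over the same phases.
#' @return agreement ratio in `[0, 1]`.
#' @export
rater_agreement <- function(labels_e1, labels_e2) {
  stopifnot(length(labels_e1) == length(labels_e2))
  a <- labels_e1 != 0; b <- labels_e2 != 0
  n_or <- sum(a | b)
  if (n_or == 0L) return(1)
  sum(a & b) / n_or
}

#' Paired t-test between two per-subject AUC vectors
#'
#' Two-sided paired t-test on subject-wise AUC values of two classifier
#' specifications. Degenerate cases: identical vectors give p = 1;
#' a constant non-zero difference has zero variance and is reported as
#' p = 0 with attribute `zero_variance = TRUE`.
#'
#' @param aucs_A,aucs_B equal-length per-subject AUC vectors.
#' @return p-value with attributes `statistic` and `zero_variance`.
#' @export
compare_models_ttest <- function(aucs_A, aucs_B) {
  if (length(aucs_A) != length(aucs_B))
    stop("AUC vectors must have equal length", call. = FALSE)
  d <- aucs_A - aucs_B
  n <- length(d)
  sd_d <- stats::sd(d)
  # guard the degenerate constant-difference case against rounding noise
  degenerate <- !is.finite(sd_d) || sd_d < 1e-12 ||
    sd_d < 1e-9 * abs(mean(d))
  if (degenerate) {
    zero <- abs(mean(d)) < 1e-12
    return(structure(if (zero) 1 else 0,
                     statistic = if (zero) 0 else Inf,
                     zero_variance = TRUE))
  }
  tstat <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  structure(p, statistic = tstat, zero_variance = FALSE)
}

#' Pick the better-performing foot per subject
#'
#' @param eval_df data.frame with columns `subject`, `foot`, `auc` (one
#'   row per subject/foot).
#' @return data.frame with `subject`, `foot` (chosen side), `auc`, and
#'   a `tie` flag; ties resolve to the left foot.
#' @export
select_best_foot <- function(eval_df) {
  out <- lapply(split(eval_df, eval_df$subject), function(d) {
    if (nrow(d) == 1L)
      return(data.frame(subject = d$subject, foot = d$foot, auc = d$auc,
                        tie = FALSE))
    l <- d[d$foot == "left", ]; r <- d[d$foot == "right", ]
    tie <- isTRUE(all.equal(l$auc, r$auc))
    pick <- if (tie || l$auc >= r$auc) l else r
    data.frame(subject = pick$subject, foot = pick$foot, auc = pick$auc,
               tie = tie)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of pre-akinesia motion phases labeled as other FoG subtypes
#'
#' Among motion phases ending within `horizon_s` seconds before the
#' start of an akinesia episode (`[start - horizon_s, start)`), the
#' fraction that fall inside an annotated FoG episode of a non-akinesia
#' subtype.
#'
#' @param phases data.frame with `t_end`.
#' @param episodes annotation data.frame; must contain akinesia
#'   episodes.
#' @param horizon_s look-back horizon before akinesia onset, s.
#' @return fraction in `[0, 1]`, or `NA` when no akinesia episode or no
#'   qualifying phase exists.
#' @export
preakinesia_fraction <- function(phases, episodes, horizon_s = 3.0) {
  ak <- episodes[episodes$subtype == "akinesia", , drop = FALSE]
  if (nrow(ak) == 0L) return(NA_real_)
  te <- phases$t_end
  qualifying <- vapply(te, function(ti)
    any(ak$start - horizon_s <= ti & ti < ak$start), logical(1))
  if (!any(qualifying)) return(NA_real_)
  other <- episodes[episodes$subtype != "akinesia", , drop = FALSE]
  lab <- if (nrow(other)) vapply(te, function(ti)
    any(other$start <= ti & ti < other$end), logical(1))
  else rep(FALSE, length(te))
  mean(lab[qualifying])
}

#' Leave-one-patient-out cross-validation
#'
#' For each held-out subject, trains on all remaining subjects (both
#' feet pooled) and evaluates each of the held-out subject's feet
#' separately. Standardisation happens inside [train_classifier()] on
#' training data only; for `SVM_5`, the five most important base
#' features are selected by chi-square ranking on the training fold
#' (unless the spec fixes a subset). Folds whose training labels
#' collapse to one class are skipped with a warning.
#'
#' @param rows feature table: columns `subject`, `foot`, `t_end`,
#'   `label`, and the 10 features.
#' @param spec a [classifier_spec()].
#' @param seed integer seed passed to the per-fold fits.
#' @return object of class `lopo_result`: list with `per_foot`
#'   (data.frame of subject, foot, sensitivity, specificity, accuracy,
#'   auc, counts), `per_subject_auc` (mean AUC over the subject's
#'   feet), and `summary` (mean and SD of each metric across feet).
#' @export
lopo_cross_validate <- function(rows, spec, seed = 1L) {
  subjects <- unique(rows$subject)
  if (length(subjects) < 2L) stop("need at least 2 subjects", call. = FALSE)
  res <- list()
  for (s in subjects) {
    train_rows <- rows[rows$subject != s, , drop = FALSE]
    feats <- feature_names()
    if (spec$model == "SVM_5") {
      feats <- if (!is.null(spec$feature_subset)) spec$feature_subset
      else {
        imp <- rank_features(train_rows[, feature_names(), drop = FALSE],
                             train_rows$label)
        imp$feature[seq_len(5L)]
      }
    }
    dtrain <- build_design_matrix(train_rows, spec$variant, features = feats)
    if (length(unique(dtrain$y)) < 2L) {
      warning("fold for subject ", s, " skipped: single-class training data")
      next
    }
    model <- train_classifier(dtrain$X, dtrain$y, spec, seed = seed)
    for (ft in unique(rows$foot[rows$subject == s])) {
      test_rows <- rows[rows$subject == s & rows$foot == ft, , drop = FALSE]
      dtest <- build_design_matrix(test_rows, spec$variant, features = feats)
      if (nrow(dtest$X) == 0L) next
      sc <- predict(model, dtest$X)
      m <- evaluate_metrics(sc, dtest$y)
      res[[paste(s, ft)]] <- data.frame(
        subject = s, foot = ft, sensitivity = m$sensitivity,
        specificity = m$specificity, accuracy = m$accuracy, auc = m$auc,
        n_fog = m$n_fog, n_normal = m$n_normal)
    }
  }
  per_foot <- do.call(rbind, res)
  rownames(per_foot) <- NULL
  per_subject_auc <- vapply(split(per_foot$auc, per_foot$subject),
                            mean, numeric(1), na.rm = TRUE)
  summary_df <- data.frame(
    metric = c("sensitivity", "specificity", "accuracy", "auc"),
    mean = vapply(c("sensitivity", "specificity", "accuracy", "auc"),
                  function(m) mean(per_foot[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(c("sensitivity", "specificity", "accuracy", "auc"),
                function(m) stats::sd(per_foot[[m]], na.rm = TRUE), numeric(1)))
  rownames(summary_df) <- NULL
  structure(list(per_foot = per_foot, per_subject_auc = per_subject_auc,
                 summary = summary_df, spec = spec),
            class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf("LOPO-CV %s %s: %d (subject, foot) results\n",
              x$spec$variant, x$spec$model, nrow(x$per_foot)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Serialise / restore a fitted model as JSON
#'
#' Portable text persistence for `fog_model` objects (support vectors
#' or boosted trees, scaling, and the spec).
#'
#' @param model a `fog_model`.
#' @param path output JSON path.
#' @return `path` (save) / the restored `fog_model` (load).
#' @export
save_model_json <- function(model, path) {
  jsonlite::write_json(.serialize_model(model), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  .deserialize_model(jsonlite::read_json(path, simplifyVector = TRUE))
}

.serialize_model <- function(m) {
  out <- list(spec = unclass(m$spec), center = m$center, scale = m$scale,
              features = m$features, seed = m$seed, model = m$spec$model)
  if (m$spec$model == "AdaBoost") {
    out$fit <- list(alphas = m$fit$alphas, criterion = m$fit$criterion,
                    max_depth = m$fit$max_depth,
                    learning_rate = m$fit$learning_rate,
                    trees = lapply(m$fit$trees, .tree_to_table))
  } else {
    out$fit <- list(Xsv = m$fit$Xsv, coef = m$fit$coef, b = m$fit$b,
                    gamma = m$fit$gamma)
  }
  out
}

# Flatten a nested tree into a node table (preorder ids), JSON-stable.
.tree_to_table <- function(node) {
  rows <- list()
  add <- function(nd) {
    id <- length(rows) + 1L
    rows[[id]] <<- data.frame(
      leaf = nd$leaf,
      feature = if (nd$leaf) NA_integer_ else as.integer(nd$feature),
      threshold = if (nd$leaf) NA_real_ else nd$threshold,
      p = nd$p, left = NA_integer_, right = NA_integer_)
    if (!nd$leaf) {
      l <- add(nd$left)
      r <- add(nd$right)
      rows[[id]]$left <<- l
      rows[[id]]$right <<- r
    }
    id
  }
  add(node)
  do.call(rbind, rows)
}

.table_to_tree <- function(tab, id = 1L) {
  row <- tab[id, ]
  if (isTRUE(row$leaf)) return(list(leaf = TRUE, p = row$p))
  list(leaf = FALSE, feature = row$feature, threshold = row$threshold,
       p = row$p,
       left = .table_to_tree(tab, row$left),
       right = .table_to_tree(tab, row$right))
}

.deserialize_model <- function(x) {
  spec <- structure(x$spec, class = "classifier_spec")
  fit <- if (x$model == "AdaBoost") {
    list(trees = lapply(x$fit$trees, .table_to_tree),
         alphas = x$fit$alphas,
         criterion = x$fit$criterion, max_depth = x$fit$max_depth,
         learning_rate = x$fit$learning_rate)
  } else {
    list(Xsv = as.matrix(x$fit$Xsv), coef = x$fit$coef, b = x$fit$b,
         gamma = x$fit$gamma)
  }
  structure(list(spec = spec, fit = fit, center = x$center, scale = x$scale,
                 features = x$features, seed = x$seed),
            class = "fog_model")
}
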