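# AdaBoost over depth-limited CART trees (discrete SAMME with learning
# rate, binary labels). The weak learner is a weighted greedy binary
# tree grown on gini or entropy impurity; implemented here because no
# tree package is part of the supported dependency set.

.impurity <- function(p, criterion) {
  p <- pmin(pmax(p, 0), 1)
  if (criterion == "gini") {
    2 * p * (1 - p)
  } else { # entropy (base 2)
    q <- 1 - p
    term <- function(z) ifelse(z <= 0, 0, -z * log2(z))
    term(p) + term(q)
  }
}

# Best weighted split of one feature; returns list(threshold, score) or NULL.
.best_split_feature <- function(x, y, w, criterion) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]; ws <- w[o]
  n <- length(xs)
  cutpos <- which(diff(xs) > 0) # split between cutpos and cutpos+1
  if (!length(cutpos)) return(NULL)
  cw <- cumsum(ws)
  cw1 <- cumsum(ws * ys)
  W <- cw[n]; W1 <- cw1[n]
  wl <- cw[cutpos]; wl1 <- cw1[cutpos]
  wr <- W - wl; wr1 <- W1 - wl1
  pl <- wl1 / wl; pr <- wr1 / wr
  score <- (wl * .impurity(pl, criterion) + wr * .impurity(pr, criterion)) / W
  k <- which.min(score)
  list(threshold = (xs[cutpos[k]] + xs[cutpos[k] + 1L]) / 2,
       score = score[k])
}

.grow_tree <- function(X, y, w, depth, criterion, parent_p = NULL) {
  p <- sum(w * y) / sum(w)
  if (depth <= 0L || p <= 0 || p >= 1 || nrow(X) < 2L)
    return(list(leaf = TRUE, p = p))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    sp <- .best_split_feature(X[, j], y, w, criterion)
    if (!is.null(sp) && (is.null(best) || sp$score < best$score)) {
      best <- sp; best$feature <- j
    }
  }
  if (is.null(best) || best$score >= .impurity(p, criterion) - 1e-12)
    return(list(leaf = TRUE, p = p))
  left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       p = p,
       left = .grow_tree(X[left, , drop = FALSE], y[left], w[left],
                         depth - 1L, criterion),
       right = .grow_tree(X[!left, , drop = FALSE], y[!left], w[!left],
                          depth - 1L, criterion))
}

.predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  route <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$leaf) {
      out[idx] <<- node$p
      return(invisible())
    }
    left <- X[idx, node$feature] <= node$threshold
    route(node$left, idx[left])
    route(node$right, idx[!left])
  }
  route(tree, seq_len(n))
  out
}

# Fit AdaBoost; y in {0,1}. Returns trees, stage weights, and metadata.
.adaboost_fit <- function(X, y, n_estimators = 20L, max_depth = 3L,
                          criterion = c("entropy", "gini"),
                          learning_rate = 1) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    tree <- .grow_tree(X, y, w, as.integer(max_depth), criterion)
    pred <- as.numeric(.predict_tree(tree, X) >= 0.5)
    miss <- pred != y
    err <- sum(w[miss])
    if (err <= 0) { # perfect learner: dominate the vote and stop
      trees[[m]] <- tree
      alphas[m] <- learning_rate * log((1 - 1e-10) / 1e-10)
      break
    }
    if (err >= 0.5) break # no better than chance under current weights
    a <- learning_rate * log((1 - err) / err)
    trees[[m]] <- tree
    alphas[m] <- a
    w[miss] <- w[miss] * exp(a)
    w <- w / sum(w)
  }
  if (!length(trees))
    stop("AdaBoost: first weak learner no better than chance", call. = FALSE)
  list(trees = trees, alphas = alphas, criterion = criterion,
       max_depth = max_depth, learning_rate = learning_rate)
}

# Weighted-vote score in (-sum(alpha), +sum(alpha)); positive => class 1.
.adaboost_score <- function(fit, X) {
  X <- as.matrix(X)
  s <- numeric(nrow(X))
  for (m in seq_along(fit$trees)) {
    h <- 2 * as.numeric(.predict_tree(fit$trees[[m]], X) >= 0.5) - 1
    s <- s + fit$alphas[m] * h
  }
  s
}
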