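# Self-contained learners backing the model adapters. All take a numeric
# feature matrix `x` and a 0/1 response `y` (1 = positive/minority class)
# and return an object with a `predict_prob(fit, x)`-compatible interface.

## ---- CART / random forest (Gini criterion, Rcpp core) ----

fit_cart <- function(x, y, cp = 0.01, maxdepth = 30L, min_node = 7L,
                     mtry = 0L) {
  n <- nrow(x)
  p <- mean(y)
  root_imp <- n * 2 * p * (1 - p)
  tree <- .grow_tree_cpp(x, as.numeric(y), numeric(n),
                         seq_len(n) - 1L, 0L, 0, cp * root_imp,
                         as.integer(maxdepth), as.integer(min_node),
                         as.integer(mtry))
  structure(list(tree = tree, cp = cp,
                 importance = stats::setNames(tree$importance, colnames(x))),
            class = "cart_fit")
}

predict_cart_prob <- function(fit, x) .predict_tree_cpp(fit$tree, x)

fit_rf <- function(x, y, ntree = 500L, mtry = 3L, maxdepth = 30L,
                   min_node = 1L) {
  n <- nrow(x)
  mtry <- min(mtry, ncol(x))
  trees <- vector("list", ntree)
  imp <- numeric(ncol(x))
  for (b in seq_len(ntree)) {
    rows <- sample.int(n, n, replace = TRUE) - 1L
    trees[[b]] <- .grow_tree_cpp(x, as.numeric(y), numeric(n), rows, 0L,
                                 0, 1e-9, as.integer(maxdepth),
                                 as.integer(min_node), as.integer(mtry))
    imp <- imp + trees[[b]]$importance
  }
  structure(list(trees = trees, ntree = ntree,
                 importance = stats::setNames(imp / ntree, colnames(x))),
            class = "rf_fit")
}

predict_rf_prob <- function(fit, x) {
  p <- numeric(nrow(x))
  for (tr in fit$trees) p <- p + .predict_tree_cpp(tr, x)
  p / fit$ntree
}

## ---- gradient-boosted trees (second-order logistic loss) ----

fit_gbt <- function(x, y, nrounds = 150L, learning_rate = 0.01,
                    max_depth = 5L, gamma = 3, lambda = 1,
                    min_node = 1L) {
  n <- nrow(x)
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  base <- log(p0 / (1 - p0))
  f <- rep(base, n)
  trees <- vector("list", nrounds)
  imp <- numeric(ncol(x))
  rows <- seq_len(n) - 1L
  for (k in seq_len(nrounds)) {
    p <- stats::plogis(f)
    grad <- p - y
    hess <- pmax(p * (1 - p), 1e-12)
    tr <- .grow_tree_cpp(x, grad, hess, rows, 1L, lambda, gamma,
                         as.integer(max_depth), as.integer(min_node), 0L)
    trees[[k]] <- tr
    imp <- imp + tr$importance
    f <- f + learning_rate * .predict_tree_cpp(tr, x)
  }
  structure(list(trees = trees, base = base, eta = learning_rate,
                 importance = stats::setNames(imp, colnames(x))),
            class = "gbt_fit")
}

predict_gbt_prob <- function(fit, x) {
  f <- rep(fit$base, nrow(x))
  for (tr in fit$trees) f <- f + fit$eta * .predict_tree_cpp(tr, x)
  stats::plogis(f)
}

## ---- radial-kernel SVM via sequential minimal optimisation ----

# Features are centred/scaled on the training set (the convention of the
# usual radial-SVM front ends) so gamma acts on comparable coordinates.
fit_svm_rbf <- function(x, y, cost = 1, gamma = 0.1, tol = 1e-3,
                        max_sweeps = 200L) {
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  ys <- ifelse(y > 0, 1, -1)
  d2 <- as.matrix(stats::dist(xs))^2
  K <- exp(-gamma * d2)
  alpha <- numeric(n)
  b <- 0
  E <- as.vector(K %*% (alpha * ys)) + b - ys
  C <- cost
  quiet_pass <- 0L
  sweeps <- 0L
  while (quiet_pass < 2L && sweeps < max_sweeps) {
    changed <- 0L
    for (i in seq_len(n)) {
      ri <- E[i] * ys[i]
      if (!((ri < -tol && alpha[i] < C) || (ri > tol && alpha[i] > 0)))
        next
      j <- which.max(abs(E - E[i]))  # deterministic second choice
      if (j == i) next
      eta <- 2 * K[i, j] - K[i, i] - K[j, j]
      if (eta >= 0) next
      if (ys[i] == ys[j]) {
        L <- max(0, alpha[i] + alpha[j] - C)
        H <- min(C, alpha[i] + alpha[j])
      } else {
        L <- max(0, alpha[j] - alpha[i])
        H <- min(C, C + alpha[j] - alpha[i])
      }
      if (L >= H) next
      aj_new <- alpha[j] - ys[j] * (E[i] - E[j]) / eta
      aj_new <- min(max(aj_new, L), H)
      if (abs(aj_new - alpha[j]) < 1e-7) next
      ai_new <- alpha[i] + ys[i] * ys[j] * (alpha[j] - aj_new)
      b1 <- b - E[i] - ys[i] * (ai_new - alpha[i]) * K[i, i] -
        ys[j] * (aj_new - alpha[j]) * K[i, j]
      b2 <- b - E[j] - ys[i] * (ai_new - alpha[i]) * K[i, j] -
        ys[j] * (aj_new - alpha[j]) * K[j, j]
      b_new <- if (ai_new > 0 && ai_new < C) b1
               else if (aj_new > 0 && aj_new < C) b2
               else (b1 + b2) / 2
      E <- E + ys[i] * (ai_new - alpha[i]) * K[, i] +
        ys[j] * (aj_new - alpha[j]) * K[, j] + (b_new - b)
      alpha[i] <- ai_new
      alpha[j] <- aj_new
      b <- b_new
      changed <- changed + 1L
    }
    sweeps <- sweeps + 1L
    quiet_pass <- if (changed == 0L) quiet_pass + 1L else 0L
  }
  sv <- alpha > 1e-8
  structure(list(sv_x = xs[sv, , drop = FALSE],
                 sv_coef = (alpha * ys)[sv], b = b, gamma = gamma,
                 cost = cost, center = ctr, scale = scl,
                 sweeps = sweeps),
            class = "svm_fit")
}

svm_decision <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  if (!nrow(fit$sv_x)) return(rep(fit$b, nrow(xs)))
  d2 <- outer(rowSums(xs^2), rowSums(fit$sv_x^2), "+") -
    2 * xs %*% t(fit$sv_x)
  as.vector(exp(-fit$gamma * pmax(d2, 0)) %*% fit$sv_coef) + fit$b
}

predict_svm_prob <- function(fit, x) {
  # decision value mapped through a logistic link purely for a [0,1]
  # score; the 0.5 threshold reproduces the sign rule
  stats::plogis(svm_decision(fit, x))
}

## ---- neural networks (0 or 1 hidden layer, ReLU, resilient backprop) ----

# Full-batch resilient backpropagation (the training family of the usual R
# feed-forward net package): per-weight step sizes adapted by gradient
# sign, stopping when the largest absolute partial derivative of the
# penalised log-loss falls below `threshold` or `maxit` steps elapse.
fit_mlp <- function(x, y, hidden = 0L, decay = 0, maxit = 5000L,
                    threshold = 0.01, init_half_width = 0.5,
                    step0 = 0.1) {
  n <- nrow(x); d <- ncol(x)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rng <- pmax(hi - lo, 1e-8)
  xs <- sweep(sweep(x, 2, lo), 2, rng, "/")
  nw <- if (hidden > 0) (d + 1) * hidden + hidden + 1 else d + 1
  w <- stats::runif(nw, -init_half_width, init_half_width)
  unpack <- function(w) {
    if (hidden > 0) {
      W1 <- matrix(w[seq_len(d * hidden)], d, hidden)
      b1 <- w[d * hidden + seq_len(hidden)]
      W2 <- w[d * hidden + hidden + seq_len(hidden)]
      b2 <- w[nw]
      list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    } else {
      list(W2 = w[seq_len(d)], b2 = w[d + 1])
    }
  }
  grad_fn <- function(w) {
    pr <- unpack(w)
    if (hidden > 0) {
      A <- sweep(xs %*% pr$W1, 2, pr$b1, "+")
      H <- pmax(A, 0)  # ReLU
      p <- stats::plogis(as.vector(H %*% pr$W2) + pr$b2)
      delta <- (p - y) / n
      gW2 <- as.vector(crossprod(H, delta))
      gb2 <- sum(delta)
      dH <- outer(delta, pr$W2) * (A > 0)
      gW1 <- crossprod(xs, dH)
      gb1 <- colSums(dH)
      c(as.vector(gW1), gb1, gW2, gb2) + decay * w
    } else {
      p <- stats::plogis(as.vector(xs %*% pr$W2) + pr$b2)
      delta <- (p - y) / n
      c(as.vector(crossprod(xs, delta)), sum(delta)) + decay * w
    }
  }
  # rprop+ update
  step <- rep(step0, nw)
  g_prev <- numeric(nw)
  for (it in seq_len(maxit)) {
    g <- grad_fn(w)
    if (max(abs(g)) < threshold) break
    sgn <- g * g_prev
    step <- ifelse(sgn > 0, pmin(step * 1.2, 50),
                   ifelse(sgn < 0, pmax(step * 0.5, 1e-6), step))
    g_eff <- ifelse(sgn < 0, 0, g)  # skip update after a sign flip
    w <- w - sign(g_eff) * step
    g_prev <- ifelse(sgn < 0, 0, g)
  }
  structure(list(w = w, hidden = hidden, lo = lo, rng = rng,
                 unpack = unpack, iterations = it),
            class = "mlp_fit")
}

predict_mlp_prob <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$lo), 2, fit$rng, "/")
  pr <- fit$unpack(fit$w)
  if (fit$hidden > 0) {
    H <- pmax(sweep(xs %*% pr$W1, 2, pr$b1, "+"), 0)
    stats::plogis(as.vector(H %*% pr$W2) + pr$b2)
  } else {
    stats::plogis(as.vector(xs %*% pr$W2) + pr$b2)
  }
}

## ---- k nearest neighbours (FNN-backed) ----

fit_knn <- function(x, y, k = 20L) {
  structure(list(x = x, y = y, k = min(as.integer(k), nrow(x))),
            class = "knn_fit")
}

predict_knn_prob <- function(fit, x) {
  cl <- FNN::knn(fit$x, x, factor(fit$y, levels = c(0, 1)), k = fit$k,
                 prob = TRUE)
  win <- attr(cl, "prob")
  ifelse(cl == "1", win, 1 - win)
}

## ---- shared helpers ----

# stratified fold assignment for k-fold cross-validation
cv_folds_assign <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}
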