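## ---- in-repo learners -------------------------------------------------

## Holte's 1R with equal-width fallback discretization for numeric features
oner_fit <- function(x, y, n_bins = 10) {
  levels_y <- levels(y)
  majority <- levels_y[which.max(table(y))]
  best <- NULL
  for (f in names(x)) {
    v <- x[[f]]
    rng <- range(v)
    if (!is.finite(diff(rng)) || diff(rng) == 0) next
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bins <- findInterval(v, breaks, all.inside = TRUE)
    rule <- vapply(seq_len(n_bins), function(b) {
      yy <- y[bins == b]
      if (length(yy) == 0) majority else levels_y[which.max(table(yy))]
    }, character(1))
    ## Laplace-smoothed class distribution per bin, for ranking scores
    prob <- t(vapply(seq_len(n_bins), function(b) {
      cnt <- table(y[bins == b])[levels_y]
      cnt[is.na(cnt)] <- 0
      (cnt + 1) / sum(cnt + 1)
    }, numeric(length(levels_y))))
    colnames(prob) <- levels_y
    acc <- mean(rule[bins] == as.character(y))
    if (is.null(best) || acc > best$acc) {
      best <- list(feature = f, breaks = breaks, rule = rule, prob = prob,
                   acc = acc, levels = levels_y)
    }
  }
  if (is.null(best)) stop("1R: all features are constant", call. = FALSE)
  structure(best, class = "oner")
}

oner_predict <- function(model, x) {
  v <- x[[model$feature]]
  bins <- findInterval(v, model$breaks, all.inside = TRUE)
  bins <- pmin(pmax(bins, 1L), nrow(model$prob))
  model$prob[bins, , drop = FALSE]
}

## k nearest neighbours with min-max scaled Euclidean distance and
## per-class vote fractions (needed for ranking metrics)
knn_fit <- function(x, y, k) {
  x <- as.matrix(x)
  rng <- apply(x, 2, range)
  scale_col <- function(m) {
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    sweep(sweep(m, 2, rng[1, ]), 2, span, "/")
  }
  structure(list(x = scale_col(x), y = y, k = k, rng = rng,
                 scale_col = scale_col, levels = levels(y)),
            class = "rresp_knn")
}

knn_predict <- function(model, x) {
  xq <- model$scale_col(as.matrix(x))
  k <- min(model$k, nrow(model$x))
  out <- matrix(0, nrow(xq), length(model$levels),
                dimnames = list(NULL, model$levels))
  for (i in seq_len(nrow(xq))) {
    d2 <- colSums((t(model$x) - xq[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    votes <- table(model$y[nn])[model$levels]
    votes[is.na(votes)] <- 0
    out[i, ] <- votes / k
  }
  out
}

## SAMME AdaBoost over rpart trees
ada_fit <- function(x, y, n_trees = 10, maxdepth = 3) {
  n <- nrow(x)
  k <- nlevels(y)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  dat <- data.frame(x, .y = y, check.names = FALSE)
  for (m in seq_len(n_trees)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       cp = 0.001,
                                                       xval = 0))
    pred <- predict(fit, dat, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / k) break            # worse than chance: stop
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break                # perfect separation
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas, levels = levels(y)),
            class = "rresp_ada")
}

ada_predict <- function(model, x) {
  dat <- data.frame(x, check.names = FALSE)
  score <- matrix(0, nrow(dat), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (m in seq_along(model$trees)) {
    cl <- as.character(predict(model$trees[[m]], dat, type = "class"))
    for (lv in model$levels) {
      score[cl == lv, lv] <- score[cl == lv, lv] + model$alphas[m]
    }
  }
  sweep(score, 1, pmax(rowSums(score), 1e-12), "/")
}

## bagged rpart trees, averaged class probabilities
bag_fit <- function(x, y, n_trees = 10) {
  dat <- data.frame(x, .y = y, check.names = FALSE)
  n <- nrow(dat)
  trees <- purrr::map(seq_len(n_trees), function(m) {
    idx <- sample.int(n, n, replace = TRUE)
    rpart::rpart(.y ~ ., data = dat[idx, ], method = "class",
                 control = rpart::rpart.control(xval = 0))
  })
  structure(list(trees = trees, levels = levels(y)), class = "rresp_bag")
}

bag_predict <- function(model, x) {
  dat <- data.frame(x, check.names = FALSE)
  probs <- purrr::map(model$trees, function(tr) {
    p <- predict(tr, dat, type = "prob")
    p[, model$levels, drop = FALSE]
  })
  Reduce(`+`, probs) / length(probs)
}

## ---- roster -----------------------------------------------------------

#' The 12-classifier roster
#'
#' Returns the algorithm specifications evaluated by [run_cv()]: 1R,
#' decision tree (DT), 1- and 5-nearest neighbours, naive Bayes (NB), an
#' RBF-kernel machine (RBF), a linear-kernel support vector machine (SVM),
#' multinomial logistic regression (LR), AdaBoost (AdaB), Bagging (Bag) and
#' random forest (RF) each combining 10 decision trees, and a single
#' hidden-layer multilayer perceptron (MLP). Hyperparameters are the
#' documented ecosystem defaults of the underlying implementations, not a
#' bit-for-bit reproduction of any other toolkit.
#'
#' Each specification is a list with `id`, `fit(x, y)` and
#' `predict(model, x)`; `predict` returns a matrix of per-class scores with
#' one column per class level.
#'
#' @param ids Subset of algorithm ids to return; default all 12.
#' @return Named list of algorithm specifications.
#' @export
#' @examples
#' names(rresp_algorithms())
rresp_algorithms <- function(ids = NULL) {
  specs <- list(
    `1R` = list(
      fit = function(x, y) oner_fit(x, y),
      predict = oner_predict
    ),
    DT = list(
      fit = function(x, y) {
        rpart::rpart(.y ~ ., data = data.frame(x, .y = y, check.names = FALSE),
                     method = "class",
                     control = rpart::rpart.control(xval = 0))
      },
      predict = function(m, x) {
        predict(m, data.frame(x, check.names = FALSE), type = "prob")
      }
    ),
    `1NN` = list(
      fit = function(x, y) knn_fit(x, y, k = 1),
      predict = knn_predict
    ),
    `5NN` = list(
      fit = function(x, y) knn_fit(x, y, k = 5),
      predict = knn_predict
    ),
    NB = list(
      fit = function(x, y) e1071::naiveBayes(x, y),
      predict = function(m, x) predict(m, x, type = "raw")
    ),
    RBF = list(
      fit = function(x, y) {
        e1071::svm(x, y, kernel = "radial", probability = TRUE, scale = TRUE)
      },
      predict = function(m, x) {
        p <- attr(predict(m, x, probability = TRUE), "probabilities")
        p[, levels(m$fitted), drop = FALSE]
      }
    ),
    SVM = list(
      fit = function(x, y) {
        e1071::svm(x, y, kernel = "linear", probability = TRUE, scale = TRUE)
      },
      predict = function(m, x) {
        p <- attr(predict(m, x, probability = TRUE), "probabilities")
        p[, levels(m$fitted), drop = FALSE]
      }
    ),
    LR = list(
      fit = function(x, y) {
        nnet::multinom(.y ~ ., data = data.frame(x, .y = y, check.names = FALSE),
                       trace = FALSE, maxit = 200, MaxNWts = 5000)
      },
      predict = function(m, x) {
        p <- predict(m, data.frame(x, check.names = FALSE), type = "probs")
        if (is.null(dim(p))) {  # two-class: vector of P(second level)
          p <- cbind(1 - p, p)
          colnames(p) <- m$lev
        }
        p[, m$lev, drop = FALSE]
      }
    ),
    AdaB = list(
      fit = function(x, y) ada_fit(x, y, n_trees = 10),
      predict = ada_predict
    ),
    Bag = list(
      fit = function(x, y) bag_fit(x, y, n_trees = 10),
      predict = bag_predict
    ),
    RF = list(
      fit = function(x, y) randomForest::randomForest(x, y, ntree = 10),
      predict = function(m, x) {
        predict(m, x, type = "prob")[, levels(m$y), drop = FALSE]
      }
    ),
    MLP = list(
      fit = function(x, y) {
        xm <- as.matrix(x)
        ctr <- apply(xm, 2, min)
        span <- apply(xm, 2, max) - ctr
        span[span == 0] <- 1
        xs <- sweep(sweep(xm, 2, ctr), 2, span, "/")
        net <- nnet::nnet(xs, nnet::class.ind(y), size = 8, softmax = TRUE,
                          decay = 0.01, maxit = 150, trace = FALSE,
                          MaxNWts = 5000)
        structure(list(net = net, ctr = ctr, span = span, levels = levels(y)),
                  class = "rresp_mlp")
      },
      predict = function(m, x) {
        xs <- sweep(sweep(as.matrix(x), 2, m$ctr), 2, m$span, "/")
        p <- predict(m$net, xs)
        colnames(p) <- m$levels
        p
      }
    )
  )
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(specs))
    if (length(missing)) {
      stop("unknown algorithm id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    specs <- specs[ids]
  }
  purrr::imap(specs, function(s, id) {
    s$id <- id
    s
  })
}
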