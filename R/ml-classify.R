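# rpart user-written splitting method implementing gain-ratio and
# accuracy split criteria (rpart itself ships information gain and Gini).
# y arrives as 0/1; eval's label is the class-1 proportion of the node.
.rpart_custom_method <- function(criterion) {
  itemp <- function(y, offset, parms = NULL, wt = NULL) {
    list(y = y, parms = parms, numresp = 1, numy = 1,
         summary = function(yval, dev, wt, ylevel, digits) {
           paste("p(class2) =", format(signif(yval, digits)))
         })
  }
  etemp <- function(y, wt, parms) {
    p <- stats::weighted.mean(y, wt)
    list(label = p, deviance = sum(wt) * .entropy2(p))
  }
  stemp <- function(y, wt, x, parms, continuous) {
    n <- length(y)
    tot1 <- sum(y)
    ones_l <- cumsum(y)[-n]
    n_l <- seq_len(n - 1)
    ones_r <- tot1 - ones_l
    n_r <- n - n_l
    Hp <- .entropy2(tot1 / n)
    ig <- Hp - (n_l / n) * .entropy2(ones_l / n_l) -
      (n_r / n) * .entropy2(ones_r / n_r)
    if (criterion == "gainratio") {
      si <- .entropy2(n_l / n)
      good <- ifelse(si > 0, ig / si, 0)
    } else {  # accuracy: gain in correctly classified fraction
      corr_parent <- max(tot1, n - tot1)
      corr_split <- pmax(ones_l, n_l - ones_l) + pmax(ones_r, n_r - ones_r)
      good <- (corr_split - corr_parent) / n
    }
    good[x[-n] == x[-1]] <- 0
    list(goodness = pmax(good, 0), direction = rep(-1, n - 1))
  }
  list(eval = etemp, split = stemp, init = itemp)
}

.stratified_split <- function(y, train_frac, seed) {
  set.seed(seed)
  train <- logical(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    n_tr <- round(train_frac * length(idx))
    train[sample(idx, n_tr)] <- TRUE
  }
  if (any(table(y[train]) == 0) || any(table(y[!train]) == 0)) {
    stop("a class is absent from a partition; use a different seed or split fraction",
         call. = FALSE)
  }
  train
}

#' Train and evaluate a classifier on codon features
#'
#' Splits the feature table into stratified train and test partitions
#' (default 70/30), fits the requested model on the training rows and
#' reports percentage accuracy on the held-out rows only. Supported
#' models: k-nearest-neighbour (\code{"knn"}, default k = 10), naive
#' Bayes (\code{"nb"}), logistic regression (\code{"logreg"}), a single
#' decision tree (\code{"tree"}), random forest (\code{"forest"}), and the
#' optional margin classifier (\code{"svm"}) and feed-forward network
#' (\code{"ann"}) backends. Trees accept four split criteria: information
#' gain and Gini index (native \pkg{rpart} splits) plus gain ratio and
#' accuracy (user-written split functions); the random forest uses Gini.
#'
#' @param table A \code{feature_table}.
#' @param model Model name.
#' @param criterion Tree split criterion (tree model only).
#' @param k Number of neighbours for k-NN (default 10).
#' @param train_frac Training fraction of the stratified split
#'   (default 0.7).
#' @param seed Seed controlling the split and any stochastic fit.
#' @param ntree Number of trees for the random forest (default 500).
#' @param ... Further arguments passed to the underlying fitting function.
#' @return Object of class \code{classifier_report}: list with
#'   \code{model}, \code{hyperparameters}, \code{split} (fraction, seed,
#'   partition sizes), \code{accuracy} (percent, held-out), and the
#'   \code{fitted} model object (for tree: reusable with
#'   \code{\link{extract_rules}}).
#' @export
train_eval <- function(table,
                       model = c("knn", "nb", "logreg", "tree", "forest",
                                 "svm", "ann"),
                       criterion = c("infogain", "gainratio", "gini",
                                     "accuracy"),
                       k = 10, train_frac = 0.7, seed = 1L, ntree = 500,
                       ...) {
  model <- match.arg(model)
  criterion <- match.arg(criterion)
  stopifnot(inherits(table, "feature_table"))
  feats <- setdiff(names(table), "label")
  y <- droplevels(table$label)
  if (nlevels(y) != 2) stop("label must have exactly 2 classes", call. = FALSE)
  train <- .stratified_split(y, train_frac, seed)
  x <- table[, feats, drop = FALSE]
  # syntactic column names for formula interfaces; codon names are already
  # syntactic (letters only) but keep this robust for plug-in features
  names(x) <- make.names(names(x))
  feats <- names(x)
  dtr <- data.frame(x[train, , drop = FALSE], label = y[train],
                    check.names = FALSE)
  dte <- data.frame(x[!train, , drop = FALSE], label = y[!train],
                    check.names = FALSE)
  set.seed(seed)
  hyper <- list()
  fitted <- NULL
  pred <- switch(model,
    knn = {
      hyper <- list(k = k)
      class::knn(dtr[feats], dte[feats], dtr$label, k = k, ...)
    },
    nb = {
      fitted <- e1071::naiveBayes(label ~ ., data = dtr, ...)
      predict(fitted, dte)
    },
    logreg = {
      fitted <- suppressWarnings(
        stats::glm(label ~ ., data = dtr, family = stats::binomial(), ...)
      )
      p <- suppressWarnings(predict(fitted, dte, type = "response"))
      factor(levels(y)[(p >= 0.5) + 1], levels = levels(y))
    },
    tree = {
      hyper <- list(criterion = criterion)
      fitted <- .fit_tree(dtr, criterion, ...)
      .predict_tree(fitted, dte)
    },
    forest = {
      hyper <- list(criterion = "gini", ntree = ntree)
      if (!criterion %in% c("gini", "infogain")) {
        warning("random forest splits on Gini impurity; 'criterion' ignored",
                call. = FALSE)
      }
      fitted <- randomForest::randomForest(label ~ ., data = dtr,
                                           ntree = ntree, ...)
      predict(fitted, dte)
    },
    svm = {
      fitted <- e1071::svm(label ~ ., data = dtr, ...)
      predict(fitted, dte)
    },
    ann = {
      fitted <- nnet::nnet(label ~ ., data = dtr, size = 10, maxit = 300,
                           decay = 1e-3, trace = FALSE, ...)
      factor(predict(fitted, dte, type = "class"), levels = levels(y))
    }
  )
  acc <- 100 * mean(pred == dte$label)
  structure(
    list(model = model, hyperparameters = hyper,
         split = list(train_frac = train_frac, seed = seed,
                      n_train = nrow(dtr), n_test = nrow(dte)),
         accuracy = acc, fitted = fitted),
    class = "classifier_report"
  )
}

.fit_tree <- function(dtr, criterion, ...) {
  if (criterion %in% c("infogain", "gini")) {
    split <- if (criterion == "infogain") "information" else "gini"
    fit <- rpart::rpart(label ~ ., data = dtr, method = "class",
                        parms = list(split = split), ...)
  } else {
    d <- dtr
    d$label01 <- as.integer(d$label == levels(d$label)[2])
    d$label <- NULL
    fit <- rpart::rpart(label01 ~ ., data = d,
                        method = .rpart_custom_method(criterion), ...)
  }
  attr(fit, "codonpref_levels") <- levels(dtr$label)
  attr(fit, "codonpref_criterion") <- criterion
  fit
}

.predict_tree <- function(fit, newdata) {
  lv <- attr(fit, "codonpref_levels")
  if (identical(fit$method, "class") ||
      (is.character(fit$method) && fit$method == "class")) {
    predict(fit, newdata, type = "class")
  } else {
    p <- predict(fit, newdata)
    factor(lv[(p >= 0.5) + 1], levels = lv)
  }
}

#' @export
print.classifier_report <- function(x, ...) {
  hp <- if (length(x$hyperparameters) > 0) {
    paste0(" (", paste(names(x$hyperparameters), unlist(x$hyperparameters),
                       sep = " = ", collapse = ", "), ")")
  } else ""
  cat(sprintf("<classifier_report> %s%s: %.2f%% accuracy on %d held-out CDS (%d trained, split seed %d)\n",
              x$model, hp, x$accuracy, x$split$n_test, x$split$n_train,
              x$split$seed))
  invisible(x)
}

# map frame rows of an rpart object to their primary split rows
.primary_splits <- function(fit) {
  fr <- fit$frame
  out <- rep(NA_integer_, nrow(fr))
  r <- 0L
  for (i in seq_len(nrow(fr))) {
    if (fr$var[i] != "<leaf>") {
      out[i] <- r + 1L
      r <- r + 1L + fr$ncompete[i] + fr$nsurrogate[i]
    }
  }
  out
}

#' Extract discrimination rules from a fitted decision tree
#'
#' Converts every root-to-leaf path of a fitted \pkg{rpart} tree into an
#' ordered list of threshold conditions on codon percentages plus the
#' leaf's predicted class label. A tree with no split yields an empty rule
#' list with a warning.
#'
#' @param fitted_tree An \pkg{rpart} fit from \code{\link{train_eval}}
#'   (model \code{"tree"}), or any classification \code{rpart} object.
#' @param labels Optional character vector of the two class labels
#'   (taken from the fit when available).
#' @return Object of class \code{decision_rules}: list of rules, each with
#'   \code{conditions} (data.frame: \code{feature}, \code{comparator}
#'   (\code{"<="} or \code{">"}), \code{threshold}) and \code{label}.
#' @export
extract_rules <- function(fitted_tree, labels = NULL) {
  stopifnot(inherits(fitted_tree, "rpart"))
  fr <- fitted_tree$frame
  if (nrow(fr) == 1) {
    warning("tree has a single leaf; no discrimination rules", call. = FALSE)
    return(structure(list(), class = "decision_rules"))
  }
  if (is.null(labels)) labels <- attr(fitted_tree, "codonpref_levels")
  ylv <- attr(fitted_tree, "ylevels")
  node_ids <- as.integer(rownames(fr))
  prim <- .primary_splits(fitted_tree)
  splits <- fitted_tree$splits
  leaf_label <- function(i) {
    if (!is.null(ylv)) {
      ylv[fr$yval[i]]
    } else if (!is.null(labels)) {
      labels[(fr$yval[i] >= 0.5) + 1]
    } else {
      as.character(fr$yval[i])
    }
  }
  rules <- list()
  for (i in which(fr$var == "<leaf>")) {
    node <- node_ids[i]
    path <- integer(0)
    k <- node
    while (k > 1) {
      path <- c(k, path)
      k <- k %/% 2
    }
    conds <- do.call(rbind, lapply(path, function(child) {
      parent <- child %/% 2
      pi <- match(parent, node_ids)
      sp <- splits[prim[pi], , drop = FALSE]
      goes_left <- child %% 2 == 0
      # ncat -1: values < cutpoint go left; ncat +1: values >= cutpoint go left
      left_is_low <- sp[1, "ncat"] < 0
      low_side <- goes_left == left_is_low
      data.frame(feature = rownames(sp),
                 comparator = if (low_side) "<=" else ">",
                 threshold = unname(sp[1, "index"]),
                 stringsAsFactors = FALSE)
    }))
    rules[[length(rules) + 1]] <- list(conditions = conds,
                                       label = leaf_label(i))
  }
  structure(rules, class = "decision_rules")
}

#' Render decision rules as discrimination-rule text
#'
#' One line per rule in the style
#' \code{If \% GAC (>8.861] and \% AGG (<=1.441] -> Label} (the comparator
#' is printed as a Unicode \dQuote{less-than-or-equal} sign; thresholds
#' carry three decimals).
#'
#' @param rules A \code{decision_rules} object.
#' @param collapse Separator between rules (default newline; use
#'   \code{"; "} for the single-line table style).
#' @return Character string.
#' @export
render_rules <- function(rules, collapse = "\n") {
  stopifnot(inherits(rules, "decision_rules"))
  if (length(rules) == 0) return("")
  lines <- vapply(rules, function(r) {
    conds <- vapply(seq_len(nrow(r$conditions)), function(j) {
      cmp <- if (r$conditions$comparator[j] == "<=") "≤" else ">"
      sprintf("%% %s (%s%.3f]", r$conditions$feature[j], cmp,
              r$conditions$threshold[j])
    }, character(1))
    sprintf("If %s → %s", paste(conds, collapse = " and "), r$label)
  }, character(1))
  paste(lines, collapse = collapse)
}

#' @export
print.decision_rules <- function(x, ...) {
  cat(sprintf("<decision_rules> %d rule(s)\n", length(x)))
  if (length(x) > 0) cat(render_rules(x), "\n")
  invisible(x)
}
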