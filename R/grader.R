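## Grading: stratified 70/30 split, per-type two-layer sigmoid network
## trained by full-batch backpropagation on min-max scaled grade targets,
## and the evaluation stack (confusion matrix, precision/recall/F1,
## accuracy, one-vs-rest ROC/AUC).

#' Valid grade range of a cataract type
#'
#' Grade 0 is the normal (transparent) lens on every scale; nuclear scales
#' run to 6, cortical and posterior subcapsular to 5.
#'
#' @param type one of `"NO"`, `"NC"`, `"C"`, `"P"`.
#' @return integer length-2 vector `c(min_grade, max_grade)`.
#' @export
grade_range <- function(type) {
  switch(match.arg(type, c("NO", "NC", "C", "P")),
         NO = c(0L, 6L), NC = c(0L, 6L), C = c(0L, 5L), P = c(0L, 5L))
}

#' Grade label
#'
#' @param type cataract type, one of `"NO"`, `"NC"`, `"C"`, `"P"`.
#' @param grade integer grade within the type's LOCS III range.
#' @return an object of class `grade_label`.
#' @export
grade_label <- function(type, grade) {
  rng <- grade_range(type)
  grade <- as.integer(grade)
  if (is.na(grade) || grade < rng[1] || grade > rng[2])
    stop(sprintf("grade %s outside the %s range %d..%d",
                 grade, type, rng[1], rng[2]))
  structure(list(cataract_type = type, grade = grade), class = "grade_label")
}

#' @export
print.grade_label <- function(x, ...) {
  cat(sprintf("<grade %s%d>\n", x$cataract_type, x$grade))
  invisible(x)
}

#' Train/test split
#'
#' Disjoint, exhaustive 70/30 partition (by default) of `n` items,
#' deterministic given `seed`. Unstratified, the training set has exactly
#' `round(ratio * n)` items. Stratified, per-class training counts are
#' assigned by largest remainder so that class proportions are preserved
#' within one item and the total still equals `round(ratio * n)`; a
#' singleton class goes to the training set with a warning.
#'
#' @param n number of items, at least 2.
#' @param ratio training fraction.
#' @param seed integer seed.
#' @param stratify_by optional vector of length `n` of class labels.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(n, ratio = 0.7, seed = 1L, stratify_by = NULL) {
  stopifnot(n >= 2, ratio > 0, ratio < 1)
  n_train <- round(ratio * n)
  if (is.null(stratify_by)) {
    train <- with_seed(seed, sort(sample.int(n, n_train)))
  } else {
    stopifnot(length(stratify_by) == n)
    f <- factor(stratify_by)
    counts <- table(f)
    if (any(counts == 1))
      warning("singleton class(es) assigned to the training set: ",
              paste(names(counts)[counts == 1], collapse = ", "))
    base <- floor(ratio * counts)
    rem <- ratio * counts - base
    extra <- n_train - sum(base)
    take <- as.vector(base)
    if (extra > 0) {
      ord <- order(-rem, seq_along(rem))
      take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
    } else if (extra < 0) {
      ord <- order(rem, seq_along(rem))
      k <- 0
      for (i in ord) {
        if (k == -extra) break
        if (take[i] > 0) { take[i] <- take[i] - 1; k <- k + 1 }
      }
    }
    take <- pmax(take, ifelse(counts == 1, 1, 0))   # singletons train
    train <- with_seed(seed, {
      picked <- integer(0)
      for (i in seq_along(levels(f))) {
        members <- which(f == levels(f)[i])
        k <- min(take[i], length(members))
        picked <- c(picked, if (k > 0) sample(members, k))
      }
      sort(picked)
    })
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

ann_forward <- function(model, X) {
  H <- sigmoid(sweep(X %*% model$W1, 2, model$b1, `+`))
  out <- sigmoid(H %*% model$W2 + model$b2)
  list(hidden = H, output = as.vector(out))
}

scale_features <- function(X, center, scale) {
  sweep(sweep(X, 2, center, `-`), 2, scale, `/`)
}

#' Train a shallow sigmoid grading network
#'
#' Two-layer network (one sigmoid hidden layer, one sigmoid output unit)
#' trained by full-batch gradient descent on the mean squared error against
#' grade targets scaled to `(grade - min) / (max - min)`. Features are
#' standardized internally. Deterministic given `seed`.
#'
#' @param features numeric matrix (rows = images, columns = features) or
#'   data frame.
#' @param labels integer grades, all of one cataract type.
#' @param type cataract type, fixes the output scaling range.
#' @param hidden_dim hidden layer width.
#' @param epochs gradient-descent iterations.
#' @param learning_rate step size.
#' @param seed integer seed for the weight initialization.
#' @return an object of class `cataract_ann`.
#' @export
train_ann <- function(features, labels, type, hidden_dim = 8L,
                      epochs = 20000L, learning_rate = 1, seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  bad <- which(!apply(is.finite(X), 1, all))
  if (length(bad))
    stop("non-finite feature value in row(s): ", paste(head(bad, 5),
                                                       collapse = ", "))
  stopifnot(nrow(X) == length(labels))
  rng <- grade_range(type)
  y <- (as.numeric(labels) - rng[1]) / (rng[2] - rng[1])
  stopifnot(all(y >= 0), all(y <= 1))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale_features(X, ctr, scl)
  p <- ncol(X); Hd <- as.integer(hidden_dim); n <- nrow(X)
  init <- with_seed(seed, list(
    W1 = matrix(runif(p * Hd, -0.5, 0.5), p, Hd),
    b1 = runif(Hd, -0.5, 0.5),
    W2 = matrix(runif(Hd, -0.5, 0.5), Hd, 1),
    b2 = runif(1, -0.5, 0.5)))
  W1 <- init$W1; b1 <- init$b1; W2 <- init$W2; b2 <- init$b2
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    H <- sigmoid(sweep(Xs %*% W1, 2, b1, `+`))
    out <- as.vector(sigmoid(H %*% W2 + b2))
    err <- out - y
    loss <- mean(err^2)
    dout <- 2 * err * out * (1 - out) / n          # dL/dz2
    gW2 <- t(H) %*% dout
    gb2 <- sum(dout)
    dH <- (dout %*% t(W2)) * H * (1 - H)           # dL/dz1
    gW1 <- t(Xs) %*% dH
    gb1 <- colSums(dH)
    W1 <- W1 - learning_rate * gW1
    b1 <- b1 - learning_rate * gb1
    W2 <- W2 - learning_rate * gW2
    b2 <- b2 - learning_rate * gb2
  }
  structure(list(type = type, input_dim = p, hidden_dim = Hd,
                 W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 x_center = ctr, x_scale = scl,
                 min_grade = rng[1], max_grade = rng[2],
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 learning_rate = learning_rate, final_loss = loss,
                 feature_names = colnames(X)),
            class = "cataract_ann")
}

#' @export
print.cataract_ann <- function(x, ...) {
  cat(sprintf("Shallow sigmoid grading network (%s, grades %d..%d)\n",
              x$type, x$min_grade, x$max_grade))
  cat(sprintf("  %d -> %d -> 1 units; %d epochs, lr %g, seed %d\n",
              x$input_dim, x$hidden_dim, x$epochs, x$learning_rate, x$seed))
  cat(sprintf("  final training MSE (scaled targets): %.5f\n", x$final_loss))
  invisible(x)
}

#' @export
summary.cataract_ann <- function(object, ...) {
  print(object)
  cat("  features:", paste(object$feature_names, collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.cataract_ann <- function(object, ...) {
  list(W1 = object$W1, b1 = object$b1, W2 = object$W2, b2 = object$b2)
}

#' Predict grades
#'
#' The raw sigmoid output in `(0, 1)` is rescaled to
#' `[min_grade, max_grade]`, rounded to the nearest integer and clipped to
#' the valid range. The raw score is kept for ROC analysis.
#'
#' @param model a [train_ann()] fit.
#' @param features numeric matrix/data frame with `model$input_dim` columns
#'   (a single feature vector is also accepted).
#' @return data frame with columns `grade` (integer) and `raw` (the sigmoid
#'   output).
#' @export
predict_grade <- function(model, features) {
  stopifnot(inherits(model, "cataract_ann"))
  X <- if (is.null(dim(features))) matrix(features, nrow = 1)
       else as.matrix(features)
  if (ncol(X) != model$input_dim)
    stop(sprintf("feature length %d does not match input_dim %d",
                 ncol(X), model$input_dim))
  raw <- ann_forward(model, scale_features(X, model$x_center, model$x_scale))$output
  g <- round(model$min_grade + raw * (model$max_grade - model$min_grade))
  g <- pmin(pmax(g, model$min_grade), model$max_grade)
  data.frame(grade = as.integer(g), raw = raw)
}

#' @export
predict.cataract_ann <- function(object, newdata,
                                 type = c("grade", "raw"), ...) {
  type <- match.arg(type)
  pr <- predict_grade(object, newdata)
  if (type == "grade") pr$grade else pr$raw
}

#' ROC curve and AUC for a binary score
#'
#' Trapezoidal area under the ROC curve of `scores` against binary
#' `positive` labels (higher score = more positive). Invariant under any
#' strictly increasing transform of the scores.
#'
#' @param scores numeric scores.
#' @param positive logical vector of the same length.
#' @return list with `fpr`, `tpr` (curve points) and `auc`.
#' @export
roc_curve <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(list(fpr = NA, tpr = NA, auc = NA_real_))
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  s <- scores[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- c(diff(s) != 0, TRUE)   # collapse score ties
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Evaluate grading predictions
#'
#' Builds the confusion matrix (rows = true grade, columns = predicted) and
#' the standard per-class metrics: precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` (both 0 when the denominator is 0), F1 (their harmonic
#' mean), one-vs-rest accuracy, and overall accuracy `trace/n`. When raw
#' scores are supplied, per-class one-vs-rest ROC/AUC is computed from the
#' negative distance of the raw score to each class's scaled target, with
#' macro AUC the unweighted mean over classes present in the truth.
#'
#' @param true_grades,predicted_grades integer grade vectors of equal length.
#' @param raw_scores optional raw sigmoid outputs (for ROC/AUC).
#' @param classes grade values the report covers; defaults to the full range
#'   of `type`, or to the observed grades when `type` is missing.
#' @param type optional cataract type fixing `classes` and the score scaling.
#' @return an object of class `eval_report`.
#' @export
evaluate_grading <- function(true_grades, predicted_grades, raw_scores = NULL,
                             classes = NULL, type = NULL) {
  if (length(true_grades) != length(predicted_grades))
    stop("true and predicted grade vectors differ in length")
  n <- length(true_grades)
  stopifnot(n >= 1)
  if (is.null(classes))
    classes <- if (!is.null(type)) {
      rng <- grade_range(type); rng[1]:rng[2]
    } else sort(unique(c(true_grades, predicted_grades)))
  tf <- factor(true_grades, levels = classes)
  pf <- factor(predicted_grades, levels = classes)
  cm <- table(true = tf, predicted = pf)
  acc <- sum(diag(cm)) / n
  k <- length(classes)
  prec <- rec <- f1 <- cls_acc <- auc <- numeric(k)
  roc <- vector("list", k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    tn <- n - tp - fp - fn
    prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[i] <- if (prec[i] + rec[i] == 0) 0 else
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    cls_acc[i] <- (tp + tn) / n
    if (!is.null(raw_scores)) {
      target <- (classes[i] - min(classes)) / max(1, diff(range(classes)))
      rc <- roc_curve(-abs(raw_scores - target), true_grades == classes[i])
      roc[[i]] <- rc
      auc[i] <- rc$auc
    } else auc[i] <- NA_real_
  }
  present <- tabulate(tf, k) > 0
  macro_auc <- if (any(!is.na(auc[present]))) mean(auc[present], na.rm = TRUE)
               else NA_real_
  structure(list(confusion = cm, classes = classes, n = n,
                 accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 class_accuracy = cls_acc, auc = auc, roc = roc,
                 macro_auc = macro_auc, type = type),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  lab <- if (!is.null(x$type)) paste0(x$type, x$classes) else x$classes
  cat(sprintf("Grading evaluation (n = %d)\n", x$n))
  tab <- data.frame(Class = lab,
                    Recall = round(100 * x$recall, 2),
                    Precision = round(100 * x$precision, 2),
                    `F1.score` = round(100 * x$f1, 2),
                    Accuracy = round(100 * x$class_accuracy, 2),
                    AUC = round(100 * x$auc, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("Overall accuracy: %.2f%%   macro one-vs-rest AUC: %s\n",
              100 * x$accuracy,
              if (is.na(x$macro_auc)) "NA"
              else sprintf("%.2f%%", 100 * x$macro_auc)))
  invisible(x)
}

#' @export
plot.eval_report <- function(x, ...) {
  ok <- which(vapply(x$roc, function(r) !is.null(r) && !anyNA(r$auc),
                     logical(1)))
  if (!length(ok)) stop("no ROC curves in this report (no raw scores)")
  plot(0:1, 0:1, type = "l", lty = 3, col = "gray",
       xlab = "False positive rate", ylab = "True positive rate",
       main = "One-vs-rest ROC", ...)
  for (i in ok)
    lines(x$roc[[i]]$fpr, x$roc[[i]]$tpr, col = i)
  legend("bottomright", bty = "n", col = ok, lty = 1,
         legend = sprintf("%s%d (AUC %.2f)",
                          if (!is.null(x$type)) x$type else "",
                          x$classes[ok], x$auc[ok]))
  invisible(x)
}

#' Serialize a grading network to JSON
#'
#' @param model a `cataract_ann`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_ann <- function(model, path) {
  stopifnot(inherits(model, "cataract_ann"))
  obj <- unclass(model)
  obj$W1 <- as.vector(obj$W1); obj$W2 <- as.vector(obj$W2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a grading network from JSON
#'
#' @param path file written by [write_ann()].
#' @return a `cataract_ann`.
#' @export
read_ann <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W1 <- matrix(obj$W1, obj$input_dim, obj$hidden_dim)
  obj$W2 <- matrix(obj$W2, obj$hidden_dim, 1)
  obj$feature_names <- unlist(obj$feature_names)
  structure(obj, class = "cataract_ann")
}
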