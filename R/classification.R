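#' Nonparametric sensitivity index A-prime
#'
#' Standard nonparametric approximation from hit rate H and false-alarm
#' rate F: for `H >= F`,
#' `A' = 0.5 + (H - F)(1 + H - F) / (4 H (1 - F))`, and the symmetric
#' complement `1 - A'(F, H)` otherwise. Degenerate corners (`H = F`,
#' including 0/0 and 1/1) return 0.5; `H = 1, F = 0` returns 1.
#'
#' @param hit_rate,false_alarm_rate probabilities in `[0, 1]` (vectorized).
#' @return numeric in `[0, 1]`.
#' @export
a_prime <- function(hit_rate, false_alarm_rate) {
  stopifnot(all(hit_rate >= 0 & hit_rate <= 1),
            all(false_alarm_rate >= 0 & false_alarm_rate <= 1))
  one <- function(h, f) {
    if (h == f) return(0.5)
    if (h > f) 0.5 + (h - f) * (1 + h - f) / (4 * h * (1 - f))
    else 1 - (0.5 + (f - h) * (1 + f - h) / (4 * f * (1 - h)))
  }
  mapply(one, hit_rate, false_alarm_rate)
}

#' One-sided binomial test against chance
#'
#' Exact upper-tail probability of observing at least `correct` successes
#' in `total` trials at the chance rate (the observed count is included in
#' the tail).
#'
#' @param correct,total counts, `0 <= correct <= total`.
#' @param chance success probability in (0, 1).
#' @return p-value.
#' @export
binomial_vs_chance <- function(correct, total, chance) {
  stopifnot(correct >= 0, correct <= total, chance > 0, chance < 1)
  stats::pbinom(correct - 1, total, chance, lower.tail = FALSE)
}

# Standardize-and-fit a linear maximum-margin classifier (LIBSVM via
# e1071: linear kernel, C = 1, one-vs-one voting). Features are z-scored
# with the training fold's mean/SD (constant columns left unscaled).
fit_linear_svm <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  Xs <- scale(X, center = mu, scale = sd)
  model <- e1071::svm(Xs, y, kernel = "linear", cost = 1, scale = FALSE)
  list(model = model, mu = mu, sd = sd, levels = levels(y))
}

# Predict labels and per-class scores (sums of signed one-vs-one decision
# values) for new rows.
predict_linear_svm <- function(fit, Xnew) {
  Xs <- scale(as.matrix(Xnew), center = fit$mu, scale = fit$sd)
  pr <- stats::predict(fit$model, Xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  scores <- matrix(0, nrow = nrow(Xs), ncol = length(fit$levels),
                   dimnames = list(NULL, fit$levels))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    scores[, pair[1]] <- scores[, pair[1]] + dv[, cn]
    scores[, pair[2]] <- scores[, pair[2]] - dv[, cn]
  }
  list(pred = as.character(pr), scores = scores)
}

# Rank-based (Mann-Whitney) AUC of score for a binary truth vector.
rank_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix from true and predicted labels
#'
#' @param true,predicted label vectors of equal length.
#' @param levels category order (default: sorted union).
#' @return K x K integer matrix, rows = true, columns = predicted.
#' @export
confusion_matrix <- function(true, predicted, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(true, predicted)))
  table(true = factor(true, levels), predicted = factor(predicted, levels))
}

# Full evaluation report from truth, predictions and per-class scores.
build_report <- function(true, pred, scores, chance) {
  lev <- colnames(scores)
  conf <- confusion_matrix(true, pred, lev)
  n <- length(true)
  acc <- sum(diag(conf)) / n
  row_n <- rowSums(conf)
  per_cat <- ifelse(row_n > 0, diag(conf) / row_n, NA_real_)
  hits <- per_cat
  fa <- vapply(seq_along(lev), function(k) {
    neg <- n - row_n[k]
    if (neg == 0) return(NA_real_)
    (sum(conf[, k]) - conf[k, k]) / neg
  }, numeric(1))
  ap <- rep(NA_real_, length(lev))
  ok <- !is.na(hits) & !is.na(fa)
  ap[ok] <- a_prime(hits[ok], fa[ok])
  auc <- vapply(lev, function(k) rank_auc(scores[, k], true == k), numeric(1))
  structure(
    list(confusion = conf,
         accuracy = acc,
         per_category_accuracy = stats::setNames(per_cat, lev),
         auc = mean(auc, na.rm = TRUE),
         auc_per_category = auc,
         a_prime_per_category = stats::setNames(ap, lev),
         a_prime_mean = mean(ap, na.rm = TRUE),
         chance = chance,
         binomial_p = binomial_vs_chance(sum(diag(conf)), n, chance),
         n = n),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n=%d accuracy=%.3f (chance %.3f, p=%.3g) AUC=%.3f A'=%.3f\n",
              x$n, x$accuracy, x$chance, x$binomial_p, x$auc, x$a_prime_mean))
  invisible(x)
}

#' Leave-one-out linear classification
#'
#' Each scene is held out in turn and predicted by a linear
#' maximum-margin classifier (LIBSVM linear kernel, C = 1, one-vs-one
#' voting; prediction ties resolved by category order) trained on all
#' remaining scenes, with features z-scored on each training fold.
#' Deterministic given the input order.
#'
#' @param features numeric matrix or data frame, scenes x d.
#' @param labels category label per scene (basic- or superordinate-level;
#'   chance defaults to 1 / number of distinct labels).
#' @param chance chance probability for the binomial test.
#' @return an `evaluation_report`: confusion matrix (rows = true),
#'   overall and per-category accuracy, macro one-vs-rest AUC from
#'   decision-value scores, per-category A', and the exact binomial p
#'   against chance.
#' @export
loo_evaluate <- function(features, labels, chance = NULL) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels), ncol(X) >= 1)
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("need >= 2 categories")
  singletons <- names(which(table(labels) == 1))
  if (length(singletons))
    warning("categories with a single scene can never be predicted as themselves in leave-one-out: ",
            paste(singletons, collapse = ", "))
  if (is.null(chance)) chance <- 1 / length(lev)
  n <- nrow(X)
  pred <- character(n)
  scores <- matrix(NA_real_, n, length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(n)) {
    fit <- fit_linear_svm(X[-i, , drop = FALSE], labels[-i])
    out <- predict_linear_svm(fit, X[i, , drop = FALSE])
    pred[i] <- out$pred
    scores[i, colnames(out$scores)] <- out$scores
  }
  scores[is.na(scores)] <- -Inf
  build_report(labels, pred, scores, chance)
}

#' Train on one database's features, test on another
#'
#' Fits the linear classifier once on the training features and predicts
#' every test scene, evaluating cross-database transfer. The featurizer
#' must map both databases into one feature space: `"ensemble"` uses the
#' seven ensemble columns; `"bow"` uses instance counts over the union of
#' the two vocabularies; alternatively pass a
#' `function(db, vocabulary)` returning a scenes x d matrix, called with
#' the vocabulary union.
#'
#' @param train,test [scene_database()] objects sharing a taxonomy.
#' @param featurizer `"ensemble"`, `"bow"`, or a function (see above).
#' @param level `"basic"` or `"superordinate"` labels.
#' @return an `evaluation_report` on the test database.
#' @export
cross_database <- function(train, test, featurizer = c("ensemble", "bow"),
                           level = c("basic", "superordinate")) {
  level <- match.arg(level)
  vocab_union <- sort(union(train$vocabulary, test$vocabulary))
  feat_fun <- if (is.function(featurizer)) {
    featurizer
  } else {
    switch(match.arg(featurizer),
      ensemble = function(db, vocabulary) {
        f <- ensemble_feature_matrix(db)
        as.matrix(f[, c("density", "unique_count", "mean_size",
                        "size_variance", "com_x", "com_y", "spacing_cv")])
      },
      bow = function(db, vocabulary) {
        m <- count_matrix(db)
        full <- matrix(0L, nrow(m), length(vocabulary),
                       dimnames = list(rownames(m), vocabulary))
        full[, colnames(m)] <- m
        full
      })
  }
  lab <- function(db) {
    if (level == "basic") scene_categories(db) else scene_superordinates(db)
  }
  y_tr <- lab(train); y_te <- lab(test)
  missing <- setdiff(unique(y_te), unique(y_tr))
  if (length(missing))
    warning("test categories absent from training data are never predicted: ",
            paste(missing, collapse = ", "))
  fit <- fit_linear_svm(feat_fun(train, vocab_union), y_tr)
  out <- predict_linear_svm(fit, feat_fun(test, vocab_union))
  lev <- sort(unique(c(y_te, fit$levels)))
  scores <- matrix(-Inf, length(y_te), length(lev), dimnames = list(NULL, lev))
  scores[, colnames(out$scores)] <- out$scores
  build_report(y_te, out$pred, scores, 1 / length(lev))
}

#' Classification accuracy with k-object feature subsets
#'
#' Leave-one-out bag-of-words accuracy using only `k` vocabulary objects,
#' chosen either at random (without replacement, `reps` seeded draws) or
#' as the `k` objects with the highest overall mutual information with
#' the K-way category variable. With `k` equal to the vocabulary size,
#' both modes reduce to the full bag-of-words accuracy.
#'
#' @param db a [scene_database()].
#' @param k number of objects (<= vocabulary size).
#' @param mode `"random"` or `"top-MI"`.
#' @param reps random draws (ignored for `"top-MI"`).
#' @param seed RNG seed for the draws.
#' @param level `"basic"` or `"superordinate"`.
#' @return list with `mean` accuracy, `ci` (2.5/97.5 percentiles over
#'   draws), `accuracies`, and the `objects` of the last draw.
#' @export
feature_subset_experiment <- function(db, k, mode = c("random", "top-MI"),
                                      reps = 10, seed = 1L,
                                      level = c("basic", "superordinate")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  cm <- count_matrix(db)
  stopifnot(k >= 1, k <= ncol(cm))
  labels <- if (level == "basic") scene_categories(db) else scene_superordinates(db)
  pick_list <- if (mode == "top-MI") {
    list(utils::head(mutual_information(db)$overall$object, k))
  } else {
    set.seed(seed)
    lapply(seq_len(reps), function(i) sample(colnames(cm), k))
  }
  accs <- vapply(pick_list, function(objs)
    loo_evaluate(cm[, objs, drop = FALSE], labels)$accuracy, numeric(1))
  list(mean = mean(accs),
       ci = if (length(accs) > 1) stats::quantile(accs, c(0.025, 0.975), names = FALSE)
            else c(accs, accs),
       accuracies = accs,
       objects = pick_list[[length(pick_list)]])
}

#' Accuracy as a function of the number of ensemble statistics
#'
#' Leave-one-out accuracy averaged over every combination of ensemble
#' statistics of each size (the center of mass counts as one statistic
#' with two columns), with a least-squares line over sizes summarizing
#' how performance grows with ensemble dimensionality.
#'
#' @param db a [scene_database()].
#' @param sizes subset sizes to evaluate (default 1:6).
#' @param level `"basic"` or `"superordinate"`.
#' @return list with `by_size` (data frame `size`, `mean_accuracy`,
#'   `n_subsets`), `slope` (accuracy per added statistic), `r_squared`,
#'   and `per_subset` (accuracy of every combination).
#' @export
ensemble_combination_sweep <- function(db, sizes = 1:6,
                                       level = c("basic", "superordinate")) {
  level <- match.arg(level)
  feats <- ensemble_feature_matrix(db)
  labels <- if (level == "basic") feats$category
            else unname(db$taxonomy[feats$category])
  groups <- ensemble_feature_groups()
  per_subset <- list()
  for (size in sizes) {
    combos <- utils::combn(names(groups), size, simplify = FALSE)
    for (cmb in combos) {
      cols <- unlist(groups[cmb], use.names = FALSE)
      acc <- loo_evaluate(feats[, cols, drop = FALSE], labels)$accuracy
      per_subset[[length(per_subset) + 1L]] <- data.frame(
        size = size, subset = paste(cmb, collapse = "+"), accuracy = acc,
        stringsAsFactors = FALSE)
    }
  }
  per_subset <- do.call(rbind, per_subset)
  by_size <- do.call(rbind, lapply(split(per_subset, per_subset$size), function(d)
    data.frame(size = d$size[1], mean_accuracy = mean(d$accuracy),
               n_subsets = nrow(d))))
  rownames(by_size) <- NULL
  fit <- stats::lm(mean_accuracy ~ size, data = by_size)
  list(by_size = by_size,
       slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       per_subset = per_subset)
}

#' Correlation between two classifiers' error patterns
#'
#' Pearson correlation over the off-diagonal cells of two confusion
#' matrices after normalizing each row to proportions. At the
#' superordinate level the matrices are first aggregated by the taxonomy.
#'
#' @param a,b K x K confusion matrices with identical category order.
#' @param level `"basic"` or `"superordinate"`.
#' @param taxonomy required for `level = "superordinate"`: named map from
#'   the matrices' categories to superordinates.
#' @return Pearson r; `NA` (with a warning) when either off-diagonal
#'   pattern has zero variance.
#' @export
confusion_correlation <- function(a, b, level = c("basic", "superordinate"),
                                  taxonomy = NULL) {
  level <- match.arg(level)
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)), all(rownames(a) == rownames(b)))
  if (level == "superordinate") {
    if (is.null(taxonomy)) stop("taxonomy required at superordinate level")
    agg <- function(m) {
      g <- factor(unname(taxonomy[rownames(m)]))
      t(rowsum(t(rowsum(m, g)), g)) # rows = true group, cols = predicted
    }
    a <- agg(a); b <- agg(b)
  }
  norm <- function(m) {
    rs <- rowSums(m)
    m / ifelse(rs > 0, rs, 1)
  }
  off <- !diag(TRUE, nrow(a))
  va <- norm(a)[off]; vb <- norm(b)[off]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero variance in off-diagonal errors; correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb)
}
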