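test_that("A-prime reproduces its closed-form limits and formula", {
  expect_equal(a_prime(0.7, 0.7), 0.5)
  expect_equal(a_prime(0, 0), 0.5)
  expect_equal(a_prime(1, 1), 0.5)
  expect_equal(a_prime(1, 0), 1.0)
  set.seed(73)
  for (rep in 1:20) {
    h <- runif(1); f <- runif(1, 0, h)
    expect_equal(a_prime(h, f),
                 0.5 + (h - f) * (1 + h - f) / (4 * h * (1 - f)))
    expect_gte(a_prime(h, f), 0.5)
    expect_lte(a_prime(h, f), 1)
    # symmetric complement below the diagonal
    expect_equal(a_prime(f, h), 1 - a_prime(h, f))
  }
})

test_that("the binomial test gives exact upper-tail probabilities", {
  # all correct at chance 1/16: p = (1/16)^20
  expect_equal(binomial_vs_chance(20, 20, 1 / 16), (1 / 16)^20)
  # observing exactly the expected count leaves roughly half the mass above
  p <- binomial_vs_chance(40, 160, 0.25)
  expect_gt(p, 0.4)
  expect_lt(p, 0.6)
  # random cases against direct pmf summation
  set.seed(79)
  for (rep in 1:20) {
    total <- sample(5:60, 1)
    correct <- sample(0:total, 1)
    ch <- runif(1, 0.05, 0.9)
    expect_equal(binomial_vs_chance(correct, total, ch),
                 sum(dbinom(correct:total, total, ch)))
  }
})

test_that("linearly separable classes are classified perfectly, permuted labels at chance", {
  set.seed(83)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  y <- rep(c("p", "q"), each = 20)
  rep1 <- loo_evaluate(X, y)
  expect_equal(rep1$accuracy, 1.0)
  expect_equal(rep1$auc, 1.0)
  expect_equal(sum(rep1$confusion), 40)
  expect_equal(unname(rowSums(rep1$confusion)), c(20, 20))

  # 16 balanced classes with shuffled labels: accuracy near 1/16
  set.seed(89)
  X16 <- matrix(rnorm(160 * 4), 160)
  y16 <- sample(rep(paste0("c", 1:16), each = 10))
  rep2 <- loo_evaluate(X16, y16)
  expect_equal(rep2$chance, 1 / 16)
  expect_lt(rep2$accuracy, 1 / 16 + 4 * sqrt((1 / 16) * (15 / 16) / 160))
})

test_that("leave-one-out predictions equal an explicit fold-by-fold refit", {
  set.seed(97)
  n <- 40
  X <- matrix(rnorm(n * 3), n)
  X[, 1] <- X[, 1] + rep(c(0, 1.5, 3, 4.5), each = 10)
  y <- rep(c("a", "b", "c", "d"), each = 10)
  got <- loo_evaluate(X, y)
  ref_pred <- character(n)
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    mu <- colMeans(tr); s <- apply(tr, 2, sd); s[s == 0] <- 1
    fit <- e1071::svm(scale(tr, mu, s), factor(y[-i]), kernel = "linear",
                      cost = 1, scale = FALSE)
    ref_pred[i] <- as.character(predict(fit, scale(X[i, , drop = FALSE], mu, s)))
  }
  ref_conf <- confusion_matrix(y, ref_pred, sort(unique(y)))
  expect_equal(unclass(got$confusion), unclass(ref_conf))
  expect_equal(got$accuracy, mean(ref_pred == y))
})

test_that("LOO accuracy does not exceed resubstitution on the same data", {
  db <- default_database(scenes_per_category = 5, seed = 3)
  feats <- ensemble_feature_matrix(db)
  X <- as.matrix(feats[, 3:9])
  y <- feats$category
  loo <- loo_evaluate(X, y)
  resub <- cross_database(db, db, "ensemble")
  expect_gte(resub$accuracy, loo$accuracy)
})

test_that("cross-database transfer generalizes across independent draws", {
  train <- default_database(scenes_per_category = 8, seed = 101)
  test <- default_database(scenes_per_category = 8, seed = 202)
  rep_b <- cross_database(train, test, "bow")
  expect_gt(rep_b$accuracy, 3 * rep_b$chance)
  rep_e <- cross_database(train, test, "ensemble")
  expect_gt(rep_e$accuracy, rep_e$chance)
  # disjoint vocabularies carry no shared information: chance-level transfer
  a <- make_label_db(list(p = replicate(6, c("a1", "a2"), simplify = FALSE),
                          q = replicate(6, c("a3"), simplify = FALSE)),
                     taxonomy = c(p = "indoor", q = "natural"))
  b <- make_label_db(list(p = replicate(6, c("b1"), simplify = FALSE),
                          q = replicate(6, c("b2", "b3"), simplify = FALSE)),
                     taxonomy = c(p = "indoor", q = "natural"))
  rep_d <- cross_database(a, b, "bow")
  expect_lte(rep_d$accuracy, 0.6)
})

test_that("singleton and missing categories are warned about", {
  X <- matrix(rnorm(10), 5)
  expect_warning(loo_evaluate(X, c("a", "a", "b", "b", "c")), "single scene")
  a <- make_label_db(list(p = replicate(5, "u", simplify = FALSE),
                          q = replicate(5, "v", simplify = FALSE)),
                     taxonomy = c(p = "indoor", q = "natural", r = "urban"))
  b <- make_label_db(list(p = replicate(3, "u", simplify = FALSE),
                          r = replicate(3, "w", simplify = FALSE)),
                     taxonomy = c(p = "indoor", q = "natural", r = "urban"))
  expect_warning(cross_database(a, b, "bow"), "never predicted")
})

test_that("feature subsets: full vocabulary equals full bag-of-words, seeded and ranked", {
  db <- default_database(scenes_per_category = 4, seed = 7)
  cm <- count_matrix(db)
  full <- loo_evaluate(cm, scene_categories(db))$accuracy
  V <- ncol(cm)
  expect_equal(feature_subset_experiment(db, V, "top-MI")$mean, full)
  expect_equal(feature_subset_experiment(db, V, "random", reps = 2, seed = 1)$mean,
               full)
  r1 <- feature_subset_experiment(db, 8, "random", reps = 3, seed = 11)
  r2 <- feature_subset_experiment(db, 8, "random", reps = 3, seed = 11)
  expect_identical(r1$accuracies, r2$accuracies)
})

test_that("top-MI subsets dominate random subsets when exclusive objects carry the signal", {
  # one exclusive object per category amid a large pool of uninformative
  # noise labels: the informative subset is unambiguous, random subsets
  # mostly pick noise
  set.seed(107)
  spec <- list()
  for (ci in 1:8) {
    spec[[paste0("cat", ci)]] <- lapply(1:6, function(i) {
      noise <- paste0("noise", 1:40)[runif(40) < 0.3]
      c(paste0("excl", ci), noise, "filler")
    })
  }
  db <- make_label_db(spec)
  for (k in c(2, 4, 8)) {
    top <- feature_subset_experiment(db, k, "top-MI")
    rnd <- feature_subset_experiment(db, k, "random", reps = 4, seed = 13)
    expect_gte(top$mean, rnd$mean)
  }
})

test_that("the ensemble combination sweep matches a least-squares oracle", {
  db <- default_database(scenes_per_category = 4, seed = 19)
  # restrict to 8 categories to keep the sweep small
  keep <- scene_categories(db) %in% names(db$taxonomy)[1:8]
  db8 <- scene_database(db$scenes[keep], db$taxonomy[1:8])
  sweep <- ensemble_combination_sweep(db8, sizes = c(1, 2, 6))
  expect_equal(nrow(sweep$per_subset), 6 + 15 + 1)
  # the single size-6 subset is the full ensemble accuracy
  feats <- ensemble_feature_matrix(db8)
  full <- loo_evaluate(feats[, 3:9], feats$category)$accuracy
  expect_equal(sweep$by_size$mean_accuracy[sweep$by_size$size == 6], full)
  # slope and r^2 equal closed-form least squares on the produced points
  fit <- lm(mean_accuracy ~ size, data = sweep$by_size)
  expect_equal(sweep$slope, unname(coef(fit)[2]))
  expect_equal(sweep$r_squared, summary(fit)$r.squared)
})

test_that("confusion correlation compares off-diagonal error patterns", {
  a <- matrix(c(8, 2, 1,
                1, 9, 3,
                2, 1, 7), 3, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_equal(confusion_correlation(a, a), 1)
  # reversing the error structure flips the sign
  b <- a
  b[1, 2] <- 1; b[1, 3] <- 2
  b[2, 1] <- 3; b[2, 3] <- 1
  b[3, 1] <- 1; b[3, 2] <- 2
  expect_lt(confusion_correlation(a, b), 0)
  # direct Pearson oracle on the normalized off-diagonal cells
  na <- a / rowSums(a); nb <- b / rowSums(b)
  off <- !diag(TRUE, 3)
  expect_equal(confusion_correlation(a, b), cor(na[off], nb[off]))
  # superordinate aggregation by a taxonomy
  tax <- c(x = "indoor", y = "indoor", z = "natural")
  agg_a <- matrix(c(8 + 2 + 1 + 9, 1 + 3, 2 + 1, 7), 2, byrow = TRUE)
  na2 <- agg_a / rowSums(agg_a)
  r_sup <- confusion_correlation(a, a, "superordinate", taxonomy = tax)
  expect_equal(r_sup, 1)
  # zero error variance is flagged
  d <- diag(c(5, 5, 5)); dimnames(d) <- dimnames(a)
  expect_warning(r0 <- confusion_correlation(d, d), "zero variance")
  expect_true(is.na(r0))
})
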