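test_that("count matrix records exact instance counts", {
  db <- make_label_db(list(kitchen = list(c("sky", "tree", "tree"), "stove")))
  m <- count_matrix(db)
  expect_equal(m["kitchen_1", "sky"], 1L)
  expect_equal(m["kitchen_1", "tree"], 2L)
  expect_equal(m["kitchen_2", "stove"], 1L)
  expect_equal(m["kitchen_2", "tree"], 0L)
  # column sums equal a direct scan over scene labels
  db2 <- default_database(scenes_per_category = 2, seed = 23)
  m2 <- count_matrix(db2)
  direct <- table(unlist(lapply(db2$scenes, scene_labels)))
  expect_equal(colSums(m2)[names(direct)], unclass(direct)[names(direct)],
               ignore_attr = TRUE)
})

test_that("object frequency is the fraction of category scenes with the object", {
  db <- make_label_db(list(
    bathroom = list(c("faucet", "sink"), c("faucet"), c("faucet", "towel")),
    coast = list(c("sky"), c("sky", "faucet"))
  ), taxonomy = c(bathroom = "indoor", coast = "natural"))
  freq <- object_frequency(db)
  expect_equal(freq$per_category["faucet", "bathroom"], 1.0)
  expect_equal(freq$per_category["towel", "bathroom"], 1 / 3)
  expect_equal(freq$per_category["faucet", "coast"], 0.5)
  expect_equal(freq$overall$n_scenes[freq$overall$object == "faucet"], 4)
})

test_that("rank-frequency slope is 0 for uniform and -1 for exact Zipf counts", {
  uni <- make_label_db(list(x = list(rep(letters[1:6], each = 3))))
  expect_equal(rank_frequency(uni)$slope, 0)
  # counts 60/r are integers for r = 1..5
  zipf_counts <- 60 / (1:5)
  labs <- rep(paste0("obj", 1:5), zipf_counts)
  zipf <- make_label_db(list(x = list(labs)))
  expect_equal(rank_frequency(zipf)$slope, -1)
})

test_that("diagnosticity is a conditional probability with rows summing to one", {
  db <- make_label_db(list(
    bathroom = list(c("bath mat", "sink"), c("bath mat"), "sink"),
    kitchen = list(c("sink", "stove"), "stove"),
    coast = list("sky", c("sky", "sink"))
  ), taxonomy = c(bathroom = "indoor", kitchen = "indoor", coast = "natural"))
  dt <- diagnosticity(db, min_instances = 0)
  expect_equal(dt$prob["bath mat", "bathroom"], 1.0)
  # sink: 2 bathroom, 1 kitchen, 1 coast of 4 scenes containing it
  expect_equal(dt$prob["sink", ], c(bathroom = 0.5, coast = 0.25, kitchen = 0.25))
  expect_equal(unname(rowSums(dt$prob)), rep(1, nrow(dt$prob)))
  expect_equal(unname(dt$support["sink"]), 4)
  # the min_instances filter marks rare objects as non-reportable
  dt10 <- diagnosticity(db, min_instances = 10)
  expect_false(any(dt10$reportable))
})

test_that("an object spread over k equal categories has diagnosticity 1/k", {
  db <- make_label_db(list(
    a = list(c("wall"), c("wall")), b = list(c("wall"), c("wall")),
    c = list(c("wall"), c("wall")), d = list(c("wall"), c("wall"))
  ))
  dt <- diagnosticity(db, min_instances = 0)
  expect_equal(unname(dt$prob["wall", ]), rep(0.25, 4))
})

test_that("landmark-object diagnosticity selects largest/central deterministically", {
  db1 <- make_label_db(list(only = list(c("a", "b"), c("a"))))
  lm <- landmark_object_diagnosticity(db1, "largest")
  expect_true(all(lm$per_scene$diagnosticity == 1.0)) # single category

  # area tie between "zebra" and "apple": lexicographically smaller wins
  tie <- scene_database(list(
    make_scene("t", "x", c("zebra", "apple"),
               rbind(c(0, 0, 2, 2), c(5, 5, 2, 2)))
  ), c(x = "indoor"))
  expect_equal(landmark_object_diagnosticity(tie, "largest")$per_scene$object,
               "apple")

  # central mode picks the object nearest the image center
  central <- scene_database(list(
    make_scene("c", "x", c("near", "far"),
               rbind(c(4.5, 4.5, 1, 1), c(0, 0, 1, 1)))
  ), c(x = "indoor"))
  expect_equal(landmark_object_diagnosticity(central, "most-central")$per_scene$object,
               "near")

  # mean equals a brute-force per-scene lookup on a synthetic database
  db <- default_database(scenes_per_category = 3, seed = 29)
  lm2 <- landmark_object_diagnosticity(db, "largest")
  dt <- diagnosticity(db, min_instances = 0)
  brute <- vapply(db$scenes, function(s) {
    areas <- vapply(s$objects, function(o) polygon_area(o$polygon), numeric(1))
    labs <- scene_labels(s)
    best <- order(-areas, labs)[1]
    dt$prob[labs[best], s$category]
  }, numeric(1))
  expect_equal(lm2$mean, mean(brute))
})

test_that("specificity counts categories and matches a direct set scan", {
  db <- make_label_db(list(
    a = list(c("wall", "rare")), b = list("wall"), c = list(c("wall", "mid")),
    d = list(c("mid"))
  ))
  sp <- specificity(db)
  expect_equal(sp$n_categories[sp$object == "wall"], 3L)
  expect_equal(sp$n_categories[sp$object == "rare"], 1L)
  expect_equal(sp$n_categories[sp$object == "mid"], 2L)
})

test_that("co-occurrence counts, sparsity and always-together pairs are exact", {
  db <- make_label_db(list(x = list(
    c("fork", "knife"), c("fork", "knife", "plate"), c("plate"), c("cup")
  )))
  co <- cooccurrence(db)
  expect_equal(co$joint["fork", "knife"], 2)
  expect_equal(co$prob["fork", "knife"], 1) # always together
  expect_equal(co$joint["fork", "cup"], 0)
  expect_true(any(co$always_together$object_a == "fork" &
                    co$always_together$object_b == "knife"))
  # brute-force pair enumeration over the presence sets
  sets <- list(c("fork", "knife"), c("fork", "knife", "plate"), "plate", "cup")
  vocab <- colnames(co$joint)
  for (i in seq_along(vocab)) for (j in seq_along(vocab)) {
    expected <- sum(vapply(sets, function(s)
      all(c(vocab[i], vocab[j]) %in% s), logical(1)))
    expect_equal(co$joint[i, j], expected)
  }
  # observed pairings: fork-knife, fork-plate, knife-plate of C(4,2)=6
  expect_equal(co$sparsity, 3 / 6)
})

test_that("frequent group mining equals exhaustive enumeration on small fixtures", {
  db <- make_label_db(list(bath = list(
    c("faucet", "sink", "towel", "mirror"),
    c("faucet", "sink", "towel"),
    c("faucet", "sink", "bath"),
    c("faucet", "towel"),
    c("sink", "towel", "mirror")
  )))
  for (n in 1:4) {
    got <- frequent_groups(db, "bath", n, top_k = 5)
    want <- exhaustive_groups(db, "bath", n, top_k = 5)
    expect_equal(got, want, info = paste("group size", n))
  }
  # n = 1 reduces to the most frequent single object
  expect_equal(frequent_groups(db, "bath", 1, top_k = 1)$group, "faucet")
  # n larger than any scene's unique count: empty result
  expect_equal(nrow(frequent_groups(db, "bath", 5)), 0L)
})

test_that("frequent-group supports are anti-monotone in group size", {
  db <- default_database(scenes_per_category = 5, seed = 37)
  g3 <- frequent_groups(db, "bathroom", 3, top_k = 5)
  g2 <- frequent_groups(db, "bathroom", 2, top_k = 100)
  for (i in seq_len(nrow(g3))) {
    members <- strsplit(g3$group[i], " + ", fixed = TRUE)[[1]]
    for (pair in utils::combn(members, 2, simplify = FALSE)) {
      sup2 <- group_diagnosticity(db, pair)$support
      expect_gte(sup2, g3$support[i])
    }
  }
})

test_that("group diagnosticity is a ratio of joint-presence counts", {
  db <- make_label_db(list(
    bath = list(c("faucet", "sink"), c("faucet", "sink"), "faucet"),
    kitchen = list(c("faucet", "sink"), "stove")
  ), taxonomy = c(bath = "indoor", kitchen = "indoor"))
  gd <- group_diagnosticity(db, c("faucet", "sink"))
  expect_equal(gd$support, 3L)
  expect_equal(gd$prob[["bath"]], 2 / 3)
  expect_equal(gd$prob[["kitchen"]], 1 / 3)
  # group unique to one category
  gd2 <- group_diagnosticity(db, c("stove"))
  expect_equal(gd2$prob[["kitchen"]], 1.0)
  # unseen group is flagged undefined
  gd3 <- group_diagnosticity(db, c("faucet", "stove"))
  expect_equal(gd3$support, 0L)
  expect_true(all(is.na(gd3$prob)))
})

test_that("unique combinations count distinct presence sets", {
  same <- make_label_db(list(x = list(c("a", "b"), c("b", "a", "a"), c("a", "b"))))
  uc <- unique_combinations(same)
  expect_equal(uc$n_unique, 1L)
  expect_false(any(uc$per_scene$is_unique))
  distinct <- make_label_db(list(x = list("a", "b", c("a", "b"))))
  expect_equal(unique_combinations(distinct)$n_unique, 3L)
  db <- default_database(scenes_per_category = 3, seed = 41)
  expect_lte(unique_combinations(db)$n_unique, length(db$scenes))
})

test_that("exact binomial coefficients match closed forms and base R", {
  expect_equal(as.character(combination_count(7, 0)), "1")
  expect_equal(as.character(combination_count(5, 2)), "10")
  expect_equal(as.character(combination_count(30, 15)), "155117520")
  expect_equal(attr(combination_count(30, 15), "numeric"), choose(30, 15))
  expect_error(combination_count(5, 6), "out of range")
  # symmetric and consistent with double arithmetic while it is exact
  expect_equal(as.character(combination_count(617, 6)),
               as.character(combination_count(617, 611)))
  expect_equal(attr(combination_count(617, 6), "numeric"), choose(617, 6))
})

test_that("database entropy reproduces closed-form distributions", {
  expect_equal(database_entropy(stats::setNames(rep(1, 617), paste0("o", 1:617)))$entropy_bits,
               log2(617))
  expect_equal(database_entropy(c(only = 42))$entropy_bits, 0)
  # probabilities (0.5, 0.25, 0.125, 0.125) -> 1.75 bits
  expect_equal(database_entropy(c(a = 4, b = 2, c = 1, d = 1))$entropy_bits, 1.75)
  db <- default_database(scenes_per_category = 2, seed = 43)
  ent <- database_entropy(db)
  expect_lte(ent$entropy_bits, ent$uniform_limit_bits)
})

test_that("binary mutual information matches the joint-entropy oracle", {
  # perfect association with P(S) = 0.5 carries exactly one bit
  db <- make_contingency_db(5, 0, 0, 5)
  mi <- mutual_information(db)
  expect_equal(mi$binary["obj", "S"], 1.0)
  # independence carries zero bits
  db0 <- make_contingency_db(4, 4, 4, 4)
  expect_equal(mutual_information(db0)$binary["obj", "S"], 0)
  # random 2x2 tables against H(S) + H(O) - H(S, O)
  set.seed(47)
  for (rep in 1:50) {
    tb <- sample(0:6, 4, replace = TRUE)
    if (sum(tb[1:2]) == 0 || sum(tb[3:4]) == 0) next # need both categories
    dbr <- make_contingency_db(tb[1], tb[2], tb[3], tb[4])
    got <- mutual_information(dbr)$binary["obj", "S"]
    expect_equal(got, mi_joint_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
})

test_that("K-way mutual information ranks category-exclusive objects first", {
  db <- make_label_db(list(
    a = list(c("xa", "shared"), c("xa", "shared"), c("xa")),
    b = list(c("xb", "shared"), c("xb"), c("xb", "shared")),
    c = list(c("xc", "shared"), c("xc"), c("xc"))
  ))
  mi <- mutual_information(db)
  expect_true(all(mi$binary >= 0))
  top3 <- mi$overall$object[1:3]
  expect_setequal(top3, c("xa", "xb", "xc"))
  expect_equal(mi$overall$mi_bits[mi$overall$object == "shared"],
               utils::tail(mi$overall$mi_bits, 1))
})
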