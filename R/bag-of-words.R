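#' Scene-by-object count matrix
#'
#' The bag-of-words representation: one row per scene, one column per
#' vocabulary label, each cell the number of instances of that object in
#' that scene. Presence is `count > 0`.
#'
#' @param db a [scene_database()].
#' @return integer matrix with scene ids as row names and the (sorted)
#'   vocabulary as column names.
#' @export
count_matrix <- function(db) {
  vocab <- db$vocabulary
  m <- matrix(0L, nrow = length(db$scenes), ncol = length(vocab),
              dimnames = list(vapply(db$scenes, `[[`, character(1), "scene_id"),
                              vocab))
  for (i in seq_along(db$scenes)) {
    tab <- table(scene_labels(db$scenes[[i]]))
    m[i, names(tab)] <- as.integer(tab)
  }
  m
}

#' Binary presence matrix (count > 0)
#' @param db a [scene_database()], or a count matrix.
#' @return integer 0/1 matrix of the same shape as [count_matrix()].
#' @export
presence_matrix <- function(db) {
  m <- if (is.matrix(db)) db else count_matrix(db)
  (m > 0) + 0L
}

# scenes-in-category indicator matrix (scenes x categories)
category_indicator <- function(db) {
  cats <- sort(unique(scene_categories(db)))
  m <- matrix(0L, nrow = length(db$scenes), ncol = length(cats),
              dimnames = list(NULL, cats))
  m[cbind(seq_along(db$scenes), match(scene_categories(db), cats))] <- 1L
  m
}

#' Object frequency per category and overall
#'
#' For every (object, category) pair, the fraction of that category's
#' scenes containing at least one instance of the object; plus, per
#' object, the total number of scenes containing it and the total instance
#' count over the database.
#'
#' @param db a [scene_database()].
#' @return list with `per_category` (matrix objects x categories of
#'   presence fractions) and `overall` (data frame `object`, `n_scenes`,
#'   `n_instances`, sorted by decreasing `n_instances`).
#' @export
object_frequency <- function(db) {
  cm <- count_matrix(db)
  pm <- presence_matrix(cm)
  ind <- category_indicator(db)
  n_cat <- colSums(ind)
  per_cat <- t(t(crossprod(pm, ind)) / n_cat) # objects x categories
  overall <- data.frame(object = colnames(cm),
                        n_scenes = colSums(pm),
                        n_instances = colSums(cm),
                        stringsAsFactors = FALSE, row.names = NULL)
  overall <- overall[order(-overall$n_instances, overall$object), , drop = FALSE]
  rownames(overall) <- NULL
  list(per_category = per_cat, overall = overall)
}

#' Rank-frequency table and Zipf slope
#'
#' Objects ordered by decreasing total instance count; the least-squares
#' slope of log(count) on log(rank) summarizes how Zipf-like the marginal
#' object distribution is (an exact `c / rank` law gives slope -1; a
#' uniform distribution gives 0).
#'
#' @param db a [scene_database()].
#' @param top_ranks fit the slope over the first `top_ranks` ranks only
#'   (`Inf` = all). The heavy head is where the power law is assessed.
#' @return list with `table` (data frame `rank`, `object`, `count`) and
#'   `slope`.
#' @export
rank_frequency <- function(db, top_ranks = Inf) {
  counts <- colSums(count_matrix(db))
  if (length(counts) < 2) stop("need >= 2 distinct objects")
  ord <- order(-counts, names(counts))
  tab <- data.frame(rank = seq_along(ord), object = names(counts)[ord],
                    count = unname(counts[ord]), stringsAsFactors = FALSE)
  fit_tab <- tab[tab$count > 0 & tab$rank <= top_ranks, , drop = FALSE]
  slope <- unname(stats::coef(stats::lm(log(count) ~ log(rank), data = fit_tab))[2])
  list(table = tab, slope = slope)
}

#' Object diagnosticity
#'
#' Diagnosticity of object O for category S is the conditional probability
#' `p(S | O present)`, estimated as the number of scenes of S containing O
#' divided by the number of scenes containing O anywhere. Rows sum to 1
#' over categories. Because rare objects are trivially diagnostic, reports
#' conventionally restrict to objects with at least `min_instances`
#' database instances; the full table is always computed and the filter is
#' carried as metadata.
#'
#' @param db a [scene_database()].
#' @param min_instances reporting filter on total instance count
#'   (default 10).
#' @return list of class `diagnosticity_table`: `prob` (matrix objects x
#'   categories), `support` (scenes containing each object),
#'   `n_instances`, `min_instances`, and `reportable` (logical filter).
#' @export
diagnosticity <- function(db, min_instances = 10) {
  pm <- presence_matrix(db)
  ind <- category_indicator(db)
  joint <- crossprod(pm, ind)          # objects x categories: scenes of S with O
  support <- rowSums(joint)            # scenes containing O
  prob <- joint / support
  n_inst <- colSums(count_matrix(db))
  structure(
    list(prob = prob, support = support,
         n_instances = n_inst[rownames(prob)],
         min_instances = min_instances,
         reportable = n_inst[rownames(prob)] >= min_instances),
    class = "diagnosticity_table"
  )
}

#' Top diagnostic objects for a category
#'
#' @param dt a [diagnosticity()] table.
#' @param category category name.
#' @param k number of objects.
#' @param apply_filter drop objects under the table's `min_instances`
#'   filter (default TRUE).
#' @return data frame `object`, `diagnosticity`, `support`, sorted by
#'   decreasing diagnosticity (ties broken by label).
#' @export
top_diagnostic <- function(dt, category, k = 10, apply_filter = TRUE) {
  v <- dt$prob[, category]
  if (apply_filter) v <- v[dt$reportable]
  ord <- order(-v, names(v))
  head_n <- utils::head(ord, k)
  data.frame(object = names(v)[head_n], diagnosticity = unname(v[head_n]),
             support = unname(dt$support[names(v)[head_n]]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Diagnosticity of a scene's landmark object
#'
#' For every scene, selects one landmark object — the largest by polygon
#' area, or the one whose bounding-box center lies nearest the image
#' center — and reports that object's diagnosticity for the scene's own
#' category (no instance filter). Ties are broken by the lexicographically
#' smaller label, then by object order, for determinism.
#'
#' @param db a [scene_database()].
#' @param mode `"largest"` or `"most-central"`.
#' @return list with `per_scene` (data frame `scene_id`, `category`,
#'   `object`, `diagnosticity`), `mean`, and `ci` (2.5/97.5 percentiles).
#' @export
landmark_object_diagnosticity <- function(db, mode = c("largest", "most-central")) {
  mode <- match.arg(mode)
  dt <- diagnosticity(db, min_instances = 0)
  rows <- lapply(db$scenes, function(s) {
    labels <- scene_labels(s)
    score <- if (mode == "largest") {
      vapply(s$objects, function(o) polygon_area(o$polygon), numeric(1))
    } else {
      -vapply(s$objects, function(o) {
        ctr <- object_bbox_center(o$polygon)
        sqrt((ctr[1] - s$width / 2)^2 + (ctr[2] - s$height / 2)^2)
      }, numeric(1))
    }
    best <- order(-score, labels)[1]
    data.frame(scene_id = s$scene_id, category = s$category,
               object = labels[best],
               diagnosticity = dt$prob[labels[best], s$category],
               stringsAsFactors = FALSE)
  })
  per_scene <- do.call(rbind, rows)
  list(per_scene = per_scene, mean = mean(per_scene$diagnosticity),
       ci = stats::quantile(per_scene$diagnosticity, c(0.025, 0.975), names = FALSE))
}

#' Scene-object specificity
#'
#' The number of basic-level categories in which each object is found at
#' least once.
#'
#' @param db a [scene_database()].
#' @return data frame `object`, `n_categories` (integer in
#'   `[1, #categories]`), plus a `histogram` attribute (`table` over
#'   `n_categories`).
#' @export
specificity <- function(db) {
  dt <- diagnosticity(db, min_instances = 0)
  n_cat <- rowSums(dt$prob > 0)
  out <- data.frame(object = names(n_cat), n_categories = as.integer(n_cat),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "histogram") <- table(out$n_categories)
  out
}

#' Object co-occurrence structure
#'
#' Symmetric joint-presence counts over all scene pairs of objects, the
#' fraction of possible pairings observed at least once, and a conditional
#' co-occurrence probability defined as
#' `joint-presence scenes / scenes containing either object` (so 1 means
#' the two objects are always found together).
#'
#' @param db a [scene_database()].
#' @return list with `joint` (objects x objects counts; the diagonal holds
#'   per-object scene counts), `prob` (Jaccard-style conditional
#'   probability, `NA` where neither object occurs), `sparsity` (observed
#'   fraction of off-diagonal pairings) and `always_together` (data frame
#'   of object pairs with probability 1).
#' @export
cooccurrence <- function(db) {
  pm <- presence_matrix(db)
  joint <- crossprod(pm)                       # V x V
  n <- diag(joint)
  either <- outer(n, n, `+`) - joint
  prob <- ifelse(either > 0, joint / either, NA_real_)
  v <- ncol(pm)
  off <- joint[upper.tri(joint)]
  sparsity <- if (v >= 2) mean(off > 0) else NA_real_
  idx <- which(upper.tri(joint) & !is.na(prob) & prob == 1 & joint > 0, arr.ind = TRUE)
  always <- data.frame(object_a = rownames(joint)[idx[, 1]],
                       object_b = colnames(joint)[idx[, 2]],
                       n_joint = joint[idx], stringsAsFactors = FALSE)
  list(joint = joint, prob = prob, sparsity = sparsity,
       always_together = always[order(always$object_a, always$object_b), ,
                                drop = FALSE])
}

# Support of each candidate itemset (list of character vectors) in a
# presence matrix restricted to the relevant scenes.
itemset_support <- function(pm, sets) {
  vapply(sets, function(s) sum(rowSums(pm[, s, drop = FALSE]) == length(s)),
         integer(1))
}

#' Most frequent object groups of size n in a category
#'
#' Exact top-k frequent itemset mining over the presence sets of one
#' category's scenes, by levelwise (apriori) candidate generation with
#' support pruning: a size-n group can only be frequent if all its
#' size-(n-1) subsets are. The support threshold starts near the top of
#' the support range and is lowered until at least `top_k` size-n groups
#' are found (or it reaches 1), so the returned top-k is exact. Ties are
#' broken by lexicographic set order.
#'
#' @param db a [scene_database()].
#' @param category basic-level category.
#' @param n group size (1..5 typical).
#' @param top_k number of groups to return.
#' @return data frame `group` (labels joined by `" + "`), `support`
#'   (scene count), `frequency` (support / category scene count); empty if
#'   no scene has `n` distinct objects.
#' @export
frequent_groups <- function(db, category, n, top_k = 10) {
  stopifnot(n >= 1)
  keep <- scene_categories(db) == category
  if (!any(keep)) stop("no scenes in category ", category)
  pm <- presence_matrix(db)[keep, , drop = FALSE]
  pm <- pm[, colSums(pm) > 0, drop = FALSE]
  n_scenes <- nrow(pm)

  mine <- function(min_support) {
    items <- sort(colnames(pm)[colSums(pm) >= min_support])
    level <- lapply(items, identity)
    k <- 1L
    while (k < n && length(level)) {
      keys <- vapply(level, function(s) paste(s[-length(s)], collapse = "\r"),
                     character(1))
      cands <- list()
      for (key in unique(keys)) {
        grp <- level[keys == key]
        if (length(grp) < 2) next
        tails <- vapply(grp, function(s) s[length(s)], character(1))
        ord <- order(tails)
        for (a in seq_along(ord)[-length(ord)]) for (b in seq((a + 1), length(ord))) {
          cands[[length(cands) + 1L]] <- c(grp[[ord[a]]], tails[ord[b]])
        }
      }
      if (length(cands)) {
        prev_keys <- vapply(level, paste, character(1), collapse = "\r")
        ok <- vapply(cands, function(s) {
          all(vapply(seq_along(s), function(i)
            paste(s[-i], collapse = "\r") %in% prev_keys, logical(1)))
        }, logical(1))
        cands <- cands[ok]
      }
      if (!length(cands)) return(list())
      sup <- itemset_support(pm, cands)
      level <- cands[sup >= min_support]
      k <- k + 1L
    }
    level
  }

  thr <- max(1L, floor(n_scenes / 2))
  repeat {
    sets <- mine(thr)
    if (length(sets) >= top_k || thr == 1L) break
    thr <- max(1L, floor(thr / 2))
  }
  if (!length(sets)) {
    return(data.frame(group = character(), support = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  sup <- itemset_support(pm, sets)
  key <- vapply(sets, paste, character(1), collapse = " + ")
  ord <- order(-sup, key)
  out <- data.frame(group = key[ord], support = sup[ord],
                    frequency = sup[ord] / n_scenes,
                    stringsAsFactors = FALSE, row.names = NULL)
  utils::head(out, top_k)
}

#' Diagnosticity of an object group
#'
#' `p(category | all group members present)`: the fraction of scenes
#' containing the full group that belong to each category. Undefined
#' (all-`NA`, with `support = 0`) when no scene contains the group.
#'
#' @param db a [scene_database()].
#' @param group non-empty character vector of object labels.
#' @return list with `prob` (named vector over categories) and `support`.
#' @export
group_diagnosticity <- function(db, group) {
  stopifnot(length(group) >= 1)
  pm <- presence_matrix(db)
  group_known <- intersect(group, colnames(pm))
  cats <- sort(unique(scene_categories(db)))
  if (length(group_known) < length(group)) {
    return(list(prob = stats::setNames(rep(NA_real_, length(cats)), cats),
                support = 0L))
  }
  has <- rowSums(pm[, group, drop = FALSE]) == length(group)
  support <- sum(has)
  if (support == 0) {
    return(list(prob = stats::setNames(rep(NA_real_, length(cats)), cats),
                support = 0L))
  }
  tab <- table(factor(scene_categories(db)[has], levels = cats))
  list(prob = stats::setNames(as.numeric(tab) / support, cats),
       support = as.integer(support))
}

#' Unique object combinations
#'
#' Number of distinct object-presence sets over the database, and per
#' superordinate (and category) the fraction of scenes whose combination
#' is shared with no other scene in the database.
#'
#' @param db a [scene_database()].
#' @return list with `n_unique` (distinct combinations), `per_scene`
#'   (data frame `scene_id`, `category`, `is_unique`), `by_superordinate`
#'   and `by_category` (fractions of scenes with an unshared combination).
#' @export
unique_combinations <- function(db) {
  keys <- vapply(db$scenes, function(s)
    paste(sort(unique(scene_labels(s))), collapse = "\r"), character(1))
  tab <- table(keys)
  is_unique <- tab[keys] == 1
  cats <- scene_categories(db)
  sups <- scene_superordinates(db)
  list(
    n_unique = length(tab),
    per_scene = data.frame(
      scene_id = vapply(db$scenes, `[[`, character(1), "scene_id"),
      category = cats, is_unique = as.vector(is_unique),
      stringsAsFactors = FALSE),
    by_superordinate = tapply(as.vector(is_unique), sups, mean),
    by_category = tapply(as.vector(is_unique), cats, mean)
  )
}

# --- exact big-integer binomial coefficients -------------------------------
# Digits little-endian in base 1e4; only multiply/divide by small integers
# are needed for the multiplicative C(n, k) recurrence, which stays exact
# because each partial product C(m, i) is an integer.

bigint_mul_small <- function(d, m) {
  carry <- 0
  out <- numeric(0)
  for (x in d) {
    v <- x * m + carry
    out <- c(out, v %% 1e4)
    carry <- v %/% 1e4
  }
  while (carry > 0) {
    out <- c(out, carry %% 1e4)
    carry <- carry %/% 1e4
  }
  out
}

bigint_div_small <- function(d, m) {
  rem <- 0
  out <- numeric(length(d))
  for (i in rev(seq_along(d))) {
    v <- rem * 1e4 + d[i]
    out[i] <- v %/% m
    rem <- v %% m
  }
  if (rem != 0) stop("non-exact big-integer division")
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

bigint_to_string <- function(d) {
  paste0(d[length(d)],
         paste(sprintf("%04d", rev(d[-length(d)])), collapse = ""))
}

#' Exact binomial coefficient
#'
#' `C(n, k)` as an exact arbitrary-precision integer (decimal string),
#' computed with the multiplicative recurrence under exact big-integer
#' arithmetic. Quantifies combinatorial limits such as the number of
#' possible k-object combinations from a vocabulary.
#'
#' @param vocabulary_size n (>= 0).
#' @param k 0 <= k <= n.
#' @return character scalar of decimal digits, with a `numeric` attribute
#'   holding the double approximation.
#' @examples
#' combination_count(5, 2)      # "10"
#' combination_count(617, 6)    # ~ 7.5e13
#' @export
combination_count <- function(vocabulary_size, k) {
  n <- vocabulary_size
  if (k < 0 || k > n) stop("k out of range")
  k <- min(k, n - k)
  d <- 1
  if (k > 0) {
    for (i in seq_len(k)) {
      d <- bigint_mul_small(d, n - k + i)
      d <- bigint_div_small(d, i)
    }
  }
  s <- bigint_to_string(d)
  attr(s, "numeric") <- as.numeric(s)
  s
}

plogp2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Database object entropy
#'
#' Shannon entropy in bits per object of the marginal object distribution,
#' `H = -sum p(o) log2 p(o)` with `p(o)` the instance count divided by the
#' total instance count. The uniform limit `log2(V)` (attained iff all
#' objects are equally frequent) is returned alongside.
#'
#' @param db a [scene_database()], or a named vector of instance counts.
#' @return list with `entropy_bits`, `uniform_limit_bits`,
#'   `vocabulary_size`, `n_instances`.
#' @export
database_entropy <- function(db) {
  counts <- if (inherits(db, "scene_database")) colSums(count_matrix(db)) else db
  counts <- counts[counts > 0]
  if (!length(counts) || sum(counts) == 0) stop("empty database")
  p <- counts / sum(counts)
  list(entropy_bits = -sum(plogp2(p)),
       uniform_limit_bits = log2(length(counts)),
       vocabulary_size = length(counts),
       n_instances = sum(counts))
}

#' Mutual information between object presence and scene category
#'
#' For every (object, category) pair, the mutual information in bits
#' between binary presence `O` and binary category membership `S`,
#' computed as `I(S, O) = H(S) - H(S | O)` expanded over the four cells of
#' the presence-by-membership table (with the convention `0 log 0 = 0`).
#' Also ranks objects by their mutual information with the full K-way
#' category variable, `I(O; C) = H(C) - H(C | O)` — the ranking used to
#' pick the overall most informative objects.
#'
#' @param db a [scene_database()].
#' @return list of class `mi_table`: `binary` (matrix objects x
#'   categories, bits), `binary_sum` (row sums), `overall` (data frame
#'   `object`, `mi_bits` against the K-way category variable, sorted
#'   decreasing with lexicographic tie-break).
#' @export
mutual_information <- function(db) {
  pm <- presence_matrix(db)
  ind <- category_indicator(db)
  total <- nrow(pm)
  joint <- crossprod(pm, ind)      # objects x categories: |S & O|
  n_o <- colSums(pm)               # scenes containing each object
  n_s <- colSums(ind)              # scenes per category

  p_o <- n_o / total
  p_s <- n_s / total
  # binary I(S, O) = H(S) - P(O) H(S|O=1) - P(~O) H(S|O=0), per pair
  p_s_mat <- matrix(p_s, nrow = length(n_o), ncol = length(n_s), byrow = TRUE)
  h_s <- -(plogp2(p_s_mat) + plogp2(1 - p_s_mat))
  p_s_given_o <- sweep(joint, 1, n_o, `/`)                 # |S&O| / |O|
  p_s_given_o[n_o == 0, ] <- 0
  p_s_given_no <- sweep(sweep(joint, 2, n_s, `-`) * -1, 1, total - n_o, `/`)
  p_s_given_no[total - n_o == 0, ] <- 0
  h_s_given_o <- -(plogp2(p_s_given_o) + plogp2(1 - p_s_given_o))
  h_s_given_no <- -(plogp2(p_s_given_no) + plogp2(1 - p_s_given_no))
  mi <- h_s - p_o * h_s_given_o - (1 - p_o) * h_s_given_no
  mi[mi < 0 & mi > -1e-12] <- 0    # clamp float negatives at independence
  dimnames(mi) <- dimnames(joint)

  # K-way I(O; C) = H(C) - P(O) H(C|O=1) - P(~O) H(C|O=0)
  h_c <- -sum(plogp2(p_s))
  h_c_o <- -rowSums(plogp2(p_s_given_o))
  h_c_no <- -rowSums(plogp2(p_s_given_no))
  kway <- h_c - p_o * h_c_o - (1 - p_o) * h_c_no
  kway[kway < 0 & kway > -1e-12] <- 0
  overall <- data.frame(object = names(kway), mi_bits = unname(kway),
                        stringsAsFactors = FALSE)
  overall <- overall[order(-overall$mi_bits, overall$object), , drop = FALSE]
  rownames(overall) <- NULL
  structure(list(binary = mi, binary_sum = rowSums(mi), overall = overall),
            class = "mi_table")
}
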