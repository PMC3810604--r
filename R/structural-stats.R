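#' Position variance of an object
#'
#' Dispersion of an object's normalized bounding-box centers across all
#' its instances: `var(x / width) + var(y / height)` (sample variances).
#' Low values mark position-specific, often boundary, objects; high
#' values mark objects found throughout the image plane.
#'
#' @param db a [scene_database()].
#' @param object object label; `NULL` computes the variance for every
#'   object.
#' @param category restrict to instances within one basic-level category.
#' @return for a single object, a numeric scalar (`NA` with fewer than 2
#'   instances); otherwise a data frame `object`, `n_instances`,
#'   `position_variance` sorted by increasing variance.
#' @export
position_variance <- function(db, object = NULL, category = NULL) {
  scenes <- db$scenes
  if (!is.null(category)) scenes <- scenes[scene_categories(db) == category]
  pos <- list()
  for (s in scenes) {
    for (obj in s$objects) {
      ctr <- object_bbox_center(obj$polygon)
      pos[[length(pos) + 1L]] <- data.frame(
        object = obj$label, x = ctr[1] / s$width, y = ctr[2] / s$height,
        stringsAsFactors = FALSE)
    }
  }
  pos <- do.call(rbind, pos)
  one <- function(lab) {
    sub <- pos[pos$object == lab, , drop = FALSE]
    if (nrow(sub) < 2) return(NA_real_)
    stats::var(sub$x) + stats::var(sub$y)
  }
  if (!is.null(object)) return(one(object))
  labs <- sort(unique(pos$object))
  out <- data.frame(object = labs,
                    n_instances = as.integer(table(pos$object)[labs]),
                    position_variance = vapply(labs, one, numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$position_variance), , drop = FALSE]
}

# Per-scene occupancy of one object on the normalized grid: the union of
# the object's instance masks in that scene (logical grid x grid matrix),
# or the per-instance masks when union = FALSE.
scene_object_masks <- function(scene, object, grid, union = TRUE) {
  masks <- lapply(scene$objects[scene_labels(scene) == object], function(o)
    polygon_raster_mask(o$polygon, scene$width, scene$height, grid, grid))
  if (!union) return(masks)
  Reduce(`|`, masks, matrix(FALSE, grid, grid))
}

#' Occupancy map of an object
#'
#' Each instance's polygon is rasterized onto a common normalized
#' `grid x grid` raster (cell centers, even-odd rule, image coordinates
#' scaled to the unit square) and the masks are summed, showing where the
#' object tends to appear regardless of image size.
#'
#' @param db a [scene_database()].
#' @param object object label.
#' @param grid raster resolution per side (default 64).
#' @return list of class `occupancy_map`: `grid` (matrix of counts, rows =
#'   y from the top), `object`, `n_instances`.
#' @export
occupancy_map <- function(db, object, grid = 64) {
  acc <- matrix(0, grid, grid)
  n <- 0L
  for (s in db$scenes) {
    for (m in scene_object_masks(s, object, grid, union = FALSE)) {
      acc <- acc + m
      n <- n + 1L
    }
  }
  if (n == 0) stop("object not present: ", object)
  structure(list(grid = acc, object = object, n_instances = n),
            class = "occupancy_map")
}

# Welch two-sample t statistic and p-value per column of X between rows
# g == levels[1] and g == levels[2] (unequal variances, Satterthwaite
# df — the groups here are typically unbalanced). Columns occupied by
# fewer than `min_occupied` rows are not tested (p = 1): near-empty cells
# have too little information for the t approximation and would inflate
# the family-wise error. Returns list(t, p, diff, df).
cellwise_t <- function(X, g, min_occupied = 5) {
  lev <- if (is.factor(g)) levels(g) else unique(g)
  a <- X[g == lev[1], , drop = FALSE]
  b <- X[g == lev[2], , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- colSums(sweep(a, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(b, 2, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  se <- sqrt(se2)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  t <- ifelse(se > 0, (m1 - m2) / se, 0)
  p <- 2 * stats::pt(-abs(t), df = df)
  p[se == 0] <- 1
  p[colSums(X > 0) < min_occupied] <- 1
  list(t = t, p = p, diff = m1 - m2, df = df)
}

# Exact conditional (Fisher) two-sided p-value per column of a binary
# occupancy matrix: per cell, the occupied counts in the two groups form
# a 2x2 table and the hypergeometric tail gives an exact p (two-sided as
# twice the smaller tail, capped at 1). Exactness keeps the Bonferroni
# threshold honest where the binary cells are sparse and the groups
# unbalanced, which breaks the t approximation far in the tail.
cellwise_fisher <- function(X, g) {
  lev <- if (is.factor(g)) levels(g) else unique(g)
  occ <- X > 0
  n1 <- sum(g == lev[1]); n2 <- sum(g == lev[2])
  k1 <- colSums(occ[g == lev[1], , drop = FALSE])
  m <- colSums(occ)
  p_hi <- stats::phyper(k1 - 1, m, n1 + n2 - m, n1, lower.tail = FALSE)
  p_lo <- stats::phyper(k1, m, n1 + n2 - m, n1)
  pmin(1, 2 * pmin(p_hi, p_lo))
}

# scenes-by-cells binary occupancy of `object` for scenes containing it,
# plus the superordinate group of each such scene.
object_occupancy_rows <- function(db, object, grid, split) {
  groups <- split_groups(db$taxonomy, split)
  keep <- which(vapply(db$scenes, function(s) object %in% scene_labels(s),
                       logical(1)))
  if (!length(keep)) stop("object not present: ", object)
  X <- t(vapply(db$scenes[keep], function(s)
    as.numeric(scene_object_masks(s, object, grid)), numeric(grid * grid)))
  cat_of <- scene_categories(db)[keep]
  grp <- ifelse(cat_of %in% groups[[1]], names(groups)[1],
                ifelse(cat_of %in% groups[[2]], names(groups)[2], NA))
  ok <- !is.na(grp)
  list(X = X[ok, , drop = FALSE], group = grp[ok],
       group_names = names(groups),
       n_instances = vapply(names(groups), function(gn) {
       idx <- keep[ok][grp[ok] == gn]
       sum(vapply(db$scenes[idx], function(s)
         sum(scene_labels(s) == object), numeric(1)))
     }, numeric(1)))
}

#' Indoor/outdoor location contrast for an object
#'
#' Where in the image is an object found when indoors versus outdoors?
#' Per grid cell, the difference between the two groups' mean per-scene
#' occupancy (a scene's occupancy is the binary union of the object's
#' masks in that scene), tested per cell over scenes with
#' Bonferroni-corrected significance (`alpha / number of cells`). The
#' default per-cell test is Fisher's exact test on the 2 x 2
#' occupied-by-group table — exact for the binary, often sparse and
#' unbalanced cell data, so the Bonferroni family-wise rate holds; a
#' Welch t-test (`test = "t"`, with near-empty cells untested) is
#' available but is anti-conservative in the far tail on such data. A
#' Welch t map is returned in either case as a descriptive statistic.
#' The map is antisymmetric under swapping the two groups. Requires at
#' least `min_instances` instances of the object in each group.
#'
#' @param db a [scene_database()].
#' @param object object label.
#' @param split superordinate split (see [split_groups()]).
#' @param grid raster resolution (default 64).
#' @param min_instances minimum instances per group (default 10).
#' @param alpha family-wise significance level (default 0.05).
#' @param test per-cell test: `"fisher"` (exact, default) or `"t"`.
#' @return list of class `location_contrast`: `difference` (grid matrix,
#'   group1 minus group2), `t`, `p` (matrices), `significant` (logical
#'   mask at the Bonferroni threshold), `any_significant`, `n_scenes` and
#'   `n_instances` per group, `alpha_cell`.
#' @export
location_contrast_map <- function(db, object, split = "indoor-vs-outdoor",
                                  grid = 64, min_instances = 10, alpha = 0.05,
                                  test = c("fisher", "t")) {
  test <- match.arg(test)
  occ <- object_occupancy_rows(db, object, grid, split)
  if (any(occ$n_instances < min_instances))
    stop(sprintf("object '%s' needs >= %d instances in each group (has %s)",
                 object, min_instances,
                 paste(occ$n_instances, collapse = "/")))
  g <- factor(occ$group, levels = occ$group_names)
  res <- cellwise_t(occ$X, g)
  if (test == "fisher") res$p <- cellwise_fisher(occ$X, g)
  alpha_cell <- alpha / (grid * grid)
  shape <- function(v) matrix(v, grid, grid)
  structure(
    list(difference = shape(res$diff), t = shape(res$t), p = shape(res$p),
         significant = shape(res$p < alpha_cell),
         any_significant = any(res$p < alpha_cell),
         n_scenes = table(occ$group)[occ$group_names],
         n_instances = occ$n_instances, alpha_cell = alpha_cell,
         object = object),
    class = "location_contrast"
  )
}

#' Permutation calibration of the location contrast
#'
#' Null check: repeatedly permutes the group labels of the scenes entering
#' [location_contrast_map()] and records how often any cell reaches
#' Bonferroni significance. Under the null the family-wise rate should not
#' exceed `alpha`.
#'
#' @inheritParams location_contrast_map
#' @param n_perm number of permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @return list with `fwer` (fraction of permutations with any significant
#'   cell) and `n_perm`.
#' @export
location_contrast_null <- function(db, object, split = "indoor-vs-outdoor",
                                   grid = 64, alpha = 0.05, n_perm = 200,
                                   seed = 1L, test = c("fisher", "t")) {
  test <- match.arg(test)
  occ <- object_occupancy_rows(db, object, grid, split)
  g <- factor(occ$group, levels = occ$group_names)
  alpha_cell <- alpha / (grid * grid)
  set.seed(seed)
  hits <- vapply(seq_len(n_perm), function(i) {
    gp <- sample(g)
    p <- if (test == "fisher") cellwise_fisher(occ$X, gp)
         else cellwise_t(occ$X, gp)$p
    any(p < alpha_cell)
  }, logical(1))
  list(fwer = mean(hits), n_perm = n_perm)
}

#' Pooled occupancy of the designated object per category
#'
#' For each basic-level category, selects one object — the most
#' informative (highest binary mutual information with the category,
#' among objects present in it), the most diagnostic, or a seeded random
#' choice among the category's objects — and pools the occupancy masks of
#' that object's instances within that category's scenes into one map.
#' Used to compare where diagnostic versus informative objects sit in the
#' image.
#'
#' @param db a [scene_database()].
#' @param mode `"top-MI"`, `"top-diagnosticity"` or `"random"`.
#' @param grid raster resolution.
#' @param seed seed for `mode = "random"`.
#' @return list of class `occupancy_map` (pooled `grid`, `n_instances`)
#'   with a `chosen` data frame (`category`, `object`).
#' @export
informative_object_map <- function(db, mode = c("top-MI", "top-diagnosticity", "random"),
                                   grid = 64, seed = 1L) {
  mode <- match.arg(mode)
  cats <- sort(unique(scene_categories(db)))
  freq <- object_frequency(db)$per_category
  score <- switch(mode,
    "top-MI" = mutual_information(db)$binary,
    "top-diagnosticity" = diagnosticity(db, min_instances = 0)$prob,
    "random" = NULL)
  if (mode == "random") set.seed(seed)
  acc <- matrix(0, grid, grid)
  n <- 0L
  chosen <- data.frame(category = cats, object = NA_character_,
                       stringsAsFactors = FALSE)
  for (ci in seq_along(cats)) {
    cat_i <- cats[ci]
    present <- rownames(freq)[freq[, cat_i] > 0]
    obj <- if (mode == "random") {
      sample(sort(present), 1)
    } else {
      v <- score[present, cat_i]
      names(v) <- present
      names(v)[order(-v, names(v))][1] # max, lexicographic tie-break
    }
    chosen$object[ci] <- obj
    for (s in db$scenes[scene_categories(db) == cat_i]) {
      for (m in scene_object_masks(s, obj, grid, union = FALSE)) {
        acc <- acc + m
        n <- n + 1L
      }
    }
  }
  structure(list(grid = acc, object = paste0("<per-category ", mode, ">"),
                 n_instances = n, chosen = chosen),
            class = "occupancy_map")
}

#' Quadrant features of a scene
#'
#' Counts of each object in each image quadrant (TL, TR, BL, BR), with
#' instances assigned to the quadrant containing their bounding-box
#' center. Centers exactly on a midline go to the lower-index quadrant
#' (left before right, top before bottom), so every instance is counted
#' exactly once and rows sum to the scene's instance counts.
#'
#' @param scene a [scene_annotation()].
#' @param vocabulary label set for the rows; defaults to the scene's own
#'   labels.
#' @return integer matrix `vocabulary x 4` with columns `TL`, `TR`, `BL`,
#'   `BR`.
#' @export
quadrant_features <- function(scene, vocabulary = NULL) {
  if (is.null(vocabulary)) vocabulary <- sort(unique(scene_labels(scene)))
  m <- matrix(0L, nrow = length(vocabulary), ncol = 4,
              dimnames = list(vocabulary, c("TL", "TR", "BL", "BR")))
  for (obj in scene$objects) {
    if (!obj$label %in% vocabulary) next
    ctr <- object_bbox_center(obj$polygon)
    right <- ctr[1] > scene$width / 2
    bottom <- ctr[2] > scene$height / 2
    q <- 1L + right + 2L * bottom
    m[obj$label, q] <- m[obj$label, q] + 1L
  }
  m
}

#' Quadrant feature matrix for a database
#'
#' The structural classifier's representation: each object is represented
#' four times, once per quadrant, giving a scenes x (4 * vocabulary)
#' count matrix.
#'
#' @param db a [scene_database()].
#' @return integer matrix; columns named `<label>|TL` etc.
#' @export
quadrant_matrix <- function(db) {
  vocab <- db$vocabulary
  out <- t(vapply(db$scenes, function(s)
    as.integer(quadrant_features(s, vocab)),
    integer(length(vocab) * 4)))
  colnames(out) <- as.vector(outer(vocab, c("TL", "TR", "BL", "BR"),
                                   paste, sep = "|"))
  rownames(out) <- vapply(db$scenes, `[[`, character(1), "scene_id")
  out
}
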