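#' Per-scene ensemble statistics
#'
#' The six summary statistics describing a scene's objects as unnamed
#' "things":
#' \describe{
#'   \item{density}{total number of labeled regions.}
#'   \item{unique_count}{number of distinct labels.}
#'   \item{mean_size, size_variance}{mean and variance of per-object area
#'     expressed as a fraction of image area. Because labeling a
#'     three-dimensional scene yields overlapping polygons, sizes can sum
#'     to more than 1.}
#'   \item{com_x, com_y}{center of mass: the area-weighted mean of object
#'     bounding-box centers, normalized to `[0, 1]` per axis. `com_y` is
#'     reported as the fraction from the image \emph{bottom}, so a larger
#'     value means a higher center of mass.}
#'   \item{spacing_cv}{spacing regularity: SD of pairwise Euclidean
#'     distances between (unweighted) object centers divided by the mean
#'     pairwise distance. Coordinates are normalized by image width and
#'     height first so differently sized images are comparable; the ratio
#'     itself is additionally scale-invariant. Undefined (`NA`) for scenes
#'     with fewer than 2 objects; with exactly 2 objects there is a single
#'     distance and the SD is 0 by convention.}
#' }
#'
#' @param scene a [scene_annotation()] with at least one object.
#' @return a list of class `ensemble_features` with the fields above.
#' @export
ensemble_features <- function(scene) {
  n <- length(scene$objects)
  if (n < 1) stop("scene has no objects")
  labels <- scene_labels(scene)
  areas <- vapply(scene$objects, function(o) polygon_area(o$polygon), numeric(1))
  frac <- areas / (scene$width * scene$height)
  centers <- t(vapply(scene$objects, function(o) object_bbox_center(o$polygon),
                      numeric(2)))
  wts <- if (sum(frac) > 0) frac / sum(frac) else rep(1 / n, n)
  com_x <- sum(wts * centers[, 1]) / scene$width
  com_y <- 1 - sum(wts * centers[, 2]) / scene$height

  spacing_cv <- NA_real_
  if (n >= 2) {
    norm_centers <- cbind(centers[, 1] / scene$width, centers[, 2] / scene$height)
    d <- stats::dist(norm_centers)
    spacing_cv <- if (length(d) == 1L) 0 else stats::sd(d) / mean(d)
  }
  structure(
    list(density = n, unique_count = length(unique(labels)),
         mean_size = mean(frac),
         size_variance = if (n == 1L) 0 else stats::var(frac),
         com_x = com_x, com_y = com_y, spacing_cv = spacing_cv),
    class = "ensemble_features"
  )
}

#' Ensemble feature matrix for a database
#'
#' One row per scene with the seven ensemble columns (`com` contributes
#' `com_x` and `com_y`). Scenes with a single object have `spacing_cv`
#' imputed to 0 so the matrix is complete for classification; such scenes
#' are flagged in the `spacing_defined` column.
#'
#' @param db a [scene_database()].
#' @return data frame with `scene_id`, `category`, the feature columns and
#'   `spacing_defined`.
#' @export
ensemble_feature_matrix <- function(db) {
  rows <- lapply(db$scenes, function(s) {
    f <- ensemble_features(s)
    data.frame(scene_id = s$scene_id, category = s$category,
               density = f$density, unique_count = f$unique_count,
               mean_size = f$mean_size, size_variance = f$size_variance,
               com_x = f$com_x, com_y = f$com_y,
               spacing_cv = if (is.na(f$spacing_cv)) 0 else f$spacing_cv,
               spacing_defined = !is.na(f$spacing_cv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Grouping of ensemble columns into the six statistics
#'
#' Used by [ensemble_combination_sweep()]: the center of mass is one
#' statistic contributing two columns.
#'
#' @return named list mapping statistic name to feature-column names.
#' @export
ensemble_feature_groups <- function() {
  list(density = "density", unique_count = "unique_count",
       mean_size = "mean_size", size_variance = "size_variance",
       center_of_mass = c("com_x", "com_y"), spacing_cv = "spacing_cv")
}

#' Per-category mean and SD of each ensemble statistic
#'
#' @param db a [scene_database()].
#' @return long data frame: `category`, `statistic`, `mean`, `sd`, `n`.
#' @export
category_summary <- function(db) {
  feats <- ensemble_feature_matrix(db)
  cols <- c("density", "unique_count", "mean_size", "size_variance",
            "com_x", "com_y", "spacing_cv")
  out <- list()
  for (cat in unique(feats$category)) {
    sub <- feats[feats$category == cat, , drop = FALSE]
    if (!nrow(sub)) {
      warning("empty category omitted: ", cat)
      next
    }
    for (col in cols) {
      v <- sub[[col]]
      if (col == "spacing_cv") v <- v[sub$spacing_defined]
      out[[length(out) + 1L]] <- data.frame(
        category = cat, statistic = col,
        mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Superordinate contrast on category means of an ensemble statistic
#'
#' Two-sample equal-variance t-test where the unit of analysis is the
#' basic-level category mean: with the full 16-category taxonomy this
#' gives df = 14 for the indoor-vs-outdoor split (8 vs 8 categories) and
#' df = 6 for urban-vs-natural (4 vs 4). Two-tailed p.
#'
#' @param db a [scene_database()].
#' @param field one of the ensemble columns (e.g. `"density"`, `"com_y"`).
#' @param split `"indoor-vs-outdoor"` or `"urban-vs-natural"`.
#' @return list with `t`, `df`, `p`, and the two `group_means`.
#' @export
superordinate_contrast <- function(db, field,
                                   split = c("indoor-vs-outdoor", "urban-vs-natural")) {
  split <- match.arg(split)
  summ <- category_summary(db)
  summ <- summ[summ$statistic == field, , drop = FALSE]
  if (!nrow(summ)) stop("unknown ensemble field: ", field)
  groups <- split_groups(db$taxonomy, split)
  g1 <- summ$mean[summ$category %in% groups[[1]]]
  g2 <- summ$mean[summ$category %in% groups[[2]]]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least 2 categories with scenes")
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       group_means = stats::setNames(c(mean(g1), mean(g2)), names(groups)))
}
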