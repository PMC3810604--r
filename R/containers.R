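#' Construct a polygon
#'
#' A polygon is an n x 2 numeric matrix of vertex coordinates in pixel
#' units, 0-based, x increasing rightward and y increasing downward from
#' the top-left image corner (the LabelMe convention). Vertices are stored
#' in the order given; the polygon is implicitly closed.
#'
#' @param x,y numeric vectors of equal length (>= 3) with finite values,
#'   or `x` alone may be an n x 2 matrix.
#' @return a numeric matrix of class `scene_polygon` with columns `x`, `y`.
#' @examples
#' p <- polygon_coords(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygon_area(p)
#' @export
polygon_coords <- function(x, y = NULL) {
  if (is.null(y)) {
    stopifnot(is.matrix(x), ncol(x) == 2)
    m <- x
  } else {
    stopifnot(length(x) == length(y))
    m <- cbind(x, y)
  }
  storage.mode(m) <- "double"
  if (nrow(m) < 3) stop("a polygon needs at least 3 vertices")
  if (!all(is.finite(m))) stop("polygon coordinates must be finite")
  dimnames(m) <- list(NULL, c("x", "y"))
  class(m) <- c("scene_polygon", "matrix", "array")
  m
}

#' Construct an object annotation
#'
#' One labeled region: a canonical (or raw, before cleaning) label and its
#' bounding polygon.
#'
#' @param label non-empty character scalar.
#' @param polygon a polygon as returned by [polygon_coords()].
#' @return a list of class `object_annotation`.
#' @export
object_annotation <- function(label, polygon) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!inherits(polygon, "scene_polygon")) polygon <- polygon_coords(polygon)
  structure(list(label = label, polygon = polygon), class = "object_annotation")
}

#' Construct a scene annotation
#'
#' One image's worth of annotation: identifier, pixel dimensions, the
#' basic-level category it belongs to, and the list of labeled polygons.
#'
#' @param scene_id character scalar identifier.
#' @param width,height image dimensions in pixels, > 0.
#' @param category basic-level category label.
#' @param objects list of [object_annotation()] objects.
#' @return a list of class `scene_annotation`.
#' @export
scene_annotation <- function(scene_id, width, height, category, objects = list()) {
  stopifnot(width > 0, height > 0, is.character(category), length(category) == 1L)
  ok <- vapply(objects, inherits, logical(1), "object_annotation")
  if (!all(ok)) stop("`objects` must be a list of object_annotation")
  structure(
    list(scene_id = as.character(scene_id), width = as.numeric(width),
         height = as.numeric(height), category = category,
         objects = unname(objects)),
    class = "scene_annotation"
  )
}

#' @export
print.scene_annotation <- function(x, ...) {
  cat(sprintf("<scene_annotation> %s [%gx%g] category=%s, %d objects\n",
              x$scene_id, x$width, x$height, x$category, length(x$objects)))
  invisible(x)
}

#' Labels of a scene's objects
#' @param scene a [scene_annotation()].
#' @return character vector, one entry per object instance.
#' @export
scene_labels <- function(scene) {
  vapply(scene$objects, `[[`, character(1), "label")
}

#' Construct a scene database
#'
#' A collection of annotated scenes plus the category taxonomy mapping
#' basic-level categories to superordinates (`indoor`, `urban`, `natural`).
#' The vocabulary (sorted set of labels appearing in any scene) is derived
#' on construction.
#'
#' @param scenes list of [scene_annotation()] objects.
#' @param taxonomy named character vector: `names()` are basic-level
#'   categories, values are superordinate labels.
#' @return a list of class `scene_database` with elements `scenes`,
#'   `taxonomy`, `vocabulary`.
#' @export
scene_database <- function(scenes, taxonomy) {
  ok <- vapply(scenes, inherits, logical(1), "scene_annotation")
  if (!all(ok)) stop("`scenes` must be a list of scene_annotation")
  stopifnot(is.character(taxonomy), !is.null(names(taxonomy)))
  cats <- vapply(scenes, `[[`, character(1), "category")
  missing <- setdiff(unique(cats), names(taxonomy))
  if (length(missing))
    stop("scene categories absent from taxonomy: ", paste(missing, collapse = ", "))
  vocab <- sort(unique(unlist(lapply(scenes, scene_labels), use.names = FALSE)))
  structure(
    list(scenes = unname(scenes), taxonomy = taxonomy,
         vocabulary = as.character(vocab)),
    class = "scene_database"
  )
}

#' @export
print.scene_database <- function(x, ...) {
  cat(sprintf("<scene_database> %d scenes, %d categories, %d-label vocabulary\n",
              length(x$scenes), length(unique(scene_categories(x))),
              length(x$vocabulary)))
  invisible(x)
}

#' Basic-level category of every scene
#' @param db a [scene_database()].
#' @return character vector parallel to `db$scenes`.
#' @export
scene_categories <- function(db) {
  vapply(db$scenes, `[[`, character(1), "category")
}

#' Superordinate category of every scene
#' @param db a [scene_database()].
#' @return character vector (`indoor`, `urban` or `natural`) per scene.
#' @export
scene_superordinates <- function(db) {
  unname(db$taxonomy[scene_categories(db)])
}

#' Membership of basic-level categories in a superordinate split
#'
#' @param taxonomy named character vector (basic -> superordinate).
#' @param split `"indoor-vs-outdoor"` (indoor vs urban+natural) or
#'   `"urban-vs-natural"` (outdoor categories only).
#' @return list of two character vectors of basic-level categories, named
#'   after the two groups.
#' @export
split_groups <- function(taxonomy, split = c("indoor-vs-outdoor", "urban-vs-natural")) {
  split <- match.arg(split)
  if (split == "indoor-vs-outdoor") {
    list(indoor = names(taxonomy)[taxonomy == "indoor"],
         outdoor = names(taxonomy)[taxonomy %in% c("urban", "natural")])
  } else {
    list(urban = names(taxonomy)[taxonomy == "urban"],
         natural = names(taxonomy)[taxonomy == "natural"])
  }
}
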