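#' Parse a LabelMe annotation document
#'
#' Reads one image's annotation in the LabelMe XML dialect: a root
#' `<annotation>` holding `<filename>`, `<folder>`, an `<imagesize>`
#' element (`<nrows>`, `<ncols>`) and one `<object>` per labeled region,
#' each with a `<name>` and a `<polygon>` of `<pt><x/><y/></pt>` vertices.
#' Objects flagged `<deleted>1</deleted>` are dropped; objects with fewer
#' than 3 vertices are skipped with a warning. Label text is preserved
#' verbatim (cleaning is a separate, table-driven step; see
#' [normalize_labels()]).
#'
#' @param x XML text, a file path, or an `xml2` document.
#' @param category basic-level category; defaults to the `<folder>` element.
#' @param width,height image size in pixels; defaults to `<imagesize>`.
#'   Must be supplied if the document carries no size element.
#' @return a [scene_annotation()].
#' @export
parse_labelme_xml <- function(x, category = NULL, width = NULL, height = NULL) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  get1 <- function(node, path) {
    n <- xml2::xml_find_first(node, path)
    if (inherits(n, "xml_missing")) NULL else xml2::xml_text(n)
  }
  scene_id <- get1(doc, "./filename")
  if (is.null(scene_id) || !nzchar(scene_id)) scene_id <- "scene"
  if (is.null(category)) category <- get1(doc, "./folder")
  if (is.null(category) || !nzchar(category))
    stop("no category: document has no <folder> and none was supplied")
  if (is.null(width)) width <- as.numeric(get1(doc, "./imagesize/ncols"))
  if (is.null(height)) height <- as.numeric(get1(doc, "./imagesize/nrows"))
  if (!length(width) || !length(height) || is.na(width) || is.na(height))
    stop("image size missing from document and not supplied")

  objects <- list()
  for (node in xml2::xml_find_all(doc, "./object")) {
    deleted <- get1(node, "./deleted")
    if (!is.null(deleted) && trimws(deleted) == "1") next
    label <- get1(node, "./name")
    if (is.null(label) || !nzchar(trimws(label))) next
    xs <- as.numeric(xml2::xml_text(xml2::xml_find_all(node, "./polygon/pt/x")))
    ys <- as.numeric(xml2::xml_text(xml2::xml_find_all(node, "./polygon/pt/y")))
    if (length(xs) < 3 || length(xs) != length(ys)) {
      warning(sprintf("skipping object '%s' in %s: polygon has %d vertices",
                      label, scene_id, length(xs)))
      next
    }
    objects[[length(objects) + 1L]] <-
      object_annotation(trimws(label), polygon_coords(xs, ys))
  }
  scene_annotation(scene_id, width, height, category, objects)
}

#' Serialize a scene annotation to LabelMe XML
#'
#' Inverse of [parse_labelme_xml()]: labels, vertex lists and image
#' dimensions round-trip exactly. Output is deterministic (byte-stable for
#' a given scene).
#'
#' @param scene a [scene_annotation()].
#' @return a single character string of XML.
#' @export
write_labelme_xml <- function(scene) {
  num <- function(v) formatC(v, format = "g", digits = 15)
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  lines <- c(
    "<annotation>",
    sprintf("  <filename>%s</filename>", esc(scene$scene_id)),
    sprintf("  <folder>%s</folder>", esc(scene$category)),
    "  <imagesize>",
    sprintf("    <nrows>%s</nrows>", num(scene$height)),
    sprintf("    <ncols>%s</ncols>", num(scene$width)),
    "  </imagesize>"
  )
  for (obj in scene$objects) {
    pts <- apply(obj$polygon, 1, function(v)
      sprintf("      <pt><x>%s</x><y>%s</y></pt>", num(v[1]), num(v[2])))
    lines <- c(lines,
               "  <object>",
               sprintf("    <name>%s</name>", esc(obj$label)),
               "    <deleted>0</deleted>",
               "    <polygon>", pts, "    </polygon>",
               "  </object>")
  }
  paste0(paste(c(lines, "</annotation>"), collapse = "\n"), "\n")
}

#' Read a folder of LabelMe annotations as a scene database
#'
#' @param path directory containing one `.xml` file per image.
#' @param taxonomy named character vector (basic -> superordinate), e.g.
#'   from [read_taxonomy()].
#' @return a [scene_database()].
#' @export
read_scene_dir <- function(path, taxonomy) {
  files <- sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
  if (!length(files)) stop("no .xml annotation files under ", path)
  scene_database(lapply(files, parse_labelme_xml), taxonomy)
}

#' Write a scene database as a folder of LabelMe annotations
#'
#' @param db a [scene_database()].
#' @param path output directory (created if needed). One file per scene,
#'   named `<scene_id>.xml`.
#' @return invisibly, the file paths written.
#' @export
write_scene_dir <- function(db, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(db$scenes, function(s) {
    f <- file.path(path, paste0(s$scene_id, ".xml"))
    writeLines(write_labelme_xml(s), f, sep = "")
    f
  }, character(1))
  invisible(paths)
}

#' Read a category taxonomy from CSV
#'
#' Two columns: `basic`, `superordinate`.
#'
#' @param path CSV file path.
#' @return named character vector mapping basic-level categories to
#'   superordinates.
#' @export
read_taxonomy <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("basic", "superordinate") %in% names(d)))
  stats::setNames(d$superordinate, d$basic)
}

#' Construct a label-normalization table
#'
#' The cleaning procedure is table-driven: each raw label maps either to a
#' canonical label (`action = "rename"`) or to removal
#' (`action = "delete"`), tagged with the class of change (misspelling,
#' plural, subordinate, superordinate, synonym, container, part, other).
#' Rename targets must themselves be canonical: a target that is also a
#' raw key would need a second pass, and such chains are rejected.
#'
#' @param raw character vector of raw labels.
#' @param action `"rename"` or `"delete"` per entry.
#' @param target canonical label for renames; `NA` for deletions.
#' @param change_class change-class tag per entry.
#' @return data frame of class `label_normalization_table`.
#' @export
normalization_table <- function(raw, action, target = NA_character_, change_class = "other") {
  raw <- as.character(raw)
  d <- data.frame(raw = raw, action = rep_len(as.character(action), length(raw)),
                  target = rep_len(as.character(target), length(raw)),
                  change_class = rep_len(as.character(change_class), length(raw)),
                  stringsAsFactors = FALSE)
  valid_classes <- c("misspelling", "plural", "subordinate", "superordinate",
                     "synonym", "container", "part", "other")
  if (!all(d$action %in% c("rename", "delete")))
    stop("action must be 'rename' or 'delete'")
  if (!all(d$change_class %in% valid_classes))
    stop("unknown change_class")
  if (anyDuplicated(d$raw)) stop("duplicate raw labels in normalization table")
  bad <- d$action == "rename" & (is.na(d$target) | !nzchar(d$target))
  if (any(bad)) stop("rename entries need a target label")
  chained <- intersect(d$target[d$action == "rename"], d$raw)
  if (length(chained))
    stop("rename chain detected: target(s) also raw keys: ",
         paste(chained, collapse = ", "))
  class(d) <- c("label_normalization_table", "data.frame")
  d
}

#' Read a normalization table from CSV
#'
#' Columns: `raw`, `action` (either `delete` or `rename:<target>`),
#' `change_class`.
#'
#' @param path CSV file path.
#' @return a [normalization_table()].
#' @export
read_normalization_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("raw", "action", "change_class") %in% names(d)))
  is_rename <- startsWith(d$action, "rename:")
  normalization_table(
    raw = d$raw,
    action = ifelse(is_rename, "rename", d$action),
    target = ifelse(is_rename, sub("^rename:", "", d$action), NA_character_),
    change_class = d$change_class
  )
}

#' Apply a label-normalization table to a database
#'
#' Every annotation whose raw label appears in the table is renamed to its
#' canonical label or removed; labels absent from the table pass through
#' unchanged. The operation is idempotent (rename targets are canonical by
#' construction) and never grows the vocabulary.
#'
#' @param db a [scene_database()].
#' @param table a [normalization_table()].
#' @return list with elements `database` (the cleaned [scene_database()],
#'   vocabulary recomputed) and `changes` (data frame of change counts per
#'   `change_class` and `action`).
#' @export
normalize_labels <- function(db, table) {
  if (!inherits(table, "label_normalization_table"))
    stop("`table` must be a normalization_table")
  action <- stats::setNames(table$action, table$raw)
  target <- stats::setNames(table$target, table$raw)
  cls <- stats::setNames(table$change_class, table$raw)
  tally <- list()
  bump <- function(change_class, act, n = 1L) {
    key <- paste(change_class, act, sep = "\r")
    tally[[key]] <<- (tally[[key]] %||% 0L) + n
  }
  scenes <- lapply(db$scenes, function(s) {
    kept <- list()
    for (obj in s$objects) {
      a <- action[obj$label]
      if (is.na(a)) {
        kept[[length(kept) + 1L]] <- obj
      } else if (a == "delete") {
        bump(cls[[obj$label]], "delete")
      } else {
        bump(cls[[obj$label]], "rename")
        kept[[length(kept) + 1L]] <- object_annotation(target[[obj$label]], obj$polygon)
      }
    }
    scene_annotation(s$scene_id, s$width, s$height, s$category, kept)
  })
  changes <- if (length(tally)) {
    parts <- strsplit(names(tally), "\r", fixed = TRUE)
    data.frame(change_class = vapply(parts, `[`, character(1), 1),
               action = vapply(parts, `[`, character(1), 2),
               n = unlist(tally, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(change_class = character(), action = character(), n = integer(),
               stringsAsFactors = FALSE)
  }
  list(database = scene_database(scenes, db$taxonomy),
       changes = changes[order(changes$change_class, changes$action), , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
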