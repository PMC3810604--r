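# Small fixture builders used across the suite. All geometry is
# rectangles so exact areas/centers are known in closed form.

rect_poly <- function(x0, y0, w, h) {
  polygon_coords(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

# scene with one rectangle per row of `rects` (x0, y0, w, h)
make_scene <- function(id, category, labels, rects, width = 10, height = 10) {
  objs <- lapply(seq_along(labels), function(i)
    object_annotation(labels[i], do.call(rect_poly, as.list(rects[i, ]))))
  scene_annotation(id, width, height, category, objs)
}

# scene where each label gets a default unit square at distinct positions
make_label_scene <- function(id, category, labels, width = 10, height = 10) {
  n <- length(labels)
  rects <- cbind(x0 = (seq_len(n) - 1) %% 8, y0 = (seq_len(n) - 1) %/% 8,
                 w = 1, h = 1)
  make_scene(id, category, labels, rects, width, height)
}

# database from a list: category -> list of label vectors (one per scene)
make_label_db <- function(spec, taxonomy = NULL) {
  scenes <- list()
  for (cat in names(spec)) {
    for (i in seq_along(spec[[cat]])) {
      scenes[[length(scenes) + 1L]] <-
        make_label_scene(sprintf("%s_%d", cat, i), cat, spec[[cat]][[i]])
    }
  }
  if (is.null(taxonomy))
    taxonomy <- stats::setNames(rep("indoor", length(spec)), names(spec))
  scene_database(scenes, taxonomy)
}

# independent even-odd point-in-polygon used as a rasterization oracle
oracle_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  wind <- rep(FALSE, length(px))
  for (k in seq_along(px)) {
    cnt <- 0L
    for (i in seq_len(n)) {
      j <- if (i == 1L) n else i - 1L
      x1 <- poly[i, 1]; y1 <- poly[i, 2]; x2 <- poly[j, 1]; y2 <- poly[j, 2]
      if ((y1 > py[k]) != (y2 > py[k])) {
        xint <- (x2 - x1) * (py[k] - y1) / (y2 - y1) + x1
        if (px[k] < xint) cnt <- cnt + 1L
      }
    }
    wind[k] <- cnt %% 2L == 1L
  }
  wind
}

# binary mutual information (bits) from a 2x2 contingency table via
# joint entropies: I = H(S) + H(O) - H(S, O)
mi_joint_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  H <- function(v) { v <- v[v > 0] / N; -sum(v * log2(v)) }
  H(c(a + b, c + d)) + H(c(a + c, b + d)) - H(c(a, b, c, d))
}

# database realizing a 2x2 presence-by-membership table for object "obj":
# a scenes of category S with obj, b without; c scenes of T with obj,
# d without. Scenes lacking obj carry a filler label.
make_contingency_db <- function(a, b, c, d) {
  spec <- list(
    S = c(replicate(a, c("obj", "filler"), simplify = FALSE),
          replicate(b, "filler", simplify = FALSE)),
    T = c(replicate(c, c("obj", "filler"), simplify = FALSE),
          replicate(d, "filler", simplify = FALSE))
  )
  spec <- lapply(spec, function(x) x[lengths(x) > 0])
  make_label_db(spec, taxonomy = c(S = "indoor", T = "natural"))
}

# exhaustive frequent-itemset enumeration (oracle for frequent_groups)
exhaustive_groups <- function(db, category, n, top_k = 10) {
  keep <- scene_categories(db) == category
  sets <- lapply(db$scenes[keep], function(s) sort(unique(scene_labels(s))))
  items <- sort(unique(unlist(sets)))
  if (length(items) < n) {
    return(data.frame(group = character(), support = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  combos <- utils::combn(items, n, simplify = FALSE)
  sup <- vapply(combos, function(g)
    sum(vapply(sets, function(s) all(g %in% s), logical(1))), integer(1))
  keysets <- vapply(combos, paste, character(1), collapse = " + ")
  ord <- order(-sup, keysets)
  out <- data.frame(group = keysets[ord], support = sup[ord],
                    frequency = sup[ord] / sum(keep),
                    stringsAsFactors = FALSE, row.names = NULL)
  utils::head(out[out$support > 0, ], top_k)
}
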