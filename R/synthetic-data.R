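#' Construct a category generative profile
#'
#' One basic-level category's generative description: which objects occur
#' (per-scene presence probabilities), how many labeled regions a scene has
#' (negative-binomial count), how large objects are (log-normal area
#' fraction), and where they sit vertically (per-object normal band on the
#' normalized bbox-center y, measured downward from the image top).
#'
#' @param category,superordinate labels.
#' @param object_probs named numeric vector in `[0, 1]`: per-scene
#'   probability that a scene of this category contains at least one
#'   instance of each object.
#' @param density_mean mean total labeled regions per scene (> 0).
#' @param density_size negative-binomial dispersion (`Inf` = deterministic
#'   count, i.e. a point mass at `round(density_mean)`).
#' @param size_meanlog,size_sdlog log-normal parameters of per-object area
#'   as a fraction of image area.
#' @param y_mean,y_sd per-object vertical placement: named vectors aligned
#'   with `object_probs` (mean and SD of normalized center y in `[0, 1]`).
#' @param multiplicity_weight named non-negative vector: relative weight of
#'   each object when surplus regions become duplicate instances. Defaults
#'   to `object_probs`; set 0 for objects that occur at most once per
#'   scene (distinctive objects like a bath mat), leaving multiplicity to
#'   countable background objects (windows, chairs, trees).
#' @return a list of class `category_profile`.
#' @export
category_profile <- function(category, superordinate, object_probs,
                             density_mean, density_size = 5,
                             size_meanlog, size_sdlog = 0.6,
                             y_mean, y_sd, multiplicity_weight = NULL) {
  stopifnot(all(object_probs >= 0 & object_probs <= 1), density_mean > 0,
            !is.null(names(object_probs)),
            all(names(object_probs) %in% names(y_mean)),
            all(names(object_probs) %in% names(y_sd)))
  if (is.null(multiplicity_weight)) multiplicity_weight <- object_probs
  stopifnot(all(names(object_probs) %in% names(multiplicity_weight)),
            all(multiplicity_weight >= 0))
  structure(
    list(category = category, superordinate = superordinate,
         object_probs = object_probs,
         density_mean = density_mean, density_size = density_size,
         size_meanlog = size_meanlog, size_sdlog = size_sdlog,
         y_mean = y_mean[names(object_probs)],
         y_sd = y_sd[names(object_probs)],
         multiplicity_weight = multiplicity_weight[names(object_probs)]),
    class = "category_profile"
  )
}

#' Construct a generator configuration
#'
#' @param profiles list of [category_profile()] objects (>= 1).
#' @param scenes_per_category scenes to draw per profile (>= 1).
#' @param image_size `c(width, height)` in pixels.
#' @param seed integer master seed; every scene derives its own substream
#'   from `(seed, profile index, scene index)` so individual scenes are
#'   independently reproducible.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(profiles, scenes_per_category = 50,
                             image_size = c(640, 480), seed = 1L) {
  stopifnot(length(profiles) >= 1, scenes_per_category >= 1,
            length(image_size) == 2, all(image_size > 0))
  ok <- vapply(profiles, inherits, logical(1), "category_profile")
  if (!all(ok)) stop("`profiles` must be category_profile objects")
  structure(
    list(profiles = profiles,
         scenes_per_category = as.integer(scenes_per_category),
         image_size = as.numeric(image_size), seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Superordinate-specific shared vocabularies. Overlap across pools is
# deliberate ("window", "door", "plant", "tree", "sky", "person" span
# superordinates) so that scene-object specificity and cross-superordinate
# location contrasts are exercised. "wall" is added to every category.
shared_pools <- function() {
  list(
    indoor = c("ceiling", "floor", "window", "door", "chair", "table",
               "light", "lamp", "painting", "plant", "curtain", "cabinet",
               "pillow", "mirror", "shelf", "book", "bottle", "rug",
               "clock", "poster", "box", "person", "switch", "vent"),
    urban = c("building", "sky", "road", "window", "car", "sidewalk",
              "tree", "door", "person", "sign", "streetlight", "plant",
              "fence", "pole", "bus", "truck", "van", "awning", "balcony",
              "bridge"),
    natural = c("sky", "tree", "mountain", "rock", "grass", "field",
                "river", "cloud", "bush", "ground", "sand", "ocean",
                "hill", "path", "snow", "water", "land", "boat")
  )
}

# Fixed vertical placement (normalized y from image top) for boundary-like
# objects; everything else inherits its category's band. "door", "window"
# and "plant" are placed higher (smaller y) indoors than outdoors,
# planting a real indoor/outdoor location contrast for those objects.
vertical_overrides <- function(superordinate) {
  base <- c(sky = 0.12, cloud = 0.12, ceiling = 0.08, light = 0.15,
            floor = 0.90, rug = 0.92, carpet = 0.92, ground = 0.88,
            road = 0.80, sidewalk = 0.85, ocean = 0.60, sand = 0.85,
            field = 0.75, grass = 0.85, mountain = 0.40, hill = 0.55,
            wall = 0.40, building = 0.40, skyscraper = 0.35)
  shift <- if (superordinate == "indoor") c(door = 0.42, window = 0.35, plant = 0.40)
           else c(door = 0.62, window = 0.55, plant = 0.70)
  c(base, shift)
}

# Scale Zipf weights w so that sum(min(cap, s * w)) == target.
scale_capped <- function(w, target, cap = 0.95) {
  if (target <= 0) return(rep(0, length(w)))
  if (target >= cap * length(w)) return(rep(cap, length(w)))
  f <- function(s) sum(pmin(cap, s * w)) - target
  s <- stats::uniroot(f, c(1e-9, 1e9), tol = 1e-10)$root
  pmin(cap, s * w)
}

#' Default generative profiles for the 16-category taxonomy
#'
#' Sixteen basic-level categories (8 indoor, 4 urban, 4 natural) with:
#' per-category mean total region counts of 20.2, 18.3, 25.8, 15.6, 22.6,
#' 33.1, 24.8, 27.1 (indoor: bathroom ... office), 12.3, 20.0, 20.1, 13.3
#' (urban) and 5.5, 7.4, 5.1, 7.8 (natural) — e.g. kitchens average 33.1
#' regions and mountains 5.1; mean object-size fractions from 0.050
#' (living room) to 0.429 (mountain); presence-probability sums calibrated
#' so the expected number of distinct objects per scene matches the
#' corresponding unique-region means (19.5 for kitchens down to 3.2 for
#' mountains). Each category carries 3 exclusive objects at presence
#' probability 0.9 plus a shared, superordinate-specific vocabulary with
#' Zipf-decaying (1/rank) presence weights, so the realized marginal
#' rank-frequency distribution is approximately Zipfian.
#'
#' @return named list of 16 [category_profile()] objects.
#' @export
default_profiles <- function() {
  cats <- data.frame(
    category = c("bathroom", "bedroom", "conference_room", "corridor",
                 "dining_room", "kitchen", "living_room", "office",
                 "skyscraper", "city_center", "street", "highway",
                 "coast", "open_country", "mountain", "forest"),
    superordinate = rep(c("indoor", "urban", "natural"), c(8, 4, 4)),
    density = c(20.2, 18.3, 25.8, 15.6, 22.6, 33.1, 24.8, 27.1,
                12.3, 20.0, 20.1, 13.3, 5.5, 7.4, 5.1, 7.8),
    unique = c(14.7, 12.5, 8.6, 7.9, 12.2, 19.5, 15.2, 15.9,
               5.0, 9.0, 8.4, 7.7, 4.4, 7.7, 3.2, 4.5),
    mean_size = c(0.057, 0.069, 0.103, 0.140, 0.071, 0.054, 0.050, 0.053,
                  0.249, 0.174, 0.200, 0.120, 0.239, 0.252, 0.429, 0.290),
    stringsAsFactors = FALSE
  )
  exclusive <- list(
    bathroom = c("bath mat", "shower curtain", "toothbrush"),
    bedroom = c("bedspread", "headboard", "nightstand"),
    conference_room = c("microphone", "podium", "projection screen"),
    corridor = c("exit sign", "fire alarm", "alcove"),
    dining_room = c("buffet", "wine glass", "placemat"),
    kitchen = c("cutting board", "kettle", "stove hood"),
    living_room = c("coffee table", "ottoman", "fireplace"),
    office = c("file organizer", "mouse pad", "keyboard"),
    skyscraper = c("skyscraper", "antenna", "mast"),
    city_center = c("arcade", "porch", "shop window"),
    street = c("crosswalk", "curb", "motorcycle"),
    highway = c("median", "overpass", "guardrail"),
    coast = c("seagull", "lighthouse", "pier"),
    open_country = c("cow", "hay bale", "windmill"),
    mountain = c("mountain pass", "glacier", "summit"),
    forest = c("waterfall", "fallen log", "fern")
  )
  pools <- shared_pools()
  wall_prob <- c(indoor = 0.50, urban = 0.30, natural = 0.06)
  band_mean <- c(indoor = 0.52, urban = 0.42, natural = 0.38)

  profiles <- vector("list", nrow(cats))
  names(profiles) <- cats$category
  for (i in seq_len(nrow(cats))) {
    cat_i <- cats$category[i]; sup <- cats$superordinate[i]
    pool <- pools[[sup]]
    excl <- exclusive[[cat_i]]
    target_shared <- cats$unique[i] - 3 * 0.9 - wall_prob[[sup]]
    shared_p <- scale_capped(1 / seq_along(pool), max(target_shared, 0.2))
    probs <- c(stats::setNames(rep(0.9, 3), excl),
               stats::setNames(shared_p, pool),
               wall = wall_prob[[sup]])
    probs <- probs[probs > 0]
    ov <- vertical_overrides(sup)
    ym <- stats::setNames(rep(band_mean[[sup]], length(probs)), names(probs))
    hit <- intersect(names(probs), names(ov))
    ym[hit] <- ov[hit]
    ys <- stats::setNames(rep(0.12, length(probs)), names(probs))
    mean_size <- cats$mean_size[i]
    sdlog <- 0.6
    mult <- probs
    mult[excl] <- 0 # distinctive objects occur once per scene
    profiles[[cat_i]] <- category_profile(
      category = cat_i, superordinate = sup,
      object_probs = probs,
      density_mean = cats$density[i], density_size = 5,
      size_meanlog = log(mean_size) - sdlog^2 / 2, size_sdlog = sdlog,
      y_mean = ym, y_sd = ys, multiplicity_weight = mult
    )
  }
  profiles
}

#' Draw one synthetic scene from a category profile
#'
#' Presence of each object is an independent Bernoulli draw with its
#' profile probability (at least one object is guaranteed), so presence
#' frequencies recover `object_probs` exactly in expectation and the mean
#' number of distinct objects equals `sum(object_probs)`. On top of the
#' present objects, a negative-binomial surplus with mean
#' `density_mean - sum(object_probs)` adds duplicate instances (sampled
#' by `multiplicity_weight`), so the mean total region count equals
#' `density_mean`.
#' Each instance is an axis-aligned rectangle with a log-normal area
#' fraction, random aspect ratio, horizontal center uniform and vertical
#' center drawn from the object's vertical band, clipped to the image.
#'
#' Uses the current R random stream; seed it (or use
#' [generate_database()], which derives a per-scene substream) for
#' reproducibility.
#'
#' @param profile a [category_profile()].
#' @param scene_id identifier for the scene.
#' @param width,height image size in pixels.
#' @return a [scene_annotation()].
#' @export
generate_scene <- function(profile, scene_id = "scene", width = 640, height = 480) {
  p <- profile$object_probs
  present <- names(p)[stats::runif(length(p)) < p]
  if (!length(present)) present <- names(p)[which.max(p)]
  mu_extra <- max(profile$density_mean - sum(p), 0)
  extra <- if (is.infinite(profile$density_size)) {
    round(mu_extra)
  } else if (mu_extra > 0) {
    stats::rnbinom(1, size = profile$density_size, mu = mu_extra)
  } else 0L
  labels <- present
  if (extra > 0) {
    w <- profile$multiplicity_weight[present]
    if (sum(w) == 0) w <- p[present]
    labels <- c(labels, sample(present, extra, replace = TRUE, prob = w / sum(w)))
  }
  objects <- lapply(labels, function(lab) {
    a <- stats::rlnorm(1, profile$size_meanlog, profile$size_sdlog)
    a <- min(max(a, 5e-4), 0.95)
    aspect <- exp(stats::rnorm(1, 0, 0.3))
    rw <- min(sqrt(a * width * height * aspect), 0.98 * width)
    rh <- min(a * width * height / rw, 0.98 * height)
    cx <- stats::runif(1, rw / 2, width - rw / 2)
    cy <- stats::rnorm(1, profile$y_mean[[lab]] * height, profile$y_sd[[lab]] * height)
    cy <- min(max(cy, rh / 2), height - rh / 2)
    object_annotation(lab, polygon_coords(
      x = cx + c(-rw, rw, rw, -rw) / 2,
      y = cy + c(-rh, -rh, rh, rh) / 2
    ))
  })
  scene_annotation(scene_id, width, height, profile$category, objects)
}

# 32-bit-safe per-scene seed derived from (master seed, profile, scene).
derive_seed <- function(seed, profile_index, scene_index) {
  s <- (abs(as.numeric(seed)) %% 100003) * 20011 +
    profile_index * 104729 + scene_index
  as.integer(s %% 2147483647L)
}

#' Generate a full synthetic scene database
#'
#' Draws `scenes_per_category` scenes from every profile, assembling the
#' taxonomy from the profiles. Fully reproducible: each scene is generated
#' under a substream seeded from `(seed, profile index, scene index)`.
#'
#' @param config a [generator_config()]; or pass `profiles`/`seed`/
#'   `scenes_per_category` directly to build one.
#' @param ... arguments forwarded to [generator_config()] when `config` is
#'   a list of profiles.
#' @return a [scene_database()].
#' @examples
#' db <- generate_database(generator_config(default_profiles()[1:2],
#'                                          scenes_per_category = 5, seed = 1))
#' db
#' @export
generate_database <- function(config, ...) {
  if (!inherits(config, "generator_config"))
    config <- generator_config(config, ...)
  scenes <- list()
  for (i in seq_along(config$profiles)) {
    prof <- config$profiles[[i]]
    for (j in seq_len(config$scenes_per_category)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(derive_seed(config$seed, i, j))
      sc <- generate_scene(prof, sprintf("%s_%04d", prof$category, j),
                           config$image_size[1], config$image_size[2])
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      scenes[[length(scenes) + 1L]] <- sc
    }
  }
  taxonomy <- stats::setNames(
    vapply(config$profiles, `[[`, character(1), "superordinate"),
    vapply(config$profiles, `[[`, character(1), "category")
  )
  scene_database(scenes, taxonomy)
}

#' The recovery-study database
#'
#' Convenience constructor for the synthetic database used throughout the
#' package's own evaluation: all 16 default profiles at a given number of
#' scenes per category.
#'
#' @param scenes_per_category scenes per category (default 50).
#' @param seed master seed.
#' @return a [scene_database()] of `16 * scenes_per_category` scenes.
#' @export
default_database <- function(scenes_per_category = 50, seed = 1L) {
  generate_database(generator_config(default_profiles(),
                                     scenes_per_category = scenes_per_category,
                                     seed = seed))
}
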