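#' Build a pipeline configuration
#'
#' @param output_dir directory for the report bundle.
#' @param input directory of LabelMe XML annotations; `NULL` to simulate a
#'   synthetic database instead.
#' @param taxonomy_file 2-column CSV (`basic`, `superordinate`); required
#'   with `input`.
#' @param normalization_file optional 3-column cleaning CSV (`raw`,
#'   `action`, `change_class`).
#' @param stages subset of `c("ensemble", "bow", "structure", "classify")`;
#'   ingestion/simulation and cleaning run whenever needed.
#' @param scenes_per_category scenes per category when simulating.
#' @param grid occupancy-map resolution.
#' @param min_instances diagnosticity reporting filter.
#' @param seed master seed, recorded in the manifest.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, input = NULL, taxonomy_file = NULL,
                            normalization_file = NULL,
                            stages = c("ensemble", "bow", "structure", "classify"),
                            scenes_per_category = 20, grid = 64,
                            min_instances = 10, seed = 1L) {
  stages <- match.arg(stages, c("ensemble", "bow", "structure", "classify"),
                      several.ok = TRUE)
  if (!is.null(input) && is.null(taxonomy_file))
    stop("`taxonomy_file` is required when reading annotations")
  for (f in c(input, taxonomy_file, normalization_file)) {
    if (!is.null(f) && !file.exists(f)) stop("missing input: ", f)
  }
  structure(
    list(output_dir = output_dir, input = input,
         taxonomy_file = taxonomy_file,
         normalization_file = normalization_file, stages = stages,
         scenes_per_category = as.integer(scenes_per_category),
         grid = as.integer(grid), min_instances = as.integer(min_instances),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the object-scene context pipeline
#'
#' Orchestrates the full analysis on either an ingested annotation folder
#' or a simulated database: ensemble statistics (per-scene features,
#' per-category summaries, superordinate contrasts), bag-of-words
#' statistics (frequencies, Zipf fit, diagnosticity, specificity, entropy,
#' mutual information, unique combinations), structural statistics
#' (position variance, quadrant features) and leave-one-out linear
#' classification of the ensemble and bag-of-words representations at
#' both category levels. All tables are written as CSV/JSON under the
#' output directory together with a `manifest.json` recording the seed,
#' configuration and package version; identical configurations produce
#' identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of the output file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  emit_csv <- function(d, name) {
    p <- file.path(out, name)
    utils::write.csv(d, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  emit_json <- function(x, name) {
    p <- file.path(out, name)
    write_json_out(x, p)
    paths[[name]] <<- p
  }

  db <- if (is.null(config$input)) {
    default_database(config$scenes_per_category, config$seed)
  } else {
    read_scene_dir(config$input, read_taxonomy(config$taxonomy_file))
  }
  cleaning_changes <- NULL
  if (!is.null(config$normalization_file)) {
    res <- normalize_labels(db, read_normalization_table(config$normalization_file))
    db <- res$database
    cleaning_changes <- res$changes
    emit_csv(cleaning_changes, "cleaning_changes.csv")
  }

  if ("ensemble" %in% config$stages) {
    feats <- ensemble_feature_matrix(db)
    emit_csv(feats, "ensemble_features.csv")
    emit_csv(category_summary(db), "ensemble_category_summary.csv")
    contrasts <- list()
    for (field in c("density", "unique_count", "mean_size", "size_variance",
                    "com_y", "spacing_cv")) {
      for (split in c("indoor-vs-outdoor", "urban-vs-natural")) {
        contrasts[[paste(field, split, sep = ".")]] <-
          superordinate_contrast(db, field, split)
      }
    }
    emit_json(contrasts, "ensemble_contrasts.json")
  }

  if ("bow" %in% config$stages) {
    freq <- object_frequency(db)
    emit_csv(freq$overall, "object_frequency_overall.csv")
    pc <- as.data.frame(as.table(freq$per_category), stringsAsFactors = FALSE)
    names(pc) <- c("object", "category", "frequency")
    emit_csv(pc[pc$frequency > 0, ], "object_frequency_per_category.csv")
    rf <- rank_frequency(db, top_ranks = 50)
    emit_csv(rf$table, "rank_frequency.csv")
    dt <- diagnosticity(db, config$min_instances)
    trip <- as.data.frame(as.table(dt$prob), stringsAsFactors = FALSE)
    names(trip) <- c("object", "category", "diagnosticity")
    trip <- trip[trip$diagnosticity > 0 & dt$reportable[trip$object], ]
    emit_csv(trip, "diagnosticity.csv")
    emit_csv(specificity(db), "specificity.csv")
    mi <- mutual_information(db)
    emit_csv(mi$overall, "mutual_information_overall.csv")
    ent <- database_entropy(db)
    uc <- unique_combinations(db)
    emit_json(list(zipf_slope = rf$slope,
                   entropy = ent,
                   cooccurrence_sparsity = cooccurrence(db)$sparsity,
                   unique_combinations = uc$n_unique,
                   unique_fraction_by_superordinate = as.list(uc$by_superordinate)),
              "bow_summary.json")
  }

  if ("structure" %in% config$stages) {
    emit_csv(position_variance(db), "position_variance.csv")
    qm <- quadrant_matrix(db)
    nz <- which(qm > 0, arr.ind = TRUE)
    emit_csv(data.frame(scene_id = rownames(qm)[nz[, 1]],
                        feature = colnames(qm)[nz[, 2]],
                        count = qm[nz], stringsAsFactors = FALSE),
             "quadrant_features_sparse.csv")
  }

  if ("classify" %in% config$stages) {
    feats <- ensemble_feature_matrix(db)
    fm <- as.matrix(feats[, c("density", "unique_count", "mean_size",
                              "size_variance", "com_x", "com_y", "spacing_cv")])
    cm <- count_matrix(db)
    reports <- list()
    for (level in c("basic", "superordinate")) {
      labels <- if (level == "basic") scene_categories(db)
                else scene_superordinates(db)
      for (rep_name in c("ensemble", "bow")) {
        X <- if (rep_name == "ensemble") fm else cm
        r <- loo_evaluate(X, labels)
        key <- paste(rep_name, level, sep = ".")
        reports[[key]] <- list(accuracy = r$accuracy, auc = r$auc,
                               a_prime = r$a_prime_mean, chance = r$chance,
                               binomial_p = r$binomial_p, n = r$n)
        emit_csv(as.data.frame.matrix(r$confusion),
                 paste0("confusion_", rep_name, "_", level, ".csv"))
      }
    }
    emit_json(reports, "classification_reports.json")
  }

  manifest <- list(
    package = "scenestats",
    version = as.character(utils::packageVersion("scenestats")),
    seed = config$seed,
    stages = config$stages,
    scenes_per_category = config$scenes_per_category,
    grid = config$grid,
    min_instances = config$min_instances,
    input = config$input %||% "synthetic",
    n_scenes = length(db$scenes),
    vocabulary_size = length(db$vocabulary),
    outputs = names(paths)
  )
  emit_json(manifest, "manifest.json")
  invisible(paths)
}
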